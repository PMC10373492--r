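test_that("transformations follow z-score and Pareto definitions", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 2, 2), c = c(1, 4, 9))
  rownames(m) <- paste0("s", 1:3)
  z <- cbind(x = exp(c(1, 2, 3)))
  expect_message(tr <- transform_tables(m, z), "invariant")
  # constant column dropped
  expect_false("b" %in% colnames(tr$X))
  # z-score of log contaminant (1,2,3) is (-1,0,1)
  expect_equal(unname(tr$Z[, "x"]), c(-1, 0, 1))
  # Pareto property: variance of each scaled column equals the sd of the
  # pre-scaled (logged) column
  expect_equal(unname(apply(tr$X, 2, var)),
               unname(apply(log(m[, c("a", "c")]), 2, sd)))
  # zeros replaced by half the column minimum before logging
  m0 <- cbind(a = c(0, 2, 4), b = c(1, 2, 3))
  tr0 <- transform_tables(m0)
  expect_true(all(is.finite(tr0$X)))
})

test_that("pearson matrix matches cor.test and handles degenerate columns", {
  set.seed(13)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  Z <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("u", "v")))
  pm <- pearson_matrix(X, Z)
  for (i in 1:3) for (j in 1:2) {
    ct <- cor.test(X[, i], Z[, j])
    expect_equal(pm$r[i, j], unname(ct$estimate))
    expect_equal(pm$p[i, j], ct$p.value, tolerance = 1e-12)
  }
  self <- pearson_matrix(X)
  expect_equal(diag(self$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(diag(self$p), rep(0, 3), ignore_attr = TRUE)
  expect_equal(pearson_matrix(cbind(X[, 1]), cbind(-X[, 1]))$r[1, 1], -1)
  # zero-variance column -> NA
  expect_true(is.na(pearson_matrix(cbind(rep(1, 20)), cbind(Z[, 1]))$r[1, 1]))
})

test_that("the group correlation contrast is a Welch t-test", {
  # closed-form Welch on a 3+3 toy
  x <- c(0.5, 0.6, 0.7); y <- c(0.1, 0.2, 0.0)
  p <- correlation_sign_test(x, y)
  sx <- var(x) / 3; sy <- var(y) / 3
  tt <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df <- (sx + sy)^2 / (sx^2 / 2 + sy^2 / 2)
  expect_equal(as.numeric(p), 2 * pt(abs(tt), df, lower.tail = FALSE))
  # identical groups -> p = 1
  expect_equal(as.numeric(correlation_sign_test(x, x)), 1)
  expect_error(correlation_sign_test(0.5, y), "at least 2")
  # planted shift: high-mass adducts more PAH-positive
  set.seed(17)
  p2 <- correlation_sign_test(rnorm(30, 0.4, 0.1), rnorm(30, 0, 0.1))
  expect_lt(as.numeric(p2), 0.01)
})

test_that("PERMANOVA matches vegan on a one-factor design", {
  set.seed(23)
  X <- matrix(rnorm(60), 12, 5)
  f <- rep(c("C", "R"), each = 6)
  mine <- permanova(X, data.frame(status = f), n_perm = 199, seed = 1)
  ref <- vegan::adonis2(dist(X) ~ status, data = data.frame(status = f),
                        permutations = 199)
  expect_equal(mine$SS[1], ref$SumOfSqs[1], tolerance = 1e-9)
  expect_equal(mine$pseudo_F[1], ref$F[1], tolerance = 1e-9)
  expect_equal(mine$R2[1], ref$R2[1], tolerance = 1e-9)
  # R2 components sum to 1
  expect_equal(sum(mine$R2[1:2]), 1)
  expect_true(is.finite(mine$dispersion_p[1]))
})

test_that("permutation p equals exhaustive enumeration on a 6-sample toy", {
  set.seed(29)
  X <- matrix(rnorm(12), 6, 2)
  f <- factor(rep(c("A", "B"), each = 3))
  mine <- permanova(X, data.frame(g = f), seed = 1, exact = TRUE)
  # independent brute force: between/within decomposition of raw data over
  # all 720 observation permutations
  fstat <- function(rows) {
    Xi <- X[rows, , drop = FALSE]
    gm <- colMeans(Xi)
    ssw <- 0; ssb <- 0
    for (lv in levels(f)) {
      Xg <- Xi[f == lv, , drop = FALSE]
      mg <- colMeans(Xg)
      ssw <- ssw + sum(sweep(Xg, 2, mg)^2)
      ssb <- ssb + nrow(Xg) * sum((mg - gm)^2)
    }
    (ssb / 1) / (ssw / 4)
  }
  perms <- dnadduct:::.all_permutations(6)
  f_obs <- fstat(1:6)
  f_all <- vapply(perms, fstat, numeric(1))
  p_oracle <- mean(f_all >= f_obs - 1e-12)
  expect_equal(mine$p[1], p_oracle)
  expect_equal(mine$pseudo_F[1], f_obs, tolerance = 1e-9)
})

test_that("PERMANOVA handles the two-factor interaction design and errors", {
  set.seed(31)
  X <- matrix(rnorm(120), 24, 5)
  fac <- data.frame(status = rep(c("C", "R"), each = 12),
                    basin = rep(rep(c("BS", "NBP"), each = 6), 2))
  res <- permanova(X, fac, n_perm = 99, seed = 2)
  expect_equal(res$term[1:3], c("status", "basin", "status:basin"))
  expect_equal(sum(res$R2[1:4]), 1)
  expect_true(all(res$p[1:3] >= 1 / 100 & res$p[1:3] <= 1))
  # strongly separated groups hit the permutation floor
  Xs <- X; Xs[fac$status == "C", ] <- Xs[fac$status == "C", ] + 10
  rs <- permanova(Xs, fac["status"], n_perm = 999, seed = 3)
  expect_equal(rs$p[1], 0.001)
  expect_error(permanova(X[1:3, ], data.frame(g = c("a", "b", "b")),
                         seed = 1), "at least 2")
})

test_that("PERMANOVA is invariant to reordering and to orthogonal rotation", {
  set.seed(37)
  X <- matrix(rnorm(50), 10, 5)
  f <- data.frame(g = rep(c("A", "B"), each = 5))
  r1 <- permanova(X, f, n_perm = 99, seed = 4)
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  r2 <- permanova(X %*% Q, f, n_perm = 99, seed = 4)
  expect_equal(r1$pseudo_F[1], r2$pseudo_F[1], tolerance = 1e-9)
  expect_equal(r1$p[1], r2$p[1])
  perm <- sample(10)
  r3 <- permanova(X[perm, ], data.frame(g = f$g[perm]), n_perm = 99,
                  seed = 4)
  expect_equal(r3$pseudo_F[1], r1$pseudo_F[1], tolerance = 1e-9)
})

test_that("SIMPER decomposes Bray-Curtis and conserves 100%", {
  # hand case: A = {(1,0)}, B = {(0,1)} -> dissimilarity 1, 50% each
  ab <- rbind(c(1, 0), c(0, 1))
  colnames(ab) <- c("x", "y")
  s <- simper(ab, c("A", "B"))
  expect_equal(attr(s, "overall"), 1)
  expect_equal(sort(s$contribution), c(50, 50))
  # contributions sum to 100 on random data and match vegan
  set.seed(41)
  m <- matrix(rlnorm(80), 8, 10,
              dimnames = list(NULL, paste0("v", 1:10)))
  g <- rep(c("A", "B"), each = 4)
  s2 <- simper(m, g)
  expect_equal(sum(s2$contribution), 100)
  expect_true(all(diff(s2$cumulative) >= -1e-12))
  veg <- summary(vegan::simper(m, g))[[1]]
  mine_pct <- s2$contribution[match(rownames(veg), s2$variable)]
  expect_equal(mine_pct, 100 * veg$average / sum(veg$average),
               tolerance = 1e-9)
  # the selected set is the smallest prefix reaching 80%
  ksel <- sum(s2$selected)
  expect_gte(s2$cumulative[ksel], 80)
  expect_true(ksel == 1 || s2$cumulative[ksel - 1] < 80)
  # degenerate cases
  same <- rbind(c(1, 2), c(1, 2))
  expect_warning(s3 <- simper(same, c("A", "B")), "identical")
  expect_false(any(s3$selected))
  expect_error(simper(rbind(c(0, 0), c(1, 1)), c("A", "B")), "all-zero")
  expect_error(simper(rbind(c(-1, 1), c(1, 1)), c("A", "B")),
               "non-negative")
})

test_that("volcano flags planted fold changes symmetrically", {
  R <- c(0.99, 1, 1.01)
  m <- rbind(4 * R[1], 4 * R[2], 4 * R[3], R[1], R[2], R[3])
  m <- cbind(up4 = m[, 1], down4 = rev(m[, 1]), flat = rep(1, 6))
  g <- factor(rep(c("Contaminated", "Reference"), each = 3))
  v <- volcano(m, g)
  expect_equal(v$log2_fc[v$adduct_id == "up4"], 2)
  expect_equal(v$flag[v$adduct_id == "up4"], "up")
  expect_equal(v$log2_fc[v$adduct_id == "down4"], -2)
  expect_equal(v$flag[v$adduct_id == "down4"], "down")
  expect_equal(v$flag[v$adduct_id == "flat"], "ns")
  # identical groups -> all ns
  m2 <- matrix(rep(c(1, 2, 3, 1, 2, 3), 2), 6, 2)
  v2 <- volcano(m2, g)
  expect_true(all(v2$flag == "ns"))
  expect_error(volcano(m[1:3, , drop = FALSE], factor(c("C", "C", "R"))),
               ">= 2")
})
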