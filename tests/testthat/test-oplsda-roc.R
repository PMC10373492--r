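make_class_data <- function(n = 40, p = 20, shift = 2, seed = 51) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- rep(c("C", "R"), each = n / 2)
  X[y == "C", 1] <- X[y == "C", 1] + shift
  list(X = X, y = y)
}

test_that("OPLS-DA recovers a planted separating variable with top VIP", {
  d <- make_class_data(n = 40, p = 51, shift = 4)
  fit <- oplsda(d$X, d$y, n_orth = 1, seed = 1)
  expect_equal(names(which.max(fit$vip)), "v1")
  expect_equal(fit$misclassification, 0)
  expect_gt(fit$R2Y, 0.5)
  expect_gte(fit$R2Y, fit$Q2)
})

test_that("VIP normalisation holds on any fitted model", {
  d <- make_class_data(seed = 52)
  for (k in 0:2) {
    fit <- oplsda(d$X, d$y, n_orth = k, seed = 2)
    expect_equal(mean(fit$vip^2), 1, tolerance = 1e-9)
  }
})

test_that("zero orthogonal components reduce to one-component PLS-DA", {
  d <- make_class_data(seed = 53)
  fit <- oplsda(d$X, d$y, n_orth = 0, seed = 3)
  # independent reference: NIPALS PLS via mixOmics
  ref <- mixOmics::pls(d$X, as.numeric(factor(d$y)) - 1, ncomp = 1,
                       scale = FALSE, mode = "regression")
  r <- cor(fit$scores, ref$variates$X[, 1])
  expect_equal(abs(r), 1, tolerance = 1e-8)
})

test_that("label permutation drives median Q2 at or below zero", {
  d <- make_class_data(n = 24, p = 30, shift = 0, seed = 54)
  set.seed(55)
  q2 <- vapply(1:20, function(b) {
    oplsda(d$X, sample(d$y), n_orth = 1, seed = b)$Q2
  }, numeric(1))
  expect_lte(median(q2), 0)
})

test_that("prediction applies the stored orthogonal correction", {
  d <- make_class_data(seed = 56)
  fit <- oplsda(d$X, d$y, n_orth = 1, seed = 4)
  expect_equal(predict(fit, d$X), fit$scores, tolerance = 1e-9)
  expect_error(oplsda(d$X, rep("C", 40), seed = 1), "2 classes")
  Xz <- cbind(d$X, z = 0)
  expect_error(oplsda(Xz, d$y, seed = 1), "zero-variance")
})

test_that("ROC AUC equals the normalised Mann-Whitney statistic", {
  # hand case: 3 of 4 discordant-free pairs
  r <- roc_analysis(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), n_boot = 200,
                    seed = 1)
  expect_equal(r$auc, 0.75)
  # trivial cases
  expect_equal(roc_analysis(c(0, 0, 1, 1), c(0, 0, 1, 1), n_boot = 50,
                            seed = 1)$auc, 1.0)
  expect_equal(roc_analysis(rep(1, 6), c(0, 1, 0, 1, 0, 1), n_boot = 50,
                            seed = 1)$auc, 0.5)
  # oracle on arbitrary tied inputs: rank-based Mann-Whitney U
  set.seed(57)
  for (rep in 1:5) {
    s <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)
    y <- sample(c(0, 1), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    rk <- rank(s)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    u <- sum(rk[y == 1]) - n1 * (n1 + 1) / 2
    expect_equal(roc_analysis(s, y, n_boot = 10, seed = 1)$auc,
                 u / (n1 * n0))
  }
  # cross-check against pROC
  set.seed(58)
  s <- rnorm(40); y <- rep(c(0, 1), 20)
  expect_equal(roc_analysis(s, y, n_boot = 10, seed = 1)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("ROC confidence interval brackets the point estimate", {
  d <- make_class_data(n = 30, p = 2, shift = 1.5, seed = 59)
  r <- roc_analysis(d$X[, 1], d$y == "C", n_boot = 500, seed = 5)
  expect_lte(r$ci_lo, r$auc)
  expect_gte(r$ci_hi, r$auc)
  expect_true(r$misclassification >= 0 && r$misclassification <= 100)
  # a feature panel is combined by logistic regression
  rp <- roc_analysis(d$X[, 1:2], d$y == "C", n_boot = 100, seed = 6)
  expect_gte(rp$auc, 0.5)
  expect_error(roc_analysis(d$X[, 1], rep(1, 30), n_boot = 10, seed = 1),
               "2 classes")
})
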