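# Column-wise half-minimum substitution for zeros (log-readiness).
.half_min_fill <- function(m) {
  apply(m, 2, function(x) {
    if (any(x <= 0)) {
      pos <- x[x > 0]
      x[x <= 0] <- if (length(pos)) min(pos) / 2 else NA_real_
    }
    x
  })
}

#' Transform adduct and contaminant matrices for statistics
#'
#' Adducts: log of the dG-normalised areas (zeros replaced by half the
#' column minimum), then Pareto scaling (centre, divide by the square root
#' of the column standard deviation). Contaminants: log then column
#' z-scores. Columns invariant after transformation are dropped with a
#' message.
#'
#' @param norm_area samples x adducts matrix of dG-normalised areas (or an
#'   [adduct_table()], whose `norm_area` is used).
#' @param contaminants optional samples x contaminants matrix of
#'   concentrations.
#' @param drop_invariant drop zero-variance columns (default TRUE).
#' @return list with `X` (Pareto-scaled log adducts) and `Z` (z-scored log
#'   contaminants, NULL if none given).
#' @export
transform_tables <- function(norm_area, contaminants = NULL,
                             drop_invariant = TRUE) {
  if (inherits(norm_area, "adduct_table")) norm_area <- norm_area$norm_area
  A <- log(.half_min_fill(as.matrix(norm_area)))
  drop_cols <- function(m, what) {
    sds <- apply(m, 2, stats::sd)
    bad <- !is.finite(sds) | sds == 0
    if (drop_invariant && any(bad)) {
      message("dropping ", sum(bad), " invariant ", what, " column(s): ",
              paste(colnames(m)[bad], collapse = ", "))
      m <- m[, !bad, drop = FALSE]
    }
    m
  }
  A <- drop_cols(A, "adduct")
  X <- apply(A, 2, function(x) (x - mean(x)) / sqrt(stats::sd(x)))
  rownames(X) <- rownames(A)
  Z <- NULL
  if (!is.null(contaminants)) {
    Cm <- log(.half_min_fill(as.matrix(contaminants)))
    Cm <- drop_cols(Cm, "contaminant")
    Z <- scale(Cm)
    attr(Z, "scaled:center") <- NULL
    attr(Z, "scaled:scale") <- NULL
  }
  list(X = X, Z = Z)
}

#' Pearson correlation matrix with two-tailed p-values
#'
#' Correlates the columns of `X` against the columns of `Z` (or against
#' each other when `Z` is NULL). p-values come from the t transform
#' `t = r sqrt((n-2)/(1-r^2))`. Zero-variance columns yield NA.
#'
#' @param X,Z numeric matrices with matching rows.
#' @return list with matrices `r`, `p`, and `n` (complete pairs).
#' @export
pearson_matrix <- function(X, Z = NULL) {
  X <- as.matrix(X)
  Y <- if (is.null(Z)) X else as.matrix(Z)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 3)
  r <- suppressWarnings(stats::cor(X, Y))
  n <- nrow(X)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-12] <- 0
  list(r = r, p = p, n = n)
}

#' Compare PAH-correlation tendencies of two adduct groups
#'
#' Welch two-sample t-test on per-adduct mean contaminant correlations,
#' e.g. high-mass vs low-mass adducts' mean Pearson r with the PAH
#' congeners.
#'
#' @param r_high,r_low numeric vectors of per-adduct mean correlations.
#' @return two-tailed p-value, with the `htest` in attribute `"test"`.
#' @export
correlation_sign_test <- function(r_high, r_low) {
  if (length(r_high) < 2 || length(r_low) < 2)
    stop("both groups need at least 2 adducts")
  tt <- stats::t.test(r_high, r_low, var.equal = FALSE)
  structure(tt$p.value, test = tt)
}

# Gower-centred inner-product matrix of a distance matrix.
.gower <- function(d) {
  A <- -0.5 * as.matrix(d)^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

# Hat matrix of a column set (Moore-Penrose via QR).
.hat <- function(M) {
  q <- qr(M)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Permutational multivariate analysis of variance (Type III)
#'
#' PERMANOVA on a Euclidean (default) distance matrix with marginal
#' (Type III) sums of squares under sum-to-zero contrasts, pseudo-F per
#' term, and p-values from free permutation of observations:
#' `p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)`. With two factors the
#' interaction is included. PERMDISP (distance-to-centroid homogeneity,
#' via vegan's `betadisper`/`permutest`) is run alongside for each factor.
#'
#' @param X samples x variables matrix (distances computed on rows), or a
#'   `dist` object.
#' @param factors data.frame of 1 or 2 factors (rows match samples).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations (required).
#' @param exact enumerate all `n!` permutations instead (only for small n);
#'   p is then the exact proportion of permutations with `F >= F_obs`.
#' @param method distance for `stats::dist` (default `"euclidean"`).
#' @param permdisp also run PERMDISP per factor (disable in bulk
#'   simulations where only the PERMANOVA p is needed).
#' @return object of class `permanova` — data.frame with one row per term
#'   plus Residual/Total: `df`, `SS`, `R2`, `pseudo_F`, `p`,
#'   `dispersion_p`.
#' @export
permanova <- function(X, factors, n_perm = 999, seed, exact = FALSE,
                      method = "euclidean", permdisp = TRUE) {
  if (missing(seed)) stop("a permutation seed is required")
  factors <- as.data.frame(factors)
  factors[] <- lapply(factors, factor)
  n <- nrow(factors)
  d <- if (inherits(X, "dist")) X else stats::dist(as.matrix(X),
                                                   method = method)
  stopifnot(attr(d, "Size") == n)
  if (any(table(interaction(factors, drop = TRUE)) < 2))
    stop("every factor-level cell needs at least 2 samples")
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  fml <- if (ncol(factors) >= 2)
    stats::as.formula(paste("~", paste(names(factors), collapse = "*")))
  else stats::as.formula(paste("~", names(factors)[1]))
  M <- stats::model.matrix(fml, data = factors)
  asgn <- attr(M, "assign")
  terms_lab <- attr(stats::terms(fml, data = factors), "term.labels")
  G <- .gower(d)
  H_full <- .hat(M)
  df_res <- n - qr(M)$rank
  ss_stats <- function(Gm) {
    ss_tot <- sum(diag(Gm))
    ss_res <- ss_tot - sum(H_full * Gm)  # tr(H G), H symmetric idempotent
    ss_terms <- vapply(seq_along(terms_lab), function(k) {
      Mk <- M[, asgn != k, drop = FALSE]
      sum(H_full * Gm) - sum(.hat(Mk) * Gm)
    }, numeric(1))
    list(tot = ss_tot, res = ss_res, terms = ss_terms)
  }
  # hat matrices are permutation-fixed; only G is permuted
  Hk <- lapply(seq_along(terms_lab), function(k)
    .hat(M[, asgn != k, drop = FALSE]))
  df_terms <- vapply(seq_along(terms_lab), function(k) sum(asgn == k),
                     numeric(1))
  f_of <- function(Gm) {
    trHG <- sum(H_full * Gm)
    ss_res <- sum(diag(Gm)) - trHG
    ss_t <- vapply(seq_along(terms_lab), function(k)
      trHG - sum(Hk[[k]] * Gm), numeric(1))
    (ss_t / df_terms) / (ss_res / df_res)
  }
  obs <- ss_stats(G)
  F_obs <- (obs$terms / df_terms) / (obs$res / df_res)
  if (exact) {
    perms <- .all_permutations(n)
    F_perm <- vapply(perms, function(p) f_of(G[p, p]),
                     numeric(length(terms_lab)))
    F_perm <- matrix(F_perm, nrow = length(terms_lab))
    pval <- rowMeans(F_perm >= F_obs - 1e-12)
    n_perm <- ncol(F_perm)
  } else {
    set.seed(seed)
    count <- numeric(length(terms_lab))
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      count <- count + (f_of(G[p, p]) >= F_obs - 1e-12)
    }
    pval <- (count + 1) / (n_perm + 1)
  }
  disp_p <- if (permdisp) vapply(names(factors), function(f) {
    bd <- vegan::betadisper(d, factors[[f]])
    pt <- vegan::permutest(bd, permutations = n_perm)
    pt$tab[1, "Pr(>F)"]
  }, numeric(1)) else stats::setNames(rep(NA_real_, ncol(factors)),
                                      names(factors))
  out <- data.frame(
    term = c(terms_lab, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1),
    SS = c(obs$terms, obs$res, obs$tot),
    R2 = c(obs$terms, obs$res, obs$tot) / obs$tot,
    pseudo_F = c(F_obs, NA, NA),
    p = c(pval, NA, NA),
    dispersion_p = c(disp_p[match(terms_lab, names(factors))], NA, NA))
  structure(out, class = c("permanova", "data.frame"),
            n_perm = n_perm, seed = if (exact) NA else seed, exact = exact)
}

.all_permutations <- function(n) {
  if (n > 8) stop("exact enumeration limited to n <= 8")
  if (n == 1) return(list(1L))
  sub <- .all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (i in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = i - 1L)
  }
  out
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (Type III, sum-to-zero contrasts), ",
      attr(x, "n_perm"), " permutations\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' SIMPER: similarity-percentage decomposition
#'
#' Attributes the average between-group Bray-Curtis dissimilarity to
#' individual variables: for each between-group sample pair the per-variable
#' contribution is `|x_i - x_j| / sum_k (x_ik + x_jk)`; contributions are
#' averaged over all pairs and expressed as percentages (they sum to 100).
#' Variables are sorted by decreasing contribution and the smallest prefix
#' reaching `cutoff` percent cumulative contribution is marked selected.
#' Runs on non-negative abundances (dG-normalised areas, not Pareto-scaled
#' values).
#'
#' @param abund samples x variables non-negative matrix.
#' @param groups two-level grouping factor.
#' @param cutoff cumulative-contribution cutoff, percent (default 80).
#' @return object of class `simper_result` — data.frame `variable`,
#'   `contribution`, `cumulative`, `selected`, with the overall average
#'   Bray-Curtis dissimilarity in attribute `"overall"`.
#' @export
simper <- function(abund, groups, cutoff = 80) {
  abund <- as.matrix(abund)
  if (any(abund < 0)) stop("SIMPER requires non-negative abundances")
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2, nrow(abund) == length(groups))
  zero <- rowSums(abund) == 0
  if (any(zero)) {
    lab <- if (!is.null(rownames(abund))) rownames(abund)[zero]
           else which(zero)
    stop("all-zero sample(s): ", paste(lab, collapse = ", "))
  }
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  contrib <- numeric(ncol(abund))
  total <- 0
  for (i in ia) for (j in ib) {
    denom <- sum(abund[i, ] + abund[j, ])
    c_ij <- abs(abund[i, ] - abund[j, ]) / denom
    contrib <- contrib + c_ij
    total <- total + sum(c_ij)
  }
  npair <- length(ia) * length(ib)
  overall <- total / npair
  if (overall == 0) {
    warning("groups are identical: zero Bray-Curtis dissimilarity")
    pct <- rep(0, ncol(abund))
  } else pct <- 100 * contrib / total
  ids <- colnames(abund)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(abund)))
  ord <- order(-pct)
  cum <- cumsum(pct[ord])
  sel <- if (overall == 0) rep(FALSE, length(ord))
         else seq_along(ord) <= which(cum >= cutoff)[1]
  out <- data.frame(variable = ids[ord], contribution = pct[ord],
                    cumulative = cum, selected = sel)
  rownames(out) <- NULL
  structure(out, class = c("simper_result", "data.frame"), overall = overall)
}

#' Volcano-style group contrast
#'
#' Per adduct: `log2(mean Contaminated / mean Reference)` on the
#' dG-normalised areas and a two-tailed Welch t-test on the log-transformed
#' values. Flags `up` when `log2 FC >= fc_threshold` and `p <= p_threshold`,
#' `down` for the mirror condition, `ns` otherwise. Zero group means are
#' replaced by half the smallest positive value of the adduct (flagged in
#' `substituted`).
#'
#' @param norm_area samples x adducts matrix of dG-normalised areas.
#' @param groups two-level factor; the first level is the numerator
#'   ("Contaminated") of the fold change.
#' @param fc_threshold absolute log2 fold-change threshold (default 2).
#' @param p_threshold p-value threshold (default 0.1).
#' @return data.frame `adduct_id`, `log2_fc`, `p`, `q` (Benjamini-Hochberg,
#'   reported but not used for flagging), `flag`, `substituted`.
#' @export
volcano <- function(norm_area, groups, fc_threshold = 2, p_threshold = 0.1) {
  m <- as.matrix(norm_area)
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2)
  if (any(table(groups) < 2)) stop("both groups need >= 2 samples")
  ic <- groups == levels(groups)[1]
  logm <- log(.half_min_fill(m))
  res <- vapply(seq_len(ncol(m)), function(j) {
    mc <- mean(m[ic, j]); mr <- mean(m[!ic, j])
    subst <- FALSE
    if (mc <= 0 || mr <= 0) {
      pos <- m[, j][m[, j] > 0]
      rep0 <- if (length(pos)) min(pos) / 2 else NA_real_
      if (mc <= 0) mc <- rep0
      if (mr <= 0) mr <- rep0
      subst <- TRUE
    }
    p <- tryCatch(stats::t.test(logm[ic, j], logm[!ic, j],
                                var.equal = FALSE)$p.value,
                  error = function(e) NA_real_)
    c(log2(mc / mr), p, subst)
  }, numeric(3))
  ids <- colnames(m)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(m)))
  fc <- res[1, ]; p <- res[2, ]
  flag <- rep("ns", ncol(m))
  eps <- 1e-9  # boundary fold changes count as reaching the threshold
  flag[fc >= fc_threshold - eps & !is.na(p) & p <= p_threshold] <- "up"
  flag[fc <= -fc_threshold + eps & !is.na(p) & p <= p_threshold] <- "down"
  data.frame(adduct_id = ids, log2_fc = fc, p = p,
             q = stats::p.adjust(p, "BH"), flag = flag,
             substituted = as.logical(res[3, ]))
}
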