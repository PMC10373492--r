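# One OSC-PLS fit on centred X, centred y: removes n_orth orthogonal
# components, then one predictive PLS component.
.opls_core <- function(Xc, yc, n_orth) {
  W_o <- NULL; P_o <- NULL; T_o <- NULL
  w <- drop(crossprod(Xc, yc)); w <- w / sqrt(sum(w^2))
  if (n_orth > 0) for (k in seq_len(n_orth)) {
    t1 <- drop(Xc %*% w)
    p <- drop(crossprod(Xc, t1)) / sum(t1^2)
    w_o <- p - drop(crossprod(w, p)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break
    w_o <- w_o / nw
    t_o <- drop(Xc %*% w_o)
    p_o <- drop(crossprod(Xc, t_o)) / sum(t_o^2)
    Xc <- Xc - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
    w <- drop(crossprod(Xc, yc)); w <- w / sqrt(sum(w^2))
  }
  t1 <- drop(Xc %*% w)
  p1 <- drop(crossprod(Xc, t1)) / sum(t1^2)
  q1 <- sum(yc * t1) / sum(t1^2)
  list(w = w, p = p1, q = q1, t = t1, W_o = W_o, P_o = P_o, T_o = T_o)
}

# Apply a fitted core to new (already centred) data -> predictive scores.
.opls_scores <- function(fit, Xc) {
  if (!is.null(fit$W_o)) for (k in seq_len(ncol(fit$W_o))) {
    t_o <- drop(Xc %*% fit$W_o[, k])
    Xc <- Xc - tcrossprod(t_o, fit$P_o[, k])
  }
  drop(Xc %*% fit$w)
}

# Deterministic stratified fold assignment.
.stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (lv in unique(y)) {
    idx <- which(y == lv)
    idx <- idx[sample.int(length(idx))]
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Orthogonal PLS discriminant analysis (OPLS-DA)
#'
#' Orthogonal-signal-corrected PLS with one predictive and `n_orth`
#' orthogonal components; binary response coded 0/1 and centred. Reports
#' R2Y on the full fit, Q2 from stratified k-fold cross-validation
#' (`1 - PRESS/TSS`), and per-variable VIP on the predictive component
#' (`VIP_j = sqrt(K) * |w_j|`, so `mean(VIP^2) = 1`). With
#' `n_orth = "auto"` the orthogonal-component count is chosen by Q2
#' maximisation over 0--3.
#'
#' @param X samples x variables matrix, no zero-variance columns.
#' @param y binary class labels (factor, character or 0/1).
#' @param n_orth number of orthogonal components (default 1) or `"auto"`.
#' @param folds cross-validation folds (default 10, capped at the size of
#'   the smaller class).
#' @param seed RNG seed for fold assignment (required).
#' @return object of class `oplsda`: `scores` (predictive), `loadings`,
#'   `weights`, `ortho_scores`, `ortho_loadings`, `R2Y`, `Q2`, `vip`,
#'   `n_orth`, `misclassification` (training, percent), `levels`,
#'   `fitted_class`.
#' @export
oplsda <- function(X, y, n_orth = 1, folds = 10, seed) {
  if (missing(seed)) stop("a cross-validation seed is required")
  X <- as.matrix(X)
  yf <- factor(y)
  if (nlevels(yf) != 2) stop("y must have exactly 2 classes")
  if (any(apply(X, 2, stats::sd) == 0)) stop("zero-variance columns in X")
  y01 <- as.numeric(yf) - 1
  if (identical(n_orth, "auto")) {
    q2s <- vapply(0:3, function(k)
      oplsda(X, y, n_orth = k, folds = folds, seed = seed)$Q2, numeric(1))
    n_orth <- (0:3)[which.max(q2s)]
  }
  mx <- colMeans(X); my <- mean(y01)
  Xc <- sweep(X, 2, mx)
  yc <- y01 - my
  fit <- .opls_core(Xc, yc, n_orth)
  yhat <- fit$t * fit$q
  R2Y <- 1 - sum((yc - yhat)^2) / sum(yc^2)
  folds_eff <- max(2L, min(folds, min(table(yf))))
  set.seed(seed)
  fid <- .stratified_folds(y01, folds_eff)
  press <- 0
  for (k in seq_len(folds_eff)) {
    tr <- fid != k
    mx_k <- colMeans(X[tr, , drop = FALSE]); my_k <- mean(y01[tr])
    sdk <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    if (any(sdk == 0)) next
    fk <- .opls_core(sweep(X[tr, , drop = FALSE], 2, mx_k), y01[tr] - my_k,
                     n_orth)
    sc <- .opls_scores(fk, sweep(X[!tr, , drop = FALSE], 2, mx_k))
    press <- press + sum((y01[!tr] - (sc * fk$q + my_k))^2)
  }
  Q2 <- 1 - press / sum((y01 - my)^2)
  K <- ncol(X)
  vip <- sqrt(K) * abs(fit$w)
  names(vip) <- colnames(X)
  fitted_class <- levels(yf)[(yhat + my >= 0.5) + 1]
  structure(list(
    scores = fit$t, loadings = fit$p, weights = fit$w, q = fit$q,
    ortho_scores = fit$T_o, ortho_loadings = fit$P_o, ortho_weights = fit$W_o,
    R2Y = R2Y, Q2 = Q2, vip = vip, n_orth = n_orth,
    misclassification = 100 * mean(fitted_class != as.character(yf)),
    levels = levels(yf), y = yf, fitted_class = fitted_class,
    center = mx, y_center = my), class = "oplsda")
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA: 1 predictive + %d orthogonal component(s)\nR2Y = %.3f, Q2 = %.3f, training misclassification = %.1f%%\n",
    x$n_orth, x$R2Y, x$Q2, x$misclassification))
  invisible(x)
}

#' Predictive scores for new samples
#'
#' Applies the stored orthogonal-signal removal and predictive weights to
#' new data; returns the predictive component score per sample.
#' @param object an [oplsda()] fit.
#' @param newdata samples x variables matrix with the training columns.
#' @param ... unused.
#' @export
predict.oplsda <- function(object, newdata, ...) {
  Xc <- sweep(as.matrix(newdata), 2, object$center)
  .opls_scores(list(W_o = object$ortho_weights, P_o = object$ortho_loadings,
                    w = object$weights), Xc)
}
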