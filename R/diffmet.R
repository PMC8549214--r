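# PLS / OPLS discriminant analysis for two-class metabolomics, with
# cross-validated Q2 and VIP scoring, plus the univariate Mann-Whitney/BH
# track and the combined differential-metabolite call.

# center and unit-variance (or Pareto) scale a matrix; zero-variance
# columns are dropped with a warning
.scale_matrix <- function(X, scale = c("uv", "pareto", "none"),
                          center = NULL, scalev = NULL) {
  scale <- match.arg(scale)
  if (is.null(center)) center <- colMeans(X)
  s <- if (is.null(scalev)) {
    sdv <- apply(X, 2L, sd)
    switch(scale, uv = sdv, pareto = sqrt(sdv), none = rep(1, ncol(X)))
  } else scalev
  Xs <- sweep(X, 2L, center, "-")
  Xs <- sweep(Xs, 2L, ifelse(s == 0, 1, s), "/")
  list(X = Xs, center = center, scale = s)
}

.check_binary_y <- function(y) {
  u <- unique(y)
  if (length(u) != 2) stop("y must have exactly two classes")
  as.numeric(y == u[order(as.character(u))][2L])
}

#' Fit a PLS-DA model (NIPALS, single response)
#'
#' Partial least squares discriminant analysis for a binary class vector,
#' fitted by the NIPALS algorithm on the centered/scaled feature matrix and
#' the centered 0/1 class response. Successive score vectors are mutually
#' orthogonal.
#'
#' @param X numeric matrix, samples x features.
#' @param y binary class vector (factor, character or 0/1), one per row.
#' @param n_comp number of components (default 2).
#' @param scale feature scaling: `"uv"` (unit variance, the metabolomics
#'   default), `"pareto"` or `"none"`.
#' @return List of class `plsda_model` with per-component weights `W`,
#'   scores `T`, X-loadings `P`, y-loadings `q`, plus centering/scaling
#'   vectors and `features` (zero-variance features are dropped with a
#'   warning).
#' @export
fit_plsda <- function(X, y, n_comp = 2L, scale = c("uv", "pareto", "none")) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows must match y")
  yb <- .check_binary_y(y)
  sdv <- apply(X, 2L, sd)
  if (any(sdv == 0)) {
    warning(sprintf("dropping %d zero-variance feature(s)", sum(sdv == 0)))
    X <- X[, sdv > 0, drop = FALSE]
  }
  sc <- .scale_matrix(X, scale)
  Xw <- sc$X
  yc <- yb - mean(yb)
  J <- ncol(Xw)
  W <- P <- matrix(0, J, n_comp, dimnames = list(colnames(Xw), NULL))
  Tm <- matrix(0, nrow(Xw), n_comp)
  qv <- numeric(n_comp)
  yr <- yc
  for (a in seq_len(n_comp)) {
    w <- drop(crossprod(Xw, yr))
    w <- w / sqrt(sum(w^2))
    t <- drop(Xw %*% w)
    p <- drop(crossprod(Xw, t)) / sum(t^2)
    q <- sum(yr * t) / sum(t^2)
    Xw <- Xw - tcrossprod(t, p)
    yr <- yr - t * q
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t; qv[a] <- q
  }
  structure(
    list(W = W, T = Tm, P = P, q = qv, center = sc$center,
         scale_vec = sc$scale, scaling = scale, y = yc,
         features = colnames(X)),
    class = "plsda_model"
  )
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis in the
#' Trygg-Wold formulation: class-orthogonal structured variation is
#' stripped from the (centered/scaled) feature matrix in `n_ortho` rounds,
#' after which a single predictive component is extracted. With
#' `n_ortho = 0` the model reduces exactly to one-component PLS-DA.
#'
#' Each orthogonal round computes `w` proportional to `X'y`, the loading
#' `p = X't/(t't)` of the corresponding score, removes the predictive part
#' `w_o = p - (w'p) w` (normalized), forms `t_o = X w_o`, and deflates
#' `X <- X - t_o p_o'`.
#'
#' @inheritParams fit_plsda
#' @param n_ortho number of orthogonal components (default 1).
#' @return List of class `opls_model` with the predictive weights `w`,
#'   scores `t`, loadings `p`, y-loading `q`, orthogonal blocks
#'   `W_ortho`/`T_ortho`/`P_ortho`, explained class variance `R2Y`, the
#'   centering/scaling vectors, and the VIP scores of the predictive
#'   component.
#' @export
fit_oplsda <- function(X, y, n_ortho = 1L,
                       scale = c("uv", "pareto", "none")) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows must match y")
  if (n_ortho < 0) stop("n_ortho must be >= 0")
  yb <- .check_binary_y(y)
  sdv <- apply(X, 2L, sd)
  if (any(sdv == 0)) {
    warning(sprintf("dropping %d zero-variance feature(s)", sum(sdv == 0)))
    X <- X[, sdv > 0, drop = FALSE]
  }
  sc <- .scale_matrix(X, scale)
  Xw <- sc$X
  yc <- yb - mean(yb)
  J <- ncol(Xw)
  Wo <- Po <- matrix(0, J, max(n_ortho, 1L),
                     dimnames = list(colnames(Xw), NULL))
  To <- matrix(0, nrow(Xw), max(n_ortho, 1L))
  for (a in seq_len(n_ortho)) {
    w <- drop(crossprod(Xw, yc)); w <- w / sqrt(sum(w^2))
    t <- drop(Xw %*% w)
    p <- drop(crossprod(Xw, t)) / sum(t^2)
    w_o <- p - sum(w * p) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) break  # no orthogonal structure left
    w_o <- w_o / nrm
    t_o <- drop(Xw %*% w_o)
    p_o <- drop(crossprod(Xw, t_o)) / sum(t_o^2)
    Xw <- Xw - tcrossprod(t_o, p_o)
    Wo[, a] <- w_o; Po[, a] <- p_o; To[, a] <- t_o
  }
  if (n_ortho == 0) { Wo <- Wo[, 0, drop = FALSE]
                      Po <- Po[, 0, drop = FALSE]
                      To <- To[, 0, drop = FALSE] }
  w <- drop(crossprod(Xw, yc)); w <- w / sqrt(sum(w^2))
  t <- drop(Xw %*% w)
  p <- drop(crossprod(Xw, t)) / sum(t^2)
  q <- sum(yc * t) / sum(t^2)
  r2y <- 1 - sum((yc - t * q)^2) / sum(yc^2)
  model <- structure(
    list(w = setNames(w, colnames(Xw)), t = t, p = p, q = q,
         W_ortho = Wo, T_ortho = To, P_ortho = Po, n_ortho = n_ortho,
         R2Y = r2y, center = sc$center, scale_vec = sc$scale,
         scaling = scale, y = yc, features = colnames(X)),
    class = "opls_model"
  )
  model$vip <- vip(model)
  model
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("<opls_model> %d features, %d orthogonal component(s), R2Y = %.3f\n",
              length(x$w), x$n_ortho, x$R2Y))
  invisible(x)
}

# project new samples through a fitted OPLS model: scale with training
# vectors, strip orthogonal components, return predictive scores
.opls_predict <- function(model, Xnew) {
  Xs <- .scale_matrix(Xnew[, names(model$w), drop = FALSE],
                      model$scaling, model$center, model$scale_vec)$X
  if (ncol(model$W_ortho) > 0) {
    for (a in seq_len(ncol(model$W_ortho))) {
      t_o <- drop(Xs %*% model$W_ortho[, a])
      Xs <- Xs - tcrossprod(t_o, model$P_ortho[, a])
    }
  }
  drop(Xs %*% model$w)
}

#' Variable importance in projection (VIP)
#'
#' VIP over the predictive component(s) of a PLS-family model:
#' `VIP_j = sqrt(J * sum_a SSY_a (w_aj/||w_a||)^2 / sum_a SSY_a)`, where
#' `SSY_a` is the class variance explained by component `a` and `J` the
#' number of features. The scores are normalized so that their mean square
#' is exactly 1; features with VIP > 1 are conventionally treated as
#' influential.
#'
#' @param model an `opls_model` (single predictive component) or
#'   `plsda_model` (all components enter the sum).
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  if (inherits(model, "opls_model")) {
    W <- matrix(model$w, ncol = 1L,
                dimnames = list(names(model$w), NULL))
    ssy <- sum(model$t^2) * model$q^2
  } else if (inherits(model, "plsda_model")) {
    W <- model$W
    ssy <- colSums(model$T^2) * model$q^2
  } else stop("model must be a fitted opls_model or plsda_model")
  J <- nrow(W)
  wn <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
  v <- sqrt(J * drop(wn^2 %*% ssy) / sum(ssy))
  setNames(v, rownames(W))
}

#' Cross-validated predictive ability Q2 of an OPLS-DA model
#'
#' Stratified k-fold cross-validation of the full fitting procedure
#' (centering, scaling, orthogonal deflation and the predictive component
#' are all re-estimated inside each training fold). Q2 = 1 - PRESS/SS with
#' SS the total sum of squares of the centered class vector. Fold
#' assignment is seeded and stratified by class, so a fixed seed gives an
#' identical Q2.
#'
#' @inheritParams fit_oplsda
#' @param folds number of folds (default 10); reduced with a warning when a
#'   class has fewer members than folds.
#' @param seed integer seed for the fold assignment.
#' @return List with `Q2`, `folds` used, and the per-sample out-of-fold
#'   predictions `y_hat`.
#' @export
cross_validate_q2 <- function(X, y, n_ortho = 1L, folds = 10L, seed = 1L,
                              scale = c("uv", "pareto", "none")) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  if (nrow(X) < 4) stop("at least 4 samples are required")
  yb <- .check_binary_y(y)
  min_class <- min(table(yb))
  if (min_class < folds) {
    folds <- max(2L, min_class)
    warning(sprintf("reducing folds to %d (smallest class size)", folds))
  }
  fold_id <- integer(length(yb))
  rng <- .seeded_rng(seed)
  for (cl in unique(yb)) {
    idx <- which(yb == cl)
    idx <- idx[order(idx)]  # ties in class counts resolved by sample order
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  .restore_rng(rng)
  y_hat <- numeric(length(yb))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    m <- suppressWarnings(
      fit_oplsda(X[!test, , drop = FALSE], yb[!test], n_ortho, scale))
    t_new <- .opls_predict(m, X[test, , drop = FALSE])
    # back to the raw 0/1 scale using the training class mean
    y_hat[test] <- t_new * m$q + mean(yb[!test])
  }
  press <- sum((yb - y_hat)^2)
  ss <- sum((yb - mean(yb))^2)
  list(Q2 = 1 - press / ss, folds = folds, y_hat = y_hat)
}

# run code under a temporary seed, restoring the caller's RNG state; the
# generator kind is pinned so results do not depend on ambient RNGkind
.seeded_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  suppressWarnings(set.seed(seed, kind = "Mersenne-Twister",
                            normal.kind = "Inversion",
                            sample.kind = "Rejection"))
  old
}
.restore_rng <- function(old) {
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Mann-Whitney tests with Benjamini-Hochberg correction
#'
#' Two-sided Mann-Whitney-Wilcoxon test per feature between two groups
#' (exact for small tie-free samples, normal approximation with tie and
#' continuity correction otherwise), with BH-adjusted q-values across
#' features.
#'
#' @param X numeric matrix, samples x features.
#' @param groups two-level vector aligned with rows of `X`.
#' @return data.frame with columns `id`, `p`, `q`.
#' @export
univariate_mwu_fdr <- function(X, groups) {
  X <- as.matrix(X)
  u <- sort(unique(as.character(groups)))
  if (length(u) != 2) stop("exactly two groups are required")
  ia <- groups == u[1L]; ib <- groups == u[2L]
  if (sum(ia) < 2 || sum(ib) < 2) stop("each group needs >= 2 samples")
  exact <- max(sum(ia), sum(ib)) <= 20
  p <- vapply(seq_len(ncol(X)), function(j) {
    suppressWarnings(
      wilcox.test(X[ia, j], X[ib, j], exact = exact)$p.value)
  }, numeric(1L))
  data.frame(id = colnames(X), p = p, q = p.adjust(p, "BH"),
             stringsAsFactors = FALSE)
}

#' Call differential metabolites
#'
#' Combines multivariate VIP scores with the univariate track: a metabolite
#' is significant in `"untargeted"` mode when `VIP > 1` and the BH q-value
#' is `< 0.05` (FDR-validated), and in `"targeted"` mode when `VIP > 1`
#' and the raw Mann-Whitney p-value is `< 0.05`. All inequalities are
#' strict. Per-category proportions are summarized over the significant
#' metabolites.
#'
#' @param vip_scores named numeric vector of VIP scores.
#' @param univariate data.frame from [univariate_mwu_fdr()].
#' @param mode `"untargeted"` or `"targeted"`.
#' @param categories optional named character vector mapping metabolite id
#'   to chemical category.
#' @param vip_thresh,p_thresh thresholds (defaults 1 and 0.05).
#' @return List with `results` (data.frame: id, category, VIP, p, q,
#'   significant) and `category_proportions` (over significant DMs).
#' @export
call_dms <- function(vip_scores, univariate,
                     mode = c("untargeted", "targeted"),
                     categories = NULL, vip_thresh = 1, p_thresh = 0.05) {
  mode <- match.arg(mode)
  if (!setequal(names(vip_scores), univariate$id))
    stop("VIP and univariate results must cover the same metabolites")
  univariate <- univariate[match(names(vip_scores), univariate$id), ]
  crit <- if (mode == "untargeted") univariate$q else univariate$p
  sig <- vip_scores > vip_thresh & crit < p_thresh
  cat_col <- if (is.null(categories)) NA_character_
             else unname(categories[names(vip_scores)])
  res <- data.frame(
    id = names(vip_scores),
    category = cat_col,
    VIP = unname(vip_scores),
    p = univariate$p,
    q = univariate$q,
    significant = sig,
    stringsAsFactors = FALSE
  )
  prop <- if (!is.null(categories) && any(sig)) {
    tt <- table(res$category[res$significant])
    setNames(as.numeric(tt) / sum(tt), names(tt))
  } else NULL
  list(results = res, category_proportions = prop)
}
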