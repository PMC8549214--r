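# Biomarker panels: binary logistic regression on standardized markers and
# ROC/AUC evaluation, including cross-cohort application with frozen
# training standardization.

# IRLS for binomial logistic regression with an optional ridge penalty on
# the non-intercept coefficients
.logistic_irls <- function(X, y, ridge = 0, tol = 1e-8, max_iter = 100L) {
  Xd <- cbind(`(Intercept)` = 1, X)
  beta <- rep(0, ncol(Xd))
  pen <- c(0, rep(ridge, ncol(X)))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtWX <- crossprod(Xd * w, Xd) + diag(pen, ncol(Xd))
    beta_new <- tryCatch(
      drop(solve(XtWX, crossprod(Xd * w, z))),
      error = function(e) NULL)
    if (is.null(beta_new)) return(NULL)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  list(beta = beta, converged = converged, iterations = it,
       fitted = plogis(drop(Xd %*% beta)))
}

#' Fit a logistic biomarker panel
#'
#' Maximum-likelihood binary logistic regression (iteratively reweighted
#' least squares) of the class label on the standardized marker values.
#' Markers with zero variance carry no information; their coefficient is
#' fixed at 0 and they are flagged as dropped. If the fit shows complete
#' separation (diverging coefficients / boundary fitted probabilities),
#' the model is refit with a small ridge penalty (1e-6) and flagged.
#'
#' @param X numeric matrix, samples x features, containing the markers.
#' @param y binary class vector aligned with rows of `X`.
#' @param markers character vector of marker column names.
#' @return Object of class `panel_model`: coefficients, intercept,
#'   per-marker standardization (`center`, `scale`), `separation` flag,
#'   `dropped` markers, convergence info, and the training ROC
#'   (`roc_result`).
#' @export
fit_panel <- function(X, y, markers) {
  X <- as.matrix(X)
  if (!all(markers %in% colnames(X)))
    stop("all panel markers must be columns of X")
  yb <- .check_binary_y(y)
  if (min(table(yb)) < 2) stop("each class needs >= 2 samples")
  Xm <- X[, markers, drop = FALSE]
  ctr <- colMeans(Xm)
  scl <- apply(Xm, 2L, sd)
  dropped <- markers[scl == 0]
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(Xm, 2L, ctr, "-"), 2L, scl, "/")
  keep <- setdiff(markers, dropped)
  fit <- .logistic_irls(Xs[, keep, drop = FALSE], yb)
  separation <- is.null(fit) || !fit$converged ||
    any(fit$fitted > 1 - 1e-8) || any(fit$fitted < 1e-8) ||
    any(abs(fit$beta) > 1e6)
  if (separation)
    fit <- .logistic_irls(Xs[, keep, drop = FALSE], yb, ridge = 1e-6)
  coefs <- setNames(rep(0, length(markers)), markers)
  coefs[keep] <- fit$beta[-1L]
  model <- structure(
    list(markers = markers, coefficients = coefs,
         intercept = fit$beta[1L], center = ctr, scale = scl,
         dropped = dropped, separation = separation,
         converged = fit$converged, iterations = fit$iterations,
         classes = sort(unique(as.character(y)))),
    class = "panel_model"
  )
  model$roc <- roc_auc(panel_score(model, X), yb)
  model
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("<panel_model> %d markers, training AUC = %.3f%s\n",
              length(x$markers), x$roc$auc,
              if (x$separation) " (separation; ridge fit)" else ""))
  invisible(x)
}

#' Linear score of a fitted panel on new samples
#'
#' Applies the trained coefficients with the training-time standardization
#' vectors (frozen, so cross-cohort evaluation is well defined).
#'
#' @param model a `panel_model`.
#' @param X numeric matrix containing all panel marker columns.
#' @return Numeric vector of linear predictor values.
#' @export
panel_score <- function(model, X) {
  X <- as.matrix(X)
  missing <- setdiff(model$markers, colnames(X))
  if (length(missing))
    stop("missing marker column(s): ", paste(missing, collapse = ", "))
  Xs <- sweep(sweep(X[, model$markers, drop = FALSE], 2L, model$center, "-"),
              2L, model$scale, "/")
  drop(model$intercept + Xs %*% model$coefficients)
}

#' ROC curve and AUC
#'
#' AUC as the normalized Mann-Whitney U statistic (ties counted 1/2),
#' together with the ROC curve from a threshold sweep over the unique
#' scores. The trapezoidal integral of the returned curve equals the
#' U-statistic AUC to machine precision.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels aligned with `scores`.
#' @return Object of class `roc_result`: `auc`, `curve` (data.frame with
#'   `threshold`, `fpr`, `tpr`, starting at (0,0) and ending at (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  yb <- .check_binary_y(labels)
  n_pos <- sum(yb == 1); n_neg <- sum(yb == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[yb == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & yb == 1) / n_pos,
                numeric(1L))
  fpr <- vapply(thr, function(t) sum(scores >= t & yb == 0) / n_neg,
                numeric(1L))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1)
    curve <- rbind(curve, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  structure(list(auc = auc, curve = curve), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%d thresholds)\n", x$auc,
              nrow(x$curve)))
  invisible(x)
}

#' Trapezoidal area under a ROC curve
#'
#' Direct integration of the (FPR, TPR) polyline; serves as the
#' independent cross-check of the U-statistic AUC.
#'
#' @param roc a `roc_result`.
#' @return Numeric AUC.
#' @export
roc_trapezoid <- function(roc) {
  cv <- roc$curve
  sum(diff(cv$fpr) * (head(cv$tpr, -1) + cv$tpr[-1]) / 2)
}

#' Apply a trained panel to another cohort
#'
#' Scores the new cohort with the trained coefficients and the frozen
#' training standardization, then evaluates the ROC against the new
#' labels. This is the cross-syndrome specificity check: a panel built for
#' one syndrome should lose discrimination on the other.
#'
#' @param model a `panel_model`.
#' @param X_other,y_other marker matrix and labels of the target cohort.
#' @return A `roc_result`.
#' @export
cross_apply <- function(model, X_other, y_other) {
  roc_auc(panel_score(model, X_other), y_other)
}
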