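# Summary-statistic reduction: per-statistic Box-Cox + standardization
# fitted on the calibration simulations, followed by partial least squares
# against the parameters.  The fitted transform is a fixed linear map
# thereafter and is applied identically to observed and simulated vectors.

# one-dimensional Box-Cox with automatic positive shift; lambda by profile
# likelihood on a grid (MASS::boxcox on an intercept-only model)
.fit_boxcox <- function(x) {
  shift <- if (min(x) <= 0) 1 - min(x) else 0
  xs <- x + shift
  bc <- MASS::boxcox(xs ~ 1, lambda = seq(-2, 2, 0.1), plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  list(shift = shift, lambda = lambda)
}

.apply_boxcox <- function(x, p) {
  xs <- pmax(x + p$shift, .Machine$double.eps)
  if (abs(p$lambda) < 1e-8) log(xs) else (xs^p$lambda - 1) / p$lambda
}

#' Fit the PLS summary-statistic transform
#'
#' Statistics are Box-Cox transformed (with automatic shifting) and
#' standardized using the calibration set, then partial least squares
#' components maximizing covariance with the parameters are extracted.
#' Zero-variance statistics are dropped and recorded.  The returned object
#' is a deterministic linear transform; an RMSE-versus-components curve
#' (in-sample prediction of the parameters) is included for choosing the
#' number of components.
#'
#' @param stats calibration matrix of raw summary statistics
#'   (simulations x statistics, named columns).
#' @param params matrix of the generating parameters (log10 scale),
#'   same row count.
#' @param ncomp number of PLS components to extract (capped at the number of
#'   informative statistics).
#' @param boxcox apply the marginal Box-Cox step?
#' @return object of class `pls_transform` with `$rmse` (per component
#'   count) and `$dropped` (zero-variance statistics).
#' @export
fit_pls <- function(stats, params, ncomp = 28L, boxcox = TRUE) {
  stopifnot(nrow(stats) == nrow(params))
  if (nrow(stats) < ncomp + 10L)
    stop("calibration too small for ", ncomp, " components")
  keep <- apply(stats, 2L, function(x) stats::var(x) > 0)
  dropped <- colnames(stats)[!keep]
  X <- stats[, keep, drop = FALSE]
  if (ncomp > ncol(X)) stop("ncomp exceeds the number of usable statistics")
  bc <- NULL
  if (boxcox) {
    bc <- lapply(seq_len(ncol(X)), function(j) .fit_boxcox(X[, j]))
    for (j in seq_len(ncol(X))) X[, j] <- .apply_boxcox(X[, j], bc[[j]])
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  fit <- mixOmics::pls(Xs, params, ncomp = ncomp, scale = FALSE,
                       mode = "regression")
  scores <- fit$variates$X
  # PLS scores are linear in the centred statistics; recover the rotation by
  # least squares (exact for a linear map)
  rot <- qr.solve(Xs, scores)
  rmse <- vapply(seq_len(ncomp), function(k) {
    pred <- cbind(1, scores[, seq_len(k), drop = FALSE])
    beta <- qr.solve(pred, params)
    sqrt(mean((params - pred %*% beta)^2))
  }, 0)
  structure(list(keep = keep, boxcox = bc, center = ctr, scale = scl,
                 rotation = rot, ncomp = ncomp, rmse = rmse,
                 dropped = dropped, stat_names = colnames(stats)[keep]),
            class = "pls_transform")
}

#' @export
print.pls_transform <- function(x, ...) {
  cat("<pls_transform> ", x$ncomp, " components from ", length(x$stat_names),
      " statistics", sep = "")
  if (length(x$dropped))
    cat(" (", length(x$dropped), " zero-variance dropped)", sep = "")
  cat("\n  in-sample parameter RMSE by components: ",
      paste(signif(x$rmse, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Project summary statistics into PLS space
#'
#' @param transform a [fit_pls()] result.
#' @param stats numeric vector or matrix of raw statistics in registry order.
#' @return matrix of component scores (rows = inputs).
#' @export
pls_project <- function(transform, stats) {
  if (is.null(dim(stats))) stats <- matrix(stats, 1L,
                                           dimnames = list(NULL, names(stats)))
  X <- stats[, transform$keep, drop = FALSE]
  if (!is.null(transform$boxcox))
    for (j in seq_len(ncol(X)))
      X[, j] <- .apply_boxcox(X[, j], transform$boxcox[[j]])
  Xs <- sweep(sweep(X, 2L, transform$center), 2L, transform$scale, "/")
  unname(Xs %*% transform$rotation)
}
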