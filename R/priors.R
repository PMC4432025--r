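# Log10-uniform priors.

#' Prior specification
#'
#' All parameters have uniform priors on the log10 scale; a draw of
#' parameter `p` is `10^u` with `u ~ Uniform(lo_p, hi_p)`.  Divergence-time
#' parameters listed in `ordered` are constrained to be increasing
#' (enforced by rejection at sampling time).
#'
#' @param bounds named list of `c(lo, hi)` log10 bounds.
#' @param ordered parameter names whose natural-scale values must be
#'   strictly increasing in the given order (default: every name beginning
#'   with `"T"`, in `bounds` order).
#' @return object of class `prior_spec` (a data frame with rownames = names).
#' @export
prior_spec <- function(bounds, ordered = NULL) {
  lo <- vapply(bounds, `[`, 0, 1L)
  hi <- vapply(bounds, `[`, 0, 2L)
  if (any(lo >= hi)) {
    eq <- lo > hi
    if (any(eq)) stop("prior lower bounds must not exceed upper bounds")
  }
  if (is.null(ordered)) ordered <- grep("^T", names(bounds), value = TRUE)
  out <- data.frame(lo = lo, hi = hi, row.names = names(bounds))
  attr(out, "ordered") <- ordered
  class(out) <- c("prior_spec", "data.frame")
  out
}

#' Default priors for the four-species spruce models
#'
#' Population sizes (diploid) and divergence times (generations) get the
#' study's log10-uniform bounds; the migration prior (unstated in the source
#' analysis) defaults to log10-uniform(-2, 1) migrants per generation,
#' spanning negligible to strong gene flow.
#'
#' @param gene_flow include the migration parameter(s)?
#' @param tie_migration single shared `Nm` (default) or three independent
#'   connection-specific parameters.
#' @param nm_bounds log10 bounds of the migration prior.
#' @return a [prior_spec()].
#' @export
default_spruce_priors <- function(gene_flow = FALSE, tie_migration = TRUE,
                                  nm_bounds = c(-2, 1)) {
  b <- list(NSCH = c(4.5, 5.0), NSMI = c(4.5, 5.0), NL = c(5.3, 5.5),
            NW = c(5.4, 5.6), N1 = c(4.5, 5.7), N2 = c(3.8, 5.0),
            N3 = c(3.8, 6.0), T1 = c(5.1, 5.3), T2 = c(5.2, 5.5),
            T3 = c(5.5, 5.8))
  if (gene_flow) {
    if (tie_migration) {
      b$Nm <- nm_bounds
    } else {
      b$Nm_SCH_SMI <- nm_bounds
      b$Nm_LIK_WIL <- nm_bounds
      b$Nm_N1_N2 <- nm_bounds
    }
  }
  prior_spec(b, ordered = c("T1", "T2", "T3"))
}

#' Midpoint of a prior (natural scale)
#' @param spec a [prior_spec()].
#' @return named vector of `10^((lo+hi)/2)`.
#' @export
prior_midpoint <- function(spec) {
  setNames(10^((spec$lo + spec$hi) / 2), rownames(spec))
}

#' Sample from the prior
#'
#' Independent log10-uniform draws per parameter; draws violating the time
#' ordering are rejected and redrawn.
#'
#' @param spec a [prior_spec()].
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @param log10_scale return log10 values (default) or natural scale.
#' @return `n x p` matrix with parameter columns.
#' @export
sample_prior <- function(spec, n, seed = NULL, log10_scale = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(spec)
  ord <- attr(spec, "ordered")
  draw <- function(m) {
    x <- matrix(runif(m * p, rep(spec$lo, each = m), rep(spec$hi, each = m)),
                m, p, dimnames = list(NULL, rownames(spec)))
    x
  }
  x <- draw(n)
  if (length(ord) >= 2L) {
    bad <- which(!apply(x[, ord, drop = FALSE], 1L, function(z)
      all(diff(z) > 0)))
    guard <- 0L
    while (length(bad)) {
      x[bad, ] <- draw(length(bad))
      bad <- bad[!apply(x[bad, ord, drop = FALSE], 1L, function(z)
        all(diff(z) > 0))]
      guard <- guard + 1L
      if (guard > 10000L) stop("time-ordering rejection did not converge")
    }
  }
  if (log10_scale) x else 10^x
}

# prior log-density on the log10 scale (uniform box + ordering constraint)
.prior_logdens <- function(spec, theta) {
  inside <- all(theta >= spec$lo & theta <= spec$hi)
  ord <- attr(spec, "ordered")
  if (inside && length(ord) >= 2L)
    inside <- all(diff(theta[ord]) > 0)
  if (inside) 0 else -Inf
}
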