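# Small shared numerical helpers.

#' Harmonic-type coalescent constants
#'
#' `a1n(n)` is the harmonic number \eqn{a_1 = \sum_{i=1}^{n-1} 1/i} and
#' `a2n(n)` the corresponding sum of squared reciprocals, the normalising
#' constants of Watterson's estimator and the neutrality test variances.
#'
#' @param n sample size (number of sequences), `n >= 2`.
#' @return a numeric scalar.
#' @keywords internal
a1n <- function(n) sum(1 / seq_len(n - 1L))

#' @rdname a1n
#' @keywords internal
a2n <- function(n) sum(1 / seq_len(n - 1L)^2)

#' Highest posterior density interval
#'
#' Narrowest interval containing at least `level` posterior mass, computed
#' from (optionally weighted) draws by scanning sorted-sample windows.
#'
#' @param x numeric draws.
#' @param level target mass, default 0.95.
#' @param w optional non-negative weights, recycled against `x`.
#' @return numeric `c(lower, upper)`.
#' @export
hpdi <- function(x, level = 0.95, w = NULL) {
  stopifnot(length(x) >= 2, level > 0, level < 1)
  o <- order(x)
  x <- x[o]
  n <- length(x)
  if (is.null(w)) {
    m <- max(1L, ceiling(level * n))
    if (m >= n) return(range(x))
    widths <- x[(m + 1L):n] - x[seq_len(n - m)]
    i <- which.min(widths)
    c(x[i], x[i + m])
  } else {
    w <- rep_len(w, n)[o]
    cw <- cumsum(w) / sum(w)
    best <- c(x[1L], x[n])
    bw <- diff(range(x))
    j <- 1L
    for (i in seq_len(n)) {
      lo_mass <- if (i > 1L) cw[i - 1L] else 0
      while (j < n && cw[j] - lo_mass < level) j <- j + 1L
      if (cw[j] - lo_mass >= level && x[j] - x[i] < bw) {
        bw <- x[j] - x[i]
        best <- c(x[i], x[j])
      }
      if (j == n && cw[n] - lo_mass < level) break
    }
    best
  }
}

#' Posterior mode from a kernel density estimate
#'
#' @param x numeric draws.
#' @param w optional weights.
#' @return location of the density maximum.
#' @export
posterior_mode <- function(x, w = NULL) {
  if (length(unique(x)) == 1L) return(x[1L])
  if (!is.null(w)) {
    w <- rep_len(w, length(x))
    bw <- stats::bw.nrd0(x)
    d <- density(x, weights = w / sum(w), bw = bw)
  } else {
    d <- density(x)
  }
  d$x[which.max(d$y)]
}

# log(sum(exp(x))) without overflow
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
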