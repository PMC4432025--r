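# Outgroup polarization and the maximum-frequency-of-derived-mutation
# (MFDM) neutrality test.
#
# Under neutrality the basal split of the sample genealogy is uniform on
# {1, ..., n-1}, so the size of the larger basal clade is uniform on
# {ceil(n/2), ..., n-1}.  A derived mutation observed in k > n/2 sequences
# forces the larger basal clade to contain at least k leaves, which gives the
# closed-form p-value p = 2 (n - k) / (n - 1); mutations at frequencies
# k <= n/2 are uninformative (p = 1).

#' Polarize segregating sites against outgroup sequences
#'
#' For every segregating site at which all outgroup sequences agree on one
#' non-missing allele, the derived state is taken to be any ingroup allele
#' differing from the outgroup allele; at multi-allelic sites the derived
#' count is the largest derived-class count.  Sites with outgroup
#' disagreement or missing outgroup data are excluded and counted.
#'
#' @param alignment a [locus_alignment()].
#' @param subset ingroup sample ids.
#' @param outgroups outgroup sample ids (at least one).
#' @return object of class `polarized_spectrum`: `k` (per-site derived
#'   counts), `n` (ingroup sample size), `sites` (1-based positions),
#'   `n_excluded`.
#' @export
polarize_sites <- function(alignment, subset, outgroups) {
  if (!length(outgroups)) stop("at least one outgroup sequence is required")
  ing <- .subset_code(alignment, subset)
  out <- .subset_code(alignment, outgroups)
  n <- nrow(ing)
  cnt <- .allele_counts(ing)           # L x 4
  seg <- rowSums(cnt > 0) >= 2L
  k <- integer(0)
  sites <- integer(0)
  excluded <- 0L
  for (s in which(seg)) {
    og <- out[, s]
    og <- og[og > 0L]
    if (!length(og) || length(unique(og)) != 1L) {
      excluded <- excluded + 1L
      next
    }
    anc <- og[1L]
    derived <- cnt[s, setdiff(1:4, anc)]
    k <- c(k, max(derived))
    sites <- c(sites, s)
  }
  structure(list(k = k, n = n, sites = sites, n_excluded = excluded),
            class = "polarized_spectrum")
}

#' @export
print.polarized_spectrum <- function(x, ...) {
  cat("<polarized_spectrum> n = ", x$n, ", ", length(x$k),
      " polarized sites (", x$n_excluded, " excluded)\n", sep = "")
  invisible(x)
}

#' MFDM neutrality test p-value
#'
#' @param spectrum a [polarize_sites()] result, or the maximum derived count
#'   `k_max` when `n` is given.
#' @param n ingroup sample size (only when `spectrum` is a plain count).
#' @param alpha significance level for the `significant` flag.
#' @return object of class `mfdm_result`: `k_max`, `n`, `p_value`,
#'   `significant`, `note`.
#' @export
mfdm_pvalue <- function(spectrum, n = NULL, alpha = 0.05) {
  if (inherits(spectrum, "polarized_spectrum")) {
    n <- spectrum$n
    k_max <- if (length(spectrum$k)) max(spectrum$k) else NA_integer_
  } else {
    k_max <- spectrum
    if (is.null(n)) stop("n required when passing k_max directly")
  }
  if (!is.na(k_max) && n < 4) stop("MFDM test needs n >= 4")
  if (is.na(k_max)) {
    out <- list(k_max = NA_integer_, n = n, p_value = 1,
                significant = FALSE, note = "insufficient variation")
  } else {
    p <- if (k_max > n / 2) min(1, 2 * (n - k_max) / (n - 1)) else 1
    out <- list(k_max = k_max, n = n, p_value = p,
                significant = p < alpha, note = NA_character_)
  }
  class(out) <- "mfdm_result"
  out
}

#' @export
print.mfdm_result <- function(x, ...) {
  if (!is.na(x$note)) {
    cat("<mfdm_result> NA (", x$note, ")\n", sep = "")
  } else {
    cat("<mfdm_result> n = ", x$n, ", k_max = ", x$k_max, ", p = ",
        formatC(x$p_value, digits = 4, format = "f"),
        if (x$significant) " *" else "", "\n", sep = "")
  }
  invisible(x)
}

#' Per-locus, per-species MFDM table
#'
#' Applies the MFDM test to every locus and every (non-outgroup) species of
#' a dataset, polarizing against the dataset's outgroup samples.  Loci or
#' species without polarizable variation are reported as `NA`.
#'
#' @param dataset a [multilocus_dataset()] whose partition flags outgroups.
#' @param alpha significance level.
#' @return data frame of p-values, loci as rows and species as columns.
#' @export
mfdm_table <- function(dataset, alpha = 0.05) {
  part <- dataset$partition
  species <- species_labels(part)
  og <- part$sample_id[part$is_outgroup]
  if (!length(og)) stop("dataset has no outgroup samples")
  rows <- lapply(dataset$loci, function(l) {
    p <- vapply(species, function(sp) {
      ids <- intersect(species_samples(part, sp), sample_ids(l))
      ogl <- intersect(og, sample_ids(l))
      if (length(ids) < 4L || !length(ogl)) return(NA_real_)
      sp_spec <- polarize_sites(l, ids, ogl)
      if (!length(sp_spec$k)) return(NA_real_)
      mfdm_pvalue(sp_spec, alpha = alpha)$p_value
    }, 0)
    as.data.frame(as.list(p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(dataset$loci)
  out
}
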