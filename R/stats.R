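# Per-species, per-pair and per-locus diversity statistics.
#
# Missing data (N or gap) are handled by pairwise deletion: every statistic
# uses the sites comparable for the sequences involved.

.subset_code <- function(alignment, subset) {
  seqs <- alignment$seqs
  if (is.null(subset)) subset <- rownames(seqs)
  miss <- setdiff(subset, rownames(seqs))
  if (length(miss))
    stop("samples not in alignment: ", paste(head(miss, 3L), collapse = ", "))
  .encode_alignment(seqs[subset, , drop = FALSE])
}

# per-column allele counts for an encoded matrix: 4 x L counts of A,C,G,T
.allele_counts <- function(code) {
  vapply(1:4, function(a) colSums(code == a), numeric(ncol(code)))
}

#' Number of segregating sites
#'
#' Counts alignment columns at which at least two distinct non-missing bases
#' occur among the chosen sequences.
#'
#' @param alignment a [locus_alignment()].
#' @param subset sample ids to use (default: all).
#' @return integer count.
#' @export
segregating_sites <- function(alignment, subset = NULL) {
  code <- .subset_code(alignment, subset)
  if (nrow(code) < 2L) stop("need at least 2 sequences")
  cnt <- .allele_counts(code)
  sum(rowSums(cnt > 0) >= 2L)
}

#' Watterson's estimator of the population mutation rate
#'
#' \eqn{\theta_W = S / (a_1 L)} per site, with
#' \eqn{a_1 = \sum_{i=1}^{n-1} 1/i}.
#'
#' @param S number of segregating sites.
#' @param n number of sequences (must be at least 2).
#' @param L sequence length in base pairs (site-equivalents allowed).
#' @return per-site estimate.
#' @export
watterson_theta <- function(S, n, L) {
  stopifnot(S >= 0, L > 0)
  if (n < 2) stop("Watterson's estimator needs n >= 2")
  S / (a1n(n) * L)
}

# observed site class of a variable column: silent iff the exchange between
# the two most common alleles is synonymous under the annotation; columns of
# unannotated alignments are all "total".
.column_classes <- function(alignment) {
  if (is.null(alignment$site_classes)) rep("silent", alignment$L)
  else alignment$site_classes
}

.class_weights <- function(alignment, site_class) {
  L <- alignment$L
  if (site_class == "total") return(rep(1, L))
  if (is.null(alignment$silent_weight))
    stop("alignment has no site-class annotation; run classify_sites() first")
  w <- alignment$silent_weight
  w[is.na(w)] <- 0
  if (site_class == "silent") w else 1 - w
}

#' Nucleotide diversity
#'
#' Mean per-site pairwise difference: for every pair of sequences the number
#' of differing, mutually comparable sites of the requested class divided by
#' the pair's comparable site-equivalents of that class, averaged over all
#' pairs.
#'
#' @param alignment a [locus_alignment()] (classified via [classify_sites()]
#'   when `site_class != "total"`).
#' @param subset sample ids to use.
#' @param site_class `"total"`, `"silent"` or `"nonsynonymous"`.
#' @return per-site diversity, or `NA` when no comparable sites of the class
#'   exist.
#' @export
nucleotide_diversity <- function(alignment, subset = NULL,
                                 site_class = "total") {
  site_class <- match.arg(site_class, c("total", "silent", "nonsynonymous"))
  code <- .subset_code(alignment, subset)
  if (nrow(code) < 2L) stop("need at least 2 sequences")
  w <- .class_weights(alignment, site_class)
  use <- rep(TRUE, ncol(code))
  if (site_class != "total") {
    cls <- .column_classes(alignment)
    use <- cls == site_class
  }
  ps <- .cpp_pair_stats(code, w, use)
  ut <- upper.tri(ps$comp)
  ok <- ps$comp[ut] > 0
  if (!any(ok)) return(NA_real_)
  mean(ps$diff[ut][ok] / ps$comp[ut][ok])
}

#' Mean number of pairwise differences within a sample
#'
#' Raw difference counts (not per site) averaged over all sequence pairs;
#' the quantity entering Tajima's D and the ABC summary vector.
#'
#' @inheritParams nucleotide_diversity
#' @return mean pairwise difference count.
#' @export
mean_pairwise_diff <- function(alignment, subset = NULL) {
  code <- .subset_code(alignment, subset)
  if (nrow(code) < 2L) stop("need at least 2 sequences")
  ps <- .cpp_pair_stats(code, rep(1, ncol(code)), rep(TRUE, ncol(code)))
  mean(ps$diff[upper.tri(ps$diff)])
}

#' Mean pairwise differences between two groups
#'
#' @param alignment a [locus_alignment()].
#' @param subsetA,subsetB sample id vectors (non-empty).
#' @return mean difference count over all A x B pairs.
#' @export
mean_between_diff <- function(alignment, subsetA, subsetB) {
  if (!length(subsetA) || !length(subsetB)) stop("empty subset")
  code <- .subset_code(alignment, c(subsetA, subsetB))
  ps <- .cpp_pair_stats(code, rep(1, ncol(code)), rep(TRUE, ncol(code)))
  ia <- seq_along(subsetA)
  ib <- length(subsetA) + seq_along(subsetB)
  mean(ps$diff[ia, ib, drop = FALSE])
}

# mutation counts used by the neutrality tests
.eta_counts <- function(code) {
  cnt <- .allele_counts(code)
  nall <- rowSums(cnt > 0)
  seg <- nall >= 2L
  eta <- sum(pmax(nall[seg] - 1L, 0L))
  # singleton mutations: alleles observed in exactly one sequence at a
  # segregating site
  eta_s <- sum(cnt[seg, , drop = FALSE] == 1L)
  list(S = sum(seg), eta = eta, eta_s = eta_s)
}

# Tajima (1989) constants and statistic from sufficient statistics
.tajima_d_from <- function(n, S, khat) {
  if (S < 1 || n < 4) return(NA_real_)
  a1 <- a1n(n); a2 <- a2n(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Fu & Li (1993) D* (no outgroup), with the later variance correction
.fu_li_dstar_from <- function(n, eta, eta_s) {
  if (eta < 1 || n < 4) return(NA_real_)
  a1 <- a1n(n); a2 <- a2n(n)
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * (a1 + 1 / n) - 3) / (n - 2) - 1 / n)
  vd <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
           2 * (n * a1 * (a1 + 1)) / (n - 1)^2) / (a1^2 + a2)
  ud <- (n / (n - 1)) * (a1 - n / (n - 1)) - vd
  ((n / (n - 1)) * eta - a1 * eta_s) / sqrt(ud * eta + vd * eta^2)
}

#' Tajima's D
#'
#' Contrasts the mean pairwise difference count with the Watterson estimate
#' of the same quantity, normalised by its neutral standard deviation.
#' Undefined (`NA` with `defined = FALSE`) when there is no variation or
#' fewer than 4 sequences.
#'
#' @inheritParams nucleotide_diversity
#' @return list with `value` and `defined`.
#' @export
tajimas_d <- function(alignment, subset = NULL) {
  code <- .subset_code(alignment, subset)
  n <- nrow(code)
  ec <- .eta_counts(code)
  ps <- .cpp_pair_stats(code, rep(1, ncol(code)), rep(TRUE, ncol(code)))
  khat <- mean(ps$diff[upper.tri(ps$diff)])
  v <- .tajima_d_from(n, ec$S, khat)
  list(value = v, defined = !is.na(v))
}

#' Fu and Li's D* (no outgroup)
#'
#' Contrasts the total number of mutations with the number of singleton
#' mutations.  Undefined when there is no variation or fewer than 4
#' sequences.
#'
#' @inheritParams nucleotide_diversity
#' @return list with `value` and `defined`.
#' @export
fu_li_dstar <- function(alignment, subset = NULL) {
  code <- .subset_code(alignment, subset)
  ec <- .eta_counts(code)
  v <- .fu_li_dstar_from(nrow(code), ec$eta, ec$eta_s)
  list(value = v, defined = !is.na(v))
}

#' Private segregating sites of two groups
#'
#' Sites polymorphic within one group and monomorphic within the other.
#'
#' @param alignment a [locus_alignment()].
#' @param subsetA,subsetB disjoint sample id vectors, each of size >= 2.
#' @return named integer vector `c(A = ..., B = ...)`.
#' @export
private_segregating_sites <- function(alignment, subsetA, subsetB) {
  if (length(intersect(subsetA, subsetB)))
    stop("subsets overlap")
  if (length(subsetA) < 2L || length(subsetB) < 2L)
    stop("each subset needs >= 2 sequences")
  polyA <- .poly_mask(.subset_code(alignment, subsetA))
  polyB <- .poly_mask(.subset_code(alignment, subsetB))
  c(A = sum(polyA & !polyB), B = sum(polyB & !polyA))
}

.poly_mask <- function(code) {
  cnt <- .allele_counts(code)
  rowSums(cnt > 0) >= 2L
}

#' Population differentiation with permutation test
#'
#' \eqn{\Phi_{ST} = 1 - \bar d_w / \bar d_t} from pairwise nucleotide
#' difference counts, where \eqn{\bar d_w} pools all within-group pairs and
#' \eqn{\bar d_t} all pairs.  Hudson's
#' \eqn{F_{ST} = 1 - \bar d_w' / d_{xy}} (mean of the two within-group means
#' over the between-group mean) is available as a variant.  Significance is
#' assessed by permuting group labels; the p-value uses
#' \eqn{p = (b + 1)/(m + 1)} with `>=`, which includes the observed
#' arrangement and can never be zero.
#'
#' @param alignment a [locus_alignment()] (typically [concatenate_loci()]
#'   output so the statistic spans all loci).
#' @param subsetA,subsetB sample id vectors, each of size >= 2.
#' @param n_perm number of label permutations.
#' @param seed optional RNG seed, recorded in the result.
#' @param statistic `"phist"` or `"hudson"`.
#' @return object of class `pairwise_divergence`: `fst`, `p_value`,
#'   `mean_between_diff`, `total_S_pair`, `n_perm`, `seed`, `defined`.
#' @export
fst_with_permutation <- function(alignment, subsetA, subsetB,
                                 n_perm = 10000L, seed = NULL,
                                 statistic = c("phist", "hudson")) {
  statistic <- match.arg(statistic)
  if (length(subsetA) < 2L || length(subsetB) < 2L)
    stop("each subset needs >= 2 sequences")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ids <- c(subsetA, subsetB)
  code <- .subset_code(alignment, ids)
  ps <- .cpp_pair_stats(code, rep(1, ncol(code)), rep(TRUE, ncol(code)))
  d <- ps$diff
  nA <- length(subsetA)
  n <- nrow(d)
  stat_fun <- function(ia) {
    ib <- setdiff(seq_len(n), ia)
    wA <- d[ia, ia][upper.tri(diag(length(ia)))]
    wB <- d[ib, ib][upper.tri(diag(length(ib)))]
    btw <- mean(d[ia, ib, drop = FALSE])
    if (statistic == "phist") {
      tot <- mean(d[upper.tri(d)])
      if (tot == 0) return(NA_real_)
      1 - mean(c(wA, wB)) / tot
    } else {
      if (btw == 0) return(NA_real_)
      1 - mean(c(mean(wA), mean(wB))) / btw
    }
  }
  obs <- stat_fun(seq_len(nA))
  btw <- mean(d[seq_len(nA), (nA + 1L):n, drop = FALSE])
  Spair <- sum(.poly_mask(code))
  if (is.na(obs)) {
    out <- list(fst = NA_real_, p_value = NA_real_, mean_between_diff = btw,
                total_S_pair = Spair, n_perm = n_perm, seed = seed,
                statistic = statistic, defined = FALSE)
    class(out) <- "pairwise_divergence"
    return(out)
  }
  b <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample.int(n, nA)
    s <- stat_fun(perm)
    if (!is.na(s) && s >= obs) b <- b + 1L
  }
  out <- list(fst = obs, p_value = (b + 1) / (n_perm + 1),
              mean_between_diff = btw, total_S_pair = Spair,
              n_perm = n_perm, seed = seed, statistic = statistic,
              defined = TRUE)
  class(out) <- "pairwise_divergence"
  out
}

#' @export
print.pairwise_divergence <- function(x, ...) {
  cat("<pairwise_divergence> ", toupper(x$statistic), " = ",
      formatC(x$fst, digits = 4, format = "f"), ", p = ",
      formatC(x$p_value, digits = 4, format = "g"), " (", x$n_perm,
      " permutations)\n", sep = "")
  invisible(x)
}

#' Pairwise linkage disequilibrium (r-squared)
#'
#' For every pair of biallelic SNPs among phased haplotypes computes
#' \eqn{r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))} from the 2x2 haplotype table,
#' Fisher's exact p, and a Bonferroni significance flag at
#' `alpha / n_pairs`.
#'
#' @param alignment a [locus_alignment()].
#' @param subset sample ids to use.
#' @param alpha family-wise significance level.
#' @return data frame with one row per SNP pair (`site_i`, `site_j` 1-based,
#'   `r2`, `fisher_p`, `bonferroni_significant`); zero rows when fewer than
#'   two biallelic SNPs exist.
#' @export
ld_r2 <- function(alignment, subset = NULL, alpha = 0.05) {
  code <- .subset_code(alignment, subset)
  cnt <- .allele_counts(code)
  biall <- which(rowSums(cnt > 0) == 2L)
  empty <- data.frame(site_i = integer(0), site_j = integer(0),
                      r2 = numeric(0), fisher_p = numeric(0),
                      bonferroni_significant = logical(0))
  if (length(biall) < 2L) return(empty)
  pairs <- combn(biall, 2L)
  res <- apply(pairs, 2L, function(pr) {
    x <- code[, pr[1L]]; y <- code[, pr[2L]]
    ok <- x > 0L & y > 0L
    x <- x[ok]; y <- y[ok]
    if (length(unique(x)) < 2L || length(unique(y)) < 2L)
      return(c(NA_real_, NA_real_))
    tab <- table(x, y)
    pA <- sum(tab[1L, ]) / sum(tab)
    pB <- sum(tab[, 1L]) / sum(tab)
    pAB <- tab[1L, 1L] / sum(tab)
    D <- pAB - pA * pB
    r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
    c(r2, fisher.test(tab)$p.value)
  })
  keep <- !is.na(res[1L, ])
  npair <- sum(keep)
  if (!npair) return(empty)
  data.frame(site_i = pairs[1L, keep], site_j = pairs[2L, keep],
             r2 = res[1L, keep], fisher_p = res[2L, keep],
             bonferroni_significant = res[2L, keep] < alpha / npair,
             row.names = NULL)
}

#' Per-genome diversity table
#'
#' Species-by-genome summary mirroring the layout of a multilocus diversity
#' report: sample size, concatenated length, segregating sites, Watterson's
#' theta and nucleotide diversity, for total, nonsynonymous and silent sites
#' (classes require [classify_sites()] annotation on the nuclear loci).
#'
#' @param dataset a [multilocus_dataset()].
#' @param digits rounding applied to the reported estimates.
#' @return data frame with one row per genome x species combination.
#' @export
diversity_table <- function(dataset, digits = 6) {
  part <- dataset$partition
  species <- species_labels(part)
  rows <- list()
  for (g in unique(dataset$genome)) {
    concat <- suppressWarnings(concatenate_loci(dataset, g))
    has_cls <- !is.null(concat$site_classes)
    for (sp in species) {
      ids <- intersect(species_samples(part, sp), sample_ids(concat))
      if (length(ids) < 2L) next
      S <- segregating_sites(concat, ids)
      row <- data.frame(
        genome = g, species = sp, n = length(ids), L = concat$L, S = S,
        theta_w = round(watterson_theta(S, length(ids), concat$L), digits),
        pi = round(nucleotide_diversity(concat, ids), digits))
      if (has_cls) {
        wsil <- concat$silent_weight
        for (cl in c("nonsynonymous", "silent")) {
          wt <- if (cl == "silent") wsil else 1 - wsil
          Lcl <- sum(wt, na.rm = TRUE)
          cls <- concat$site_classes
          codecl <- .subset_code(concat, ids)[, cls == cl, drop = FALSE]
          Scl <- if (ncol(codecl)) sum(.poly_mask(codecl)) else 0L
          row[[paste0("L_", cl)]] <- round(Lcl, 2)
          row[[paste0("S_", cl)]] <- Scl
          row[[paste0("theta_w_", cl)]] <-
            if (Lcl > 0) round(watterson_theta(Scl, length(ids), Lcl), digits)
            else NA_real_
          row[[paste0("pi_", cl)]] <-
            round(nucleotide_diversity(concat, ids, cl), digits)
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Pairwise divergence table over all species
#'
#' @param dataset a [multilocus_dataset()].
#' @param genome genome tag whose loci enter the statistic.
#' @param n_perm permutations per pair.
#' @param seed RNG seed.
#' @param statistic `"phist"` or `"hudson"`.
#' @return data frame of species pairs with the statistic and p-value.
#' @export
fst_table <- function(dataset, genome = "nuclear", n_perm = 1000L,
                      seed = NULL, statistic = "phist") {
  concat <- suppressWarnings(concatenate_loci(dataset, genome))
  part <- dataset$partition
  species <- species_labels(part)
  if (!is.null(seed)) set.seed(seed)
  prs <- combn(species, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    a <- prs[1L, i]; b <- prs[2L, i]
    fa <- intersect(species_samples(part, a), sample_ids(concat))
    fb <- intersect(species_samples(part, b), sample_ids(concat))
    r <- fst_with_permutation(concat, fa, fb, n_perm = n_perm,
                              statistic = statistic)
    data.frame(species_a = a, species_b = b, fst = r$fst,
               p_value = r$p_value, n_perm = n_perm)
  })
  do.call(rbind, rows)
}
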