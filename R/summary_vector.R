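# The ABC summary-statistic vector.
#
# One registry fixes the names and order of the statistics for a given
# species set; the observed path (multilocus alignments) and the simulated
# path (biallelic derived-count matrices) fill the identical registry, and
# undefined entries are imputed as 0 with a parallel defined-mask so that
# distances are always computable and the imputation rule matches on both
# sides.

#' Summary-statistic registry
#'
#' Per species: segregating sites `S`, private segregating sites `Sp`,
#' Tajima's D `D`, Fu & Li's D* `Ds`, mean pairwise differences `pi`.
#' Per species pair: Hudson's `FST`, mean between-group differences `dxy`,
#' total segregating sites over the pair `Spair`.  For four species this
#' yields 20 + 18 = 38 statistics; `drop` removes named families (e.g.
#' `drop = "Ds"` for a reduced set).
#'
#' @param species ordered character vector of species labels.
#' @param drop optional statistic family names to omit
#'   (`"S","Sp","D","Ds","pi","FST","dxy","Spair"`).
#' @return character vector of statistic names, attribute `species` retained.
#' @export
stat_registry <- function(species, drop = NULL) {
  stopifnot(length(species) >= 2L)
  fams_sp <- setdiff(c("S", "Sp", "D", "Ds", "pi"), drop)
  fams_pr <- setdiff(c("FST", "dxy", "Spair"), drop)
  per_sp <- as.vector(outer(fams_sp, species, paste, sep = "_"))
  prs <- combn(species, 2L)
  per_pr <- as.vector(apply(prs, 2L, function(p)
    paste(fams_pr, p[1L], p[2L], sep = "_")))
  out <- c(per_sp, per_pr)
  attr(out, "species") <- species
  out
}

# Core computation from per-site species allele-count arrays.
# `counts` is a list with one entry per species: an L x A matrix of allele
# counts (A alleles; for simulated biallelic data A = 2).  All entries share
# the same L (concatenated sites).
.sumstats_from_counts <- function(counts, n_sp, registry) {
  species <- attr(registry, "species")
  k <- length(species)
  L <- nrow(counts[[1L]])
  vals <- setNames(numeric(length(registry)), registry)
  defined <- setNames(rep(TRUE, length(registry)), registry)

  nall <- lapply(counts, function(cm) rowSums(cm > 0))
  poly <- lapply(nall, function(x) x >= 2L)
  neff <- lapply(counts, rowSums)

  # expected pairwise-difference contribution per site, within species
  pi_site <- lapply(seq_len(k), function(i) {
    cm <- counts[[i]]
    ne <- neff[[i]]
    ok <- ne >= 2L
    out <- numeric(L)
    prs <- choose(ne[ok], 2L)
    same <- rowSums(choose(cm[ok, , drop = FALSE], 2L))
    out[ok] <- 1 - same / prs
    out
  })

  set_val <- function(name, v, def = TRUE) {
    if (!name %in% registry) return(invisible(NULL))
    if (is.na(v) || !def) {
      vals[name] <<- 0
      defined[name] <<- FALSE
    } else vals[name] <<- v
    invisible(NULL)
  }

  for (i in seq_len(k)) {
    sp <- species[i]
    S <- sum(poly[[i]])
    others_mono <- Reduce(`&`, lapply(setdiff(seq_len(k), i),
                                      function(j) !poly[[j]]))
    if (is.null(others_mono)) others_mono <- rep(TRUE, L)
    pii <- sum(pi_site[[i]])
    eta <- sum(pmax(nall[[i]] - 1L, 0L))
    eta_s <- sum(counts[[i]][poly[[i]], , drop = FALSE] == 1L)
    set_val(paste0("S_", sp), S)
    set_val(paste0("Sp_", sp), sum(poly[[i]] & others_mono))
    set_val(paste0("pi_", sp), pii)
    d <- .tajima_d_from(n_sp[i], S, pii)
    set_val(paste0("D_", sp), d, def = !is.na(d))
    ds <- .fu_li_dstar_from(n_sp[i], eta, eta_s)
    set_val(paste0("Ds_", sp), ds, def = !is.na(ds))
  }

  prs <- combn(seq_len(k), 2L)
  for (c0 in seq_len(ncol(prs))) {
    i <- prs[1L, c0]; j <- prs[2L, c0]
    nm <- paste(species[i], species[j], sep = "_")
    cmi <- counts[[i]]; cmj <- counts[[j]]
    # shared allele columns (both matrices use the same allele ordering)
    A <- min(ncol(cmi), ncol(cmj))
    ni <- neff[[i]]; nj <- neff[[j]]
    ok <- ni >= 1L & nj >= 1L
    same <- rowSums(cmi[, seq_len(A), drop = FALSE] *
                    cmj[, seq_len(A), drop = FALSE])
    dxy_site <- numeric(L)
    dxy_site[ok] <- 1 - same[ok] / (ni[ok] * nj[ok])
    dxy <- sum(dxy_site)
    set_val(paste0("dxy_", nm), dxy)
    cmu <- cmi[, seq_len(A), drop = FALSE] + cmj[, seq_len(A), drop = FALSE]
    Spair <- sum(rowSums(cmu > 0) >= 2L)
    set_val(paste0("Spair_", nm), Spair)
    hw <- mean(c(sum(pi_site[[i]]), sum(pi_site[[j]])))
    fst <- if (dxy > 0) 1 - hw / dxy else NA_real_
    set_val(paste0("FST_", nm), fst, def = !is.na(fst))
  }

  structure(vals, defined = defined, class = c("summary_vector", "numeric"))
}

#' @export
print.summary_vector <- function(x, ...) {
  cat("<summary_vector> ", length(x), " statistics (",
      sum(!attr(x, "defined")), " imputed)\n", sep = "")
  print(round(unclass(x), 4), ...)
  invisible(x)
}

# observed path: allele-count list from a multilocus dataset
.counts_from_dataset <- function(dataset, species, genome = "nuclear") {
  part <- dataset$partition
  sel <- dataset$loci[dataset$genome %in% genome]
  per_species <- lapply(species, function(sp) {
    ids <- species_samples(part, sp)
    blocks <- lapply(sel, function(l) {
      use <- intersect(ids, sample_ids(l))
      code <- .encode_alignment(l$seqs[use, , drop = FALSE])
      .allele_counts(code)   # L x 4
    })
    do.call(rbind, blocks)
  })
  names(per_species) <- species
  per_species
}

# simulated path: k x S derived-count matrix -> allele-count list
.counts_from_sim <- function(K, n_sp) {
  k <- nrow(K)
  lapply(seq_len(k), function(i) {
    der <- K[i, ]
    cbind(n_sp[i] - der, der)   # ancestral, derived
  })
}

#' Compute the ABC summary vector
#'
#' Works identically on observed multilocus data and on simulated biallelic
#' derived-count matrices; statistics undefined on the data (e.g. Tajima's D
#' without variation) are imputed as 0 and flagged in the `defined`
#' attribute.
#'
#' @param x a [multilocus_dataset()], or an integer matrix of per-species
#'   derived allele counts (`length(species)` rows, one column per SNP) as
#'   produced by [simulate_dataset()] with `format = "counts"`.
#' @param species ordered species labels; for the matrix input, the rows.
#' @param registry statistic registry from [stat_registry()]; defaults to
#'   the full registry of `species`.
#' @param n_sp sequences per species (matrix input only).
#' @param genome genome tag(s) to include (dataset input only).
#' @return named numeric vector of class `summary_vector` with a logical
#'   `defined` attribute.
#' @export
summary_vector <- function(x, species, registry = stat_registry(species),
                           n_sp = NULL, genome = "nuclear") {
  if (!setequal(attr(registry, "species"), species) ||
      !identical(attr(registry, "species"), species))
    stop("registry species do not match the requested species")
  if (inherits(x, "multilocus_dataset")) {
    part <- x$partition
    n_sp <- vapply(species, function(sp)
      length(species_samples(part, sp)), 0L)
    counts <- .counts_from_dataset(x, species, genome)
    .sumstats_from_counts(counts, n_sp, registry)
  } else if (is.matrix(x)) {
    if (is.null(n_sp)) stop("n_sp required for matrix input")
    if (nrow(x) != length(species)) stop("matrix rows must match species")
    .sumstats_from_counts(.counts_from_sim(x, n_sp), n_sp, registry)
  } else stop("unsupported input type")
}
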