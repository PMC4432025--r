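# Multilocus alignment containers and input/output.
#
# A locus alignment is stored as a character matrix (rows = haplotype
# sequences, columns = aligned sites, uppercase A/C/G/T/-/N).  Coordinates
# are 0-based half-open internally and 1-based in user-facing reports.

VALID_BASES <- c("A", "C", "G", "T", "-", "N")

#' Construct a single-locus alignment
#'
#' @param locus_id character scalar identifying the locus.
#' @param seqs character matrix of aligned sequences (rows = samples, with
#'   rownames giving unique sample ids) over `A,C,G,T,-,N`; lowercase input
#'   is accepted and normalised. Ambiguous IUPAC codes are converted to `N`.
#' @param site_classes optional per-site labels in
#'   `c("nonsynonymous", "silent", "unassigned")`.
#' @return an object of class `locus_alignment` with fields `locus_id`,
#'   `seqs`, `L` and `site_classes`.
#' @export
locus_alignment <- function(locus_id, seqs, site_classes = NULL) {
  stopifnot(is.character(locus_id), length(locus_id) == 1L, is.matrix(seqs))
  if (ncol(seqs) == 0L) stop("alignment '", locus_id, "' has zero length")
  if (is.null(rownames(seqs)) || anyDuplicated(rownames(seqs)))
    stop("alignment '", locus_id, "' needs unique sample ids as rownames")
  seqs <- toupper(seqs)
  seqs[!seqs %in% VALID_BASES] <- "N"
  if (!is.null(site_classes)) {
    stopifnot(length(site_classes) == ncol(seqs))
  }
  structure(
    list(locus_id = locus_id, seqs = seqs, L = ncol(seqs),
         site_classes = site_classes),
    class = "locus_alignment"
  )
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus_id, ": ", nrow(x$seqs), " sequences x ",
      x$L, " sites\n", sep = "")
  if (!is.null(x$site_classes))
    cat("  site classes: ", paste(names(table(x$site_classes)),
        table(x$site_classes), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Sample ids of an alignment
#' @param alignment a `locus_alignment`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(alignment) rownames(alignment$seqs)

#' Construct a sample-to-species partition
#'
#' @param mapping data frame with columns `sample_id`, `species` and
#'   optionally logical `is_outgroup`.
#' @return an object of class `species_partition`.
#' @export
species_partition <- function(mapping) {
  stopifnot(all(c("sample_id", "species") %in% names(mapping)))
  if (anyDuplicated(mapping$sample_id))
    stop("duplicated sample ids in species mapping")
  if (is.null(mapping$is_outgroup)) mapping$is_outgroup <- FALSE
  mapping$sample_id <- as.character(mapping$sample_id)
  mapping$species <- as.character(mapping$species)
  mapping$is_outgroup <- as.logical(mapping$is_outgroup)
  if (!any(!mapping$is_outgroup))
    stop("partition needs at least one non-outgroup species")
  structure(mapping[c("sample_id", "species", "is_outgroup")],
            class = c("species_partition", "data.frame"))
}

#' Species labels of a partition
#' @param partition a `species_partition`.
#' @param outgroup include outgroup species?
#' @return character vector of species labels.
#' @export
species_labels <- function(partition, outgroup = FALSE) {
  keep <- if (outgroup) rep(TRUE, nrow(partition)) else !partition$is_outgroup
  unique(partition$species[keep])
}

#' Sample ids belonging to a species
#' @param partition a `species_partition`.
#' @param species species label(s).
#' @return character vector of sample ids.
#' @export
species_samples <- function(partition, species) {
  partition$sample_id[partition$species %in% species]
}

#' Bundle loci into a multilocus dataset
#'
#' @param loci list of [locus_alignment()] objects.
#' @param partition a [species_partition()].
#' @param genome character vector (recycled) tagging each locus as
#'   `"nuclear"`, `"chloroplast"` or `"mitochondrial"`.
#' @return an object of class `multilocus_dataset`.
#' @export
multilocus_dataset <- function(loci, partition, genome = "nuclear") {
  stopifnot(length(loci) > 0L)
  ids <- vapply(loci, function(l) l$locus_id, "")
  if (anyDuplicated(ids)) stop("duplicated locus ids")
  names(loci) <- ids
  genome <- rep_len(match.arg(genome,
    c("nuclear", "chloroplast", "mitochondrial"), several.ok = TRUE),
    length(loci))
  names(genome) <- ids
  for (l in loci) {
    unknown <- setdiff(sample_ids(l), partition$sample_id)
    if (length(unknown))
      stop("locus ", l$locus_id, ": samples not in partition: ",
           paste(head(unknown, 3L), collapse = ", "))
  }
  structure(list(loci = loci, partition = partition, genome = genome),
            class = "multilocus_dataset")
}

#' @export
print.multilocus_dataset <- function(x, ...) {
  cat("<multilocus_dataset> ", length(x$loci), " loci (",
      paste(names(table(x$genome)), table(x$genome), collapse = ", "),
      "), ", nrow(x$partition), " mapped samples, species: ",
      paste(species_labels(x$partition), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read multilocus FASTA alignments and a species map
#'
#' Each FASTA file holds one locus; the locus id is the file name without
#' extension.  Samples absent from the mapping are excluded with a warning;
#' ragged alignments are rejected with an error naming the offending record.
#'
#' @param paths character vector of FASTA file paths.
#' @param mapping_path TSV file with columns `sample_id`, `species` and
#'   optionally `is_outgroup`.
#' @param genome genome tag(s) recycled over loci.
#' @return a [multilocus_dataset()].
#' @export
read_fasta_loci <- function(paths, mapping_path, genome = "nuclear") {
  stopifnot(length(paths) > 0L)
  map <- read.delim(mapping_path, stringsAsFactors = FALSE)
  partition <- species_partition(map)
  loci <- lapply(paths, function(p) {
    locus_id <- sub("\\.[^.]*$", "", basename(p))
    recs <- ape::read.FASTA(p)
    if (length(recs) == 0L) stop("empty FASTA file: ", p)
    lens <- lengths(recs)
    if (length(unique(lens)) != 1L) {
      bad <- names(recs)[lens != stats::median(lens)][1L]
      stop("locus ", locus_id, ": ragged alignment (record '", bad,
           "' has deviating length)")
    }
    m <- toupper(as.character(as.matrix(recs)))
    unmapped <- setdiff(rownames(m), partition$sample_id)
    if (length(unmapped)) {
      warning("locus ", locus_id, ": excluding ", length(unmapped),
              " unmapped sample(s): ", paste(head(unmapped, 3L), collapse = ", "))
      m <- m[!rownames(m) %in% unmapped, , drop = FALSE]
    }
    locus_alignment(locus_id, m)
  })
  multilocus_dataset(loci, partition, genome)
}

#' Write a locus alignment as FASTA
#'
#' @param alignment a [locus_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(alignment$seqs))) {
    writeLines(paste0(">", rownames(alignment$seqs)[i]), con)
    writeLines(paste(alignment$seqs[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Recode alignment gaps as binary indel characters
#'
#' Contiguous gap runs are treated as single insertion/deletion events
#' (simple indel coding): every distinct run (same start and end) becomes one
#' presence/absence character scored `1` for sequences carrying exactly that
#' run, `0` for sequences ungapped across it, and `NA` for sequences whose
#' gaps partially overlap it.  All gap-containing columns are then removed
#' from the nucleotide alignment and `L` updated.
#'
#' @param alignment a [locus_alignment()].
#' @return the gap-free alignment, with the binary character matrix (samples
#'   x indel characters) in `$indels`.
#' @export
code_indels <- function(alignment) {
  seqs <- alignment$seqs
  gap <- seqs == "-"
  if (!any(gap)) {
    alignment$indels <- matrix(integer(0), nrow = nrow(seqs), ncol = 0,
                               dimnames = list(rownames(seqs), NULL))
    return(alignment)
  }
  runs <- list()
  for (i in seq_len(nrow(seqs))) {
    r <- rle(gap[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) runs[[length(runs) + 1L]] <- c(starts[j], ends[j])
  }
  runs <- unique(runs)
  runs <- runs[order(vapply(runs, `[`, 1L, 1L))]
  indels <- matrix(NA_integer_, nrow(seqs), length(runs),
                   dimnames = list(rownames(seqs),
                                   vapply(runs, function(r)
                                     paste0("indel_", r[1L], "_", r[2L]), "")))
  for (k in seq_along(runs)) {
    r <- runs[[k]]
    span <- gap[, r[1L]:r[2L], drop = FALSE]
    flank_gap <- (r[1L] > 1L & gap[, max(r[1L] - 1L, 1L)]) |
      (r[2L] < ncol(seqs) & gap[, min(r[2L] + 1L, ncol(seqs))])
    exact <- rowSums(span) == ncol(span) & !flank_gap
    none <- rowSums(span) == 0L
    indels[exact, k] <- 1L
    indels[none, k] <- 0L
  }
  keep <- colSums(gap) == 0L
  out <- locus_alignment(alignment$locus_id, seqs[, keep, drop = FALSE],
                         alignment$site_classes[keep])
  out$indels <- indels
  out
}

# codon -> amino acid map built from the standard genetic code (via ape)
.genetic_code <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- c("A", "C", "G", "T")
      codons <- as.matrix(expand.grid(b, b, b, stringsAsFactors = FALSE,
                                      KEEP.OUT.ATTRS = FALSE))
      dm <- ape::as.DNAbin(matrix(tolower(codons), ncol = 3L))
      aa <- toupper(as.character(ape::trans(dm, code = 1)))
      cache <<- setNames(as.vector(aa),
                         apply(codons, 1L, paste0, collapse = ""))
    }
    cache
  }
})

# fraction of the three possible single-base changes at codon position pos
# that are synonymous
.syn_fraction <- function(codon, pos) {
  gc <- .genetic_code()
  aa <- gc[[codon]]
  alt <- setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))
  syn <- vapply(alt, function(b) {
    mut <- codon
    substr(mut, pos, pos) <- b
    identical(gc[[mut]], aa)
  }, TRUE)
  mean(syn)
}

#' Annotate site classes by codon degeneracy
#'
#' Coding positions (given as 1-based inclusive intervals per locus) are
#' scored by fractional degeneracy: the silent weight of a position is the
#' fraction of its three possible single-base changes that are synonymous in
#' the consensus codon context, so the silent and nonsynonymous
#' site-equivalents of every codon sum to exactly 3.  Non-coding positions
#' are silent with weight 1.  Fractional weights are stored in
#' `$silent_weight`; `$site_classes` carries the rounded labels.
#'
#' @param alignment a [locus_alignment()].
#' @param cds_frames data frame with columns `locus_id`, `cds_start`,
#'   `cds_end` (1-based, inclusive) and `frame` (0, 1 or 2: offset of the
#'   first complete codon).
#' @return the alignment with `site_classes` and `silent_weight` filled in.
#' @export
classify_sites <- function(alignment, cds_frames) {
  L <- alignment$L
  w <- rep(1, L)   # silent weight; non-coding positions are silent
  lab <- rep("silent", L)
  rows <- cds_frames[cds_frames$locus_id == alignment$locus_id, , drop = FALSE]
  cons <- apply(alignment$seqs, 2L, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (!length(col)) "N" else names(sort(table(col), decreasing = TRUE))[1L]
  })
  for (r in seq_len(nrow(rows))) {
    s <- rows$cds_start[r]; e <- rows$cds_end[r]; fr <- rows$frame[r]
    if (s < 1L || e > L || s > e) stop("CDS annotation outside alignment bounds")
    first <- s + fr
    starts <- seq(first, e - 2L, by = 3L)
    for (cs in starts) {
      codon <- paste(cons[cs:(cs + 2L)], collapse = "")
      if (grepl("[^ACGT]", codon)) {
        lab[cs:(cs + 2L)] <- "unassigned"
        w[cs:(cs + 2L)] <- NA_real_
        next
      }
      for (p in 0:2) {
        f <- .syn_fraction(codon, p + 1L)
        w[cs + p] <- f
        lab[cs + p] <- if (f >= 0.5) "silent" else "nonsynonymous"
      }
    }
    # positions in the CDS but not part of a complete codon stay unassigned
    partial <- setdiff(s:e, as.vector(outer(starts, 0:2, `+`)))
    if (length(partial)) {
      lab[partial] <- "unassigned"
      w[partial] <- NA_real_
    }
  }
  alignment$site_classes <- lab
  alignment$silent_weight <- w
  alignment
}

#' Concatenate loci of one genome
#'
#' Loci tagged with `genome` are joined side by side over their shared
#' samples; samples missing from any member locus are dropped with a warning.
#'
#' @param dataset a [multilocus_dataset()].
#' @param genome genome tag to concatenate.
#' @return a [locus_alignment()] whose `$boundaries` records the 1-based end
#'   column of each member locus.
#' @export
concatenate_loci <- function(dataset, genome = "nuclear") {
  sel <- dataset$loci[dataset$genome == genome]
  if (!length(sel)) stop("no loci tagged '", genome, "'")
  shared <- Reduce(intersect, lapply(sel, sample_ids))
  if (!length(shared)) stop("no samples shared across '", genome, "' loci")
  dropped <- setdiff(unique(unlist(lapply(sel, sample_ids))), shared)
  if (length(dropped))
    warning("dropping ", length(dropped),
            " sample(s) missing from some loci: ",
            paste(head(dropped, 3L), collapse = ", "))
  mats <- lapply(sel, function(l) l$seqs[shared, , drop = FALSE])
  out <- locus_alignment(paste0("concat_", genome), do.call(cbind, mats))
  cls <- lapply(sel, `[[`, "site_classes")
  if (!any(vapply(cls, is.null, TRUE)))
    out$site_classes <- unlist(cls, use.names = FALSE)
  out$boundaries <- cumsum(vapply(sel, `[[`, 0L, "L"))
  out
}

# integer coding for the distance kernels: A,C,G,T -> 1..4, else 0 (missing).
# Gaps are treated as missing for site statistics (pairwise deletion).
.encode_alignment <- function(seqs) {
  code <- matrix(match(seqs, c("A", "C", "G", "T"), nomatch = 0L),
                 nrow = nrow(seqs), dimnames = dimnames(seqs))
  code
}
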