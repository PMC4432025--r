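# Study-shaped synthetic datasets with known ground truth.
#
# The template mirrors the sampling design of the real four-species study:
# 11 unlinked nuclear loci totalling 4,986 bp sampled as phased haplotypes
# (60/98/100/72 sequences for SCH/SMI/LIK/WIL), three chloroplast and two
# mitochondrial loci sampled as haploid organelle haplotypes (53/49/91/86),
# and two outgroup sequences per locus for polarization.  Organelle loci
# within a genome share one non-recombining genealogy simulated at half the
# nuclear effective size (uniparental inheritance); the outgroup lineage
# diverges at 4 x T3 by default.

#' Study-shaped synthetic-data template
#'
#' @param truth named parameter vector (natural scale) of the generating
#'   four-species model; defaults to the prior midpoints of
#'   [default_spruce_priors()] with the requested gene flow.
#' @param gene_flow simulate with post-divergence migration?
#' @param nuclear_samples,organelle_samples named sequence counts per species.
#' @param nuclear_lengths lengths of the 11 nuclear loci (bp; default sums
#'   to 4,986).
#' @param cp_lengths,mt_lengths organelle locus lengths (bp).
#' @param mu per-site per-generation mutation rate.
#' @param outgroup_factor outgroup divergence as a multiple of `T3`.
#' @return object of class `study_template`.
#' @export
study_template <- function(truth = NULL, gene_flow = TRUE,
                           nuclear_samples = c(SCH = 60L, SMI = 98L,
                                               LIK = 100L, WIL = 72L),
                           organelle_samples = c(SCH = 53L, SMI = 49L,
                                                 LIK = 91L, WIL = 86L),
                           nuclear_lengths = c(501, 492, 480, 468, 462, 453,
                                               447, 441, 432, 411, 399),
                           cp_lengths = c(620, 540, 540),
                           mt_lengths = c(681, 680),
                           mu = 1.41e-8, outgroup_factor = 4) {
  if (is.null(truth))
    truth <- prior_midpoint(default_spruce_priors(gene_flow = gene_flow))
  stopifnot(all(nuclear_lengths > 0), all(cp_lengths > 0),
            all(mt_lengths > 0), outgroup_factor > 1)
  structure(list(truth = truth, gene_flow = gene_flow,
                 nuclear_samples = nuclear_samples,
                 organelle_samples = organelle_samples,
                 nuclear_lengths = nuclear_lengths,
                 cp_lengths = cp_lengths, mt_lengths = mt_lengths,
                 mu = mu, outgroup_factor = outgroup_factor),
            class = "study_template")
}

# extend a four-species model with an outgroup deme merging above the root
.with_outgroup <- function(model, t_out, n_out = 100) {
  sizes <- c(model$sizes, OUT = unname(n_out), ROOT = unname(n_out))
  times <- c(model$times, TOUT = unname(t_out))
  topology <- c(model$topology, list(TOUT = c(model$root, "OUT", "ROOT")))
  demographic_model(sizes, times, topology, model$migration)
}

# scale a model's population sizes (organelle effective size = factor x
# nuclear, default one half for uniparental haploid genomes)
.scale_sizes <- function(model, factor) {
  demographic_model(model$sizes * factor, model$times, model$topology,
                    model$migration)
}

# turn a 0/1 haplotype matrix into aligned sequences: a random ancestral
# sequence with each SNP assigned a distinct position and a random derived
# base (infinite sites)
.matrix_to_seqs <- function(M, length_bp, ids) {
  S <- ncol(M)
  if (S > length_bp)
    stop("more SNPs than sites; increase the locus length")
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, length_bp, replace = TRUE)
  pos <- sort(sample.int(length_bp, S))
  seqs <- matrix(rep(anc, each = nrow(M)), nrow = nrow(M),
                 dimnames = list(ids, NULL))
  for (s in seq_len(S)) {
    der <- sample(setdiff(bases, anc[pos[s]]), 1L)
    seqs[M[, s] == 1L, pos[s]] <- der
  }
  seqs
}

#' Generate a study-shaped synthetic dataset
#'
#' Simulates the full multilocus design under the template's generating
#' model: per-locus FASTA-ready alignments for nuclear, chloroplast and
#' mitochondrial genomes (organelle loci share one genealogy per genome at
#' half the nuclear effective size), two outgroup sequences per locus, a
#' sample-to-species map, and the ground-truth parameters.
#'
#' @param template a [study_template()].
#' @param seed RNG seed (same seed, same dataset).
#' @param dir optional output directory; when given, per-locus FASTA files,
#'   `species_map.tsv` and `truth.json` are written there.
#' @return list with `dataset` (a [multilocus_dataset()] including the
#'   outgroup samples) and `truth`.
#' @export
generate_study_like_dataset <- function(template, seed = NULL, dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- template$truth
  model <- spruce_model(truth, gene_flow = template$gene_flow)
  t_out <- template$outgroup_factor * unname(truth["T3"])
  species <- names(template$nuclear_samples)

  make_ids <- function(samples, prefix) {
    unlist(lapply(names(samples), function(sp)
      sprintf("%s_%s_%03d", prefix, sp, seq_len(samples[[sp]]))))
  }

  sim_genome <- function(samples, lengths, size_factor, shared, prefix) {
    m <- .scale_sizes(model, size_factor)
    m <- .with_outgroup(m, t_out, n_out = 100 * size_factor)
    samp <- c(samples, OUT = 2L)
    cfg <- loci_config(lengths, samp, template$mu)
    mats <- simulate_dataset(m, cfg, format = "matrices",
                             shared_genealogy = shared)
    ing_ids <- make_ids(samples, prefix)
    ids <- c(ing_ids, paste0(prefix, "_PBRE_001"), paste0(prefix, "_PMEY_001"))
    lapply(seq_along(mats), function(l)
      locus_alignment(paste0(prefix, "_locus", l),
                      .matrix_to_seqs(mats[[l]], lengths[l], ids)))
  }

  nuc <- sim_genome(template$nuclear_samples, template$nuclear_lengths,
                    1, FALSE, "nuc")
  cp <- sim_genome(template$organelle_samples, template$cp_lengths,
                   0.5, TRUE, "cp")
  mt <- sim_genome(template$organelle_samples, template$mt_lengths,
                   0.5, TRUE, "mt")

  all_ids <- unique(unlist(lapply(c(nuc, cp, mt), sample_ids)))
  sp_of <- sub("^[a-z]+_([A-Z]+)_.*$", "\\1", all_ids)
  mapping <- data.frame(sample_id = all_ids,
                        species = sp_of,
                        is_outgroup = sp_of %in% c("PBRE", "PMEY"))
  partition <- species_partition(mapping)
  dataset <- multilocus_dataset(
    c(nuc, cp, mt), partition,
    genome = rep(c("nuclear", "chloroplast", "mitochondrial"),
                 c(length(nuc), length(cp), length(mt))))

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (l in dataset$loci)
      write_locus_fasta(l, file.path(dir, paste0(l$locus_id, ".fasta")))
    write.table(mapping, file.path(dir, "species_map.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(dataset = dataset, truth = truth)
}

#' Observed summary vector and diversity report from a dataset
#'
#' Runs the same statistics pipeline on a (synthetic or real) dataset that
#' the ABC machinery expects for the observation: the nuclear summary vector
#' over the requested species plus a diversity-table report.
#'
#' @param dataset a [multilocus_dataset()].
#' @param species ordered species labels (default: all non-outgroup species).
#' @param registry statistic registry (default: full registry of `species`).
#' @return list with `vector` (a [summary_vector()]) and `table`
#'   (a [diversity_table()]).
#' @export
make_observed_vector <- function(dataset, species = NULL, registry = NULL) {
  if (is.null(species)) species <- species_labels(dataset$partition)
  if (is.null(registry)) registry <- stat_registry(species)
  # outgroups never enter the summary statistics
  keep <- dataset$partition$sample_id[!dataset$partition$is_outgroup]
  loci <- lapply(dataset$loci, function(l) {
    ids <- intersect(sample_ids(l), keep)
    locus_alignment(l$locus_id, l$seqs[ids, , drop = FALSE], l$site_classes)
  })
  ds <- multilocus_dataset(loci, dataset$partition, unname(dataset$genome))
  list(vector = summary_vector(ds, species, registry),
       table = diversity_table(ds))
}
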