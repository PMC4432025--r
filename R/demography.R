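# Demographic models for the structured coalescent: a set of present-day
# demes that merge pairwise at divergence times, with optional symmetric
# migration (in migrants per generation, Nm) between designated pairs of
# coexisting demes.  Population sizes are diploid individuals; times are in
# generations.

#' Construct a demographic model
#'
#' @param sizes named numeric vector of diploid population sizes: one entry
#'   per present-day deme and one per ancestral deme created by a merge.
#' @param times named numeric vector of divergence times (generations),
#'   strictly increasing in the order given.
#' @param topology named list, one entry per time (same order): each is
#'   `c(demeA, demeB, ancestor)` stating that `demeA` and `demeB` merge into
#'   `ancestor` at that time.  Ancestor labels can be reused in later merges.
#' @param migration optional named numeric vector of symmetric migrant
#'   numbers per generation, names of the form `"A~B"`; migration is active
#'   in every epoch during which both demes exist.
#' @return object of class `demographic_model`.
#' @export
demographic_model <- function(sizes, times = numeric(0), topology = list(),
                              migration = NULL) {
  stopifnot(!is.null(names(sizes)), length(topology) == length(times))
  if (any(sizes <= 0)) stop("population sizes must be positive")
  if (length(times)) {
    stopifnot(!is.null(names(times)))
    if (any(diff(times) <= 0) || any(times <= 0))
      stop("divergence times must be positive and strictly increasing")
  }
  if (!length(topology)) {
    if (length(sizes) != 1L)
      stop("a model without divergence events must have a single deme")
    return(structure(list(sizes = sizes, times = numeric(0),
                          topology = list(), migration = migration,
                          present = names(sizes), root = names(sizes)),
                     class = "demographic_model"))
  }
  if (!is.null(migration) && any(migration < 0))
    stop("migration rates must be non-negative")
  present <- character(0)
  active <- character(0)
  # reconstruct the present-day demes by walking merges
  all_named <- unique(unlist(lapply(topology, function(m) m[1:2])))
  ancestors <- vapply(topology, `[`, "", 3L)
  present <- setdiff(all_named, ancestors)
  missing_sizes <- setdiff(c(present, ancestors), names(sizes))
  if (length(missing_sizes))
    stop("missing population sizes for: ",
         paste(missing_sizes, collapse = ", "))
  # validate the merge sequence
  active <- present
  for (i in seq_along(topology)) {
    m <- topology[[i]]
    if (!all(m[1:2] %in% active))
      stop("merge ", i, " references inactive deme(s): ",
           paste(setdiff(m[1:2], active), collapse = ", "))
    active <- c(setdiff(active, m[1:2]), m[3L])
  }
  if (length(active) != 1L)
    stop("model must end in a single ancestral deme")
  if (!is.null(migration)) {
    prs <- strsplit(names(migration), "~", fixed = TRUE)
    bad <- vapply(prs, function(p)
      length(p) != 2L || !all(p %in% c(present, ancestors)), TRUE)
    if (any(bad)) stop("malformed migration pair names")
  }
  structure(list(sizes = sizes, times = times, topology = topology,
                 migration = migration, present = present,
                 root = active),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model> ", length(x$present), " present-day demes (",
      paste(x$present, collapse = ", "), ")\n", sep = "")
  for (i in seq_along(x$topology)) {
    m <- x$topology[[i]]
    cat("  ", names(x$times)[i], " = ", format(x$times[i], big.mark = ","),
        " gen: ", m[1L], " + ", m[2L], " -> ", m[3L], "\n", sep = "")
  }
  if (!is.null(x$migration) && any(x$migration > 0)) {
    on <- x$migration[x$migration > 0]
    cat("  migration (Nm): ",
        paste(names(on), signif(on, 3), sep = " = ", collapse = ", "),
        "\n", sep = "")
  } else cat("  no migration\n")
  invisible(x)
}

#' Four-species divergence model
#'
#' The default speciation scenario for the SCH/SMI/LIK/WIL species set:
#' SCH and SMI merge at `T1` into ancestor `N2`, LIK and WIL merge at `T2`
#' into `N1`, and the two ancestors merge at `T3` into `N3`.  With
#' `gene_flow = TRUE` symmetric migration links SCH~SMI, LIK~WIL and N1~N2
#' whenever both demes coexist (the gene-flow variant); otherwise all
#' migration is zero (the isolation variant).
#'
#' @param params named numeric vector with entries `NSCH, NSMI, NL, NW, N1,
#'   N2, N3` (diploid sizes), `T1 < T2 < T3` (generations) and, when
#'   `gene_flow = TRUE`, either a single `Nm` (shared by all three
#'   connections) or `Nm_SCH_SMI`, `Nm_LIK_WIL`, `Nm_N1_N2`.
#' @param gene_flow include post-divergence migration?
#' @return a [demographic_model()].
#' @export
spruce_model <- function(params, gene_flow = FALSE) {
  need <- c("NSCH", "NSMI", "NL", "NW", "N1", "N2", "N3", "T1", "T2", "T3")
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "))
  sizes <- c(SCH = unname(params["NSCH"]), SMI = unname(params["NSMI"]),
             LIK = unname(params["NL"]), WIL = unname(params["NW"]),
             N1 = unname(params["N1"]), N2 = unname(params["N2"]),
             N3 = unname(params["N3"]))
  times <- c(T1 = unname(params["T1"]), T2 = unname(params["T2"]),
             T3 = unname(params["T3"]))
  migration <- NULL
  if (gene_flow) {
    if ("Nm" %in% names(params)) {
      nm <- rep(unname(params["Nm"]), 3L)
    } else {
      need_nm <- c("Nm_SCH_SMI", "Nm_LIK_WIL", "Nm_N1_N2")
      miss <- setdiff(need_nm, names(params))
      if (length(miss))
        stop("missing migration parameters: ", paste(miss, collapse = ", "))
      nm <- unname(params[need_nm])
    }
    migration <- setNames(nm, c("SCH~SMI", "LIK~WIL", "N1~N2"))
  }
  demographic_model(
    sizes, times,
    topology = list(T1 = c("SCH", "SMI", "N2"),
                    T2 = c("LIK", "WIL", "N1"),
                    T3 = c("N2", "N1", "N3")),
    migration = migration)
}

#' Three-species divergence model
#'
#' Generic two-merge model used by the stepwise topology tests: `pair`
#' merges first (at `Ta`, into ancestor `A1`), the remaining species joins at
#' `Tb` (into root `A2`).  Optional symmetric migration within the first pair
#' and between `A1` and the third species.
#'
#' @param species character vector of the three species labels.
#' @param pair length-2 subset of `species` merging first.
#' @param params named vector: `N_<sp>` per species, `NA1`, `NA2`, `Ta < Tb`,
#'   optional `Nm`.
#' @param gene_flow include migration?
#' @return a [demographic_model()].
#' @export
three_taxon_model <- function(species, pair, params, gene_flow = FALSE) {
  stopifnot(length(species) == 3L, all(pair %in% species))
  third <- setdiff(species, pair)
  sizes <- setNames(unname(params[paste0("N_", species)]), species)
  sizes <- c(sizes, A1 = unname(params["NA1"]), A2 = unname(params["NA2"]))
  times <- c(Ta = unname(params["Ta"]), Tb = unname(params["Tb"]))
  migration <- NULL
  if (gene_flow) {
    nm <- unname(params["Nm"])
    migration <- setNames(c(nm, nm),
                          c(paste(pair[1L], pair[2L], sep = "~"),
                            paste("A1", third, sep = "~")))
  }
  demographic_model(
    sizes, times,
    topology = list(Ta = c(pair[1L], pair[2L], "A1"),
                    Tb = c("A1", third, "A2")),
    migration = migration)
}

#' Per-locus simulation configuration
#'
#' @param lengths numeric vector of locus lengths (bp).
#' @param samples named integer vector: sampled sequences per species
#'   (haploid lineage counts).
#' @param mu per-site per-generation mutation rate.
#' @return object of class `loci_config`.
#' @export
loci_config <- function(lengths, samples, mu = 1.41e-8) {
  stopifnot(all(lengths > 0), mu >= 0, all(samples >= 1),
            !is.null(names(samples)))
  structure(list(lengths = lengths, samples = samples, mu = mu),
            class = "loci_config")
}

# Flatten a demographic model into the epoch arrays consumed by the C++
# engine.  Deme slots follow the order of `samples`; species sampled must be
# present-day demes of the model.
.compile_demography <- function(model, samples) {
  species <- names(samples)
  if (!all(species %in% model$present))
    stop("sampled species not in model: ",
         paste(setdiff(species, model$present), collapse = ", "))
  slots <- model$present
  # sampled demes first so leaf ordering is predictable
  slots <- c(species, setdiff(slots, species))
  k <- length(slots)
  nE <- length(model$times) + 1L
  sizes <- matrix(1, nE, k)
  mig <- array(0, c(nE, k, k))
  label <- slots  # active label per slot, updated through merges
  ev_from <- ev_to <- integer(nE - 1L)
  for (e in seq_len(nE)) {
    for (s in seq_len(k))
      if (!is.na(label[s])) sizes[e, s] <- model$sizes[[label[s]]]
    if (!is.null(model$migration)) {
      for (nm in names(model$migration)) {
        p <- strsplit(nm, "~", fixed = TRUE)[[1L]]
        i <- match(p[1L], label)
        j <- match(p[2L], label)
        if (!is.na(i) && !is.na(j) && model$migration[[nm]] > 0) {
          # backward per-lineage rate out of the deme the lineage occupies
          mig[e, i, j] <- model$migration[[nm]] / (2 * sizes[e, i])
          mig[e, j, i] <- model$migration[[nm]] / (2 * sizes[e, j])
        }
      }
    }
    if (e < nE) {
      m <- model$topology[[e]]
      i <- match(m[1L], label)
      j <- match(m[2L], label)
      if (is.na(i) || is.na(j)) stop("merge references inactive deme")
      # move lineages from slot j into slot i; slot i becomes the ancestor
      ev_from[e] <- j - 1L
      ev_to[e] <- i - 1L
      label[j] <- NA_character_
      label[i] <- m[3L]
    }
  }
  samp <- integer(k)
  samp[seq_along(samples)] <- unname(samples)
  leaf_group <- rep(seq_along(samples) - 1L, unname(samples))
  list(samp = samp, sizes = sizes, mig = as.vector(aperm(mig, c(3L, 2L, 1L))),
       ev_time = unname(model$times), ev_from = ev_from, ev_to = ev_to,
       leaf_group = leaf_group, species = species)
}

#' Simulate genealogies under a demographic model
#'
#' Independent structured-coalescent genealogies (one per replicate):
#' within-deme coalescence at rate \eqn{1/(2N)} per pair per generation,
#' migration as exponential lineage movements, demes merging at the
#' divergence times.
#'
#' @param model a [demographic_model()].
#' @param config a [loci_config()] (only `samples` is used).
#' @param reps number of genealogies.
#' @param seed optional RNG seed.
#' @param summaries_only if `TRUE` (default) return a matrix of TMRCA and
#'   total branch length per replicate; otherwise a list of trees
#'   (`parent`, `time`, `n_leaves`, plus the species of each leaf).
#' @return matrix or list, see `summaries_only`.
#' @export
simulate_genealogies <- function(model, config, reps = 1L, seed = NULL,
                                 summaries_only = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  cd <- .compile_demography(model, config$samples)
  if (summaries_only) {
    .cpp_tree_summaries(cd$samp, cd$sizes, cd$mig, cd$ev_time, cd$ev_from,
                        cd$ev_to, as.integer(reps))
  } else {
    lapply(seq_len(reps), function(i) {
      tr <- .cpp_sim_tree(cd$samp, cd$sizes, cd$mig, cd$ev_time, cd$ev_from,
                          cd$ev_to)
      tr$leaf_species <- cd$species[cd$leaf_group + 1L]
      tr
    })
  }
}

#' Simulate a multilocus SNP dataset
#'
#' Unlinked loci: each locus receives an independent genealogy (or, with
#' `shared_genealogy = TRUE`, all loci reuse one genealogy, as appropriate
#' for non-recombining uniparental genomes).  Mutations are Poisson with
#' mean `mu * length * total branch length` and dropped uniformly on
#' branches; every mutation creates a new biallelic site (infinite sites).
#'
#' @param model a [demographic_model()].
#' @param config a [loci_config()].
#' @param seed optional RNG seed (same seed, same data).
#' @param format `"matrices"` for per-locus 0/1 haplotype matrices (rows in
#'   species block order) or `"counts"` for a single per-species
#'   derived-count matrix over all SNPs (the fast path feeding
#'   [summary_vector()]).
#' @param shared_genealogy reuse one genealogy across loci?
#' @return list of matrices with a `species` attribute, or a counts matrix
#'   with rownames = species and attribute `n_sp`.
#' @export
simulate_dataset <- function(model, config, seed = NULL,
                             format = c("matrices", "counts"),
                             shared_genealogy = FALSE) {
  format <- match.arg(format)
  if (!is.null(seed)) set.seed(seed)
  cd <- .compile_demography(model, config$samples)
  mu_l <- config$mu * config$lengths
  if (format == "counts") {
    K <- .cpp_sim_counts(cd$samp, cd$sizes, cd$mig, cd$ev_time, cd$ev_from,
                         cd$ev_to, cd$leaf_group, length(config$samples),
                         mu_l, shared_genealogy)
    rownames(K) <- cd$species
    attr(K, "n_sp") <- unname(config$samples)
    K
  } else {
    ml <- .cpp_sim_matrices(cd$samp, cd$sizes, cd$mig, cd$ev_time, cd$ev_from,
                            cd$ev_to, mu_l, shared_genealogy)
    sp <- cd$species[cd$leaf_group + 1L]
    ml <- lapply(ml, function(m) {
      attr(m, "species") <- sp
      m
    })
    names(ml) <- paste0("locus", seq_along(ml))
    ml
  }
}
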