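# Likelihood-free inference: calibration simulations, ABC-MCMC with a
# distance threshold in PLS space, GLM (linear regression) posterior
# adjustment, HPDI summaries, Bayes-factor model comparison and the stepwise
# topology-selection driver.

#' Build a simulator closure for ABC
#'
#' Binds a model constructor, sampling design and statistic registry into a
#' function mapping a named parameter vector (natural scale) to a raw
#' summary-statistic vector, the unit of work of every ABC step.
#'
#' @param model_fn function taking named natural-scale parameters and
#'   returning a [demographic_model()] (e.g. a wrapper around
#'   [spruce_model()]).
#' @param config a [loci_config()].
#' @param registry a [stat_registry()] whose species match `config$samples`.
#' @return function `f(params)` returning a named statistic vector.
#' @export
make_simulator <- function(model_fn, config, registry) {
  species <- attr(registry, "species")
  stopifnot(identical(species, names(config$samples)))
  n_sp <- unname(config$samples)
  mu_l <- config$mu * config$lengths
  function(params) {
    model <- model_fn(params)
    cd <- .compile_demography(model, config$samples)
    K <- .cpp_sim_counts(cd$samp, cd$sizes, cd$mig, cd$ev_time, cd$ev_from,
                         cd$ev_to, cd$leaf_group, length(species), mu_l,
                         FALSE)
    .sumstats_from_counts(.counts_from_sim(K, n_sp), n_sp, registry)
  }
}

#' Calibration simulations from the prior
#'
#' @param simulator a [make_simulator()] closure.
#' @param priors a [prior_spec()].
#' @param n number of simulations.
#' @param seed optional RNG seed.
#' @return list with `params` (n x p, log10) and `stats` (n x s, raw).
#' @export
abc_calibrate <- function(simulator, priors, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- sample_prior(priors, n)
  first <- simulator(10^params[1L, ])
  stats <- matrix(NA_real_, n, length(first),
                  dimnames = list(NULL, names(first)))
  stats[1L, ] <- as.numeric(first)
  for (i in seq_len(n)[-1L])
    stats[i, ] <- as.numeric(simulator(10^params[i, ]))
  list(params = params, stats = stats)
}

# truncated-normal proposal helpers (componentwise, box truncation)
.rtnorm1 <- function(m, s, lo, hi) {
  for (i in 1:100) {
    x <- rnorm(1L, m, s)
    if (x >= lo && x <= hi) return(x)
  }
  runif(1L, lo, hi)
}

.tnorm_mass <- function(m, s, lo, hi) {
  stats::pnorm(hi, m, s) - stats::pnorm(lo, m, s)
}

#' ABC-MCMC sampler
#'
#' A Markov chain over the parameters: proposals are componentwise truncated
#' normals inside the prior box with standard deviation `phi/10` of the
#' prior width; a proposal is accepted iff (a) its simulated statistics lie
#' within the tolerance -- Euclidean distance in PLS space no greater than
#' the `delta`-quantile of the calibration distances to the observed vector
#' -- and (b) a Metropolis-Hastings draw on the prior ratio (including the
#' truncation correction) passes.  The chain starts at the calibration
#' sample closest to the observation.
#'
#' @param observed raw observed summary-statistic vector (registry order).
#' @param simulator a [make_simulator()] closure.
#' @param priors a [prior_spec()].
#' @param transform a [fit_pls()] transform (fitted on the calibration set).
#' @param calib the calibration list from [abc_calibrate()].
#' @param n_steps chain length (one simulation per step).
#' @param phi proposal-range scale.
#' @param delta tolerance quantile in (0, 1].
#' @param n_retain how many of the visited simulations to retain for the
#'   GLM stage (closest by distance).
#' @param seed optional RNG seed (same seed, same chain).
#' @return object of class `abc_posterior`.
#' @export
abc_mcmc <- function(observed, simulator, priors, transform, calib,
                     n_steps = 20000L, phi = 1, delta = 0.01,
                     n_retain = 1000L, seed = NULL) {
  stopifnot(delta > 0, delta <= 1)
  if (!is.null(seed)) set.seed(seed)
  obs_p <- pls_project(transform, as.numeric(observed))
  calib_p <- pls_project(transform, calib$stats)
  dcal <- sqrt(rowSums(sweep(calib_p, 2L, obs_p)^2))
  eps <- unname(quantile(dcal, delta))
  p <- nrow(priors)
  lo <- priors$lo; hi <- priors$hi
  sdv <- phi * (hi - lo) / 10
  cur <- calib$params[which.min(dcal), ]
  cur_d <- min(dcal)
  if (cur_d > eps) {
    # rare: the closest calibration point sits outside the tolerance; pull
    # the threshold up to it so the chain can start
    eps <- cur_d
  }
  pars <- matrix(NA_real_, n_steps, p, dimnames = list(NULL, rownames(priors)))
  dist <- numeric(n_steps)
  acc <- logical(n_steps)
  prop_pars <- matrix(NA_real_, n_steps, p,
                      dimnames = list(NULL, rownames(priors)))
  prop_stats <- matrix(NA_real_, n_steps, ncol(calib_p))
  prop_dist <- rep(NA_real_, n_steps)
  n_acc <- 0L
  for (it in seq_len(n_steps)) {
    prop <- vapply(seq_len(p), function(j)
      .rtnorm1(cur[j], sdv[j], lo[j], hi[j]), 0)
    names(prop) <- rownames(priors)
    if (is.finite(.prior_logdens(priors, prop))) {
      s <- simulator(10^prop)
      sp <- pls_project(transform, as.numeric(s))
      d <- sqrt(sum((sp - obs_p)^2))
      prop_pars[it, ] <- prop
      prop_stats[it, ] <- sp
      prop_dist[it] <- d
      # Hastings correction for the box-truncated proposals
      lhr <- sum(log(.tnorm_mass(cur, sdv, lo, hi)) -
                   log(.tnorm_mass(prop, sdv, lo, hi)))
      if (d <= eps && log(runif(1L)) <= lhr) {
        cur <- prop
        cur_d <- d
        acc[it] <- TRUE
        n_acc <- n_acc + 1L
      }
    }
    pars[it, ] <- cur
    dist[it] <- cur_d
    if (it == 10L * n_retain && n_acc == 0L)
      stop("ABC-MCMC: no acceptances in ", it, " steps; ",
           "check the tolerance and the observed statistics")
  }
  # retained pool for the GLM stage: the closest simulated proposals
  ok <- which(!is.na(prop_dist))
  ret_idx <- ok[order(prop_dist[ok])][seq_len(min(n_retain, length(ok)))]
  out <- list(params = pars, distances = dist, accepted = acc,
              retained_params = prop_pars[ret_idx, , drop = FALSE],
              retained_stats = prop_stats[ret_idx, , drop = FALSE],
              retained_dist = prop_dist[ret_idx],
              obs_pls = obs_p, eps = eps, delta = delta, phi = phi,
              priors = priors, transform = transform,
              acceptance_rate = n_acc / n_steps, method = "mcmc",
              adjusted = NULL, weights = NULL)
  class(out) <- "abc_posterior"
  out
}

#' Rejection ABC over a simulation pool
#'
#' Retains the `n_retain` pool simulations closest to the observation in
#' PLS space; the same retained-sample object feeds [glm_adjust()] and
#' [bayes_factor()].
#'
#' @inheritParams abc_mcmc
#' @param pool list with `params` and `stats` (e.g. [abc_calibrate()]).
#' @return object of class `abc_posterior`.
#' @export
abc_reject <- function(observed, pool, priors, transform, n_retain = 1000L) {
  obs_p <- pls_project(transform, as.numeric(observed))
  pool_p <- pls_project(transform, pool$stats)
  d <- sqrt(rowSums(sweep(pool_p, 2L, obs_p)^2))
  idx <- order(d)[seq_len(min(n_retain, length(d)))]
  out <- list(params = pool$params, distances = d, accepted = NULL,
              retained_params = pool$params[idx, , drop = FALSE],
              retained_stats = pool_p[idx, , drop = FALSE],
              retained_dist = d[idx],
              obs_pls = obs_p, eps = max(d[idx]), delta = NA_real_,
              phi = NA_real_, priors = priors, transform = transform,
              acceptance_rate = length(idx) / length(d), method = "rejection",
              adjusted = NULL, weights = NULL)
  class(out) <- "abc_posterior"
  out
}

#' GLM (local-linear) posterior adjustment
#'
#' Regresses the retained parameters on the retained PLS statistics and
#' shifts every draw to the observed statistic value
#' (\eqn{\theta^* = \theta - B (s - s_{obs})}), the standard ABC regression
#' adjustment.  Adjusted draws are clipped to the prior box; Epanechnikov
#' weights on distance are attached.  A singular design falls back to the
#' unadjusted draws with a warning.
#'
#' @param posterior an `abc_posterior`.
#' @return the posterior with `$adjusted` and `$weights` filled.
#' @export
glm_adjust <- function(posterior) {
  th <- posterior$retained_params
  st <- posterior$retained_stats
  if (nrow(th) < 100L)
    stop("need at least 100 retained draws for the GLM adjustment")
  X <- cbind(1, st)
  B <- tryCatch(qr.solve(X, th), error = function(e) NULL)
  if (is.null(B) || any(!is.finite(B))) {
    warning("singular GLM design; returning unadjusted draws")
    posterior$adjusted <- th
    posterior$weights <- rep(1, nrow(th))
    return(posterior)
  }
  obs <- as.numeric(posterior$obs_pls)
  shift <- (st - matrix(obs, nrow(st), ncol(st), byrow = TRUE)) %*%
    B[-1L, , drop = FALSE]
  adj <- th - shift
  # clip to prior support
  lo <- posterior$priors$lo; hi <- posterior$priors$hi
  for (j in seq_len(ncol(adj)))
    adj[, j] <- pmin(pmax(adj[, j], lo[j]), hi[j])
  d <- posterior$retained_dist
  eps <- max(d) * (1 + 1e-12)
  posterior$adjusted <- adj
  posterior$weights <- pmax(1 - (d / eps)^2, 1e-8)
  posterior
}

#' Posterior summaries with time conversion
#'
#' Kernel-density posterior modes and highest-posterior-density intervals
#' for every parameter, on the log10 and natural scales.  Divergence-time
#' parameters (names starting with `"T"`) are additionally reported in years
#' (`gen_time` years per generation) and in million years, with a
#' mutation-rate sensitivity band obtained by rescaling the point estimate
#' to the slow and fast rates in `mu_interval` (time estimates scale as
#' `mu / mu_alt`).
#'
#' @param posterior an `abc_posterior` (GLM-adjusted draws are used when
#'   present).
#' @param level HPDI mass.
#' @param mu reference per-site per-generation mutation rate.
#' @param gen_time generation time in years.
#' @param mu_interval slow/fast mutation-rate bounds for the sensitivity
#'   band.
#' @return data frame, one row per parameter.
#' @export
summarize_posterior <- function(posterior, level = 0.95, mu = 1.41e-8,
                                gen_time = 50,
                                mu_interval = c(1.11e-8, 1.71e-8)) {
  draws <- if (!is.null(posterior$adjusted)) posterior$adjusted
           else posterior$retained_params
  if (nrow(draws) < 100L) stop("need at least 100 draws to summarize")
  w <- posterior$weights
  out <- lapply(colnames(draws), function(pn) {
    x <- draws[, pn]
    md <- posterior_mode(x, w)
    hp <- hpdi(x, level, w)
    row <- data.frame(parameter = pn, mode_log10 = md, mode = 10^md,
                      hpdi_lo = 10^hp[1L], hpdi_hi = 10^hp[2L])
    if (startsWith(pn, "T")) {
      row$mode_myr <- 10^md * gen_time / 1e6
      row$hpdi_lo_myr <- 10^hp[1L] * gen_time / 1e6
      row$hpdi_hi_myr <- 10^hp[2L] * gen_time / 1e6
      row$mode_myr_slow <- row$mode_myr * mu / mu_interval[1L]
      row$mode_myr_fast <- row$mode_myr * mu / mu_interval[2L]
    } else {
      row$mode_myr <- row$hpdi_lo_myr <- row$hpdi_hi_myr <- NA_real_
      row$mode_myr_slow <- row$mode_myr_fast <- NA_real_
    }
    row
  })
  do.call(rbind, out)
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat("<abc_posterior> (", x$method, "), ", nrow(x$retained_params),
      " retained draws", sep = "")
  if (x$method == "mcmc")
    cat(", acceptance rate ", signif(x$acceptance_rate, 3), sep = "")
  cat(if (is.null(x$adjusted)) ", unadjusted\n" else ", GLM-adjusted\n")
  invisible(x)
}

#' @export
summary.abc_posterior <- function(object, level = 0.95, ...) {
  summarize_posterior(object, level = level, ...)
}

#' @export
coef.abc_posterior <- function(object, ...) {
  s <- summarize_posterior(object)
  setNames(s$mode, s$parameter)
}

#' @export
plot.abc_posterior <- function(x, parameters = NULL, ...) {
  draws <- if (!is.null(x$adjusted)) x$adjusted else x$retained_params
  if (is.null(parameters)) parameters <- colnames(draws)
  old <- par(mfrow = c(ceiling(length(parameters) / 3), min(3, length(parameters))),
             mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (pn in parameters) {
    d <- density(draws[, pn])
    plot(d, main = pn, xlab = "log10 value",
         xlim = c(x$priors[pn, "lo"], x$priors[pn, "hi"]), ...)
    abline(v = posterior_mode(draws[, pn], x$weights), lty = 2)
  }
  invisible(x)
}

# ABC-GLM marginal log-density of the observation under a model: average
# multivariate-normal likelihood of the observed PLS statistics over the
# retained draws' fitted statistic means, with the GLM residual covariance.
.glm_marginal_loglik <- function(posterior) {
  th <- posterior$retained_params
  st <- posterior$retained_stats
  obs <- as.numeric(posterior$obs_pls)
  X <- cbind(1, th)
  B <- tryCatch(qr.solve(X, st), error = function(e) NULL)
  if (is.null(B)) return(NA_real_)
  fitted <- X %*% B
  res <- st - fitted
  S <- crossprod(res) / (nrow(st) - ncol(X))
  S <- S + diag(1e-10 * max(diag(S)) + 1e-300, ncol(S))
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  logdet <- 2 * sum(log(diag(ch)))
  k <- ncol(st)
  dev <- sweep(fitted, 2L, obs)
  z <- backsolve(ch, t(dev), transpose = TRUE)
  ll <- -0.5 * (k * log(2 * pi) + logdet + colSums(z^2))
  .logsumexp(ll) - log(length(ll))
}

#' Bayes-factor model comparison
#'
#' Compares two models by the ratio of the marginal densities of the
#' observed statistics, each estimated from the model's retained-sample GLM
#' likelihood at the observed point.  Both posteriors must share the
#' statistic registry and PLS transform.  The conventional decision rule
#' calls the comparison in favour of X when `BF > threshold`.
#'
#' @param posteriorX,posteriorY `abc_posterior` objects for the two models,
#'   fitted to the same observation with the same transform.
#' @param threshold decision threshold (default 3).
#' @return object of class `model_comparison`: `log_ml_x`, `log_ml_y`,
#'   `bf` (X over Y), `decision`.
#' @export
bayes_factor <- function(posteriorX, posteriorY, threshold = 3) {
  lx <- .glm_marginal_loglik(posteriorX)
  ly <- .glm_marginal_loglik(posteriorY)
  if (is.na(lx) || is.na(ly) || (lx == -Inf && ly == -Inf)) {
    out <- list(log_ml_x = lx, log_ml_y = ly, bf = NA_real_,
                decision = "undecidable", threshold = threshold)
    class(out) <- "model_comparison"
    return(out)
  }
  bf <- exp(lx - ly)
  decision <- if (bf > threshold) "X"
              else if (bf < 1 / threshold) "Y"
              else "undecided"
  out <- list(log_ml_x = lx, log_ml_y = ly, bf = bf, decision = decision,
              threshold = threshold)
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> BF(X vs Y) = ", signif(x$bf, 4), " -> ",
      switch(x$decision, X = "X preferred", Y = "Y preferred",
             undecided = "undecided (BF <= threshold both ways)",
             "undecidable"), "\n", sep = "")
  invisible(x)
}

#' Stepwise four-species model selection
#'
#' Reproduces the sequential topology-testing design: (1) the three rooted
#' topologies of the first focal species with the two reference species,
#' (2) the same for the second focal species, (3) the placement of the two
#' focal species against the reference clade, (4) gene flow versus none on
#' the winning topology.  Each step simulates a reference pool per candidate
#' under shared priors, projects through a PLS transform fitted on the
#' pooled calibration, and ranks candidates by ABC-GLM marginal density;
#' a step is decided when the best candidate beats every rival with
#' `BF > threshold`, otherwise it is flagged unresolved and the
#' highest-density candidate carries forward.
#'
#' @param dataset a [multilocus_dataset()] (the observation).
#' @param config a [loci_config()] describing the simulated design (samples
#'   must cover the four species).
#' @param priors_3tax,priors_4tax [prior_spec()] objects for the 3-taxon and
#'   4-taxon steps; defaults are derived from [default_spruce_priors()].
#' @param n_pool simulations per candidate model per step.
#' @param n_retain retained simulations per candidate.
#' @param ncomp PLS components per step.
#' @param focal,reference focal species pair and reference species pair
#'   (defaults: SCH/SMI focal, LIK/WIL reference).
#' @param threshold Bayes-factor decision threshold.
#' @param seed RNG seed.
#' @return object of class `stepwise_selection`: per-step tables and the
#'   final model choice.
#' @export
stepwise_model_selection <- function(dataset, config,
                                     priors_3tax = NULL, priors_4tax = NULL,
                                     n_pool = 2000L, n_retain = 200L,
                                     ncomp = 8L,
                                     focal = c("SCH", "SMI"),
                                     reference = c("LIK", "WIL"),
                                     threshold = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  part <- dataset$partition
  if (is.null(priors_4tax)) priors_4tax <- default_spruce_priors(TRUE)
  steps <- list()

  rank_models <- function(observed, sims, registry) {
    # sims: named list of pools; shared PLS transform from the pooled stats
    # (parameters restricted to the columns common to all candidates, since
    # e.g. the gene-flow variant has an extra migration parameter)
    common <- Reduce(intersect, lapply(sims, function(s) colnames(s$params)))
    all_stats <- do.call(rbind, lapply(sims, `[[`, "stats"))
    all_params <- do.call(rbind, lapply(sims, function(s)
      s$params[, common, drop = FALSE]))
    tr <- fit_pls(all_stats, all_params, ncomp = min(ncomp, ncol(all_stats) - 1L))
    posts <- lapply(sims, function(s)
      abc_reject(observed, s, attr(s, "priors"), tr, n_retain))
    ml <- vapply(posts, .glm_marginal_loglik, 0)
    ord <- order(ml, decreasing = TRUE)
    best <- names(sims)[ord[1L]]
    bfs <- exp(ml[ord[1L]] - ml[-ord[1L]])
    resolved <- all(bfs > threshold)
    list(table = data.frame(model = names(sims), log_ml = ml,
                            bf_vs_best = exp(ml - ml[ord[1L]])),
         best = best, resolved = resolved, posteriors = posts)
  }

  run_3tax <- function(focal_sp) {
    trio <- c(focal_sp, reference)
    registry <- stat_registry(trio)
    observed <- summary_vector(dataset, trio, registry)
    cfg <- loci_config(config$lengths, config$samples[trio], config$mu)
    if (is.null(priors_3tax)) {
      pri <- prior_spec(list(N_1 = c(4.5, 5.2), N_2 = c(4.5, 5.2),
                             N_3 = c(4.5, 5.2), NA1 = c(4.0, 5.5),
                             NA2 = c(4.0, 5.5), Ta = c(5.0, 5.5),
                             Tb = c(5.4, 5.9)), ordered = c("Ta", "Tb"))
    } else pri <- priors_3tax
    pairs <- combn(trio, 2L, simplify = FALSE)
    sims <- lapply(pairs, function(pr) {
      sim <- make_simulator(function(th) {
        names(th)[1:3] <- paste0("N_", trio)
        three_taxon_model(trio, pr, th)
      }, cfg, registry)
      s <- abc_calibrate(sim, pri, n_pool)
      attr(s, "priors") <- pri
      s
    })
    names(sims) <- vapply(pairs, function(p)
      paste0("(", p[1L], ",", p[2L], ")"), "")
    r <- rank_models(observed, sims, registry)
    r$posteriors <- NULL
    r
  }

  steps$step1 <- run_3tax(focal[1L])
  steps$step2 <- run_3tax(focal[2L])

  # step 3: placement of the focal species against the reference clade
  species4 <- c(focal, reference)
  registry4 <- stat_registry(species4)
  observed4 <- summary_vector(dataset, species4, registry4)
  cfg4 <- loci_config(config$lengths, config$samples[species4], config$mu)
  pri_a <- default_spruce_priors(FALSE)
  topo_fns <- list(
    "focal_clade" = function(th) spruce_model(th, gene_flow = FALSE),
    "focal1_with_ref" = function(th) {
      # focal[1] joins the reference clade first, then focal[2]
      demographic_model(
        sizes = c(SCH = unname(th["NSCH"]), SMI = unname(th["NSMI"]),
                  LIK = unname(th["NL"]), WIL = unname(th["NW"]),
                  N1 = unname(th["N1"]), N2 = unname(th["N2"]),
                  N3 = unname(th["N3"])),
        times = c(T1 = unname(th["T1"]), T2 = unname(th["T2"]),
                  T3 = unname(th["T3"])),
        topology = list(T1 = c("LIK", "WIL", "N1"),
                        T2 = c("SCH", "N1", "N2"),
                        T3 = c("SMI", "N2", "N3")))
    },
    "focal2_with_ref" = function(th) {
      demographic_model(
        sizes = c(SCH = unname(th["NSCH"]), SMI = unname(th["NSMI"]),
                  LIK = unname(th["NL"]), WIL = unname(th["NW"]),
                  N1 = unname(th["N1"]), N2 = unname(th["N2"]),
                  N3 = unname(th["N3"])),
        times = c(T1 = unname(th["T1"]), T2 = unname(th["T2"]),
                  T3 = unname(th["T3"])),
        topology = list(T1 = c("LIK", "WIL", "N1"),
                        T2 = c("SMI", "N1", "N2"),
                        T3 = c("SCH", "N2", "N3")))
    })
  sims3 <- lapply(topo_fns, function(fn) {
    sim <- make_simulator(fn, cfg4, registry4)
    s <- abc_calibrate(sim, pri_a, n_pool)
    attr(s, "priors") <- pri_a
    s
  })
  steps$step3 <- rank_models(observed4, sims3, registry4)
  steps$step3$posteriors <- NULL

  # step 4: gene flow vs none on the winning (default) topology
  pri_b <- if (is.null(priors_4tax)) default_spruce_priors(TRUE) else priors_4tax
  sims4 <- list(
    isolation = {
      sim <- make_simulator(function(th) spruce_model(th, gene_flow = FALSE),
                            cfg4, registry4)
      s <- abc_calibrate(sim, pri_a, n_pool)
      attr(s, "priors") <- pri_a
      s
    },
    gene_flow = {
      sim <- make_simulator(function(th) spruce_model(th, gene_flow = TRUE),
                            cfg4, registry4)
      s <- abc_calibrate(sim, pri_b, n_pool)
      attr(s, "priors") <- pri_b
      s
    })
  steps$step4 <- rank_models(observed4, sims4, registry4)
  final_posts <- steps$step4$posteriors
  steps$step4$posteriors <- NULL

  out <- list(steps = steps,
              final_topology = steps$step3$best,
              final_gene_flow = steps$step4$best == "gene_flow",
              resolved = vapply(steps, `[[`, TRUE, "resolved"),
              final_posterior = final_posts[[steps$step4$best]])
  class(out) <- "stepwise_selection"
  out
}

#' @export
print.stepwise_selection <- function(x, ...) {
  cat("<stepwise_selection>\n")
  for (nm in names(x$steps)) {
    s <- x$steps[[nm]]
    cat("  ", nm, ": best = ", s$best,
        if (s$resolved) " (resolved)" else " (UNRESOLVED, carried forward)",
        "\n", sep = "")
  }
  cat("  final: topology ", x$final_topology, ", gene flow ",
      if (x$final_gene_flow) "yes" else "no", "\n", sep = "")
  invisible(x)
}
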