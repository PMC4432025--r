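test_that("prior draws respect bounds, ordering, and log10-uniformity", {
  pri <- default_spruce_priors(gene_flow = TRUE)
  x <- sample_prior(pri, 10000, seed = 1)
  expect_true(all(x[, "N1"] >= 4.5 & x[, "N1"] <= 5.7))
  expect_true(all(x[, "T1"] < x[, "T2"] & x[, "T2"] < x[, "T3"]))
  # a parameter whose bounds overlap only partially with the order
  # constraint is no longer marginally uniform, so test one that is: NSCH
  ks <- suppressWarnings(
    stats::ks.test(x[, "NSCH"], "punif", 4.5, 5.0)$p.value)
  expect_gt(ks, 0.01)
  # degenerate bound gives a constant
  pd <- prior_spec(list(A = c(2, 2 + 1e-12)))
  expect_true(all(abs(sample_prior(pd, 100, seed = 2)[, 1] - 2) < 1e-9))
})

test_that("PLS recovers a linear low-rank map and RMSE is monotone in components", {
  set.seed(4)
  n <- 600; p_stats <- 12; p_par <- 3
  theta <- matrix(runif(n * p_par), n, p_par,
                  dimnames = list(NULL, paste0("t", 1:p_par)))
  A <- matrix(rnorm(p_par * p_stats), p_par, p_stats)
  stats_m <- theta %*% A + matrix(rnorm(n * p_stats, sd = 0.05), n, p_stats)
  colnames(stats_m) <- paste0("s", 1:p_stats)
  tr <- fit_pls(stats_m, theta, ncomp = 8, boxcox = FALSE)
  # nesting monotonicity of in-sample RMSE
  expect_true(all(diff(tr$rmse) < 1e-10))
  # elbow at the true dimension: component 3 captures nearly everything
  expect_lt(tr$rmse[3], 0.1)
  expect_gt(tr$rmse[1] / tr$rmse[3], 2)
  # zero-variance statistics are dropped
  stats2 <- cbind(stats_m, const = 1)
  tr2 <- fit_pls(stats2, theta, ncomp = 8, boxcox = FALSE)
  expect_identical(tr2$dropped, "const")
  # ncomp beyond the usable rank errors
  expect_error(fit_pls(stats_m[, 1:4], theta, ncomp = 8, boxcox = FALSE),
               "ncomp")
  # projection of training rows equals training scores
  pr <- pls_project(tr, stats_m[1:5, ])
  expect_equal(dim(pr), c(5L, 8L))
})

test_that("stats independent of parameters give a flat RMSE curve", {
  set.seed(5)
  theta <- matrix(runif(400 * 2), 400, 2, dimnames = list(NULL, c("a", "b")))
  stats_m <- matrix(rnorm(400 * 6), 400, 6,
                    dimnames = list(NULL, paste0("s", 1:6)))
  tr <- fit_pls(stats_m, theta, ncomp = 5, boxcox = FALSE)
  expect_lt((tr$rmse[1] - tr$rmse[5]) / tr$rmse[1], 0.05)
})

# shared small ABC setup used by several blocks
abc_setup <- function(seed = 1, n_cal = 600, gene_flow = TRUE,
                      n_per_sp = 8L, n_loci = 5L) {
  pri <- default_spruce_priors(gene_flow = gene_flow)
  cfg <- test_config(n_per_sp = n_per_sp, n_loci = n_loci)
  reg <- stat_registry(test_species)
  sim <- make_simulator(function(th) spruce_model(th, gene_flow = gene_flow),
                        cfg, reg)
  cal <- abc_calibrate(sim, pri, n_cal, seed = seed)
  tr <- fit_pls(cal$stats, cal$params, ncomp = 8)
  list(pri = pri, cfg = cfg, reg = reg, sim = sim, cal = cal, tr = tr)
}

test_that("with delta = 1 the ABC-MCMC chain samples the prior", {
  s <- abc_setup(seed = 2, n_cal = 400)
  truth <- prior_midpoint(s$pri)
  obs <- s$sim(truth)
  post <- abc_mcmc(obs, s$sim, s$pri, s$tr, s$cal, n_steps = 4000,
                   phi = 2, delta = 1, n_retain = 400, seed = 3)
  expect_gt(post$acceptance_rate, 0.5)
  # marginals of unordered parameters match the prior; thin the chain so the
  # KS test sees approximately independent draws
  thin <- post$params[seq(25L, nrow(post$params), by = 25L), ]
  for (pn in c("NSCH", "NL", "N3")) {
    ks <- suppressWarnings(stats::ks.test(
      thin[, pn], "punif", s$pri[pn, "lo"], s$pri[pn, "hi"])$p.value)
    expect_gt(ks, 0.001)
  }
})

test_that("the chain is deterministic given a seed", {
  s <- abc_setup(seed = 4, n_cal = 300)
  obs <- s$sim(prior_midpoint(s$pri))
  p1 <- abc_mcmc(obs, s$sim, s$pri, s$tr, s$cal, n_steps = 300,
                 delta = 0.05, n_retain = 100, seed = 8)
  p2 <- abc_mcmc(obs, s$sim, s$pri, s$tr, s$cal, n_steps = 300,
                 delta = 0.05, n_retain = 100, seed = 8)
  expect_identical(p1$params, p2$params)
  expect_identical(p1$retained_dist, p2$retained_dist)
})

test_that("GLM adjustment shrinks posterior spread on a linear system and stays in the prior", {
  set.seed(6)
  # linear toy: stats = A theta + noise; observed at a known theta
  n <- 3000; p_par <- 3; p_stats <- 6
  pri <- prior_spec(setNames(rep(list(c(0, 1)), p_par),
                             paste0("t", 1:p_par)), ordered = character(0))
  theta <- sample_prior(pri, n, seed = 7)
  A <- matrix(rnorm(p_par * p_stats), p_par, p_stats)
  stats_m <- theta %*% A + matrix(rnorm(n * p_stats, sd = 0.1), n, p_stats)
  colnames(stats_m) <- paste0("s", 1:p_stats)
  tr <- fit_pls(stats_m, theta, ncomp = 4, boxcox = FALSE)
  truth <- c(t1 = 0.5, t2 = 0.5, t3 = 0.5)
  obs <- as.numeric(truth %*% A)
  names(obs) <- colnames(stats_m)
  pool <- list(params = theta, stats = stats_m)
  post <- abc_reject(obs, pool, pri, tr, n_retain = 500)
  adj <- glm_adjust(post)
  # adjusted draws never leave the prior box
  expect_true(all(adj$adjusted >= 0 & adj$adjusted <= 1))
  # regression adjustment reduces the spread around the truth
  for (j in 1:p_par) {
    expect_lte(var(adj$adjusted[, j]), var(post$retained_params[, j]))
  }
  # posterior mean lands near the truth
  expect_lt(max(abs(colMeans(adj$adjusted) - 0.5)), 0.1)
})

test_that("adjustment is a near-identity when stats carry no information", {
  set.seed(8)
  n <- 1000
  pri <- prior_spec(list(a = c(0, 1), b = c(0, 1)), ordered = character(0))
  theta <- sample_prior(pri, n)
  stats_m <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("s", 1:4)))
  tr <- fit_pls(stats_m, theta, ncomp = 3, boxcox = FALSE)
  obs <- setNames(rep(0, 4), paste0("s", 1:4))
  post <- abc_reject(obs, list(params = theta, stats = stats_m), pri, tr,
                     n_retain = 400)
  adj <- glm_adjust(post)
  expect_lt(max(abs(colMeans(adj$adjusted) -
                      colMeans(post$retained_params))), 0.05)
})

test_that("posterior summaries convert generations to years correctly", {
  set.seed(9)
  pri <- prior_spec(list(T1 = c(4.9, 5.1)))
  draws <- matrix(5.0, 200, 1, dimnames = list(NULL, "T1"))
  draws[, 1] <- draws[, 1] + rnorm(200, sd = 1e-6)
  post <- structure(list(retained_params = draws, adjusted = NULL,
                         weights = NULL, priors = pri),
                    class = "abc_posterior")
  s <- summarize_posterior(post, gen_time = 50)
  # 10^5 generations x 50 years = 5.0 Myr
  expect_equal(s$mode_myr, 5.0, tolerance = 1e-3)
  expect_equal(s$mode_myr_slow, 5.0 * 1.41 / 1.11, tolerance = 1e-3)
  expect_equal(s$mode_myr_fast, 5.0 * 1.41 / 1.71, tolerance = 1e-3)
})

test_that("HPDI behaves like the closed form for uniform draws and covers the mode", {
  set.seed(10)
  x <- runif(20000)
  hp <- hpdi(x, 0.95)
  expect_equal(hp[2] - hp[1], 0.95, tolerance = 0.02)
  # unimodal draws: mode near the mean (within kernel-density noise)
  y <- rnorm(5000, mean = 3)
  expect_lt(abs(posterior_mode(y) - 3), 0.25)
  # weighted version reduces to unweighted with equal weights
  hw <- hpdi(x, 0.95, w = rep(1, length(x)))
  expect_equal(hw, hp, tolerance = 0.01)
})

test_that("Bayes factors are reciprocal and equal 1 for identical models", {
  s <- abc_setup(seed = 12, n_cal = 500)
  obs <- s$sim(prior_midpoint(s$pri))
  postX <- abc_reject(obs, s$cal, s$pri, s$tr, n_retain = 200)
  bfXX <- bayes_factor(postX, postX)
  expect_equal(bfXX$bf, 1)
  # reciprocity on two different retained sets
  cal2 <- abc_calibrate(s$sim, s$pri, 500, seed = 13)
  postY <- abc_reject(obs, cal2, s$pri, s$tr, n_retain = 200)
  bfXY <- bayes_factor(postX, postY)
  bfYX <- bayes_factor(postY, postX)
  expect_equal(bfXY$bf * bfYX$bf, 1, tolerance = 1e-10)
})

test_that("summary vectors are order-invariant and registry mismatches error", {
  th <- prior_midpoint(default_spruce_priors())
  model <- spruce_model(th)
  cfg <- test_config(n_per_sp = 6L, n_loci = 3L)
  reg <- stat_registry(test_species)
  K <- simulate_dataset(model, cfg, seed = 33, format = "counts")
  sv <- summary_vector(K, test_species, reg, n_sp = attr(K, "n_sp"))
  # permuting SNP columns leaves the vector unchanged
  K2 <- K[, sample(ncol(K)), drop = FALSE]
  attr(K2, "n_sp") <- attr(K, "n_sp")
  sv2 <- summary_vector(K2, test_species, reg, n_sp = attr(K2, "n_sp"))
  expect_equal(unclass(sv), unclass(sv2))
  expect_error(summary_vector(K, rev(test_species), reg,
                              n_sp = attr(K, "n_sp")), "registry")
  # zero-variation input: S-type entries 0, undefined entries imputed at 0
  K0 <- matrix(integer(0), nrow = 4, ncol = 0)
  sv0 <- summary_vector(K0, test_species, reg, n_sp = rep(6L, 4))
  expect_true(all(sv0 == 0))
  expect_true(any(!attr(sv0, "defined")))
})
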