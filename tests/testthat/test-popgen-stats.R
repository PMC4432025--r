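test_that("segregating sites counts polymorphic columns within the subset", {
  a <- aln_from_strings(c("AAAA", "AAAA", "AAAA"))
  expect_equal(segregating_sites(a), 0L)
  # columns 1, 2, 4 polymorphic by hand
  b <- aln_from_strings(c("ACGT", "CCGA", "ACGA", "AGGT"))
  expect_equal(segregating_sites(b), 3L)
  # polymorphism only outside the subset is not counted
  expect_equal(segregating_sites(b, c("s1", "s3")), 1L)
  expect_error(segregating_sites(b, "s1"), "at least 2")
})

test_that("Watterson's estimator matches hand-computed values", {
  expect_equal(watterson_theta(0, 10, 100), 0)
  # a = 1 + 1/2 = 1.5 by hand
  expect_equal(watterson_theta(5, 3, 1000), 5 / (1.5 * 1000))
  expect_error(watterson_theta(5, 1, 100), "n >= 2")
})

test_that("nucleotide diversity equals the brute-force all-pairs oracle", {
  two <- aln_from_strings(c(paste0(strrep("A", 99), "C"), strrep("A", 100)))
  expect_equal(nucleotide_diversity(two), 0.01)
  same <- aln_from_strings(c("ACGT", "ACGT"))
  expect_equal(nucleotide_diversity(same), 0)
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    L <- sample(20:60, 1)
    m <- matrix(sample(c("A", "C", "G", "T", "N"), n * L, replace = TRUE,
                       prob = c(0.3, 0.3, 0.15, 0.15, 0.1)), n, L)
    rownames(m) <- paste0("s", 1:n)
    a <- locus_alignment("rand", m)
    expect_equal(nucleotide_diversity(a), brute_pi(a), tolerance = 1e-12)
    expect_equal(mean_pairwise_diff(a), brute_k(a), tolerance = 1e-12)
  }
})

test_that("Tajima's D matches an independent formula oracle and is undefined at S=0", {
  a <- aln_from_strings(c("AAAAA", "AAAAA", "AAAAA", "AAAAA"))
  expect_false(tajimas_d(a)$defined)
  # fixed 5-sequence toy with 3 segregating sites
  b <- aln_from_strings(c("ACGTA", "ACGTA", "ATGTA", "ACGCA", "GCGTA"))
  got <- tajimas_d(b)
  expect_true(got$defined)
  expect_equal(got$value, oracle_tajima(5, 3, brute_k(b)), tolerance = 1e-12)
})

test_that("Fu & Li's D* matches the formula oracle and is negative for all-singleton data", {
  # every mutation a singleton (n = 5, three singleton sites)
  b <- aln_from_strings(c("ACGTA", "ACGTC", "ATGTA", "ACCTA", "ACGTA"))
  got <- fu_li_dstar(b)
  expect_true(got$defined)
  expect_equal(got$value, oracle_dstar(5, 3, 3), tolerance = 1e-12)
  expect_lt(got$value, 0)
  expect_false(fu_li_dstar(aln_from_strings(c("AAAA", "AAAA", "AAAA",
                                              "AAAA")))$defined)
})

test_that("neutrality statistics center near zero under neutral simulations", {
  set.seed(101)
  m <- demographic_model(sizes = c(A = 10000))
  cfg <- loci_config(lengths = 5000, samples = c(A = 20L), mu = 5e-7)
  nrep <- 600
  vals_d <- vals_ds <- rep(NA_real_, nrep)
  for (i in seq_len(nrep)) {
    M <- simulate_dataset(m, cfg, format = "matrices")[[1]]
    seqs <- matrix("A", nrow(M), max(ncol(M), 1))
    seqs[M == 1] <- "G"
    rownames(seqs) <- paste0("s", seq_len(nrow(M)))
    a <- locus_alignment("neutral", seqs)
    td <- tajimas_d(a)
    fd <- fu_li_dstar(a)
    if (td$defined) vals_d[i] <- td$value
    if (fd$defined) vals_ds[i] <- fd$value
  }
  # The normalized statistics have a small inherent negative mean under
  # neutrality (the numerator and the variance estimate in the denominator
  # are correlated); an independent coalescent implementation reproduces
  # means near -0.10 at this design.  Assert the means sit in that known
  # small-bias band rather than at exactly zero.
  for (x in list(vals_d, vals_ds)) {
    x <- x[!is.na(x)]
    expect_lt(abs(mean(x)), 0.2)
  }
})

test_that("the unnormalized Tajima contrast has mean exactly zero under neutrality", {
  # E[mean pairwise differences] = E[S]/a1 = theta*L under the neutral
  # coalescent, so the numerator of D is an exactly zero-mean quantity
  set.seed(303)
  n <- 20L
  a1 <- sum(1 / 1:(n - 1))
  m <- demographic_model(sizes = c(A = 10000))
  cfg <- loci_config(lengths = 5000, samples = c(A = n), mu = 5e-7)
  nrep <- 800
  num <- numeric(nrep)
  for (i in seq_len(nrep)) {
    K <- simulate_dataset(m, cfg, format = "counts")
    k <- as.numeric(K)
    S <- sum(k > 0 & k < n)
    khat <- sum(2 * k * (n - k) / (n * (n - 1)))
    num[i] <- khat - S / a1
  }
  se <- sd(num) / sqrt(nrep)
  expect_lt(abs(mean(num)), 3 * se)
})

test_that("private segregating sites match exhaustive classification", {
  a <- aln_from_strings(c("ACGT", "ACGA", "ACGT",   # group A: site 4 poly
                          "ATGT", "ATGT", "ACGT"),  # group B: site 2 poly
                        ids = paste0("s", 1:6))
  got <- private_segregating_sites(a, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(unname(got), c(1L, 1L))
  # both polymorphic at a shared site counts for neither
  b <- aln_from_strings(c("AT", "AA", "CA", "CT", "AA", "AT"),
                        ids = paste0("s", 1:6))
  gotb <- private_segregating_sites(b, paste0("s", 1:3), paste0("s", 4:6))
  # site 1: A poly (A,A,C): yes; B poly (C,A,A): yes -> neither
  # site 2: A poly (T,A,A): yes; B poly (T,A,T): yes -> neither
  expect_equal(unname(gotb), c(0L, 0L))
  expect_error(private_segregating_sites(a, paste0("s", 1:3),
                                         paste0("s", 3:5)), "overlap")
})

test_that("mean between-group differences match brute force", {
  a <- aln_from_strings(c("AAAA", "AAAT", "AAAA", "AAAT"),
                        ids = paste0("s", 1:4))
  # identical groups: between mean equals within mean by symmetry
  expect_equal(mean_between_diff(a, c("s1", "s2"), c("s3", "s4")), 0.5)
  b <- aln_from_strings(c("AAAA", "AAAA", "CAAA", "CAAA"),
                        ids = paste0("s", 1:4))
  expect_equal(mean_between_diff(b, c("s1", "s2"), c("s3", "s4")), 1)
  expect_error(mean_between_diff(a, character(0), "s1"), "empty")
})

test_that("PhiST is 0 for identical groups, 1 for fixed differences, and matches hand computation", {
  # fixed differences at every variable site
  a <- aln_from_strings(c("AAAA", "AAAA", "TTTT", "TTTT"),
                        ids = paste0("s", 1:4))
  r <- fst_with_permutation(a, c("s1", "s2"), c("s3", "s4"), n_perm = 99,
                            seed = 1)
  expect_equal(r$fst, 1)
  # hand-computed toy: 8 sequences, known distance matrix
  b <- aln_from_strings(c("AAAA", "AAAT", "AAAA", "AAAT",
                          "TTAA", "TTAT", "TTAA", "TTAA"),
                        ids = paste0("s", 1:8))
  A <- paste0("s", 1:4); B <- paste0("s", 5:8)
  seqs <- b$seqs
  dmat <- as.matrix(stats::dist(t(sapply(seq_len(8), function(i)
    match(seqs[i, ], c("A", "C", "G", "T")))), method = "manhattan"))
  dmat <- (dmat > 0) * dmat  # manhattan on codes != hamming in general
  # recompute hamming by hand instead
  ham <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) ham[i, j] <- sum(seqs[i, ] != seqs[j, ])
  wA <- ham[1:4, 1:4][upper.tri(diag(4))]
  wB <- ham[5:8, 5:8][upper.tri(diag(4))]
  tot <- ham[upper.tri(ham)]
  phist_hand <- 1 - mean(c(wA, wB)) / mean(tot)
  rb <- fst_with_permutation(b, A, B, n_perm = 199, seed = 2)
  expect_equal(rb$fst, phist_hand, tolerance = 1e-12)
  expect_true(rb$p_value > 0 && rb$p_value <= 1)
  # Hudson variant for the same data
  dxy <- mean(ham[1:4, 5:8])
  hud_hand <- 1 - mean(c(mean(wA), mean(wB))) / dxy
  rh <- fst_with_permutation(b, A, B, n_perm = 99, seed = 3,
                             statistic = "hudson")
  expect_equal(rh$fst, hud_hand, tolerance = 1e-12)
  # label relabeling invariance
  rswap <- fst_with_permutation(b, B, A, n_perm = 99, seed = 2)
  expect_equal(rswap$fst, rb$fst, tolerance = 1e-12)
})

test_that("PhiST of two samples from one panmictic pool is near zero with a large p", {
  set.seed(7)
  m <- demographic_model(sizes = c(A = 10000))
  cfg <- loci_config(lengths = 2000, samples = c(A = 16L), mu = 5e-7)
  mats <- simulate_dataset(m, cfg, format = "matrices")
  M <- mats[[1]]
  seqs <- matrix("A", nrow(M), max(ncol(M), 1))
  seqs[M == 1] <- "G"
  rownames(seqs) <- paste0("s", seq_len(nrow(M)))
  a <- locus_alignment("pan", seqs)
  r <- fst_with_permutation(a, paste0("s", 1:8), paste0("s", 9:16),
                            n_perm = 499, seed = 9)
  expect_lt(abs(r$fst), 0.15)
  expect_gt(r$p_value, 0.05)
})

test_that("permutation p-values are valid (never anti-conservative) under the null", {
  # With discrete sequence data the permutation distribution has ties, and
  # the estimator p = (b+1)/(m+1) is deliberately conservative, so the null
  # p-values stochastically dominate the uniform rather than matching it
  # exactly.  Validity means the rejection rate never exceeds the nominal
  # level beyond Monte-Carlo error.
  set.seed(11)
  m <- demographic_model(sizes = c(A = 5000))
  cfg <- loci_config(lengths = 2000, samples = c(A = 12L), mu = 5e-7)
  pv <- replicate(200, {
    mats <- simulate_dataset(m, cfg, format = "matrices")
    M <- mats[[1]]
    seqs <- matrix("A", nrow(M), max(ncol(M), 1))
    seqs[M == 1] <- "G"
    rownames(seqs) <- paste0("s", seq_len(nrow(M)))
    a <- locus_alignment("pan", seqs)
    # random labels onto panmictic data
    lab <- sample(paste0("s", 1:12))
    fst_with_permutation(a, lab[1:6], lab[7:12], n_perm = 199)$p_value
  })
  pv <- pv[!is.na(pv)]
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    mc <- 3 * sqrt(alpha * (1 - alpha) / length(pv))
    expect_lte(mean(pv <= alpha), alpha + mc)
  }
  # and the p-values are not degenerate: they spread over the unit interval
  expect_gt(mean(pv <= 0.5), 0.25)
})

test_that("LD r-squared matches the 2x2 haplotype-table computation", {
  # perfectly coupled pair
  a <- aln_from_strings(c("AT", "AT", "GC", "GC"))
  r <- ld_r2(a)
  expect_equal(nrow(r), 1L)
  expect_equal(r$r2, 1)
  # independent equifrequent pair
  b <- aln_from_strings(c("AT", "AC", "GT", "GC"))
  expect_equal(ld_r2(b)$r2, 0)
  # counts 40/10/10/40 -> r2 = 0.36 by direct computation
  strings <- c(rep("AT", 40), rep("AC", 10), rep("GT", 10), rep("GC", 40))
  cc <- aln_from_strings(strings, ids = paste0("h", seq_along(strings)))
  rc <- ld_r2(cc)
  expect_equal(rc$r2, 0.36, tolerance = 1e-12)
  # monomorphic input -> empty result
  expect_equal(nrow(ld_r2(aln_from_strings(c("AA", "AA")))), 0L)
})

test_that("theta_W reproduces published-style cells from (n, S, L) alone", {
  # printed-precision checks across three genomes (4 decimal rounding as in
  # a standard diversity table)
  expect_equal(round(watterson_theta(32, 60, 4986), 4), 0.0014)
  expect_equal(round(watterson_theta(38, 98, 4986), 4), 0.0015)
  expect_equal(round(watterson_theta(1, 53, 1361), 5), 0.00016)
  expect_equal(round(watterson_theta(9, 91, 1699), 5), 0.00104)
})
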