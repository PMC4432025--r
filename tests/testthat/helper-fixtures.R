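# In-code fixtures shared across the test files.

# small alignment from a character vector of equal-length strings
aln_from_strings <- function(strings, ids = NULL, locus_id = "toy") {
  if (is.null(ids)) ids <- paste0("s", seq_along(strings))
  m <- do.call(rbind, strsplit(toupper(strings), ""))
  rownames(m) <- ids
  locus_alignment(locus_id, m)
}

# brute-force nucleotide diversity: mean over pairs of per-site Hamming
# distance on mutually non-missing sites
brute_pi <- function(aln, subset = NULL) {
  seqs <- aln$seqs
  if (!is.null(subset)) seqs <- seqs[subset, , drop = FALSE]
  n <- nrow(seqs)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- seqs[i, ]; b <- seqs[j, ]
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    if (sum(ok) == 0) next
    vals <- c(vals, sum(a[ok] != b[ok]) / sum(ok))
  }
  mean(vals)
}

# brute-force mean pairwise difference counts
brute_k <- function(aln, subset = NULL) {
  seqs <- aln$seqs
  if (!is.null(subset)) seqs <- seqs[subset, , drop = FALSE]
  n <- nrow(seqs)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- seqs[i, ]; b <- seqs[j, ]
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    vals <- c(vals, sum(a[ok] != b[ok]))
  }
  mean(vals)
}

# independent constant-by-constant oracle for Tajima's D (1989)
oracle_tajima <- function(n, S, khat) {
  a1 <- sum(1 / 1:(n - 1)); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (khat - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# independent oracle for Fu & Li's D* (no outgroup)
oracle_dstar <- function(n, eta, eta_s) {
  a1 <- sum(1 / 1:(n - 1)); a2 <- sum(1 / (1:(n - 1))^2)
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (1.5 - (2 * (a1 + 1 / n) - 3) / (n - 2) - 1 / n)
  vd <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
           2 * n * a1 * (a1 + 1) / (n - 1)^2) / (a1^2 + a2)
  ud <- n / (n - 1) * (a1 - n / (n - 1)) - vd
  (n / (n - 1) * eta - a1 * eta_s) / sqrt(ud * eta + vd * eta^2)
}

# tiny default four-species design used by the ABC tests
test_species <- c("SCH", "SMI", "LIK", "WIL")
test_config <- function(n_per_sp = 12L, n_loci = 11L, len = 450) {
  loci_config(lengths = rep(len, n_loci),
              samples = setNames(rep(as.integer(n_per_sp), 4), test_species))
}
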