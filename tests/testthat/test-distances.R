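test_that("k2p matches hand-derived values and flags saturation", {
  # identical sequences
  z <- k2p("ACGTACGTAC", "ACGTACGTAC")
  expect_true(z$defined)
  expect_equal(z$d, 0)
  expect_equal(z$p_transitions, 0)

  # 10 sites, one transition (A->G) and one transversion (A->C):
  # P = Q = 0.1, d = -1/2 ln(0.7 * sqrt(0.8)) = 0.2341233 (hand-evaluated)
  e <- k2p("AAAAAAAAAA", "GCAAAAAAAA")
  expect_equal(e$p_transitions, 0.1)
  expect_equal(e$q_transversions, 0.1)
  expect_equal(e$d, 0.2341233, tolerance = 1e-5)
  expect_equal(e$d, brute_k2p("AAAAAAAAAA", "GCAAAAAAAA"), tolerance = 1e-12)

  # log-domain violation: P = 0.5, Q = 0 -> undefined, never NaN
  s <- k2p(paste(rep("A", 10), collapse = ""),
           paste(rep(c("A", "G"), 5), collapse = ""))
  expect_false(s$defined)
  expect_true(is.na(s$d))

  # no comparable sites
  n <- k2p("NNNN", "ACGT")
  expect_false(n$defined)
  expect_equal(n$n_sites_compared, 0L)
})

test_that("k2p agrees exactly with a brute-force oracle on random pairs", {
  worst <- 0
  for (i in 1:1000) {
    set.seed(i)
    L <- sample(20:60, 1)
    s1 <- paste(sample(c("A", "C", "G", "T", "-", "N"), L, replace = TRUE,
                       prob = c(rep(0.23, 4), 0.04, 0.04)), collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "T", "-", "N"), L, replace = TRUE,
                       prob = c(rep(0.23, 4), 0.04, 0.04)), collapse = "")
    mine <- k2p(s1, s2)
    ref <- brute_k2p(s1, s2)
    if (is.na(ref)) {
      expect_false(mine$defined)
    } else {
      expect_true(mine$defined)
      worst <- max(worst, abs(mine$d - ref))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("distance_matrix complete deletion equals k2p on reduced columns", {
  a <- aln(s1 = "ACGTAC-TAC", s2 = "ACGAACGTAC", s3 = "ACGTACGTNC")
  dm <- distance_matrix(a, deletion = "complete")
  keep <- setdiff(1:10, c(7, 9))  # the gap and N columns
  expect_equal(dm$n_columns_used, length(keep))
  manual <- k2p(a$mat["s1", ], a$mat["s2", ], columns = keep)
  expect_equal(dm$d["s1", "s2"], manual$d)
  # identical sequences give a zero matrix
  id3 <- aln(x = "ACGT", y = "ACGT", z = "ACGT")
  expect_true(all(distance_matrix(id3)$d == 0))
  # all-gap columns under complete deletion -> instructive error
  bad <- aln(x = "A-", y = "-A")
  expect_error(distance_matrix(bad, "complete"), "pairwise")
})

test_that("distance_matrix cross-checks against ape::dist.dna (K80)", {
  s <- random_seqs(8, 200, seed = 42)
  a <- dna_alignment(s)
  dm <- distance_matrix(a, deletion = "pairwise")
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(
    do.call(rbind, strsplit(tolower(s), ""))), model = "K80",
    pairwise.deletion = TRUE))
  expect_equal(unname(dm$d), unname(ref[rownames(dm$d), colnames(dm$d)]),
               tolerance = 1e-10)
})

test_that("K2P distance is monotone in P and Q and near JC for low divergence", {
  d_of <- function(P, Q) -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  grid <- seq(0, 0.2, by = 0.02)
  for (Q in grid) {
    ds <- vapply(grid, d_of, numeric(1), Q = Q)
    expect_true(all(diff(ds) > 0))  # monotone in P at fixed Q
  }
  for (P in grid) {
    ds <- vapply(grid, function(q) d_of(P, q), numeric(1))
    expect_true(all(diff(ds) > 0))  # monotone in Q at fixed P
  }
  # transitions:transversions 1:2 (JC-like): K2P within 5% of JC for d <= 0.1
  for (ptot in seq(0.01, 0.095, by = 0.005)) {
    P <- ptot / 3; Q <- 2 * ptot / 3
    jc <- -3 / 4 * log(1 - 4 / 3 * ptot)
    expect_equal(d_of(P, Q), jc, tolerance = 0.05 * jc)
  }
})

test_that("divergence summary separates within and between groups", {
  a <- aln(a1 = "AAAAAAAAAA", a2 = "AAAAAAAAAA",
           b1 = "AAAAAAGGGG", b2 = "AAAAAAGGGG")
  dm <- distance_matrix(a)
  g <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  ds <- divergence_summary(dm, g, n_boot = 0)
  expect_equal(unname(ds$mean_within), c(0, 0))
  expect_equal(ds$mean_between["A", "B"], dm$d["a1", "b1"])
  # singleton group: within mean reported missing, not zero
  g2 <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "C")
  ds2 <- divergence_summary(dm, g2, n_boot = 0)
  expect_true(is.na(ds2$mean_within[["B"]]))
  # bootstrap SE is available and non-negative
  ds3 <- divergence_summary(dm, g, alignment = a, n_boot = 50, seed = 1)
  expect_gte(ds3$standard_error, 0)
})

test_that("simulated within-species divergence matches the generator target", {
  cfg <- simulation_config(n_species = 3, specimens_per_species = 4,
                           references_per_species = 1, outgroup_n = 2,
                           delta_intra = 0.005, delta_inter = 0.08,
                           locus_rates = c(tufA = 1), seq_lengths = c(tufA = 2000L),
                           n_sites = 3, n_discordant = 0, min_inter_frac = 0.5,
                           seed = 11)
  within_means <- vapply(1:5, function(s) {
    cfg$seed <- s
    sim <- simulate_dataset(cfg)
    dm <- distance_matrix(sim$alignments$tufA)
    ds <- divergence_summary(dm, sim$truth$species, n_boot = 0)
    mean(ds$mean_within, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(within_means), 0.003)
  expect_lt(mean(within_means), 0.007)
})
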