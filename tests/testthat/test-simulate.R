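test_that("simulation is deterministic and satisfies its invariants", {
  cfg <- simulation_config(n_species = 3, specimens_per_species = 3,
                           references_per_species = 2, outgroup_n = 2,
                           delta_intra = 0.005, delta_inter = 0.07,
                           locus_rates = c(tufA = 1, ITS = 1.3),
                           seq_lengths = c(tufA = 300L, ITS = 250L),
                           n_sites = 3, n_discordant = 1, seed = 5)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$alignments$tufA$mat, s2$alignments$tufA$mat)
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(s1$truth$discordant_ids, s2$truth$discordant_ids)

  for (a in s1$alignments) {
    expect_s3_class(a, "dna_alignment")
    expect_true(all(names(s1$truth$species) %in% aln_ids(a)))
    expect_true(all(a$mat %in% c("A", "C", "G", "T")))
  }
  expect_setequal(names(s1$truth$species),
                  s1$metadata$specimen_id)
  # config validation
  expect_error(simulation_config(delta_intra = 0.1, delta_inter = 0.05),
               "delta_intra")
  expect_error(simulation_config(seq_lengths = c(tufA = 50L),
                                 locus_rates = c(tufA = 1)), ">= 100")
})

test_that("zero mutation rate yields identical sequences and zero distances", {
  cfg <- simulation_config(n_species = 2, specimens_per_species = 2,
                           references_per_species = 1, outgroup_n = 2,
                           delta_intra = 0.001, delta_inter = 0.05,
                           locus_rates = c(tufA = 0), seq_lengths = c(tufA = 200L),
                           n_sites = 2, n_discordant = 0, seed = 3)
  sim <- simulate_dataset(cfg)
  m <- sim$alignments$tufA$mat
  expect_true(all(apply(m, 2, function(col) length(unique(col)) == 1)))
  dm <- distance_matrix(sim$alignments$tufA)
  expect_true(all(dm$d == 0))
})

test_that("expected divergences scale linearly and match simulation", {
  cfg <- simulation_config(delta_intra = 0.004, delta_inter = 0.06,
                           locus_rates = c(tufA = 1, ITS = 1.3),
                           seq_lengths = c(tufA = 813L, ITS = 732L))
  ed <- expected_divergence(cfg)
  expect_equal(ed$expected_intra, c(0.004, 0.004 * 1.3))
  expect_equal(ed$expected_inter, c(0.06, 0.06 * 1.3))
  # doubling the interspecific target doubles the expectation (pre-saturation)
  cfg2 <- simulation_config(delta_inter = 0.12, delta_intra = 0.004)
  expect_equal(expected_divergence(cfg2)$expected_inter[1], 0.12)
  # zero coalescent depth -> zero intraspecific expectation
  cfg3 <- simulation_config(delta_intra = 0, delta_inter = 0.06,
                            n_discordant = 0L)
  expect_equal(expected_divergence(cfg3)$expected_intra[1], 0)

  # empirical means track the closed form across seeds (one locus, rate 1)
  base <- simulation_config(n_species = 4, specimens_per_species = 4,
                            references_per_species = 1, outgroup_n = 2,
                            delta_intra = 0.005, delta_inter = 0.08,
                            locus_rates = c(tufA = 1),
                            seq_lengths = c(tufA = 1500L), n_sites = 3,
                            n_discordant = 0, min_inter_frac = 0.5, seed = 1)
  intra <- numeric(0); inter <- numeric(0)
  for (s in 1:8) {
    base$seed <- s
    sim <- simulate_dataset(base)
    dm <- distance_matrix(sim$alignments$tufA)
    g <- sim$truth$species
    ds <- divergence_summary(dm, g, n_boot = 0)
    intra <- c(intra, mean(ds$mean_within, na.rm = TRUE))
    inter <- c(inter, mean(ds$mean_between[upper.tri(ds$mean_between)],
                           na.rm = TRUE))
  }
  expect_equal(mean(intra), 0.005, tolerance = 0.4)
  expect_equal(mean(inter), 0.08, tolerance = 0.2)
})

test_that("discordant specimens change membership at the second locus only", {
  cfg <- simulation_config(n_species = 4, specimens_per_species = 3,
                           references_per_species = 1, outgroup_n = 2,
                           delta_intra = 0.004, delta_inter = 0.08,
                           locus_rates = c(tufA = 1, ITS = 1),
                           seq_lengths = c(tufA = 300L, ITS = 300L),
                           n_sites = 3, n_discordant = 2, min_inter_frac = 0.5,
                           seed = 9)
  sim <- simulate_dataset(cfg)
  m1 <- sim$truth$memberships$tufA
  m2 <- sim$truth$memberships$ITS
  moved <- names(m1)[m1 != m2]
  expect_setequal(moved, sim$truth$discordant_ids)
  expect_equal(length(moved), 2)
})

test_that("synonym pairs duplicate a reference at zero divergence", {
  sim <- fixture_dataset("synonym")
  refs <- sim$references
  syn_rows <- refs[grepl("_syn$", refs$species), ]
  expect_equal(nrow(syn_rows), 2)
  for (locus in names(sim$alignments)) {
    a <- sim$alignments[[locus]]
    for (i in seq_len(nrow(syn_rows))) {
      src_sp <- sub("_syn$", "", syn_rows$species[i])
      src_id <- refs$sequence_id[refs$species == src_sp][1]
      expect_identical(a$mat[syn_rows$sequence_id[i], ], a$mat[src_id, ])
    }
  }
})

test_that("gmyc tree generator controls stem and tuft depths", {
  tr <- simulate_gmyc_tree(5, 4, 0.05, 0.005, seed = 2)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  bt <- ape::branching.times(tr)
  deep <- bt[bt > 0.02]; shallow <- bt[bt <= 0.02]
  expect_equal(length(deep), 4)          # S - 1 species splits
  expect_equal(min(deep), 0.05, tolerance = 1e-8)
  expect_lte(max(shallow), 0.005 + 1e-9)
})
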