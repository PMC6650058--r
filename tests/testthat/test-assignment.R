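# constructed rooted tree with references of two species plus outgroup:
#   (((spec, refS1a), (refS1b, refS2)), OUT)
.toy_tree <- function() {
  ape::read.tree(text = paste0(
    "(((spec:0.002,refS1a:0.002):0.01,(refS1b:0.01,refS2:0.012):0.004):0.05,",
    "OUT:0.1);"))
}

.toy_refs <- data.frame(
  sequence_id = c("refS1a", "refS1b", "refS2", "OUT"),
  species = c("S1", "S1", "S2", "Outgroup spp."),
  stringsAsFactors = FALSE)

.toy_dm <- function(d_spec_s1 = 0.004, d_spec_s2 = 0.031) {
  ids <- c("spec", "refS1a", "refS1b", "refS2", "OUT")
  D <- matrix(0.2, 5, 5, dimnames = list(ids, ids)); diag(D) <- 0
  D["spec", "refS1a"] <- D["refS1a", "spec"] <- d_spec_s1
  D["spec", "refS1b"] <- D["refS1b", "spec"] <- d_spec_s1
  D["spec", "refS2"] <- D["refS2", "spec"] <- d_spec_s2
  as_k2p_dist(D)
}

test_that("assign_on_tree follows the smallest reference-bearing clade", {
  # sister to a single reference -> that species
  res <- assign_on_tree(.toy_tree(), .toy_refs, .toy_dm())
  expect_equal(res$call[res$specimen_id == "spec"], "S1")

  # clade with two species: lowest mean K2P wins
  tr2 <- ape::read.tree(text = paste0(
    "((spec:0.01,(refS1a:0.005,refS2:0.005):0.005):0.05,OUT:0.1);"))
  refs2 <- .toy_refs[.toy_refs$sequence_id != "refS1b", ]
  res2 <- assign_on_tree(tr2, refs2, .toy_dm(0.004, 0.031))
  expect_equal(res2$call, "S1")
  expect_equal(res2$k2p_margin, 0.031 - 0.004)
  res2b <- assign_on_tree(tr2, refs2, .toy_dm(0.031, 0.004))
  expect_equal(res2b$call, "S2")

  # specimen attaching below every reference clade -> unassigned
  tr3 <- ape::read.tree(text = paste0(
    "(spec:0.05,((refS1a:0.01,refS1b:0.01):0.02,refS2:0.03):0.02);"))
  res3 <- assign_on_tree(tr3, .toy_refs[.toy_refs$sequence_id != "OUT", ],
                         .toy_dm())
  expect_true(is.na(res3$call))

  expect_error(assign_on_tree(ape::unroot(.toy_tree()), .toy_refs, .toy_dm()),
               "rooted")
})

test_that("gene majority requires a strict majority of tree calls", {
  calls <- rbind(U1 = c("S1", "S1", "S2"),
                 U2 = c("S1", "S2", NA),
                 U3 = c(NA, NA, NA),
                 U4 = c("S2", "S2", "S2"))
  m <- gene_majority(calls)
  expect_equal(unname(m["U1"]), "S1")     # 2 of 3
  expect_true(is.na(m["U2"]))             # no majority
  expect_true(is.na(m["U3"]))
  expect_equal(unname(m["U4"]), "S2")
  # single tree passes through
  single <- gene_majority(matrix(c("S1", NA), 2, 1,
                                 dimnames = list(c("U1", "U2"), NULL)))
  expect_equal(unname(single["U1"]), "S1")
  expect_true(is.na(single["U2"]))
})

test_that("synonym map merges near-zero species pairs transitively", {
  ids <- c("rA", "rB", "rC", "rD")
  D <- matrix(0.05, 4, 4, dimnames = list(ids, ids)); diag(D) <- 0
  D["rA", "rB"] <- D["rB", "rA"] <- 0.000   # laetevirens-rigida style
  D["rB", "rC"] <- D["rC", "rB"] <- 0.001   # australis-pertusa style
  D["rA", "rC"] <- D["rC", "rA"] <- 0.001
  D["rC", "rD"] <- D["rD", "rC"] <- 0.007   # complex: not merged
  refs <- data.frame(sequence_id = ids, species = c("a_sp", "b_sp", "c_sp", "d_sp"))
  syn <- build_synonym_map(refs, as_k2p_dist(D), threshold = 0.002)
  expect_equal(unname(syn[c("a_sp", "b_sp", "c_sp")]),
               rep("a_sp", 3))             # transitive closure, alphabetical
  expect_equal(unname(syn["d_sp"]), "d_sp")
  # preference override picks the canonical name
  syn2 <- build_synonym_map(refs, as_k2p_dist(D), threshold = 0.002,
                            prefer = c(b_sp = "c_sp"))
  expect_equal(unname(syn2["a_sp"]), "c_sp")
  # idempotent
  expect_true(all(syn[unname(syn)] == unname(syn)))
})

test_that("combine_genes applies synonym mapping, discordance and fallbacks", {
  syn <- c(pertusa = "australis", australis = "australis",
           ohnoi = "ohnoi", torta = "torta", linza = "linza")
  g1 <- c(U1 = "australis", U2 = "ohnoi", U3 = NA, U4 = NA, U5 = "torta")
  g2 <- c(U1 = "pertusa", U2 = "australis", U3 = "torta", U4 = NA,
          U5 = "linza")
  out <- combine_genes(g1, g2, syn)
  expect_equal(out$final_call[out$specimen_id == "U1"], "australis")
  expect_equal(out$final_call[out$specimen_id == "U2"], "discordant")
  expect_equal(out$detail[out$specimen_id == "U2"], "ohnoi vs australis")
  expect_equal(out$final_call[out$specimen_id == "U3"], "torta")
  expect_equal(out$flag[out$specimen_id == "U3"], "single-gene")
  expect_equal(out$final_call[out$specimen_id == "U4"], "unidentified")
  expect_equal(out$final_call[out$specimen_id == "U5"], "discordant")

  # symmetric in gene order
  out2 <- combine_genes(g2, g1, syn)
  expect_equal(out2$final_call, out$final_call)
})

test_that("composition report gives Table-1 style counts and percentages", {
  atab <- combine_genes(c(U1 = "S1", U2 = "S1", U3 = "S2", U4 = "S1"),
                        c(U1 = "S1", U2 = "S1", U3 = "S2", U4 = "S2"))
  meta <- data.frame(specimen_id = paste0("U", 1:4),
                     site_code = c("1a", "1a", "2b", "2b"))
  comp <- composition_report(atab, meta)
  s1 <- comp[comp$species == "S1", ]
  expect_equal(s1$n_specimens, 2)
  expect_equal(s1$relative_frequency, 50.0)
  expect_equal(comp[comp$species == "discordant", "n_specimens"], 1)
  expect_equal(comp[comp$species == "discordant", "relative_frequency"], 25.0)
  expect_equal(comp[comp$species == "Total", "n_specimens"], 4)
  expect_equal(sum(comp$n_specimens[comp$species != "Total"]), 4)
  # metadata must cover every specimen
  expect_error(composition_report(atab, meta[1:2, ]), "missing from metadata")
})

test_that("delimitation comparison counts intersecting groups per species", {
  atab <- combine_genes(c(U1 = "S1", U2 = "S1", U3 = "S2", U4 = "S2"),
                        c(U1 = "S1", U2 = "S1", U3 = "S2", U4 = "S2"))
  congruent <- structure(c(U1 = 1L, U2 = 1L, U3 = 2L, U4 = 2L, ref1 = 3L),
                         n_groups = 3L, class = "species_partition")
  split_s1 <- structure(c(U1 = 1L, U2 = 2L, U3 = 3L, U4 = 3L, ref1 = 4L),
                        n_groups = 4L, class = "species_partition")
  cmp <- delimitation_comparison(atab, list(a = congruent, b = split_s1))
  expect_equal(cmp$a[cmp$species == "S1"], 1)
  expect_equal(cmp$b[cmp$species == "S1"], 2)
  expect_equal(cmp$a[cmp$species == "Non-sampled (reference-only) groups"], 1)
  expect_equal(cmp$a[cmp$species == "Total groups"], 3)
  expect_equal(cmp$b[cmp$species == "Total groups of analyzed specimens"], 3)
})

test_that("reference curation keeps supported monophyletic representatives", {
  sim <- fixture_dataset("clean")
  a <- sim$alignments$tufA
  # candidates: all reference+outgroup tips, with one specimen of another
  # species mislabeled as species_01
  cand_ids <- c(sim$references$sequence_id,
                "U001")  # a species_01 specimen, honest label
  cand_ids <- intersect(cand_ids, aln_ids(a))
  mislab <- names(sim$truth$species)[sim$truth$species == "species_02"][1]
  cand_ids <- c(cand_ids, mislab)
  roles <- a$roles[cand_ids]
  roles[!cand_ids %in% paste0("outgroup_", 1:3)] <- "reference"
  sub <- dna_alignment(a$mat[cand_ids, , drop = FALSE], a$locus, roles)
  labels <- stats::setNames(sim$references$species, sim$references$sequence_id)
  labels <- labels[intersect(names(labels), cand_ids)]
  labels <- labels[!grepl("Outgroup", labels)]
  labels["U001"] <- "species_01"
  labels[mislab] <- "species_01"  # mislabeled candidate
  cur <- curate_references(sub, labels, n_bootstrap = 30, seed = 5)
  # the mislabeled candidate is rejected for clustering away from conspecifics
  expect_true(mislab %in% cur$rejected$sequence_id)
  # at most two representatives per species survive
  expect_true(all(table(cur$references$species) <= 2))
  # species_01 had 3 honest candidates forming a clade -> exactly 2 kept
  expect_equal(sum(cur$references$species == "species_01"), 2)
})
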