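## Two-locus specimen simulator.
##
## Species relationships are drawn from a Yule process and rescaled so the
## mean between-species path length matches the interspecific divergence
## target; within each species, samples coalesce under a Kingman coalescent
## rescaled to the intraspecific target; sequences evolve under K80(kappa)
## with per-locus rate multipliers via exact per-branch transition
## probabilities (phangorn::simSeq). Gene-discordant specimens are created
## by swapping their species membership at the second locus; synonym pairs
## by duplicating a reference sequence under a second species name; no
## indels are simulated.

#' Simulation configuration
#'
#' Defaults mirror an island-wide green-tide survey design: nine Ulva species with
#' specimen counts (74, 47, 30, 13, 9, 8, 4, 4, 4), two reference sequences
#' per species, a three-tip outgroup clade, locus lengths 813 (tufA) and
#' 732 (ITS) with rate multipliers 1.0 and 1.3, intraspecific K2P target
#' 0.4 percent, interspecific target 6 percent, kappa = 2, 23 collection
#' sites and five gene-discordant specimens.
#'
#' @param n_species Number of ingroup species S.
#' @param specimens_per_species Integer vector (recycled to S).
#' @param references_per_species References simulated per species.
#' @param outgroup_n Outgroup tips.
#' @param delta_intra,delta_inter Target within/between-species K2P
#'   (substitutions/site, locus multiplier 1).
#' @param kappa Transition/transversion rate ratio.
#' @param locus_rates Named numeric vector of per-locus rate multipliers.
#' @param seq_lengths Named integer vector of per-locus alignment lengths.
#' @param n_discordant Specimens whose species membership is swapped at the
#'   second locus.
#' @param n_synonym_pairs Reference species duplicated under a synonym name.
#' @param n_sites Number of collection sites.
#' @param outgroup_depth_mult Outgroup divergence as a multiple of
#'   \code{delta_inter}.
#' @param min_inter_frac Minimum between-species divergence as a fraction of
#'   the mean: the youngest species split is deepened (all pendant edges
#'   lengthened by a common constant before rescaling) until every species
#'   pair diverges by at least this fraction of \code{delta_inter}. The
#'   default 0.15 mirrors barcode surveys where the closest good-species
#'   pair sits at roughly 1 percent against a 6-9 percent mean.
#' @param seed RNG seed (fixed seed gives bit-identical output).
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_species = 9L,
                              specimens_per_species = c(74L, 47L, 30L, 13L,
                                                        9L, 8L, 4L, 4L, 4L),
                              references_per_species = 2L,
                              outgroup_n = 3L,
                              delta_intra = 0.004,
                              delta_inter = 0.06,
                              kappa = 2.0,
                              locus_rates = c(tufA = 1.0, ITS = 1.3),
                              seq_lengths = c(tufA = 813L, ITS = 732L),
                              n_discordant = 5L,
                              n_synonym_pairs = 0L,
                              n_sites = 23L,
                              outgroup_depth_mult = 2.0,
                              min_inter_frac = 0.15,
                              seed = 1L) {
  if (n_species < 1L) stop("n_species must be >= 1")
  if (delta_intra >= delta_inter) stop("delta_intra must be < delta_inter")
  if (any(seq_lengths < 100L)) stop("sequence lengths must be >= 100")
  if (!identical(names(locus_rates), names(seq_lengths))) {
    stop("locus_rates and seq_lengths must have identical locus names")
  }
  spp <- rep_len(as.integer(specimens_per_species), n_species)
  if (n_discordant > sum(spp)) stop("n_discordant exceeds total specimens")
  if (n_discordant > 0L && n_species < 2L) stop("discordance needs >= 2 species")
  if (n_synonym_pairs > n_species) stop("n_synonym_pairs exceeds n_species")
  structure(list(n_species = as.integer(n_species),
                 specimens_per_species = spp,
                 references_per_species = as.integer(references_per_species),
                 outgroup_n = as.integer(outgroup_n),
                 delta_intra = delta_intra, delta_inter = delta_inter,
                 kappa = kappa, locus_rates = locus_rates,
                 seq_lengths = seq_lengths,
                 n_discordant = as.integer(n_discordant),
                 n_synonym_pairs = as.integer(n_synonym_pairs),
                 n_sites = as.integer(n_sites),
                 outgroup_depth_mult = outgroup_depth_mult,
                 min_inter_frac = min_inter_frac,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Closed-form expected divergences per locus
#'
#' The simulator rescales genealogies so the mean within-species pairwise
#' path equals \code{delta_intra} and the mean between-species path equals
#' \code{delta_inter} (in substitutions/site), then multiplies by the locus
#' rate; the expected K2P estimates equal these path lengths (K2P is a
#' consistent estimator of the K80 path length, pre-saturation).
#'
#' @param cfg A \code{simulation_config}.
#' @return A data.frame with columns \code{locus}, \code{expected_intra},
#'   \code{expected_inter}.
#' @export
expected_divergence <- function(cfg) {
  data.frame(locus = names(cfg$locus_rates),
             expected_intra = unname(cfg$delta_intra * cfg$locus_rates),
             expected_inter = unname(cfg$delta_inter * cfg$locus_rates),
             row.names = NULL)
}

## rescale a phylo so its mean pairwise cophenetic distance equals target
.rescale_mean_pairwise <- function(tr, target) {
  if (is.null(tr$edge.length)) stop("tree has no edge lengths")
  cur <- mean(ape::cophenetic.phylo(tr)[upper.tri(diag(ape::Ntip(tr)))])
  if (cur <= 0) {
    if (target > 0) stop("cannot rescale a zero-depth tree to positive target")
    return(tr)
  }
  tr$edge.length <- tr$edge.length * target / cur
  tr
}

## graft an ultrametric subtree in place of a tip, shortening the pendant
## edge by the subtree's height so the result stays ultrametric
.graft_at_tip <- function(tree, tip_label, subtree) {
  i <- match(tip_label, tree$tip.label)
  if (is.na(i)) stop("tip not found: ", tip_label)
  if (ape::Ntip(subtree) == 1L) {  # single sample: rename the tip
    tree$tip.label[i] <- subtree$tip.label
    return(tree)
  }
  h <- max(ape::branching.times(subtree))
  e <- which(tree$edge[, 2L] == i)
  if (tree$edge.length[e] < h) {
    stop("infeasible scaling: within-species tree deeper than the pendant edge")
  }
  tree$edge.length[e] <- tree$edge.length[e] - h
  ape::bind.tree(tree, subtree, where = i, position = 0)
}

## coalescent genealogy for one species' samples, rescaled to delta_intra
.species_tuft <- function(labels, delta_intra) {
  m <- length(labels)
  if (m == 1L) {
    tr <- list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = labels,
               edge.length = 0, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::rcoal(m, tip.label = labels)
  .rescale_mean_pairwise(tr, delta_intra)
}

#' Simulate a two-locus specimen dataset with ground truth
#'
#' @param cfg A \code{\link{simulation_config}}.
#' @return A list of class \code{simulated_dataset}: \code{alignments}
#'   (named list of \code{dna_alignment}, one per locus), \code{metadata},
#'   \code{references} (reference table including any synonym names),
#'   \code{truth} (list: \code{species} named vector specimen -> true
#'   species, \code{discordant_ids}, \code{discordant_species} per-locus
#'   memberships, \code{synonym_groups}, \code{species_tree}) and
#'   \code{config}.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  S <- cfg$n_species
  sp_names <- sprintf("species_%02d", seq_len(S))
  spp <- cfg$specimens_per_species
  specimen_ids <- sprintf("U%03d", seq_len(sum(spp)))
  spec_species <- rep(sp_names, spp)
  names(spec_species) <- specimen_ids
  ref_ids <- unlist(lapply(seq_len(S), function(s)
    sprintf("ref_%s_%d", sp_names[s], seq_len(cfg$references_per_species))))
  ref_species <- rep(sp_names, each = cfg$references_per_species)
  names(ref_species) <- ref_ids
  out_ids <- sprintf("outgroup_%d", seq_len(cfg$outgroup_n))

  ## species tree: Yule shape, mean pairwise path = delta_inter - delta_intra
  ## (each within-species tuft adds ~delta_intra to a cross-species path)
  if (S >= 2L) {
    sp_tree <- ape::rphylo(S, birth = 1, death = 0)
    sp_tree$tip.label <- sp_names
    sp_target <- cfg$delta_inter - cfg$delta_intra
    if (sp_target <= 0) stop("infeasible scaling: delta_inter too small")
    ## enforce the minimum interspecific divergence: adding a constant c to
    ## every pendant edge shifts every pairwise path by 2c while keeping the
    ## tree ultrametric; solve (min + 2c)/(mean + 2c) = min_inter_frac
    D <- ape::cophenetic.phylo(sp_tree)
    dv <- D[upper.tri(D)]
    f <- cfg$min_inter_frac
    if (f > 0 && f < 1 && min(dv) < f * mean(dv)) {
      cc <- (f * mean(dv) - min(dv)) / (2 * (1 - f))
      pend <- sp_tree$edge[, 2L] <= S
      sp_tree$edge.length[pend] <- sp_tree$edge.length[pend] + cc
    }
    sp_tree <- .rescale_mean_pairwise(sp_tree, sp_target)
  } else {
    sp_tree <- NULL
  }

  ## discordant specimens: membership swapped at the second locus
  disc_ids <- character(0)
  if (cfg$n_discordant > 0L) {
    disc_ids <- sample(specimen_ids, cfg$n_discordant)
  }
  memberships <- list()
  loci <- names(cfg$locus_rates)
  for (li in seq_along(loci)) {
    mem <- spec_species
    if (li == 2L && length(disc_ids)) {
      shift <- match(mem[disc_ids], sp_names) %% S + 1L
      mem[disc_ids] <- sp_names[shift]
    }
    memberships[[loci[li]]] <- mem
  }

  ## outgroup stem: mean outgroup-ingroup path ~ outgroup_depth_mult * inter;
  ## the root must sit above the ingroup crown, so deepen it when a deep
  ## Yule draw would otherwise make the graft impossible
  root_depth <- cfg$outgroup_depth_mult * cfg$delta_inter / 2
  ing_h <- if (S >= 2L) max(ape::branching.times(sp_tree)) else 0
  root_depth <- max(root_depth, 1.25 * ing_h, cfg$delta_intra)
  if (root_depth <= 0) stop("infeasible scaling: zero root depth")

  alignments <- list()
  for (li in seq_along(loci)) {
    locus <- loci[li]
    mem <- memberships[[locus]]
    backbone <- ape::read.tree(text = sprintf("(INGROUP:%.10f,OUTGROUP:%.10f);",
                                              root_depth, root_depth))
    full <- backbone
    if (S >= 2L) {
      full <- .graft_at_tip(full, "INGROUP", sp_tree)
    } else {
      full$tip.label[full$tip.label == "INGROUP"] <- sp_names[1L]
    }
    ## per-species tufts: specimens of this locus's membership + references
    for (s in seq_len(S)) {
      members <- c(names(mem)[mem == sp_names[s]],
                   ref_ids[ref_species == sp_names[s]])
      tuft <- .species_tuft(members, cfg$delta_intra)
      ## species must be monophyletic: samples have to coalesce before the
      ## species' most recent split, so shrink a too-deep tuft to fit the
      ## pendant edge
      if (ape::Ntip(tuft) > 1L) {
        pend <- full$edge.length[full$edge[, 2L] ==
                                   match(sp_names[s], full$tip.label)]
        h <- max(ape::branching.times(tuft))
        if (h >= pend) tuft$edge.length <- tuft$edge.length * 0.9 * pend / h
      }
      full <- .graft_at_tip(full, sp_names[s], tuft)
    }
    out_tuft <- .species_tuft(out_ids, cfg$delta_intra)
    full <- .graft_at_tip(full, "OUTGROUP", out_tuft)
    full$edge.length <- full$edge.length * cfg$locus_rates[[locus]]
    k <- cfg$kappa
    sim <- phangorn::simSeq(full, l = cfg$seq_lengths[[locus]],
                            Q = c(1, k, 1, 1, k, 1))
    mat <- toupper(as.character(sim))
    rownames(mat) <- names(sim)
    roles <- c(stats::setNames(rep("specimen", length(specimen_ids)), specimen_ids),
               stats::setNames(rep("reference", length(ref_ids)), ref_ids),
               stats::setNames(rep("outgroup", length(out_ids)), out_ids))
    mat <- mat[c(specimen_ids, ref_ids, out_ids), , drop = FALSE]
    alignments[[locus]] <- dna_alignment(mat, locus = locus, roles = roles)
  }

  ## synonym pairs: duplicate the first reference of the chosen species
  ## under a synonym name (zero divergence)
  ref_table <- data.frame(sequence_id = ref_ids,
                          species = unname(ref_species),
                          stringsAsFactors = FALSE)
  synonym_groups <- list()
  if (cfg$n_synonym_pairs > 0L) {
    syn_sp <- sp_names[seq_len(cfg$n_synonym_pairs)]
    for (sp in syn_sp) {
      src <- ref_ids[ref_species == sp][1L]
      syn_name <- paste0(sp, "_syn")
      syn_id <- paste0("ref_", syn_name)
      for (locus in names(alignments)) {
        a <- alignments[[locus]]
        mat <- rbind(a$mat, a$mat[src, , drop = FALSE])
        rownames(mat)[nrow(mat)] <- syn_id
        roles <- c(a$roles, stats::setNames("reference", syn_id))
        alignments[[locus]] <- dna_alignment(mat, locus = a$locus,
                                             roles = roles)
      }
      ref_table <- rbind(ref_table,
                         data.frame(sequence_id = syn_id, species = syn_name))
      synonym_groups[[sp]] <- c(sp, syn_name)
    }
  }
  ## outgroup references: outgroup tips act as references for the outgroup
  ## pseudo-species, as in reference libraries that include the outgroup
  ref_table <- rbind(ref_table,
                     data.frame(sequence_id = out_ids,
                                species = "Outgroup spp."))

  metadata <- data.frame(
    specimen_id = specimen_ids,
    site_code = sprintf("site_%02d", sample.int(cfg$n_sites,
                                                length(specimen_ids),
                                                replace = TRUE)),
    morphotype = sample(c(sp_names, ""), length(specimen_ids), replace = TRUE),
    stringsAsFactors = FALSE)

  structure(list(alignments = alignments,
                 metadata = metadata,
                 references = ref_table,
                 truth = list(species = spec_species,
                              discordant_ids = sort(disc_ids),
                              memberships = memberships,
                              synonym_groups = synonym_groups,
                              species_tree = sp_tree),
                 config = cfg),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d species, %d specimens, loci: %s (seed %d)\n",
              x$config$n_species, length(x$truth$species),
              paste(names(x$alignments), collapse = ", "), x$config$seed))
  invisible(x)
}

#' Frozen small fixture datasets
#'
#' Three deterministic desk-scale datasets used across the test-suite:
#' \code{"clean"} (5 species, clear barcode gap), \code{"discordant"}
#' (clean plus 2 locus-swapped specimens) and \code{"synonym"} (clean plus 2
#' synonym reference pairs).
#'
#' @param name One of \code{"clean"}, \code{"discordant"}, \code{"synonym"}.
#' @return A \code{simulated_dataset}.
#' @export
fixture_dataset <- function(name = c("clean", "discordant", "synonym")) {
  name <- match.arg(name)
  base <- list(n_species = 5L, specimens_per_species = 4L,
               references_per_species = 2L, outgroup_n = 3L,
               delta_intra = 0.005, delta_inter = 0.08,
               locus_rates = c(tufA = 1.0, ITS = 1.3),
               seq_lengths = c(tufA = 600L, ITS = 500L),
               n_sites = 6L, n_discordant = 0L, n_synonym_pairs = 0L,
               min_inter_frac = 0.6)  # clean-gap fixtures
  extra <- switch(name,
    clean = list(seed = 101L),
    discordant = list(seed = 202L, n_discordant = 2L),
    synonym = list(seed = 303L, n_synonym_pairs = 2L))
  simulate_dataset(do.call(simulation_config, utils::modifyList(base, extra)))
}

#' Simulate an ultrametric species/coalescent tree for GMYC studies
#'
#' Species stems follow a Yule process rescaled so the shallowest
#' between-species split sits at \code{stem_depth}; within each species a
#' Kingman coalescent is rescaled to crown height \code{tuft_depth}. The
#' stem/tuft depth ratio controls how cleanly a single threshold can
#' separate the two processes.
#'
#' @param n_species Number of species.
#' @param tips_per_species Samples per species (recycled).
#' @param stem_depth Height of the shallowest species split.
#' @param tuft_depth Crown height of every within-species genealogy.
#' @param seed RNG seed.
#' @return An ultrametric \code{phylo}; tip labels \code{s<i>_<j>} encode
#'   the true species.
#' @export
simulate_gmyc_tree <- function(n_species = 5L, tips_per_species = 4L,
                               stem_depth = 0.05, tuft_depth = 0.005,
                               seed = 1L) {
  if (tuft_depth >= stem_depth) stop("tuft_depth must be < stem_depth")
  set.seed(seed)
  tps <- rep_len(as.integer(tips_per_species), n_species)
  sp <- ape::rphylo(n_species, birth = 1, death = 0)
  bt <- ape::branching.times(sp)
  sp$edge.length <- sp$edge.length * stem_depth / min(bt)
  sp$tip.label <- paste0("s", seq_len(n_species))
  full <- sp
  for (i in seq_len(n_species)) {
    labs <- paste0("s", i, "_", seq_len(tps[i]))
    if (tps[i] == 1L) { full$tip.label[full$tip.label == paste0("s", i)] <- labs; next }
    tuft <- ape::rcoal(tps[i], tip.label = labs)
    tuft$edge.length <- tuft$edge.length * tuft_depth /
      max(ape::branching.times(tuft))
    full <- .graft_at_tip(full, paste0("s", i), tuft)
  }
  full
}

#' Write a simulated dataset to disk (FASTA + TSV + JSON ground truth)
#'
#' @param sim A \code{simulated_dataset}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (locus in names(sim$alignments)) {
    write_fasta(sim$alignments[[locus]], file.path(dir, paste0(locus, ".fasta")))
  }
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$references, file.path(dir, "references.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(species = as.list(sim$truth$species),
                            discordant_ids = sim$truth$discordant_ids,
                            synonym_groups = sim$truth$synonym_groups),
                       file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
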