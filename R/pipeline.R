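## End-to-end orchestration: distances -> trees (+ external Newick trees)
## -> per-gene assignment -> two-gene consensus -> ABGD sweep -> GMYC ->
## composition and delimitation reports.

#' Pipeline configuration
#'
#' @param n_bootstrap Bootstrap replicates for the native NJ trees.
#' @param seed Seed recorded in the manifest and used for every stochastic
#'   step.
#' @param deletion Deletion mode for distance matrices.
#' @param abgd An \code{\link{abgd_config}}.
#' @param abgd_select_X Gap width at which the sweep partition is selected
#'   (default 1.5).
#' @param synonym_threshold Between-species mean K2P below which reference
#'   species are merged as synonyms.
#' @param support_threshold Bootstrap support regarded as strong monophyly.
#' @param run_gmyc Run GMYC per locus (default TRUE).
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_bootstrap = 100L, seed = 1L,
                            deletion = c("complete", "pairwise"),
                            abgd = abgd_config(),
                            abgd_select_X = 1.5,
                            synonym_threshold = 0.002,
                            support_threshold = 70,
                            run_gmyc = TRUE) {
  deletion <- match.arg(deletion)
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed), deletion = deletion,
                 abgd = abgd, abgd_select_X = abgd_select_X,
                 synonym_threshold = synonym_threshold,
                 support_threshold = support_threshold,
                 run_gmyc = isTRUE(run_gmyc)),
            class = "pipeline_config")
}

#' Cross-check the id spaces of all pipeline inputs
#'
#' @param alignments Named list of \code{dna_alignment} (one per locus).
#' @param metadata Metadata data.frame.
#' @param references Reference table.
#' @param external_trees Optional named list (locus -> list of \code{phylo}).
#' @return A list of class \code{input_diagnostics} with \code{warnings} and
#'   \code{errors} (character vectors); fatal problems raise an error.
#' @export
validate_inputs <- function(alignments, metadata, references,
                            external_trees = NULL) {
  warnings <- character(0); errors <- character(0)
  specimen_sets <- lapply(alignments, function(a)
    names(a$roles)[a$roles == "specimen"])
  common <- Reduce(intersect, specimen_sets)
  if (!length(common)) {
    errors <- c(errors, "no specimen id shared across loci")
  }
  for (locus in names(alignments)) {
    miss <- setdiff(unique(unlist(specimen_sets)), specimen_sets[[locus]])
    if (length(miss)) {
      warnings <- c(warnings, sprintf(
        "%d specimen(s) missing from locus %s: %s", length(miss), locus,
        paste(utils::head(miss, 10L), collapse = ", ")))
    }
    refs_here <- intersect(references$sequence_id, aln_ids(alignments[[locus]]))
    if (!length(refs_here)) {
      errors <- c(errors, sprintf("no reference sequence present in locus %s",
                                  locus))
    }
    orphan_meta <- setdiff(specimen_sets[[locus]], metadata$specimen_id)
    if (length(orphan_meta)) {
      warnings <- c(warnings, sprintf(
        "%d specimen(s) of locus %s absent from metadata", length(orphan_meta),
        locus))
    }
  }
  if (!is.null(external_trees)) {
    for (locus in names(external_trees)) {
      for (tr in external_trees[[locus]]) {
        unknown <- setdiff(tr$tip.label, aln_ids(alignments[[locus]]))
        if (length(unknown)) {
          errors <- c(errors, sprintf(
            "external %s tree has tips absent from the alignment: %s", locus,
            paste(utils::head(unknown, 5L), collapse = ", ")))
        }
      }
    }
  }
  if (length(errors)) stop("input validation failed:\n  ",
                           paste(errors, collapse = "\n  "))
  structure(list(warnings = warnings, errors = errors),
            class = "input_diagnostics")
}

#' Run the full two-locus delimitation pipeline
#'
#' Stages: distance matrices -> NJ trees with bootstrap (plus any external
#' trees) rooted on the outgroup -> per-tree assignment -> per-gene majority
#' -> synonym map -> two-gene consensus -> ABGD prior sweep with IP/RP
#' selection -> GMYC on UPGMA chronograms of collapsed haplotypes ->
#' composition and delimitation-comparison tables.
#'
#' @param alignments Named list of two \code{dna_alignment} objects; roles
#'   must mark references and outgroup tips.
#' @param metadata Metadata data.frame (\code{specimen_id},
#'   \code{site_code}).
#' @param references Reference table (\code{sequence_id}, \code{species}).
#' @param config A \code{\link{pipeline_config}}.
#' @param external_trees Optional named list locus -> list of rooted or
#'   unrooted \code{phylo} (e.g. ML/BI inferences run elsewhere); each is
#'   used as an additional inference in the per-gene majority.
#' @param out_dir Optional directory; when given, all report tables are
#'   written there as TSV/JSON together with a run manifest.
#' @return A list of class \code{pipeline_result}.
#' @export
run_pipeline <- function(alignments, metadata, references,
                         config = pipeline_config(),
                         external_trees = NULL, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  diagnostics <- stage("validate", validate_inputs(alignments, metadata,
                                                   references, external_trees))
  loci <- names(alignments)
  dms <- list(); trees <- list(); stats <- list()
  per_gene_calls <- list(); synonym_maps <- list()
  abgd_out <- list(); gmyc_out <- list()
  for (locus in loci) {
    a <- alignments[[locus]]
    outgroup <- names(a$roles)[a$roles == "outgroup"]
    stats[[locus]] <- stage("site_statistics", site_statistics(a))
    dm <- stage("distances", distance_matrix(a, deletion = config$deletion))
    dms[[locus]] <- dm
    nj_tree <- stage("trees", {
      tr <- bootstrap_supports(a, tree_config("nj", config$n_bootstrap,
                                              config$seed, config$deletion))
      if (length(outgroup)) root_with_outgroup(tr, outgroup) else tr
    })
    tr_list <- list(nj = nj_tree)
    for (et in seq_along(external_trees[[locus]])) {
      tr <- external_trees[[locus]][[et]]
      if (!ape::is.rooted(tr) && length(outgroup)) {
        tr <- root_with_outgroup(tr, intersect(outgroup, tr$tip.label))
      }
      tr_list[[paste0("external_", et)]] <- tr
    }
    trees[[locus]] <- tr_list
    calls <- stage("assignment", lapply(tr_list, function(tr) {
      res <- assign_on_tree(tr, references, dm)
      stats::setNames(res$call, res$specimen_id)
    }))
    per_gene_calls[[locus]] <- gene_majority(calls)
    ref_ids <- intersect(references$sequence_id, dm$ids)
    synonym_maps[[locus]] <- stage("synonyms", build_synonym_map(
      references[references$sequence_id %in% ref_ids, ],
      subset_distance_matrix(dm, ref_ids),
      threshold = config$synonym_threshold))
    abgd_out[[locus]] <- stage("abgd", {
      ## ABGD requires a fully defined matrix: drop saturated sequences
      und <- rowSums(!dm$defined)
      keep <- dm$ids[und == 0]
      dropped <- setdiff(dm$ids, keep)
      sw <- abgd_sweep(subset_distance_matrix(dm, keep), config$abgd)
      list(sweep = sw,
           selected = select_partition(sw, X = config$abgd_select_X),
           dropped_saturated = dropped)
    })
    if (config$run_gmyc) {
      gmyc_out[[locus]] <- stage("gmyc", {
        ing <- aln_ids(a)[a$roles != "outgroup"]
        sub <- dna_alignment(a$mat[ing, , drop = FALSE], a$locus, a$roles[ing])
        hap <- collapse_haplotypes(sub)
        chrono <- ultrametricize(hap$alignment, deletion = config$deletion)
        fit <- gmyc_fit(chrono)
        ## expand entities from haplotype representatives to all members
        ent <- fit$entities
        full <- unlist(lapply(names(ent), function(rep_id)
          stats::setNames(rep(ent[[rep_id]], length(hap$map[[rep_id]])),
                          hap$map[[rep_id]])))
        fit$entities_full <- structure(full, n_groups = attr(ent, "n_groups"),
                                       class = "species_partition")
        fit
      })
    }
  }
  ## synonym maps merged across loci (a pair near zero at either locus)
  all_species <- sort(unique(references$species))
  merged_pairs <- NULL
  for (sm in synonym_maps) {
    for (sp in names(sm)) {
      if (sm[[sp]] != sp) merged_pairs <- rbind(merged_pairs, c(sp, sm[[sp]]))
    }
  }
  synonyms <- .merge_components(all_species, merged_pairs)
  atab <- stage("combine", combine_genes(per_gene_calls[[1L]],
                                         if (length(loci) > 1L)
                                           per_gene_calls[[2L]] else
                                           stats::setNames(character(0),
                                                           character(0)),
                                         synonyms))
  composition <- stage("composition", composition_report(atab, metadata))
  partitions <- list()
  for (locus in loci) {
    partitions[[paste0("abgd_", locus)]] <- abgd_out[[locus]]$selected$rp
    if (config$run_gmyc) {
      partitions[[paste0("gmyc_", locus)]] <- gmyc_out[[locus]]$entities_full
    }
  }
  comparison <- stage("comparison", delimitation_comparison(atab, partitions))
  result <- structure(list(
    diagnostics = diagnostics, site_stats = stats, distance_matrices = dms,
    trees = trees, per_gene_calls = per_gene_calls, synonyms = synonyms,
    assignment = atab, composition = composition, abgd = abgd_out,
    gmyc = gmyc_out, comparison = comparison, config = config),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_reports(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d specimens; final calls: %s\n", nrow(x$assignment),
              paste(sprintf("%s=%d", names(table(x$assignment$final_call)),
                            table(x$assignment$final_call)), collapse = ", ")))
  invisible(x)
}

#' Write the pipeline report bundle
#'
#' Assignment, composition (Table 1 analog), per-locus ABGD sweep (S2
#' analog), GMYC JSON (S3 analog), delimitation comparison (Table 2 analog)
#' and a run manifest with the seed.
#'
#' @param result A \code{pipeline_result}.
#' @param out_dir Output directory (created if needed).
#' @export
write_pipeline_reports <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.table(df, file.path(out_dir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  w(result$assignment, "assignment.tsv")
  w(result$composition, "composition.tsv")
  w(result$comparison, "delimitation_comparison.tsv")
  for (locus in names(result$abgd)) {
    w(result$abgd[[locus]]$sweep$table, sprintf("abgd_sweep_%s.tsv", locus))
    write_partition(result$abgd[[locus]]$selected$rp,
                    file.path(out_dir, sprintf("abgd_partition_%s.tsv", locus)))
  }
  for (locus in names(result$gmyc)) {
    write_gmyc_report(result$gmyc[[locus]],
                      entities_path = file.path(out_dir,
                        sprintf("gmyc_entities_%s.tsv", locus)),
                      report_path = file.path(out_dir,
                        sprintf("gmyc_fit_%s.json", locus)))
  }
  for (locus in names(result$trees)) {
    write_newick(result$trees[[locus]]$nj,
                 file.path(out_dir, sprintf("nj_%s.nwk", locus)))
  }
  manifest <- list(
    package = "ulvabarcode",
    version = as.character(utils::packageVersion("ulvabarcode")),
    seed = result$config$seed,
    n_bootstrap = result$config$n_bootstrap,
    deletion = result$config$deletion,
    loci = names(result$distance_matrices),
    warnings = result$diagnostics$warnings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
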