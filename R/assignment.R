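## Tree-based specimen-to-species assignment and the two-gene consensus.
##
## The decision procedure mirrors standard multi-marker barcoding practice:
## a specimen is assigned to the species of the smallest clade that contains
## it together with at least one reference sequence; when that clade mixes
## references of several species the candidate with the lowest mean K2P
## distance to the specimen wins; per gene, the call is taken by majority
## across tree inferences; across genes, agreeing calls (after synonym
## mapping) give the final species, disagreement gives "discordant", a call
## at a single gene passes through flagged, and no call at all gives
## "unidentified".

#' Curate candidate reference sequences
#'
#' Builds a bootstrap NJ tree of the candidates (plus outgroup), keeps up to
#' two representatives per species whose conspecifics form a supported
#' monophyletic clade, and discards candidates that cluster away from their
#' conspecifics (a candidate is droppable when its removal restores
#' conspecific monophyly and its nearest K2P neighbour is heterospecific).
#'
#' @param a A \code{dna_alignment} of candidate references; roles must mark
#'   the outgroup tips.
#' @param labels Named character vector candidate id -> species name.
#' @param support_threshold Minimum bootstrap support for "strong" monophyly
#'   (default 70).
#' @param n_bootstrap,seed Bootstrap settings for the curation tree.
#' @param max_per_species Representatives retained per species (default 2;
#'   the most mutually divergent pair is kept).
#' @return A list of class \code{curation_result}: \code{references} (a
#'   reference-table data.frame), \code{rejected} (id, species, reason) and
#'   \code{tree}.
#' @export
curate_references <- function(a, labels, support_threshold = 70,
                              n_bootstrap = 100L, seed = 1L,
                              max_per_species = 2L) {
  outgroup <- names(a$roles)[a$roles == "outgroup"]
  if (!length(outgroup)) stop("curation requires outgroup tips (role 'outgroup')")
  if (!all(names(labels) %in% aln_ids(a))) {
    stop("labels name ids absent from the alignment")
  }
  dm <- distance_matrix(a, deletion = "complete")
  tr <- bootstrap_supports(a, tree_config("nj", n_bootstrap, seed, "complete"))
  tr <- root_with_outgroup(tr, outgroup)
  desc <- .tip_descendants(tr)
  tipset <- function(node) tr$tip.label[desc[[node]]]
  mrca_tipset <- function(ids) {
    if (length(ids) == 1L) return(ids)
    tipset(ape::getMRCA(tr, ids))
  }
  mono <- function(ids) setequal(mrca_tipset(ids), ids)
  clade_support <- function(ids) {
    if (length(ids) == 1L) return(100)
    node <- ape::getMRCA(tr, ids)
    lab <- tr$node.label[node - ape::Ntip(tr)]
    if (is.null(lab) || !nzchar(lab)) NA_real_ else as.numeric(lab)
  }
  nearest_heterospecific <- function(id, species) {
    others <- setdiff(names(labels), id)
    dd <- dm$d[id, others]
    nn <- others[which.min(dd)]
    !identical(unname(labels[nn]), unname(species))
  }
  species <- sort(unique(labels))
  kept <- character(0)
  rejected <- data.frame(sequence_id = character(0), species = character(0),
                         reason = character(0))
  for (sp in species) {
    members <- names(labels)[labels == sp]
    dropped <- character(0)
    while (length(members) >= 2L && !mono(members)) {
      ## droppable: removal restores monophyly AND nearest neighbour is
      ## heterospecific
      cand <- Filter(function(id) {
        rest <- setdiff(members, id)
        (length(rest) == 1L || mono(rest)) && nearest_heterospecific(id, sp)
      }, members)
      if (!length(cand)) break
      ## drop the candidate farthest (mean K2P) from its conspecifics
      md <- vapply(cand, function(id)
        mean(dm$d[id, setdiff(members, id)]), numeric(1))
      drop_id <- cand[which.max(md)]
      dropped <- c(dropped, drop_id)
      members <- setdiff(members, drop_id)
    }
    if (length(dropped)) {
      rejected <- rbind(rejected, data.frame(
        sequence_id = dropped, species = sp,
        reason = "clusters with distantly related species"))
    }
    if (length(members) >= 2L && !mono(members)) {
      rejected <- rbind(rejected, data.frame(
        sequence_id = members, species = sp,
        reason = "conspecifics not monophyletic"))
      next
    }
    sup <- clade_support(members)
    if (length(members) >= 2L && !is.na(sup) && sup < support_threshold) {
      rejected <- rbind(rejected, data.frame(
        sequence_id = members, species = sp,
        reason = sprintf("clade support %.0f below threshold %.0f",
                         sup, support_threshold)))
      next
    }
    if (length(members) > max_per_species) {
      ## keep the most mutually divergent pair (or top-k by that criterion)
      sub <- dm$d[members, members]
      best <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
      keep_ids <- members[unique(c(best[1L], best[2L]))][seq_len(max_per_species)]
      rejected <- rbind(rejected, data.frame(
        sequence_id = setdiff(members, keep_ids), species = sp,
        reason = "redundant (representatives already kept)"))
      members <- keep_ids
    }
    kept <- c(kept, members)
  }
  refs <- data.frame(sequence_id = kept, species = unname(labels[kept]),
                     locus = a$locus, accession = kept,
                     stringsAsFactors = FALSE)
  structure(list(references = refs, rejected = rejected, tree = tr),
            class = "curation_result")
}

#' Assign specimens to species on one rooted tree
#'
#' For each specimen tip, walks rootward to the smallest clade containing at
#' least one reference; if all references in that clade belong to one
#' species, that species is called; with several species, the one with the
#' lowest mean K2P distance to the specimen wins; when the smallest such
#' clade is the root, the specimen is unassigned.
#'
#' @param tree A rooted \code{phylo} containing specimen and reference tips.
#' @param refs Reference table (data.frame with \code{sequence_id},
#'   \code{species}); outgroup references may carry a pseudo-species name.
#' @param dm A \code{k2p_dist} covering the tree's tips.
#' @return A data.frame (one row per specimen): \code{specimen_id},
#'   \code{call} (species name or NA = unassigned), \code{k2p_to_call},
#'   \code{k2p_margin} (runner-up minus winner; NA when unambiguous).
#' @export
assign_on_tree <- function(tree, refs, dm) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted (use root_with_outgroup)")
  bad <- setdiff(tree$tip.label, dm$ids)
  if (length(bad)) stop("tree tips absent from distance matrix: ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  ref_ids <- intersect(refs$sequence_id, tree$tip.label)
  sp_of <- stats::setNames(refs$species, refs$sequence_id)
  specimens <- setdiff(tree$tip.label, refs$sequence_id)
  desc <- .tip_descendants(tree)
  parent <- .parents(tree)
  root <- ape::Ntip(tree) + 1L
  out <- lapply(specimens, function(id) {
    tip <- match(id, tree$tip.label)
    node <- parent[tip]
    repeat {
      tips_here <- tree$tip.label[desc[[node]]]
      refs_here <- intersect(tips_here, ref_ids)
      if (length(refs_here) || node == root) break
      node <- parent[node]
    }
    if (!length(refs_here) || node == root) {
      return(data.frame(specimen_id = id, call = NA_character_,
                        k2p_to_call = NA_real_, k2p_margin = NA_real_))
    }
    cand <- sort(unique(unname(sp_of[refs_here])))
    means <- vapply(cand, function(sp) {
      rr <- refs_here[sp_of[refs_here] == sp]
      mean(dm$d[id, rr], na.rm = TRUE)
    }, numeric(1))
    ord <- order(means, cand)  # lowest K2P, alphabetical tie-break
    data.frame(specimen_id = id, call = cand[ord[1L]],
               k2p_to_call = means[ord[1L]],
               k2p_margin = if (length(cand) > 1L)
                 means[ord[2L]] - means[ord[1L]] else NA_real_)
  })
  do.call(rbind, out)
}

#' Majority call across tree inferences for one gene
#'
#' @param calls A character matrix or data.frame (rows = specimens, columns
#'   = trees; NA = unassigned), or a list of per-tree call vectors named by
#'   specimen.
#' @return Named character vector specimen -> call (NA when no species gets
#'   strictly more than half of the tree calls).
#' @export
gene_majority <- function(calls) {
  if (is.list(calls) && !is.data.frame(calls)) {
    ids <- sort(unique(unlist(lapply(calls, names))))
    calls <- vapply(calls, function(v) unname(v[ids]), character(length(ids)))
    if (is.null(dim(calls))) calls <- matrix(calls, nrow = length(ids))
    rownames(calls) <- ids
  }
  calls <- as.matrix(calls)
  n_trees <- ncol(calls)
  res <- apply(calls, 1L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_character_)
    tab <- table(v)
    top <- tab[which.max(tab)]
    if (top > n_trees / 2) names(top) else NA_character_
  })
  stats::setNames(as.character(res), rownames(calls))
}

#' Merge reference species with near-zero divergence into synonyms
#'
#' Species whose between-species mean K2P among references falls below the
#' threshold are merged (transitively); the canonical name is the
#' alphabetically first member unless overridden by \code{prefer}.
#'
#' @param refs Reference table (\code{sequence_id}, \code{species}).
#' @param dm A \code{k2p_dist} covering the reference ids.
#' @param threshold Merge threshold on the between-species mean K2P
#'   (default 0.002, i.e. 0.2 percent).
#' @param prefer Optional named character vector canonical-name overrides
#'   (component member -> preferred canonical name).
#' @return Named character vector species -> canonical name (idempotent).
#' @export
build_synonym_map <- function(refs, dm, threshold = 0.002, prefer = NULL) {
  species <- sort(unique(refs$species))
  pairs <- NULL
  if (length(species) >= 2L) {
    cmb <- utils::combn(species, 2L)
    for (k in seq_len(ncol(cmb))) {
      ia <- refs$sequence_id[refs$species == cmb[1L, k]]
      ib <- refs$sequence_id[refs$species == cmb[2L, k]]
      v <- dm$d[ia, ib]
      v <- v[!is.na(v)]
      if (length(v) && mean(v) < threshold) pairs <- rbind(pairs, cmb[, k])
    }
  }
  canon <- .merge_components(species, pairs)
  if (!is.null(prefer)) {
    for (sp in names(prefer)) {
      if (sp %in% names(canon)) {
        canon[canon == canon[[sp]]] <- prefer[[sp]]
      }
    }
  }
  canon
}

#' Combine the two gene calls into the final specimen call
#'
#' @param call_gene1,call_gene2 Named character vectors specimen -> per-gene
#'   majority call (NA = unassigned; a specimen may be missing entirely from
#'   one gene).
#' @param synonyms Synonym map from \code{\link{build_synonym_map}} (applied
#'   before comparison); NULL for none.
#' @return A data.frame of class \code{assignment_table}: one row per
#'   specimen with \code{gene1_call}, \code{gene2_call}, \code{final_call}
#'   (species, \code{"discordant"} or \code{"unidentified"}), \code{flag}
#'   (\code{"two-gene"}, \code{"single-gene"}, \code{"discordant"},
#'   \code{"unidentified"}) and \code{detail} (the "A vs B" pair for
#'   discordant specimens).
#' @export
combine_genes <- function(call_gene1, call_gene2, synonyms = NULL) {
  ids <- sort(union(names(call_gene1), names(call_gene2)))
  canon <- function(x) {
    if (is.null(synonyms)) return(x)
    ifelse(!is.na(x) & x %in% names(synonyms), synonyms[x], x)
  }
  g1 <- canon(unname(call_gene1[ids]))
  g2 <- canon(unname(call_gene2[ids]))
  final <- character(length(ids)); flag <- character(length(ids))
  detail <- rep(NA_character_, length(ids))
  for (i in seq_along(ids)) {
    a <- g1[i]; b <- g2[i]
    if (!is.na(a) && !is.na(b)) {
      if (a == b) { final[i] <- a; flag[i] <- "two-gene" }
      else {
        final[i] <- "discordant"; flag[i] <- "discordant"
        detail[i] <- paste(a, "vs", b)
      }
    } else if (!is.na(a)) { final[i] <- a; flag[i] <- "single-gene"
    } else if (!is.na(b)) { final[i] <- b; flag[i] <- "single-gene"
    } else { final[i] <- "unidentified"; flag[i] <- "unidentified" }
  }
  structure(data.frame(specimen_id = ids, gene1_call = g1, gene2_call = g2,
                       final_call = final, flag = flag, detail = detail,
                       stringsAsFactors = FALSE),
            class = c("assignment_table", "data.frame"))
}

#' Species composition and relative-frequency report
#'
#' One row per final call (species, discordant), with specimen count,
#' relative frequency (percent, 1 decimal), number of distinct sites and
#' the sorted site list, plus a totals row.
#'
#' @param atab An \code{assignment_table}.
#' @param meta Metadata data.frame (\code{specimen_id}, \code{site_code}).
#' @return A data.frame.
#' @export
composition_report <- function(atab, meta) {
  if (!all(c("specimen_id", "site_code") %in% names(meta))) {
    stop("metadata with specimen_id and site_code required")
  }
  m <- merge(atab, meta[, c("specimen_id", "site_code")], by = "specimen_id")
  missing <- setdiff(atab$specimen_id, meta$specimen_id)
  if (length(missing)) {
    stop("specimens missing from metadata: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  total <- nrow(m)
  cats <- sort(unique(m$final_call))
  ## species rows first (alphabetical), then discordant/unidentified
  cats <- c(setdiff(cats, c("discordant", "unidentified")),
            intersect(c("discordant", "unidentified"), cats))
  rows <- lapply(cats, function(cc) {
    sub <- m[m$final_call == cc, ]
    sites <- sort(unique(sub$site_code))
    data.frame(species = cc, n_specimens = nrow(sub),
               relative_frequency = round(100 * nrow(sub) / total, 1),
               n_sites = length(sites),
               sites = paste(sites, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(species = "Total", n_specimens = total,
                        relative_frequency = 100,
                        n_sites = length(unique(m$site_code)), sites = ""))
}

#' Compare phylogenetic species against ABGD/GMYC partitions
#'
#' For each species in the final assignment, counts how many groups of each
#' delimitation partition intersect that species' specimens; adds a row for
#' reference-only (non-sampled) groups and totals.
#'
#' @param atab An \code{assignment_table}.
#' @param partitions Named list of \code{species_partition} objects (e.g.
#'   \code{list(abgd_tufA = ..., gmyc_tufA = ...)}).
#' @return A data.frame (species x methods).
#' @export
delimitation_comparison <- function(atab, partitions) {
  species <- sort(unique(atab$final_call[!atab$final_call %in%
                                           c("discordant", "unidentified")]))
  count_groups <- function(part, ids) {
    ids <- intersect(ids, names(part))
    length(unique(part[ids]))
  }
  rows <- lapply(species, function(sp) {
    ids <- atab$specimen_id[atab$final_call == sp]
    c(list(species = sp),
      lapply(partitions, count_groups, ids = ids))
  })
  specimen_ids <- atab$specimen_id
  nonsampled <- c(list(species = "Non-sampled (reference-only) groups"),
                  lapply(partitions, function(part) {
                    with_spec <- unique(part[intersect(specimen_ids, names(part))])
                    length(setdiff(unique(part), with_spec))
                  }))
  totals <- c(list(species = "Total groups"),
              lapply(partitions, function(part) length(unique(part))))
  tot_sampled <- c(list(species = "Total groups of analyzed specimens"),
                   lapply(partitions, function(part)
                     length(unique(part[intersect(specimen_ids, names(part))]))))
  do.call(rbind, lapply(c(rows, list(nonsampled, totals, tot_sampled)),
                        as.data.frame, stringsAsFactors = FALSE))
}
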