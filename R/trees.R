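## Distance-based tree building: NJ, UPGMA, column-bootstrap supports,
## outgroup rooting. These are the native, desk-scale stand-ins for the
## heavier ML/BI/chronogram inferences the pipeline can also ingest as
## external Newick files.

.check_dm_defined <- function(dm) {
  und <- which(!dm$defined & upper.tri(dm$defined), arr.ind = TRUE)
  if (nrow(und)) {
    pairs <- apply(und, 1L, function(r)
      paste(dm$ids[r[1L]], dm$ids[r[2L]], sep = "-"))
    stop("undefined (saturated) distances for pairs: ",
         paste(utils::head(pairs, 10L), collapse = ", "),
         if (length(pairs) > 10L) " ..." else "")
  }
}

#' Neighbor-joining tree from a K2P distance matrix
#'
#' Saitou-Nei agglomeration (via \code{ape::nj}). Negative branch-length
#' estimates are clamped to zero; the total clamped deficit is recorded in
#' the \code{"negative_length_deficit"} attribute.
#'
#' @param dm A \code{k2p_dist} with all entries defined and >= 3 ids.
#' @return An unrooted binary \code{phylo}.
#' @export
neighbor_joining <- function(dm) {
  if (length(dm$ids) < 3L) stop("need >= 3 sequences for NJ")
  .check_dm_defined(dm)
  tr <- ape::nj(dm$d)
  neg <- tr$edge.length < 0
  deficit <- -sum(tr$edge.length[neg])
  tr$edge.length[neg] <- 0
  attr(tr, "negative_length_deficit") <- deficit
  tr
}

#' UPGMA (average-linkage) ultrametric tree
#'
#' @param dm A \code{k2p_dist} with all entries defined and >= 2 ids.
#' @return A rooted ultrametric \code{phylo}; node heights equal half the
#'   average-linkage merge distances.
#' @export
upgma_tree <- function(dm) {
  if (length(dm$ids) < 2L) stop("need >= 2 sequences for UPGMA")
  .check_dm_defined(dm)
  phangorn::upgma(stats::as.dist(dm$d))
}

#' Tree inference configuration
#'
#' @param method \code{"nj"} or \code{"upgma"}.
#' @param n_bootstrap Number of bootstrap replicates (default 1000).
#' @param seed Base RNG seed; replicate r uses \code{seed + r}.
#' @param deletion Deletion mode for the distance computation.
#' @return A list of class \code{tree_config}.
#' @export
tree_config <- function(method = c("nj", "upgma"), n_bootstrap = 1000L,
                        seed = 1L, deletion = c("complete", "pairwise")) {
  method <- match.arg(method)
  deletion <- match.arg(deletion)
  if (n_bootstrap < 0L) stop("n_bootstrap must be >= 0")
  structure(list(method = method, n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed), deletion = deletion),
            class = "tree_config")
}

.build_tree <- function(dm, method) {
  if (method == "nj") neighbor_joining(dm) else upgma_tree(dm)
}

#' Distance tree with column-bootstrap split supports
#'
#' The point estimate is built from the full alignment; supports are the
#' percentage of replicate trees (alignment columns resampled with
#' replacement) containing each internal split of the point tree. Supports
#' are stored as internal node labels; with \code{n_bootstrap = 0} the point
#' tree is returned without labels.
#'
#' @param a A \code{dna_alignment}.
#' @param cfg A \code{\link{tree_config}}.
#' @param mask Optional 1-based columns to exclude.
#' @return A \code{phylo} with numeric node labels in [0, 100] (root label
#'   empty).
#' @export
bootstrap_supports <- function(a, cfg = tree_config(), mask = NULL) {
  dm <- distance_matrix(a, deletion = cfg$deletion, mask = mask)
  point <- .build_tree(dm, cfg$method)
  if (cfg$n_bootstrap == 0L) return(point)
  mat <- a$mat
  if (!is.null(mask)) mat <- mat[, -mask, drop = FALSE]
  enc <- .encode_dna(mat)
  if (cfg$deletion == "complete") {
    enc <- enc[, .complete_deletion_columns(enc), drop = FALSE]
  }
  L <- ncol(enc)
  reps <- vector("list", cfg$n_bootstrap)
  kept <- 0L
  for (r in seq_len(cfg$n_bootstrap)) {
    set.seed(cfg$seed + r)
    cols <- sample.int(L, L, replace = TRUE)
    res <- .k2p_matrix_from_enc(enc[, cols, drop = FALSE], "pairwise")
    if (any(!res$defined)) next  # saturated replicate: skip, count below
    dimnames(res$d) <- list(dm$ids, dm$ids)
    sub <- dm
    sub$d <- res$d
    sub$defined <- res$defined
    kept <- kept + 1L
    reps[[kept]] <- .build_tree(sub, cfg$method)
  }
  reps <- reps[seq_len(kept)]
  if (kept == 0L) {
    warning("all bootstrap replicates were saturated; no supports computed")
    return(point)
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  sup <- round(100 * counts / kept, 1)
  lab <- as.character(sup)
  lab[1L] <- ""  # root
  point$node.label <- lab
  attr(point, "n_bootstrap_effective") <- kept
  point
}

#' Root a tree with an outgroup
#'
#' Roots on the edge separating the outgroup from the ingroup. A multi-tip
#' outgroup must be monophyletic in the unrooted tree; otherwise an error is
#' raised (or, if \code{midpoint_fallback = TRUE}, midpoint rooting is used).
#'
#' @param tree An (un)rooted \code{phylo}.
#' @param outgroup_ids Tip labels of the outgroup.
#' @param midpoint_fallback Fall back to midpoint rooting when the outgroup
#'   is not monophyletic (default FALSE).
#' @return A rooted \code{phylo}.
#' @export
root_with_outgroup <- function(tree, outgroup_ids, midpoint_fallback = FALSE) {
  missing <- setdiff(outgroup_ids, tree$tip.label)
  if (length(missing)) {
    stop("outgroup ids absent from tree: ", paste(missing, collapse = ", "))
  }
  ingroup <- setdiff(tree$tip.label, outgroup_ids)
  # a bipartition of an unrooted tree: either side may look monophyletic
  # relative to the arbitrary stored root
  ok <- length(outgroup_ids) == 1L ||
    ape::is.monophyletic(tree, outgroup_ids) ||
    ape::is.monophyletic(tree, ingroup)
  if (!ok) {
    if (midpoint_fallback) return(phangorn::midpoint(tree))
    stop("outgroup {", paste(outgroup_ids, collapse = ","),
         "} is not monophyletic in the unrooted tree; ",
         "cannot root (set midpoint_fallback = TRUE to override)")
  }
  ## edgelabel keeps support labels attached to the same splits
  ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE,
            edgelabel = TRUE)
}
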