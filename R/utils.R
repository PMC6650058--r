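## Internal tree helpers shared across modules.

## Tip descendants (tip indices) for every node of a phylo, indexed by node
## number; a tip's entry is itself. Postorder accumulation.
.tip_descendants <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- max(tree$edge)
  out <- vector("list", nn)
  for (i in seq_len(ntip)) out[[i]] <- i
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

## parent vector indexed by node number (0 for the root)
.parents <- function(tree) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent
}

## union-find canonicalisation of a merge list: given character ids and a
## two-column matrix of pairs to merge, return named vector id -> canonical
## (alphabetically smallest member of each component)
.merge_components <- function(ids, pairs) {
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (length(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- match(pairs[r, 1L], ids); j <- match(pairs[r, 2L], ids)
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_along(ids), find, integer(1))
  canon <- vapply(seq_along(ids), function(i) {
    members <- ids[comp == comp[i]]
    sort(members)[1L]
  }, character(1))
  stats::setNames(canon, ids)
}
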