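# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# build an alignment from named sequence strings
aln <- function(..., locus = "tufA", roles = NULL) {
  dna_alignment(c(...), locus = locus, roles = roles)
}

# brute-force K2P: per-site table lookup, no vectorised shortcuts
brute_k2p <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  bases <- c("A", "C", "G", "T")
  ts_pairs <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(a)) {
    if (!(a[i] %in% bases) || !(b[i] %in% bases)) next
    n <- n + 1L
    if (a[i] == b[i]) next
    is_ts <- any(vapply(ts_pairs, function(p)
      p[1] == a[i] && p[2] == b[i], logical(1)))
    if (is_ts) ts <- ts + 1L else tv <- tv + 1L
  }
  if (n == 0L) return(NA_real_)
  P <- ts / n; Q <- tv / n
  arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -0.5 * log(arg1 * sqrt(arg2))
}

# random aligned sequences (pure ACGT)
random_seqs <- function(n, L, seed) {
  set.seed(seed)
  s <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  names(s) <- sprintf("seq%02d", seq_len(n))
  s
}

# random additive distance matrix from a random tree with positive lengths;
# returns list(tree, dm-like k2p_dist object)
random_additive_dm <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  D <- ape::cophenetic.phylo(tr)
  ids <- rownames(D)
  dm <- structure(list(ids = ids, d = D,
                       defined = matrix(TRUE, n, n, dimnames = dimnames(D)),
                       n_sites = matrix(1L, n, n), deletion_mode = "complete",
                       n_columns_used = NA_integer_),
                  class = "k2p_dist")
  list(tree = tr, dm = dm)
}

# wrap a plain symmetric matrix as a k2p_dist
as_k2p_dist <- function(D) {
  ids <- rownames(D)
  if (is.null(ids)) {
    ids <- sprintf("t%02d", seq_len(nrow(D)))
    dimnames(D) <- list(ids, ids)
  }
  structure(list(ids = ids, d = D,
                 defined = matrix(TRUE, nrow(D), ncol(D), dimnames = dimnames(D)),
                 n_sites = matrix(1L, nrow(D), ncol(D)),
                 deletion_mode = "complete", n_columns_used = NA_integer_),
            class = "k2p_dist")
}

# brute-force average-linkage (UPGMA) merge heights, O(n^3), list-based
brute_upgma_heights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  active <- rep(TRUE, nrow(D))
  heights <- numeric(0)
  avg_d <- function(ci, cj) mean(D[clusters[[ci]], clusters[[cj]]])
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- c(NA, NA); bestd <- Inf
    for (i in idx) for (j in idx) {
      if (i < j) {
        dd <- avg_d(i, j)
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd / 2)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    active[best[2]] <- FALSE
  }
  sort(heights)
}
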