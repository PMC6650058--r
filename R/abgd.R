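## Automatic Barcode Gap Discovery.
##
## Given a prior maximum intraspecific divergence P and a relative gap width
## X, the barcode gap is the first jump in the sorted pairwise-distance
## vector that (i) reaches beyond the prior (its right edge exceeds P) and
## (ii) is more than X times the typical gap width among smaller distances.
## Sequences are partitioned by single linkage below the gap midpoint; the
## recursive partition re-applies gap detection inside each group. The
## partition retained across a prior sweep is the one minimising the
## difference between initial and recursive group counts (ties towards the
## larger prior).
##
## The gap-significance window is this package's deterministic dialect of
## the original slope-based detector: for gap i (between sorted distances
## D[i] and D[i+1]) the reference width w_i is the mean of gaps 1..i; the
## very first gap, which has no left window, is compared against the mean of
## the remaining gaps instead, so reference-only data whose barcode gap is
## the first gap can still be split.

#' ABGD configuration
#'
#' @param priors Ordered vector of prior intraspecific divergences P
#'   (default 20 log-spaced values in [0.001, 0.1]).
#' @param relative_gap_widths Relative gap widths X (default 1.0, 1.5, 2.0).
#' @return A list of class \code{abgd_config}.
#' @export
abgd_config <- function(priors = exp(seq(log(0.001), log(0.1), length.out = 20)),
                        relative_gap_widths = c(1.0, 1.5, 2.0)) {
  if (any(priors <= 0 | priors >= 1)) stop("priors must lie in (0, 1)")
  if (any(relative_gap_widths <= 0)) stop("relative gap widths must be > 0")
  structure(list(priors = sort(priors),
                 relative_gap_widths = relative_gap_widths),
            class = "abgd_config")
}

#' Detect a barcode gap in a sorted distance vector
#'
#' @param distances Numeric vector of pairwise distances (sorted internally).
#' @param P Prior maximum intraspecific divergence.
#' @param X Relative gap width.
#' @return The gap-midpoint threshold, or \code{NULL} when no significant
#'   gap lies beyond the prior (including fewer than 2 distances).
#' @export
detect_gap <- function(distances, P, X) {
  d <- sort(distances)
  m <- length(d)
  if (m < 2L) return(NULL)
  g <- diff(d)
  for (i in seq_len(m - 1L)) {
    if (d[i + 1L] <= P) next  # gap must reach beyond the prior
    w <- if (i >= 2L) mean(g[1:i]) else if (m - 1L >= 2L) mean(g[-1L]) else NA
    if (is.na(w)) next
    ## relative tolerance so equal spacings never read as significant under
    ## floating-point noise
    significant <- if (w > 0) g[i] > X * w * (1 + 1e-9) else g[i] > 0
    if (significant) return((d[i] + d[i + 1L]) / 2)
  }
  NULL
}

#' Partition sequences by single linkage below a threshold
#'
#' Groups are the connected components of the graph joining pairs with
#' distance strictly below \code{theta}; group ids are contiguous from 1 in
#' order of first appearance.
#'
#' @param dm A \code{k2p_dist} (all entries defined).
#' @param theta Distance threshold (>= 0).
#' @return A named integer vector (id -> group) of class
#'   \code{species_partition} with attribute \code{n_groups}.
#' @export
partition_at_threshold <- function(dm, theta) {
  if (theta < 0) stop("theta must be >= 0")
  ids <- dm$ids
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- which(!is.na(dm$d) & dm$d < theta & upper.tri(dm$d), arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges[e, 1L]); rj <- find(edges[e, 2L])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  grp <- match(roots, unique(roots))
  names(grp) <- ids
  structure(grp, n_groups = length(unique(grp)), class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cat(sprintf("<species_partition> %d sequences in %d group(s)\n",
              length(x), attr(x, "n_groups")))
  invisible(x)
}

n_groups <- function(p) attr(p, "n_groups")

.single_partition <- function(ids) {
  grp <- rep(1L, length(ids))
  names(grp) <- ids
  structure(grp, n_groups = 1L, class = "species_partition")
}

#' Initial and recursive ABGD partition at one prior
#'
#' The initial partition (IP) cuts at the globally detected gap (one group
#' when no gap is found); the recursive partition (RP) is the fixed point of
#' re-applying gap detection within each group using that group's own
#' pairwise distances, at the same prior and gap width.
#'
#' @param dm A \code{k2p_dist}; undefined entries are rejected.
#' @param P Prior maximum intraspecific divergence.
#' @param X Relative gap width.
#' @param max_depth Maximum recursion depth (default 10).
#' @return A list of class \code{abgd_result}: \code{ip}, \code{rp},
#'   \code{theta} (or NULL), \code{P}, \code{X}, \code{converged}.
#' @export
abgd_partition <- function(dm, P, X, max_depth = 10L) {
  .check_dm_defined(dm)
  ids <- dm$ids
  all_d <- dm$d[upper.tri(dm$d)]
  theta <- detect_gap(all_d, P, X)
  ip <- if (is.null(theta)) .single_partition(ids)
        else partition_at_threshold(dm, theta)
  rp <- ip
  converged <- TRUE
  for (depth in seq_len(max_depth)) {
    changed <- FALSE
    new_groups <- list()
    for (g in seq_len(n_groups(rp))) {
      members <- names(rp)[rp == g]
      if (length(members) < 3L) { new_groups[[length(new_groups) + 1L]] <- members; next }
      sub <- subset_distance_matrix(dm, members)
      sub_d <- sub$d[upper.tri(sub$d)]
      th <- detect_gap(sub_d, P, X)
      if (is.null(th)) {
        new_groups[[length(new_groups) + 1L]] <- members
      } else {
        subp <- partition_at_threshold(sub, th)
        if (n_groups(subp) > 1L) changed <- TRUE
        for (sg in seq_len(n_groups(subp))) {
          new_groups[[length(new_groups) + 1L]] <- names(subp)[subp == sg]
        }
      }
    }
    grp <- integer(length(ids)); names(grp) <- ids
    for (k in seq_along(new_groups)) grp[new_groups[[k]]] <- k
    ## renumber in order of first appearance over the original id ordering
    grp <- grp[ids]
    grp <- match(grp, unique(grp))
    names(grp) <- ids
    rp <- structure(grp, n_groups = length(unique(grp)),
                    class = "species_partition")
    if (!changed) break
    if (depth == max_depth) converged <- FALSE
  }
  if (!converged) warning("ABGD recursion did not converge by max_depth")
  structure(list(ip = ip, rp = rp, theta = theta, P = P, X = X,
                 converged = converged),
            class = "abgd_result")
}

#' @export
print.abgd_result <- function(x, ...) {
  cat(sprintf("ABGD at P = %.4g, X = %.1f: IP %d group(s), RP %d group(s)%s\n",
              x$P, x$X, n_groups(x$ip), n_groups(x$rp),
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Sweep ABGD over priors and gap widths
#'
#' @param dm A \code{k2p_dist}.
#' @param config An \code{\link{abgd_config}}.
#' @param max_depth Passed to \code{\link{abgd_partition}}.
#' @return A list of class \code{abgd_sweep}: \code{table} (data.frame with
#'   columns P, X, n_ip, n_rp) and \code{results} (list of
#'   \code{abgd_result}, row-parallel to the table).
#' @export
abgd_sweep <- function(dm, config = abgd_config(), max_depth = 10L) {
  rows <- expand.grid(P = config$priors, X = config$relative_gap_widths,
                      KEEP.OUT.ATTRS = FALSE)
  results <- vector("list", nrow(rows))
  for (r in seq_len(nrow(rows))) {
    results[[r]] <- abgd_partition(dm, rows$P[r], rows$X[r], max_depth)
  }
  tab <- data.frame(P = rows$P, X = rows$X,
                    n_ip = vapply(results, function(x) n_groups(x$ip), integer(1)),
                    n_rp = vapply(results, function(x) n_groups(x$rp), integer(1)))
  structure(list(table = tab, results = results), class = "abgd_sweep")
}

#' @export
print.abgd_sweep <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Select the retained partition from an ABGD sweep
#'
#' Chooses the prior minimising |n_ip - n_rp|, with ties broken towards the
#' larger prior. When \code{X} is given, the sweep is first restricted to
#' that gap width.
#'
#' @param sweep An \code{abgd_sweep}.
#' @param X Optional gap width to restrict to.
#' @return The chosen \code{abgd_result}.
#' @export
select_partition <- function(sweep, X = NULL) {
  tab <- sweep$table
  idx <- seq_len(nrow(tab))
  if (!is.null(X)) idx <- idx[abs(tab$X[idx] - X) < 1e-12]
  if (!length(idx)) stop("no sweep rows (check X)")
  diffs <- abs(tab$n_ip[idx] - tab$n_rp[idx])
  best <- idx[diffs == min(diffs)]
  best <- best[which.max(tab$P[best])]
  sweep$results[[best]]
}

#' Write an ABGD sweep table (S2-style) or partition membership to TSV
#'
#' @param sweep An \code{abgd_sweep}.
#' @param path Output path.
#' @export
write_abgd_sweep <- function(sweep, path) {
  utils::write.table(sweep$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_abgd_sweep
#' @param partition A \code{species_partition}.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(data.frame(sequence_id = names(partition),
                                group = as.integer(partition)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
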