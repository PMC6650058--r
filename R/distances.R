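## Kimura 2-parameter (K80) distances and divergence summaries.
##
## P = proportion of compared sites that are transitions, Q = transversions;
## d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q)).
## A pair is "undefined" (saturated) when a log argument is <= 0 or when no
## sites are comparable; undefined pairs are flagged, never NaN.

## encode A/C/G/T as 1..4, everything else (gaps, N, ambiguity codes) as NA
.encode_dna <- function(mat) {
  x <- match(mat, c("A", "C", "G", "T"))
  dim(x) <- dim(mat)
  rownames(x) <- rownames(mat)
  x
}

.k2p_d <- function(P, Q) {
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  ok <- !is.na(a) & !is.na(b) & a > 0 & b > 0
  d <- a  # inherit shape (vector or matrix)
  d[] <- NA_real_
  d[ok] <- -0.5 * log(a[ok] * sqrt(b[ok]))
  d
}

#' Kimura 2-parameter distance between two sequences
#'
#' @param seq_a,seq_b Character vectors of single characters, or length-1
#'   strings, of equal length.
#' @param columns Optional integer vector of 1-based columns to use (the
#'   deletion set); default all columns.
#' @return A list of class \code{k2p_estimate} with elements
#'   \code{p_transitions}, \code{q_transversions}, \code{n_sites_compared},
#'   \code{d} and \code{defined}.
#' @export
k2p <- function(seq_a, seq_b, columns = NULL) {
  if (length(seq_a) == 1L) seq_a <- strsplit(seq_a, "")[[1L]]
  if (length(seq_b) == 1L) seq_b <- strsplit(seq_b, "")[[1L]]
  if (length(seq_a) != length(seq_b)) stop("sequences must have equal length")
  a <- toupper(seq_a); b <- toupper(seq_b)
  if (!is.null(columns)) { a <- a[columns]; b <- b[columns] }
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) {
    return(structure(list(p_transitions = NA_real_, q_transversions = NA_real_,
                          n_sites_compared = 0L, d = NA_real_, defined = FALSE),
                     class = "k2p_estimate"))
  }
  diffs <- a != b
  purine_a <- a %in% c("A", "G")
  purine_b <- b %in% c("A", "G")
  ts <- sum(diffs & (purine_a == purine_b))
  tv <- sum(diffs) - ts
  P <- ts / n; Q <- tv / n
  d <- .k2p_d(P, Q)
  structure(list(p_transitions = P, q_transversions = Q,
                 n_sites_compared = n, d = unname(d),
                 defined = !is.na(d)),
            class = "k2p_estimate")
}

#' @export
print.k2p_estimate <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("K2P d = %.6f (P = %.4f, Q = %.4f, n = %d sites)\n",
                x$d, x$p_transitions, x$q_transversions, x$n_sites_compared))
  } else {
    cat(sprintf("K2P undefined (saturated or no comparable sites; n = %d)\n",
                x$n_sites_compared))
  }
  invisible(x)
}

## columns with only unambiguous bases in every sequence
.complete_deletion_columns <- function(enc) which(colSums(is.na(enc)) == 0L)

## Pairwise P/Q/N counts for an encoded matrix via indicator cross-products.
## Returns list of n x n matrices: N (comparable sites), TS, TV.
.pair_counts <- function(enc) {
  valid <- !is.na(enc)
  storage.mode(valid) <- "double"
  ind <- lapply(1:4, function(b) {
    m <- (enc == b) & !is.na(enc)
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "double"
    m
  })
  N <- valid %*% t(valid)
  matches <- Reduce(`+`, lapply(ind, function(m) m %*% t(m)))
  TS <- ind[[1]] %*% t(ind[[3]]) + ind[[3]] %*% t(ind[[1]]) +  # A-G
        ind[[2]] %*% t(ind[[4]]) + ind[[4]] %*% t(ind[[2]])    # C-T
  list(N = N, TS = TS, TV = N - matches - TS)
}

.k2p_matrix_from_enc <- function(enc, deletion) {
  if (deletion == "complete") {
    keep <- .complete_deletion_columns(enc)
    if (length(keep) == 0L) {
      stop("complete deletion removes every column; use deletion = \"pairwise\"")
    }
    enc <- enc[, keep, drop = FALSE]
  }
  pc <- .pair_counts(enc)
  P <- ifelse(pc$N > 0, pc$TS / pc$N, NA_real_)
  Q <- ifelse(pc$N > 0, pc$TV / pc$N, NA_real_)
  d <- .k2p_d(P, Q)
  defined <- !is.na(d)
  d[!defined] <- NA_real_
  diag(d) <- 0; diag(defined) <- TRUE
  list(d = d, defined = defined, n_sites = pc$N,
       columns_used = if (deletion == "complete") ncol(enc) else NA_integer_)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' Under complete deletion, every column containing any gap, 'N' or IUPAC
#' ambiguity code in any sequence is removed before all pairwise
#' computations; under pairwise deletion, sites are masked per pair.
#'
#' @param a A \code{dna_alignment}.
#' @param deletion \code{"complete"} (default) or \code{"pairwise"}.
#' @param mask Optional 1-based columns to exclude before any deletion.
#' @return An object of class \code{k2p_dist}: list with \code{ids},
#'   \code{d} (symmetric numeric matrix, NA where undefined),
#'   \code{defined} (logical matrix), \code{n_sites}, \code{deletion_mode}.
#' @export
distance_matrix <- function(a, deletion = c("complete", "pairwise"),
                            mask = NULL) {
  deletion <- match.arg(deletion)
  if (aln_nseq(a) < 2L) stop("need >= 2 sequences")
  mat <- a$mat
  if (!is.null(mask)) mat <- mat[, -mask, drop = FALSE]
  enc <- .encode_dna(mat)
  res <- .k2p_matrix_from_enc(enc, deletion)
  dimnames(res$d) <- dimnames(res$defined) <- list(aln_ids(a), aln_ids(a))
  structure(list(ids = aln_ids(a), d = res$d, defined = res$defined,
                 n_sites = res$n_sites, deletion_mode = deletion,
                 n_columns_used = res$columns_used),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  nundef <- sum(!x$defined[upper.tri(x$defined)])
  cat(sprintf("<k2p_dist> %d sequences, %s deletion%s; %d undefined pair(s)\n",
              length(x$ids), x$deletion_mode,
              if (!is.na(x$n_columns_used))
                sprintf(" (%d columns used)", x$n_columns_used) else "",
              nundef))
  invisible(x)
}

#' Subset a distance matrix by id
#' @param dm A \code{k2p_dist}.
#' @param ids Ids to keep.
#' @return A \code{k2p_dist} restricted to \code{ids}.
#' @export
subset_distance_matrix <- function(dm, ids) {
  stopifnot(all(ids %in% dm$ids))
  structure(list(ids = ids, d = dm$d[ids, ids, drop = FALSE],
                 defined = dm$defined[ids, ids, drop = FALSE],
                 n_sites = dm$n_sites[match(ids, dm$ids), match(ids, dm$ids),
                                      drop = FALSE],
                 deletion_mode = dm$deletion_mode,
                 n_columns_used = dm$n_columns_used),
            class = "k2p_dist")
}

.pair_values <- function(dm, ids_a, ids_b = NULL) {
  if (is.null(ids_b)) {
    sub <- dm$d[ids_a, ids_a, drop = FALSE]
    sub[upper.tri(sub)]
  } else {
    as.vector(dm$d[ids_a, ids_b, drop = FALSE])
  }
}

#' Within- and between-group divergence summary
#'
#' Means are taken over defined pairs only; a group of size one has an
#' undefined (NA) within-group mean. The overall mean covers all defined
#' pairs, including ungrouped ids. The standard error of the overall mean is
#' estimated by bootstrap over alignment columns when an alignment is
#' supplied.
#'
#' @param dm A \code{k2p_dist}.
#' @param grouping Named character vector id -> group label; ids absent or NA
#'   are excluded from group means but kept in the overall mean.
#' @param alignment Optional \code{dna_alignment} (needed for the bootstrap
#'   standard error).
#' @param n_boot Number of column-bootstrap replicates (default 1000; 0
#'   disables the SE).
#' @param seed RNG seed for the bootstrap.
#' @return A list of class \code{divergence_summary}.
#' @export
divergence_summary <- function(dm, grouping, alignment = NULL,
                               n_boot = 1000L, seed = 1L) {
  groups <- sort(unique(stats::na.omit(unname(grouping))))
  mean_def <- function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }
  within <- vapply(groups, function(g) {
    ids <- names(grouping)[!is.na(grouping) & grouping == g]
    if (length(ids) < 2L) return(NA_real_)
    mean_def(.pair_values(dm, ids))
  }, numeric(1))
  between <- matrix(NA_real_, length(groups), length(groups),
                    dimnames = list(groups, groups))
  if (length(groups) >= 2L) {
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i < j) {
        ia <- names(grouping)[!is.na(grouping) & grouping == groups[i]]
        ib <- names(grouping)[!is.na(grouping) & grouping == groups[j]]
        between[i, j] <- between[j, i] <- mean_def(.pair_values(dm, ia, ib))
      }
    }
  }
  overall <- mean_def(dm$d[upper.tri(dm$d)])
  se <- NA_real_
  if (!is.null(alignment) && n_boot > 0L) {
    enc <- .encode_dna(alignment$mat)
    if (dm$deletion_mode == "complete") {
      enc <- enc[, .complete_deletion_columns(enc), drop = FALSE]
    }
    L <- ncol(enc)
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      res <- .k2p_matrix_from_enc(enc[, cols, drop = FALSE],
                                  if (dm$deletion_mode == "complete")
                                    "pairwise" else dm$deletion_mode)
      mean_def(res$d[upper.tri(res$d)])
    }, numeric(1))
    se <- stats::sd(reps, na.rm = TRUE)
  }
  structure(list(groups = groups, mean_within = within,
                 mean_between = between, overall_mean = overall,
                 standard_error = se, n_boot = n_boot),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf("Overall mean K2P: %.2f%%%s\n", 100 * x$overall_mean,
              if (!is.na(x$standard_error))
                sprintf(" (+/- %.2f%%)", 100 * x$standard_error) else ""))
  if (length(x$groups)) {
    cat("Within-group means (%):\n")
    print(round(100 * x$mean_within, 2))
  }
  invisible(x)
}

#' Export a K2P matrix as a square PHYLIP matrix or TSV
#'
#' @param dm A \code{k2p_dist}.
#' @param path Output path.
#' @param format \code{"phylip"} or \code{"tsv"}.
#' @export
write_distance_matrix <- function(dm, path, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  d <- dm$d
  if (format == "phylip") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(dm$ids)), con)
    for (i in seq_along(dm$ids)) {
      writeLines(paste(c(format(dm$ids[i], width = 10),
                         sprintf("%.8f", d[i, ])), collapse = "  "), con)
    }
  } else {
    utils::write.table(data.frame(id = rownames(d), d, check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
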