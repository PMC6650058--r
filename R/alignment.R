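## Alignment container and alignment-level statistics.
##
## Sequences are stored as an n x L character matrix in canonical upper case.
## IUPAC ambiguity codes and 'N' are retained in storage but treated as
## missing data by the site statistics and by the distance machinery
## (mirroring "complete deletion" behaviour of the standard barcoding tools).

.IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-")
.ROLES <- c("specimen", "reference", "outgroup")

#' Construct an aligned sequence set
#'
#' @param seqs Named character vector of equal-length sequence strings, or a
#'   character matrix (rows = sequences, rownames = ids).
#' @param locus Locus label, e.g. \code{"tufA"} or \code{"ITS"}.
#' @param roles Named character vector mapping sequence ids to one of
#'   \code{"specimen"}, \code{"reference"}, \code{"outgroup"}. Ids missing
#'   from \code{roles} default to \code{"specimen"}.
#' @return An object of class \code{dna_alignment}: a list with elements
#'   \code{mat} (character matrix), \code{locus} and \code{roles}.
#' @export
dna_alignment <- function(seqs, locus = "locus", roles = NULL) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
    ids <- rownames(mat)
  } else {
    ids <- names(seqs)
    if (is.null(ids)) stop("sequences must be named")
    n <- nchar(seqs)
    if (length(seqs) == 0L) stop("alignment contains no sequences")
    if (length(unique(n)) != 1L) {
      bad <- names(seqs)[n != n[1L]][1L]
      stop(sprintf("unequal sequence lengths: record '%s' has %d characters, expected %d",
                   bad, nchar(seqs[[bad]]), n[1L]))
    }
    mat <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
    rownames(mat) <- ids
  }
  if (ncol(mat) < 1L) stop("alignment length must be >= 1")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sequence id: '%s'", ids[duplicated(ids)][1L]))
  }
  bad <- which(!(mat %in% .IUPAC_CODES))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(mat)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(mat)) + 1L
    stop(sprintf("illegal character '%s' in record '%s' at column %d",
                 mat[bad[1L]], ids[i], j))
  }
  r <- rep("specimen", length(ids))
  names(r) <- ids
  if (!is.null(roles)) {
    unknown <- setdiff(names(roles), ids)
    if (length(unknown)) {
      stop("role_map names absent from alignment: ", paste(unknown, collapse = ", "))
    }
    if (!all(roles %in% .ROLES)) {
      stop("roles must be one of: ", paste(.ROLES, collapse = ", "))
    }
    r[names(roles)] <- roles
  }
  structure(list(mat = mat, locus = locus, roles = r), class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment> locus=%s: %d sequences x %d columns\n",
              x$locus, nrow(x$mat), ncol(x$mat)))
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$roles)), table(x$roles)),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Alignment accessors
#'
#' @param a A \code{dna_alignment}.
#' @return \code{aln_ids}: sequence ids; \code{aln_length}: number of
#'   columns; \code{aln_nseq}: number of sequences.
#' @export
aln_ids <- function(a) rownames(a$mat)

#' @rdname aln_ids
#' @export
aln_length <- function(a) ncol(a$mat)

#' @rdname aln_ids
#' @export
aln_nseq <- function(a) nrow(a$mat)

#' Read an aligned FASTA file
#'
#' @param path Path to a multi-record aligned FASTA file.
#' @param locus_name Locus label attached to the alignment.
#' @param role_map Optional named character vector (id -> role); see
#'   \code{\link{dna_alignment}}.
#' @return A \code{dna_alignment}. Sequence order is preserved and input is
#'   case-normalised to upper case.
#' @export
read_fasta <- function(path, locus_name = "locus", role_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  seqs <- vapply(recs, function(r) as.character(r)[1L], character(1))
  names(seqs) <- vapply(recs, function(r) attr(r, "name"), character(1))
  dna_alignment(seqs, locus = locus_name, roles = role_map)
}

#' Write an alignment to FASTA
#'
#' @param a A \code{dna_alignment}.
#' @param path Output path.
#' @export
write_fasta <- function(a, path) {
  seqs <- apply(a$mat, 1L, paste, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = aln_ids(a), file.out = path,
                      nbchar = 80)
  invisible(path)
}

#' Per-column site statistics of an alignment
#'
#' Counts variable, parsimony-informative and singleton columns. Only
#' unambiguous bases (A, C, G, T) are considered; gaps, 'N' and IUPAC
#' ambiguity codes are treated as missing, so an all-gap column is
#' non-variable. A column is variable when at least two distinct bases are
#' present, parsimony-informative when at least two distinct bases are each
#' carried by at least two sequences, and a singleton site otherwise.
#'
#' @param a A \code{dna_alignment}.
#' @param mask Optional integer vector of 1-based columns to exclude (e.g.
#'   ambiguously aligned regions).
#' @return A list of class \code{site_stats} with \code{alignment_length},
#'   \code{n_variable}, \code{n_parsimony_informative}, \code{n_singleton}.
#' @export
site_statistics <- function(a, mask = NULL) {
  mat <- a$mat
  if (!is.null(mask)) {
    if (any(mask < 1L | mask > ncol(mat))) stop("mask columns out of range")
    mat <- mat[, -mask, drop = FALSE]
  }
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) colSums(mat == b), numeric(ncol(mat)))
  if (ncol(mat) == 1L) counts <- matrix(counts, nrow = 1L)  # vapply drops dim
  present <- counts > 0L
  variable <- rowSums(present) >= 2L
  informative <- rowSums(counts >= 2L) >= 2L & variable
  structure(list(alignment_length = ncol(mat),
                 n_variable = sum(variable),
                 n_parsimony_informative = sum(informative),
                 n_singleton = sum(variable & !informative)),
            class = "site_stats")
}

#' @export
print.site_stats <- function(x, ...) {
  cat(sprintf("%d columns: %d variable (%d parsimony-informative, %d singleton)\n",
              x$alignment_length, x$n_variable, x$n_parsimony_informative,
              x$n_singleton))
  invisible(x)
}

#' Read / write Newick trees
#'
#' Thin wrappers around \code{ape::read.tree} / \code{ape::write.tree} used
#' to carry externally built trees (e.g. ML or Bayesian chronograms) into the
#' pipeline. Internal node labels are preserved so bootstrap/posterior
#' supports survive the round trip.
#'
#' @param path Path to a Newick file.
#' @return A \code{phylo} object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  tr
}

#' @rdname read_newick
#' @param tree A \code{phylo} object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read the specimen metadata table
#'
#' Tab-separated with header columns \code{specimen_id}, \code{site_code},
#' \code{morphotype} (morphotype may be empty).
#'
#' @param path Path to a TSV file.
#' @return A data.frame.
#' @export
read_metadata <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "site_code")
  if (!all(need %in% names(m))) {
    stop("metadata table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"morphotype" %in% names(m)) m$morphotype <- ""
  m
}

#' Read the reference table
#'
#' Tab-separated with header columns \code{sequence_id}, \code{species} and
#' optionally \code{locus}, \code{accession}.
#'
#' @param path Path to a TSV file.
#' @return A data.frame mapping reference sequence ids to species names.
#' @export
read_reference_table <- function(path) {
  r <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "species")
  if (!all(need %in% names(r))) {
    stop("reference table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(r$sequence_id)) stop("duplicate reference sequence_id")
  if (any(!nzchar(r$species))) stop("empty species name in reference table")
  r
}
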