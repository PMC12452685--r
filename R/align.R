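check_residues <- function(x, what = "sequence") {
  bad <- setdiff(unique(strsplit(x, "")[[1]]), AA_ALPHABET)
  if (length(bad))
    stop(what, " contains non-amino-acid characters: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment of two protein sequences. A gap run
#' of length L costs `gap_open + L * gap_extend`. Percent identity is the
#' fraction of identical aligned positions over the alignment columns,
#' excluding terminal gap columns (so length differences do not dominate).
#'
#' @param a,b Protein sequences (strings over the 20 residues plus X).
#' @param submat Substitution matrix name ("BLOSUM62") or a named matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @return A list of class `pairwise_alignment` with `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `score` and `identity`.
#' @examples
#' global_align("ACDE", "ACDF")$identity  # 0.75
#' @export
global_align <- function(a, b, submat = "BLOSUM62", gap_open = 11,
                         gap_extend = 1) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  a <- toupper(a); b <- toupper(b)
  check_residues(a, "sequence a")
  check_residues(b, "sequence b")
  S <- resolve_submat(submat)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  C <- S[av, bv, drop = FALSE]
  res <- affine_dp_cpp(C, gap_open, gap_extend, 1.0)
  ai <- res$a_index
  bi <- res$b_index
  arow <- ifelse(ai > 0, av[pmax(ai, 1)], GAP_CHAR)
  brow <- ifelse(bi > 0, bv[pmax(bi, 1)], GAP_CHAR)
  structure(list(aligned_a = paste(arow, collapse = ""),
                 aligned_b = paste(brow, collapse = ""),
                 score = res$score,
                 identity = alignment_identity(arow, brow)),
            class = "pairwise_alignment")
}

# identity over alignment columns, excluding terminal gap columns
alignment_identity <- function(arow, brow) {
  both <- arow != GAP_CHAR & brow != GAP_CHAR
  if (!any(both)) return(0)
  core <- seq(min(which(both)), max(which(both)))
  sum(arow[core] == brow[core] & both[core]) / length(core)
}

#' Pairwise percent identity
#'
#' Convenience wrapper around [global_align()] returning only the
#' identity fraction.
#'
#' @inheritParams global_align
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, submat = "BLOSUM62", gap_open = 11,
                              gap_extend = 1) {
  global_align(a, b, submat, gap_open, gap_extend)$identity
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %.1f, identity %.3f\n",
              x$score, x$identity))
  w <- 60
  n <- nchar(x$aligned_a)
  for (s in seq(1, n, by = w)) {
    e <- min(s + w - 1, n)
    cat(substr(x$aligned_a, s, e), "\n")
    cat(substr(x$aligned_b, s, e), "\n\n")
  }
  invisible(x)
}

#' Pairwise distance matrix from global alignments
#'
#' Distance is `1 - identity` from [global_align()] of every sequence
#' pair; the matrix is symmetric with a zero diagonal and feeds both the
#' progressive-alignment guide tree and the UPGMA phylogeny.
#'
#' @param records A `gox_records` data.frame or a named character vector
#'   of sequences (>= 2).
#' @inheritParams global_align
#' @return A symmetric numeric matrix with accession dimnames.
#' @export
estimate_distances <- function(records, submat = "BLOSUM62", gap_open = 11,
                               gap_extend = 1) {
  seqs <- as_named_seqs(records)
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  S <- resolve_submat(submat)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      id <- global_align(seqs[[i]], seqs[[j]], S, gap_open,
                         gap_extend)$identity
      d[i, j] <- d[j, i] <- 1 - id
    }
  }
  d
}

as_named_seqs <- function(records) {
  if (is.data.frame(records)) {
    stats::setNames(records$residues, records$accession)
  } else {
    seqs <- as.character(records)
    if (is.null(names(records))) stop("sequences must be named")
    stats::setNames(seqs, names(records))
  }
}
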