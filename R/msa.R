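#' Progressive multiple sequence alignment
#'
#' Aligns sequences progressively along a guide tree: profiles are merged
#' in tree post-order by profile-profile global alignment (mean pairwise
#' substitution score between column residue distributions, affine gaps,
#' terminal gap runs half-weighted). Gaps once inserted are never removed.
#'
#' @param records A `gox_records` data.frame or named character vector of
#'   sequences.
#' @param guide Guide tree (`upgma_tree`, e.g. from [build_guide_tree()]);
#'   built from [estimate_distances()] when NULL. Leaves must match the
#'   sequence names.
#' @inheritParams global_align
#' @return An object of class `protein_msa`: equal-length gapped rows,
#'   one per input sequence, in input order.
#' @export
progressive_align <- function(records, guide = NULL, submat = "BLOSUM62",
                              gap_open = 11, gap_extend = 1) {
  seqs <- as_named_seqs(records)
  if (length(seqs) < 2) stop("need at least 2 sequences")
  for (i in seq_along(seqs)) check_residues(seqs[[i]], names(seqs)[i])
  if (is.null(guide))
    guide <- build_guide_tree(estimate_distances(seqs, submat, gap_open,
                                                 gap_extend))
  phy <- as_phylo(guide)
  if (!setequal(phy$tip.label, names(seqs)))
    stop("guide tree leaves do not match sequence names")
  S <- resolve_submat(submat)[AA_ALPHABET, AA_ALPHABET]

  ntip <- length(phy$tip.label)
  children <- split(phy$edge[, 2], phy$edge[, 1])

  align_node <- function(node) {
    if (node <= ntip) {
      lab <- phy$tip.label[node]
      m <- matrix(strsplit(seqs[[lab]], "")[[1]], nrow = 1)
      rownames(m) <- lab
      return(m)
    }
    kids <- children[[as.character(node)]]
    if (length(kids) != 2) stop("guide tree must be binary")
    merge_alignments(align_node(kids[1]), align_node(kids[2]), S,
                     gap_open, gap_extend)
  }
  m <- align_node(ntip + 1L)
  m <- m[match(names(seqs), rownames(m)), , drop = FALSE]
  new_protein_msa(apply(m, 1, paste, collapse = ""))
}

# column residue distributions over the 21-letter alphabet; gap mass is
# dropped (gappy columns carry less weight in the match score)
profile_of <- function(m) {
  n <- nrow(m)
  apply(m, 2, function(col) {
    tabulate(match(col, AA_ALPHABET), length(AA_ALPHABET)) / n
  })
}

merge_alignments <- function(A, B, S, gap_open, gap_extend) {
  PA <- profile_of(A)
  PB <- profile_of(B)
  C <- t(PA) %*% S %*% PB
  res <- affine_dp_cpp(C, gap_open, gap_extend, 0.5)
  ai <- res$a_index
  bi <- res$b_index
  ncols <- length(ai)
  out <- matrix(GAP_CHAR, nrow(A) + nrow(B), ncols)
  out[seq_len(nrow(A)), ai > 0] <- A[, ai[ai > 0], drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), bi > 0] <- B[, bi[bi > 0], drop = FALSE]
  rownames(out) <- c(rownames(A), rownames(B))
  out
}

new_protein_msa <- function(rows) {
  stopifnot(length(unique(nchar(rows))) == 1)
  structure(list(labels = names(rows), rows = unname(rows),
                 ncol = nchar(rows[[1]])),
            class = "protein_msa")
}

#' Construct a multiple alignment object from gapped rows
#'
#' @param rows Named character vector of equal-length gapped sequences.
#' @return A `protein_msa` object.
#' @export
protein_msa <- function(rows) {
  if (is.null(names(rows))) names(rows) <- paste0("S", seq_along(rows))
  new_protein_msa(rows)
}

#' @export
as.matrix.protein_msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$rows, ""))
  rownames(m) <- x$labels
  m
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("<protein_msa> %d sequences x %d columns\n",
              length(x$rows), x$ncol))
  shown <- utils::head(seq_along(x$rows), 5)
  for (i in shown)
    cat(sprintf("%-12s %s%s\n", x$labels[i], substr(x$rows[i], 1, 50),
                if (x$ncol > 50) "..." else ""))
  if (length(x$rows) > 5) cat("... and", length(x$rows) - 5, "more\n")
  invisible(x)
}

#' Remove gaps from an alignment row
#'
#' @param msa A `protein_msa`.
#' @param label Row label.
#' @return The ungapped sequence string.
#' @export
ungap_row <- function(msa, label) {
  i <- match(label, msa$labels)
  if (is.na(i)) stop("no such row: ", label)
  gsub(GAP_CHAR, "", msa$rows[i], fixed = TRUE)
}

#' Write an alignment to aligned FASTA
#'
#' @param msa A `protein_msa`.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path, width = 60) {
  write_fasta(stats::setNames(msa$rows, msa$labels), path, width)
}

#' Read an aligned FASTA file as a multiple alignment
#'
#' @param path Path to aligned FASTA.
#' @return A `protein_msa`.
#' @export
read_msa_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  rows <- toupper(as.character(aa))
  names(rows) <- sub("\\s.*$", "", names(aa))
  new_protein_msa(rows)
}
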