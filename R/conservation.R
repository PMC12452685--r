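#' Physicochemical residue property table
#'
#' Ten-property table (hydrophobic, polar, small, tiny, aliphatic,
#' aromatic, positive, negative, charged, proline) in the
#' Livingstone-Barton/AMAS tradition, packaged as a TSV and used as the
#' single source for conservation scoring. X (unknown) carries no
#' properties.
#'
#' @return A logical matrix, residues x properties.
#' @export
residue_properties <- function() {
  tab <- utils::read.delim(gox_extdata("residue_properties.tsv"),
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1]) == 1
  rownames(m) <- tab$residue
  m
}

#' Per-column conservation profile of an alignment
#'
#' For every column: residue counts, modal frequencies and an AMAS-style
#' conservation score on the 0-11 scale. A score of 11 means absolute
#' conservation (a single residue type and no gaps). Otherwise the score
#' is the number of physicochemical properties whose presence/absence is
#' uniform across the column's residue types, capped at 10 and reduced by
#' 1 when the gap fraction exceeds 0.2 -- so 10 means full property
#' conservation despite residue variation. Residue types below
#' `min_residue_freq` of the column's residues are treated as noise and
#' ignored by the property-uniformity count (large alignments score
#' robustly in the presence of rare stray residues); all frequencies
#' (`top_freq`, `top2_freq`) keep gap rows in the denominator.
#'
#' @param msa A `protein_msa`.
#' @param props Property table from [residue_properties()].
#' @param min_residue_freq Noise floor for the property-uniformity count,
#'   as a fraction of the column's non-gap residues.
#' @param min_freq Modal-frequency threshold used only to render the
#'   consensus symbols (fixed residue vs two-residue class vs x).
#' @return An object of class `consensus_track`: per-column data.frame
#'   `profiles` (index, modal residues, top_freq, top2_freq, gap_count,
#'   gap_frac, score), the residue `counts` matrix, the `consensus`
#'   symbol vector and `n_rows`.
#' @export
profile_columns <- function(msa, props = residue_properties(),
                            min_residue_freq = 0.05, min_freq = 0.80) {
  if (!inherits(msa, "protein_msa")) stop("msa must be a protein_msa")
  m <- as.matrix(msa)
  if (!nrow(m) || !ncol(m)) stop("empty alignment")
  n <- nrow(m)
  nc <- ncol(m)
  symbols <- c(AA_ALPHABET, GAP_CHAR)
  counts <- apply(m, 2, function(col) {
    idx <- match(col, symbols)
    if (anyNA(idx))
      stop("alignment contains invalid characters: ",
           paste(unique(col[is.na(idx)]), collapse = ", "))
    tabulate(idx, length(symbols))
  })
  rownames(counts) <- symbols
  gap_count <- counts[GAP_CHAR, ]
  res_counts <- counts[AA_ALPHABET, , drop = FALSE]

  modal1 <- character(nc); modal2 <- character(nc)
  top_freq <- numeric(nc); top2_freq <- numeric(nc)
  score <- integer(nc)
  for (j in seq_len(nc)) {
    cnt <- res_counts[, j]
    ord <- order(-cnt, AA_ALPHABET)
    modal1[j] <- AA_ALPHABET[ord[1]]
    modal2[j] <- if (cnt[ord[2]] > 0) AA_ALPHABET[ord[2]] else ""
    top_freq[j] <- cnt[ord[1]] / n
    top2_freq[j] <- (cnt[ord[1]] + cnt[ord[2]]) / n
    score[j] <- column_score(cnt, gap_count[j], n, props, min_residue_freq)
  }
  gap_frac <- gap_count / n
  consensus <- ifelse(top_freq >= min_freq, modal1,
                      ifelse(top2_freq >= min_freq,
                             paste0("[", modal1, "/", modal2, "]"), "x"))
  structure(list(profiles = data.frame(index = seq_len(nc),
                                       modal1 = modal1, modal2 = modal2,
                                       top_freq = top_freq,
                                       top2_freq = top2_freq,
                                       gap_count = as.integer(gap_count),
                                       gap_frac = gap_frac,
                                       score = score,
                                       stringsAsFactors = FALSE),
                 counts = counts, consensus = consensus, n_rows = n,
                 min_freq = min_freq),
            class = "consensus_track")
}

column_score <- function(res_cnt, gaps, n, props, min_residue_freq) {
  nongap <- n - gaps
  if (nongap == 0) return(0L)
  types <- AA_ALPHABET[res_cnt > 0]
  if (length(types) == 1 && gaps == 0) return(11L)
  considered <- AA_ALPHABET[res_cnt / nongap >= min_residue_freq]
  if (!length(considered)) considered <- types
  p <- props[considered, , drop = FALSE]
  uniform <- colSums(p) %in% c(0L, nrow(p))
  s <- min(sum(uniform), 10L)
  if (gaps / n > 0.2) s <- s - 1L
  max(s, 0L)
}

#' @export
print.consensus_track <- function(x, ...) {
  cat(sprintf("<consensus_track> %d columns, %d rows\n",
              nrow(x$profiles), x$n_rows))
  cat("consensus:", paste(utils::head(x$consensus, 40), collapse = ""),
      if (nrow(x$profiles) > 40) "..." else "", "\n")
  cat(sprintf("columns with score >= 9: %d\n",
              sum(x$profiles$score >= 9)))
  invisible(x)
}

#' Write a consensus track to TSV
#'
#' @param track A `consensus_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  df <- track$profiles
  df$consensus <- track$consensus
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
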