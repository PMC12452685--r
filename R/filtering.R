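#' Dataset filter configuration
#'
#' Bundles the dataset-construction thresholds: header keyword exclusion,
#' the 420-460 residue length window, and the reference-anchored identity
#' band (kept iff `min_identity < identity < max_identity`, both strict,
#' so the reference itself is excluded by the upper bound).
#'
#' @param min_len,max_len Length window in residues (inclusive).
#' @param min_identity,max_identity Identity band as fractions; strict
#'   inequalities at both ends.
#' @param exclusion_keywords Lowercase substrings; a record whose header
#'   description contains any of them (case-insensitively) is dropped.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_len = 420, max_len = 460,
                          min_identity = 0.35, max_identity = 0.97,
                          exclusion_keywords = c("partial", "synthetic",
                                                 "hypothetical", "fragment")) {
  stopifnot(min_len <= max_len,
            min_identity >= 0, min_identity < max_identity,
            max_identity <= 1)
  structure(list(min_len = min_len, max_len = max_len,
                 min_identity = min_identity, max_identity = max_identity,
                 exclusion_keywords = tolower(exclusion_keywords)),
            class = "filter_config")
}

#' Exclude records by header keywords
#'
#' Drops every record whose header description contains one of the
#' configured exclusion keywords (case-insensitive substring match, e.g.
#' partial/synthetic/hypothetical sequences).
#'
#' @param records A `gox_records` data.frame.
#' @param config A [filter_config()].
#' @return A list with `kept` (records) and `dropped` (data.frame with
#'   `accession` and the triggering `reason`).
#' @export
exclude_by_keywords <- function(records, config = filter_config()) {
  desc <- tolower(records$description)
  reason <- rep(NA_character_, nrow(records))
  for (kw in config$exclusion_keywords) {
    hit <- is.na(reason) & grepl(kw, desc, fixed = TRUE)
    reason[hit] <- kw
  }
  dropped <- data.frame(accession = records$accession[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  list(kept = records[is.na(reason), , drop = FALSE], dropped = dropped)
}

#' Filter records by sequence length
#'
#' Keeps records with `min_len <= length <= max_len` (both inclusive).
#'
#' @inheritParams exclude_by_keywords
#' @return The kept records.
#' @export
length_filter <- function(records, config = filter_config()) {
  len <- nchar(records$residues)
  records[len >= config$min_len & len <= config$max_len, , drop = FALSE]
}

#' Filter records by identity to a reference sequence
#'
#' Aligns every record globally against the reference and keeps those with
#' `min_identity < identity < max_identity` (strict at both ends; the
#' reference itself, at identity 1, is excluded by the upper bound).
#'
#' @inheritParams exclude_by_keywords
#' @param reference Reference sequence (string) or a single-row records
#'   data.frame.
#' @inheritParams global_align
#' @return The kept records, with the computed identities in attribute
#'   `identity` (named by accession, for all input records).
#' @export
identity_band_filter <- function(records, reference,
                                 config = filter_config(),
                                 submat = "BLOSUM62", gap_open = 11,
                                 gap_extend = 1) {
  ref <- if (is.data.frame(reference)) reference$residues[1] else reference
  stopifnot(is.character(ref), nzchar(ref))
  S <- resolve_submat(submat)
  ids <- vapply(records$residues, function(s)
    global_align(s, ref, S, gap_open, gap_extend)$identity, numeric(1))
  names(ids) <- records$accession
  keep <- ids > config$min_identity & ids < config$max_identity
  out <- records[keep, , drop = FALSE]
  attr(out, "identity") <- ids
  out
}

#' Apply all dataset filters
#'
#' Keyword exclusion, then length window, then identity band. The filters
#' commute; this order is just the cheapest-first execution.
#'
#' @inheritParams identity_band_filter
#' @return A list with `kept` (records) and `dropped` (data.frame of
#'   `accession`, `stage`, `reason`).
#' @export
apply_filters <- function(records, reference, config = filter_config(),
                          submat = "BLOSUM62", gap_open = 11,
                          gap_extend = 1) {
  kw <- exclude_by_keywords(records, config)
  dropped <- if (nrow(kw$dropped))
    data.frame(accession = kw$dropped$accession, stage = "keyword",
               reason = kw$dropped$reason, stringsAsFactors = FALSE)
  else
    data.frame(accession = character(), stage = character(),
               reason = character(), stringsAsFactors = FALSE)
  lenkept <- length_filter(kw$kept, config)
  lendrop <- setdiff(kw$kept$accession, lenkept$accession)
  if (length(lendrop)) {
    len <- nchar(kw$kept$residues)[match(lendrop, kw$kept$accession)]
    dropped <- rbind(dropped,
                     data.frame(accession = lendrop, stage = "length",
                                reason = as.character(len),
                                stringsAsFactors = FALSE))
  }
  idkept <- identity_band_filter(lenkept, reference, config, submat,
                                 gap_open, gap_extend)
  ids <- attr(idkept, "identity")
  iddrop <- setdiff(lenkept$accession, idkept$accession)
  if (length(iddrop))
    dropped <- rbind(dropped,
                     data.frame(accession = iddrop, stage = "identity",
                                reason = sprintf("%.4f", ids[iddrop]),
                                stringsAsFactors = FALSE))
  list(kept = idkept, dropped = dropped)
}
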