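#' Extract conserved motifs from a consensus track
#'
#' A column is conserved iff its conservation score is at least
#' `min_score` and its modal frequency (or the joint frequency of the two
#' most frequent residues) is at least `min_freq`. Conserved columns
#' render as a fixed residue (modal frequency alone passes the bar) or a
#' two-residue class, ordered by descending frequency with alphabetical
#' tie-break. Maximal blocks of conserved columns are joined across
#' interior wildcard runs of at most `max_wildcard_run` columns; blocks
#' are kept when they span at least `min_length` columns and contain at
#' least `min_anchors` non-wildcard tokens, and are named M1, M2, ... in
#' order of appearance.
#'
#' @param track A `consensus_track` from [profile_columns()].
#' @param min_score Conservation-score threshold (0-11 scale).
#' @param min_freq Frequency threshold (gap rows count in the denominator).
#' @param max_wildcard_run Longest interior non-conserved run bridged.
#' @param min_length Minimum block length in columns.
#' @param min_anchors Minimum number of non-wildcard tokens.
#' @return A list of `motif_pattern` objects with `start_column` /
#'   `end_column` set.
#' @export
extract_motifs <- function(track, min_score = 9, min_freq = 0.80,
                           max_wildcard_run = 3, min_length = 6,
                           min_anchors = 3) {
  stopifnot(inherits(track, "consensus_track"))
  pr <- track$profiles
  conserved <- pr$score >= min_score &
    (pr$top_freq >= min_freq | pr$top2_freq >= min_freq)
  if (!any(conserved)) return(list())
  cols <- which(conserved)
  # group conserved columns, bridging interior runs <= max_wildcard_run
  breaks <- which(diff(cols) > max_wildcard_run + 1L)
  starts <- cols[c(1L, breaks + 1L)]
  ends <- cols[c(breaks, length(cols))]
  out <- list()
  for (b in seq_along(starts)) {
    span <- starts[b]:ends[b]
    tokens <- lapply(span, function(j) {
      if (conserved[j]) {
        if (pr$top_freq[j] >= min_freq) new_token("fixed", pr$modal1[j])
        else new_token("class", c(pr$modal1[j], pr$modal2[j]))
      } else new_token("wild")
    })
    n_anchor <- sum(conserved[span])
    if (length(span) >= min_length && n_anchor >= min_anchors)
      out[[length(out) + 1L]] <- motif_pattern(tokens,
                                              start_column = starts[b],
                                              end_column = ends[b])
  }
  for (i in seq_along(out)) out[[i]]$name <- paste0("M", i)
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Write extracted motifs to TSV
#'
#' @param motifs List of `motif_pattern` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motifs_tsv <- function(motifs, path) {
  df <- data.frame(name = vapply(motifs, function(m) m$name %||% "", ""),
                   pattern = vapply(motifs, render_motif, ""),
                   start_column = vapply(motifs, `[[`, 1L, "start_column"),
                   end_column = vapply(motifs, `[[`, 1L, "end_column"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detect a proline-rich motif (PRM)
#'
#' Collects the columns whose proline frequency reaches `min_freq` inside
#' the densest window of `window` columns, reports every P-x-x-x-P and
#' P-x-x-P spacing among consecutive prolines, and renders the composite
#' spacing pattern (runs longer than 3 print as `(x)n`).
#'
#' @param x A `consensus_track`, or a plain consensus/residue string (a
#'   position counts as proline iff the character is P).
#' @param min_freq Per-column proline frequency threshold.
#' @param window Window width in columns.
#' @return An object of class `prm_report`: `proline_columns`,
#'   `n_prolines`, `submotifs` (type/start/end), `composite` (pattern
#'   string, empty when fewer than 2 prolines) and `frequencies`.
#' @examples
#' detect_prm("PAAAPAAAAAAPAAAAAPAAPAAAAAAAAPAAAP")
#' @export
detect_prm <- function(x, min_freq = 0.80, window = 60) {
  if (inherits(x, "consensus_track")) {
    p_freq <- x$counts["P", ] / x$n_rows
  } else if (is.character(x) && length(x) == 1) {
    p_freq <- as.numeric(strsplit(toupper(x), "")[[1]] == "P")
  } else stop("x must be a consensus_track or a single string")
  cols <- which(p_freq >= min_freq)
  if (length(cols)) {
    # densest window of `window` consecutive columns, earliest on ties
    counts <- vapply(cols, function(s)
      sum(cols >= s & cols <= s + window - 1L), integer(1))
    best <- cols[which.max(counts)]
    cols <- cols[cols >= best & cols <= best + window - 1L]
  }
  spacing <- if (length(cols) >= 2) diff(cols) - 1L else integer(0)
  sub <- data.frame(type = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  for (i in seq_along(spacing)) {
    if (spacing[i] == 3L)
      sub <- rbind(sub, data.frame(type = "PxxxP", start = cols[i],
                                   end = cols[i + 1]))
    if (spacing[i] == 2L)
      sub <- rbind(sub, data.frame(type = "PxxP", start = cols[i],
                                   end = cols[i + 1]))
  }
  composite <- if (length(cols) >= 2) {
    parts <- "P"
    for (g in spacing) {
      parts <- c(parts,
                 if (g == 0) character(0)
                 else if (g <= 3) rep("x", g)
                 else paste0("(x)", g),
                 "P")
    }
    paste(parts, collapse = "-")
  } else ""
  structure(list(proline_columns = cols, n_prolines = length(cols),
                 submotifs = sub, composite = composite,
                 frequencies = p_freq[cols]),
            class = "prm_report")
}

#' @export
print.prm_report <- function(x, ...) {
  cat(sprintf("<prm_report> %d conserved prolines\n", x$n_prolines))
  if (x$n_prolines) {
    cat("columns:", paste(x$proline_columns, collapse = ", "), "\n")
    if (nzchar(x$composite)) cat("composite:", x$composite, "\n")
    if (nrow(x$submotifs))
      cat("submotifs:", paste(x$submotifs$type, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Proline spacings of a composite PRM pattern
#'
#' Inverse of the composite rendering: parses a spacing pattern such as
#' `P-x-x-x-P-(x)6-P` back into the number of x positions between
#' consecutive prolines (useful to check that a composite regenerates
#' the proline positions exactly).
#'
#' @param composite Composite pattern string.
#' @return Integer vector of between-proline spacings.
#' @export
prm_spacings <- function(composite) {
  p <- parse_motif(composite)
  gaps <- integer(0)
  pending <- 0L
  first <- TRUE
  for (tk in p$tokens) {
    if (tk$type == "wild") {
      if (tk$min != tk$max) stop("composite must have fixed spacings")
      pending <- pending + tk$min
    } else if (tk$type == "fixed" && tk$residues == "P") {
      if (!first) gaps <- c(gaps, pending)
      pending <- 0L
      first <- FALSE
    } else stop("composite may only contain P and wildcards")
  }
  gaps
}
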