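# PROSITE-style motif patterns in the field's dash notation:
# fixed residue "G", two-or-more residue class "[V/I]", wildcard "x",
# fixed run "(x)6" / "x(3)", variable run "x(1,2)".

new_token <- function(type, residues = NULL, min = 1L, max = 1L) {
  list(type = type, residues = residues, min = as.integer(min),
       max = as.integer(max))
}

#' Construct a motif pattern from tokens
#'
#' Adjacent wildcards are merged into one variable-length run; the first
#' and last tokens must be non-wildcard.
#'
#' @param tokens List of tokens from [parse_motif()] internals.
#' @param name Optional motif name (e.g. "M1").
#' @param start_column,end_column Alignment columns when extracted.
#' @return An object of class `motif_pattern`.
#' @export
motif_pattern <- function(tokens, name = NULL, start_column = NA_integer_,
                          end_column = NA_integer_) {
  tokens <- merge_wildcards(tokens)
  if (!length(tokens)) stop("empty pattern")
  if (tokens[[1]]$type == "wild" ||
      tokens[[length(tokens)]]$type == "wild")
    stop("first and last pattern tokens must be non-wildcard")
  structure(list(tokens = tokens, name = name,
                 start_column = start_column, end_column = end_column),
            class = "motif_pattern")
}

merge_wildcards <- function(tokens) {
  out <- list()
  for (tk in tokens) {
    nlast <- length(out)
    if (tk$type == "wild" && nlast && out[[nlast]]$type == "wild") {
      out[[nlast]]$min <- out[[nlast]]$min + tk$min
      out[[nlast]]$max <- out[[nlast]]$max + tk$max
    } else {
      out[[nlast + 1L]] <- tk
    }
  }
  out
}

#' Parse a motif pattern string
#'
#' Accepts the dash notation used throughout: `[V/I]-x-G-x(1,2)-G`,
#' fixed wildcard runs as `x(3)` or `(x)6`.
#'
#' @param x Pattern string (or an already-parsed `motif_pattern`,
#'   returned unchanged).
#' @param name Optional name.
#' @return A `motif_pattern`.
#' @examples
#' parse_motif("[V/I]-x-G-x(1,2)-G-x-x-G-x-x-x-[G/A]")
#' @export
parse_motif <- function(x, name = NULL) {
  if (inherits(x, "motif_pattern")) return(x)
  stopifnot(is.character(x), length(x) == 1)
  parts <- strsplit(trimws(x), "-", fixed = TRUE)[[1]]
  tokens <- lapply(parts, function(p) {
    if (grepl("^[A-Z]$", p)) return(new_token("fixed", p))
    if (grepl("^\\[[A-Z](/[A-Z])+\\]$", p)) {
      res <- strsplit(gsub("\\[|\\]", "", p), "/", fixed = TRUE)[[1]]
      return(new_token("class", res))
    }
    if (p == "x") return(new_token("wild"))
    m <- regmatches(p, regexec("^x\\((\\d+),(\\d+)\\)$", p))[[1]]
    if (length(m))
      return(new_token("wild", min = m[2], max = m[3]))
    m <- regmatches(p, regexec("^x\\((\\d+)\\)$", p))[[1]]
    if (length(m)) return(new_token("wild", min = m[2], max = m[2]))
    m <- regmatches(p, regexec("^\\(x\\)(\\d+)$", p))[[1]]
    if (length(m)) return(new_token("wild", min = m[2], max = m[2]))
    stop("unparseable pattern token: '", p, "'")
  })
  motif_pattern(tokens, name = name)
}

#' Render a motif pattern in canonical dash notation
#'
#' Fixed-length wildcard runs up to 3 render as repeated `x`; longer
#' fixed runs as `(x)n`; variable runs as `x(m,n)`. Class residues are
#' printed in the stored order (descending frequency when extracted).
#'
#' @param p A `motif_pattern`.
#' @return The pattern string.
#' @export
render_motif <- function(p) {
  stopifnot(inherits(p, "motif_pattern"))
  parts <- unlist(lapply(p$tokens, function(tk) {
    switch(tk$type,
           fixed = tk$residues,
           class = paste0("[", paste(tk$residues, collapse = "/"), "]"),
           wild = if (tk$min == tk$max) {
             if (tk$min <= 3) rep("x", tk$min)
             else paste0("(x)", tk$min)
           } else sprintf("x(%d,%d)", tk$min, tk$max))
  }))
  paste(parts, collapse = "-")
}

#' @export
format.motif_pattern <- function(x, ...) {
  paste0(if (!is.null(x$name)) paste0(x$name, ": ") else "", render_motif(x),
         if (!is.na(x$start_column))
           sprintf(" [columns %d-%d]", x$start_column, x$end_column)
         else "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern>", format(x), "\n")
  invisible(x)
}

#' Token-level motif equality
#'
#' Two patterns are equal when their canonical token lists match;
#' residue classes are compared as sets (`[V/I]` equals `[I/V]`).
#'
#' @param a,b Patterns or pattern strings.
#' @return TRUE or FALSE.
#' @export
motifs_equal <- function(a, b) {
  a <- parse_motif(a); b <- parse_motif(b)
  if (length(a$tokens) != length(b$tokens)) return(FALSE)
  for (i in seq_along(a$tokens)) {
    ta <- a$tokens[[i]]; tb <- b$tokens[[i]]
    if (ta$type != tb$type) return(FALSE)
    if (ta$type == "wild") {
      if (ta$min != tb$min || ta$max != tb$max) return(FALSE)
    } else if (!setequal(ta$residues, tb$residues)) return(FALSE)
  }
  TRUE
}

token_min_len <- function(p) sum(vapply(p$tokens, `[[`, 1L, "min"))

#' Match a motif pattern against a sequence
#'
#' Reports every match, enumerating all variable wildcard-length
#' assignments; overlapping hits (and hits of different length at the
#' same start) are all reported.
#'
#' @param p A `motif_pattern` or pattern string.
#' @param seq Residue string.
#' @return A data.frame with 1-based `start`, `end` and the `match`
#'   substring, ordered by start then end.
#' @examples
#' match_pattern("P-x-x-x-P", "PAAAP")
#' @export
match_pattern <- function(p, seq) {
  p <- parse_motif(p)
  stopifnot(is.character(seq), length(seq) == 1)
  chars <- strsplit(toupper(seq), "")[[1]]
  nseq <- length(chars)
  ntok <- length(p$tokens)
  hits_start <- integer(0); hits_end <- integer(0)
  rec <- function(ti, pos, start) {
    if (ti > ntok) {
      hits_start <<- c(hits_start, start)
      hits_end <<- c(hits_end, pos - 1L)
      return(invisible())
    }
    tk <- p$tokens[[ti]]
    if (tk$type == "wild") {
      for (len in tk$min:tk$max)
        if (pos + len - 1L <= nseq) rec(ti + 1L, pos + len, start)
    } else {
      if (pos > nseq) return(invisible())
      ok <- if (tk$type == "fixed") chars[pos] == tk$residues
            else chars[pos] %in% tk$residues
      if (ok) rec(ti + 1L, pos + 1L, start)
    }
  }
  maxstart <- nseq - token_min_len(p) + 1L
  if (maxstart >= 1) for (s in seq_len(maxstart)) rec(1L, s, s)
  if (length(hits_start)) {
    df <- unique(data.frame(start = hits_start, end = hits_end))
    df <- df[order(df$start, df$end), , drop = FALSE]
    df$match <- substring(seq, df$start, df$end)
    rownames(df) <- NULL
    df
  } else {
    data.frame(start = integer(), end = integer(), match = character(),
               stringsAsFactors = FALSE)
  }
}

matches_fully <- function(p, seq) {
  h <- match_pattern(p, seq)
  any(h$start == 1L & h$end == nchar(seq))
}

# lightweight whole-string matcher on a character vector (no hit table)
full_match_chars <- function(tokens, chars) {
  n <- length(chars)
  rec <- function(ti, pos) {
    if (ti > length(tokens)) return(pos == n + 1L)
    tk <- tokens[[ti]]
    if (tk$type == "wild") {
      for (len in tk$min:tk$max)
        if (pos + len <= n + 1L && rec(ti + 1L, pos + len)) return(TRUE)
      return(FALSE)
    }
    if (pos > n) return(FALSE)
    if (!(chars[pos] %in% tk$residues)) return(FALSE)
    rec(ti + 1L, pos + 1L)
  }
  rec(1L, 1L)
}

#' Does one pattern subsume another?
#'
#' TRUE iff every string matching `specific` also matches `general`.
#' Decided by enumerating the strings of `specific` over a reduced
#' alphabet: the residues named by either pattern plus one sentinel
#' residue standing in for all others (sound and complete, since the
#' patterns cannot distinguish unmentioned residues).
#'
#' @param general,specific Patterns or pattern strings.
#' @param max_enum Safety cap on the number of enumerated strings.
#' @return TRUE or FALSE.
#' @examples
#' pattern_subsumes("[V/I]-x-G-x(1,2)-G-x-x-G-x-x-x-[G/A]",
#'                  "[V/I]-[I/V]-G-A-G-x-[V/I]-G-x-x-x-A")
#' @export
pattern_subsumes <- function(general, specific, max_enum = 2e6) {
  general <- parse_motif(general)
  specific <- parse_motif(specific)
  mentioned <- unique(unlist(lapply(c(general$tokens, specific$tokens),
                                    function(tk) tk$residues)))
  sentinel <- setdiff(AA20, mentioned)
  alphabet <- c(mentioned, if (length(sentinel)) sentinel[1])
  # per-position choice sets of `specific` for one wildcard-length choice
  choice_sets <- function(lens) {
    sets <- list(); w <- 0L
    for (tk in specific$tokens) {
      if (tk$type == "wild") {
        w <- w + 1L
        sets <- c(sets, rep(list(alphabet), lens[w]))
      } else sets <- c(sets, list(tk$residues))
    }
    sets
  }
  wilds <- Filter(function(tk) tk$type == "wild", specific$tokens)
  len_choices <- if (length(wilds))
    expand.grid(lapply(wilds, function(tk) tk$min:tk$max))
  else data.frame(row.names = 1)
  tried <- 0L
  for (r in seq_len(nrow(len_choices))) {
    sets <- choice_sets(as.integer(len_choices[r, ]))
    # depth-first enumeration so a counterexample exits immediately
    chars <- character(length(sets))
    dfs <- function(i) {
      if (i > length(sets)) {
        tried <<- tried + 1L
        if (tried > max_enum)
          stop("subsumption check too large (over ", format(max_enum),
               " strings)")
        return(full_match_chars(general$tokens, chars))
      }
      for (res in sets[[i]]) {
        chars[i] <<- res
        if (!dfs(i + 1L)) return(FALSE)
      }
      TRUE
    }
    if (length(sets) && !dfs(1L)) return(FALSE)
  }
  TRUE
}

#' Packaged library of known motif patterns
#'
#' The eight consensus motifs (M1-M8), the extended Rossmann-fold
#' FAD-binding signature, the W-x-x-x-[F/Y] interaction motif and the
#' proline-rich composite, ready for scanning new sequences.
#'
#' @return A named list of `motif_pattern` objects; the raw table is in
#'   attribute `table`.
#' @export
known_motifs <- function() {
  tab <- utils::read.delim(gox_extdata("known_motifs.tsv"),
                           stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i)
    parse_motif(tab$pattern[i], name = tab$name[i]))
  names(out) <- tab$name
  attr(out, "table") <- tab
  out
}
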