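#' Parse an NCBI-style FASTA header
#'
#' Splits a header into accession (first whitespace-delimited token),
#' protein-name label ("ontology") and bracketed organism. The organism is
#' taken from the last balanced `[...]` span; the ontology is the text
#' between accession and organism, trimmed.
#'
#' @param header Character vector of header lines (without the leading `>`).
#' @return A data.frame with columns `accession`, `description`,
#'   `ontology_raw` and `organism` (empty string when absent).
#' @examples
#' parse_fasta_header("ACZ58378.1 glyphosate oxidoreductase [Ochrobactrum sp. G-1]")
#' @export
parse_fasta_header <- function(header) {
  header <- trimws(header)
  accession <- sub("\\s.*$", "", header)
  description <- trimws(substring(header, nchar(accession) + 1L))
  ontology <- character(length(header))
  organism <- character(length(header))
  for (i in seq_along(header)) {
    rest <- description[i]
    spans <- gregexpr("\\[[^][]*\\]", rest)[[1]]
    if (spans[1] != -1) {
      k <- length(spans)
      s <- spans[k]
      len <- attr(spans, "match.length")[k]
      organism[i] <- substr(rest, s + 1L, s + len - 2L)
      ontology[i] <- trimws(substr(rest, 1L, s - 1L))
    } else {
      organism[i] <- ""
      ontology[i] <- rest
    }
  }
  data.frame(accession = accession, description = description,
             ontology_raw = ontology, organism = organism,
             stringsAsFactors = FALSE)
}

validate_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) stop("malformed FASTA in ", path, ": file is empty")
  first <- nonempty[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA in ", path, ": line ", first,
         " does not start a record ('>' expected)")
  last_header <- NA_integer_
  seen_seq <- FALSE
  for (i in nonempty) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) {
      if (!is.na(last_header) && !seen_seq)
        stop("malformed FASTA in ", path, ": header at line ", last_header,
             " has no sequence")
      last_header <- i
      seen_seq <- FALSE
    } else {
      if (grepl("[^A-Za-z*.-]", ln))
        stop("malformed FASTA in ", path, ": line ", i,
             " contains non-sequence characters")
      seen_seq <- TRUE
    }
  }
  if (!is.na(last_header) && !seen_seq)
    stop("malformed FASTA in ", path, ": header at line ", last_header,
         " has no sequence")
  invisible(TRUE)
}

#' Read an annotated protein FASTA file
#'
#' Reads protein sequences and parses their headers into sequence records:
#' accession, raw and grouped ontology label, organism, and taxonomy at the
#' best available rank (from a packaged/offline taxonomy table).
#'
#' @param path Path to a FASTA file.
#' @param taxonomy Optional taxonomy lookup table from
#'   [load_taxonomy_table()]; organisms not in the table (or records
#'   without a bracketed organism) get `best_rank = "none"`.
#' @param rules Ontology grouping rules from [load_ontology_rules()];
#'   defaults to the packaged rule set.
#' @return A data.frame of class `gox_records` with one row per sequence:
#'   `accession`, `description`, `ontology_raw`, `ontology_grouped`,
#'   `organism`, `residues`, the seven `tax_*` rank columns and
#'   `best_rank`.
#' @export
read_annotated_fasta <- function(path, taxonomy = NULL,
                                 rules = default_ontology_rules()) {
  validate_fasta_lines(path)
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  meta <- parse_fasta_header(headers)
  dup <- unique(meta$accession[duplicated(meta$accession)])
  if (length(dup))
    stop("duplicate accessions in ", path, ": ", paste(dup, collapse = ", "))
  rec <- meta
  rec$ontology_grouped <- normalize_ontology(rec$ontology_raw, rules)
  rec$residues <- toupper(as.character(aa))
  if (any(!nzchar(rec$residues)))
    stop("empty sequence for accession ",
         rec$accession[!nzchar(rec$residues)][1])
  rec <- attach_taxonomy(rec, taxonomy)
  rownames(rec) <- NULL
  class(rec) <- c("gox_records", "data.frame")
  rec
}

#' Attach taxonomy information to sequence records
#'
#' Fills the `tax_domain` ... `tax_species` columns and `best_rank` (the
#' deepest populated rank) by looking up each record's organism in a
#' taxonomy table. Unknown or absent organisms get `best_rank = "none"`.
#'
#' @param records A `gox_records` data.frame (or any data.frame with an
#'   `organism` column).
#' @param taxonomy A taxonomy table from [load_taxonomy_table()], or NULL.
#' @return `records` with taxonomy columns populated.
#' @export
attach_taxonomy <- function(records, taxonomy = NULL) {
  for (r in TAX_RANKS) records[[paste0("tax_", r)]] <- ""
  records$best_rank <- "none"
  if (is.null(taxonomy)) return(records)
  idx <- match(records$organism, taxonomy$organism)
  hit <- which(!is.na(idx) & nzchar(records$organism))
  for (i in hit) {
    row <- taxonomy[idx[i], ]
    depth <- match(row$rank, TAX_RANKS)
    if (is.na(depth)) next
    names <- strsplit(row$lineage, ";", fixed = TRUE)[[1]]
    names <- trimws(names)
    depth <- min(depth, length(names))
    for (k in seq_len(depth))
      records[[paste0("tax_", TAX_RANKS[k])]][i] <- names[k]
    records$best_rank[i] <- TAX_RANKS[depth]
  }
  records
}

#' Load an organism taxonomy lookup table
#'
#' The table is a TSV with columns `organism`, `rank` (one of domain,
#' phylum, class, order, family, genus, species) and `lineage`
#' (semicolon-separated names from domain down to `rank`). It stands in
#' for a live taxonomy service so analyses stay reproducible offline.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of class `taxonomy_table`.
#' @export
load_taxonomy_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("organism", "rank", "lineage")
  if (!all(need %in% names(tab)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(tab$rank), TAX_RANKS)
  if (length(bad))
    stop("unknown taxonomy rank(s): ", paste(bad, collapse = ", "))
  class(tab) <- c("taxonomy_table", "data.frame")
  tab
}

#' Write sequence records to FASTA
#'
#' Headers are reconstructed as `accession description`, so a write/read
#' cycle reproduces accessions and sequences byte-identically. Sequences
#' are wrapped at `width` columns.
#'
#' @param records A `gox_records` data.frame, or a named character vector
#'   of sequences.
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  if (is.data.frame(records)) {
    seqs <- records$residues
    headers <- ifelse(nzchar(records$description),
                      paste(records$accession, records$description),
                      records$accession)
  } else {
    seqs <- as.character(records)
    headers <- names(records)
    if (is.null(headers)) stop("sequences must be named")
  }
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- headers
  Biostrings::writeXStringSet(aa, filepath = path, width = width)
  invisible(path)
}

#' @export
print.gox_records <- function(x, ...) {
  cat(sprintf("<gox_records> %d sequences, lengths %d-%d\n", nrow(x),
              min(nchar(x$residues)), max(nchar(x$residues))))
  shown <- utils::head(x[, c("accession", "ontology_grouped", "organism",
                             "best_rank")], 6)
  print.data.frame(shown)
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more\n")
  invisible(x)
}
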