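# Ontology here means the protein-name label parsed from a FASTA header
# (e.g. "FAD-binding oxidoreductase"), not a formal GO term.

norm_key <- function(x) trimws(gsub("[ _-]+", " ", tolower(x)))

#' Load ontology grouping rules
#'
#' Rules come from a YAML file with two maps: `synonyms` (raw label to
#' canonical label; spelling/punctuation variants of the same name) and
#' `groups` (canonical label to subtype label; e.g. all D-amino acid
#' dehydrogenase variants to "(D-) amino acid dehydrogenase"). Keys are
#' matched case-insensitively, ignoring runs of spaces, underscores and
#' hyphens.
#'
#' @param path Path to the YAML rules file.
#' @return An object of class `ontology_rules`.
#' @seealso [default_ontology_rules()], [normalize_ontology()]
#' @export
load_ontology_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  syn <- unlist(raw$synonyms %||% list())
  grp <- unlist(raw$groups %||% list())
  names(syn) <- norm_key(names(syn))
  names(grp) <- norm_key(names(grp))
  structure(list(synonyms = syn, groups = grp), class = "ontology_rules")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default ontology grouping rules
#'
#' The packaged rule set covering the FAD-binding/-dependent oxidoreductase
#' spelling variants and the (D-) amino acid dehydrogenase / Gox /
#' dependent-oxidoreductase subtype groupings.
#'
#' @return An object of class `ontology_rules`.
#' @export
default_ontology_rules <- function() {
  load_ontology_rules(gox_extdata("ontology_rules.yaml"))
}

#' Normalize a protein-name label to its subtype
#'
#' Applies the synonym map, then the group map. Unknown labels are returned
#' unchanged; the function is total and idempotent.
#'
#' @param label Character vector of raw labels.
#' @param rules An `ontology_rules` object.
#' @return Character vector of subtype labels.
#' @examples
#' normalize_ontology("oxidoreductase_ FAD-binding")
#' normalize_ontology("D-amino acid dehydrogenase small subunit")
#' @export
normalize_ontology <- function(label, rules = default_ontology_rules()) {
  stopifnot(is.character(label))
  key <- norm_key(label)
  hit <- match(key, names(rules$synonyms))
  canon <- ifelse(is.na(hit), label, unname(rules$synonyms[hit]))
  key2 <- norm_key(canon)
  hit2 <- match(key2, names(rules$groups))
  ifelse(is.na(hit2), canon, unname(rules$groups[hit2]))
}

#' Ontology composition report
#'
#' Aggregates sequence records (or a label/count fixture table) into
#' subtype counts and fractions after applying the grouping rules.
#'
#' @param x Either a `gox_records` data.frame, or a data.frame with
#'   columns `protein_type` and `count` (a transcribed published table).
#' @param rules An `ontology_rules` object.
#' @return A data.frame (`subtype`, `count`, `fraction`), sorted by
#'   decreasing count, with attributes `n_records` (total count),
#'   `n_subtypes` and `n_raw_labels` (distinct input labels).
#' @export
ontology_report <- function(x, rules = default_ontology_rules()) {
  if (is.data.frame(x) && all(c("protein_type", "count") %in% names(x))) {
    labels <- x$protein_type
    weights <- x$count
  } else if (is.data.frame(x) && "ontology_raw" %in% names(x)) {
    labels <- x$ontology_raw
    weights <- rep(1L, length(labels))
  } else {
    stop("x must be sequence records or a protein_type/count table")
  }
  if (!length(labels) || sum(weights) == 0) stop("empty input")
  subtype <- normalize_ontology(labels, rules)
  counts <- tapply(weights, subtype, sum)
  out <- data.frame(subtype = names(counts),
                    count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$subtype), ]
  out$fraction <- out$count / sum(out$count)
  rownames(out) <- NULL
  attr(out, "n_records") <- sum(out$count)
  attr(out, "n_subtypes") <- nrow(out)
  attr(out, "n_raw_labels") <- length(unique(labels))
  out
}

#' Taxonomy annotation report
#'
#' Summarizes how deeply the records are taxonomically annotated
#' (per-rank fractions, each record counted once at its deepest populated
#' rank) and the per-class composition.
#'
#' @param records A `gox_records` data.frame.
#' @return A list of class `taxonomy_report` with elements `rank_table`
#'   (`rank`, `count`, `fraction`) and `class_table` (`class`, `count`).
#' @export
taxonomy_report <- function(records) {
  ranks <- factor(records$best_rank, levels = c(TAX_RANKS, "none"))
  rank_table <- data.frame(rank = levels(ranks),
                           count = as.integer(table(ranks)),
                           stringsAsFactors = FALSE)
  rank_table$fraction <- rank_table$count / nrow(records)
  cls <- records$tax_class[nzchar(records$tax_class)]
  if (length(cls)) {
    tab <- sort(table(cls), decreasing = TRUE)
    class_table <- data.frame(class = names(tab), count = as.integer(tab),
                              stringsAsFactors = FALSE)
  } else {
    class_table <- data.frame(class = character(), count = integer(),
                              stringsAsFactors = FALSE)
  }
  structure(list(rank_table = rank_table, class_table = class_table,
                 n_records = nrow(records)),
            class = "taxonomy_report")
}

#' @export
print.taxonomy_report <- function(x, ...) {
  cat("<taxonomy_report>", x$n_records, "records\n")
  print.data.frame(x$rank_table)
  if (nrow(x$class_table)) {
    cat("top classes:\n")
    print.data.frame(utils::head(x$class_table, 5))
  }
  invisible(x)
}
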