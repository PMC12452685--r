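# Region-annotation handling: consumes per-sequence predicted regions
# (signal peptide, transmembrane, cytoplasmic, non-cytoplasmic, named
# domains) from a TSV standing in for InterPro/CDD/Phobius output, and
# classifies each sequence into an architecture group (1a-1f without a
# signal peptide, 2a-2d with one).

REGION_TYPES <- c("signal_peptide", "transmembrane", "cytoplasmic",
                  "non_cytoplasmic", "named_domain")

#' Merge synonymous region-type labels
#'
#' Annotation databases label the same region type differently;
#' SIGNAL_PEPTIDE and SignalP_noTM merge into signal_peptide, TMhelix and
#' TRANSMEMBRANE into transmembrane (case-insensitive). Unknown labels
#' become named domains.
#'
#' @param x Character vector of raw region-type labels.
#' @return Character vector over the closed region-type set.
#' @examples
#' merge_labels(c("TMhelix", "SignalP_noTM", "DadA"))
#' @export
merge_labels <- function(x) {
  key <- toupper(gsub("[ _-]+", "_", trimws(x)))
  out <- rep("named_domain", length(x))
  out[key %in% c("SIGNAL_PEPTIDE", "SIGNALP_NOTM", "SIGNAL")] <- "signal_peptide"
  out[key %in% c("TMHELIX", "TRANSMEMBRANE", "TM")] <- "transmembrane"
  out[key == "CYTOPLASMIC"] <- "cytoplasmic"
  out[key %in% c("NON_CYTOPLASMIC", "NONCYTOPLASMIC")] <- "non_cytoplasmic"
  out
}

#' Load per-sequence region annotations
#'
#' Reads a TSV with columns accession, type, name, start, end, source;
#' validates 1-based inclusive coordinates against the sequence lengths
#' and applies [merge_labels()]. Overlapping regions are permitted.
#'
#' @param path Path to the TSV.
#' @param records The `gox_records` the annotations refer to.
#' @return A data.frame of class `region_annotations` with an added
#'   `region_type` column.
#' @export
load_regions <- function(path, records) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "type", "name", "start", "end", "source")
  if (!all(need %in% names(tab)))
    stop("region table must have columns: ", paste(need, collapse = ", "))
  lens <- stats::setNames(nchar(records$residues), records$accession)
  for (i in seq_len(nrow(tab))) {
    acc <- tab$accession[i]
    if (!acc %in% names(lens))
      stop("row ", i, ": unknown accession ", acc)
    if (is.na(tab$start[i]) || is.na(tab$end[i]) ||
        tab$start[i] < 1 || tab$end[i] < tab$start[i] ||
        tab$end[i] > lens[[acc]])
      stop("row ", i, " (", acc, "): coordinates ", tab$start[i], "-",
           tab$end[i], " out of range for length ", lens[[acc]])
  }
  tab$region_type <- merge_labels(tab$type)
  class(tab) <- c("region_annotations", "data.frame")
  tab
}

#' Architecture subcategory rules
#'
#' Loads the rule table mapping region-presence patterns to subcategory
#' labels. Group 1 covers sequences without a signal peptide (1a-1f),
#' group 2 those with one (2a-2d); within each group the pattern over
#' {TM, C, NC} (transmembrane, cytoplasmic, non-cytoplasmic) selects the
#' subcategory. The packaged default is a reconstruction ordered by
#' increasing combination complexity and is meant to be edited.
#'
#' @param path Path to a YAML rule file; defaults to the packaged table.
#' @return An object of class `architecture_rules` (pattern -> label maps
#'   for both groups).
#' @export
architecture_rules <- function(path = gox_extdata("architecture_rules.yaml")) {
  raw <- yaml::read_yaml(path)
  as_map <- function(group) {
    out <- character(0)
    for (label in names(group))
      for (pat in group[[label]])
        out[normalize_pattern(pat)] <- label
    out
  }
  structure(list(group1 = as_map(raw$group1), group2 = as_map(raw$group2)),
            class = "architecture_rules")
}

normalize_pattern <- function(x) {
  parts <- setdiff(toupper(strsplit(x, "+", fixed = TRUE)[[1]]), "")
  paste(sort(parts), collapse = "+")
}

presence_pattern <- function(region_types) {
  has <- c(TM = "transmembrane" %in% region_types,
           C = "cytoplasmic" %in% region_types,
           NC = "non_cytoplasmic" %in% region_types)
  paste(sort(names(has)[has]), collapse = "+")
}

#' Classify sequences into architecture groups
#'
#' The signal peptide splits group 1 (absent) from group 2 (present);
#' the presence pattern of transmembrane/cytoplasmic/non-cytoplasmic
#' regions picks the subcategory from the rule table. Sequences with no
#' annotated regions at all fall in 1a.
#'
#' @param regions A `region_annotations` data.frame (possibly empty).
#' @param records The `gox_records` to classify (all of them; records with
#'   no region rows are covered too).
#' @param rules An `architecture_rules` object.
#' @return A data.frame (`accession`, `group` label, `pattern`).
#' @export
classify_architecture <- function(regions, records,
                                  rules = architecture_rules()) {
  if (!"region_type" %in% names(regions))
    regions$region_type <- merge_labels(regions$type)
  split_regions <- split(regions$region_type, regions$accession)
  out <- data.frame(accession = records$accession,
                    group = NA_character_, pattern = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    rt <- split_regions[[out$accession[i]]] %||% character(0)
    has_sp <- "signal_peptide" %in% rt
    pat <- presence_pattern(rt)
    map <- if (has_sp) rules$group2 else rules$group1
    label <- unname(map[match(pat, names(map))])
    if (is.na(label))
      stop("no rule for presence pattern '", pat, "' in group ",
           if (has_sp) 2 else 1, " (accession ", out$accession[i], ")")
    out$group[i] <- label
    out$pattern[i] <- if (has_sp && nzchar(pat)) paste0("SP+", pat)
                      else if (has_sp) "SP" else pat
  }
  out
}

#' Architecture distributions across clusters and phyla
#'
#' Builds the presence/count tables of architecture groups across the
#' phylogenetic clusters and across the bacterial phyla.
#'
#' @param arch Classification from [classify_architecture()].
#' @param assignment A `cluster_assignment` covering the accessions.
#' @param records The `gox_records` (for `tax_phylum`).
#' @return A list of class `architecture_distributions` with
#'   `cluster_counts`, `cluster_presence`, `phylum_counts`,
#'   `phylum_presence` (groups x clusters / phyla matrices).
#' @export
architecture_distributions <- function(arch, assignment, records) {
  cl <- assignment[match(arch$accession, names(assignment))]
  if (anyNA(cl)) stop("every classified accession must be clustered")
  phylum <- records$tax_phylum[match(arch$accession, records$accession)]
  phylum <- ifelse(is.na(phylum) | !nzchar(phylum), "unclassified", phylum)
  groups <- sort(unique(arch$group))
  cluster_counts <- as.matrix(table(group = factor(arch$group, groups),
                                    cluster = as.integer(cl)))
  phylum_counts <- as.matrix(table(group = factor(arch$group, groups),
                                   phylum = phylum))
  structure(list(cluster_counts = cluster_counts,
                 cluster_presence = cluster_counts > 0,
                 phylum_counts = phylum_counts,
                 phylum_presence = phylum_counts > 0),
            class = "architecture_distributions")
}

#' @export
print.architecture_distributions <- function(x, ...) {
  cat("<architecture_distributions> groups x clusters presence:\n")
  print(ifelse(x$cluster_presence, "x", ""))
  invisible(x)
}
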