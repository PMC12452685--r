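AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) paste(sample(AA, len, replace = TRUE),
                                      collapse = "")

# minimal records data.frame for functions that only need labels
make_records <- function(accession, residues = NULL, ontology = "FAD-binding oxidoreductase",
                         organism = "", tax_class = "", tax_phylum = "",
                         description = NULL) {
  n <- length(accession)
  if (is.null(residues)) residues <- vapply(rep(60, n), random_protein, "")
  ontology <- rep_len(ontology, n)
  if (is.null(description)) description <- ontology
  df <- data.frame(accession = accession,
                   description = rep_len(description, n),
                   ontology_raw = ontology,
                   ontology_grouped = normalize_ontology(ontology),
                   organism = rep_len(organism, n),
                   residues = residues,
                   stringsAsFactors = FALSE)
  for (r in c("domain", "phylum", "class", "order", "family", "genus",
              "species"))
    df[[paste0("tax_", r)]] <- rep("", n)
  df$tax_class <- rep_len(tax_class, n)
  df$tax_phylum <- rep_len(tax_phylum, n)
  df$best_rank <- rep("none", n)
  class(df) <- c("gox_records", "data.frame")
  df
}

make_assignment <- function(clusters, accessions) {
  structure(as.integer(clusters), names = accessions,
            k = max(clusters), cut_height = NA_real_,
            class = "cluster_assignment")
}

table2_fixture <- function() {
  utils::read.delim(system.file("extdata", "table2_ontologies.tsv",
                                package = "goxprofiler"),
                    stringsAsFactors = FALSE)
}

table1_fixture <- function() {
  utils::read.delim(system.file("extdata", "table1_classes.tsv",
                                package = "goxprofiler"),
                    stringsAsFactors = FALSE)
}

# substitute exactly k positions with a different residue
mutate_exact <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(AA, chars[p]), 1)
  paste(chars, collapse = "")
}
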