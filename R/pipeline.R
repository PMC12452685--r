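#' Pipeline configuration
#'
#' Collects every path and parameter of the full analysis (filter ->
#' align -> tree -> clusters -> motifs -> architecture -> reports). All
#' referenced input files must exist at construction time; the output
#' directory is created if needed.
#'
#' @param fasta Input protein FASTA.
#' @param reference Reference-sequence FASTA (first record used).
#' @param out_dir Output directory for stage files and the manifest.
#' @param taxonomy Optional taxonomy TSV ([load_taxonomy_table()]).
#' @param regions Optional region-annotation TSV ([load_regions()]).
#' @param rules_file Optional ontology-rules YAML (packaged default
#'   otherwise).
#' @param filter A [filter_config()].
#' @inheritParams global_align
#' @param k Number of phylogenetic clusters.
#' @param groups Number of supergroups.
#' @param min_score,min_freq Motif-extraction thresholds.
#' @param seed Seed for the (seeded) stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, reference, out_dir,
                            taxonomy = NULL, regions = NULL,
                            rules_file = NULL,
                            filter = filter_config(),
                            submat = "BLOSUM62", gap_open = 11,
                            gap_extend = 1, k = 10, groups = 4,
                            min_score = 9, min_freq = 0.80, seed = 1) {
  for (p in c(fasta, reference, taxonomy, regions, rules_file))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  structure(list(fasta = fasta, reference = reference, out_dir = out_dir,
                 taxonomy = taxonomy, regions = regions,
                 rules_file = rules_file, filter = filter, submat = submat,
                 gap_open = gap_open, gap_extend = gap_extend, k = k,
                 groups = groups, min_score = min_score,
                 min_freq = min_freq, seed = seed),
            class = "pipeline_config")
}

#' Run the full profiling pipeline
#'
#' Executes the stages in fixed order, writing each stage's outputs
#' before the next begins and recording every parameter, record count and
#' output-file checksum in a run manifest (written as JSON). A stage
#' failure is recorded in the manifest and stops downstream stages.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(parameters = list(
    filter = unclass(config$filter), submat = as.character(config$submat)[1],
    gap_open = config$gap_open, gap_extend = config$gap_extend,
    k = config$k, groups = config$groups, min_score = config$min_score,
    min_freq = config$min_freq, seed = config$seed),
    stages = list())
  state <- new.env(parent = emptyenv())
  failed <- FALSE

  stage <- function(name, fun) {
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible())
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      failed <<- TRUE
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
    } else {
      res$status <- "ok"
      if (!is.null(res$outputs))
        res$md5 <- as.list(tools::md5sum(unlist(res$outputs)))
      manifest$stages[[name]] <<- res
    }
    invisible()
  }

  stage("read", function() {
    rules <- if (is.null(config$rules_file)) default_ontology_rules()
             else load_ontology_rules(config$rules_file)
    tax <- if (is.null(config$taxonomy)) NULL
           else load_taxonomy_table(config$taxonomy)
    state$rules <- rules
    state$records <- read_annotated_fasta(config$fasta, tax, rules)
    state$reference <- read_annotated_fasta(config$reference, tax, rules)
    list(counts = list(records = nrow(state$records)))
  })

  stage("filter", function() {
    fr <- apply_filters(state$records, state$reference$residues[1],
                        config$filter, config$submat, config$gap_open,
                        config$gap_extend)
    state$kept <- fr$kept
    write_fasta(fr$kept, out("kept.fa"))
    utils::write.table(fr$dropped, out("dropped.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(counts = list(kept = nrow(fr$kept), dropped = nrow(fr$dropped)),
         outputs = list(out("kept.fa"), out("dropped.tsv")))
  })

  stage("distances", function() {
    state$dm <- estimate_distances(state$kept, config$submat,
                                   config$gap_open, config$gap_extend)
    utils::write.table(round(state$dm, 6), out("distances.tsv"),
                       sep = "\t", quote = FALSE)
    list(counts = list(n = nrow(state$dm)),
         outputs = list(out("distances.tsv")))
  })

  stage("tree", function() {
    state$tree <- upgma(state$dm)
    writeLines(to_newick(state$tree), out("tree.nwk"))
    list(counts = list(leaves = length(state$tree$labels)),
         outputs = list(out("tree.nwk")))
  })

  stage("align", function() {
    state$msa <- progressive_align(state$kept, state$tree, config$submat,
                                   config$gap_open, config$gap_extend)
    write_msa_fasta(state$msa, out("msa.afa"))
    list(counts = list(rows = length(state$msa$rows),
                       columns = state$msa$ncol),
         outputs = list(out("msa.afa")))
  })

  stage("clusters", function() {
    k <- min(config$k, length(state$tree$labels))
    assignment <- cut_clusters(state$tree, k)
    sg <- supergroup_clusters(state$tree, assignment,
                              min(config$groups, k))
    state$assignment <- assignment
    comp <- cluster_composition(assignment, state$kept)
    df <- data.frame(accession = names(assignment),
                     cluster = as.integer(assignment),
                     group = unname(sg[as.character(as.integer(assignment))]),
                     stringsAsFactors = FALSE)
    utils::write.table(df, out("clusters.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(comp$class_counts, out("cluster_classes.tsv"),
                       sep = "\t", quote = FALSE)
    list(counts = list(k = k, groups = length(unique(sg))),
         focal_median = comp$focal_median,
         outputs = list(out("clusters.tsv"), out("cluster_classes.tsv")))
  })

  stage("motifs", function() {
    track <- profile_columns(state$msa, min_freq = config$min_freq)
    motifs <- extract_motifs(track, min_score = config$min_score,
                             min_freq = config$min_freq)
    prm <- detect_prm(track, min_freq = config$min_freq)
    write_track_tsv(track, out("track.tsv"))
    write_motifs_tsv(motifs, out("motifs.tsv"))
    state$motifs <- motifs
    list(counts = list(motifs = length(motifs),
                       prm_prolines = prm$n_prolines),
         outputs = list(out("track.tsv"), out("motifs.tsv")))
  })

  stage("architecture", function() {
    if (is.null(config$regions))
      return(list(counts = list(classified = 0)))
    regions <- load_regions(config$regions, state$records)
    regions <- regions[regions$accession %in% state$kept$accession, ,
                       drop = FALSE]
    arch <- classify_architecture(regions, state$kept)
    dist <- architecture_distributions(arch, state$assignment, state$kept)
    utils::write.table(arch, out("architecture.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(dist$cluster_counts, out("architecture_clusters.tsv"),
                       sep = "\t", quote = FALSE)
    list(counts = list(classified = nrow(arch),
                       groups = length(unique(arch$group))),
         outputs = list(out("architecture.tsv"),
                        out("architecture_clusters.tsv")))
  })

  stage("report", function() {
    ont <- ontology_report(state$kept, state$rules)
    utils::write.table(ont, out("ontology_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    taxr <- taxonomy_report(state$kept)
    utils::write.table(taxr$rank_table, out("rank_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(counts = list(subtypes = attr(ont, "n_subtypes")),
         outputs = list(out("ontology_report.tsv"), out("rank_report.tsv")))
  })

  manifest$status <- if (failed) "failed" else "ok"
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
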