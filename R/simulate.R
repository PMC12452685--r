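# Synthetic protein-family generator. The defaults emulate the study
# dataset's structure: 420-460 residue sequences around a 440-residue
# root, 10 clades, a reference-anchored identity band reachable by the
# substitution settings, header ontologies drawn with the published
# subtype proportions, and taxonomy annotated at mixed ranks with the
# published rank frequencies.

#' Simulation configuration
#'
#' @param n_sequences Number of sequences.
#' @param length_range Root length window in residues.
#' @param background Residue sampling probabilities over the 20 standard
#'   residues (uniform when NULL).
#' @param motifs List of planted motifs, each
#'   `list(pattern =, offset =, conservation =)` with the offset in root
#'   coordinates and conservation in `[0, 1]`.
#' @param n_clades Number of clades.
#' @param between_divergence Substitution fraction applied to the root to
#'   create each clade ancestor.
#' @param within_divergence Substitution fraction applied to a clade
#'   ancestor for each sequence.
#' @param indel_rate Expected number of indel events per sequence
#'   (placed outside planted motif spans).
#' @param ontology_freqs Named probabilities for header ontology labels;
#'   defaults to the transcribed published ontology table.
#' @param rank_freqs Named probabilities over taxonomy ranks; defaults to
#'   the published annotation-depth fractions (domain 0.3%, phylum 2.8%,
#'   class 10.7%, order 7.8%, family 7.6%, genus 32.8%, species 38%).
#' @param keyword_fraction Fraction of records given an exclusion keyword
#'   ("partial protein" etc.) in the header, for filter testing.
#' @param seed Integer seed; the same seed reproduces identical output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_sequences = 200,
                              length_range = c(420, 460),
                              background = NULL,
                              motifs = list(),
                              n_clades = 10,
                              between_divergence = 0.40,
                              within_divergence = 0.08,
                              indel_rate = 2,
                              ontology_freqs = NULL,
                              rank_freqs = c(domain = 0.003, phylum = 0.028,
                                             class = 0.107, order = 0.078,
                                             family = 0.076, genus = 0.328,
                                             species = 0.380),
                              keyword_fraction = 0,
                              seed = 1) {
  if (is.null(background)) background <- rep(1 / 20, 20)
  if (is.null(ontology_freqs)) {
    tab <- utils::read.delim(gox_extdata("table2_ontologies.tsv"),
                             stringsAsFactors = FALSE)
    ontology_freqs <- stats::setNames(tab$count / sum(tab$count),
                                      tab$protein_type)
  }
  motifs <- lapply(motifs, function(m) {
    m$pattern <- parse_motif(m$pattern)
    stopifnot(m$conservation >= 0, m$conservation <= 1)
    m
  })
  structure(list(n_sequences = n_sequences, length_range = length_range,
                 background = background, motifs = motifs,
                 n_clades = n_clades,
                 between_divergence = between_divergence,
                 within_divergence = within_divergence,
                 indel_rate = indel_rate,
                 ontology_freqs = ontology_freqs,
                 rank_freqs = rank_freqs / sum(rank_freqs),
                 keyword_fraction = keyword_fraction, seed = seed),
            class = "simulation_config")
}

mutate_seq <- function(chars, fraction, background) {
  n <- length(chars)
  k <- round(fraction * n)
  if (k == 0) return(chars)
  pos <- sample.int(n, k)
  chars[pos] <- sample(AA20, k, replace = TRUE, prob = background)
  chars
}

# realize a pattern's non-wildcard positions in root coordinates;
# wildcard lengths are fixed at draw time (once per motif)
instantiate_pattern <- function(pattern, wild_lens) {
  pos <- integer(0); res <- list()
  at <- 1L; w <- 0L
  for (tk in pattern$tokens) {
    if (tk$type == "wild") {
      w <- w + 1L
      at <- at + wild_lens[w]
    } else {
      pos <- c(pos, at)
      res[[length(res) + 1L]] <- tk$residues
      at <- at + 1L
    }
  }
  list(offsets = pos, residues = res, width = at - 1L)
}

#' Simulate an annotated protein family
#'
#' Generates a clade-structured family: the root is mutated into clade
#' ancestors, each ancestor into sequences; planted motifs are resampled
#' per sequence at the configured conservation level honoring their
#' tokens (fixed residue, class member, free); indels fall outside motif
#' spans; headers carry sampled ontology and mixed-rank taxonomy labels;
#' a region-annotation table with a planted architecture group per
#' sequence is emitted. Deterministic under the config seed.
#'
#' @param config A [simulation_config()].
#' @return A list of class `simulated_family`: `records` (a
#'   `gox_records` data.frame), `regions`, `taxonomy` (lookup table) and
#'   `truth` (per-sequence clade, divergence, header fields and planted
#'   group; per-motif spans and wildcard lengths).
#' @export
simulate_family <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- round(mean(config$length_range))
  root <- sample(AA20, L, replace = TRUE, prob = config$background)

  motif_info <- lapply(config$motifs, function(m) {
    wl <- vapply(Filter(function(tk) tk$type == "wild", m$pattern$tokens),
                 function(tk) sample(tk$min:tk$max, 1), integer(1))
    inst <- instantiate_pattern(m$pattern, wl)
    if (m$offset + inst$width - 1L > min(config$length_range))
      stop("planted motif does not fit inside the minimum sequence length")
    list(pattern = m$pattern, conservation = m$conservation,
         offset = m$offset, wild_lens = wl, inst = inst,
         span = m$offset:(m$offset + inst$width - 1L))
  })
  motif_cols <- unlist(lapply(motif_info, `[[`, "span"))
  if (anyDuplicated(motif_cols))
    stop("planted motif spans overlap after wildcard expansion")

  n <- config$n_sequences
  clades <- rep(seq_len(config$n_clades), length.out = n)
  ancestors <- lapply(seq_len(config$n_clades), function(c)
    mutate_seq(root, config$between_divergence, config$background))

  lineages <- lapply(seq_len(config$n_clades), function(c) {
    g <- sprintf("Genus%02d", c)
    c("Bacteria", sprintf("Phylum%02d", (c - 1) %% 4 + 1),
      sprintf("Class%02d", c), sprintf("Order%02d", c),
      sprintf("Family%02d", c), g, paste(g, "simulans"))
  })

  arch_labels <- c("1a", "1b", "1c", "1d", "2b", "2c")
  acc <- sprintf("SYN%04d.1", seq_len(n))
  residues <- character(n)
  truth_seq <- data.frame(accession = acc, clade = clades,
                          divergence = NA_real_,
                          ontology_raw = NA_character_,
                          organism = NA_character_,
                          rank = NA_character_,
                          has_keyword = FALSE,
                          arch_group = sample(arch_labels, n, replace = TRUE),
                          stringsAsFactors = FALSE)

  tax_rows <- list()
  regions <- list()
  for (i in seq_len(n)) {
    chars <- mutate_seq(ancestors[[clades[i]]], config$within_divergence,
                        config$background)
    for (mi in motif_info) {
      for (k in seq_along(mi$inst$offsets)) {
        p <- mi$offset + mi$inst$offsets[k] - 1L
        allowed <- mi$inst$residues[[k]]
        chars[p] <- if (stats::runif(1) < mi$conservation) {
          if (length(allowed) == 1) allowed
          else sample(allowed, 1, prob = c(0.6, rep(0.4 / (length(allowed) - 1),
                                                    length(allowed) - 1)))
        } else sample(AA20, 1, prob = config$background)
      }
    }
    truth_seq$divergence[i] <- mean(chars != root)
    # indels only downstream of the planted motif spans so planted
    # positions never shift (conserved blocks flanked by a gappy tail)
    tail_start <- if (length(motif_cols)) max(motif_cols) + 1L else 1L
    n_events <- stats::rpois(1, config$indel_rate)
    for (e in seq_len(n_events)) {
      len <- sample.int(8, 1)
      if (stats::runif(1) < 0.5) {
        if (length(chars) - len < config$length_range[1]) next
        if (tail_start > length(chars) - len + 1L) next
        pool <- tail_start:(length(chars) - len + 1L)
        s <- pool[sample.int(length(pool), 1)]
        chars <- chars[-seq(s, s + len - 1)]
      } else {
        if (length(chars) + len > config$length_range[2]) next
        pool <- tail_start:(length(chars) + 1L)
        s <- pool[sample.int(length(pool), 1)]
        ins <- sample(AA20, len, replace = TRUE, prob = config$background)
        chars <- append(chars, ins, after = s - 1)
      }
    }
    residues[i] <- paste(chars, collapse = "")

    rank <- sample(names(config$rank_freqs), 1, prob = config$rank_freqs)
    depth <- match(rank, TAX_RANKS)
    lin <- lineages[[clades[i]]][seq_len(depth)]
    organism <- if (rank == "domain") "bacterium"
                else if (rank == "species") lin[depth]
                else paste(lin[depth], "sp.")
    tax_rows[[length(tax_rows) + 1L]] <-
      data.frame(organism = organism, rank = rank,
                 lineage = paste(lin, collapse = ";"),
                 stringsAsFactors = FALSE)
    ont <- sample(names(config$ontology_freqs), 1,
                  prob = config$ontology_freqs)
    kw <- stats::runif(1) < config$keyword_fraction
    if (kw) ont <- paste(ont, "partial")
    truth_seq$ontology_raw[i] <- ont
    truth_seq$organism[i] <- organism
    truth_seq$rank[i] <- rank
    truth_seq$has_keyword[i] <- kw

    regions[[i]] <- regions_for_group(acc[i], truth_seq$arch_group[i],
                                      nchar(residues[i]))
  }

  taxonomy <- unique(do.call(rbind, tax_rows))
  class(taxonomy) <- c("taxonomy_table", "data.frame")
  headers <- paste0(acc, " ", truth_seq$ontology_raw, " [",
                    truth_seq$organism, "]")
  meta <- parse_fasta_header(headers)
  rec <- meta
  rec$ontology_grouped <- normalize_ontology(rec$ontology_raw)
  rec$residues <- residues
  rec <- attach_taxonomy(rec, taxonomy)
  class(rec) <- c("gox_records", "data.frame")

  regions <- do.call(rbind, regions)
  regions$region_type <- merge_labels(regions$type)
  class(regions) <- c("region_annotations", "data.frame")

  structure(list(records = rec, regions = regions, taxonomy = taxonomy,
                 truth = list(sequences = truth_seq,
                              motifs = motif_info, root = root),
                 config = config),
            class = "simulated_family")
}

# regions consistent with a planted architecture group label under the
# packaged default rule table: 1a={}, 1b={TM}, 1c={NC}, 1d={C+NC},
# 2b={NC}, 2c={C+NC} (each plus a signal peptide for group 2)
regions_for_group <- function(acc, group, len) {
  row <- function(type, name, start, end, source)
    data.frame(accession = acc, type = type, name = name, start = start,
               end = end, source = source, stringsAsFactors = FALSE)
  out <- row("DadA", "DadA", 30, len - 10, "CDD")  # named domain, always
  if (startsWith(group, "2"))
    out <- rbind(out, row("SIGNAL_PEPTIDE", "-", 1, 22, "PHOBIUS"))
  if (group == "1b")
    out <- rbind(out, row("TMhelix", "-", 5, 22, "PHOBIUS"))
  if (group %in% c("1d", "2c"))
    out <- rbind(out, row("CYTOPLASMIC", "-", 1, 4, "PHOBIUS"))
  if (group %in% c("1c", "1d", "2b", "2c"))
    out <- rbind(out, row("NON_CYTOPLASMIC", "-", 23, len, "PHOBIUS"))
  out
}

#' @export
print.simulated_family <- function(x, ...) {
  cat(sprintf("<simulated_family> %d sequences, %d clades, %d planted motifs\n",
              nrow(x$records), x$config$n_clades, length(x$truth$motifs)))
  invisible(x)
}

#' Simulate an alignment with planted motif patterns
#'
#' Builds an `n_rows` x `n_cols` alignment of i.i.d. background residues
#' and plants the given patterns at non-overlapping offsets separated by
#' at least `min_separation` background columns. Fixed and class
#' positions are drawn token-consistently with probability
#' `conservation` (class members weighted 60/40 so the rendered class
#' order is reproducible) and uniformly over the 20 residues otherwise;
#' wildcard positions stay background. Variable wildcards are planted at
#' their minimum length.
#'
#' @param patterns List of patterns or pattern strings.
#' @param n_rows,n_cols Alignment dimensions.
#' @param conservation Per-column conservation level in `[0, 1]`.
#' @param seed Integer seed.
#' @param min_separation Minimum background columns between motifs.
#' @param offsets Optional explicit start columns (otherwise evenly
#'   spread).
#' @return A list of class `simulated_alignment`: `msa` (a
#'   `protein_msa`) and `truth` (patterns, offsets, planted columns).
#' @export
simulate_alignment <- function(patterns, n_rows = 200, n_cols = 400,
                               conservation = 0.95, seed = 1,
                               min_separation = 10, offsets = NULL) {
  patterns <- lapply(patterns, parse_motif)
  set.seed(seed)
  insts <- lapply(patterns, function(p) {
    wl <- vapply(Filter(function(tk) tk$type == "wild", p$tokens),
                 `[[`, 1L, "min")
    instantiate_pattern(p, wl)
  })
  widths <- vapply(insts, `[[`, 1L, "width")
  k <- length(patterns)
  if (is.null(offsets)) {
    slack <- n_cols - sum(widths) - (k + 1) * min_separation
    if (slack < 0) stop("patterns do not fit in ", n_cols, " columns")
    extra <- floor(slack / (k + 1))
    gap <- min_separation + extra
    offsets <- integer(k)
    at <- gap + 1L
    for (i in seq_len(k)) {
      offsets[i] <- at
      at <- at + widths[i] + gap
    }
  }
  if (length(offsets) != k) stop("one offset per pattern required")
  spans <- mapply(function(o, w) o:(o + w - 1L), offsets, widths,
                  SIMPLIFY = FALSE)
  if (anyDuplicated(unlist(spans)))
    stop("planted spans overlap")
  if (max(unlist(spans)) > n_cols) stop("planted span exceeds n_cols")

  m <- matrix(sample(AA20, n_rows * n_cols, replace = TRUE), n_rows, n_cols)
  for (i in seq_len(k)) {
    inst <- insts[[i]]
    for (t in seq_along(inst$offsets)) {
      col <- offsets[i] + inst$offsets[t] - 1L
      allowed <- inst$residues[[t]]
      conserved <- stats::runif(n_rows) < conservation
      draw <- if (length(allowed) == 1) rep(allowed, n_rows)
              else sample(allowed, n_rows, replace = TRUE,
                          prob = c(0.6, rep(0.4 / (length(allowed) - 1),
                                            length(allowed) - 1)))
      m[conserved, col] <- draw[conserved]
      m[!conserved, col] <- sample(AA20, sum(!conserved), replace = TRUE)
    }
  }
  rows <- apply(m, 1, paste, collapse = "")
  names(rows) <- sprintf("S%03d", seq_len(n_rows))
  structure(list(msa = new_protein_msa(rows),
                 truth = list(patterns = patterns, offsets = offsets,
                              spans = spans)),
            class = "simulated_alignment")
}

#' In-text fixture bundle
#'
#' Bundles the transcriptions of the published summary tables, the known
#' motif library, a consensus string realizing the proline-rich composite
#' spacing, a planted-motif alignment carrying all eight consensus motifs,
#' and a 10-clade / 4-supergroup ultrametric tree fixture.
#'
#' @param seed Seed for the planted alignment.
#' @param n_rows,n_cols Planted alignment dimensions.
#' @param conservation Planted per-column conservation.
#' @return A list with `table1` (phylum/class counts), `table2`
#'   (ontology counts), `prm_consensus` (string), `alignment` (a
#'   `simulated_alignment` with M1-M8 planted), and `tree`
#'   (list: `dm`, `clades`, `supergroups`).
#' @export
plant_paper_fixtures <- function(seed = 1, n_rows = 200, n_cols = 400,
                                 conservation = 0.95) {
  table1 <- utils::read.delim(gox_extdata("table1_classes.tsv"),
                              stringsAsFactors = FALSE)
  table2 <- utils::read.delim(gox_extdata("table2_ontologies.tsv"),
                              stringsAsFactors = FALSE)
  km <- known_motifs()
  m18 <- km[paste0("M", 1:8)]
  spacing <- prm_spacings(render_motif(km$prm_composite))
  pos <- cumsum(c(1L, spacing + 1L))
  prm <- rep("A", max(pos) )
  prm[pos] <- "P"
  alignment <- simulate_alignment(m18, n_rows = n_rows, n_cols = n_cols,
                                  conservation = conservation, seed = seed)

  # 10 clades of 4 leaves; supergroups {1-4}, {5,6}, {7,8}, {9,10}
  sg <- rep(c(1, 1, 1, 1, 2, 2, 3, 3, 4, 4))
  clades <- rep(1:10, each = 4)
  leaf_sg <- sg[clades]
  nleaf <- length(clades)
  dm <- matrix(1.2, nleaf, nleaf)
  dm[outer(leaf_sg, leaf_sg, "==")] <- 0.8
  dm[outer(clades, clades, "==")] <- 0.4
  dm[outer(seq_len(nleaf), seq_len(nleaf), "==")] <- 0
  labels <- sprintf("L%02d", seq_len(nleaf))
  dimnames(dm) <- list(labels, labels)
  list(table1 = table1, table2 = table2,
       prm_consensus = paste(prm, collapse = ""),
       alignment = alignment,
       tree = list(dm = dm,
                   clades = stats::setNames(clades, labels),
                   supergroups = stats::setNames(leaf_sg, labels)))
}
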