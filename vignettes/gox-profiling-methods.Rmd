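---
title: "Methods: evolutionary profiling of Gox-related oxidoreductases"
author: "goxprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary profiling of Gox-related oxidoreductases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goxprofiler)
```

## The problem

Glyphosate oxidoreductase (Gox) is a bacterial FAD-dependent enzyme that
cleaves the C–N bond of the herbicide glyphosate, yielding AMPA and
glyoxylate. Gox itself is poorly characterized: few annotated sequences,
no experimental structure, and no established protein subfamily. The
standard way to make progress on such a protein is comparative: collect
its homologs, filter them to a coherent family, align them, build a
phylogeny, and read off what is conserved — residues, motifs and domain
architectures — as candidate determinants of function.

`goxprofiler` implements that workflow as a tested, reusable R package.
Each stage is an exported function with a documented contract, so the
pipeline can be run end to end (`run_pipeline()`) or stage by stage, and
every stage can be validated against synthetic data with known ground
truth.

## Dataset construction

Homolog sets retrieved from sequence databases arrive as annotated FASTA.
The package parses each header into an accession (first
whitespace-delimited token), a protein-name label — called the *ontology*
here, as is common in annotation pipelines; it is not a Gene Ontology
term — and a bracketed organism (the last balanced `[...]` span, per
NCBI convention). Organism names are resolved against a packaged
taxonomy table (never a network call, so analyses are reproducible
offline) at whatever rank the header supports; each record is counted
once at its deepest populated rank, so rank fractions sum to one.

Protein-name labels are noisy: the same activity appears under several
spellings ("FAD-binding oxidoreductase", "oxidoreductase_ FAD-binding",
...). `normalize_ontology()` applies a synonym map (case-insensitive,
ignoring runs of spaces/underscores/hyphens — exactly the variation seen
in real headers) and then a grouping map that merges, e.g., all D-amino
acid dehydrogenase variants into "(D-) amino acid dehydrogenase". The
function is total (unknown labels pass through) and idempotent.

Filtering uses three rules, applied in any order (they commute):

* **keyword exclusion** — headers containing "partial", "synthetic",
  "hypothetical" or "fragment" (configurable) are dropped with the
  triggering keyword recorded;
* **length window** — 420–460 residues inclusive, bracketing the
  430-residue reference;
* **identity band** — global-alignment identity to the reference must lie
  strictly between 0.35 and 0.97. The lower bound enforces homology, the
  upper bound removes near-duplicates and the reference itself.

"Similarity" thresholds in comparative studies are often left undefined;
this package pins the metric to percent identity from a global
Needleman–Wunsch alignment (BLOSUM62, affine gaps, open 11 / extend 1,
where a gap run of length L costs `open + L * extend`). Identity is
computed over alignment columns excluding terminal gap runs, so a length
difference inside the 420–460 window cannot dominate the estimate. The
metric and thresholds are exposed in `filter_config()` for users who
prefer a different reading.

## Alignment

Multiple alignment is single-pass progressive: pairwise distances
(`1 - identity`) feed a UPGMA guide tree, and profiles are merged in
tree post-order by profile–profile global alignment. Column match scores
are the mean pairwise substitution score between the two columns'
residue distributions; gap penalties are affine with terminal gap runs
half-weighted, and traceback ties resolve deterministically (diagonal,
then consume-first-profile, then consume-second). The dynamic program is
a single Rcpp kernel shared by the pairwise and profile paths. There is
no iterative refinement; downstream statistics are threshold-based and
tolerant to small alignment differences, which is also why the package
does not attempt to reproduce any particular aligner byte for byte.

## Phylogeny and clusters

The tree is UPGMA (average linkage, node height = merge distance / 2),
computed via `stats::hclust` and wrapped with an `ape` phylo
representation for Newick serialization and height arithmetic. UPGMA is
exact on ultrametric inputs — the test suite checks cophenetic
reconstruction against a naive agglomeration oracle — and its rooted,
clock-like shape is what makes "cut into k monophyletic clusters"
well-defined: `cut_clusters(tree, k)` removes the k−1 highest internal
nodes and numbers the resulting subtrees by first leaf appearance.
Supergroups reuse the same cut at a coarser level, so each cluster falls
entirely inside one supergroup. Defaults (k = 10, 4 supergroups) mirror
the scale of the published analysis but are plain parameters.
Tie-breaking among equal-distance pairs follows `hclust`'s deterministic
order. Heights are reported as-is; no rooting interpretation is imposed.

## Conservation scoring and motifs

Per-column conservation uses an AMAS-style 0–11 scale driven by a
packaged ten-property table (hydrophobic, polar, small, tiny, aliphatic,
aromatic, positive, negative, charged, proline):

* **11** — absolute conservation: one residue type, no gaps;
* **otherwise** — the number of properties whose presence/absence is
  uniform across the column's residue types, capped at 10, minus 1 when
  the gap fraction exceeds 0.2.

Two numerical choices matter here. First, the property table excludes
valine from "small", so that the canonical aliphatic column {V, I, L}
is uniform in all ten properties and scores 10 — the scale's intended
"full physicochemical conservation despite residue variation". Second,
property uniformity is evaluated over residue types carrying at least 5%
of the column's residues (`min_residue_freq`). Without this noise floor
a single stray residue in a 200-row column would erase the score, and no
realistically conserved column (e.g. 95–97% pure, as reported for
conserved prolines in real alignments of thousands of sequences) could
ever reach the score ≥ 9 bar used for motif inference. Modal frequencies
(`top_freq`, `top2_freq`) keep gap rows in the denominator: a gappy
column cannot be called 80% conserved.

Motif extraction marks a column conserved iff score ≥ 9 and modal (or
two-residue joint) frequency ≥ 0.80, renders it as a fixed residue or a
two-residue class (frequency order, alphabetical on ties), joins
conserved runs across interior wildcard gaps of at most 3 columns (the
longest interior run in the published motif set), and keeps blocks at
least 6 columns long with at least 3 anchors, naming them M1, M2, ... by
position. Patterns use the field's dash notation with `x(m,n)` for
variable wildcards; `match_pattern()` enumerates all wildcard
assignments (overlapping hits included) and `pattern_subsumes()` decides
pattern generality by enumeration over a reduced alphabet — the residues
either pattern mentions plus one sentinel standing for all others, which
is sound and complete because patterns cannot distinguish unmentioned
residues.

The proline-rich region is handled by its own detector because its
spacings exceed the 3-column wildcard bridge: `detect_prm()` collects
columns with proline frequency ≥ 0.80 inside the densest 60-column
window and reports the P-x-x-x-P / P-x-x-P spacings and the composite
spacing pattern. The 0.80 default is configurable, since reported
conserved prolines in real data sit both above and marginally around
that bar.

## Domain architectures

Region annotations (signal peptide, transmembrane, cytoplasmic,
non-cytoplasmic, named domains) are consumed from TSV — the package
never runs the predictors themselves. Database-specific labels are
merged (SIGNAL_PEPTIDE/SignalP_noTM; TMhelix/TRANSMEMBRANE). The signal
peptide splits group 1 (absent) from group 2 (present); within each
group the presence pattern over {transmembrane, cytoplasmic,
non-cytoplasmic} selects a subcategory (1a–1f, 2a–2d). The exact
pattern-to-subcategory boundaries are shipped as an editable YAML rule
table ordered by increasing combination complexity; the defaults are a
reconstruction (the source categorization is figure-only), with
anchor cases fixed: no regions at all is 1a, a single transmembrane
helix (the reference's annotation) is 1b, and a signal peptide alone is
2a, which may legitimately be empty on a given dataset.

## The synthetic generator

`simulate_family()` generates what the pipeline consumes: a root
sequence (default 440 residues, i.i.d. uniform background), clade
ancestors at 40% substitution divergence, sequences at 8% within-clade
divergence, indels (mean 2 events/sequence, ≤ 8 residues) restricted
downstream of planted motif spans so planted coordinates never shift —
mirroring conserved blocks flanked by unstructured, gap-prone regions —
lengths confined to 420–460, headers with ontology labels drawn at the
published subtype proportions and taxonomy at the published rank-depth
proportions (0.3% domain ... 38% species), and a region table realizing
a planted architecture group per sequence. `simulate_alignment()` plants
motif patterns directly into an alignment at a chosen per-column
conservation level (class members weighted 60/40 so rendered class order
is stable). Everything is deterministic under the config seed.

What the generator does *not* emulate: substitution-matrix-structured
residue exchange (mutations are uniform), rate heterogeneity across
sites, codon-level processes, and realistic indel length distributions.
Passing tests therefore demonstrate algorithmic correctness on data with
known truth, not biological realism of any particular inference.

## Problem sizes and determinism

The shipped tests and the acceptance script run at deliberately modest
scales chosen as the smallest sizes at which the statistical checks are
stable: planted-motif recovery uses 200-row × 400-column alignments over
20 seeds; family simulations use 8–100 sequences; UPGMA oracle checks
use n ≤ 8 matrices plus random ultrametric inputs up to n = 12. All
randomness flows through explicit seeds; reruns are byte-identical
(the pipeline manifest records md5 checksums of every stage output to
make this checkable).

## Known limitations

* Distance estimation is all-pairs global alignment, O(n² L²); no k-mer
  pre-screening is implemented, so very large datasets (thousands of
  sequences) are outside the intended scale.
* The conservation score is a pinned reconstruction of the AMAS-style
  scale, not a re-implementation of any specific viewer's code path.
* The architecture subcategory boundaries beyond the anchor cases are
  editable conventions, not ground truth.
* UPGMA assumes clock-like divergence; no maximum-likelihood or
  bootstrap machinery is provided.
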