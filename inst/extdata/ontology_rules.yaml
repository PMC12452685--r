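# Protein-name ("ontology") grouping rules.
#
# synonyms: raw header label -> canonical label. Matching is
# case-insensitive and ignores runs of spaces/underscores/hyphens, so the
# keys below cover the punctuation variants seen in NCBI headers.
# groups: canonical label -> subtype label (applied after synonyms).
synonyms:
  "FAD-binding oxidoreductase": "FAD-binding oxidoreductase"
  "oxidoreductase_ FAD-binding": "FAD-binding oxidoreductase"
  "oxidoreductase_ FAD-binding protein": "FAD-binding oxidoreductase"
  "FAD-dependent oxidoreductase": "FAD-binding oxidoreductase"
  "FAD-dependent/binding oxidoreductase": "FAD-binding oxidoreductase"
  "FAD-binding/dependent oxidoreductase": "FAD-binding oxidoreductase"
  "FAD dependent oxidoreductase": "FAD-binding oxidoreductase"
groups:
  "amino acid dehydrogenase": "(D-) amino acid dehydrogenase"
  "D-amino acid dehydrogenase": "(D-) amino acid dehydrogenase"
  "D-amino acid dehydrogenase 1": "(D-) amino acid dehydrogenase"
  "D-amino acid dehydrogenase small subunit": "(D-) amino acid dehydrogenase"
  "putative D-amino acid dehydrogenase protein": "(D-) amino acid dehydrogenase"
  "dependent oxidoreductase": "dependent oxidoreductase"
  "dependent oxidoreductase family protein": "dependent oxidoreductase"
  "Gox": "Gox"
  "Gox (Glyphosate oxidoreductase)": "Gox"
  "Gox (FAD-dependent glyphosate oxidase)": "Gox"
  "FAD-dependent glyphosate oxidase": "Gox"
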