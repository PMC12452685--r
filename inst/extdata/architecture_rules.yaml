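# Architecture subcategory rule table. Group 1 = no signal peptide,
# group 2 = signal peptide present; subcategories are decided by the
# presence pattern over {TM (transmembrane), C (cytoplasmic),
# NC (non-cytoplasmic)}, ordered by increasing combination complexity.
# The exact subcategory boundaries are a reconstruction and can be edited;
# every one of the 8 possible patterns must be covered in each group.
group1:
  "1a": [""]
  "1b": ["TM"]
  "1c": ["NC"]
  "1d": ["C+NC"]
  "1e": ["TM+NC", "TM+C+NC"]
  "1f": ["C", "TM+C"]
group2:
  "2a": [""]
  "2b": ["TM", "NC"]
  "2c": ["C", "C+NC", "TM+NC"]
  "2d": ["TM+C", "TM+C+NC"]
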