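# Scanner configuration. The reference block describes the element window:
# a synthetic 33-nt stand-in is shown here; replace `sequence` with the
# 33-bp element of your reference species (e.g. the AGAMOUS second-intron
# element) to scan real genomic sequences.
reference:
  sequence: AAGAATGTATTACATCGTCATTGGCTAATCACG
  hexamer_offset: 0
  core: TGACG
  degenerate_positions:
    '0': ACT
params:
  max_dev_full: 7
  min_dev_partial_report: 15
  core_both_strands: true
  count_degenerate_as_match: true
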