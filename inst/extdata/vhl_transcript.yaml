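# VHL transcript map used for cDNA region assignment.
# Coding exon bounds in cDNA (c.) coordinates; the exon1/exon2 and
# exon2/exon3 junctions are fixed by the canonical splice positions
# c.340+1/c.341-1 and c.463+1/c.464-1.
# e1prime_window: positive intron-1 offsets (from c.340) treated as the
# cryptic exon E1' (a deep-intron-1 exonized segment whose variants
# associate with erythrocytosis rather than VHL syndrome). The window is
# an approximation declared here as data; swap the file to change it.
transcript_id: NM_000551.4
cds_exon_bounds:
  - [1, 340]
  - [341, 463]
  - [464, 642]
e1prime_window: [400, 800]
utr_allowance: 0
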