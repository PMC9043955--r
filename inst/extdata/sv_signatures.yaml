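# Structural-variant signature segments on the packaged SYNTHETIC reference
# alignment (synthetic_petota_igs_alignment.fasta). Column ranges are
# 1-based inclusive. Replace alignment and coordinates with a real
# reference alignment to type real sect. Petota spacers.
reference_alignment: synthetic_petota_igs_alignment.fasta
segments:
  indel_I:
    start: 60
    end: 75
  indel_II:
    start: 120
    end: 131
  GC_DUP:
    start: 219
    end: 220
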