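locus:
  name: synthetic140
  amplicon: AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCACGCCCTGGAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGC
  protospacer: CGTGAACCCCCTGCACGCCC
  pam_strand: plus
  fwd_primer: AAAACTCCATGTGTAACTCC
  rev_primer: GCTAAGTCGTTTATTAGAAC
donor:
  ssodn: CCTTTCCATATCTCGTGAACCCCCTGCACGTGATGGAGTACAATTAGGATATTCATCCCTACA
  strand: pam
  biotin_end: three_prime
  arm_upstream_nt: 30
  arm_downstream_nt: 30
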