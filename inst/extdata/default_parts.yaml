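# Default parts library for sgRNA transcription-unit construction.
#
# - Promoter sequences end exactly at the transcription start site (+1):
#   the transcribed sgRNA begins at the first guide base, with no extra
#   5' nucleotides.
# - `dcas9_handle` is the 42-nt S. pyogenes sgRNA hairpin region bound by
#   dCas9, as used throughout the CRISPRi literature.
# - `pBAD_mini` and the terminator sequences are SYNTHETIC representative
#   placeholders (realistic length and hairpin/U-tract structure, free of
#   internal Type IIs sites); replace them with your lab's parts. The
#   terminator `strength` annotations carry the published dimensionless
#   terminator-strength values for the named parts.
promoters:
  pBAD_mini:
    sequence: ACATTGATTATTTGCACGGCGTCACACTTTGCTATGCCATAGCATTTTTATCCATAAGATTAGCGGATCCTACCTGACGCTTTCTCCATA
  J23101:
    sequence: TTTACAGCTAGCTCAGTCCTAGGTATTATGCTAGC
dcas9_handle: GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCG
terminators:
  TrrnB:
    sequence: CCTAGCGGTATCAGTACCGCTAGGTTTTTTTT
    strength: 84
  L3S2P55:
    sequence: GCCTGACTACTTCGGTAGTCAGGCTTTTTTTT
    strength: 260
  L3S2P21:
    sequence: CCACGTTGACAACGGTCAACGTGGTTTTTTTT
    strength: 380
type_iis:
  name: BsaI
  recognition: GGTCTC
  spacer: A
scars: [AATG, GCTT, CGCT, TGCC, ACTA, TTAC, CAGT, GGAC]
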