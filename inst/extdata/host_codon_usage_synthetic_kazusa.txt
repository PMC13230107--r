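# Synthetic host codon usage table (Kazusa dialect).
# Constructed by phagecub::host_usage_table(); not a real organism table.
UUU 37.67 ( 37674)  CUU 49.86 ( 49860)  AUU 48.18 ( 48184)  GUU 42.13 ( 42127)
UCU 30.66 ( 30656)  CCU 25.53 ( 25531)  ACU 33.83 ( 33829)  GCU 49.79 ( 49786)
UAU 28.26 ( 28256)  CAU 18.84 ( 18837)  AAU 38.53 ( 38531)  GAU 45.38 ( 45380)
UGU 8.56 (  8562)  CGU 25.44 ( 25439)  AGU 8.76 (  8759)  GGU 45.96 ( 45956)
UUC 6.46 (  6458)  CUC 8.55 (  8547)  AUC 8.26 (  8260)  GUC 7.22 (  7222)
UCC 5.26 (  5255)  CCC 4.38 (  4377)  ACC 5.80 (  5799)  GCC 8.54 (  8535)
UAC 4.84 (  4844)  CAC 3.23 (  3229)  AAC 6.61 (  6605)  GAC 7.78 (  7780)
UGC 1.47 (  1468)  CGC 4.36 (  4361)  AGC 5.26 (  5255)  GGC 7.88 (  7878)
UUA 14.25 ( 14246)  CUA 14.25 ( 14246)  AUA 13.77 ( 13767)  GUA 12.04 ( 12036)
UCA 8.76 (  8759)  CCA 7.30 (  7295)  ACA 9.67 (  9665)  GCA 14.23 ( 14225)
UAA 1.95 (  1950)  CAA 36.01 ( 36006)  AAA 54.01 ( 54009)  GAA 56.71 ( 56709)
UGA 0.60 (   600)  CGA 7.27 (  7268)  AGA 7.27 (  7268)  GGA 13.13 ( 13130)
UUG 5.70 (  5698)  CUG 5.70 (  5698)  AUG 24.07 ( 24072)  GUG 4.81 (  4814)
UCG 3.50 (  3503)  CCG 2.92 (  2918)  ACG 3.87 (  3866)  GCG 5.69 (  5690)
UAG 0.45 (   450)  CAG 4.12 (  4115)  AAG 6.17 (  6172)  GAG 6.48 (  6481)
UGG 11.03 ( 11033)  CGG 2.91 (  2907)  AGG 2.91 (  2907)  GGG 5.25 (  5252)
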