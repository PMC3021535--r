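ID HSE_canonical_synthetic
BF heat shock factor (synthetic counts)
P0      A      C      G      T
01     25     25     25     25
02      2      1     95      2
03     95      2      1      2
04     94      2      2      2
05     25     25     25     25
06     25     25     25     25
07      2      2      2     94
08      1      2      2     95
09      2     95      2      1
10     25     25     25     25
11     25     25     25     25
12      2      1     95      2
13     95      2      1      2
14     94      2      2      2
15     25     25     25     25
XX
//
ID BEAF_like_synthetic
BF boundary element associated factor (synthetic counts)
PO      A      C      G      T
01      3     90      3      4
02      4      3     90      3
03     90      3      3      4
04      3      4      3     90
05     90      3      4      3
06      3     90      3      4
07      4      3     90      3
XX
//
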