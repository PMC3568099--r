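# ordinal expressions (unigram)
first
second
third
fourth
fifth
sixth
seventh
eighth
ninth
tenth
eleventh
twelfth
1st
2nd
3rd
4th
5th
6th
7th
8th
9th
10th
11th
12th
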