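# Synthetic MS2 spectral library (constructed for tests/examples; the
# compound names are fictitious and the spectra are not real reference
# spectra).
Name: SyntheticCompound_A
PrecursorMZ: 180.0634
PrecursorType: [M+H]+
HMDB: HMDB0000SYN1
Num Peaks: 5
60.0444 100
85.0284 62
97.0284 40
121.0283 25
163.0601 80

Name: SyntheticCompound_B
PrecursorMZ: 132.1019
PrecursorType: [M+H]+
KEGG: C99901
Num Peaks: 4
43.0542 35
69.0699 100
86.0964 55
115.0866 20

Name: SyntheticCompound_C
PrecursorMZ: 205.0972
PrecursorType: [M+H]+
INCHIKEY: SYNTHETICAAAAAA-UHFFFAOYSA-N
Num Peaks: 6
74.0237 15
91.0542 40
118.0651 100
132.0808 30
146.0600 22
188.0706 65

Name: SyntheticCompound_D
PrecursorMZ: 268.1041
PrecursorType: [M+H]+
HMDB: HMDB0000SYN4
Num Peaks: 5
57.0699 28
84.0808 100
119.0491 33
136.0618 70
250.0935 18

Name: SyntheticCompound_E
PrecursorMZ: 304.0912
PrecursorType: [M+H]+
KEGG: C99905
Num Peaks: 4
97.0284 45
138.0550 100
182.0448 27
286.0806 60

Name: SyntheticCompound_F
PrecursorMZ: 166.0863
PrecursorType: [M+H]+
Num Peaks: 3
77.0386 30
103.0542 100
149.0598 48
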