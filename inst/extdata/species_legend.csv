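code,species
A,Amomum koenigii
B,Amomum kravanh
C,Amomum longiligulare
D,Amomum tsaoko
E,Amomum villosum
F,Amomum maximum
G,Amomum paratsaoko
H,Alpinia galanga
I,Alpinia katsumadai
J,Alpinia zerumbet
K,Alpinia japonica
L,Alpinia oxyphylla
M,Zingiber striolatum
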