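# Coefficients of the aliphatic index (relative volume of aliphatic side
# chains): AI = X(Ala) + a*X(Val) + b*(X(Ile) + X(Leu)), X in mole percent.
# Source: Ikai (1980) J Biochem 88:1895-1898.
aa	coefficient
A	1.0
V	2.9
I	3.9
L	3.9
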