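# pKa set for the Henderson-Hasselbalch isoelectric-point model.
# Source: Bjellqvist et al. (1993) Electrophoresis 14:1023-1031, as popularised
# by the Expasy ProtParam tool (simplified: one value per site, no
# position-specific N-terminal adjustment). An alternative set may be supplied
# to isoelectric_point() as a file of the same layout.
# site: Nterm, Cterm, or a one-letter residue code; charge: +1 basic, -1 acidic.
site	pka	charge
Nterm	7.5	1
Cterm	3.55	-1
D	4.05	-1
E	4.45	-1
C	9.0	-1
Y	10.0	-1
H	5.98	1
K	10.0	1
R	12.0	1
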