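---
title: "Measuring codon usage bias and the forces that shape it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring codon usage bias and the forces that shape it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubtools)
```

## The problem

Synonymous codons are not used equally. In a set of protein-coding
sequences — here motivated by human genes whose defects disturb metabolism
and lead to neurodegeneration — the pattern of synonymous choice carries a
signature of the forces acting on the genes: directional mutation pressure
(which pushes base composition, especially at the nearly neutral third codon
position), natural selection (e.g. for translational efficiency) and
compositional constraints. `cubtools` implements the complete desk-top
analysis used to read that signature from a FASTA of coding sequences, plus
a seeded generator of synthetic coding sequences so every stage of the
pipeline can be exercised and validated without downloading transcripts.

## Admission rules

A sequence enters the analysis only if it is in frame (length a multiple of
three), contains no base other than A, C, G, T (ambiguity codes and the RNA
letter U are rejected), and carries no internal stop codon. A terminal stop
is stripped by default, so stop codons never enter any statistic: all
downstream work is over the 61 sense codons encoding 20 amino acids.
Duplicate ids are a hard error rather than a warning — silently double
counting a transcript would bias every pooled statistic.

## The indices

**Composition.** Percent A/C/G/T overall and at each codon position, GC and
AT content, GC1, GC2, GC3, AT3 and GC12 = (GC1 + GC2)/2. The GC12 mean is
the standard neutrality-plot convention. Strand skews are computed as
(A − T)/(A + T) and (G − C)/(G + C) over the whole sequence, with 0 declared
on an empty denominator; these formulas are a documented convention, since
"nucleotide skew" is used loosely in this literature.

**Dinucleotide odds ratios.** For dinucleotide XY,
`odds = f(XY) / (f(X) f(Y))`, with f(XY) over all L − 1 overlapping windows
of the linear sequence (crossing codon junctions; the sequence is not
treated as circular) and mononucleotide frequencies over all L bases — the
O(1/L) difference between the two denominators is accepted and documented.
Odds below 0.78 are called underrepresented and above 1.25 overrepresented,
with strict inequalities at the boundaries. CpG and TpA depletion are the
classic signals in mammalian genes.

**RSCU.** `RSCU_j = x_j / (n_i / k_i)` for codon j of a family with n_i
occurrences and degeneracy k_i; values in a present family always sum to
k_i. Values above 1.6 / below 0.6 flag over-/underrepresented codons. A
codon is *rare* when its pooled data-set frequency falls below 1% (10 in
1,000).

**ENc.** Wright's effective number of codons aggregates per-family
homozygosities `F̂ = (n Σp² − 1)/(n − 1)` into
`Nc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆`. Six-fold families (Leu, Ser,
Arg) are kept intact, the CodonW convention. Values run from 20 (one codon
per amino acid) to 61 (uniform usage); below 35 is conventionally read as
strong bias, above 50 as near-random usage. Three numerical choices needed a
decision:

* a family's F̂ can be non-positive at very small n (e.g. two occurrences
  split over two codons); such estimates are treated as undefined and
  excluded from the class mean, mirroring the guard in ENc implementations;
* if the single 3-fold family (Ile) is undefined, F̄₃ is imputed as
  (F̄₂ + F̄₄)/2 — some convention is required because the class has one
  member;
* sampling noise can push the raw sum above 61, so Nc is capped there. The
  exact ceiling of 61 is attained under the probability convention
  F = Σp², which is exposed as an option for analytic work and used for the
  uniform-usage worked example.

If an entire required degeneracy class (2-, 4- or 6-fold) is undefined the
function errors naming the class; very short sequences can legitimately hit
this, which is why the bundled simulations use gene lengths in the hundreds
of codons, the realistic scale for these genes.

**ICDI.** Per degenerate family, `S = Σ(RSCU − 1)² / (k(k − 1))`; the index
is the mean of S over families present in the gene, 0 under equal usage and
1 when each family uses a single codon. Averaging over *present* families
avoids NA propagation on short genes; a fixed `/18` denominator (absent
families scored 0) is available as an option since either reading is
defensible.

**CAI.** Relative adaptiveness weights are `w_j = f_j / max(f)` within each
family of a reference usage table; zero reference counts are replaced by 0.5
before normalisation (Sharp–Li smoothing) so logs stay finite. The index is
the geometric mean of w over all codon occurrences in degenerate families
(Met and Trp excluded — they carry no synonymous signal), accumulated in log
space. The bundled reference is the Kazusa/CUTG *Homo sapiens* table
(93,487 CDSs, 40,662,582 codons), shipped as a plain TSV with provenance in
its header; any table of the same layout can be substituted.

## Force diagnostics

**PR2 parity.** x = A3/(A3 + T3) against y = G3/(G3 + C3); (0.5, 0.5) means
no strand-asymmetric mutation/selection bias at third positions. The
A-ratio is taken as abscissa and the G-ratio as ordinate.

**Neutrality plot.** OLS of GC12 on GC3 across genes. The slope estimates
the share of GC12 variation due to directional mutation pressure:
`mutation_pct = slope × 100`, the remainder attributed to selection and
other constraints. The implementation always reports slope × 100 exactly; a
slope of 0.1732 is therefore 17.32% mutation — rounded summaries that quote
17.25% for the same fit are treated as a transcription slip.

**ENc–GC3 curve.** The null expectation when composition alone drives bias
is `Nc = 2 + s + 29/(s² + (1 − s)²)` with s the GC3 fraction; the reported
deviation is expected − observed, so genes under selection sit at positive
deviations (below the curve).

**Correlations and regressions.** Pearson by default (the tool pairs r with
t-distribution p-values; Spearman is available), no multiple-testing
correction — matching how these panels are conventionally analysed, where
individual r values are read descriptively.

**PCA.** Each gene's RSCU vector over the 59 codons of degenerate families
is column-mean-centred (no unit-variance scaling: RSCU values already share
a scale) and decomposed with `prcomp`. NA entries — families absent from a
gene — are imputed with the column mean, which keeps short genes in the
analysis and contributes zero after centring. Component signs are fixed by
forcing each component's largest-magnitude loading positive, so scores are
reproducible across BLAS builds.

## Protein indices

Each accepted CDS is translated (standard code) and scored: GRAVY (mean
Kyte–Doolittle hydropathy), aromaticity (F+Y+W fraction), Ikai's aliphatic
index (X(Ala) + 2.9 X(Val) + 3.9 (X(Ile)+X(Leu)), mole percent),
isoelectric point, instability index (Guruprasad DIWV dipeptide weights,
`10/L × Σ`, ≥ 40 flagged unstable) and charge classes (acidic D,E; basic
R,K,H — histidine counted basic; neutral the rest; hydrophobic
A,V,L,I,P,F,M,W as a documented convention, since published tools do not
agree on the set). The pI solves the Henderson–Hasselbalch net charge for
zero by bisection on pH 0–14 to |charge| < 1e-4; the bundled pKa set is the
Bjellqvist/Expasy-style one (termini 7.5/3.55; side chains D 4.05, E 4.45,
C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0), and an alternative set can be
supplied as a file. All residue-level tables ship as TSVs with provenance
headers.

## The synthetic generator

The generator exists so that the full pipeline has first-class, testable
inputs with *known* truth:

* `generate_cds()` samples amino acids and synonymous codons from
  configurable weights — uniform by default, which makes per-codon
  frequencies binomial with known expectations;
* `generate_bias_gradient(b)` interpolates each family's codon distribution
  between uniform (b = 0) and a point mass on one preferred codon (b = 1),
  realising the analytic ENc endpoints 61 and 20 and an ICDI sweep 0 to 1;
  with coverage guaranteed (every amino acid at least twice) all Wright
  homozygosities are defined;
* `generate_neutrality_dataset(beta, intercept, noise_sd, gc3_range)` gives
  gene i a GC3 target uniform in the range and a GC12 target
  `beta · GC3 + intercept + noise`. Targets are realised exactly up to
  rounding by two knobs: the amino-acid mixture (pools contributing 100%,
  50% and 0% GC at the first two positions, with the 50% pool fixed at a 30%
  share — so achievable GC12 spans 15–85%) and the count of GC-ending versus
  AT-ending synonymous codons at third positions. The pools cover all four
  degeneracy classes so ENc remains computable on generated data. The scheme
  is deterministic in its targets rather than rejection-sampled, which keeps
  200-gene data sets at sub-second cost;
* `deplete_dinucleotide()` hill-climbs over single synonymous codon swaps —
  the translation can never change — recomputing the target odds ratio
  incrementally, until the requested odds or a local optimum is reached
  (reported with a warning flag when the target is unreachable, e.g. AA
  windows inside lysine codons).

Seeding policy: every generator takes one root seed and derives per-gene
child seeds as `(seed + i × 48271) mod (2³¹ − 1)`, so data sets are
reproducible gene by gene and byte-identical across runs.

What the generator does **not** emulate: real transcripts correlate GC3 with
amino-acid composition through their actual proteomes, carry isochore
structure, alternative transcripts of the same gene, and CpG depletion tied
to methylation. Passing the bundled simulations therefore demonstrates that
the *estimators* are correct (parameter recovery, endpoint agreement,
invariances), not that any particular biological claim about a real gene
panel holds.

## Default study conditions

The `analysis/` drivers fix the simulated panel at 60 genes of 150–800
codons (a typical diagnostic-panel gene count, with lengths bracketing the several
hundred codons typical of metabolic-enzyme CDSs), a GC12–GC3 slope of
0.1732 with intercept 39.18 and 2% Gaussian noise over GC3 27–89% — the
published compositional regime for such panels. Parameter-recovery suites
use 200 genes × 300 codons per fit and slopes {0.1, 0.5, 0.9} across three
seeds, recovering each slope within ±0.05. Bias-gradient suites pool 20–40
genes × 200 codons per grid point, at which scale the Nc and ICDI responses
are strictly monotone.

## Known limitations

* Gene-level aggregation of multi-transcript genes is done by concatenating
  transcripts in id order (`per-gene` mode); other conventions
  (representative transcript, averaging) exist and give slightly different
  odds ratios.
* ENc on very short genes (tens of codons) can be undefined; this is
  reported as an error, not silently imputed, except for the single-member
  Ile class.
* Correlation p-values assume independent genes; paralogous families
  violate this, as they do in any such panel analysis.
* The hydrophobic residue set and the skew formulas are documented
  conventions where the field's tools disagree.
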