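---
title: "Methods: DE-motif context analysis for unconventional secretion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DE-motif context analysis for unconventional secretion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demotif)
```

## The problem

Proteins exported without an N-terminal signal peptide (unconventional
protein secretion, UPS) must carry some other recognizable signal. An
Asp-Glu (DE) dipeptide is one candidate, but DE occurs in almost every
protein, so the interesting question is whether the *context* of a
particular DE — its flanking charge, flanking hydrophobicity, structural
order, phosphorylatable insertions, proximity to an LC3-interacting
region (LIR), or co-evolutionary coupling — distinguishes secreted from
non-secreted cargo. `demotif` implements that analysis as a tested,
reusable pipeline, together with synthetic-data generators so every stage
can be verified without external downloads.

## The model

For each protein we characterize every DE occurrence by three physical
descriptors:

* **H** — summed Kyte-Doolittle hydropathy of up to 3 residues on either
  side of the motif (the D and E themselves excluded; windows truncate at
  the termini and the truncation is recorded). Dimensionless; for full
  flanks $H \in [-27, 27]$.
* **C** — summed formal charge of the same window (D,E $=-1$; K,R $=+1$;
  H $=0$ at physiological pH, switchable to $+1$; X imputed 0).
  Elementary charges; $C \in [-6, 6]$ for full flanks.
* **order class** — `O` if both motif residues lie in helix/sheet states,
  `D` if both lie in coil/loop, `B` (border) if they straddle the
  boundary. The package consumes a precomputed 3-state string (map
  DSSP-like H/G/I to H, E/B to E, rest to C); it does not predict
  structure.

Because most proteins carry several DE motifs, one must decide *which*
DE is the putative signal. We enumerate all 16 selection hypotheses as
the Cartesian product of four binary choices: preferred order class
(O/D), border regrouping (B treated as O or as D), charge extreme
(min/max) and hydrophobicity extreme (min/max). Selection is
lexicographic — the charge criterion is primary, hydrophobicity breaks
ties, the smallest start breaks remaining ties — because the published
case narratives name charge first; the ordering is exposed as code, not
config, to keep case ids stable. When a protein has no motif of the
preferred class the selection falls back to all of its motifs (flagged)
rather than dropping the protein, keeping $n$ constant across cases so
the 16 model p-values are comparable.

Each case yields a design matrix with one row per labelled protein
(secretory $=1$) and predictors $(H, C, \mathbf{1}[\text{order}=O])$ of
the selected motif. A binary logistic regression

$$\mathrm{logit}\,P(\text{secretory}) = \beta_0 + \beta_H H + \beta_C C +
\beta_O \mathbf{1}[O]$$

is fitted by iteratively reweighted least squares (implemented in the
package, unpenalized; convergence $\max|\Delta\beta| < 10^{-8}$ within
100 iterations). We report per-coefficient Wald p-values and the
model-level likelihood-ratio p against the intercept-only model; the
*a-posteriori* "best case" is the rankable (converged, non-separated)
case with the smallest LRT p. Ties are resolved to the lowest case id
and flagged. Internally ties and ranking are decided on deviances with a
relative tolerance, because LRT p-values underflow any absolute
comparison long before deviances stop being comparable. No
multiple-testing correction is applied to the ranking (a Bonferroni
column is emitted for transparency); no regularization by default — a
ridge option exists solely as a separation rescue.

Two signalling contexts are scanned alongside: the six phosphorylatable
diacidic insertion patterns (XDE, DXE, DEX, XED, EXD, EDX with
$X \in \{S,T,Y,H,R,K\}$ — the O- and N-phosphorylatable residues),
summarized per protein into 2×2 contingency tables with odds ratios
(Haldane-Anscombe 0.5 correction when a cell is zero) and a two-sided
Fisher exact test by hypergeometric enumeration; and LIR motifs (core
`[WFY]..[LIV]` or the extended 6-residue consensus), with DE-LIR
"contiguity" defined literally as interval overlap or zero-gap adjacency
(the gap is a parameter, default 0, since no numeric definition of
"immediate proximity" exists). Note the extended-consensus third position
is the aromatic `[WFY]`; this is what makes every extended match contain
a core match at offset 2.

## Co-evolution

The co-evolution stage is a deliberately simplified statistical-coupling
analysis. Sequences with gap fraction above 0.2 are removed
(per-sequence filtering, boundary inclusive); a majority consensus is
built per column (ties alphabetic, all-gap columns give `X`); the MSA is
binarized (1 = matches consensus, gaps 0); and the coupling of columns
$i, j$ is the co-occurrence deviation $C_{ij} = |f_{ij} - f_i f_j|$ with
zero diagonal and zeroed constant columns. A classic SCA-style
frequency weighting
$\varphi_i = |\ln(f_i(1-\bar q)/(\bar q(1-f_i)))|$ is available as
`mode = "sca_weighted"`; the plain deviation is the default because the
consensus-binarization step already departs from canonical SCA, so the
simplest faithful coupling is the honest baseline. Per-position partners
are ranked with a z-score against that position's off-diagonal scores;
the "relation" flag threshold $z \ge 2$ is declared, not inferred — no
published numeric threshold exists. Eigen-spectrum cleaning, ICA and
sector analysis are out of scope. The residue-to-column mapper works in
0-based coordinates on both sides and verifies the mapped residues are
D/E.

## The synthetic world

`gen_protein_dataset()` emulates a curated UPS dataset: each protein is
a uniform-background sequence of 120-300 residues with 1-4 planted DE
motifs (minimum spacing 8 so flanking windows stay informative), a
secondary-structure string of alternating H/E/C runs with geometric
lengths (mean 6 ordered, 5 coil — chosen so ordered, disordered *and*
border motifs all occur at useful rates), and a secretion label drawn
from the logistic model above evaluated on the signal DE selected by a
configured hypothesis case. Accidental background DE motifs participate
in selection, exactly as in real data. Defaults were fixed a priori:
planted $\beta = (-2.5, 0.25, -0.75, 1.5)$ gives moderate standardized
effects (roughly 1 SD of each feature contributes $|\beta|\cdot$SD
$\approx 0.9$-$1$ to the linear predictor) and an intercept that roughly
offsets the selection-shifted feature means, yielding a class balance in
the 30-50% range, comparable to a 57/43 curated split; the default
signal case (id 6: ordered preference, border regrouped to disordered,
minimum charge, maximum hydrophobicity) mirrors the headline hypothesis
that an ordered, low-charge, high-hydrophobicity DE context favours
secretion. `gen_msa()` plants covarying column pairs through a shared
latent Bernoulli (correlation $\rho$) with i.i.d. gaps. All generators
draw under a locally scoped seed and restore the caller's RNG state.

What the generator does *not* emulate: real secretome composition,
residue usage biases, phylogenetic correlation structure in alignments,
or structure-sequence dependence. A green recovery test therefore
establishes that the pipeline identifies planted effects of realistic
size under clean sampling assumptions — not that the biological claim is
true, and not that the method is robust to phylogenetic confounding.

## Numerical and design choices

* Coordinates are 0-based half-open internally, 1-based inclusive in all
  emitted tables.
* Kyte-Doolittle is the hydropathy scale (matching the era of the cited
  scale); `X` is imputed neutrally (0 hydropathy, 0 charge) and logged
  via the flank metadata.
* Whether the original windows included the D/E themselves is not
  documented anywhere; exclusion is the default here (the motif is
  constant across all motifs, so inclusion would only shift H by a
  constant $-7$).
* Border = the two motif residues have different order states; a
  "boundary within ±1 residue" variant was considered and rejected as a
  default because it makes B depend on window size.
* Separation in the logistic fit is detected heuristically (perfect
  classification with $\max|\eta| > 15$) and flagged; separated or
  non-converged fits are excluded from case ranking and every exclusion
  is counted in the report — silent drops are forbidden.
* Fisher's test uses probability-ordering with a $10^{-7}$ relative tie
  tolerance, verified exhaustively against `choose()`-based enumeration
  for all tables with grand total ≤ 30.
* Single-DE proteins make the 16 cases coincide *except* when the single
  motif is a border motif, whose order indicator flips with the
  regrouping axis. This is a real property of the case definitions, not
  a bug.
* The 16 case ids are this package's canonical ordering (order
  preference outermost, then regrouping, charge extreme, hydrophobicity
  extreme); any external numbering can be aligned by joining on the four
  axis columns.

## Known limitations

* The curated 100-protein dataset and the supplementary case/odds-ratio
  tables of the motivating study are not redistributable here, so no
  numeric headline value is asserted; acceptance is property-based
  (oracle equivalence, planted-truth recovery, closed forms).
* Unpenalized MLE on small strata (per-group fits with tens of proteins)
  frequently separates; the report flags rather than rescues this.
* The co-evolution stage inherits all caveats of consensus binarization:
  it measures conservation-coupled covariation, not direct contacts, and
  phylogenetic relatedness inflates couplings.
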