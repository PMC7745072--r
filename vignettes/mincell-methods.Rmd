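---
title: "Methods: integrative characterization of a near-minimal bacterium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative characterization of a near-minimal bacterium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mincell)
```

`mincell` re-implements, as one coherent toolkit, the computational spine of
an integrative whole-cell characterization of a small, wall-less bacterium
(a Mollicute with a circular chromosome under 1 Mb): physical cell-parameter
inference from biomass measurements, doubling-time estimation, genome-wide
transcription start site (TSS) mapping from 5'-RACE read starts,
Rho-independent terminator prediction with transcription-unit (TU)
reconstruction, and conversion of transcriptomic and proteomic expression
into absolute molecules per cell. Because the deposited sequencing and
proteomics data are not desk-scale inputs, the package ships a first-class
synthetic-data generator that plants known regulatory architecture in a
miniature genome, so that every stage can be validated against ground truth.
This vignette records the models, the tunable parameters, and the design
decisions taken where the procedures left genuine freedom.

## Cell physics

Cells are treated as spheres of diameter $d$ (µm): $V = \pi d^3/6$,
$A = \pi d^2$, $SA\!:\!V = 6/d$. Four cell-mass relations are intersected to
find the most probable diameter/mass window:

* buoyant mass: $CM = V \cdot D$;
* dry mass over dry-mass fraction: $CM = DM/DF$ (constant in $d$);
* water balance: $CM = (V - DM/D_{DM})\,\rho_w + DM$, where $V - DM/D_{DM}$
  is the water volume;
* the same balance with $DM$ substituted by $V \cdot D \cdot DF$.

The two water-balance forms appear typographically garbled in their printed
source; they are reconstructed here from the mass balance
*cell mass = water mass + dry mass* with the dry-matter volume $DM/D_{DM}$
and configurable water density $\rho_w$ (default 1.0 g/ml). This
reconstruction reproduces the published window within about 1.5%, which is
the tolerance used throughout. Units are fixed internally to µm and fg
(1 g/ml = 1000 fg/µm³) to avoid silent mixed-unit errors.

Defaults are the measured values: buoyant density 1.05–1.08 g/ml, dry mass
22.1 ± 4.2 fg, and the typical bacterial ranges 20–30% (dry-mass fraction)
and 1.3–1.5 g/ml (dry-mass-specific density). The window is defined by the
pairwise intersections of the *mean* curves only (the min/max envelopes are
reported but do not move the window). Intersections are bracketed on a
2001-point grid over $d \in [0.2, 1.2]$ µm and refined by bisection to
$10^{-6}$ µm; halving the grid step moves the bounds by well under 0.1 nm /
0.1 fg. The buoyant-mass and substituted-balance curves are both
proportional to $V(d)$ and so meet only at $d = 0$; that pair is skipped,
leaving five informative intersection points:

```{r}
most_probable_window()
```

Biomass accounting divides each macromolecule class mass by the measured dry
mass; the residual ("other") is dry mass minus the sum of the classes,
clamped at zero with a warning if negative. Carbohydrate composition is
normalised over the sum of the measured sugar masses, not over the rounded
class total.

## Growth kinetics

Two estimators are provided. The exponential fit regresses $\log_2$(count)
on time and reports $1/\text{slope}$ with the fit's $R^2$. The colorimetric
method uses the time shift between twofold culture dilutions: for each OD
curve, the longest contiguous segment of at least 5 points whose linear fit
reaches $R^2 \ge 0.999$ is selected by exhaustive search (ties broken by
higher $R^2$; exactly constant, zero-slope plateaus are excluded as
non-growth); the horizontal offset between consecutive curves is evaluated
from the two regression equations at the mean OD of the overlapping fitted
ranges (a symmetric choice the source procedure leaves open), and the
doubling time is the mean offset per twofold step,
$dt = \text{offset}/\log_2(\text{dilution ratio})$. Offsets are averaged
over adjacent dilution pairs (whether the original averaged all pairs or
adjacent pairs is not stated; adjacent pairs measure each twofold step once).

The simulated OD template is a monotone decline — plateau, long linear
decline (default 240 min), plateau — mimicking phenol-red acidification. An
earlier logistic template was rejected because its curvature caps attainable
$R^2$ near 0.999 at the simulated noise (0.002 OD), making the published
linearity criterion unattainable on data that should satisfy it; the real
assay's usable portion is effectively linear.

## Synthetic study system

The generator is the definition of the study conditions, fixed once:

* 30-kb circular genome, 30 genes, G+C 0.27 (the low-GC regime of these
  organisms), operons of 1–5 genes with size probabilities
  (0.45, 0.25, 0.15, 0.10, 0.05) giving ≈2 genes per TU;
* promoters: TAWAAT −10 box, TG-extension with probability 0.7, spacer to
  the +1 of 6–7 with probability 0.8 (else uniform 4–9), +1 purine with
  P(A) = 0.7 (else G);
* genes built from sense codons of translation table 4 (TGA = Trp, the
  Mollicute convention), so every planted CDS translates cleanly;
* terminators: stem 8–12 bp, loop 4–8 nt, poly-T tail 4–8 nt; stems are
  resampled until the hairpin folds at ≤ −10 kcal/mol and closes with a G:C
  outer pair — real intrinsic terminators are strong folds, and a weak A:T
  closing pair makes the stem/T-tract boundary genuinely ambiguous (the
  outermost A:T pair can be re-read as one more tail T);
* a configurable fraction of multi-gene operons carries an internal promoter
  (iTSS) near the 3' end of a gene; optionally a fraction of operon
  promoters is planted without any motif, with the upstream window resampled
  until it contains no TAWAAT-like site (otherwise "motif-assignment rate
  equals the planted fraction" could not hold exactly on finite AT-rich
  sequence);
* 5'-RACE: Poisson background (default 0.02 per base per strand) plus peaks
  of expectation strength × depth (depth 500) split 80/10/10 over the +1 and
  its neighbours; RNA-seq: negative binomial (dispersion 0.1) with mean
  proportional to planted TU abundance × gene length; proteome: multinomial
  spectra with probability proportional to copies × length; biomass truth
  equals the measured panel; growth truth 32 min.

After assembly the generator *certifies* the genome: it runs the default
terminator predictor and regenerates from a derived sub-seed if background
sequence happens to contain an extraneous detectable terminator (AT-rich
random sequence occasionally folds a strong hairpin in front of a T-run).
This keeps "planted structure is the only structure" true by construction,
which the exact-recovery validation requires. The certification is tied to
the default predictor settings and is re-run per seed.

What the simulations do *not* emulate: sequencing error, read-level
artifacts, fragment-length effects, rRNA contamination, operon read-through,
overlapping genes, and condition-dependent expression. Passing the recovery
suite therefore demonstrates correctness of the algorithms under the stated
noise models, not performance on real libraries.

## TSS mapping

Read starts per million mapped reads (RSPM) normalise each per-base count by
the library total. Significance testing works on raw counts: the background
rate is the mean count over all $2L$ sites after censoring the top 0.1% of
counts (true start sites occupy well under 0.1% of sites in this kind of
data; censoring keeps peaks from inflating the estimate, and taking the mean
over the remaining sites — zeros included — keeps it from *underestimating*
the background, which would break the error guarantee). A position is
significant when its Poisson upper-tail p-value beats a Bonferroni
correction over $2L$ sites at family-wise level $\alpha = 0.05$.
Significant positions within 5 bp on the same strand merge into one
candidate TSS represented by the maximal count (ties to the smallest
coordinate, circular-aware). On background-only simulations the empirical
family-wise false-positive rate is far below the nominal 0.05 because the
censored-mean background is, if anything, conservative.

Promoter motifs are assigned in two phases that mirror a discover/validate
motif workflow without external software: candidate −10 boxes are first
labelled by exact match to the degenerate consensus TAWAAT within the
scanned spacer range (4–9 nt), a position-weight matrix over the
EXT (TGN) + box window is built from the labelled sites
(pseudocount 0.5, genome-composition background), and every TSS is then
scanned with the PWM. A placement is admitted when its −10 box log-odds
reaches 60% of the *box* consensus score; among admissible placements the
best full-window score wins. The threshold is applied to the box columns
only: the TG extension is present in only ~70% of true promoters, so a
full-window threshold would reject real promoters that merely lack the
extension.

Context classification: a TSS inside any gene is internal (iTSS), parallel
or antiparallel by the overlapping gene's strand; otherwise it is intergenic
(gTSS), oriented by the closest downstream gene in the TSS's transcription
direction, with circular distance capped at half the genome.

## Terminators and transcription units

Candidate hairpins are enumerated in 200-bp windows downstream of every gene
end (per strand, circular wrap): stem ≥ 6 bp with at most one mismatch
(Watson–Crick plus G:U wobble), loop 3–10 nt. Free energy comes from a
nearest-neighbour stack-sum scorer (Watson–Crick stacks from the standard
parameter set, a flat weak stack for wobble pairs, +1 kcal/mol per mismatch,
length-dependent loop initiation); the engine is pluggable, so an external
folding program can be substituted. Each candidate scores

$$\text{score} = a\,(-\Delta G) + b\,(\text{T-tract length}) - c\,(\text{distance past the gene stop})$$

with defaults $a = 1$, $b = 2$, $c = 0.05$, a required tract of ≥ 3 T, and
only candidates with score > 0 retained; overlapping candidates resolve by
maximal score. One structural requirement is added to that reconstruction:
candidates must fold at or below −6 kcal/mol. Without it, marginal stems
(a few $kT$) in AT-rich sequence pass on the strength of their T-tract term
alone, which contradicts the premise that intrinsic terminators are reliable
sequence signals. The TTS is the last base of the stem-loop in transcription
direction.

Term-to-term scaffolds partition each strand of the circle: each scaffold
starts one base after a TTS and ends at the next TTS in transcription
direction (their lengths sum to the genome length per strand — a tested
invariant). Every motif-associated TSS generates a TU from the TSS to its
scaffold's TTS. Genes are attributed when completely included in the TU on
the same strand; the gene overlapped by an internal TSS is excluded from
that TSS's own TU; and the 5'-UTR bound of 500 bp applies to the TU's
*first* attributed gene — a per-gene bound would make the long multi-gene
TUs observed in this kind of data impossible, but the per-gene variant is
available via `per_gene_utr5 = TRUE`. A gene starting exactly at its TSS is
attributed with a 0-bp UTR and flagged leaderless. Gene-less TUs whose TSS
faces an antiparallel gene are dropped as orphan TSSs; other gene-less TUs
are kept as non-coding. Terminators are assumed 100% efficient (no
read-through) during reconstruction.

Orphan genes (covered by no TU) go through a two-rule rescue cascade:
first a motif-less TSS in the same scaffold initiating on a purine with an
in-bound 5'-UTR (candidates ranked by signal intensity); failing that, a TSS
at the end of the previous scaffold — across the intervening terminator —
provided the gene's expression is non-null. At most one rescue TU per
orphan gene.

## Absolute abundances

FPKM is $C \cdot 10^9 / (L \cdot N)$ averaged over replicates (arithmetic
mean); NSAF is the standard spectral-count definition
$(SpC_i/L_i)/\sum_j (SpC_j/L_j)$, with 0 for undetected proteins — the
source names NSAF without printing a formula, so the community-standard
definition is used. Molecular weights use average (not monoisotopic)
masses: DNA residue masses with a per-strand terminal correction on linear
molecules (none on circles), RNA residues plus a 5'-triphosphate term, and
protein residues plus one water. Chromosome copies are
$\text{mass} \cdot N_A / MW$. Total RNA splits 80/15/5 into
rRNA/tRNA/mRNA by mass; equimolar species counts divide a class mass by the
summed species weights. Expression converts to copies by normalising to
relative expression, weighting by molecular weight to a mass fraction,
multiplying by the class mass and dividing by the weight again — mass is
conserved exactly, and the result is invariant to rescaling all expression
values. Complex counts average subunit copies over stoichiometry (RNA
polymerase: two α, one β, one β'); the second ribosome estimate is one third
of the rRNA molecule count. Concentrations divide copies by the midpoint of
the most probable volume window (bounds are also reported).

## Problem sizes and validation

The default validation runs 20 independently seeded noise-free simulations
(30-kb genome, ~30 genes each) through the whole pipeline and requires exact
recovery — every planted +1 called with no false positives, every planted
TTS predicted, TU precision and recall of 1.0. With default noise the TSS
recall stays at 1 in practice and the family-wise false-positive rate is
checked on 100 background-only tracks. Estimator recovery uses the stated
noise levels (counts: 5% lognormal; OD: 0.002; spectra: multinomial at
40,000 spectra). These sizes keep the full suite under two minutes while
leaving each stage's statistics non-trivial.

## Known limitations

* The terminator scorer is a reconstruction; its weights are conventions,
  not fitted values, and the stack-sum energy is an approximation to a full
  folding model (the fold engine is pluggable for that reason).
* The TSS significance rule replaces an unavailable original filter; it
  reproduces the qualitative shape (a sub-0.1% significant fraction with
  controlled false positives), not that filter's exact output.
* Free energies are not strand-symmetric (the mirrored hairpin is a
  different RNA), so only positions and strands — not scores — mirror under
  reverse complement.
* Manual curation steps (riboswitches, browser-guided boundary fixes)
  are representable only as forced inputs, not algorithmically.
* The abundance stage assumes the measured class masses apply uniformly to
  the population average cell; single-cell variation is out of scope.
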