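---
title: "Methods: phased nucleosome arrays, sequence asymmetry and mutational flux around TSSs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phased nucleosome arrays, sequence asymmetry and mutational flux around TSSs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Many eukaryotic promoters show a characteristic chromatin architecture: a
nucleosome-depleted, A/T-rich region upstream of the transcription start
site (TSS), and a regularly spaced ("phased") array of nucleosomes over
C/G-richer sequence downstream.  `nucleocyclic` implements a complete
analysis of this promoter class — we call TSSs in the most strongly phased
stratum *nucleocyclic* — for a study design with two inbred strains and an
outgroup: TSS discovery from 5′-end tag libraries in three tissues,
nucleosome positioning from MNase core reads, phasing quantification by
autocorrelation, base-composition asymmetry, and per-position mutational
flux from outgroup-inferred ancestral bases.  Because the package is
validated entirely on synthetic data, every estimator is exercised against
planted ground truth by a seeded generator that is itself part of the
package.

# The analysis, stage by stage

## TSS model

Raw 5′-tag counts per genomic position and strand are normalized so each
tissue library sums to 300,000 tags — the working size of a single cell's
mRNA complement — which puts expression on an approximate copies-per-cell
scale (30 raw tags in a 9-million-tag library ≈ 1 copy).  The three
tissue tracks are averaged position-wise; positions above 0.1 (two tags
among six million, the detection floor) are grouped into clusters with a
20-bp neighbour rule, per strand.  Each cluster nominates its
highest-expression position (leftmost on ties), and nominees are retained
greedily in descending expression order subject to a pairwise spacing of
more than 500 bp, so that flanking-window statistics of retained TSSs never
overlap.  Cluster *breadth* in a tissue is the distance between the first
positions at which the strand-oriented cumulative tag sum reaches 5 % and
95 % of the total — a percentile rule on discrete positions, deliberately
without interpolation; it is zero where the cluster is unexpressed.

## Nucleosome map

Each MNase read is the 5′ anchor of a protected fragment.  Assuming a core
length $L$ (147 bp by default), a forward read at $x$ marks a putative dyad
at $x + \lfloor (L-1)/2 \rfloor$ and a reverse read at $y$ marks
$y - \lfloor (L-1)/2 \rfloor$.  Per-strand dyad counts are smoothed with a
21-bp running average.  The midpoint count with box smoothing is a declared choice: it is the
simplest dyad score with the right support, and every downstream statistic
treats the score as given.

**Mean fragment length.** For each candidate $L \in [137, 157]$ the
fragment of a forward read spans $[x, x+L-1]$ and that of a reverse read
spans $[y-L+1, y]$.  Excluding 30 bp at each end (MNase cleavage skews
composition there), the mean A/T-indicator vector over interior offsets is
computed per strand in fragment-left-to-right orientation; for reverse
reads the interior is read from the start *inferred under the candidate*,
so that the candidate length is what aligns the two strands'
distributions.  The discrepancy is the mean squared difference over the
$L-60$ interior offsets, and the estimate is the discrepancy-minimizing
$L$ (ties to the smaller length).  This start-alignment formulation is the
only one in which the candidate length enters the comparison at all: if
the reverse vector is instead read inward from the anchored end, both
vectors are independent of $L$ except in length, and the minimizer cannot
respond to the true fragment length.  The A/T indicator is used because it
is complement-symmetric, so no strand convention can bias it.

**Stable dyads.** Working from the forward-strand smoothed score only (a deliberate
simplification: with strand-balanced libraries the two per-strand scores
carry the same information, and committing to one keeps the peak caller
independent of the strand-assignment step),
candidate dyads are score maxima within 147 bp; a candidate is dropped if
another peak lies within 165 bp (both members of such pairs are dropped),
if any 25-mer within 165 bp of it recurs elsewhere in the genome (an exact
k-mer catalogue standing in for re-mapping reads with an aligner), or if
either of the other two tissues lacks a surviving peak within 10 bp.

A subtlety worth recording: box-smoothed integer counts produce *exactly
tied* plateaus whenever one 21-bp window captures all of a dyad's reads.
The peak of such a plateau is its centre — that is where the convolution
of the reads with the kernel peaks — so tied contiguous runs collapse to
their central position.  Breaking ties to the left instead biases every
call left by half the plateau width and, at tight jitter, costs tens of
percentage points of recovery within ±5 bp.  Equal-valued maxima that are
*not* contiguous are distinct peaks and are left to the 165-bp isolation
rule.

**First dyads.** The first nucleosome downstream of a TSS is the position
with the maximal smoothed score in the strand-oriented window
$[+50, +150]$; it is undefined when the window is all zero, and a dyad
shared by several TSSs is counted once.

## Phasing

For each representative TSS, tissue, and side (upstream $[-500, 0]$,
downstream $[0, +500]$, strand-oriented), the sample autocorrelation
$R(L) = \sum_x (s(x)-\bar s)(s(x-L)-\bar s) / \sum_x (s(x)-\bar s)^2$ of
the smoothed dyad score is evaluated at lags 150–220 bp (the plausible
nucleosome repeat range).  The maximizing lag is the *periodicity* and the
maximum the *consistency*; both are missing for windows off the contig or
with zero variance.  The mean-centred, full-window-variance normalization
is the conventional sample autocorrelation (identical to R's `acf`), keeps
$|R| \le 1$, and is invariant under affine transforms of the score.  TSSs
are stratified into three groups by downstream consistency in a chosen
tissue; the default stratification is rank tertiles (group sizes differing by at
most one, ties resolved by input order), a parameter-free and
deterministic rule; k-means on the consistency values is available as an
alternative.  Group 1 — the highest
stratum — is the nucleocyclic set.

## Sequence composition

Strand-oriented 500-bp windows upstream ($[-500, -1]$) and downstream
($[+1, +500]$) of each TSS are counted for A, C, G, T and the overlapping
dinucleotides AA+TT and CC+GG; asymmetry is upstream minus downstream.
The significance of an asymmetry uses the two-sample incidence z statistic
$$Z = \frac{n_1/m_1 - n_2/m_2}
{\sqrt{\mu(1-\mu)\,(1/n_1 + 1/n_2)}},\qquad
\mu = \frac{n_1+n_2}{m_1+m_2},$$
with focal-base counts $n_i$ and total counts $m_i$.  The $1/n_1 + 1/n_2$ denominator is the package's default definition of
this statistic; note that it is undefined at zero focal counts and is not
the conventional two-proportion variance.  The statistically standard $1/m_1 + 1/m_2$ form is available
via `corrected = TRUE`, holds its type-I error at the nominal level (a
property the suite verifies over 1000 null replicates), and is reported
alongside the default form by the pipeline.

Incidence profiles around anchors are per-offset base frequencies,
optionally complement-averaged for unstranded (genome-wide dyad) anchors
so that base B at $+d$ mirrors its complement at $-d$ exactly.  The stretch
70–74 bp *upstream* of dyads, where MNase cleavage preference distorts
composition, is masked and rendered by the 41-bp running average of the
remaining offsets.  The masked range is upstream-only: the downstream
linker test window $[+70, +130]$ must stay observable.

Dyad-versus-linker contrasts collect the per-offset difference between the
first-dyad profile and the genome-wide profile over $[-30, +30]$ (dyad)
and $[+70, +130]$ (linker, centred on the average linker 100 bp
downstream), 61 values each, and compare them by one-tailed Wilcoxon
rank-sum.

## Evolution

Ancestral bases are inferred by strict outgroup parsimony: the ancestor of
the strain pair is the outgroup base whenever the outgroup agrees with at
least one strain; three-way disagreements, and sites where the outgroup
matches neither strain, are undetermined; gaps and ambiguity codes exclude
a site.  This is deliberately conservative — no probabilistic
reconstruction — because undetermined sites simply leave both the
numerator and denominator of every rate.

The per-offset mutation rate of an ordered change X→Y around anchors is
the count of focal-branch X→Y events divided by all ancestor-determined
sites at that offset.  Normalizing by *all* sites rather than by
ancestral-X sites is what makes a change and its reverse directly
comparable, at the price of each rate also scaling with the incidence of
its source base.  TSS and first-dyad anchors are strand-oriented with
categories complemented on minus-strand anchors (transcribed-strand
changes); genome-wide dyads use complement-mirrored averaging.  Flux
summaries pool counts per region: the flow into base Z is the sum of X→Z
rates, the flow out the sum of Z→X rates, and the net incidence changes
sum to zero over the four bases by construction.  The directional tests
reuse the dyad-versus-linker machinery per category, and the
strand-asymmetry (transcription-coupled repair) test compares
$d(x) = \mathrm{rate}_{C\to T}(x) - \mathrm{rate}_{G\to A}(x)$ upstream
versus downstream, one-tailed.

## Association analysis

The per-TSS parameter table has 48 columns: per strain and tissue,
log10 expression (pseudocount 0.01, since expression is analysed on a log
scale) and breadth (12); per strain, tissue and side, periodicity and
consistency (24); and for the focal strain, A/C/G/T counts upstream,
downstream and their asymmetries (12).  This enumeration yields exactly $\binom{48}{2} = 1128$ pairwise
hypotheses and hence the Bonferroni level
$0.05/1128 \approx 4.4\times10^{-5}$; the roster is exposed as
configuration rather than hard-coded.  Rows with any
missing value (a tissue without tags, a truncated window, a degenerate
autocorrelation) are dropped with the count reported.  Spearman
correlations use average ranks and the t approximation for p-values; the
suite pins the implementation to the Pearson-on-ranks identity.  Group
comparisons (expression, breadth, cross-strain positional conservation)
are one-tailed Wilcoxon rank-sum tests with the direction always supplied
by the caller, exact (closed form without ties, enumeration with ties) for
small samples and tie-corrected normal approximation otherwise.

# The synthetic-data generator

The generator (`sim_config()` and the `simulate_*` functions) plants the
phenomena the analysis is designed to detect, with every default chosen
once as a realistic study condition:

* **Promoters.** TSSs are spaced > 1000 bp apart with 500-bp windows of
  60 % A+T upstream and 60 % C+G downstream (transcribed-strand
  orientation) — a clear but not caricatured composition step.
* **Nucleosomes.** A third of promoters per tissue carry a phased
  downstream array (first dyad at +100, spacing 180 bp, inside the
  nucleosome-repeat range); the rest get a +1 nucleosome at a random
  position plus disordered downstream nucleosomes.  Every promoter keeps a
  −1 nucleosome near −200 and disordered tissue-specific nucleosomes
  further upstream: real upstream windows are never empty of signal, only
  unphased.  Between promoters, background dyads shared by all tissues are
  laid down at irregular 170–230-bp gaps (irregular so that background
  regions do not masquerade as phased arrays), with a graded A/T profile
  rising from 35 % at the dyad to 70 % at the linker — the canonical
  GC-rich core / AT-rich linker organisation, and the within-core signal
  the fragment-length estimator aligns on.
* **Reads.** Tag libraries allocate a fixed total multinomially across
  promoters in proportion to log-normal expression (sd 1 in log10 units),
  spread geometrically over ±10 bp of the TSS; the within-cluster tag
  shape of real libraries is unknown, and geometric decay is a declared
  stand-in.  Nucleosome fragments have Normal midpoints (sd 2 bp) and
  Normal lengths (sd 4 bp) around the planted dyad and true core length;
  both cleavage ends are re-placed within ±2 bp with weight
  $w^{\text{A/T}}$ ($w = 2$), an end-placement reweighting rather than a
  digestion simulation, because only the end-composition artifact matters
  to the estimators under test.  Anchors are reported strand-balanced.
* **Evolution.** Sites evolve independently under per-branch 4×4
  substitution matrices (default: 2:1 transition bias, ~1.7 % per branch,
  the divergence scale of strains with a ~3.4 % SNP rate), optionally with
  position-dependent multipliers to plant dyad- or linker-localised
  mutational biases.  No indels are simulated, so the strain coordinate
  map is the identity — which is also why the cross-strain distance
  analysis has a clean ground truth.
* **Coupling.** Promoters phased in a tissue get a +1 log10 expression
  shift there, planting the phasing–expression association the
  correlation and group-comparison stages are meant to detect.  Set
  `phasing_expression_shift = 0` to generate the null.

Identical configurations reproduce bit-identical outputs: every stage
derives its own stream deterministically from the single seed, so partial
reruns of a module reproduce that module.

**What passing these tests does and does not show.**  The generator omits
indels, read-level sequencing error, alignment artifacts, rate
heterogeneity beyond the configured modulations, linked selection, and any
within-cluster tag structure beyond geometric decay.  Recovery on this
synthetic data validates the estimators' correctness and calibration, not
their robustness to the full messiness of real libraries.

# Numerical choices and degenerate inputs

* Running averages truncate their window at vector ends (a constant track
  smooths to itself) and, where offsets are masked, drop them from both
  numerator and denominator.
* Tied cluster maxima and greedy-selection ties go to the leftmost
  position; tied autocorrelation maxima to the smaller lag; tied
  fragment-length discrepancies to the smaller length; tied smoothed-score
  plateaus to their centre (see above).
* Zero-variance autocorrelation windows, all-zero first-dyad windows,
  empty tissues, truncated flanking windows and z-tests at zero focal
  counts are all reported as missing rather than guessed.
* All-tied rank-sum inputs report the boundary p = 0.5 with a degenerate
  flag.
* Problem sizes: unit tests run genomes of 80–300 kb; the packaged
  validation pipeline defaults to 1.2 Mb with 300 promoters, and the
  headline validation script runs 8 Mb with 2000 promoters, the scale at
  which the phasing–expression correlation is resolvable far beyond the
  Bonferroni threshold.

# Interfaces

Every stage is an exported R function; `run_pipeline()` chains them on a
synthetic configuration and, given an output directory, writes
FASTA/BED/bedGraph/TSV/JSON stage outputs with a checksummed manifest.  A
thin command-line wrapper (`exec/nucleocyclic`) runs the same end-to-end
pipeline from a shell; module-level work is meant to be done in R.

# Known limitations

* The ancestral-inference rule is parsimony with an outgroup tie-break;
  sites where the outgroup matches neither strain are discarded even
  though a likelihood method could often resolve them.
* Rates normalized by all determined sites confound substitution pressure
  with source-base incidence; the dyad/linker contrasts therefore compare
  *differences between anchor sets*, which cancels composition structure
  only to first order.
* The 48-parameter roster and the three-group stratification are
  conventions among several reasonable ones; both are configurable.
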