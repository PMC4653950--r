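# nucleocyclic

Promoters with strongly phased nucleosome arrays downstream of the
transcription start site (TSS) — *nucleocyclic* TSSs — are a recurrent
feature of vertebrate genomes: nucleosome-depleted, A/T-rich sequence
upstream, C/G-richer sequence carrying a regular nucleosome array
downstream, higher expression, and a distinctive local mutational
landscape.  `nucleocyclic` is an R package for identifying this promoter
class and characterising its sequence and evolutionary properties in a
two-strain + outgroup study design, validated end to end on synthetic data
with planted ground truth.

The package implements:

* **TSS model** — per-position 5′-tag normalization to a 300,000-tag
  library (≈ copies per cell), three-tissue averaging, cluster calling
  (> 0.1 expression, 20-bp gaps), representative-TSS selection (> 500 bp
  spacing), cluster breadth (5th/95th cumulative percentiles), per-tissue
  activity, and cross-strain positional conservation.
* **Nucleosome map** — smoothed dyad-score tracks from MNase read anchors,
  the mean core fragment length as the minimizer over L ∈ [137, 157] of
  the mean squared difference between strand-specific A/T incidence
  vectors over fragment interiors (30-bp cleavage-biased ends excluded),
  stable dyads (peak, 165-bp isolation, 25-mer uniqueness, cross-tissue
  filters), and first dyads in [+50, +150].
* **Phasing** — sample autocorrelation
  R(L) = Σ(s(x)−s̄)(s(x−L)−s̄) / Σ(s(x)−s̄)² of the dyad score over lags
  150–220 bp in the 500-bp windows flanking each TSS; periodicity = argmax,
  consistency = max; rank-tertile grouping with Group 1 = nucleocyclic.
* **Sequence composition** — windowed base/dinucleotide counts and
  asymmetries, the two-sample incidence z-test
  Z = (n₁/m₁ − n₂/m₂) / √(μ(1−μ)(1/n₁+1/n₂)) with μ = (n₁+n₂)/(m₁+m₂)
  (a corrected 1/m₁+1/m₂ variant behind a flag), 41-bp-smoothed incidence
  profiles with the MNase-biased 70–74-bp upstream stretch masked, and
  one-tailed dyad-versus-linker rank-sum contrasts.
* **Evolution** — outgroup-parsimony ancestral bases, per-offset mutation
  rates of all 12 ordered base changes normalized by determined sites,
  mutational-flux summaries (flow in/out per base, exactly conservative),
  dyad/linker directional tests, and the C→T versus G→A strand-asymmetry
  test.
* **Association** — the 48-parameter per-TSS table, Spearman correlation
  matrix with Bonferroni level 0.05/1128, and one-tailed group
  comparisons.
* **Synthetic data** — a seeded generator for genomes with planted
  promoters, phased and background nucleosomes, tag libraries, A/T-biased
  MNase reads, and two-branch + outgroup substitution histories, plus
  `run_pipeline()` to chain everything with a checksummed output manifest.

## Worked example

```r
library(nucleocyclic)

cfg <- sim_config(seed = 1)          # 1.2 Mb, 300 promoters, 3 tissues
run <- run_pipeline(cfg)
run
#> nucleocyclic_run: 300 aligned representative TSSs, 100 nucleocyclic (Group 1)
#>   fragment length: 147 bp; stable dyads: 2987
#>   Group-1 expression p: 9.24e-13

run$fragment_length$optimal          # planted core length was 147
#> [1] 147

run$comparisons$expression
#> group comparison (greater): n = 100 vs 200, medians 2.218 vs 0.9758,
#> p = 9.24e-13 (normal)

round(run$ztests$A$printed$z, 1)     # A-incidence asymmetry around Group 1
#> [1] 18.5

r <- run$correlation$r["Hd_Na_testes_Dw", "Hd_Exp_testes"]
p <- run$correlation$p["Hd_Na_testes_Dw", "Hd_Exp_testes"]
c(rho = round(r, 2), significant = p < bonferroni_threshold(0.05, 1128))
#> rho significant
#> 0.49        1.00
```

The run recovers the planted 147-bp core fragment length, calls the planted
background dyads as stable dyads, assigns the phased promoters to Group 1,
and finds Group-1 expression significantly higher than the rest
(one-tailed rank-sum), the planted A/T-upstream asymmetry (z ≈ 18), and a
Bonferroni-significant positive correlation between downstream nucleosome
consistency and expression — the nucleocyclic phenotype.

`run_pipeline(cfg, outdir = "out")` additionally writes FASTA genomes, BED
tag/read files, TSV tables and a checksummed `manifest.json`; the same
end-to-end run is available from a shell via `exec/nucleocyclic`.

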