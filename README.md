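# synmut

Does per-gene synonymous diversity in natural bacterial isolates predict
where synonymous substitutions accumulate during laboratory evolution?

Synonymous nucleotide diversity, θ_s, varies more than 20-fold among the
core genes of natural *E. coli* isolates. If that variation reflects
locally optimized per-gene mutation rates (θ_s ≈ 2N_e·µ under
neutrality), then an evolution experiment — where synonymous changes are
effectively neutral markers of the mutation process — should deposit its
synonymous substitutions preferentially in high-θ_s genes. `synmut` is an
R package for running that test end to end: it annotates point mutations
codon- and strand-aware on an ancestral genome, estimates per-gene θ_s
from natural-isolate codon alignments, compares the observed cumulative
distribution of synonymous substitutions over θ_s-ranked genes against a
gene-length null and θ_s-proportional alternatives with
Kolmogorov–Smirnov tests (asymptotic + Monte-Carlo), summarizes
hypermutator mutation spectra, and runs the gene-expression association
analyses (Welch's t, Wilcoxon rank-sum, Pearson r, Kendall's partial
rank-correlation controlling for gene length). A ground-truth-labeled
synthetic-data generator makes every stage runnable and testable with no
downloads.

It is aimed at microbial population geneticists and experimental-evolution
groups who have (a) an ancestral genome (FASTA) + CDS annotation (GFF3),
(b) per-clone point-mutation lists (VCF or TSV), (c) per-gene codon
alignments of natural isolates (multi-FASTA) or a precomputed θ_s table,
and optionally (d) a per-gene expression table.

## The statistics at the core

* **θ_s per gene** (Watterson, synonymous sites only):
  θ̂_s = S_syn / (a_n · L_syn), a_n = Σ_{i=1}^{n−1} 1/i, where a column is
  a synonymous segregating site iff it is polymorphic and amino-acid
  identity holds across all sequences, and L_syn is the Nei–Gojobori
  fractional synonymous-site count averaged over sequences.
* **Rate models** over genes ordered by ascending θ_s: weights ∝ length
  (`length_null`), ∝ synonymous sites (`syn_sites_null`), ∝ θ_s ×
  synonymous sites (`theta_per_site`), or ∝ θ_s (`theta_per_gene`).
* **KS comparison**: D = max |F_obs − F_model| on the discrete gene axis;
  asymptotic p from the Kolmogorov tail with
  λ = (√n + 0.12 + 0.11/√n)·D, and a seeded Monte-Carlo multinomial null
  p = (1 + #{D_sim ≥ D_obs})/(reps + 1) as the preferred p-value.
* **Partial Kendall correlation**:
  τ_xy·z = (τ_xy − τ_xz τ_yz)/√((1−τ_xz²)(1−τ_yz²)), tested with
  z = τ_xy·z / √(2(2n+5)/(9n(n−1))) assuming normality.

See `vignettes/synmut-methods.Rmd` for assumptions, parameter choices,
what the synthetic generator does and does not emulate, and known
limitations.

## Worked example

Simulate a 300-gene cohort with 200 synonymous substitutions placed under
the gene-length null, then run the full analysis:

```r
library(synmut)
params <- cohort_params(n_genes = 300, n_substitutions = 200)
sim <- simulate_cohort(params, seed = 1, out_dir = "cohort")
res <- run_pipeline(pipeline_config(
  genome = sim$files$genome, gff = sim$files$gff,
  mutations = sim$files$vcf, theta_table = sim$files$theta,
  expression = sim$files$expression, core_ids = sim$files$core,
  clones = sim$files$clones, out_dir = "cohort/results",
  seed = 1, mc_reps = 1000))
subset(res$ks, group == "all")
```

```
           mode group       D   n p_asymptotic     p_mc reps seed
    length_null   all 0.04771 200    7.429e-01 0.687313 1000    1
 syn_sites_null   all 0.04662 200    7.680e-01 0.705295 1000    1
 theta_per_site   all 0.25217 200    1.131e-11 0.000999 1000    1
 theta_per_gene   all 0.25514 200    6.128e-12 0.000999 1000    1
```

Read: the observed substitution distribution is indistinguishable from
the gene-length null it was generated under (D ≈ 0.048, Monte-Carlo
p ≈ 0.69) but decisively rejects the θ_s-proportional models (D ≈ 0.25,
p ≈ 1/(reps+1) — the smallest value 1000 replicates can resolve). The
mutation-spectrum table shows the lineage signatures the generator put
in: the *mutT*-class clone is dominated by A:T→C:G transversions, the
mismatch-repair-class clone by C:G→T:A and A:T→G:C transitions:

```
 clone_id AT_to_GC CG_to_TA AT_to_CG AT_to_TA CG_to_AT CG_to_GC total
    Ara-1        1        0       20        0        1        0    22
    Ara-2       10       22        0        1        3        1    37
```

And the association analysis reproduces the qualitative length story:

```
mean length with/without: 1533 / 870 bp
wilcoxon length p: 2.43e-16
pearson r(expression, length): 0.071
partial tau: 0.0078 (p = 0.840)
```

Genes that received a substitution are much longer on average (Wilcoxon
p ≈ 2×10⁻¹⁶); expression is weakly length-correlated; and controlling for
length, the substitution–expression partial correlation is
non-significant (p = 0.84) — substitution placement here is driven by
gene length alone, as constructed.

## Command line

A launcher is installed at `inst/scripts/synmut`:

```sh
Rscript inst/scripts/synmut simulate --out cohort --seed 1 \
    --n-genes 300 --n-substitutions 200
Rscript inst/scripts/synmut run --genome cohort/genome.fa \
    --gff cohort/genes.gff3 --mutations "$(ls cohort/*.vcf | paste -sd,)" \
    --theta cohort/theta_s.tsv --expression cohort/expression.tsv \
    --core cohort/core_genes.txt --clones cohort/clones.tsv \
    --out cohort/results --seed 1 --mc-reps 1000
```

Subcommands: `simulate`, `theta` (estimate θ_s from an alignment
directory), `annotate`, `run`.

## Acceptance

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The source study's headline numbers derive from deposited real data that
cannot be fetched offline, so no desk-scale numeric targets are reported
(the script writes an empty JSON object after running the full synthetic
pipeline as a self-check and exits nonzero on any failure). The
quantitative acceptance surface is `tests/testthat/test-acceptance.R`:
codon-engine equivalence with brute-force enumeration, the Watterson
closed form and its invariances, full-scale (2,834 genes / 1,069 events)
generator-vs-annotation ground-truth identity, KS calibration and power
at full scale, Monte-Carlo-vs-exact-enumeration agreement, and θ_s
estimator recovery within 5%. One criterion (marginal-vs-partial
expression association) fails by design of its generating model; the
analysis is in the methods vignette under *Known limitations*.
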