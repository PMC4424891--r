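# gselsim

Simulation framework for comparing **sequence-, array- and
biology-informed genomic selection** in a closed breeding population.

Whole-genome sequence genotypes promise to put every causal variant in the
prediction model, yet field results keep showing only marginal gains over
dense SNP arrays. `gselsim` reproduces the simulation logic behind that
finding: founder haplotypes from a bottlenecked coalescent calibrated to
cattle-like diversity (π ≈ 1.2×10⁻³), an explicit quantitative-trait
architecture inside predefined gene windows, gene-dropping through a
seven-generation recorded pedigree, competing predictor panels, and
cross-validated prediction of last-generation genetic merit.

## Model

Phenotypes follow an additive-dominance model over nQTN causal sites,

y_i = μ + Σ_q (γ_iq a_q + δ_iq d_q) + e_i,   e ~ N(0, V_e),

with per-QTN additive variances Va ~ Γ(5.4, 0.42) and dominance variances
Vd ~ Exp(10) drawn independently of allele frequency, effects recovered
from Vd = [2f(1−f)d]² and Va = 2f(1−f)α², and V_e calibrated to broad-sense
H² = 0.25. Marker effects are estimated with VanRaden's **nonlinear A**:
SNP-BLUP (ridge regression on centred dosages, Jacobi-preconditioned
conjugate gradient) with per-SNP variances iteratively re-weighted as

σ²_aj = σ²_a0 · 1.125^(|â_j|/sd(â) − 2),  σ²_a0 = V_A / (2 Σ p_j(1−p_j)).

Pedigree BLUP (animal model on the tabular-method numerator relationship
matrix, variance ratio (1−H²)/H² = 3) is the no-marker baseline. Accuracy
is the Pearson correlation between predicted and true breeding values of
the 500 last-generation individuals, whose phenotypes are withheld.

Panels: medium (7.5k) and high-density (17k) arrays ascertained at
MAF ≥ 0.15 in a 50-individual discovery sample, RAD/GBS windows, full
sequence, causal-only, and gene-window priors (all 65 genes, a random
half, the half plus 30 neutral windows). Genotyping, sequencing (biased
caller, rate λ) and imputation (symmetric, rate α) error models with a
minimum allele-count filter are included.

## Worked example

```r
library(gselsim)

cfg <- desk_config(n_qtn = 100, seed = 1,
                   methods = c("pedigree_blup", "medium_array", "causal"))
sc <- run_scenario(cfg, n_replicates = 5)
glance(sc)
#> # A tibble: 3 x 4
#>   method        mean_accuracy sd_accuracy n_replicates
#>   <chr>                 <dbl>       <dbl>        <int>
#> 1 causal                0.945      0.0509            5
#> 2 medium_array          0.604      0.174             5
#> 3 pedigree_blup         0.404      0.215             5
```

Knowing the causal sites themselves makes prediction nearly perfect
(≈ 0.95); a blind 1.5k-SNP array (the one-fifth-scale analogue of the 7.5k
array) does far worse and only modestly beats pedigree BLUP — the
diminishing-returns pattern that motivates the package. `autoplot(sc)`
draws the per-replicate accuracy distribution; `run_replicate(cfg, 1,
keep_objects = TRUE)` exposes every intermediate object (base population,
architecture, pedigree, panels, fits) and `export_run()` writes pedigree,
phenotype and panel tables plus a seed manifest.

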