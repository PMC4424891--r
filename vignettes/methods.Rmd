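---
title: "Simulating sequence- and array-based genomic selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating sequence- and array-based genomic selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gselsim` simulates a closed livestock breeding population from its
coalescent ancestry through seven generations of recorded matings, and asks
how well different marker panels predict the genetic merit of the youngest
generation.  This vignette is the package's own account of the model, the
choices we made where the design was genuinely open, and what the shipped
tests do and do not demonstrate.

## The simulated system

A diploid genome of ten 3-Mb chromosomes is simulated at a nucleotide
diversity of $\pi = 1.2\times10^{-3}$ per site, a value typical of
commercial cattle.  Causal variants (QTN; 20, 100, or 1000 of them) are
restricted to 65 predefined 10-kb "gene" windows clustered on seven of the
ten chromosomes.  Phenotypes follow

$$y_i = \mu + \sum_q (\gamma_{iq} a_q + \delta_{iq} d_q) + e_i,
  \qquad e_i \sim N(0, V_e),$$

with dosage $\gamma \in \{-1,0,1\}$ and heterozygosity indicator $\delta$.
Per-QTN additive variances are drawn from $\Gamma(5.4, 0.42)$ and dominance
variances from an exponential with mean $0.1$, independently of allele
frequency; effects are recovered by inverting the classical decomposition
$V_d = [2f(1-f)d]^2$, $V_a = 2f(1-f)\alpha^2$, with signs equally likely.
$V_e$ is calibrated so broad-sense heritability is $H^2 = 0.25$ under
equilibrium.

Because variance, not effect size, is frequency-independent, rare QTN carry
very large effects.  For dominance this is extreme: $d$ grows like
$1/(2f(1-f))$, so a QTN at $f = 0.005$ with $V_d = 0.1$ carries a dominance
deviation of tens of genetic standard deviations, expressed only in its rare
heterozygotes.  The *total* genotypic value is therefore leptokurtic and its
sample correlation with any smooth predictor is erratic in a 500-individual
validation set.  Accuracy is accordingly scored against **breeding values**
(the sum of substitution effects, the quantity the reference results tabulate) by
default; `truth = "g_total"` remains available in the evaluation config.

## Founder haplotypes

Founders are simulated with a sequential Markov coalescent (SMC) written in
C++: the marginal tree at the left chromosome end is a standard coalescent
under piecewise-constant demography; moving rightward, recombination
breakpoints arise at rate proportional to tree length, the branch above a
uniform point is erased and the detached lineage re-coalesces into the
remaining tree.  Marginal trees are exactly coalescent; only long-range
linkage is slightly approximated — the same approximation class as the
Markovian simulators commonly used for this population size.

The default demography has three epochs (sizes relative to the recent
epoch, times in units of $2N_0$ generations): a recovered recent population
(size 1), a domestication-style bottleneck (size 0.25 from time 0.07), and a
large ancestral population (size 1.0 beyond 0.22).  A two-epoch model
(recent reduction only) cannot jointly match the diversity target and the
observed segregating-site count at this sample size: with 2140 sequences,
$S/(\pi L) \approx 9.3$ exceeds the constant-size harmonic factor
$a_n \approx 8.3$, which requires a rare-variant excess — i.e. a recovery
after the bottleneck.  $N_0$ is calibrated analytically from the closed-form
$E[T_2]$ of the epoch structure so that expected diversity equals the
target; with these defaults one full-scale run yields $\pi = 1.21\times
10^{-3}$ and roughly $3.4\times10^5$ segregating sites over 30 Mb.

A two-breed scenario is supported as a clean isolation split (no migration)
with the split time exposed in the config and a Hudson-estimator
`fst_hudson()` helper; it is used for cross-breed ascertainment experiments
only.

## Pedigree, meiosis, and the recombination-map question

The breeding population holds 1020 pedigree founders plus seven generations
of 500, i.e. 4520 individuals, all phenotyped and genotyped.  Each
generation is produced by 20 sires drawn from the previous one; dams
produce few offspring each and are mated to at least two different sires
(non-hierarchical mating, as in dairy pedigrees).  The published design
sentence is internally inconsistent ("20 sires were mated to 50 dams, and
each dam had two offspring ... a total of 500 individuals per generation");
we resolve it as 250 dams with two offspring each, which preserves the
stated two-offspring/two-sire dam families and the 500-per-generation
census, and matches the reported pedigree-BLUP accuracy far better than
50 dams with ten offspring each.  Both designs are one config entry apart.

Meioses draw a Poisson number of crossovers per chromosome, capped at 4,
with uniform positions and no interference.  The reference design quotes a
1 cM/Mb map (0.03 expected crossovers per 3-Mb chromosome) *and* a cap of
four crossovers per chromosome per meiosis.  A cap at 4 is vacuous at mean
0.03 ($P > 4$ is $\sim 10^{-8}$) but binds exactly when the mean is of
order 3 — i.e. when the simulator treats each compressed 3-Mb chromosome as
carrying the ~1 Morgan of map of the real chromosome it stands for.  The
two readings give drastically different results: at mean 0.03, chromosomes
co-segregate essentially intact through the pedigree, every marker panel
tracks them equally well, and the reported contrasts between panels (the
RAD penalty, the array-density gradient) disappear.  At one crossover per
Mb (mean 3, capped at 4) the panels separate as reported.
`gene_drop()` therefore defaults to `meiosis_recomb_rate = 1e-6` per bp,
while the coalescent stage keeps the quoted 1 cM/Mb; both are plain config
entries, and `meiosis()` honours whatever rate it is given.

## Panels, error models, evaluation

Panel strategies: ascertained arrays (random draw of 7500 or 17 000 sites
with MAF $\ge 0.15$ — or $> 0$ — in a 50-diploid discovery sample kept out
of the pedigree), RAD (all SNPs in 100 random 10-kb windows), full
sequence, causal-only, all SNPs in the 65 gene windows, in a random half of
them, and in the half plus 30 random non-gene windows.  Ascertainment MAF is
always computed in the discovery sample.  Genotype error models follow the
stated confusion matrices (biased NGS caller with rate $\lambda$; symmetric
per-genotype rate $\alpha$ for imputation and arrays), compose in the order
NGS → K-filter → imputation, and the minimum allele-count filter drops
sites whose observed minor-allele count is below K.

SNP effects are estimated with VanRaden's nonlinear A: SNP-BLUP (ridge
regression on training-centred dosages, solved by Jacobi-preconditioned
conjugate gradient to a $10^{-8}$ relative residual, warm-started across
outer iterations) with per-SNP variances re-weighted each outer round as
$\sigma^2_{aj} = \sigma^2_{a0}\,1.125^{|\hat a_j|/sd(\hat a) - 2}$ around
$\sigma^2_{a0} = V_A / (2\sum_j p_j(1-p_j))$, for at most 10 outer rounds
or until the largest effect change falls below $10^{-6}\,sd(y)$.  For
panels much wider than the training set the identical solution is obtained
through the dual (individual-space) form; the two routes agree to solver
tolerance and both are tested against dense solves.  Pedigree BLUP solves
the animal-model mixed-model equations with the tabular-method relationship
matrix and variance ratio $(1-H^2)/H^2 = 3$.  Accuracy is the Pearson
correlation between prediction and truth in the 500 last-generation
individuals, whose phenotypes are withheld; all methods within a replicate
share the same simulated population (paired comparison).

## Reduced-scale configurations

Full-scale replicates cost minutes each, so the package ships two reduced
designs built by one scaling rule: the genome keeps full 3-Mb chromosomes
(the independent units of both linkage and between-replicate variance) but
fewer of them; founders, sires, dams, per-generation census, QTN count,
array sizes, and RAD/noise window counts all scale by the same factor;
heritability, generation count, per-dam family size, window width,
discovery-panel size and MAF threshold stay at full-scale values.  This
preserves records per effective genome segment and records per QTN, the
ratios that govern accuracy.

Scaling is not free of bias: the pool of contributing parents shrinks with
the design, and a smaller founder pool inflates chance marker–QTN linkage
(the finite-sample component of $r^2$ scales like one over the number of
contributing founder haplotypes), so very small designs overstate
marker-panel accuracy.  Measured against our own full-scale runs, the
half-scale design (`scenario_config(scale = 0.5)`: five chromosomes, 2260
individuals, 50 QTN, 3750/8500-SNP arrays) reproduces the full-scale
scenario means within replicate noise, while the one-fifth design
(`desk_config()`, scale 0.2) is a few hundredths high on marker panels and
is kept for examples and smoke tests only.  The replication script
(`scripts/acceptance.R`) therefore runs the causal-panel scenario at full
study size (a causal-only replicate costs about a minute) and the
remaining scenarios at half scale with 10 replicates — about the most that
fits a desk run — with between-replicate SDs around 0.1–0.14.  Because a
handful of replicates of a high-variance quantity is being averaged, its
numbers carry standard errors of roughly 0.04; the shipped tests compare
every scenario mean to its reference value at two such standard errors.

## Numerical and degenerate cases

Site positions are floored to integer bp and nudged to strict increase;
sites leaving the chromosome are dropped.  Zero mutation rate with a
positive diversity target raises a configuration error; monomorphic
training panels raise an argument error; `sd(\hat a) = 0` freezes the
nonlinear-A variances at $\sigma^2_{a0}$ and flags the fit degenerate; PCG
failure to converge within the iteration cap is an error carrying the
residual history.  All stages consume seeds derived deterministically from
the master seed, stage name and replicate index, so any replicate is
reproducible in isolation; restricting gene-dropping to tracked sites never
changes the alleles at those sites.

## Limitations

The generator emulates neutral, selection-free gene dropping: no selective
sweeps, no genotype-dependent fertility, no overlapping generations, no
migration beyond the clean two-breed split.  NGS errors are per-genotype
confusion draws, not read-level simulation; missing genotypes are not
modelled.  Passing tests therefore demonstrate correctness of the stated
model, not realism of any particular livestock population.  The Markovian
coalescent slightly underestimates long-range LD; at the marker densities
studied here that bias is negligible relative to between-replicate noise.
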