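#' Scenario configuration
#'
#' Builds the nested configuration that drives every stage of a simulated
#' genomic-selection study: genome and demography, gene windows and trait
#' architecture, breeding pedigree, predictor panels, and evaluation settings.
#' Defaults reproduce the reference study conditions: ten 3-Mb chromosomes at
#' nucleotide diversity 1.2e-3 shaped by an ancient bottleneck, 65 10-kb gene
#' windows holding 20 or 100 QTN, a 4520-individual seven-generation pedigree,
#' broad-sense heritability 0.25, and seven predictor panel strategies.
#'
#' `scale` shrinks the study while preserving the quantities that drive
#' cross-validation accuracy: training size, marker density per centimorgan,
#' genome length (hence the effective number of independent segments), QTN
#' count and window coverage fractions all scale together, while heritability,
#' generation number, mating ratios, the 10-kb window size, the 50-individual
#' discovery panel and the MAF threshold stay at their full-scale values.
#'
#' @param n_qtn number of causal sites (20 or 100 in the reference design).
#' @param h2 broad-sense heritability used to calibrate the residual variance.
#' @param scale linear scaling factor in (0, 1]; see Details.
#' @param seed master seed recorded in the config; per-stage seeds derive
#'   from it deterministically.
#' @return a list of class `gs_config`.
#' @export
#' @examples
#' cfg <- scenario_config(n_qtn = 20, scale = 0.1, seed = 1)
#' cfg$pedigree
scenario_config <- function(n_qtn = 100, h2 = 0.25, scale = 1, seed = 1L) {
  stopifnot(scale > 0, scale <= 1, h2 > 0, h2 < 1)
  sc <- function(x) as.integer(round(x * scale))

  # Chromosomes are the independent genome units (each keeps its full 3-Mb /
  # 0.03-Morgan structure); scaling reduces how many there are.  Gene counts
  # are reallocated proportionally to the full-scale per-chromosome pattern.
  full_counts <- c(20, 10, 10, 10, 5, 5, 5, 0, 0, 0)
  n_chrom <- max(1L, as.integer(round(10 * scale)))
  gene_counts <- regroup_counts(full_counts, n_chrom,
                                as.integer(round(sum(full_counts) * scale)))

  cfg <- list(
    genome = list(
      n_chrom = n_chrom,
      chrom_length_bp = 3000000L,
      mutation_rate = 1e-8,      # per bp per generation
      recomb_rate = 1e-8,        # coalescent-stage rate per bp (1 cM/Mb)
      # Gene-dropping crossover intensity per bp.  The reference design caps
      # crossovers at 4 per chromosome per meiosis, a cap that only binds if
      # the expected count is of order 1 per Mb (Poisson mean 3 for a 3-Mb
      # chromosome); see the methods vignette for the full argument.
      meiosis_recomb_rate = 1e-6,
      target_pi = 1.2e-3,        # per site
      # piecewise-constant sizes relative to the recent epoch, times in
      # units of 2*N0 generations: recovered recent size, domestication
      # bottleneck, large ancestral population
      demography = list(start = c(0, 0.07, 0.22), size = c(1, 0.25, 1.0)),
      n_founders = sc(1020),
      n_discovery = 50L,
      n_breed2 = 0L,
      split_time = 0.06,         # used only when n_breed2 > 0
      max_crossovers = 4L
    ),
    genes = list(
      per_chrom = gene_counts,
      window_bp = 10000L
    ),
    arch = list(
      n_qtn = if (scale < 1) as.integer(round(n_qtn * scale)) else as.integer(n_qtn),
      gamma_shape = 5.4,
      gamma_scale = 0.42,
      exp_rate = 10,
      h2 = h2,
      mu = 0,
      equal_effects = FALSE,
      qtn_scope = "genes"
    ),
    pedigree = list(
      n_generations = 7L,
      n_sires = max(2L, sc(20)),
      # 250 two-offspring dams per generation: the reading of the published
      # design that preserves both the 500-per-generation census and the
      # "two offspring with two sires" dam families (methods vignette).
      n_dams = sc(250),
      offspring_per_dam = 2L
    ),
    panels = list(
      medium_array = list(type = "array", target_size = sc(7500), maf_min = 0.15),
      hd_array = list(type = "array", target_size = sc(17000), maf_min = 0.15),
      rad = list(type = "rad", n_windows = sc(100), window_bp = 10000L),
      sequence = list(type = "sequence"),
      causal = list(type = "causal"),
      genes_all = list(type = "genes"),
      genes_half = list(type = "genes_half",
                        n_windows = as.integer(ceiling(sum(gene_counts) / 2))),
      genes_half_noise = list(type = "genes_half_noise",
                              n_windows = as.integer(ceiling(sum(gene_counts) / 2)),
                              noise_windows = sc(30), noise_window_bp = 10000L)
    ),
    evaluation = list(
      methods = c("pedigree_blup", "medium_array", "hd_array", "rad",
                  "sequence", "causal", "genes_all", "genes_half",
                  "genes_half_noise"),
      model = "nonlinear_a",
      truth = "breeding_value",
      outer_iters = 10L,
      pcg_tol = 1e-8,
      errors = list()
    ),
    scale = scale,
    seed = as.integer(seed)
  )
  class(cfg) <- "gs_config"
  cfg
}

#' Desk-scale preset
#'
#' One-fifth-scale configuration used by the shipped replication script and
#' the heavier tests.  Accuracies under this preset estimate the full-scale
#' scenario means (see the methods vignette for the scaling argument) but are
#' not identical to them.
#'
#' @inheritParams scenario_config
#' @param methods evaluation methods to run per replicate.
#' @export
desk_config <- function(n_qtn = 100, seed = 1L,
                        methods = c("pedigree_blup", "medium_array",
                                    "hd_array", "rad", "causal", "genes_all",
                                    "genes_half", "genes_half_noise")) {
  cfg <- scenario_config(n_qtn = n_qtn, scale = 0.2, seed = seed)
  cfg$evaluation$methods <- methods
  cfg
}

# Compress a per-chromosome count pattern onto fewer chromosomes: group the
# original chromosomes onto the new ones, then allocate `total` by largest
# remainder of the grouped weights.
regroup_counts <- function(full_counts, n_chrom, total) {
  grp <- ceiling(seq_along(full_counts) * n_chrom / length(full_counts))
  w <- vapply(seq_len(n_chrom),
              function(g) sum(full_counts[grp == g]), 0)
  if (sum(w) == 0) return(integer(n_chrom))
  raw <- total * w / sum(w)
  out <- floor(raw)
  rem <- total - sum(out)
  if (rem > 0) {
    ord <- order(raw - out, decreasing = TRUE)
    out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1
  }
  as.integer(out)
}

# Expected pairwise coalescence time E[T2] (in 2*N0 generations) under a
# piecewise-constant demography.
expected_t2 <- function(demography) {
  st <- demography$start
  sz <- demography$size
  stopifnot(length(st) == length(sz), st[1] == 0, all(sz > 0),
            !is.unsorted(st, strictly = TRUE))
  surv <- 1
  e_t2 <- 0
  for (e in seq_along(st)) {
    if (e < length(st)) {
      d <- st[e + 1] - st[e]
      e_t2 <- e_t2 + surv * sz[e] * (1 - exp(-d / sz[e]))
      surv <- surv * exp(-d / sz[e])
    } else {
      e_t2 <- e_t2 + surv * sz[e]
    }
  }
  e_t2
}

# Recent-epoch effective size implied by the diversity target.
calibrate_n0 <- function(genome) {
  e_t2 <- expected_t2(genome$demography)
  if (genome$mutation_rate <= 0 && genome$target_pi > 0) {
    abort("mutation rate 0 cannot attain a positive diversity target",
          class = "gs_config_error")
  }
  if (genome$target_pi <= 0) return(0)
  genome$target_pi / (4 * genome$mutation_rate * e_t2)
}

# Deterministic per-stage seed derived from the master seed.
stage_seed <- function(master, replicate, stage) {
  h <- as.double(master %% 2147483647L)
  for (k in c(replicate, utf8ToInt(stage))) {
    h <- (h * 69069 + k) %% 2147483647
  }
  as.integer(max(1, h))
}
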