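#' Place gene windows on the genome
#'
#' Distributes non-overlapping 10-kb "gene" windows across chromosomes
#' according to the configured per-chromosome counts (default
#' 20, 10, 10, 10, 5, 5, 5, 0, 0, 0 — 65 windows, 650 kb of 30 Mb).  QTN are
#' later restricted to these windows.
#'
#' @param config a [scenario_config()] list.
#' @param seed integer seed; placement is deterministic given (config, seed).
#' @return tibble with columns `window_id`, `chrom`, `start`, `end`
#'   (0-based, half-open).
#' @export
place_genes <- function(config = scenario_config(), seed = 1L) {
  g <- config$genome
  counts <- config$genes$per_chrom
  w <- config$genes$window_bp
  stopifnot(length(counts) == g$n_chrom)
  if (any(counts * w > g$chrom_length_bp)) {
    abort("gene windows do not fit on a chromosome without overlap",
          class = "gs_layout_error")
  }
  set.seed(as.integer(seed))
  out <- lapply(seq_len(g$n_chrom), function(ch) {
    k <- counts[ch]
    if (k == 0) return(NULL)
    starts <- sample_nonoverlapping_starts(k, w, g$chrom_length_bp)
    tibble(chrom = ch, start = starts, end = starts + w)
  })
  out <- bind_rows(out)
  out$window_id <- seq_len(nrow(out))
  out[, c("window_id", "chrom", "start", "end")]
}

# k non-overlapping windows of width w in [0, L): draw sorted starts in the
# compacted space [0, L - k*w] and shift each by the widths before it.
sample_nonoverlapping_starts <- function(k, w, L) {
  free <- L - k * w
  u <- sort(as.integer(floor(runif(k, 0, free + 1))))
  u + w * (seq_len(k) - 1L)
}

#' Sample QTN sites
#'
#' Draws `n_qtn` distinct causal sites uniformly among the eligible sites —
#' by default every site inside a gene window that segregates in the pedigree
#' founders (a causal site fixed among founders would carry no variance).
#' There is no constraint on QTN per gene: windows may hold several QTN or
#' none.
#'
#' @param pop a [simulate_base()] result.
#' @param layout gene windows from [place_genes()].
#' @param n_qtn number of QTN.
#' @param seed integer seed.
#' @param scope `"genes"` (default) or `"genome"` (uniform over all
#'   founder-segregating sites, used by the near-infinitesimal scenario).
#' @return integer vector of global site indices, sorted.
#' @export
sample_qtn <- function(pop, layout, n_qtn, seed = 1L, scope = "genes") {
  eligible <- if (identical(scope, "genome")) {
    seq_len(nrow(pop$sites))
  } else {
    sites_in_windows(pop$sites, layout)
  }
  f <- founder_site_frequencies(pop, eligible)
  eligible <- eligible[f > 0 & f < 1]
  if (n_qtn == 0) return(integer(0))
  if (length(eligible) < n_qtn) {
    abort(sprintf("only %d eligible sites for %d QTN", length(eligible), n_qtn),
          class = "gs_sampling_error")
  }
  set.seed(as.integer(seed))
  sort(sample(eligible, n_qtn))
}

# global site indices falling inside any window (0-based half-open)
sites_in_windows <- function(sites, windows) {
  if (nrow(windows) == 0) return(integer(0))
  hit <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(windows))) {
    hit <- hit | (sites$chrom == windows$chrom[i] &
                  sites$pos >= windows$start[i] & sites$pos < windows$end[i])
  }
  which(hit)
}

founder_site_frequencies <- function(pop, site_idx) {
  rows <- founder_sequences(pop)
  hap_col_counts_cpp(pop$haplotypes, rows)[site_idx] / length(rows)
}

#' Sample per-QTN variances
#'
#' Additive variances from a Gamma distribution (default shape 5.4, scale
#' 0.42) and dominance variances from an exponential (default rate 10,
#' mean 0.1), independently across QTN.  Absolute magnitudes are immaterial
#' for accuracy because the residual variance is re-calibrated to the target
#' heritability.
#'
#' @param n_qtn number of QTN.
#' @param gamma_shape,gamma_scale Gamma parameters for additive variances.
#' @param exp_rate exponential rate for dominance variances.
#' @param seed integer seed.
#' @return tibble with columns `va`, `vd`.
#' @export
sample_variances <- function(n_qtn, gamma_shape = 5.4, gamma_scale = 0.42,
                             exp_rate = 10, seed = 1L) {
  stopifnot(gamma_shape > 0, gamma_scale > 0, exp_rate > 0)
  set.seed(as.integer(seed))
  tibble(va = rgamma(n_qtn, shape = gamma_shape, scale = gamma_scale),
         vd = rexp(n_qtn, rate = exp_rate))
}

#' Recover additive and dominance effects from target variances
#'
#' Inverts the classical single-locus variance decomposition
#' \eqn{V_d = [2f(1-f)d]^2} and \eqn{V_a = 2f(1-f)[a + d(1-2f)]^2}: the
#' dominance effect is \eqn{|d| = \sqrt{V_d}/(2f(1-f))} and the substitution
#' effect \eqn{\alpha = a + d(1-2f) = s_a\sqrt{V_a/(2f(1-f))}}, with the
#' signs supplied by the caller (sampled \eqn{\pm 1} with equal probability
#' upstream).
#'
#' @param va,vd non-negative target variances (recycled).
#' @param f derived-allele frequency in (0, 1).
#' @param sign_a,sign_d signs (\eqn{\pm 1}) of the substitution and dominance
#'   effects.
#' @return tibble with columns `a`, `d`, `alpha`.
#' @export
#' @examples
#' effects_from_variances(0.5, 0.25, 0.5, 1, 1)  # a = d = 1
effects_from_variances <- function(va, vd, f, sign_a = 1, sign_d = 1) {
  stopifnot(all(va >= 0), all(vd >= 0))
  if (any(f <= 0 | f >= 1)) {
    abort("allele frequency must lie strictly inside (0, 1)",
          class = "gs_argument_error")
  }
  het <- 2 * f * (1 - f)
  d <- sign_d * sqrt(vd) / het
  alpha <- sign_a * sqrt(va / het)
  tibble(a = alpha - d * (1 - 2 * f), d = d, alpha = alpha)
}

#' Calibrate the environmental variance to a target heritability
#'
#' Under the equilibrium assumption the broad-sense heritability is
#' \eqn{H^2 = \sum(V_a + V_d) / (\sum(V_a + V_d) + V_e)}, so
#' \eqn{V_e = \sum(V_a + V_d)(1 - H^2)/H^2}.
#'
#' @param va,vd per-QTN variances.
#' @param h2_target broad-sense heritability in (0, 1).
#' @export
#' @examples
#' calibrate_ve(0.6, 0.4, 0.25)  # 3
calibrate_ve <- function(va, vd, h2_target) {
  if (h2_target <= 0 || h2_target >= 1) {
    abort("heritability must lie strictly inside (0, 1)",
          class = "gs_argument_error")
  }
  vg <- sum(va) + sum(vd)
  stopifnot(vg > 0)
  vg * (1 - h2_target) / h2_target
}

#' Sample a complete trait architecture
#'
#' Wires [sample_qtn()], [sample_variances()], [effects_from_variances()]
#' and [calibrate_ve()] into a `trait_architecture` object.  Allele
#' frequencies enter the effect formulas as computed in the pedigree
#' founders.  With `config$arch$equal_effects` the near-infinitesimal
#' scenario is produced instead: QTN uniform genome-wide, equal additive
#' variances, no dominance.
#'
#' @param pop a [simulate_base()] result.
#' @param layout gene windows from [place_genes()].
#' @param config a [scenario_config()] list.
#' @param seed integer seed.
#' @return `trait_architecture`: list with `qtn` tibble (site, chrom, pos,
#'   f, va, vd, a, d, alpha), `mu`, `ve`, `h2`.
#' @export
sample_architecture <- function(pop, layout, config = scenario_config(),
                                seed = 1L) {
  a <- config$arch
  scope <- if (isTRUE(a$equal_effects)) "genome" else a$qtn_scope
  qtn_sites <- sample_qtn(pop, layout, a$n_qtn, seed = seed, scope = scope)
  f <- founder_site_frequencies(pop, qtn_sites)

  set.seed(stage_seed(seed, 1L, "effects"))
  if (isTRUE(a$equal_effects)) {
    vars <- tibble(va = rep(1, a$n_qtn), vd = rep(0, a$n_qtn))
  } else {
    vars <- sample_variances(a$n_qtn, a$gamma_shape, a$gamma_scale,
                             a$exp_rate, seed = stage_seed(seed, 2L, "vars"))
  }
  set.seed(stage_seed(seed, 3L, "signs"))
  sign_a <- sample(c(-1, 1), a$n_qtn, replace = TRUE)
  sign_d <- sample(c(-1, 1), a$n_qtn, replace = TRUE)
  eff <- effects_from_variances(vars$va, vars$vd, f, sign_a, sign_d)

  qtn <- tibble(site = qtn_sites,
                chrom = pop$sites$chrom[qtn_sites],
                pos = pop$sites$pos[qtn_sites],
                f = f, va = vars$va, vd = vars$vd,
                a = eff$a, d = eff$d, alpha = eff$alpha)
  structure(
    list(qtn = qtn, mu = a$mu, ve = calibrate_ve(vars$va, vars$vd, a$h2),
         h2 = a$h2, n_qtn = a$n_qtn),
    class = "trait_architecture"
  )
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat("<trait_architecture> ", x$n_qtn, " QTN, H2 = ", x$h2,
      ", Ve = ", signif(x$ve, 4), "\n", sep = "")
  print(x$qtn, n = 5)
  invisible(x)
}

#' Genetic values from QTN genotypes
#'
#' Total genotypic value \eqn{g_i = \sum_q \gamma_{iq} a_q + \delta_{iq} d_q}
#' (dosage \eqn{\gamma \in \{-1,0,1\}}, heterozygote indicator \eqn{\delta})
#' and breeding value \eqn{bv_i = \sum_q \gamma_{iq}\alpha_q} with
#' substitution effects at founder frequencies.
#'
#' @param qtn_genotypes matrix (individuals x QTN) of dosages -1/0/1.
#' @param arch a [sample_architecture()] result.
#' @return tibble with columns `g_total`, `breeding_value`.
#' @export
genetic_values <- function(qtn_genotypes, arch) {
  q <- arch$qtn
  if (ncol(qtn_genotypes) != nrow(q)) {
    abort("genotype matrix width must equal the number of QTN",
          class = "gs_shape_error")
  }
  gam <- qtn_genotypes
  het <- (gam == 0) + 0
  tibble(g_total = drop(gam %*% q$a + het %*% q$d),
         breeding_value = drop(gam %*% q$alpha))
}

#' Dump a trait architecture as TSV
#' @param arch a [sample_architecture()] result.
#' @param file output path.
#' @export
write_architecture <- function(arch, file) {
  readr::write_tsv(arch$qtn, file)
  invisible(file)
}
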