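#' Build the breeding pedigree
#'
#' Default design: generation 0 holds the pedigree founders (unknown
#' parents); in each of the following generations a random set of sires and
#' dams is drawn from the previous generation, every dam produces a fixed
#' number of offspring, and each dam's offspring are sired by at least two
#' distinct sires (non-hierarchical mating, as in dairy cattle pedigrees).
#' At full scale this yields 1020 founders + 7 x 500 = 4520 individuals.
#' Founders beyond those used as parents stay in the pedigree (phenotyped,
#' possibly childless).
#'
#' @param config a [scenario_config()] list.
#' @param seed integer seed.
#' @return tibble with columns `id`, `sire`, `dam` (0 = unknown),
#'   `generation`, `sex` ("M"/"F").
#' @export
build_pedigree <- function(config = scenario_config(), seed = 1L) {
  p <- config$pedigree
  n_f <- config$genome$n_founders
  stopifnot(p$n_sires >= 2, p$n_dams >= 1, p$offspring_per_dam >= 2)
  set.seed(as.integer(seed))

  founder_sex <- sample(rep(c("M", "F"), length.out = n_f))
  ped <- tibble(id = seq_len(n_f), sire = 0L, dam = 0L, generation = 0L,
                sex = founder_sex)
  next_id <- n_f + 1L
  per_gen <- p$n_dams * p$offspring_per_dam

  for (g in seq_len(p$n_generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    males <- prev$id[prev$sex == "M"]
    females <- prev$id[prev$sex == "F"]
    if (length(males) < p$n_sires || length(females) < p$n_dams) {
      abort("not enough candidates of one sex in the previous generation",
            class = "gs_design_error")
    }
    sires <- sample(males, p$n_sires)
    dams <- sample(females, p$n_dams)
    off_sire <- integer(per_gen)
    off_dam <- integer(per_gen)
    k <- 0L
    for (d in dams) {
      s <- sample(sires, p$offspring_per_dam, replace = TRUE)
      s[1:2] <- sample(sires, 2L)  # >= 2 distinct sires per dam
      off_sire[k + seq_len(p$offspring_per_dam)] <- s
      off_dam[k + seq_len(p$offspring_per_dam)] <- d
      k <- k + p$offspring_per_dam
    }
    ped <- bind_rows(ped, tibble(
      id = next_id - 1L + seq_len(per_gen),
      sire = off_sire, dam = off_dam, generation = g,
      sex = rep_len(c("M", "F"), per_gen)
    ))
    next_id <- next_id + per_gen
  }
  ped
}

# Crossover plan for one meiosis: per chromosome a Poisson number of
# crossovers (mean recomb_rate * L, capped at max_crossovers), uniform
# positions, and a random starting haplotype.  RNG consumption depends only
# on the pedigree walk, never on which sites are tracked.
crossover_plan <- function(n_chrom, chrom_length_bp, recomb_rate,
                           max_crossovers) {
  lapply(seq_len(n_chrom), function(ch) {
    nx <- min(rpois(1L, recomb_rate * chrom_length_bp), max_crossovers)
    start <- rbinom(1L, 1L, 0.5)
    xpos <- if (nx > 0) sort(runif(nx, 0, chrom_length_bp)) else numeric(0)
    list(start = start, xpos = xpos)
  })
}

#' Simulate one meiosis
#'
#' Returns a gamete haplotype built from two parental haplotypes: per
#' chromosome, a Poisson(rate x length) number of crossovers capped at
#' `max_crossovers` (default 4), uniform crossover positions, no
#' interference, and a fair choice of starting haplotype.
#'
#' @param parent_haplotypes matrix (sites x 2) of parental alleles.
#' @param sites tibble of `chrom`, `pos` for the rows.
#' @param chrom_length_bp chromosome length.
#' @param recomb_rate per-bp recombination rate (1e-8 = 1 cM/Mb).
#' @param max_crossovers crossover cap per chromosome per meiosis.
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @return integer vector of gamete alleles.
#' @export
meiosis <- function(parent_haplotypes, sites, chrom_length_bp,
                    recomb_rate = 1e-8, max_crossovers = 4L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_chrom <- max(sites$chrom)
  plan <- crossover_plan(n_chrom, chrom_length_bp, recomb_rate,
                         max_crossovers)
  g <- integer(nrow(sites))
  for (ch in seq_len(n_chrom)) {
    idx <- which(sites$chrom == ch)
    if (!length(idx)) next
    g[idx] <- transmit(parent_haplotypes[idx, 1], parent_haplotypes[idx, 2],
                       sites$pos[idx], plan[[ch]])
  }
  g
}

transmit <- function(h1, h2, pos, plan) {
  if (!length(plan$xpos)) {
    if (plan$start == 0L) h1 else h2
  } else {
    src <- (plan$start + findInterval(pos, plan$xpos)) %% 2L
    ifelse(src == 0L, h1, h2)
  }
}

#' Gene-drop founder haplotypes through a pedigree
#'
#' Founders receive their base-population haplotypes verbatim (founder i of
#' the pedigree is diploid i of the `founder` role); every non-founder
#' receives one paternal and one maternal gamete via [meiosis()] rules,
#' without selection.  `tracked_sites` restricts storage to a site subset;
#' alleles at tracked sites are identical to an unrestricted run under the
#' same seed.
#'
#' @param pop a [simulate_base()] result.
#' @param ped a [build_pedigree()] tibble.
#' @param seed integer seed.
#' @param tracked_sites global site indices to carry (default: all sites).
#' @return `population_haplotypes`: list with `haplotypes` (integer matrix,
#'   tracked sites x 2N, columns 2i-1/2i = paternal/maternal haplotype of
#'   individual i), `sites` tibble (site, chrom, pos), and the pedigree.
#' @export
gene_drop <- function(pop, ped, seed = 1L, tracked_sites = NULL) {
  g <- pop$config$genome
  founder_ids <- ped$id[ped$generation == 0L]
  founder_samples <- pop$samples$sample_id[pop$samples$role == "founder"]
  if (length(founder_ids) != length(founder_samples)) {
    abort("pedigree founder count does not match base-population founders",
          class = "gs_integrity_error")
  }
  if (is.null(tracked_sites)) tracked_sites <- seq_len(nrow(pop$sites))
  tracked_sites <- sort(unique(as.integer(tracked_sites)))
  sites <- tibble(site = tracked_sites,
                  chrom = pop$sites$chrom[tracked_sites],
                  pos = pop$sites$pos[tracked_sites])

  n_ind <- nrow(ped)
  H <- matrix(0L, nrow = length(tracked_sites), ncol = 2L * n_ind)
  fh <- hap_extract_cpp(pop$haplotypes,
                        as.integer(sequence_rows(founder_samples)),
                        tracked_sites)
  H[, sequence_rows(founder_ids)] <- t(fh)

  chrom_idx <- split(seq_len(nrow(sites)), sites$chrom)
  chrom_pos <- split(sites$pos, sites$chrom)
  present_chrom <- as.integer(names(chrom_idx))

  set.seed(as.integer(seed))
  nonf <- which(ped$generation > 0L)
  xrate <- g$meiosis_recomb_rate %||% g$recomb_rate
  for (i in nonf) {
    for (parent in c(ped$sire[i], ped$dam[i])) {
      plan <- crossover_plan(g$n_chrom, g$chrom_length_bp, xrate,
                             g$max_crossovers)
      col_out <- if (parent == ped$sire[i]) 2L * ped$id[i] - 1L
                 else 2L * ped$id[i]
      c1 <- 2L * parent - 1L
      for (k in seq_along(present_chrom)) {
        idx <- chrom_idx[[k]]
        H[idx, col_out] <- transmit(H[idx, c1], H[idx, c1 + 1L],
                                    chrom_pos[[k]],
                                    plan[[present_chrom[k]]])
      }
    }
  }
  structure(list(haplotypes = H, sites = sites, pedigree = ped,
                 n_ind = n_ind, seed = as.integer(seed)),
            class = "population_haplotypes")
}

#' @export
print.population_haplotypes <- function(x, ...) {
  cat("<population_haplotypes> ", x$n_ind, " individuals, ",
      nrow(x$sites), " tracked sites\n", sep = "")
  invisible(x)
}

# dosage (-1/0/1) for given pedigree individuals at tracked-row indices
dosage_from_drop <- function(haps, rows, individuals) {
  c1 <- 2L * individuals - 1L
  m <- haps$haplotypes[rows, c1, drop = FALSE] +
       haps$haplotypes[rows, c1 + 1L, drop = FALSE] - 1L
  t(m)
}

#' Derived-allele frequencies in the pedigree founders
#'
#' @param haps a [gene_drop()] result.
#' @param ped the pedigree (defaults to the one inside `haps`).
#' @return numeric vector, one frequency per tracked site.
#' @export
founder_frequencies <- function(haps, ped = haps$pedigree) {
  founders <- ped$id[ped$generation == 0L]
  if (!length(founders)) abort("no founders present", class = "gs_integrity_error")
  cols <- sequence_rows(founders)
  rowSums(haps$haplotypes[, cols, drop = FALSE]) / length(cols)
}

#' Simulate phenotypes
#'
#' \eqn{y_i = \mu + g_i + e_i} with \eqn{e_i \sim N(0, V_e)}, for every
#' pedigree individual (molecular and phenotypic data are available for the
#' whole pedigree; masking happens at evaluation time).
#'
#' @param haps a [gene_drop()] result; QTN sites must be tracked.
#' @param arch a [sample_architecture()] result.
#' @param seed integer seed for the residuals.
#' @return tibble with `id`, `generation`, `y`, `g_total`,
#'   `breeding_value`, `e`.
#' @export
simulate_phenotypes <- function(haps, arch, seed = 1L) {
  rows <- match(arch$qtn$site, haps$sites$site)
  if (anyNA(rows)) {
    abort("QTN sites are not tracked in the gene-drop result",
          class = "gs_integrity_error")
  }
  ped <- haps$pedigree
  gam <- dosage_from_drop(haps, rows, ped$id)
  gv <- genetic_values(gam, arch)
  set.seed(as.integer(seed))
  e <- rnorm(nrow(ped), 0, sqrt(arch$ve))
  tibble(id = ped$id, generation = ped$generation,
         y = arch$mu + gv$g_total + e,
         g_total = gv$g_total, breeding_value = gv$breeding_value, e = e)
}

#' Write pedigree / phenotypes as TSV
#' @param x pedigree or phenotype tibble.
#' @param file output path.
#' @export
write_pedigree <- function(x, file) {
  readr::write_tsv(x, file)
  invisible(file)
}
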