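#' Simulate the founder (base) population
#'
#' Generates phased founder haplotypes for each chromosome independently under
#' a sequential Markov coalescent with piecewise-constant demography, then
#' assigns diploids to disjoint roles: `founder` individuals that seed the
#' breeding pedigree, a `discovery` panel used only for SNP-array
#' ascertainment, and (optionally) a `breed2` sample from a second population
#' that split from the first `split_time` (in units of 2\eqn{N_0} generations)
#' ago.  The recent effective size \eqn{N_0} is calibrated analytically so
#' that expected nucleotide diversity matches `config$genome$target_pi`.
#'
#' Sites are stored 0-based within each chromosome; every stored site
#' segregates in the full simulated sample, with allele 0 ancestral and 1
#' derived.
#'
#' @param config a [scenario_config()] list.
#' @param n_founders,n_discovery optional overrides of the config values.
#' @param seed integer seed; the simulation is bit-reproducible given
#'   (seed, config).
#' @return an object of class `base_population`: a list with `haplotypes`
#'   (raw 0/1 matrix, rows = sequences, columns = sites), `sites` (tibble of
#'   chrom and 0-based pos), `samples` (tibble of sample_id, role), realized
#'   diversity and the calibrated demographic parameters.
#' @export
#' @examples
#' cfg <- scenario_config(scale = 0.02)
#' pop <- simulate_base(cfg, seed = 42)
#' pop$realized_pi
simulate_base <- function(config = scenario_config(), n_founders = NULL,
                          n_discovery = NULL, seed = 1L) {
  g <- config$genome
  if (!is.null(n_founders)) g$n_founders <- as.integer(n_founders)
  if (!is.null(n_discovery)) g$n_discovery <- as.integer(n_discovery)
  stopifnot(g$n_founders >= 1, g$n_discovery >= 0, g$n_breed2 >= 0)

  n_dip <- g$n_founders + g$n_discovery + g$n_breed2
  n_seq <- 2L * n_dip
  if (n_seq < 2) abort("need at least one diploid", class = "gs_size_error")

  n0 <- calibrate_n0(g)
  theta_pb <- 2 * n0 * g$mutation_rate
  rho_pb <- 2 * n0 * g$recomb_rate

  pop_of_leaf <- rep(0L, n_seq)
  if (g$n_breed2 > 0) {
    breed2_dip <- (g$n_founders + g$n_discovery + 1):n_dip
    pop_of_leaf[c(2L * breed2_dip - 1L, 2L * breed2_dip)] <- 1L
  }
  split_time <- if (g$n_breed2 > 0) g$split_time else Inf

  set.seed(as.integer(seed))
  chroms <- vector("list", g$n_chrom)
  for (ch in seq_len(g$n_chrom)) {
    sim <- smc_chromosome_cpp(n_seq, as.double(g$chrom_length_bp), theta_pb,
                              rho_pb, g$demography$start, g$demography$size,
                              pop_of_leaf, split_time)
    pos <- integerize_positions(sim$positions, g$chrom_length_bp)
    h <- if (length(pos$keep) == ncol(sim$haplotypes)) sim$haplotypes
         else sim$haplotypes[, pos$keep, drop = FALSE]
    chroms[[ch]] <- list(pos = pos$pos, haplotypes = h)
  }

  haplotypes <- do.call(cbind, lapply(chroms, `[[`, "haplotypes"))
  sites <- tibble(
    chrom = rep.int(seq_len(g$n_chrom),
                    vapply(chroms, function(x) length(x$pos), 1L)),
    pos = unlist(lapply(chroms, `[[`, "pos"), use.names = FALSE)
  )

  roles <- c(rep("founder", g$n_founders), rep("discovery", g$n_discovery),
             rep("breed2", g$n_breed2))
  samples <- tibble(sample_id = seq_len(n_dip), role = roles)

  pop <- structure(
    list(haplotypes = haplotypes, sites = sites,
         n_chrom = g$n_chrom, chrom_length_bp = g$chrom_length_bp,
         samples = samples, n0 = n0, theta_pb = theta_pb, rho_pb = rho_pb,
         config = config, seed = as.integer(seed)),
    class = "base_population"
  )
  pop$realized_pi <- nucleotide_diversity(pop, breed1_sequences(pop))
  pop
}

# Floor continuous positions to bp, enforce strict increase, drop overflow.
integerize_positions <- function(pos, chrom_length_bp) {
  p <- as.integer(floor(pos))
  if (length(p) > 1) {
    for (i in 2:length(p)) if (p[i] <= p[i - 1]) p[i] <- p[i - 1] + 1L
  }
  keep <- p < chrom_length_bp
  list(pos = p[keep], keep = which(keep))
}

#' @export
print.base_population <- function(x, ...) {
  cat("<base_population> ", nrow(x$haplotypes), " sequences, ",
      ncol(x$haplotypes), " segregating sites on ", x$n_chrom,
      " chromosomes of ", x$chrom_length_bp, " bp\n", sep = "")
  cat("  realized pi = ", signif(x$realized_pi, 4),
      " (target ", x$config$genome$target_pi, ")\n", sep = "")
  print(dplyr::count(x$samples, .data$role))
  invisible(x)
}

# sequence row indices (two per diploid) for given sample ids
sequence_rows <- function(sample_ids) {
  as.integer(rbind(2L * sample_ids - 1L, 2L * sample_ids))
}

founder_sequences <- function(pop) {
  sequence_rows(pop$samples$sample_id[pop$samples$role == "founder"])
}

discovery_sequences <- function(pop) {
  sequence_rows(pop$samples$sample_id[pop$samples$role == "discovery"])
}

breed1_sequences <- function(pop) {
  sequence_rows(pop$samples$sample_id[pop$samples$role != "breed2"])
}

#' Nucleotide diversity
#'
#' Average pairwise difference count per site over a set of sequences, with
#' monomorphic sites included in the denominator (total genome length).
#'
#' @param pop a [simulate_base()] result.
#' @param sequences sequence (haplotype) row indices; defaults to all
#'   first-breed sequences.
#' @return diversity per site (dimensionless).
#' @export
nucleotide_diversity <- function(pop, sequences = NULL) {
  if (is.null(sequences)) sequences <- breed1_sequences(pop)
  k <- length(sequences)
  if (k < 2) abort("need at least two sequences", class = "gs_argument_error")
  genome_bp <- as.double(pop$n_chrom) * pop$chrom_length_bp
  if (ncol(pop$haplotypes) == 0) return(0)
  cnt <- hap_col_counts_cpp(pop$haplotypes, as.integer(sequences))
  sum(2 * cnt * (k - cnt) / (k * (k - 1))) / genome_bp
}

#' Site frequency spectrum
#'
#' Unfolded (derived-allele count classes 1..k-1) or folded (minor-allele
#' count classes 1..floor(k/2)) spectrum over a sequence subset.  Class
#' counts sum to the number of sites segregating within the subset.
#'
#' @inheritParams nucleotide_diversity
#' @param folded fold to minor-allele counts?
#' @return tibble with columns `count` (allele count class) and `n_sites`.
#' @export
site_frequency_spectrum <- function(pop, sequences = NULL, folded = FALSE) {
  if (is.null(sequences)) sequences <- breed1_sequences(pop)
  k <- length(sequences)
  if (k < 2) abort("need at least two sequences", class = "gs_argument_error")
  cnt <- hap_col_counts_cpp(pop$haplotypes, as.integer(sequences))
  cnt <- cnt[cnt > 0 & cnt < k]
  if (folded) {
    cnt <- pmin(cnt, k - cnt)
    classes <- seq_len(floor(k / 2))
  } else {
    classes <- seq_len(k - 1)
  }
  tibble(count = classes,
         n_sites = as.integer(tabulate(cnt, nbins = max(classes))[classes]))
}

#' Hudson's Fst between two diploid sample sets
#'
#' Ratio-of-averages Hudson estimator: 1 - mean within-population diversity
#' over mean between-population diversity, across segregating sites.
#'
#' @param pop a [simulate_base()] result.
#' @param samples1,samples2 diploid sample ids of the two groups.
#' @export
fst_hudson <- function(pop, samples1, samples2) {
  r1 <- sequence_rows(samples1)
  r2 <- sequence_rows(samples2)
  n1 <- length(r1); n2 <- length(r2)
  c1 <- hap_col_counts_cpp(pop$haplotypes, as.integer(r1))
  c2 <- hap_col_counts_cpp(pop$haplotypes, as.integer(r2))
  p1 <- c1 / n1; p2 <- c2 / n2
  seg <- (c1 + c2) > 0 & (c1 + c2) < (n1 + n2)
  hw <- p1 * (1 - p1) * n1 / (n1 - 1) + p2 * (1 - p2) * n2 / (n2 - 1)
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  1 - sum(hw[seg]) / sum(hb[seg])
}

#' Export phased haplotypes as VCF
#'
#' Writes a plain-text VCFv4.2 file with chromosomes "chr1".."chrK", phased
#' genotypes "0|1", and one column per diploid, restricted to an optional
#' panel.  Works on a [simulate_base()] population (columns are the
#' coalescent diploids) or a [gene_drop()] result (columns are pedigree
#' individuals).  Positions are written 1-based per VCF convention.
#'
#' @param x a `base_population` or `population_haplotypes` object.
#' @param file output path (.vcf).
#' @param panel optional [marker_panel]; default all (tracked) sites.
#' @param samples diploid/individual ids to export; default all.
#' @return `file`, invisibly.
#' @export
write_vcf <- function(x, file, panel = NULL, samples = NULL) {
  if (inherits(x, "population_haplotypes")) {
    if (is.null(samples)) samples <- x$pedigree$id
    rowsel <- if (is.null(panel)) seq_len(nrow(x$sites))
              else match(panel$sites, x$sites$site)
    if (anyNA(rowsel)) {
      abort("panel contains sites not tracked in the gene-drop result",
            class = "gs_integrity_error")
    }
    h <- t(x$haplotypes[rowsel, sequence_rows(samples), drop = FALSE])
    st <- x$sites[rowsel, c("chrom", "pos")]
    ids <- x$sites$site[rowsel]
    n_chrom <- max(st$chrom)
    chrom_len <- max(st$pos) + 1L
  } else {
    if (is.null(samples)) samples <- x$samples$sample_id
    site_idx <- if (is.null(panel)) seq_len(nrow(x$sites)) else panel$sites
    h <- hap_extract_cpp(x$haplotypes, as.integer(sequence_rows(samples)),
                         as.integer(site_idx))
    st <- x$sites[site_idx, ]
    ids <- site_idx
    n_chrom <- x$n_chrom
    chrom_len <- x$chrom_length_bp
  }
  gt <- matrix(paste0(h[seq(1, nrow(h), 2), , drop = FALSE],
                      "|",
                      h[seq(2, nrow(h), 2), , drop = FALSE]),
               nrow = length(samples))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=chr", seq_len(n_chrom), ",length=", chrom_len, ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("ind", samples)), collapse = "\t")
  )
  body <- paste(paste0("chr", st$chrom), st$pos + 1L,
                paste0("snp", ids), "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  readr::write_lines(c(header, body), file)
  invisible(file)
}

#' Write sample roles as TSV
#' @param pop a [simulate_base()] result.
#' @param file output path.
#' @export
write_roles <- function(pop, file) {
  readr::write_tsv(pop$samples, file)
  invisible(file)
}
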