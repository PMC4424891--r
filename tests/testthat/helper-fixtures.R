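# Shared fixtures: tiny configurations for fast unit tests, plus a memoised
# small population reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) assign(name, fn(), envir = .fixtures)
  .fixtures[[name]]
}

# Small constant-size genome configuration (fast coalescent runs).
tiny_config <- function(n_founders = 15L, n_discovery = 5L, n_chrom = 2L,
                        chrom_bp = 200000L, constant_size = TRUE,
                        n_qtn = 6L) {
  cfg <- scenario_config(seed = 1L)
  cfg$genome$n_chrom <- n_chrom
  cfg$genome$chrom_length_bp <- as.integer(chrom_bp)
  cfg$genome$n_founders <- as.integer(n_founders)
  cfg$genome$n_discovery <- as.integer(n_discovery)
  if (constant_size) cfg$genome$demography <- list(start = 0, size = 1)
  cfg$genes$per_chrom <- rep(2L, n_chrom)
  cfg$arch$n_qtn <- as.integer(n_qtn)
  cfg$pedigree$n_sires <- 3L
  cfg$pedigree$n_dams <- 5L
  cfg$pedigree$offspring_per_dam <- 4L
  cfg$pedigree$n_generations <- 3L
  cfg$panels$medium_array$target_size <- 50L
  cfg$panels$hd_array$target_size <- 100L
  cfg$panels$rad$n_windows <- 4L
  cfg$panels$genes_half$n_windows <- 2L
  cfg$panels$genes_half_noise$n_windows <- 2L
  cfg$panels$genes_half_noise$noise_windows <- 2L
  cfg
}

# A base population with hand-crafted haplotypes, for exact-value tests.
synthetic_pop <- function(haps01, chrom, pos, chrom_length_bp = 1000L,
                          n_chrom = max(chrom), roles = NULL) {
  n_dip <- nrow(haps01) / 2
  if (is.null(roles)) roles <- rep("founder", n_dip)
  h <- matrix(as.raw(haps01), nrow = nrow(haps01))
  structure(
    list(haplotypes = h,
         sites = tibble::tibble(chrom = chrom, pos = pos),
         n_chrom = n_chrom, chrom_length_bp = chrom_length_bp,
         samples = tibble::tibble(sample_id = seq_len(n_dip), role = roles),
         n0 = 1, theta_pb = 0, rho_pb = 0,
         config = scenario_config(), seed = 1L, realized_pi = NA_real_),
    class = "base_population"
  )
}

tiny_pop <- function() {
  fixture("tiny_pop", function() simulate_base(tiny_config(), seed = 99L))
}
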