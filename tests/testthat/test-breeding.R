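# Pedigree design, meiosis, gene-dropping and phenotypes.

test_that("default pedigree matches the reference design", {
  ped <- build_pedigree(scenario_config(), seed = 2L)
  expect_identical(nrow(ped), 4520L)
  expect_identical(max(ped$generation), 7L)
  expect_identical(sum(ped$generation == 0L), 1020L)
  expect_true(all(table(ped$generation[ped$generation > 0]) == 500L))
  # parents belong to the immediately preceding generation
  gen_of <- setNames(ped$generation, ped$id)
  nf <- ped[ped$generation > 0L, ]
  expect_true(all(gen_of[as.character(nf$sire)] == nf$generation - 1L))
  expect_true(all(gen_of[as.character(nf$dam)] == nf$generation - 1L))
  # sires male, dams female, and every dam mated to >= 2 distinct sires
  sex_of <- setNames(ped$sex, ped$id)
  expect_true(all(sex_of[as.character(nf$sire)] == "M"))
  expect_true(all(sex_of[as.character(nf$dam)] == "F"))
  n_sires_per_dam <- tapply(nf$sire, nf$dam, function(s) length(unique(s)))
  expect_true(all(n_sires_per_dam >= 2L))
  expect_identical(length(unique(nf$sire[nf$generation == 3L])), 20L)
})

test_that("crossover counts are Poisson with the configured mean, capped at 4", {
  set.seed(10)
  counts <- vapply(1:20000, function(i) {
    length(gselsim:::crossover_plan(1L, 3e6, 1e-8, 4L)[[1]]$xpos)
  }, 0L)
  expect_lte(max(counts), 4L)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 0.03), 3 * se)
  # with a Morgan-scale map the cap binds
  set.seed(11)
  capped <- vapply(1:5000, function(i) {
    length(gselsim:::crossover_plan(1L, 3e6, 1e-6, 4L)[[1]]$xpos)
  }, 0L)
  expect_lte(max(capped), 4L)
  expect_gt(mean(capped == 4L), 0.1)
})

test_that("gametes are mosaics of the two parental haplotypes", {
  sites <- tibble::tibble(chrom = rep(1:2, each = 50),
                          pos = rep(seq(0, 196000, by = 4000), 2))
  h <- cbind(rep(0L, 100), rep(1L, 100))
  g <- meiosis(h, sites, 200000L, recomb_rate = 1e-5, seed = 3L)
  expect_true(all(g %in% 0:1))
  # distinguishable parents: every allele identifies its source
  h2 <- cbind(sample(0:1, 100, TRUE), sample(0:1, 100, TRUE))
  g2 <- meiosis(h2, sites, 200000L, recomb_rate = 1e-5, seed = 4L)
  expect_true(all(g2 == h2[, 1] | g2 == h2[, 2]))
  # zero recombination copies one parental chromosome verbatim
  g3 <- meiosis(h2, sites, 200000L, recomb_rate = 0, seed = 5L)
  for (ch in 1:2) {
    idx <- which(sites$chrom == ch)
    expect_true(identical(g3[idx], h2[idx, 1]) ||
                identical(g3[idx], h2[idx, 2]))
  }
})

test_that("gene-dropping is Mendelian-consistent and assigns founders verbatim", {
  pop <- tiny_pop()
  cfg <- tiny_config()
  ped <- build_pedigree(cfg, seed = 6L)
  haps <- gene_drop(pop, ped, seed = 7L)
  H <- haps$haplotypes
  founders <- ped$id[ped$generation == 0L]
  fh <- t(gselsim:::hap_extract_cpp(pop$haplotypes,
                                    gselsim:::sequence_rows(founders),
                                    seq_len(nrow(pop$sites))))
  expect_identical(H[, gselsim:::sequence_rows(founders)], fh)
  for (i in which(ped$generation > 0L)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    pat <- H[, 2L * i - 1L]; mat <- H[, 2L * i]
    expect_true(all(pat == H[, 2L * s - 1L] | pat == H[, 2L * s]))
    expect_true(all(mat == H[, 2L * d - 1L] | mat == H[, 2L * d]))
  }
})

test_that("tracked-site restriction reproduces the full run at those sites", {
  pop <- tiny_pop()
  cfg <- tiny_config()
  ped <- build_pedigree(cfg, seed = 6L)
  full <- gene_drop(pop, ped, seed = 9L)
  sub_sites <- sort(sample(nrow(pop$sites), 11L))
  sub <- gene_drop(pop, ped, seed = 9L, tracked_sites = sub_sites)
  expect_identical(sub$haplotypes,
                   full$haplotypes[match(sub_sites, full$sites$site), ])
  # and the same seed gives identical pedigrees / drops
  expect_identical(full$haplotypes,
                   gene_drop(pop, ped, seed = 9L)$haplotypes)
})

test_that("allele frequencies drift without direction and heterozygosity declines", {
  cfg <- tiny_config(n_founders = 12L, n_discovery = 0L, n_chrom = 1L,
                     chrom_bp = 30000L)
  cfg$pedigree$n_sires <- 2L
  cfg$pedigree$n_dams <- 3L
  mean_diffs <- numeric(50)
  het_drop <- numeric(50)
  for (r in 1:50) {
    pop <- simulate_base(cfg, seed = 40L + r)
    ped <- build_pedigree(cfg, seed = 80L + r)
    haps <- gene_drop(pop, ped, seed = 120L + r)
    f0 <- founder_frequencies(haps)
    g7 <- ped$id[ped$generation == max(ped$generation)]
    cols <- gselsim:::sequence_rows(g7)
    f7 <- rowSums(haps$haplotypes[, cols, drop = FALSE]) / length(cols)
    mean_diffs[r] <- mean(f7 - f0)
    het_drop[r] <- mean(2 * f0 * (1 - f0)) - mean(2 * f7 * (1 - f7))
  }
  # no selection: drift has no direction (sign test)
  n_pos <- sum(mean_diffs > 0)
  expect_gt(n_pos, qbinom(0.0025, 50, 0.5))
  expect_lt(n_pos, qbinom(0.9975, 50, 0.5))
  # closed population: expected heterozygosity decays
  expect_gt(mean(het_drop), 0)
})

test_that("founder frequencies equal brute-force counts on a toy", {
  h <- rbind(c(1L, 0L), c(1L, 0L), c(0L, 1L), c(0L, 0L), c(1L, 1L),
             c(0L, 0L), c(1L, 0L), c(0L, 0L), c(1L, 1L), c(1L, 0L))
  pop <- synthetic_pop(h, chrom = c(1L, 1L), pos = c(5L, 9L),
                       chrom_length_bp = 100L, n_chrom = 1L)
  cfg <- tiny_config(n_founders = 5L, n_discovery = 0L, n_chrom = 1L)
  ped <- tibble::tibble(id = 1:5, sire = 0L, dam = 0L, generation = 0L,
                        sex = c("M", "F", "M", "F", "M"))
  haps <- gene_drop(pop, ped, seed = 1L)
  expect_equal(founder_frequencies(haps),
               c(sum(h[, 1]) / 10, sum(h[, 2]) / 10))
})

test_that("phenotypes follow y = mu + g + e with calibrated heritability", {
  pop <- tiny_pop()
  cfg <- tiny_config(n_qtn = 10L)
  lay <- place_genes(cfg, seed = 2L)
  arch <- sample_architecture(pop, lay, cfg, seed = 3L)
  ped <- build_pedigree(cfg, seed = 4L)
  haps <- gene_drop(pop, ped, seed = 5L, tracked_sites = arch$qtn$site)
  # ve = 0: phenotype minus mean is exactly the genotypic value
  arch0 <- arch; arch0$ve <- 1e-300; arch0$mu <- 2.5
  ph0 <- simulate_phenotypes(haps, arch0, seed = 6L)
  expect_equal(ph0$y - 2.5, ph0$g_total, tolerance = 1e-8)
  # shifting mu shifts every phenotype by the same constant
  arch1 <- arch; arch1$mu <- 0
  arch2 <- arch; arch2$mu <- 10
  y1 <- simulate_phenotypes(haps, arch1, seed = 7L)$y
  y2 <- simulate_phenotypes(haps, arch2, seed = 7L)$y
  expect_equal(y2 - y1, rep(10, length(y1)))
  # exact identity of the stored decomposition
  ph <- simulate_phenotypes(haps, arch, seed = 8L)
  expect_equal(ph$y, arch$mu + ph$g_total + ph$e)
})

test_that("realized broad-sense heritability is near its target across replicates", {
  cfg <- tiny_config(n_founders = 30L, n_qtn = 12L)
  h2 <- vapply(1:12, function(r) {
    pop <- simulate_base(cfg, seed = 500L + r)
    lay <- place_genes(cfg, seed = r)
    arch <- sample_architecture(pop, lay, cfg, seed = r)
    ped <- build_pedigree(cfg, seed = r)
    haps <- gene_drop(pop, ped, seed = r, tracked_sites = arch$qtn$site)
    ph <- simulate_phenotypes(haps, arch, seed = r)
    var(ph$g_total) / var(ph$y)
  }, 0)
  expect_lt(abs(mean(h2) - 0.25), 0.08)
})
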