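# Gene windows, QTN sampling, effect-size algebra, heritability calibration.

test_that("gene windows respect counts, bounds and non-overlap", {
  cfg <- scenario_config(seed = 1)  # full-scale layout is cheap
  lay <- place_genes(cfg, seed = 3L)
  expect_identical(nrow(lay), 65L)
  expect_identical(as.integer(tabulate(lay$chrom, 10)),
                   c(20L, 10L, 10L, 10L, 5L, 5L, 5L, 0L, 0L, 0L))
  expect_identical(sum(lay$end - lay$start), 650000L)
  expect_true(all(lay$start >= 0 & lay$end <= cfg$genome$chrom_length_bp))
  by_chrom <- split(lay, lay$chrom)
  for (b in by_chrom) {
    b <- b[order(b$start), ]
    if (nrow(b) > 1) expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
  # seeded: same seed reproduces, different seed moves windows
  expect_identical(lay, place_genes(cfg, seed = 3L))
  lay2 <- place_genes(cfg, seed = 4L)
  expect_false(identical(lay$start, lay2$start))
  expect_identical(tabulate(lay2$chrom, 10), tabulate(lay$chrom, 10))
})

test_that("oversized window requests fail cleanly", {
  cfg <- tiny_config()
  cfg$genes$per_chrom <- c(30L, 0L)  # 30 x 10 kb > 200 kb
  expect_error(place_genes(cfg), class = "gs_layout_error")
})

test_that("QTN sampling is restricted to gene windows and uniform over eligible sites", {
  pop <- tiny_pop()
  cfg <- tiny_config()
  lay <- place_genes(cfg, seed = 2L)
  expect_identical(sample_qtn(pop, lay, 0L), integer(0))
  in_win <- gselsim:::sites_in_windows(pop$sites, lay)
  q <- sample_qtn(pop, lay, 8L, seed = 5L)
  expect_identical(length(q), 8L)
  expect_true(all(q %in% in_win))
  expect_error(sample_qtn(pop, lay, length(in_win) + 1000L),
               class = "gs_sampling_error")
})

test_that("QTN sampling frequencies are uniform when windows span the genome", {
  pop <- tiny_pop()
  all_win <- tibble::tibble(chrom = 1:2, start = 0L,
                            end = pop$chrom_length_bp)
  eligible <- gselsim:::sites_in_windows(pop$sites, all_win)
  f <- gselsim:::founder_site_frequencies(pop, eligible)
  eligible <- eligible[f > 0 & f < 1]
  draws <- unlist(lapply(1:2500, function(i) {
    sample_qtn(pop, all_win, 4L, seed = i)
  }))
  counts <- table(factor(draws, levels = eligible))
  expected <- length(draws) / length(eligible)
  chisq <- sum((counts - expected)^2 / expected)
  df <- length(eligible) - 1
  expect_lt(chisq, qchisq(0.999, df))
})

test_that("variance draws match their closed-form moments and are positive", {
  v <- sample_variances(100000L, gamma_shape = 5.4, gamma_scale = 0.42,
                        exp_rate = 10, seed = 8L)
  expect_true(all(v$va > 0) && all(v$vd > 0))
  se_va <- sd(v$va) / sqrt(nrow(v))
  expect_lt(abs(mean(v$va) - 5.4 * 0.42), 3 * se_va)
  se_vd <- sd(v$vd) / sqrt(nrow(v))
  expect_lt(abs(mean(v$vd) - 0.1), 3 * se_vd)
})

test_that("effect algebra inverts the variance decomposition", {
  # f = 0.5: (1-2f) = 0 and 2f(1-f) = 0.5, so a = d = 1
  e <- effects_from_variances(0.5, 0.25, 0.5, 1, 1)
  expect_equal(e$a, 1)
  expect_equal(e$d, 1)
  # |d| = sqrt(vd) / (2f(1-f)) = 0.18/0.18
  e2 <- effects_from_variances(0.2, 0.0324, 0.1, 1, 1)
  expect_equal(abs(e2$d), 1)
  # round trip over random draws
  set.seed(1)
  f <- runif(200, 0.01, 0.99)
  va <- rgamma(200, 5.4, scale = 0.42)
  vd <- rexp(200, 10)
  sa <- sample(c(-1, 1), 200, TRUE)
  sd_ <- sample(c(-1, 1), 200, TRUE)
  e3 <- effects_from_variances(va, vd, f, sa, sd_)
  het <- 2 * f * (1 - f)
  expect_equal((het * e3$d)^2, vd, tolerance = 1e-12)
  expect_equal(het * (e3$a + e3$d * (1 - 2 * f))^2, va, tolerance = 1e-12)
  expect_error(effects_from_variances(1, 1, 0), class = "gs_argument_error")
})

test_that("environmental variance calibration matches the heritability identity", {
  expect_equal(calibrate_ve(0.5, 0.5, 0.25), 3)
  expect_equal(calibrate_ve(0.7, 0.3, 0.5), 1)
  vg <- c(0.3, 1.2, 0.5)
  ve <- calibrate_ve(vg, 0, 0.25)
  expect_equal(sum(vg) / (sum(vg) + ve), 0.25)
  expect_error(calibrate_ve(1, 1, 1.2), class = "gs_argument_error")
})

test_that("genetic values follow the additive-dominance model", {
  pop <- tiny_pop()
  cfg <- tiny_config()
  lay <- place_genes(cfg, seed = 2L)
  arch <- sample_architecture(pop, lay, cfg, seed = 11L)
  q <- nrow(arch$qtn)
  gam <- matrix(sample(c(-1L, 0L, 1L), 30 * q, TRUE), 30, q)
  gv <- genetic_values(gam, arch)
  # no dominance -> total equals breeding value
  arch0 <- arch
  arch0$qtn$d <- rep(0, q)
  arch0$qtn$alpha <- arch0$qtn$a
  gv0 <- genetic_values(gam, arch0)
  expect_equal(gv0$g_total, gv0$breeding_value)
  # all homozygous ancestral: g = -sum(a)
  gv1 <- genetic_values(matrix(-1L, 2, q), arch)
  expect_equal(gv1$g_total, rep(-sum(arch$qtn$a), 2))
  expect_error(genetic_values(gam[, -1], arch), class = "gs_shape_error")
})

test_that("population variance of genetic values matches the target under HWE", {
  pop <- tiny_pop()
  cfg <- tiny_config()
  lay <- place_genes(cfg, seed = 2L)
  arch <- sample_architecture(pop, lay, cfg, seed = 13L)
  set.seed(99)
  n <- 200000L
  # draw genotypes independently at HWE from the founder frequencies
  gam <- vapply(arch$qtn$f, function(f) {
    rbinom(n, 1L, f) + rbinom(n, 1L, f) - 1L
  }, integer(n))
  gv <- genetic_values(gam, arch)
  target <- sum(arch$qtn$va) + sum(arch$qtn$vd)
  expect_lt(abs(var(gv$g_total) - target) / target, 0.05)
})

test_that("rescaling all variances by c scales effects by sqrt(c) and ve by c", {
  f <- c(0.2, 0.5, 0.8)
  va <- c(1, 2, 3); vd <- c(0.1, 0.2, 0.3)
  e1 <- effects_from_variances(va, vd, f, 1, -1)
  cc <- 4
  e2 <- effects_from_variances(cc * va, cc * vd, f, 1, -1)
  expect_equal(e2$a, sqrt(cc) * e1$a)
  expect_equal(e2$d, sqrt(cc) * e1$d)
  expect_equal(calibrate_ve(cc * va, cc * vd, 0.25),
               cc * calibrate_ve(va, vd, 0.25))
})

test_that("flipping all substitution signs mirrors the genetic values", {
  f <- runif(10, 0.1, 0.9)
  va <- rgamma(10, 5.4, scale = 0.42); vd <- rep(0, 10)
  ep <- effects_from_variances(va, vd, f, 1, 1)
  em <- effects_from_variances(va, vd, f, -1, 1)
  gam <- matrix(sample(c(-1L, 0L, 1L), 500, TRUE), 50, 10)
  expect_equal(gam %*% ep$a, -(gam %*% em$a))
})
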