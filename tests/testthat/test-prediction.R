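# Relationship matrix, pedigree BLUP, SNP-BLUP / PCG, nonlinear A,
# prediction and accuracy.

toy_ped <- function() {
  # 1,2 founders; 3,4 their offspring (full sibs); 5 = 3 x 4 (full-sib
  # mating); 6 = 1 x 4
  tibble::tibble(id = 1:6,
                 sire = c(0L, 0L, 1L, 1L, 3L, 1L),
                 dam = c(0L, 0L, 2L, 2L, 4L, 4L),
                 generation = c(0L, 0L, 1L, 1L, 2L, 2L),
                 sex = c("M", "F", "M", "F", "M", "F"))
}

test_that("the tabular A matrix matches path-counting on a toy pedigree", {
  A <- numerator_relationship(toy_ped())
  expect_equal(A[1, 2], 0)            # unrelated founders
  expect_equal(unname(diag(A)[1:4]), c(1, 1, 1, 1))
  expect_equal(A[1, 3], 0.5)          # parent-offspring
  expect_equal(A[3, 4], 0.5)          # full sibs
  expect_equal(A[5, 5], 1.25)         # full-sib mating: F = 0.25
  expect_equal(A[3, 5], 0.75)
  expect_true(isSymmetric(A))
  expect_true(all(eigen(A, only.values = TRUE)$values > -1e-10))
  bad <- toy_ped()[c(3, 1, 2, 4, 5, 6), ]
  expect_error(numerator_relationship(bad), class = "gs_pedigree_error")
})

toy_phen <- function(ped, seed = 1) {
  set.seed(seed)
  tibble::tibble(id = ped$id, generation = ped$generation,
                 y = rnorm(nrow(ped), 10, 2),
                 g_total = rnorm(nrow(ped)),
                 breeding_value = rnorm(nrow(ped)))
}

test_that("pedigree BLUP matches a direct GLS oracle and behaves in limits", {
  set.seed(42)
  ped <- build_pedigree(tiny_config(), seed = 3L)
  n <- nrow(ped)
  phen <- tibble::tibble(id = ped$id, generation = ped$generation,
                         y = rnorm(n, 5, 3),
                         g_total = rnorm(n), breeding_value = rnorm(n))
  masked <- ped$id[ped$generation == max(ped$generation)]
  h2 <- 0.25
  ev <- pedigree_blup(ped, phen, h2, masked)
  # independent oracle: u_hat = A[, obs] (A_oo + k I)^-1 (y_o - mu_hat),
  # with the GLS mean under V = A_oo + k I (common variance factored out)
  A <- numerator_relationship(ped)
  obs <- !(ped$id %in% masked)
  k <- (1 - h2) / h2
  V <- A[obs, obs] + k * diag(sum(obs))
  Vi <- solve(V)
  one <- rep(1, sum(obs))
  mu <- drop(crossprod(one, Vi %*% phen$y[obs]) / crossprod(one, Vi %*% one))
  u <- drop(A[, obs] %*% (Vi %*% (phen$y[obs] - mu)))
  expect_equal(ev$predictions$ghat, unname(u), tolerance = 1e-8)
  # shifting all phenotypes leaves EBV unchanged (mean absorbed)
  phen2 <- phen; phen2$y <- phen$y + 100
  ev2 <- pedigree_blup(ped, phen2, h2, masked)
  expect_equal(ev2$predictions$ghat, ev$predictions$ghat, tolerance = 1e-6)
  # infinite-shrinkage limit
  ev0 <- pedigree_blup(ped, phen, 1e-9, masked)
  expect_lt(max(abs(ev0$predictions$ghat)), 1e-5)
})

toy_gm <- function(n = 20L, p = 50L, seed = 2L) {
  set.seed(seed)
  x <- matrix(sample(c(-1L, 0L, 1L), n * p, TRUE), n, p)
  structure(list(x = x, individuals = seq_len(n),
                 panel = gselsim:::new_marker_panel(seq_len(p), "toy"),
                 error_state = "clean", error_models = list()),
            class = "genotype_matrix")
}

test_that("SNP-BLUP equals a dense direct solve, and PCG equals the dual route", {
  gm <- toy_gm()
  set.seed(3)
  y <- rnorm(20, 4, 2)
  s2 <- runif(50, 0.5, 2)
  ve <- 3
  fit <- snp_blup(gm, y, s2, ve, solver = "pcg")
  X <- gm$x; storage.mode(X) <- "double"
  Z <- sweep(X, 2, colMeans(X))
  dense <- solve(crossprod(Z) + diag(ve / s2), crossprod(Z, y - mean(y)))
  expect_equal(fit$a_hat, unname(drop(dense)), tolerance = 1e-6)
  fit_dual <- snp_blup(gm, y, s2, ve, solver = "dual")
  expect_equal(fit_dual$a_hat, fit$a_hat, tolerance = 1e-6)
  # y orthogonal to every centered column -> zero effects
  y0 <- rep(5, 20)
  expect_equal(snp_blup(gm, y0, s2, ve)$a_hat, rep(0, 50))
})

test_that("equal-variance SNP-BLUP reproduces GBLUP predictions", {
  gm <- toy_gm(n = 25L, p = 40L, seed = 5L)
  set.seed(6)
  y <- rnorm(25, 0, 2)
  s2 <- 0.8; ve <- 2.5
  fit <- snp_blup(gm, y, s2, ve)
  gebv_snp <- predict_gebv(fit, gm)
  # GBLUP oracle with the marker covariance G = Z Z' sigma2_a
  X <- gm$x; storage.mode(X) <- "double"
  Z <- sweep(X, 2, colMeans(X))
  G <- tcrossprod(Z) * s2
  gebv_gblup <- drop(G %*% solve(G + diag(ve, 25), y - mean(y)))
  expect_equal(gebv_snp, gebv_gblup, tolerance = 1e-6)
})

test_that("nonlinear A applies the documented variance update", {
  gm <- toy_gm(n = 8L, p = 3L, seed = 7L)
  set.seed(8)
  y <- rnorm(8)
  va_tot <- 1.5; ve <- 2
  # hand-scripted single outer iteration
  X <- gm$x; storage.mode(X) <- "double"
  pfreq <- (colMeans(X) + 1) / 2
  s0 <- va_tot / (2 * sum(pfreq * (1 - pfreq)))
  Z <- sweep(X, 2, colMeans(X))
  a1 <- drop(solve(crossprod(Z) + diag(ve / rep(s0, 3)),
                   crossprod(Z, y - mean(y))))
  s1 <- s0 * 1.125^(abs(a1) / sd(a1) - 2)
  a2 <- drop(solve(crossprod(Z) + diag(ve / s1), crossprod(Z, y - mean(y))))
  fit <- nonlinear_a(gm, y, va_tot, ve, outer_iters = 1L, outer_tol = 0)
  expect_equal(fit$sigma2_a0, s0)
  expect_equal(fit$sigma2_a, s1, tolerance = 1e-7)
  expect_equal(fit$a_hat, a2, tolerance = 1e-7)
  # update arithmetic: multiplier 1 at |a| = 2 sd; 1.125^-2 at a = 0
  expect_equal(s0 * 1.125^(2 - 2), s0)
  expect_equal(unname(s1[abs(a1) == 0]), rep(s0 * 1.125^-2, sum(a1 == 0)))
  # outer_iters = 0 degenerates to equal-variance SNP-BLUP
  fit0 <- nonlinear_a(gm, y, va_tot, ve, outer_iters = 0L)
  fit_rr <- snp_blup(gm, y, s0, ve)
  expect_equal(fit0$a_hat, fit_rr$a_hat, tolerance = 1e-9)
})

test_that("GEBV prediction is the frozen-centering linear score", {
  gm <- toy_gm(n = 15L, p = 20L, seed = 9L)
  set.seed(10)
  y <- rnorm(15)
  fit <- snp_blup(gm, y, 1, 1)
  # zero effects -> zero predictions
  fit0 <- fit; fit0$a_hat <- rep(0, 20)
  expect_equal(predict_gebv(fit0, gm), rep(0, 15))
  # training predictions sum to zero under training-mean centering
  expect_equal(sum(predict_gebv(fit, gm)), 0, tolerance = 1e-8)
  # linearity in the effect vector
  fa <- fit; fb <- fit; fs <- fit
  fa$a_hat <- runif(20); fb$a_hat <- runif(20)
  fs$a_hat <- fa$a_hat + fb$a_hat
  expect_equal(predict_gebv(fs, gm),
               predict_gebv(fa, gm) + predict_gebv(fb, gm))
  gm_bad <- toy_gm(n = 4L, p = 19L)
  expect_error(predict_gebv(fit, gm_bad), class = "gs_shape_error")
})

test_that("accuracy is a validated Pearson correlation", {
  ids <- 1:10
  truth <- rnorm(10)
  expect_equal(accuracy(truth, truth, ids, 4:10), 1)
  expect_equal(accuracy(-truth, truth, ids, 4:10), -1)
  pred <- rnorm(10)
  expect_equal(accuracy(3 * pred + 7, truth, ids, 4:10),
               accuracy(pred, truth, ids, 4:10))
  expect_error(accuracy(pred, truth, ids, 1:2), class = "gs_argument_error")
  expect_error(accuracy(rep(1, 10), truth, ids, 4:10),
               class = "gs_accuracy_error")
})

test_that("solvers are deterministic for fixed inputs", {
  gm <- toy_gm(n = 30L, p = 60L, seed = 11L)
  set.seed(12)
  y <- rnorm(30)
  f1 <- nonlinear_a(gm, y, 1, 2, outer_iters = 3L)
  f2 <- nonlinear_a(gm, y, 1, 2, outer_iters = 3L)
  expect_identical(f1$a_hat, f2$a_hat)
})
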