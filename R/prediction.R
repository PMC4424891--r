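#' Numerator relationship matrix
#'
#' Additive relationship matrix by the tabular method (Wright/Henderson),
#' accounting for inbreeding.  The pedigree must be sorted so parents
#' precede offspring (as produced by [build_pedigree()]).
#'
#' @param ped pedigree tibble (`id`, `sire`, `dam`; 0 = unknown).
#' @return dense symmetric positive semi-definite matrix, one row per
#'   pedigree entry, in pedigree order.
#' @export
numerator_relationship <- function(ped) {
  idx <- match(ped$sire, ped$id)
  idx[ped$sire == 0L] <- NA
  ddx <- match(ped$dam, ped$id)
  ddx[ped$dam == 0L] <- NA
  if (any(idx >= seq_len(nrow(ped)), na.rm = TRUE) ||
      any(ddx >= seq_len(nrow(ped)), na.rm = TRUE)) {
    abort("pedigree must list parents before offspring",
          class = "gs_pedigree_error")
  }
  s <- ifelse(is.na(idx), 0L, idx)
  d <- ifelse(is.na(ddx), 0L, ddx)
  A <- a_tabular_cpp(as.integer(s), as.integer(d))
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Pedigree BLUP (animal model)
#'
#' Mixed-model equations for \eqn{y = 1\mu + u + e} with
#' \eqn{u \sim N(0, A\sigma_u^2)} and variance ratio
#' \eqn{k = \sigma_e^2/\sigma_u^2 = (1-h^2)/h^2}.  Individuals in
#' `masked_ids` contribute no phenotype record; EBV are returned for all.
#'
#' @param ped pedigree tibble.
#' @param phen phenotype tibble from [simulate_phenotypes()] (columns `id`,
#'   `y`, plus the truth columns).
#' @param h2 heritability used for evaluation (the reference design uses
#'   broad-sense H2 = 0.25).
#' @param masked_ids ids whose phenotypes are removed (the validation set).
#' @param truth truth column for accuracy: "g_total" or "breeding_value".
#' @return an `evaluation_result`: predictions tibble (`id`, `ghat`),
#'   method label, validation ids, and the validation accuracy.
#' @export
pedigree_blup <- function(ped, phen, h2, masked_ids, truth = "g_total") {
  stopifnot(h2 > 0, h2 < 1)
  k <- (1 - h2) / h2
  A <- numerator_relationship(ped)
  n <- nrow(ped)
  obs <- !(ped$id %in% masked_ids)
  y <- phen$y[match(ped$id, phen$id)]
  if (anyNA(y[obs])) abort("missing phenotypes for unmasked individuals",
                           class = "gs_integrity_error")
  Ainv <- chol2inv(chol(A))
  C <- rbind(
    c(sum(obs), as.numeric(obs)),
    cbind(as.numeric(obs), diag(as.numeric(obs), n) + k * Ainv)
  )
  rhs <- c(sum(y[obs]), ifelse(obs, y, 0))
  sol <- solve(C, rhs)
  ghat <- sol[-1]
  new_evaluation_result(
    predictions = tibble(id = ped$id, ghat = ghat),
    method = "pedigree_blup", phen = phen, masked_ids = masked_ids,
    truth = truth,
    details = list(mu = sol[1], h2 = h2)
  )
}

#' SNP-BLUP (ridge regression on centered dosages)
#'
#' Solves \eqn{(Z'Z + D)\hat a = Z'(y - \bar y)} where Z is the
#' column-centered dosage matrix (means taken in the training set) and
#' \eqn{D = diag(V_e/\sigma^2_{aj})}.  The default solver is a
#' Jacobi-preconditioned conjugate gradient on the SNP equations; for
#' panels much wider than the training set an algebraically equivalent
#' dual (individual-space) solve is used.  The fitted intercept is the
#' training phenotype mean.
#'
#' @param gm_train training `genotype_matrix` (or plain dosage matrix).
#' @param y_train training phenotypes.
#' @param sigma2_a per-SNP prior variances (scalar recycled).
#' @param ve residual variance.
#' @param tol PCG convergence tolerance (relative residual).
#' @param maxit PCG iteration cap.
#' @param solver "pcg", "dual", or "auto".
#' @param init optional warm-start effect vector.
#' @return a `snp_fit`: effect estimates, per-SNP variances, column means,
#'   intercept and a convergence log.
#' @export
snp_blup <- function(gm_train, y_train, sigma2_a, ve, tol = 1e-8,
                     maxit = 5000L, solver = c("auto", "pcg", "dual"),
                     init = NULL) {
  solver <- match.arg(solver)
  X <- genotype_dosage(gm_train)
  n <- nrow(X); p <- ncol(X)
  if (length(y_train) != n) {
    abort("rows of the genotype matrix must match phenotypes",
          class = "gs_shape_error")
  }
  sigma2_a <- rep_len(sigma2_a, p)
  stopifnot(all(sigma2_a > 0), ve > 0)
  xbar <- colMeans(X)
  intercept <- mean(y_train)
  yc <- y_train - intercept
  dvec <- ve / sigma2_a

  if (solver == "auto") solver <- if (p > 3L * n) "dual" else "pcg"
  if (solver == "dual") {
    W <- sweep(X, 2L, xbar, "-")
    Ws <- sweep(W, 2L, sqrt(sigma2_a / ve), "*")
    Cmat <- tcrossprod(Ws)
    diag(Cmat) <- diag(Cmat) + 1
    a_hat <- (sigma2_a / ve) * drop(crossprod(W, solve(Cmat, yc)))
    log <- tibble(iteration = 1L, rel_residual = 0, solver = "dual")
  } else {
    sol <- pcg_ridge(X, xbar, yc, dvec, tol = tol, maxit = maxit,
                     init = init)
    a_hat <- sol$a
    log <- tibble(iteration = sol$iterations, rel_residual = sol$rel_residual,
                  solver = "pcg")
    if (sol$rel_residual > tol) {
      abort(sprintf("PCG did not converge: relative residual %.3g after %d iterations",
                    sol$rel_residual, sol$iterations),
            class = "gs_convergence_error")
    }
  }
  structure(list(a_hat = a_hat, sigma2_a = sigma2_a, x_bar = xbar,
                 intercept = intercept, ve = ve,
                 panel = if (inherits(gm_train, "genotype_matrix")) gm_train$panel else NULL,
                 n_train = n, convergence = log),
            class = "snp_fit")
}

genotype_dosage <- function(gm) {
  x <- if (inherits(gm, "genotype_matrix")) gm$x else gm
  storage.mode(x) <- "double"
  x
}

# Jacobi-preconditioned CG for (Z'Z + D) a = Z'yc with Z = X - 1 xbar'.
pcg_ridge <- function(X, xbar, yc, dvec, tol, maxit, init = NULL) {
  n <- nrow(X)
  zty <- function(v) drop(crossprod(X, v)) - xbar * sum(v)
  zv <- function(a) drop(X %*% a) - sum(xbar * a)
  matvec <- function(a) zty(zv(a)) + dvec * a
  b <- zty(yc)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) {
    return(list(a = numeric(ncol(X)), iterations = 0L, rel_residual = 0))
  }
  prec <- drop(colSums(X^2)) - n * xbar^2 + dvec
  a <- if (is.null(init)) numeric(ncol(X)) else init
  r <- b - matvec(a)
  z <- r / prec
  p <- z
  rz <- sum(r * z)
  it <- 0L
  repeat {
    rel <- sqrt(sum(r^2)) / bnorm
    if (rel <= tol || it >= maxit) break
    Ap <- matvec(p)
    alpha <- rz / sum(p * Ap)
    a <- a + alpha * p
    r <- r - alpha * Ap
    z <- r / prec
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
    it <- it + 1L
  }
  list(a = a, iterations = it, rel_residual = sqrt(sum(r^2)) / bnorm)
}

#' VanRaden's nonlinear A model
#'
#' Iterative re-weighting of per-SNP variances around the common prior
#' \eqn{\sigma^2_{a0} = V_A / (2\sum_j p_j(1-p_j))} (\eqn{p_j} training
#' allele frequencies, \eqn{V_A} the total additive variance): after each
#' SNP-BLUP solve, \eqn{\sigma^2_{aj} = \sigma^2_{a0} \cdot
#' 1.125^{|\hat a_j|/sd(\hat a) - 2}}, so effects smaller than two standard
#' deviations are shrunken more and large effects less — a posterior-mode
#' analogue of BayesA.  `outer_iters = 0` degenerates exactly to SNP-BLUP
#' with equal variances.
#'
#' @inheritParams snp_blup
#' @param total_additive_variance total additive-genetic variance (in
#'   simulation, the known \eqn{\sum_q V_{a,q}}).
#' @param outer_iters maximum variance-update iterations (default 10).
#' @param outer_tol stop when `max |delta a| < outer_tol` (default
#'   `1e-6 * sd(y_train)`).
#' @return a `snp_fit` with `sigma2_a0` and an outer-iteration log.
#' @export
nonlinear_a <- function(gm_train, y_train, total_additive_variance, ve,
                        outer_iters = 10L, outer_tol = NULL, tol = 1e-8,
                        solver = "auto") {
  stopifnot(total_additive_variance > 0)
  X <- genotype_dosage(gm_train)
  pfreq <- (colMeans(X) + 1) / 2
  denom <- 2 * sum(pfreq * (1 - pfreq))
  if (denom <= 0) abort("panel is monomorphic in the training set",
                        class = "gs_argument_error")
  sigma2_a0 <- total_additive_variance / denom
  if (is.null(outer_tol)) outer_tol <- 1e-6 * sd(y_train)

  sigma2 <- rep(sigma2_a0, ncol(X))
  fit <- snp_blup(gm_train, y_train, sigma2, ve, tol = tol, solver = solver)
  outer_log <- tibble(outer = 0L, max_delta = NA_real_, sd_a = sd(fit$a_hat))
  degenerate <- FALSE
  i <- 0L
  while (i < outer_iters) {
    i <- i + 1L
    s <- sd(fit$a_hat)
    if (!is.finite(s) || s == 0) {
      degenerate <- TRUE  # hold variances at sigma2_a0
      break
    }
    sigma2 <- sigma2_a0 * 1.125^(abs(fit$a_hat) / s - 2)
    new_fit <- snp_blup(gm_train, y_train, sigma2, ve, tol = tol,
                        solver = solver, init = fit$a_hat)
    delta <- max(abs(new_fit$a_hat - fit$a_hat))
    fit <- new_fit
    outer_log <- bind_rows(outer_log,
                           tibble(outer = i, max_delta = delta,
                                  sd_a = sd(fit$a_hat)))
    if (delta < outer_tol) break
  }
  fit$sigma2_a0 <- sigma2_a0
  fit$outer_log <- outer_log
  fit$degenerate <- degenerate
  fit
}

#' Predict genomic estimated breeding values
#'
#' \eqn{\hat g_i = \sum_j (x_{ij} - \bar x_j)\hat a_j} with column means
#' frozen from the training set.
#'
#' @param fit a [snp_blup()] / [nonlinear_a()] fit.
#' @param gm_all `genotype_matrix` (or dosage matrix) on the same panel.
#' @return numeric vector of predicted merits.
#' @export
predict_gebv <- function(fit, gm_all) {
  X <- genotype_dosage(gm_all)
  if (ncol(X) != length(fit$a_hat)) {
    abort("panel mismatch between fit and genotypes",
          class = "gs_shape_error")
  }
  if (inherits(gm_all, "genotype_matrix") && !is.null(fit$panel) &&
      !identical(gm_all$panel$sites, fit$panel$sites)) {
    abort("panel mismatch between fit and genotypes",
          class = "gs_shape_error")
  }
  drop(X %*% fit$a_hat) - sum(fit$x_bar * fit$a_hat)
}

#' Cross-validation accuracy
#'
#' Pearson correlation between predicted and true genetic merit restricted
#' to the validation individuals.
#'
#' @param predicted named-by-nothing numeric vector aligned with `ids`.
#' @param truth numeric vector aligned with `ids`.
#' @param ids individual ids for both vectors.
#' @param validation_ids ids over which the correlation is computed.
#' @export
accuracy <- function(predicted, truth, ids, validation_ids) {
  sel <- ids %in% validation_ids
  if (sum(sel) < 3) abort("need at least three validation individuals",
                          class = "gs_argument_error")
  p <- predicted[sel]; t <- truth[sel]
  if (sd(p) == 0 || sd(t) == 0) {
    abort("accuracy undefined: zero variance in validation set",
          class = "gs_accuracy_error")
  }
  cor(p, t)
}

new_evaluation_result <- function(predictions, method, phen, masked_ids,
                                  truth, details = list()) {
  truth_vec <- phen[[truth]][match(predictions$id, phen$id)]
  acc <- accuracy(predictions$ghat, truth_vec, predictions$id, masked_ids)
  structure(list(predictions = predictions, method = method,
                 validation_ids = masked_ids, truth = truth,
                 accuracy = acc, details = details),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result> ", x$method, ": accuracy ",
      sprintf("%.3f", x$accuracy), " on ", length(x$validation_ids),
      " validation individuals (truth: ", x$truth, ")\n", sep = "")
  invisible(x)
}
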