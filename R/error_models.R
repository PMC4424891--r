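#' Genotyping / imputation error models
#'
#' Three per-genotype confusion models.  `ngs` is the biased
#' sequencing-caller model: a true heterozygote is miscalled to either
#' homozygote with probability \eqn{\lambda} each, while a true homozygote
#' drifts to heterozygote with probability \eqn{\lambda/5} and never jumps
#' to the opposite homozygote.  `imputation` and `array` share the
#' symmetric genotype-independent model with total error rate \eqn{\alpha}
#' split equally between the two wrong genotypes.  `k_min` is the
#' minimum-allele-count filter applied after corruption.
#'
#' @param kind one of "ngs", "imputation", "array".
#' @param lambda base NGS genotyping error rate (defaults 0.05 or 0.01).
#' @param alpha per-genotype error rate (imputation 0.20/0.01; array
#'   1e-3/1e-4).
#' @param k_min minimum allele count K for [min_allele_count_filter()].
#' @return an `error_model` list.
#' @export
error_model <- function(kind = c("ngs", "imputation", "array"),
                        lambda = 0.05, alpha = 0.2, k_min = 1L) {
  kind <- match.arg(kind)
  m <- structure(list(kind = kind, lambda = lambda, alpha = alpha,
                      k_min = as.integer(k_min)),
                 class = "error_model")
  genotype_confusion_matrix(m)  # validates rates
  m
}

#' Genotype confusion matrix
#'
#' Row-stochastic 3x3 matrix of P(observed | true) over genotypes RR, RA,
#' AA (R = ancestral/reference, A = derived/alternative).
#'
#' @param model an [error_model()].
#' @return 3x3 matrix with dimnames RR/RA/AA.
#' @export
genotype_confusion_matrix <- function(model) {
  if (model$kind == "ngs") {
    l <- model$lambda
    if (l < 0 || 2 * l > 1) {
      abort("invalid NGS error rate: need 0 <= 2*lambda <= 1",
            class = "gs_rate_error")
    }
    m <- rbind(c(1 - l / 5, l / 5, 0),
               c(l, 1 - 2 * l, l),
               c(0, l / 5, 1 - l / 5))
  } else {
    a <- model$alpha
    if (a < 0 || a > 1) {
      abort("invalid error rate: need 0 <= alpha <= 1",
            class = "gs_rate_error")
    }
    m <- rbind(c(1 - a, a / 2, a / 2),
               c(a / 2, 1 - a, a / 2),
               c(a / 2, a / 2, 1 - a))
  }
  dimnames(m) <- list(true = c("RR", "RA", "AA"),
                      observed = c("RR", "RA", "AA"))
  m
}

#' Corrupt a genotype matrix
#'
#' Resamples every genotype independently from its confusion-matrix row.
#' Models compose: apply the NGS model first, then imputation, matching the
#' stated three-step error procedure (imputation errors hit all
#' individuals).
#'
#' @param gm a [extract_genotypes()] result (clean or already corrupted).
#' @param model an [error_model()].
#' @param seed integer seed.
#' @return a `genotype_matrix` flagged `corrupted`.
#' @export
apply_genotype_errors <- function(gm, model, seed = 1L) {
  cm <- genotype_confusion_matrix(model)
  x <- gm$x
  cat_true <- x + 2L  # -1/0/1 -> 1/2/3
  set.seed(as.integer(seed))
  u <- runif(length(x))
  obs <- integer(length(x))
  for (tt in 1:3) {
    idx <- which(cat_true == tt)
    if (!length(idx)) next
    p1 <- cm[tt, 1]
    p12 <- cm[tt, 1] + cm[tt, 2]
    obs[idx] <- 1L + (u[idx] > p1) + (u[idx] > p12)
  }
  gm$x <- matrix(obs - 2L, nrow = nrow(x), ncol = ncol(x))
  gm$error_state <- "corrupted"
  gm$error_models <- c(gm$error_models, list(model))
  gm
}

#' Minimum allele-count filter
#'
#' Removes SNPs whose minor-allele count in the observed (possibly
#' corrupted) matrix is below K; applied after error corruption, as a
#' post-calling quality control.  K = 1 keeps every observed-segregating
#' site.
#'
#' @param gm a `genotype_matrix`.
#' @param K minimum allele count (>= 1).
#' @return the `genotype_matrix` reduced to surviving SNPs (panel updated).
#' @export
min_allele_count_filter <- function(gm, K = 1L) {
  stopifnot(K >= 1)
  derived <- colSums(gm$x + 1L)
  minor <- pmin(derived, 2L * nrow(gm$x) - derived)
  keep <- minor >= K
  gm$x <- gm$x[, keep, drop = FALSE]
  gm$panel$sites <- gm$panel$sites[keep]
  gm$panel$params$k_min <- as.integer(K)
  gm
}
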