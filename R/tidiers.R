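#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a SNP fit
#'
#' One row per marker: effect estimate and its working prior variance.
#'
#' @param x a [snp_blup()] / [nonlinear_a()] fit.
#' @param ... unused.
#' @export
tidy.snp_fit <- function(x, ...) {
  tibble(term = if (!is.null(x$panel)) paste0("snp", x$panel$sites)
                else paste0("snp", seq_along(x$a_hat)),
         estimate = x$a_hat, sigma2_a = x$sigma2_a, x_bar = x$x_bar)
}

#' @rdname tidy.snp_fit
#' @export
glance.snp_fit <- function(x, ...) {
  tibble(n_snp = length(x$a_hat), n_train = x$n_train,
         intercept = x$intercept, ve = x$ve,
         sigma2_a0 = x$sigma2_a0 %||% NA_real_,
         outer_iterations = if (!is.null(x$outer_log)) max(x$outer_log$outer)
                            else NA_integer_,
         pcg_iterations = max(x$convergence$iteration),
         rel_residual = max(x$convergence$rel_residual))
}

#' Tidy an evaluation result
#' @param x an `evaluation_result`.
#' @param ... unused.
#' @export
tidy.evaluation_result <- function(x, ...) x$predictions

#' @rdname tidy.evaluation_result
#' @export
glance.evaluation_result <- function(x, ...) {
  tibble(method = x$method, accuracy = x$accuracy,
         n_valid = length(x$validation_ids), truth = x$truth)
}

#' Tidy a scenario result
#' @param x a `scenario_result`.
#' @param ... unused.
#' @export
tidy.scenario_result <- function(x, ...) x$results

#' @rdname tidy.scenario_result
#' @export
glance.scenario_result <- function(x, ...) x$summary

`%||%` <- function(a, b) if (is.null(a)) b else a
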