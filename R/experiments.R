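#' Run one full simulation replicate
#'
#' One pipeline pass: base population, gene windows, trait architecture,
#' pedigree, gene-dropping, phenotypes, then every requested evaluation
#' method on the same simulated population (paired comparison).  Phenotypes
#' of the last-generation individuals are masked and accuracy is scored on
#' them.
#'
#' @param cfg a [scenario_config()] list.
#' @param replicate_index replicate number; per-stage seeds derive
#'   deterministically from `cfg$seed` and this index.
#' @param keep_objects return the intermediate objects as an attribute?
#' @return tibble with one row per method: `replicate`, `method`,
#'   `accuracy`, `n_snp`, `n_train`, `n_valid`, `truth`.
#' @export
run_replicate <- function(cfg, replicate_index = 1L, keep_objects = FALSE) {
  ss <- function(stage) stage_seed(cfg$seed, replicate_index, stage)
  methods <- cfg$evaluation$methods

  pop <- simulate_base(cfg, seed = ss("base"))
  layout <- place_genes(cfg, seed = ss("genes"))
  arch <- sample_architecture(pop, layout, cfg, seed = ss("arch"))
  ped <- build_pedigree(cfg, seed = ss("pedigree"))

  panels <- build_panels(pop, layout, arch, cfg,
                         setdiff(methods, "pedigree_blup"),
                         seed_fun = ss)
  tracked <- sort(unique(c(arch$qtn$site,
                           unlist(lapply(panels, `[[`, "sites")))))
  haps <- gene_drop(pop, ped, seed = ss("drop"), tracked_sites = tracked)
  phen <- simulate_phenotypes(haps, arch, seed = ss("phen"))

  last_gen <- max(ped$generation)
  masked <- ped$id[ped$generation == last_gen]
  train <- ped$id[ped$generation < last_gen]
  truth <- cfg$evaluation$truth

  rows <- vector("list", length(methods))
  objects <- list()
  for (m in seq_along(methods)) {
    method <- methods[m]
    t_method <- Sys.time()
    if (method == "pedigree_blup") {
      ev <- pedigree_blup(ped, phen, cfg$arch$h2, masked, truth = truth)
      n_snp <- NA_integer_
    } else {
      gm <- extract_genotypes(haps, panels[[method]])
      gm <- apply_method_errors(gm, cfg$evaluation$errors[[method]],
                                seed = ss(paste0("err_", method)))
      gm_train <- gm
      gm_train$x <- gm$x[gm$individuals %in% train, , drop = FALSE]
      gm_train$individuals <- gm$individuals[gm$individuals %in% train]
      y_train <- phen$y[match(gm_train$individuals, phen$id)]
      fit <- if (identical(cfg$evaluation$model, "snp_blup")) {
        va_tot <- sum(arch$qtn$va)
        p <- ncol(gm_train$x)
        pf <- (colMeans(gm_train$x) + 1) / 2
        snp_blup(gm_train, y_train,
                 va_tot / (2 * sum(pf * (1 - pf))), arch$ve,
                 tol = cfg$evaluation$pcg_tol)
      } else {
        nonlinear_a(gm_train, y_train, sum(arch$qtn$va), arch$ve,
                    outer_iters = cfg$evaluation$outer_iters,
                    tol = cfg$evaluation$pcg_tol)
      }
      ghat <- predict_gebv(fit, gm)
      ev <- new_evaluation_result(
        predictions = tibble(id = gm$individuals, ghat = ghat),
        method = method, phen = phen, masked_ids = masked, truth = truth,
        details = list(fit = NULL)
      )
      n_snp <- length(fit$a_hat)
      if (keep_objects) objects[[method]] <- list(fit = fit, gm = gm)
    }
    rows[[m]] <- tibble(replicate = replicate_index, method = method,
                        accuracy = ev$accuracy, n_snp = n_snp,
                        n_train = length(train), n_valid = length(masked),
                        truth = truth,
                        seconds = as.numeric(difftime(Sys.time(), t_method,
                                                      units = "secs")))
  }
  out <- bind_rows(rows)
  if (keep_objects) {
    attr(out, "objects") <- c(list(pop = pop, layout = layout, arch = arch,
                                   ped = ped, haps = haps, phen = phen,
                                   panels = panels), objects)
  }
  out
}

apply_method_errors <- function(gm, err, seed) {
  if (is.null(err)) return(gm)
  if (inherits(err, "error_model")) err <- list(err)
  for (i in seq_along(err)) {
    gm <- apply_genotype_errors(gm, err[[i]],
                                seed = seed + i - 1L)
    if (!is.null(err[[i]]$k_min) && err[[i]]$k_min > 1L) {
      gm <- min_allele_count_filter(gm, err[[i]]$k_min)
    }
  }
  gm
}

# Construct the requested marker panels; genes_half and genes_half_noise
# share the same half-subset of gene windows within a replicate.
build_panels <- function(pop, layout, arch, cfg, labels, seed_fun) {
  out <- list()
  spec <- cfg$panels
  need_half <- any(c("genes_half", "genes_half_noise") %in% labels)
  half_windows <- NULL
  if (need_half) {
    set.seed(seed_fun("half_subset"))
    nh <- spec$genes_half$n_windows
    half_windows <- layout[sort(sample(nrow(layout), nh)), ]
  }
  for (lab in labels) {
    ps <- spec[[lab]]
    if (is.null(ps)) abort(paste0("no panel spec named ", lab),
                           class = "gs_config_error")
    out[[lab]] <- switch(
      ps$type,
      array = ascertain_array(pop, maf_min = ps$maf_min,
                              target_size = ps$target_size,
                              seed = seed_fun(paste0("panel_", lab)),
                              label = lab),
      rad = window_panel(pop,
                         random_windows(cfg, ps$n_windows, ps$window_bp,
                                        seed = seed_fun(paste0("panel_", lab))),
                         label = lab),
      sequence = new_marker_panel(seq_len(nrow(pop$sites)), lab),
      causal = causal_panel(arch),
      genes = window_panel(pop, layout, label = lab),
      genes_half = window_panel(pop, half_windows, label = lab),
      genes_half_noise = {
        noise <- random_windows(cfg, ps$noise_windows, ps$noise_window_bp,
                                avoid = layout,
                                seed = seed_fun(paste0("panel_", lab)))
        window_panel(pop, bind_rows(half_windows[, c("chrom", "start", "end")],
                                    noise), label = lab)
      },
      abort(paste0("unknown panel type ", ps$type),
            class = "gs_config_error")
    )
  }
  out
}

#' Run a replicated scenario
#'
#' Independent replicates with deterministically derived seeds; returns
#' per-replicate accuracies and a per-method summary (mean, SD with n-1
#' denominator).  Failed replicates are recorded and excluded from the
#' summary.
#'
#' @param cfg a [scenario_config()] list.
#' @param n_replicates number of replicates.
#' @param progress print one line per replicate?
#' @return a `scenario_result`: list with `results` (per replicate x
#'   method), `summary`, `failures`, and the config.
#' @export
run_scenario <- function(cfg, n_replicates = 1L, progress = FALSE) {
  res <- vector("list", n_replicates)
  failures <- list()
  for (r in seq_len(n_replicates)) {
    t0 <- Sys.time()
    out <- tryCatch(run_replicate(cfg, r), error = function(e) e)
    if (inherits(out, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble(replicate = r, message = conditionMessage(out))
    } else {
      res[[r]] <- out
    }
    if (progress) {
      cat(sprintf("replicate %d/%d (%.1fs)\n", r, n_replicates,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  results <- bind_rows(res)
  summary <- results %>%
    group_by(.data$method) %>%
    summarise(mean_accuracy = mean(.data$accuracy),
              sd_accuracy = if (n() > 1) sd(.data$accuracy) else NA_real_,
              n_replicates = n(), .groups = "drop")
  structure(list(results = results, summary = summary,
                 failures = bind_rows(failures), config = cfg),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", max(x$results$replicate), " replicates\n",
      sep = "")
  print(x$summary)
  if (nrow(x$failures)) cat(nrow(x$failures), "failed replicates\n")
  invisible(x)
}

#' Compare methods across scenario results
#'
#' Stacks per-method summaries and, when results share replicates (paired
#' evaluation), adds paired accuracy differences against a baseline
#' method.
#'
#' @param ... `scenario_result` objects (or one list of them).
#' @param baseline optional method label for paired differences.
#' @return tibble of method, mean, SD, n (and paired difference columns
#'   when `baseline` is given).
#' @export
summarize_comparison <- function(..., baseline = NULL) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "scenario_result")) xs <- xs[[1]]
  results <- bind_rows(lapply(xs, `[[`, "results"))
  out <- results %>%
    group_by(.data$method) %>%
    summarise(mean_accuracy = mean(.data$accuracy),
              sd_accuracy = if (n() > 1) sd(.data$accuracy) else NA_real_,
              n_replicates = n(), .groups = "drop")
  if (!is.null(baseline)) {
    if (!baseline %in% results$method) {
      abort("baseline method not present in the results",
            class = "gs_pairing_error")
    }
    base <- results %>%
      filter(.data$method == baseline) %>%
      select("replicate", base_accuracy = "accuracy")
    diffs <- results %>%
      left_join(base, by = "replicate") %>%
      group_by(.data$method) %>%
      summarise(mean_paired_diff = mean(.data$accuracy - .data$base_accuracy),
                relative_gain = mean(.data$accuracy) /
                  mean(.data$base_accuracy) - 1,
                .groups = "drop")
    out <- left_join(out, diffs, by = "method")
  }
  out
}

#' Export a completed run
#'
#' Writes pedigree, phenotypes, panel tables, results and a manifest with
#' the resolved seeds to a directory.
#'
#' @param scenario a `scenario_result`.
#' @param out_dir output directory (created if needed).
#' @param objects optional `run_replicate(..., keep_objects = TRUE)`
#'   attribute for exporting pedigree/phenotype/panel files of one
#'   replicate.
#' @return `out_dir`, invisibly.
#' @export
export_run <- function(scenario, out_dir, objects = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(scenario$results, file.path(out_dir, "results.csv"))
  readr::write_csv(scenario$summary, file.path(out_dir, "summary.csv"))
  manifest <- list(
    master_seed = scenario$config$seed,
    scale = scenario$config$scale,
    n_replicates = max(scenario$results$replicate),
    methods = scenario$config$evaluation$methods,
    stage_seeds = lapply(seq_len(max(scenario$results$replicate)),
                         function(r) list(
                           replicate = r,
                           base = stage_seed(scenario$config$seed, r, "base"),
                           drop = stage_seed(scenario$config$seed, r, "drop"))),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(objects)) {
    write_pedigree(objects$ped, file.path(out_dir, "pedigree.tsv"))
    write_pedigree(objects$phen, file.path(out_dir, "phenotypes.tsv"))
    for (lab in names(objects$panels)) {
      write_panel(objects$pop, objects$panels[[lab]],
                  file.path(out_dir, paste0("panel_", lab, ".tsv")))
    }
  }
  invisible(out_dir)
}
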