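new_marker_panel <- function(sites, label, params = list()) {
  structure(list(sites = sort(unique(as.integer(sites))), label = label,
                 params = params),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> ", x$label, ": ", length(x$sites), " SNPs\n", sep = "")
  invisible(x)
}

#' Ascertain an array panel from a discovery sample
#'
#' Mimics commercial array design: sites segregating in a small discovery
#' panel (default the 50 diploids kept out of the pedigree) whose
#' discovery-sample MAF is at least `maf_min` are eligible, and
#' `target_size` of them are drawn at random.  `maf_min = 0` admits every
#' discovery-segregating site.  Ascertainment frequency is always computed
#' in the discovery sample, never in the pedigree.
#'
#' @param pop a [simulate_base()] result.
#' @param discovery diploid sample ids of the discovery panel (default:
#'   the `discovery` role; pass `breed2` ids for cross-breed ascertainment).
#' @param maf_min minimum discovery MAF (0 or 0.15 in the reference design).
#' @param target_size number of SNPs on the array.
#' @param seed integer seed.
#' @param label panel label.
#' @return a `marker_panel`.
#' @export
ascertain_array <- function(pop, discovery = NULL, maf_min = 0.15,
                            target_size = 7500L, seed = 1L,
                            label = "array") {
  if (is.null(discovery)) {
    discovery <- pop$samples$sample_id[pop$samples$role == "discovery"]
  }
  rows <- sequence_rows(discovery)
  k <- length(rows)
  cnt <- hap_col_counts_cpp(pop$haplotypes, as.integer(rows))
  maf <- pmin(cnt, k - cnt) / k
  eligible <- which(cnt > 0 & cnt < k & maf >= maf_min)
  if (length(eligible) < target_size) {
    abort(sprintf(
      "ascertainment failed: %d eligible SNPs for a %d-SNP array",
      length(eligible), target_size), class = "gs_ascertainment_error")
  }
  set.seed(as.integer(seed))
  new_marker_panel(sample(eligible, target_size), label,
                   list(maf_min = maf_min, target_size = target_size,
                        n_discovery = length(discovery), seed = seed))
}

#' Panel of all SNPs inside a window set
#'
#' Serves the RAD/GBS strategy (all SNPs in random 10-kb windows) and the
#' biology-informed strategies (all SNPs in the causal gene windows, in a
#' random half of them, or in the half plus random neutral windows).
#'
#' @param pop a [simulate_base()] result.
#' @param windows tibble of `chrom`, `start`, `end` (0-based half-open).
#' @param label panel label.
#' @return a `marker_panel` (possibly empty).
#' @export
window_panel <- function(pop, windows, label = "windows") {
  new_marker_panel(sites_in_windows(pop$sites, windows), label,
                   list(n_windows = nrow(windows)))
}

#' Random genomic windows
#'
#' Uniformly placed, mutually non-overlapping windows, optionally avoiding
#' an exclusion set (used for "neutral" noise windows that must not touch
#' the causal genes).
#'
#' @param config a [scenario_config()] list.
#' @param n_windows number of windows.
#' @param window_bp window width.
#' @param avoid optional tibble of windows that must not be intersected.
#' @param seed integer seed.
#' @return tibble of `chrom`, `start`, `end`.
#' @export
random_windows <- function(config, n_windows, window_bp, avoid = NULL,
                           seed = 1L) {
  g <- config$genome
  set.seed(as.integer(seed))
  out <- vector("list", n_windows)
  placed <- if (is.null(avoid)) {
    tibble(chrom = integer(0), start = integer(0), end = integer(0))
  } else {
    avoid[, c("chrom", "start", "end")]
  }
  for (i in seq_len(n_windows)) {
    repeat {
      ch <- sample.int(g$n_chrom, 1L)
      st <- as.integer(floor(runif(1, 0, g$chrom_length_bp - window_bp + 1)))
      clash <- any(placed$chrom == ch &
                   placed$start < st + window_bp & placed$end > st)
      if (!clash) break
    }
    w <- tibble(chrom = ch, start = st, end = st + as.integer(window_bp))
    placed <- bind_rows(placed, w)
    out[[i]] <- w
  }
  bind_rows(out)
}

#' Panel of the causal sites themselves
#'
#' All QTN, irrespective of their variance contribution — the upper-bound
#' "perfect biological information" strategy.
#'
#' @param arch a [sample_architecture()] result.
#' @return a `marker_panel`.
#' @export
causal_panel <- function(arch) {
  new_marker_panel(arch$qtn$site, "causal", list(n_qtn = nrow(arch$qtn)))
}

#' Extract a dosage genotype matrix
#'
#' Codes genotypes as allele1 + allele2 - 1, i.e. -1 (homozygous
#' ancestral), 0 (heterozygous), +1 (homozygous derived), for a panel and a
#' set of pedigree individuals.
#'
#' @param haps a [gene_drop()] result with the panel sites tracked.
#' @param panel a `marker_panel`.
#' @param individuals pedigree ids (default: all).
#' @return `genotype_matrix`: list with `x` (individuals x SNP integer
#'   matrix), `individuals`, the panel, and an `error_state` flag.
#' @export
extract_genotypes <- function(haps, panel, individuals = NULL) {
  if (is.null(individuals)) individuals <- haps$pedigree$id
  rows <- match(panel$sites, haps$sites$site)
  if (anyNA(rows)) {
    abort("panel contains sites not tracked in the gene-drop result",
          class = "gs_integrity_error")
  }
  x <- dosage_from_drop(haps, rows, individuals)
  structure(list(x = x, individuals = individuals, panel = panel,
                 error_state = "clean", error_models = list()),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$x), " individuals x ", ncol(x$x),
      " SNPs (", x$panel$label, ", ", x$error_state, ")\n", sep = "")
  invisible(x)
}

#' Write a panel as TSV
#' @param pop a [simulate_base()] result (for site coordinates).
#' @param panel a `marker_panel`.
#' @param file output path.
#' @export
write_panel <- function(pop, panel, file) {
  readr::write_tsv(tibble(chrom = pop$sites$chrom[panel$sites],
                          pos = pop$sites$pos[panel$sites],
                          label = panel$label), file)
  invisible(file)
}
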