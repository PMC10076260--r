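#' Default pipeline configuration
#'
#' All window sizes, probability cut-offs, merge distances and filter
#' thresholds used across the pipeline, with the defaults the analysis chain
#' is built around. Values are documented where they are consumed.
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    # ancestry windows / blocks
    window_bp = 10000, prob_threshold = 0.8, gap_bp = 50000, min_windows = 2,
    # painting
    rho = 1e-8, n_em_iter = 10,
    # excess introgression
    slop_bp = 2500, excess_merge_bp = 10000, min_support_snps = 3,
    # selection scan
    n_clusters = 5, n_fits = 20, p_threshold = 1e-3, fdr = 0.05,
    region_half_width = 5000, region_merge_bp = 5000, fst_top = 0.05,
    fst_window_bp = 10000, kinship_thin_bp = 250000,
    # variant filters
    min_qual = 30, depth_band = c(1 / 3, 4), max_gt_reads_missing = 2,
    min_dp = 3, max_missing = 0.5, min_maf = 0.05, max_het_prop = 0.01,
    thin_bp = 250000,
    # diversity
    pi_window_bp = 100000, private_freq_split = 0.05,
    # LD
    ld_maf = 0.1, ld_max_dist = 5e6, interchrom_thin_bp = 10000,
    interchrom_maf = 0.05, r2_min = 0.8, interchrom_merge_bp = 100000,
    min_pair_width = 500000,
    # traits
    h2_min = 0.65, qst_percentile = 97.5
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML file of overrides on top of [default_config()]. Unknown keys
#' are rejected; a handful of bounds are enforced. An empty or absent-override
#' file yields the full default configuration. All resolved values are logged.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param quiet suppress the start-of-run threshold log.
#' @return named list: the validated configuration.
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  cfg <- default_config()
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    if (is.null(over)) over <- list()
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  if (!quiet) {
    msg <- paste(names(cfg), vapply(cfg, function(v)
      paste(format(v, trim = TRUE), collapse = ","), ""), sep = "=")
    message("introscan config: ", paste(msg, collapse = "; "))
  }
  cfg
}

validate_config <- function(cfg) {
  in01 <- c("prob_threshold", "fdr", "max_missing", "min_maf", "max_het_prop",
            "fst_top", "private_freq_split", "ld_maf", "interchrom_maf",
            "r2_min")
  for (k in in01) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0 || cfg[[k]] > 1) {
      stop(sprintf("configuration key '%s' must lie in [0, 1] (got %s)",
                   k, format(cfg[[k]])), call. = FALSE)
    }
  }
  pos <- c("window_bp", "gap_bp", "slop_bp", "excess_merge_bp", "rho",
           "region_half_width", "region_merge_bp", "fst_window_bp",
           "kinship_thin_bp", "pi_window_bp", "ld_max_dist",
           "interchrom_thin_bp", "interchrom_merge_bp", "min_pair_width",
           "thin_bp", "n_em_iter", "n_fits", "n_clusters")
  for (k in pos) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      stop(sprintf("configuration key '%s' must be positive", k), call. = FALSE)
    }
  }
  if (cfg$p_threshold <= 0 || cfg$p_threshold > 1) {
    stop("configuration key 'p_threshold' must lie in (0, 1]", call. = FALSE)
  }
  invisible(cfg)
}
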