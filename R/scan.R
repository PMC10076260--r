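#' Scale two scan runs and extract selection regions
#'
#' Each run's raw statistics are scaled to a chi-square null by robust
#' moment matching ([chi2_scale()]) giving p-values and Benjamini-Hochberg
#' q-values. SNPs significant in a run (`p < p_threshold` and
#' `q < fdr`) seed a window of `half_width` bp either side, overlapping
#' windows or windows within `merge_bp` are merged, and the two runs are
#' combined into the extended set (union of coverage) and the restricted
#' set (interval intersection of the two runs' regions). Finally only
#' regions containing at least one FST window in the top `fst_top` fraction
#' are retained.
#'
#' @param scan_a,scan_b tibbles `chrom`, `pos`, statistic column named by
#'   `stat_col` (typically two [hapflk()] runs at different K).
#' @param fst_windows window tibble from [windowed_fst()].
#' @param stat_col name of the statistic column (default `"hapflk"`).
#' @param p_threshold,fdr significance thresholds (defaults 1e-3 and 0.05).
#' @param half_width half-width of the per-SNP region (default 5 kb, i.e. a
#'   10-kb region centred on the SNP).
#' @param merge_bp maximum distance merged (default 5 kb).
#' @param fst_top FST outlier fraction (default top 5 percent).
#' @return list with `per_snp` (both runs' scaled statistics, p and q
#'   values), `regions_a`, `regions_b`, `extended`, `restricted` (region
#'   tibbles after the FST filter), and the unfiltered `extended_all`,
#'   `restricted_all`.
#' @export
scale_and_extract <- function(scan_a, scan_b, fst_windows,
                              stat_col = "hapflk", p_threshold = 1e-3,
                              fdr = 0.05, half_width = 5000,
                              merge_bp = 5000, fst_top = 0.05) {
  run_regions <- function(scan) {
    sc <- chi2_scale(scan[[stat_col]])
    q <- stats::p.adjust(sc$p_value, method = "BH")
    sig <- !is.na(sc$p_value) & sc$p_value < p_threshold & q < fdr
    regs <- if (any(sig)) {
      merge_regions(slop_points(tibble::tibble(chrom = scan$chrom[sig],
                                               pos = scan$pos[sig]),
                                half_width),
                    gap = merge_bp)
    } else {
      tibble::tibble(chrom = character(), start = numeric(), end = numeric())
    }
    list(p = sc$p_value, q = q, scaled = sc$scaled, sig = sig, regions = regs)
  }
  a <- run_regions(scan_a)
  b <- run_regions(scan_b)
  per_snp <- tibble::tibble(chrom = scan_a$chrom, pos = scan_a$pos,
                            stat_a = scan_a[[stat_col]],
                            p_a = a$p, q_a = a$q,
                            stat_b = scan_b[[stat_col]],
                            p_b = b$p, q_b = b$q)
  extended <- merge_regions(dplyr::bind_rows(a$regions, b$regions), gap = 0)
  restricted <- intersect_regions(a$regions, b$regions)
  top <- fst_outlier_windows(fst_windows, top = fst_top)
  list(per_snp = per_snp, regions_a = a$regions, regions_b = b$regions,
       extended_all = extended, restricted_all = restricted,
       extended = filter_overlapping(extended, top),
       restricted = filter_overlapping(restricted, top),
       fst_top_windows = top)
}

#' Interval intersection of two region sets
#'
#' @param a,b tibbles `chrom`, `start`, `end`.
#' @return merged tibble of the overlapping parts (subset of both inputs'
#'   coverage).
#' @export
intersect_regions <- function(a, b) {
  if (!nrow(a) || !nrow(b)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  out <- purrr::map_dfr(seq_len(nrow(a)), function(i) {
    hits <- b[b$chrom == a$chrom[i] & b$start < a$end[i] &
                a$start[i] < b$end, , drop = FALSE]
    if (!nrow(hits)) return(NULL)
    tibble::tibble(chrom = a$chrom[i],
                   start = pmax(a$start[i], hits$start),
                   end = pmin(a$end[i], hits$end))
  })
  if (!nrow(out)) return(out)
  merge_regions(out, gap = 0)
}

#' Run the full selection scan on a panel
#'
#' Convenience wrapper: thins the panel for the kinship estimate, builds the
#' Reynolds kinship, computes windowed FST, runs [hapflk()] at `K = k1` and
#' `K = k2` (the latter from masked-imputation CV when `k2 = NULL`), and
#' extracts extended/restricted selection regions.
#'
#' @param panel phased [hap_panel()].
#' @param groups tibble `sample_id`, `group` of the populations scanned.
#' @param fst_groups optional two-group assignment for the FST windows
#'   (defaults to `groups`).
#' @param k1 first cluster count (default 5).
#' @param k2 second cluster count; `NULL` triggers [choose_k()].
#' @param n_fits EM fits per run.
#' @param chrom_lengths optional chromosome lengths.
#' @param config configuration list ([default_config()]) for thresholds.
#' @return the [scale_and_extract()] result plus `kinship`, `fst`,
#'   `k2_used`.
#' @export
selection_scan <- function(panel, groups, fst_groups = NULL, k1 = 5,
                           k2 = NULL, n_fits = 20, chrom_lengths = NULL,
                           config = default_config()) {
  if (is.null(fst_groups)) fst_groups <- groups
  thin <- thin_variants(subset_samples(panel, groups$sample_id),
                        config$kinship_thin_bp)
  kin <- build_kinship(thin, groups)
  fst <- windowed_fst(panel, fst_groups, window_bp = config$fst_window_bp,
                      chrom_lengths = chrom_lengths)
  if (is.null(k2)) {
    k2 <- choose_k(panel, n_sets = 5, mask_frac = 0.1)$K_star
  }
  sa <- hapflk(panel, groups, kin$F, K = k1, n_fits = n_fits)
  sb <- hapflk(panel, groups, kin$F, K = k2, n_fits = n_fits)
  out <- scale_and_extract(sa, sb, fst$windows,
                           p_threshold = config$p_threshold,
                           fdr = config$fdr,
                           half_width = config$region_half_width,
                           merge_bp = config$region_merge_bp,
                           fst_top = config$fst_top)
  out$kinship <- kin
  out$fst <- fst
  out$k2_used <- k2
  out
}
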