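#' Run the adaptive-introgression pipeline end to end
#'
#' Chains the full analysis on a donor + recipient panel pair: haplotype
#' painting with per-accession EM, 10-kb window assignment, genepool calls,
#' introgression blocks, the excess-introgression scan with sample-size
#' thresholds, windowed FST between recipients and donors, two
#' haplotype-cluster selection scans combined through the chi-square
#' scaling and region machinery, and finally PAIL calling as the
#' intersection of the three evidence layers.
#'
#' @param recipient_panel,donor_panel [hap_panel()]s sharing a site list.
#' @param donor_groups tibble `sample_id`, `group` (five donor races).
#' @param chrom_lengths tibble `chrom`, `length`.
#' @param genes optional gene table (`gene_id`, `chrom`, `start`, `end`)
#'   for gene-level PAIL output.
#' @param config configuration list ([default_config()]).
#' @param k1,k2 haplotype-cluster counts of the two scan runs.
#' @param n_fits,max_iter EM fits per scan run and iteration cap (scale
#'   these down for quick runs).
#' @param n_em_iter painting EM iterations per accession.
#' @return list with `painting`, `windows`, `calls`, `blocks`, `excess`
#'   (per-SNP scan + thresholds), `excess_regions`, `fst`, `scan`
#'   (selection-scan output), `pail`.
#' @export
pail_pipeline <- function(recipient_panel, donor_panel, donor_groups,
                          chrom_lengths, genes = NULL,
                          config = default_config(), k1 = 5, k2 = NULL,
                          n_fits = 20, max_iter = 100, n_em_iter = 10) {
  pt <- paint_panel(recipient_panel, donor_panel, donor_groups,
                    rho = config$rho, n_em_iter = n_em_iter)
  wm <- assign_windows(pt, chrom_lengths, window_bp = config$window_bp,
                       prob = config$prob_threshold)
  calls <- call_genepool(wm)
  blocks <- extract_blocks(wm, calls, gap_bp = config$gap_bp,
                           min_windows = config$min_windows)
  thr <- excess_thresholds(sum(calls$call == "EU_AND", na.rm = TRUE),
                           sum(calls$call == "EU_MES", na.rm = TRUE))
  ex <- scan_excess(wm, recipient_panel$sites, calls, thr)
  flagged <- tibble::tibble(chrom = ex$chrom, pos = ex$pos)[
    ex$flag_and | ex$flag_mes, ]
  ex_regions <- build_excess_regions(flagged, chrom_lengths,
                                     slop = config$slop_bp,
                                     merge_bp = config$excess_merge_bp,
                                     min_snps = config$min_support_snps)
  # scan populations: donor genepools vs called recipient genepools
  ok_calls <- calls[!calls$ambiguous, ]
  scan_groups <- dplyr::bind_rows(
    tibble::tibble(sample_id = donor_groups$sample_id,
                   group = paste0("AM_",
                                  substr(label_genepool(donor_groups$group),
                                         1, 1))),
    tibble::tibble(sample_id = ok_calls$sample_id,
                   group = sub("EU_(.).*", "EU_\\1", ok_calls$call)))
  combined <- hap_panel(rbind(donor_panel$haplotypes,
                              recipient_panel$haplotypes),
                        donor_panel$sites,
                        c(donor_panel$sample_ids,
                          recipient_panel$sample_ids))
  scan_panel <- subset_samples(combined, scan_groups$sample_id)
  fst_groups <- tibble::tibble(
    sample_id = scan_groups$sample_id,
    group = ifelse(startsWith(scan_groups$group, "AM"), "AM", "EU"))
  kin <- build_kinship(thin_variants(scan_panel, config$kinship_thin_bp),
                       scan_groups)
  fst <- windowed_fst(scan_panel, fst_groups,
                      window_bp = config$fst_window_bp,
                      chrom_lengths = chrom_lengths)
  if (is.null(k2)) {
    k2 <- choose_k(scan_panel, n_sets = 5, mask_frac = 0.1,
                   max_iter = max_iter)$K_star
  }
  sa <- hapflk(scan_panel, scan_groups, kin$F, K = k1, n_fits = n_fits,
               max_iter = max_iter)
  sb <- hapflk(scan_panel, scan_groups, kin$F, K = k2, n_fits = n_fits,
               max_iter = max_iter)
  scan <- scale_and_extract(sa, sb, fst$windows,
                            p_threshold = config$p_threshold,
                            fdr = config$fdr,
                            half_width = config$region_half_width,
                            merge_bp = config$region_merge_bp,
                            fst_top = config$fst_top)
  scan$kinship <- kin
  pail <- call_pail(ex_regions, scan$extended, scan$fst_top_windows,
                    genes = if (is.null(genes))
                      tibble::tibble(gene_id = character(),
                                     chrom = character(), start = numeric(),
                                     end = numeric()) else genes)
  list(painting = pt, windows = wm, calls = calls, blocks = blocks,
       excess = ex, excess_regions = ex_regions, fst = fst, scan = scan,
       pail = pail, k2_used = k2)
}
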