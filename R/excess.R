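#' Sample-size-derived excess-introgression thresholds
#'
#' With `n_and` Andean-assigned and `n_mes` Mesoamerican-assigned recipient
#' accessions, the expected Andean assignment fraction at a neutral SNP is
#' all Andean haplotypes plus half of the Mesoamerican ones (which carry
#' Andean material at the admixture rate), over all recipient haplotypes:
#' `F_A = (2 n_and + n_mes) / (2 (n_and + n_mes))`, and symmetrically
#' `F_M = (2 n_mes + n_and) / (2 (n_and + n_mes))`. Reported values are
#' truncated (not rounded) to three decimals, matching how the thresholds
#' are quoted downstream.
#'
#' @param n_and,n_mes accession counts (>= 0, not both zero).
#' @return list with exact `F_A`, `F_M` and 3-decimal-truncated
#'   `F_A_reported`, `F_M_reported`.
#' @export
excess_thresholds <- function(n_and, n_mes) {
  if (n_and + n_mes <= 0) stop("no recipient accessions", call. = FALSE)
  if (n_and == 0 || n_mes == 0) {
    warning("degenerate threshold: one genepool has no accessions")
  }
  tot <- 2 * (n_and + n_mes)
  f_a <- (2 * n_and + n_mes) / tot
  f_m <- (2 * n_mes + n_and) / tot
  trunc3 <- function(x) floor(x * 1000) / 1000
  list(F_A = f_a, F_M = f_m,
       F_A_reported = trunc3(f_a), F_M_reported = trunc3(f_m))
}

#' Scan SNPs for excess introgressed ancestry
#'
#' Traces each SNP's per-haplotype ancestry assignment through the window
#' map (a haplotype's assignment at a SNP is the genepool of its containing
#' window's label; `"unknown"` windows leave the haplotype out of the
#' numerator but in the denominator). `Fobs_AND` / `Fobs_MES` are the
#' proportions over all haplotypes of unambiguously called accessions, and
#' SNPs at or above the thresholds are flagged.
#'
#' @param window_map an `ancestry_windows` tibble ([assign_windows()]).
#' @param sites tibble `chrom`, `pos` of the SNPs scanned.
#' @param genepool_calls output of [call_genepool()]; ambiguous accessions
#'   are excluded.
#' @param thresholds output of [excess_thresholds()]; computed from the
#'   calls when `NULL`.
#' @return tibble `chrom`, `pos`, `fobs_and`, `fobs_mes`, `flag_and`,
#'   `flag_mes`, with the thresholds in attributes.
#' @export
scan_excess <- function(window_map, sites, genepool_calls,
                        thresholds = NULL) {
  calls <- genepool_calls[!genepool_calls$ambiguous, ]
  if (is.null(thresholds)) {
    thresholds <- excess_thresholds(sum(calls$call == "EU_AND"),
                                    sum(calls$call == "EU_MES"))
  }
  wm <- window_map[window_map$sample_id %in% calls$sample_id, ]
  haps <- unique(wm$hap_id)
  denom <- length(haps)
  n_and <- n_mes <- numeric(nrow(sites))
  window_bp <- max(wm$end - wm$start)
  for (hid in haps) {
    w <- wm[wm$hap_id == hid, ]
    key <- paste(w$chrom, w$start %/% window_bp)
    gp <- w$genepool[match(paste(sites$chrom, sites$pos %/% window_bp), key)]
    n_and <- n_and + (!is.na(gp) & gp == "AND")
    n_mes <- n_mes + (!is.na(gp) & gp == "MES")
  }
  fobs_and <- n_and / denom
  fobs_mes <- n_mes / denom
  out <- tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                        fobs_and = fobs_and, fobs_mes = fobs_mes,
                        flag_and = fobs_and >= thresholds$F_A_reported,
                        flag_mes = fobs_mes >= thresholds$F_M_reported)
  attr(out, "thresholds") <- thresholds
  attr(out, "n_haplotypes") <- denom
  out
}

#' Build excess-introgression regions from flagged SNPs
#'
#' Flagged SNP point coordinates become `2 * slop`-bp intervals (clipped at
#' chromosome ends), intervals within `merge_bp` are merged, and regions
#' supported by fewer than `min_snps` flagged SNPs are dropped.
#'
#' @param flagged tibble `chrom`, `pos` of flagged SNPs.
#' @param chrom_lengths tibble `chrom`, `length`.
#' @param slop half-width (default 2500, i.e. 5-kb regions).
#' @param merge_bp maximum merged gap (default 10 kb).
#' @param min_snps minimum supporting SNPs (default 3).
#' @return region tibble `chrom`, `start`, `end`, `n_support`.
#' @export
build_excess_regions <- function(flagged, chrom_lengths, slop = 2500,
                                 merge_bp = 10000, min_snps = 3) {
  if (!nrow(flagged)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_support = integer()))
  }
  regs <- merge_regions(slop_points(flagged, slop, chrom_lengths),
                        gap = merge_bp)
  regs <- count_support(regs, flagged)
  regs[regs$n_support >= min_snps, , drop = FALSE]
}

#' Call putative adaptive introgressed loci (PAIL)
#'
#' A PAIL region shows all three lines of evidence: excess introgression,
#' a haplotype-based selection signature, and an outlier FST window (any
#' overlap at the region level). Genes are attributed to regions by
#' interval overlap, and summarised as selection-only, introgression-only
#' or both.
#'
#' @param excess_regions regions from [build_excess_regions()].
#' @param selection_regions selection regions (already FST-filtered, e.g.
#'   the extended set of [scale_and_extract()]).
#' @param fst_outliers outlier windows ([fst_outlier_windows()]).
#' @param genes tibble `gene_id`, `chrom`, `start`, `end`.
#' @return list with `regions` (excess regions plus evidence flags and
#'   `pail`), `genes` (tibble `gene_id`, `evidence`), `summary` (counts of
#'   genes by evidence class).
#' @export
call_pail <- function(excess_regions, selection_regions, fst_outliers,
                      genes) {
  ex <- tibble::as_tibble(excess_regions)
  ex$sel_overlap <- overlaps_any(ex, selection_regions)
  ex$fst_overlap <- overlaps_any(ex, fst_outliers)
  ex$pail <- ex$sel_overlap & ex$fst_overlap
  gene_flags <- genes |>
    dplyr::mutate(
      introgression = overlaps_any(genes, ex),
      selection = overlaps_any(genes, filter_overlapping(selection_regions,
                                                         fst_outliers)),
      pail = overlaps_any(genes, ex[ex$pail, , drop = FALSE])) |>
    dplyr::filter(.data$introgression | .data$selection) |>
    dplyr::mutate(evidence = dplyr::case_when(
      .data$pail ~ "pail",
      .data$introgression & .data$selection ~ "both",
      .data$selection ~ "selection_only",
      TRUE ~ "introgression_only"))
  summary <- gene_flags |> dplyr::count(.data$evidence, name = "n_genes")
  list(regions = ex, genes = gene_flags, summary = summary)
}
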