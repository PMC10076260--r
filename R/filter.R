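#' Site- and genotype-level filter specification
#'
#' Defaults follow the standard resequencing-callset recipe this pipeline is
#' built around: QUAL >= 30; global site depth within 1/3x to 4x the mean;
#' genotypes called from two reads or fewer set to missing, then a minimum
#' genotype depth of 3; at least 50 percent genotypes non-missing; minor
#' allele frequency >= 0.05 (on non-missing alleles); heterozygous-genotype
#' proportion <= 0.01 (over non-missing genotypes, apt for selfing lines);
#' and 250-kb thinning for structure analyses.
#'
#' @param min_qual minimum site QUAL kept (inclusive).
#' @param depth_band multiplies of the mean global depth kept (inclusive).
#' @param max_gt_reads genotypes with this many reads or fewer become missing.
#' @param min_dp minimum genotype depth after the read masking.
#' @param max_missing minimum fraction of non-missing genotypes required.
#' @param min_maf minimum minor allele frequency kept.
#' @param max_het_prop maximum heterozygous-genotype proportion kept.
#' @param thin_bp spacing used by [thin_variants()].
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(min_qual = 30, depth_band = c(1 / 3, 4),
                        max_gt_reads = 2, min_dp = 3, max_missing = 0.5,
                        min_maf = 0.05, max_het_prop = 0.01,
                        thin_bp = 250000) {
  stopifnot(min_qual >= 0, length(depth_band) == 2,
            depth_band[1] < depth_band[2], max_missing >= 0,
            max_missing <= 1, min_maf >= 0, min_maf <= 0.5,
            max_het_prop >= 0, max_het_prop <= 1, thin_bp > 0)
  structure(list(min_qual = min_qual, depth_band = depth_band,
                 max_gt_reads = max_gt_reads, min_dp = min_dp,
                 max_missing = max_missing, min_maf = min_maf,
                 max_het_prop = max_het_prop, thin_bp = thin_bp),
            class = "filter_spec")
}

#' Apply the site filters in fixed order
#'
#' Order: QUAL, depth band, genotype-read masking (<= `max_gt_reads` reads,
#' then `< min_dp`), missingness, MAF, heterozygosity. Depth-dependent steps
#' are skipped with a warning when the panel carries no depth information.
#' Removal counts are attributed to the first filter that removes each site.
#'
#' @param panel a [hap_panel()].
#' @param spec a [filter_spec()].
#' @return list with `panel` (filtered; genotype masking applied) and
#'   `report` (tibble `filter`, `n_removed`, `n_remaining`).
#' @export
apply_site_filters <- function(panel, spec = filter_spec()) {
  report <- list()
  note <- function(name, keep, n_before) {
    report[[length(report) + 1]] <<- tibble::tibble(
      filter = name, n_removed = n_before - sum(keep), n_remaining = sum(keep))
  }
  # QUAL
  if (!is.null(panel$sites$qual) && any(!is.na(panel$sites$qual))) {
    keep <- is.na(panel$sites$qual) | panel$sites$qual >= spec$min_qual
  } else {
    warning("no QUAL available; QUAL filter skipped")
    keep <- rep(TRUE, n_sites(panel))
  }
  note("qual", keep, n_sites(panel))
  panel <- subset_sites(panel, keep)
  # depth band
  if (!is.null(panel$sites$depth) && any(!is.na(panel$sites$depth))) {
    mu <- mean(panel$sites$depth, na.rm = TRUE)
    keep <- is.na(panel$sites$depth) |
      (panel$sites$depth >= spec$depth_band[1] * mu &
         panel$sites$depth <= spec$depth_band[2] * mu)
  } else {
    warning("no site depth available; depth-band filter skipped")
    keep <- rep(TRUE, n_sites(panel))
  }
  note("depth_band", keep, n_sites(panel))
  panel <- subset_sites(panel, keep)
  # genotype-read masking
  if (!is.null(panel$gt_depth)) {
    low <- !is.na(panel$gt_depth) &
      (panel$gt_depth <= spec$max_gt_reads | panel$gt_depth < spec$min_dp)
    if (any(low)) {
      h <- panel$haplotypes
      n <- n_samples(panel)
      for (i in seq_len(n)) {
        h[c(2 * i - 1, 2 * i), low[i, ]] <- NA_integer_
      }
      panel <- hap_panel(h, panel$sites, panel$sample_ids, panel$phased,
                         gt_depth = panel$gt_depth)
    }
  }
  # missingness
  n <- n_samples(panel)
  h <- panel$haplotypes
  a1 <- h[seq(1, 2 * n, 2), , drop = FALSE]
  a2 <- h[seq(2, 2 * n, 2), , drop = FALSE]
  nonmiss <- colSums(!is.na(a1) & !is.na(a2))
  keep <- nonmiss / n >= spec$max_missing
  note("missingness", keep, n_sites(panel))
  panel <- subset_sites(panel, keep)
  # MAF on non-missing alleles
  f <- alt_freq(panel)
  maf <- pmin(f, 1 - f)
  keep <- !is.nan(maf) & maf >= spec$min_maf
  note("maf", keep, n_sites(panel))
  panel <- subset_sites(panel, keep)
  # heterozygosity over non-missing genotypes
  h <- panel$haplotypes
  n <- n_samples(panel)
  a1 <- h[seq(1, 2 * n, 2), , drop = FALSE]
  a2 <- h[seq(2, 2 * n, 2), , drop = FALSE]
  ok <- !is.na(a1) & !is.na(a2)
  het <- colSums((a1 != a2) & ok) / pmax(colSums(ok), 1)
  keep <- het <= spec$max_het_prop
  note("heterozygosity", keep, n_sites(panel))
  panel <- subset_sites(panel, keep)
  list(panel = panel, report = dplyr::bind_rows(report))
}

#' Thin variants to a minimum spacing
#'
#' Greedy per-chromosome scan keeping the first SNP and then the next SNP at
#' least `thin_bp` downstream of the last kept one.
#'
#' @param panel a [hap_panel()] (sites sorted).
#' @param thin_bp minimum spacing in bp (default 250 kb).
#' @return the thinned [hap_panel()].
#' @export
thin_variants <- function(panel, thin_bp = 250000) {
  keep <- logical(n_sites(panel))
  for (ch in unique(panel$sites$chrom)) {
    idx <- which(panel$sites$chrom == ch)
    last <- -Inf
    for (i in idx) {
      if (panel$sites$pos[i] - last >= thin_bp || !is.finite(last)) {
        keep[i] <- TRUE
        last <- panel$sites$pos[i]
      }
    }
  }
  subset_sites(panel, keep)
}
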