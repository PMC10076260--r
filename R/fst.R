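#' Weir & Cockerham variance components per SNP
#'
#' The 1984 diploid estimator: per site and population the non-missing
#' genotype count, allele frequency and observed heterozygosity enter the
#' among-population (`a`), among-individual (`b`) and within-individual
#' (`c`) components. Sites where fewer than two populations have at least
#' two genotyped individuals are `NA`.
#'
#' @param panel a [hap_panel()].
#' @param groups tibble `sample_id`, `group` (2+ groups).
#' @return tibble `chrom`, `pos`, `a`, `b`, `c`, `fst_site`.
#' @export
wc_fst_components <- function(panel, groups) {
  gl <- sort(unique(groups$group))
  if (length(gl) < 2) stop("at least two groups are required", call. = FALSE)
  h <- panel$haplotypes
  n_all <- n_samples(panel)
  a1 <- h[seq(1, 2 * n_all, 2), , drop = FALSE]
  a2 <- h[seq(2, 2 * n_all, 2), , drop = FALSE]
  ok <- !is.na(a1) & !is.na(a2)
  dose <- a1 + a2
  het <- (a1 != a2) & ok

  r <- length(gl)
  n_i <- p_i <- h_i <- matrix(0, nrow = r, ncol = n_sites(panel))
  for (i in seq_len(r)) {
    idx <- match(groups$sample_id[groups$group == gl[i]], panel$sample_ids)
    n_i[i, ] <- colSums(ok[idx, , drop = FALSE])
    p_i[i, ] <- colSums(dose[idx, , drop = FALSE] * ok[idx, , drop = FALSE],
                        na.rm = TRUE) / (2 * pmax(n_i[i, ], 1))
    h_i[i, ] <- colSums(het[idx, , drop = FALSE]) / pmax(n_i[i, ], 1)
  }
  nbar <- colMeans(n_i)
  rn <- r * nbar
  nc <- (rn - colSums(n_i^2) / rn) / (r - 1)
  pbar <- colSums(n_i * p_i) / rn
  s2 <- colSums(n_i * sweep(p_i, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / rn

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- colSums(n_i >= 2) < 2 | nbar <= 1 | nc <= 0
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  denom <- a + b + cc
  tibble::tibble(chrom = panel$sites$chrom, pos = panel$sites$pos,
                 a = a, b = b, c = cc,
                 fst_site = ifelse(!is.na(denom) & denom != 0, a / denom,
                                   NA_real_))
}

#' Windowed Weir & Cockerham FST
#'
#' Window estimates are ratios of summed components,
#' `sum(a) / sum(a + b + c)` over the SNPs in each non-overlapping window;
#' negative window estimates are retained. Windows without a usable
#' (polymorphic, sufficiently genotyped) SNP are `NA`.
#'
#' @param panel a [hap_panel()].
#' @param groups tibble `sample_id`, `group`.
#' @param window_bp window width (default 10 kb).
#' @param chrom_lengths optional tibble `chrom`, `length`.
#' @return list with `windows` (tibble `chrom`, `start`, `end`, `fst`,
#'   `n_snps`), `per_site` (component tibble), and `summary` (mean and IQR
#'   of the window distribution plus the global multi-SNP estimate).
#' @export
windowed_fst <- function(panel, groups, window_bp = 10000,
                         chrom_lengths = NULL) {
  comp <- wc_fst_components(panel, groups)
  if (is.null(chrom_lengths)) chrom_lengths <- panel_chrom_lengths(panel)
  windows <- purrr::map_dfr(seq_len(nrow(chrom_lengths)), function(i) {
    ch <- chrom_lengths$chrom[i]; len <- chrom_lengths$length[i]
    starts <- seq(0, len - 1, by = window_bp)
    x <- comp[comp$chrom == ch & !is.na(comp$a), ]
    wi <- x$pos %/% window_bp + 1L
    num <- den <- cnt <- rep(0, length(starts))
    if (nrow(x)) {
      agg_a <- rowsum(x$a, wi); agg_d <- rowsum(x$a + x$b + x$c, wi)
      agg_n <- rowsum(rep(1, nrow(x)), wi)
      ii <- as.integer(rownames(agg_a))
      num[ii] <- agg_a[, 1]; den[ii] <- agg_d[, 1]; cnt[ii] <- agg_n[, 1]
    }
    tibble::tibble(chrom = ch, start = starts,
                   end = pmin(starts + window_bp, len),
                   fst = ifelse(cnt > 0 & den != 0, num / den, NA_real_),
                   n_snps = cnt)
  })
  ok <- !is.na(comp$a)
  global <- sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok])
  wf <- windows$fst[!is.na(windows$fst)]
  list(windows = windows, per_site = comp,
       summary = tibble::tibble(mean = mean(wf), iqr = stats::IQR(wf),
                                global = global))
}

#' Top-quantile FST outlier windows
#'
#' @param fst_windows window tibble from [windowed_fst()].
#' @param top upper tail retained (0.05 keeps the top 5 percent).
#' @return the outlier windows (non-`NA` `fst` at or above the quantile).
#' @export
fst_outlier_windows <- function(fst_windows, top = 0.05) {
  w <- fst_windows[!is.na(fst_windows$fst), ]
  thr <- stats::quantile(w$fst, 1 - top, names = FALSE)
  w[w$fst >= thr, , drop = FALSE]
}
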