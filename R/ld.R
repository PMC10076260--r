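#' Linkage-disequilibrium decay curve
#'
#' r-squared is the squared Pearson correlation between haplotype allele
#' indicators at two sites (computed on pairwise-complete haplotypes).
#' Within each chromosome all pairs up to `max_dist` apart among sites
#' passing the MAF filter are binned by distance; the distance at which the
#' binned curve crosses r-squared = 0.2 is linearly interpolated between
#' adjacent bin midpoints (`NA` when the curve never crosses).
#'
#' @param panel a [hap_panel()].
#' @param samples optional sample subset (e.g. one group).
#' @param maf minimum minor allele frequency (default 0.1).
#' @param max_dist maximum pair distance in bp (default 5 Mb).
#' @param bin_bp distance bin width (default 50 kb).
#' @return an `ld_decay` tibble `dist_mid`, `mean_r2`, `n_pairs`, with the
#'   0.2-crossing distance in attribute `crossing_0.2` and in
#'   [glance.ld_decay()].
#' @export
ld_decay <- function(panel, samples = NULL, maf = 0.1, max_dist = 5e6,
                     bin_bp = 50000) {
  if (!is.null(samples)) panel <- subset_samples(panel, samples)
  if (nrow(panel$haplotypes) < 2) {
    stop("at least two haplotypes are required", call. = FALSE)
  }
  f <- alt_freq(panel)
  keep <- !is.nan(f) & pmin(f, 1 - f) >= maf
  panel <- subset_sites(panel, keep)
  breaks <- seq(0, max_dist, by = bin_bp)
  acc_sum <- numeric(length(breaks) - 1)
  acc_n <- numeric(length(breaks) - 1)
  for (ch in unique(panel$sites$chrom)) {
    idx <- which(panel$sites$chrom == ch)
    if (length(idx) < 2) next
    x <- panel$haplotypes[, idx, drop = FALSE]
    pos <- panel$sites$pos[idx]
    r2 <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))^2
    dd <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(dd)
    d <- dd[ut]; r <- r2[ut]
    ok <- d <= max_dist & !is.na(r)
    bi <- findInterval(d[ok], breaks, rightmost.closed = TRUE,
                       left.open = TRUE)
    bi[bi == 0] <- 1
    s <- rowsum(r[ok], bi)
    n <- rowsum(rep(1, sum(ok)), bi)
    ii <- as.integer(rownames(s))
    acc_sum[ii] <- acc_sum[ii] + s[, 1]
    acc_n[ii] <- acc_n[ii] + n[, 1]
  }
  out <- tibble::tibble(dist_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                        mean_r2 = ifelse(acc_n > 0, acc_sum / acc_n, NA_real_),
                        n_pairs = acc_n)
  cross <- NA_real_
  cc <- out[!is.na(out$mean_r2), ]
  below <- which(cc$mean_r2 < 0.2)
  if (length(below) && below[1] > 1) {
    i <- below[1]
    x1 <- cc$dist_mid[i - 1]; y1 <- cc$mean_r2[i - 1]
    x2 <- cc$dist_mid[i]; y2 <- cc$mean_r2[i]
    cross <- x1 + (0.2 - y1) * (x2 - x1) / (y2 - y1)
  }
  attr(out, "crossing_0.2") <- cross
  class(out) <- c("ld_decay", class(out))
  out
}

#' One-line LD-decay summary
#' @param x an `ld_decay` tibble.
#' @param ... unused.
#' @return tibble with the 0.2-crossing distance and pair count.
#' @method glance ld_decay
#' @export
glance.ld_decay <- function(x, ...) {
  tibble::tibble(crossing_0.2_bp = attr(x, "crossing_0.2"),
                 total_pairs = sum(x$n_pairs))
}

#' Inter-chromosomal high-LD region pairs
#'
#' SNPs are thinned deterministically (first SNP passing the MAF filter in
#' each `thin_bp` grid cell), r-squared is computed for every
#' cross-chromosome pair, pairs at or above `r2_min` are clustered (two SNP
#' pairs join when both sides are within `merge_bp` on the same chromosome
#' pair), and only region pairs spanning at least `min_width` bp on each
#' side are retained.
#'
#' @param panel a [hap_panel()].
#' @param samples optional sample subset.
#' @param thin_bp thinning grid (default 10 kb).
#' @param maf minimum minor allele frequency (default 0.05).
#' @param r2_min r-squared threshold (default 0.8).
#' @param merge_bp per-side clustering distance (default 100 kb).
#' @param min_width minimum per-side span in bp (default 500 kb; drop to
#'   50 kb when restricting to selection regions).
#' @param regions optional region tibble; only SNPs inside are used (the
#'   within-selection-regions variant).
#' @return tibble `chrom_a`, `start_a`, `end_a`, `chrom_b`, `start_b`,
#'   `end_b`, `n_pairs`, `max_r2`.
#' @export
interchrom_ld <- function(panel, samples = NULL, thin_bp = 10000,
                          maf = 0.05, r2_min = 0.8, merge_bp = 100000,
                          min_width = 500000, regions = NULL) {
  if (!is.null(samples)) panel <- subset_samples(panel, samples)
  chroms <- unique(panel$sites$chrom)
  if (length(chroms) < 2) stop("need at least two chromosomes", call. = FALSE)
  f <- alt_freq(panel)
  keep <- !is.nan(f) & pmin(f, 1 - f) >= maf
  if (!is.null(regions)) {
    keep <- keep & purrr::map_lgl(seq_len(n_sites(panel)), function(j) {
      any(regions$chrom == panel$sites$chrom[j] &
            regions$start <= panel$sites$pos[j] &
            panel$sites$pos[j] < regions$end)
    })
  }
  panel <- subset_sites(panel, keep)
  # deterministic thinning: first passing SNP per grid cell
  cell <- paste(panel$sites$chrom, panel$sites$pos %/% thin_bp)
  panel <- subset_sites(panel, !duplicated(cell))

  pairs <- list()
  for (i in seq_along(chroms)[-length(chroms)]) {
    for (j in seq((i + 1), length(chroms))) {
      ia <- which(panel$sites$chrom == chroms[i])
      ib <- which(panel$sites$chrom == chroms[j])
      if (!length(ia) || !length(ib)) next
      r2 <- suppressWarnings(
        stats::cor(panel$haplotypes[, ia, drop = FALSE],
                   panel$haplotypes[, ib, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      hit <- which(!is.na(r2) & r2 >= r2_min, arr.ind = TRUE)
      if (!nrow(hit)) next
      pairs[[length(pairs) + 1]] <- tibble::tibble(
        chrom_a = chroms[i], pos_a = panel$sites$pos[ia[hit[, 1]]],
        chrom_b = chroms[j], pos_b = panel$sites$pos[ib[hit[, 2]]],
        r2 = r2[hit])
    }
  }
  empty <- tibble::tibble(chrom_a = character(), start_a = numeric(),
                          end_a = numeric(), chrom_b = character(),
                          start_b = numeric(), end_b = numeric(),
                          n_pairs = integer(), max_r2 = numeric())
  if (!length(pairs)) return(empty)
  pr <- dplyr::bind_rows(pairs)
  # single-linkage clustering: union-find over SNP pairs
  parent <- seq_len(nrow(pr))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (key in unique(paste(pr$chrom_a, pr$chrom_b))) {
    idx <- which(paste(pr$chrom_a, pr$chrom_b) == key)
    for (u in seq_along(idx)[-1]) {
      for (v in seq_len(u - 1)) {
        iu <- idx[u]; iv <- idx[v]
        if (abs(pr$pos_a[iu] - pr$pos_a[iv]) <= merge_bp &&
            abs(pr$pos_b[iu] - pr$pos_b[iv]) <= merge_bp) {
          parent[find(iu)] <- find(iv)
        }
      }
    }
  }
  pr$comp <- vapply(seq_len(nrow(pr)), find, 1L)
  out <- pr |>
    dplyr::group_by(.data$comp) |>
    dplyr::summarise(chrom_a = .data$chrom_a[1],
                     start_a = min(.data$pos_a), end_a = max(.data$pos_a) + 1,
                     chrom_b = .data$chrom_b[1],
                     start_b = min(.data$pos_b), end_b = max(.data$pos_b) + 1,
                     n_pairs = dplyr::n(), max_r2 = max(.data$r2),
                     .groups = "drop") |>
    dplyr::select(-"comp") |>
    dplyr::filter(.data$end_a - .data$start_a >= min_width,
                  .data$end_b - .data$start_b >= min_width)
  if (!nrow(out)) return(empty)
  dplyr::arrange(out, .data$chrom_a, .data$start_a)
}

#' Private inter-chromosomal region pairs per group
#'
#' A region pair of group G is private when no other group has a pair whose
#' *both* sides overlap it (one-sided overlap leaves it private).
#'
#' @param pair_sets named list of [interchrom_ld()] outputs, one per group
#'   analysed with identical parameters.
#' @return named list of tibbles: each group's private pairs.
#' @export
private_pairs <- function(pair_sets) {
  stopifnot(length(pair_sets) >= 2)
  both_sides_overlap <- function(x, i, y) {
    if (!nrow(y)) return(FALSE)
    a_ov <- y$chrom_a == x$chrom_a[i] & y$start_a < x$end_a[i] &
      x$start_a[i] < y$end_a
    b_ov <- y$chrom_b == x$chrom_b[i] & y$start_b < x$end_b[i] &
      x$start_b[i] < y$end_b
    any(a_ov & b_ov)
  }
  purrr::imap(pair_sets, function(x, g) {
    if (!nrow(x)) return(x)
    others <- pair_sets[setdiff(names(pair_sets), g)]
    priv <- purrr::map_lgl(seq_len(nrow(x)), function(i) {
      !any(purrr::map_lgl(others, function(y) both_sides_overlap(x, i, y)))
    })
    x[priv, , drop = FALSE]
  })
}
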