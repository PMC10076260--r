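#' Phased haplotype panel
#'
#' The central container of the package: a phased, biallelic SNP panel held as
#' a haplotype-by-site matrix plus a site table. Coordinates are 0-based
#' half-open internally; VCF input is converted on read and back on write.
#'
#' @param haplotypes integer matrix, `2 * n_samples` rows (two consecutive rows
#'   per sample) by `n_sites` columns, entries 0 (ref), 1 (alt) or `NA`
#'   (missing).
#' @param sites tibble with columns `chrom`, `pos` (0-based bp), `ref`, `alt`
#'   and optionally `qual` (site quality) and `depth` (global site depth).
#' @param sample_ids character vector of sample names, length `nrow(haplotypes)/2`.
#' @param phased logical flag; unphased input is carried but flagged.
#' @param gt_depth optional `n_samples x n_sites` matrix of per-genotype read
#'   depths.
#'
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(haplotypes, sites, sample_ids, phased = TRUE,
                      gt_depth = NULL) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  sites <- tibble::as_tibble(sites)
  stopifnot(is.character(sample_ids))
  if (nrow(haplotypes) != 2L * length(sample_ids)) {
    stop("haplotype matrix must have exactly 2 rows per sample", call. = FALSE)
  }
  if (ncol(haplotypes) != nrow(sites)) {
    stop("haplotype matrix and site table disagree on the number of sites",
         call. = FALSE)
  }
  bad <- haplotypes[!is.na(haplotypes)]
  if (length(bad) && !all(bad %in% c(0L, 1L))) {
    stop("allele codes must be 0, 1 or NA", call. = FALSE)
  }
  ord_ok <- sites |>
    dplyr::mutate(.i = dplyr::row_number()) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      sorted = all(diff(.data$pos) > 0) || dplyr::n() == 1L,
      contig = all(diff(.data$.i) == 1L) || dplyr::n() == 1L,
      .groups = "drop"
    )
  if (!all(ord_ok$sorted) || !all(ord_ok$contig)) {
    stop("site positions must be strictly increasing and contiguous within ",
         "each chromosome", call. = FALSE)
  }
  rownames(haplotypes) <- hap_ids(sample_ids)
  structure(
    list(haplotypes = haplotypes, sites = sites, sample_ids = sample_ids,
         phased = isTRUE(phased), gt_depth = gt_depth),
    class = "hap_panel"
  )
}

#' Haplotype identifiers for a set of samples
#'
#' Two haplotypes per sample, suffixed `_1` and `_2`.
#' @param sample_ids character vector of sample names.
#' @return character vector of length `2 * length(sample_ids)`.
#' @export
hap_ids <- function(sample_ids) {
  as.vector(rbind(paste0(sample_ids, "_1"), paste0(sample_ids, "_2")))
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("<hap_panel> %d samples (%d haplotypes) x %d sites on %d chromosome(s); %s\n",
              length(x$sample_ids), nrow(x$haplotypes), n_sites(x),
              length(unique(x$sites$chrom)),
              if (x$phased) "phased" else "unphased"))
  invisible(x)
}

#' Number of sites in a panel
#' @param panel a `hap_panel`.
#' @return integer site count.
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' Number of samples in a panel
#' @param panel a `hap_panel`.
#' @return integer sample count.
#' @export
n_samples <- function(panel) length(panel$sample_ids)

#' Subset a panel by site index
#'
#' @param panel a `hap_panel`.
#' @param keep logical or integer index over sites.
#' @return a `hap_panel` restricted to the kept sites.
#' @export
subset_sites <- function(panel, keep) {
  if (is.logical(keep)) keep <- which(keep)
  hap_panel(panel$haplotypes[, keep, drop = FALSE],
            panel$sites[keep, , drop = FALSE],
            panel$sample_ids, panel$phased,
            gt_depth = if (!is.null(panel$gt_depth))
              panel$gt_depth[, keep, drop = FALSE] else NULL)
}

#' Subset a panel by sample
#'
#' @param panel a `hap_panel`.
#' @param samples character vector of sample ids to keep (order preserved).
#' @return a `hap_panel` with only those samples.
#' @export
subset_samples <- function(panel, samples) {
  idx <- match(samples, panel$sample_ids)
  if (anyNA(idx)) {
    stop("unknown sample(s): ", paste(samples[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  hap_panel(panel$haplotypes[rows, , drop = FALSE], panel$sites,
            samples, panel$phased,
            gt_depth = if (!is.null(panel$gt_depth))
              panel$gt_depth[idx, , drop = FALSE] else NULL)
}

#' Per-site alternate-allele frequency within a set of haplotype rows
#'
#' Computed over non-missing alleles only.
#' @param panel a `hap_panel`.
#' @param rows haplotype row indices (default all).
#' @return numeric vector of length `n_sites(panel)`; `NaN` where no
#'   non-missing allele is present.
#' @export
alt_freq <- function(panel, rows = seq_len(nrow(panel$haplotypes))) {
  h <- panel$haplotypes[rows, , drop = FALSE]
  colMeans(h, na.rm = TRUE)
}

#' Haplotype rows belonging to a set of samples
#' @param panel a `hap_panel`.
#' @param samples character sample ids.
#' @return integer row indices into `panel$haplotypes`.
#' @export
sample_rows <- function(panel, samples) {
  idx <- match(samples, panel$sample_ids)
  if (anyNA(idx)) {
    stop("unknown sample(s): ", paste(samples[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  as.vector(rbind(2L * idx - 1L, 2L * idx))
}

#' Chromosome lengths implied by a panel
#'
#' When true chromosome lengths are not supplied alongside a VCF the span is
#' taken as the last site position rounded up to the next window; generators
#' in this package carry exact lengths instead.
#' @param panel a `hap_panel`.
#' @param chrom_len optional named vector of known lengths (bp).
#' @return tibble with `chrom`, `length`.
#' @export
panel_chrom_lengths <- function(panel, chrom_len = NULL) {
  implied <- panel$sites |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(length = max(.data$pos) + 1, .groups = "drop")
  if (!is.null(chrom_len)) {
    implied$length <- unname(chrom_len[implied$chrom])
  }
  implied
}
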