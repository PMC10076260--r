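#' Merge genomic intervals
#'
#' bedtools-style merge on 0-based half-open intervals: two intervals are
#' joined when they overlap, touch, or are separated by at most `gap` bp.
#' Extra per-interval metadata is dropped; use [count_support()] to attach
#' support counts afterwards.
#'
#' @param regions tibble with `chrom`, `start`, `end`.
#' @param gap maximum separation (bp) still joined; 0 merges only
#'   overlapping/bookended intervals.
#' @return tibble of non-overlapping merged intervals sorted by
#'   `(chrom, start)`.
#' @export
merge_regions <- function(regions, gap = 0) {
  regions <- tibble::as_tibble(regions)[, c("chrom", "start", "end")]
  regions$start <- as.numeric(regions$start)
  regions$end <- as.numeric(regions$end)
  if (!nrow(regions)) return(regions)
  regions |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      .new = .data$start > dplyr::lag(cummax(.data$end), default = -Inf) + gap,
      .grp = cumsum(.data$.new)
    ) |>
    dplyr::group_by(.data$chrom, .data$.grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::select("chrom", "start", "end") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Expand point coordinates into fixed-width intervals
#'
#' bedtools slop semantics: each position becomes `[pos - slop, pos + slop)`
#' clipped to `[0, chrom_length)`. Positions are 0-based; the resulting
#' interval covers `2 * slop` bp when unclipped (the base itself sits at the
#' interval midpoint).
#'
#' @param points tibble with `chrom`, `pos`.
#' @param slop half-width in bp.
#' @param chrom_lengths tibble with `chrom`, `length`, or `NULL` for no upper
#'   clipping.
#' @return tibble with `chrom`, `start`, `end`, `pos`.
#' @export
slop_points <- function(points, slop, chrom_lengths = NULL) {
  out <- tibble::as_tibble(points) |>
    dplyr::mutate(start = pmax(.data$pos - slop, 0),
                  end = .data$pos + slop)
  if (!is.null(chrom_lengths)) {
    out <- out |>
      dplyr::left_join(chrom_lengths, by = "chrom") |>
      dplyr::mutate(end = pmin(.data$end, .data$length)) |>
      dplyr::select(-"length")
  }
  dplyr::select(out, "chrom", "start", "end", "pos")
}

#' Count supporting points per interval
#'
#' @param regions tibble with `chrom`, `start`, `end`.
#' @param points tibble with `chrom`, `pos` (0-based).
#' @return `regions` with an added `n_support` column (points with
#'   `start <= pos < end`).
#' @export
count_support <- function(regions, points) {
  if (!nrow(regions)) {
    regions$n_support <- integer()
    return(regions)
  }
  regions$n_support <- purrr::map2_int(
    seq_len(nrow(regions)), regions$chrom,
    function(i, chr) {
      sum(points$chrom == chr & points$pos >= regions$start[i] &
            points$pos < regions$end[i])
    })
  regions
}

#' Any-overlap test between two interval sets
#'
#' @param a,b tibbles with `chrom`, `start`, `end` (0-based half-open).
#' @return logical vector along `a`: does each interval of `a` overlap any
#'   interval of `b`?
#' @export
overlaps_any <- function(a, b) {
  if (!nrow(a)) return(logical())
  purrr::map_lgl(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end)
  })
}

#' Intersect two interval sets (regions of `a` overlapping `b`)
#'
#' @param a,b tibbles with `chrom`, `start`, `end`.
#' @return the rows of `a` overlapping at least one interval of `b`.
#' @export
filter_overlapping <- function(a, b) {
  a[overlaps_any(a, b), , drop = FALSE]
}
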