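#' Genepool of a donor-group label
#'
#' `AM_A*` races belong to the Andean genepool, `AM_M*` to the Mesoamerican;
#' `"unknown"` maps to `NA`.
#' @param label character vector of window / group labels.
#' @return character vector of `"AND"`, `"MES"` or `NA`.
#' @export
label_genepool <- function(label) {
  out <- rep(NA_character_, length(label))
  out[grepl("^AM_A", label)] <- "AND"
  out[grepl("^AM_M", label)] <- "MES"
  out
}

#' Assign 10-kb ancestry windows from per-SNP painting probabilities
#'
#' Per-SNP donor-group probabilities are combined by averaging within
#' non-overlapping windows along each chromosome; a window is labelled with
#' its argmax group only when that group's mean probability reaches
#' `prob`, otherwise `"unknown"`. Windows containing no SNP are `"unknown"`.
#' The final partial window of each chromosome is kept.
#'
#' @param painting a `painting` from [paint_panel()].
#' @param chrom_lengths tibble `chrom`, `length` (bp).
#' @param window_bp window size (default 10 kb).
#' @param prob assignment probability threshold (default 0.8).
#' @return an `ancestry_windows` tibble: `hap_id`, `sample_id`, `chrom`,
#'   `start`, `end`, `n_snps`, `label`, `max_prob`, `genepool`.
#' @export
assign_windows <- function(painting, chrom_lengths, window_bp = 10000,
                           prob = 0.8) {
  sites <- painting$sites
  skel <- purrr::map_dfr(seq_len(nrow(chrom_lengths)), function(i) {
    len <- chrom_lengths$length[i]
    starts <- seq(0, len - 1, by = window_bp)
    tibble::tibble(chrom = chrom_lengths$chrom[i], start = starts,
                   end = pmin(starts + window_bp, len),
                   win = seq_along(starts))
  })
  # site -> window key
  site_key <- paste(sites$chrom, sites$pos %/% window_bp + 1L)
  skel_key <- paste(skel$chrom, skel$win)
  groups <- painting$groups

  out <- purrr::imap_dfr(painting$prob, function(p, id) {
    sums <- rowsum(p, site_key)
    cnt <- as.vector(table(site_key)[rownames(sums)])
    means <- sums / cnt
    idx <- match(skel_key, rownames(means))
    mp <- matrix(NA_real_, nrow = nrow(skel), ncol = length(groups))
    mp[!is.na(idx), ] <- means[idx[!is.na(idx)], , drop = FALSE]
    best <- max.col(replace(mp, is.na(mp), -1), ties.method = "first")
    max_prob <- mp[cbind(seq_len(nrow(skel)), best)]
    n_snps <- integer(nrow(skel))
    n_snps[!is.na(idx)] <- cnt[idx[!is.na(idx)]]
    label <- ifelse(!is.na(max_prob) & max_prob >= prob, groups[best],
                    "unknown")
    tibble::tibble(hap_id = id,
                   sample_id = sub("_[12]$", "", id),
                   chrom = skel$chrom, start = skel$start, end = skel$end,
                   n_snps = n_snps, label = label,
                   max_prob = ifelse(is.na(max_prob), NA_real_, max_prob))
  })
  out$genepool <- label_genepool(out$label)
  class(out) <- c("ancestry_windows", class(out))
  out
}

#' Call the genepool of each recipient accession
#'
#' Two criteria, following the window map over both haplotypes: (a) the
#' total proportion of assigned windows attributed to the Andean vs
#' Mesoamerican genepool, and (b) the per-chromosome majority vote. The call
#' is made when both criteria agree, otherwise the accession is flagged
#' ambiguous.
#'
#' @param window_map an `ancestry_windows` tibble from [assign_windows()].
#' @return tibble per accession: `sample_id`, `call` (`EU_AND` / `EU_MES` /
#'   `NA` when ambiguous), `ambiguous`, `and_prop`, `mes_prop`,
#'   `unknown_prop`, `chrom_and`, `chrom_mes`.
#' @export
call_genepool <- function(window_map) {
  if (all(window_map$label == "unknown")) {
    stop("unassignable: every window is labelled unknown", call. = FALSE)
  }
  per_chrom <- window_map |>
    dplyr::filter(!is.na(.data$genepool)) |>
    dplyr::count(.data$sample_id, .data$chrom, .data$genepool) |>
    tidyr::pivot_wider(names_from = "genepool", values_from = "n",
                       values_fill = 0)
  for (col in c("AND", "MES")) {
    if (!col %in% names(per_chrom)) per_chrom[[col]] <- 0
  }
  votes <- per_chrom |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(chrom_and = sum(.data$AND > .data$MES),
                     chrom_mes = sum(.data$MES > .data$AND),
                     .groups = "drop")
  props <- window_map |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      and_prop = sum(.data$genepool == "AND", na.rm = TRUE) /
        max(sum(!is.na(.data$genepool)), 1L),
      mes_prop = sum(.data$genepool == "MES", na.rm = TRUE) /
        max(sum(!is.na(.data$genepool)), 1L),
      unknown_prop = mean(.data$label == "unknown"),
      .groups = "drop")
  out <- dplyr::left_join(props, votes, by = "sample_id") |>
    dplyr::mutate(
      chrom_and = dplyr::coalesce(.data$chrom_and, 0L),
      chrom_mes = dplyr::coalesce(.data$chrom_mes, 0L),
      call_a = dplyr::case_when(.data$and_prop > .data$mes_prop ~ "EU_AND",
                                .data$mes_prop > .data$and_prop ~ "EU_MES",
                                TRUE ~ NA_character_),
      call_b = dplyr::case_when(.data$chrom_and > .data$chrom_mes ~ "EU_AND",
                                .data$chrom_mes > .data$chrom_and ~ "EU_MES",
                                TRUE ~ NA_character_),
      ambiguous = is.na(.data$call_a) | is.na(.data$call_b) |
        .data$call_a != .data$call_b,
      call = ifelse(.data$ambiguous, NA_character_, .data$call_a)
    ) |>
    dplyr::select("sample_id", "call", "ambiguous", "and_prop", "mes_prop",
                  "unknown_prop", "chrom_and", "chrom_mes")
  out
}

#' Extract introgression blocks from the window map
#'
#' For each haplotype of an accession with an unambiguous genepool call,
#' windows attributed to any race of the *other* genepool are merged when
#' consecutive; runs separated by at most `gap_bp` (bridging unknown or
#' same-genepool windows, which do not count toward support) are joined; and
#' blocks supported by fewer than `min_windows` other-genepool windows are
#' dropped. Accessions flagged ambiguous are skipped.
#'
#' @param window_map an `ancestry_windows` tibble.
#' @param genepool_calls output of [call_genepool()].
#' @param gap_bp maximum joined gap (default 50 kb).
#' @param min_windows minimum supporting windows per block (default 2, i.e.
#'   single-window blocks removed).
#' @return list with `blocks` (tibble `hap_id`, `sample_id`, `chrom`,
#'   `start`, `end`, `length`, `ancestry`, `n_windows`) and `summary`
#'   (per-accession median block length over both haplotypes, `NA` when an
#'   accession carries no block).
#' @export
extract_blocks <- function(window_map, genepool_calls, gap_bp = 50000,
                           min_windows = 2) {
  calls <- genepool_calls |> dplyr::filter(!.data$ambiguous)
  blocks <- purrr::map_dfr(seq_len(nrow(calls)), function(i) {
    sid <- calls$sample_id[i]
    own <- sub("EU_", "", calls$call[i])
    other <- setdiff(c("AND", "MES"), own)
    wm <- window_map[window_map$sample_id == sid, ]
    purrr::map_dfr(split(wm, wm$hap_id), function(w) {
      cand <- w[!is.na(w$genepool) & w$genepool == other, ]
      if (!nrow(cand)) return(NULL)
      merged <- merge_regions(cand[, c("chrom", "start", "end")], gap = gap_bp)
      merged <- count_support(
        merged, tibble::tibble(chrom = cand$chrom,
                               pos = (cand$start + cand$end) / 2))
      merged <- merged[merged$n_support >= min_windows, , drop = FALSE]
      if (!nrow(merged)) return(NULL)
      tibble::tibble(hap_id = w$hap_id[1], sample_id = sid,
                     chrom = merged$chrom, start = merged$start,
                     end = merged$end, length = merged$end - merged$start,
                     ancestry = other, n_windows = merged$n_support)
    })
  })
  if (!nrow(blocks)) {
    blocks <- tibble::tibble(hap_id = character(), sample_id = character(),
                             chrom = character(), start = numeric(),
                             end = numeric(), length = numeric(),
                             ancestry = character(), n_windows = integer())
  }
  summary <- calls |>
    dplyr::select("sample_id", "call") |>
    dplyr::left_join(
      blocks |>
        dplyr::group_by(.data$sample_id) |>
        dplyr::summarise(n_blocks = dplyr::n(),
                         median_length = stats::median(.data$length),
                         .groups = "drop"),
      by = "sample_id") |>
    dplyr::mutate(n_blocks = dplyr::coalesce(.data$n_blocks, 0L))
  list(blocks = blocks, summary = summary)
}

#' Ancestry-mask a recipient panel
#'
#' Produces the two masked datasets: in the Andean-masked panel an allele
#' survives only where its haplotype's window is labelled an Andean race
#' (Mesoamerican and ambiguous/unknown material set to missing), and
#' conversely for the Mesoamerican-masked panel. Masking is idempotent.
#'
#' @param panel recipient [hap_panel()] (the haplotypes the map was built on).
#' @param window_map an `ancestry_windows` tibble covering `panel`.
#' @return list with `and_masked` and `mes_masked` panels.
#' @export
mask_introgression <- function(panel, window_map) {
  mask_one <- function(keep_pool) {
    h <- panel$haplotypes
    ids <- rownames(h)
    for (hid in unique(window_map$hap_id)) {
      row <- match(hid, ids)
      if (is.na(row)) next
      w <- window_map[window_map$hap_id == hid, ]
      drop <- w[is.na(w$genepool) | w$genepool != keep_pool, ]
      for (ch in unique(drop$chrom)) {
        d <- drop[drop$chrom == ch, ]
        si <- which(panel$sites$chrom == ch)
        pos <- panel$sites$pos[si]
        hit <- purrr::reduce(purrr::map(seq_len(nrow(d)), function(j)
          pos >= d$start[j] & pos < d$end[j]), `|`)
        h[row, si[hit]] <- NA_integer_
      }
    }
    hap_panel(h, panel$sites, panel$sample_ids, panel$phased,
              gt_depth = panel$gt_depth)
  }
  list(and_masked = mask_one("AND"), mes_masked = mask_one("MES"))
}
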