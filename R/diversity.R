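#' Per-site and regional nucleotide diversity (theta-pi)
#'
#' Per-site diversity is the average number of pairwise differences between
#' non-missing alleles: with `n` non-missing alleles of which `k` carry the
#' alternate, `pi = 2 k (n - k) / (n (n - 1))`, equivalently
#' `2 p q n / (n - 1)`. Regional estimates sum per-site values over the
#' region and divide by its span in bp; sites with fewer than two non-missing
#' alleles are skipped and counted. Sites whose proportion of non-masked
#' individuals (PIND) falls below `min_pind` are excluded, which is how
#' masked datasets are summarised at varying missingness levels.
#'
#' @param panel a [hap_panel()] (possibly ancestry-masked).
#' @param samples optional sample subset.
#' @param regions optional tibble `chrom`, `start`, `end` and optional `name`
#'   (0-based half-open); defaults to whole chromosomes.
#' @param chrom_lengths tibble `chrom`, `length`; inferred from the panel
#'   when `NULL`.
#' @param min_pind minimum proportion of individuals with at least one
#'   non-missing allele for a site to contribute (0..1).
#' @param window_bp width of the emitted diversity track (default 100 kb).
#' @return list with `per_site` (tibble `chrom`, `pos`, `pi`, `n_alleles`,
#'   `pind`), `windows` (theta-pi per bp over `window_bp` windows),
#'   `regions` (per-region theta-pi per bp) and `n_skipped`.
#' @export
theta_pi <- function(panel, samples = NULL, regions = NULL,
                     chrom_lengths = NULL, min_pind = 0,
                     window_bp = 100000) {
  if (!is.null(samples)) panel <- subset_samples(panel, samples)
  if (is.null(chrom_lengths)) chrom_lengths <- panel_chrom_lengths(panel)
  h <- panel$haplotypes
  n <- colSums(!is.na(h))
  k <- colSums(h, na.rm = TRUE)
  pi <- ifelse(n >= 2, 2 * k * (n - k) / (n * pmax(n - 1, 1)), NA_real_)
  n_ind <- n_samples(panel)
  a1 <- h[seq(1, nrow(h), 2), , drop = FALSE]
  a2 <- h[seq(2, nrow(h), 2), , drop = FALSE]
  pind <- colSums(!is.na(a1) | !is.na(a2)) / n_ind
  per_site <- tibble::tibble(chrom = panel$sites$chrom, pos = panel$sites$pos,
                             pi = pi, n_alleles = n, pind = pind)
  n_skipped <- sum(n < 2)
  use <- !is.na(pi) & pind >= min_pind

  ps <- per_site[use, ]
  windows <- purrr::map_dfr(seq_len(nrow(chrom_lengths)), function(i) {
    ch <- chrom_lengths$chrom[i]; len <- chrom_lengths$length[i]
    starts <- seq(0, len - 1, by = window_bp)
    ends <- pmin(starts + window_bp, len)
    x <- ps[ps$chrom == ch, ]
    wi <- x$pos %/% window_bp + 1L
    s <- rep(0, length(starts))
    if (nrow(x)) {
      agg <- rowsum(x$pi, wi)
      s[as.integer(rownames(agg))] <- agg[, 1]
    }
    tibble::tibble(chrom = ch, start = starts, end = ends,
                   theta_pi = s / (ends - starts))
  })
  if (is.null(regions)) {
    regions <- chrom_lengths |>
      dplyr::transmute(chrom = .data$chrom, start = 0, end = .data$length,
                       name = .data$chrom)
  }
  regions <- tibble::as_tibble(regions)
  if (!"name" %in% names(regions)) {
    regions$name <- sprintf("%s:%d-%d", regions$chrom, regions$start,
                            regions$end)
  }
  if (any(regions$end <= regions$start)) {
    stop("region length must be positive", call. = FALSE)
  }
  region_est <- regions |>
    dplyr::mutate(theta_pi_bp = purrr::map_dbl(seq_len(dplyr::n()), function(i) {
      x <- ps[ps$chrom == regions$chrom[i] & ps$pos >= regions$start[i] &
                ps$pos < regions$end[i], ]
      sum(x$pi) / (regions$end[i] - regions$start[i])
    }))
  list(per_site = per_site, windows = windows, regions = region_est,
       n_skipped = n_skipped)
}

#' Private-allele spectrum between two continental groups
#'
#' A variant is private to a continental group when it segregates there
#' (non-zero frequency over non-missing alleles) while being absent
#' (frequency zero, with at least one non-missing allele observed) in the
#' other. Private variants are split at the `freq_split` within-group
#' frequency into low and medium-high bins, and into synonymous vs
#' non-synonymous (missense + loss-of-function) classes.
#'
#' @param panel a [hap_panel()].
#' @param groups tibble `sample_id`, `continent` (two levels, e.g. `AM`/`EU`).
#' @param annotation tibble `chrom`, `pos`, `effect`, `gene_id` as from
#'   [simulate_annotation()].
#' @param freq_split frequency bin boundary (default 0.05; `< split` is low).
#' @return list with `spectrum` (tibble `continent`, `bin`, `class`, `n`),
#'   `ratios` (non-synonymous / synonymous count ratio per continent and
#'   bin) and `per_gene` (private-variant burden per gene and class).
#' @export
private_allele_spectrum <- function(panel, groups, annotation,
                                    freq_split = 0.05) {
  conts <- sort(unique(groups$continent))
  stopifnot(length(conts) == 2)
  rows <- lapply(conts, function(ct)
    sample_rows(panel, groups$sample_id[groups$continent == ct]))
  freq <- sapply(rows, function(r) alt_freq(panel, r))
  nonmiss <- sapply(rows, function(r)
    colSums(!is.na(panel$haplotypes[r, , drop = FALSE])))
  colnames(freq) <- colnames(nonmiss) <- conts

  ann <- dplyr::left_join(panel$sites[, c("chrom", "pos")],
                          annotation, by = c("chrom", "pos"))
  cls <- dplyr::case_when(
    ann$effect == "synonymous" ~ "synonymous",
    ann$effect %in% c("missense", "loss_of_function") ~ "nonsynonymous",
    TRUE ~ NA_character_)

  res <- list()
  for (ct in conts) {
    other <- setdiff(conts, ct)
    priv <- freq[, ct] > 0 & !is.na(freq[, other]) & freq[, other] == 0 &
      nonmiss[, other] > 0
    f <- freq[, ct]
    res[[ct]] <- tibble::tibble(
      continent = ct, idx = which(priv),
      freq = f[priv],
      bin = ifelse(f[priv] < freq_split, "low", "medium_high"),
      class = cls[priv], gene_id = ann$gene_id[priv])
  }
  priv_tbl <- dplyr::bind_rows(res) |> dplyr::filter(!is.na(.data$class))
  spectrum <- priv_tbl |>
    dplyr::count(.data$continent, .data$bin, .data$class, name = "n") |>
    tidyr::complete(continent = conts, bin = c("low", "medium_high"),
                    class = c("synonymous", "nonsynonymous"),
                    fill = list(n = 0L))
  ratios <- spectrum |>
    tidyr::pivot_wider(names_from = "class", values_from = "n") |>
    dplyr::mutate(nonsyn_syn_ratio = ifelse(.data$synonymous > 0,
                                            .data$nonsynonymous / .data$synonymous,
                                            NA_real_))
  per_gene <- priv_tbl |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::count(.data$continent, .data$gene_id, .data$class, name = "n")
  list(spectrum = spectrum, ratios = ratios, per_gene = per_gene)
}
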