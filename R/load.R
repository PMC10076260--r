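#' Per-accession genetic-load summary and group comparisons
#'
#' Counts non-reference alleles per accession within each effect class
#' (alt-allele dosage over both haplotypes by default, presence/absence by
#' flag; missing genotypes contribute 0) and forms the two load ratios:
#' missense / synonymous and loss-of-function / synonymous, `NA` when the
#' synonymous count is zero. Groups are then compared pairwise on each ratio
#' with a two-sided Wilcoxon rank-sum test (exact for group sizes up to 20,
#' normal approximation with tie correction otherwise).
#'
#' @param panel a [hap_panel()].
#' @param annotation tibble `chrom`, `pos`, `effect`.
#' @param groups tibble `sample_id`, `group`; every group must be non-empty.
#' @param dosage count alt-allele dosage (default) or presence when `FALSE`.
#' @return list with `per_accession` (counts + ratios + group) and `tests`
#'   (tibble `ratio`, `group1`, `group2`, `statistic`, `p_value`).
#' @export
genetic_load <- function(panel, annotation, groups, dosage = TRUE) {
  if (!nrow(groups) || any(table(factor(groups$group)) == 0)) {
    stop("empty group in group assignment", call. = FALSE)
  }
  ann <- dplyr::left_join(panel$sites[, c("chrom", "pos")], annotation,
                          by = c("chrom", "pos"))
  classes <- c("synonymous", "missense", "loss_of_function")
  h <- panel$haplotypes
  h[is.na(h)] <- 0L
  n <- n_samples(panel)
  geno <- h[seq(1, 2 * n, 2), , drop = FALSE] + h[seq(2, 2 * n, 2), , drop = FALSE]
  if (!dosage) geno <- (geno > 0) + 0L
  counts <- sapply(classes, function(cl) {
    idx <- which(!is.na(ann$effect) & ann$effect == cl)
    if (!length(idx)) return(rep(0, n))
    rowSums(geno[, idx, drop = FALSE])
  })
  per_acc <- tibble::tibble(sample_id = panel$sample_ids,
                            synonymous = unname(counts[, "synonymous"]),
                            missense = unname(counts[, "missense"]),
                            loss_of_function =
                              unname(counts[, "loss_of_function"])) |>
    dplyr::mutate(
      missense_syn = ifelse(.data$synonymous > 0,
                            .data$missense / .data$synonymous, NA_real_),
      lof_syn = ifelse(.data$synonymous > 0,
                       .data$loss_of_function / .data$synonymous, NA_real_)) |>
    dplyr::inner_join(groups[, c("sample_id", "group")], by = "sample_id")

  gl <- sort(unique(per_acc$group))
  pairs <- if (length(gl) >= 2) utils::combn(gl, 2, simplify = FALSE) else list()
  tests <- purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(c("missense_syn", "lof_syn"), function(rt) {
      x <- per_acc[[rt]][per_acc$group == pr[1]]
      y <- per_acc[[rt]][per_acc$group == pr[2]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (!length(x) || !length(y)) {
        return(tibble::tibble(ratio = rt, group1 = pr[1], group2 = pr[2],
                              statistic = NA_real_, p_value = NA_real_))
      }
      if (max(c(x, y)) == min(c(x, y))) {
        # no variation at all: the two samples are indistinguishable
        return(tibble::tibble(ratio = rt, group1 = pr[1], group2 = pr[2],
                              statistic = length(x) * length(y) / 2,
                              p_value = 1))
      }
      exact <- length(x) <= 20 && length(y) <= 20 &&
        !any(duplicated(c(x, y)))
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                                correct = !exact))
      tibble::tibble(ratio = rt, group1 = pr[1], group2 = pr[2],
                     statistic = unname(wt$statistic), p_value = wt$p.value)
    })
  })
  list(per_accession = per_acc, tests = tests)
}
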