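#' Broad-sense heritability per trait
#'
#' Random-effects variance decomposition by the ANOVA method of moments:
#' genotype (and environment, when an `env` column with more than one level
#' is present) enter as random effects and components are estimated from
#' expected mean squares, truncated at zero. Broad-sense heritability is
#' `H2 = s2_G / (s2_G + s2_env + s2_res)`. A trait observed with a single
#' replicate in a single environment is `NA`.
#'
#' @param traits tibble `sample_id`, `trait`, `rep`, `value` and optional
#'   `env`.
#' @return tibble per trait: `trait`, `sigma2_g`, `sigma2_env`,
#'   `sigma2_res`, `h2`, `n_genotypes`.
#' @export
broad_heritability <- function(traits) {
  purrr::map_dfr(split(traits, traits$trait), function(tt) {
    tt <- tt[!is.na(tt$value), ]
    has_env <- "env" %in% names(tt) && length(unique(tt$env)) > 1
    n_g <- length(unique(tt$sample_id))
    reps <- table(tt$sample_id)
    if (!has_env && all(reps <= 1)) {
      return(tibble::tibble(trait = tt$trait[1], sigma2_g = NA_real_,
                            sigma2_env = NA_real_, sigma2_res = NA_real_,
                            h2 = NA_real_, n_genotypes = n_g))
    }
    g <- factor(tt$sample_id)
    if (has_env) {
      e <- factor(tt$env)
      fit <- stats::aov(value ~ g + e, data = tt)
      ms <- summary(fit)[[1]][["Mean Sq"]]
      names(ms) <- trimws(rownames(summary(fit)[[1]]))
      ms_res <- ms[["Residuals"]]
      k_g <- nrow(tt) / n_g          # observations per genotype (balanced)
      k_e <- nrow(tt) / length(unique(tt$env))
      s2_g <- max((ms[["g"]] - ms_res) / k_g, 0)
      s2_e <- max((ms[["e"]] - ms_res) / k_e, 0)
    } else {
      fit <- stats::aov(value ~ g, data = tt)
      ms <- summary(fit)[[1]][["Mean Sq"]]
      ms_res <- ms[2]
      N <- nrow(tt)
      k_g <- (N - sum(reps^2) / N) / (n_g - 1)
      s2_g <- max((ms[1] - ms_res) / k_g, 0)
      s2_e <- 0
    }
    s2_res <- max(ms_res, 0)
    tibble::tibble(trait = tt$trait[1], sigma2_g = s2_g, sigma2_env = s2_e,
                   sigma2_res = s2_res,
                   h2 = s2_g / (s2_g + s2_e + s2_res),
                   n_genotypes = n_g)
  })
}

#' Photoperiod sensitivity from long- and short-day flowering
#'
#' `PS = DTF_longday / DTF_shortday`; values near 1 mean photoperiod
#' insensitivity. An accession that never flowered under long days (missing
#' `dtf_longday` with an observed short-day value) is `NA` with the
#' `delayed_or_no_flowering` flag set.
#'
#' @param dtf_longday,dtf_shortday days-to-flowering vectors (> 0; `NA`
#'   allowed).
#' @return tibble `ps`, `delayed_or_no_flowering`.
#' @export
photoperiod_sensitivity <- function(dtf_longday, dtf_shortday) {
  stopifnot(length(dtf_longday) == length(dtf_shortday))
  bad_sd <- is.na(dtf_shortday) | dtf_shortday <= 0
  ps <- ifelse(bad_sd | is.na(dtf_longday), NA_real_,
               dtf_longday / dtf_shortday)
  tibble::tibble(ps = ps,
                 delayed_or_no_flowering = is.na(dtf_longday) & !bad_sd)
}

#' First principal component of a trait matrix
#'
#' Traits are standardised to zero mean and unit variance; missing entries
#' are mean-imputed (count reported). PC1 is oriented to correlate
#' positively with the first input trait.
#'
#' @param trait_matrix numeric matrix or data frame, accessions x traits
#'   (>= 2 traits).
#' @return list with `scores` (PC1 per accession), `var_explained`
#'   (fraction), `n_imputed`.
#' @export
trait_pc1 <- function(trait_matrix) {
  x <- as.matrix(trait_matrix)
  if (ncol(x) < 2) stop("at least two traits are required", call. = FALSE)
  n_imp <- sum(is.na(x))
  x <- scale(x)
  x[is.na(x)] <- 0  # mean imputation post-standardisation
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  if (!is.na(stats::cor(scores, x[, 1])) && stats::cor(scores, x[, 1]) < 0) {
    scores <- -scores
  }
  list(scores = scores,
       var_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
       n_imputed = n_imp)
}

#' QST from accession-level genotypic values
#'
#' One-way random-effects decomposition on replicate means: the
#' between-group component `s2_B` comes from the group mean square via the
#' effective group size, the within-group component `s2_W` is the residual
#' mean square; negative estimates are truncated to zero. The default
#' convention is `QST = s2_B / (s2_B + 2 s2_W)` (outcrossing); with
#' `selfing = TRUE` the denominator drops the factor 2, apt for fully
#' inbred lines.
#'
#' @param traits tibble `sample_id`, `value` (replicates allowed; averaged)
#'   and optionally `trait` (single trait expected).
#' @param groups tibble `sample_id`, `group` (2+ groups, >= 3 accessions
#'   each).
#' @param selfing use the inbred-lineage denominator.
#' @return a `qst_fit` list: `sigma2_b`, `sigma2_w`, `qst`, `convention`,
#'   `n_groups`.
#' @export
qst <- function(traits, groups, selfing = FALSE) {
  means <- traits |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::inner_join(groups[, c("sample_id", "group")], by = "sample_id")
  cnt <- table(means$group)
  if (length(cnt) < 2 || any(cnt < 3)) {
    stop("need >= 2 groups with >= 3 accessions each", call. = FALSE)
  }
  fit <- stats::aov(value ~ group, data = means)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  a <- length(cnt); N <- nrow(means)
  n0 <- (N - sum(cnt^2) / N) / (a - 1)
  s2_w <- ms[2]
  s2_b <- max((ms[1] - s2_w) / n0, 0)
  denom <- s2_b + (if (selfing) 1 else 2) * s2_w
  structure(list(sigma2_b = s2_b, sigma2_w = s2_w,
                 qst = if (denom > 0) s2_b / denom else 0,
                 convention = if (selfing) "selfing" else "outcrossing",
                 n_groups = a),
            class = "qst_fit")
}

#' @export
print.qst_fit <- function(x, ...) {
  cat(sprintf("<qst_fit> QST = %.4f (s2_B = %.4f, s2_W = %.4f, %s convention, %d groups)\n",
              x$qst, x$sigma2_b, x$sigma2_w, x$convention, x$n_groups))
  invisible(x)
}

#' Tidy a QST fit
#' @param x a `qst_fit`.
#' @param ... unused.
#' @return one-row tibble of components and the QST estimate.
#' @method tidy qst_fit
#' @export
tidy.qst_fit <- function(x, ...) {
  tibble::tibble(sigma2_b = x$sigma2_b, sigma2_w = x$sigma2_w, qst = x$qst,
                 convention = x$convention, n_groups = x$n_groups)
}

#' @rdname tidy.qst_fit
#' @method glance qst_fit
#' @export
glance.qst_fit <- function(x, ...) tidy.qst_fit(x)

#' QST outlier test against reference distributions
#'
#' Places the focal trait's QST within the empirical distribution of
#' reference (metabolite) QST values filtered to high heritability, and
#' within a per-SNP FST distribution, using the `<=` empirical percentile.
#' The selection-candidate verdict fires when the focal QST reaches the
#' 97.5th percentile of the metabolite reference.
#'
#' @param qst_focal focal trait QST (scalar).
#' @param qst_reference numeric vector of reference QST values (already
#'   H2-filtered); fewer than 20 triggers a wide-interval warning.
#' @param fst_values numeric vector of per-SNP FST values (NA dropped).
#' @param percentile_call verdict percentile (default 97.5).
#' @return tibble `qst_focal`, `pct_metabolite`, `pct_fst`, `verdict`,
#'   `n_reference`.
#' @export
qst_outlier_test <- function(qst_focal, qst_reference, fst_values,
                             percentile_call = 97.5) {
  qst_reference <- qst_reference[!is.na(qst_reference)]
  if (length(qst_reference) < 20) {
    warning("fewer than 20 reference traits: percentile is wide-interval")
  }
  fst_values <- fst_values[!is.na(fst_values)]
  pct_met <- 100 * mean(qst_reference <= qst_focal)
  pct_fst <- if (length(fst_values)) 100 * mean(fst_values <= qst_focal)
  else NA_real_
  tibble::tibble(qst_focal = qst_focal, pct_metabolite = pct_met,
                 pct_fst = pct_fst,
                 verdict = ifelse(pct_met >= percentile_call,
                                  "selection-candidate", "no-call"),
                 n_reference = length(qst_reference))
}
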