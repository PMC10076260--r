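#' hapFLK-style haplotype-cluster selection statistic
#'
#' Fits a fastPHASE-style haplotype-cluster hidden Markov model (K clusters,
#' per-site cluster allele frequencies and weights, distance-dependent jump
#' probability tied across clusters) to the phased panel by EM, then at each
#' SNP replaces allele frequencies with per-population cluster frequencies
#' in a summed FLK-type quadratic form over the K clusters. Because the EM
#' fit is multimodal the statistic is averaged over `n_fits` independent
#' fits from distinct random starts (seeds derived from the session RNG, so
#' a fixed seed gives bit-identical output). Chromosomes are fitted
#' independently (a chromosome break forces a jump).
#'
#' @param panel phased [hap_panel()].
#' @param groups tibble `sample_id`, `group`; all listed samples are used.
#' @param Fm population kinship matrix (rows/cols sorted group names).
#' @param K number of haplotype clusters (>= 2).
#' @param n_fits independent EM fits to average (default 20).
#' @param max_iter,tol EM cap and log-likelihood convergence tolerance.
#' @param rho_init initial per-bp jump intensity.
#' @return tibble `chrom`, `pos`, `hapflk` (the averaged statistic),
#'   `n_fits_used`.
#' @export
hapflk <- function(panel, groups, Fm, K = 5, n_fits = 20,
                   max_iter = 100, tol = 1e-4, rho_init = 1e-6) {
  stopifnot(K >= 2)
  gl <- sort(unique(groups$group))
  stopifnot(identical(rownames(Fm), gl))
  panel <- subset_samples(panel, groups$sample_id)
  hmat <- panel$haplotypes
  pop_of_sample <- groups$group[match(panel$sample_ids, groups$sample_id)]
  pop <- match(rep(pop_of_sample, each = 2L), gl) - 1L
  dist <- site_dists(panel$sites)
  L <- n_sites(panel)
  r <- length(gl)
  Finv <- solve(Fm)
  w <- Finv %*% rep(1, r)
  sw <- sum(w)
  base_freq <- alt_freq(panel)

  acc <- matrix(0, nrow = L, ncol = 1)
  used <- 0L
  for (fit in seq_len(n_fits)) {
    init <- cluster_init(base_freq, K)
    em <- cluster_hmm_em(hmat, dist, init$theta, init$alpha, rho_init, pop,
                         n_pop = r, max_iter = max_iter, tol = tol,
                         return_gamma = FALSE)
    if (!all(is.finite(em$loglik))) {
      warning("EM fit ", fit, " did not produce a finite likelihood; excluded")
      next
    }
    q <- array(em$pop_freq, dim = c(r, K, L))
    Tsum <- numeric(L)
    for (k in seq_len(K)) {
      Q <- q[, k, , drop = TRUE]
      if (r == 1) Q <- matrix(Q, nrow = 1)
      p0 <- as.vector(crossprod(w, Q)) / sw
      usable <- p0 > 1e-6 & p0 < 1 - 1e-6
      resid <- sweep(Q, 2, p0)
      tk <- colSums(resid * (Finv %*% resid)) / (p0 * (1 - p0))
      tk[!usable] <- 0
      Tsum <- Tsum + tk
    }
    acc <- acc + Tsum
    used <- used + 1L
  }
  if (used == 0L) stop("all EM fits failed", call. = FALSE)
  tibble::tibble(chrom = panel$sites$chrom, pos = panel$sites$pos,
                 hapflk = as.vector(acc) / used, n_fits_used = used)
}

# Random EM start for the cluster model, built so that swapping allele
# labels (0 <-> 1) maps the start set onto itself (clusters come in
# mirrored pairs around the site frequency, sharing their weight column;
# an odd K gets a self-mirrored cluster at 0.5). The EM trajectory on a
# label-swapped panel is then the mirrored cluster permutation of the
# original, making the hapFLK statistic exactly label-invariant.
cluster_init <- function(base_freq, K, spread = 0.15) {
  L <- length(base_freq)
  theta <- matrix(0, nrow = K, ncol = L)
  alpha <- matrix(0, nrow = K, ncol = L)
  n_pair <- K %/% 2
  for (j in seq_len(n_pair)) {
    e <- abs(stats::rnorm(L, 0, spread))
    a <- stats::rgamma(L, 5, 1)
    theta[2 * j - 1, ] <- base_freq + e
    theta[2 * j, ] <- base_freq - e
    alpha[2 * j - 1, ] <- a
    alpha[2 * j, ] <- a
  }
  if (K %% 2 == 1) {
    theta[K, ] <- 0.5
    alpha[K, ] <- stats::rgamma(L, 5, 1)
  }
  theta <- pmin(pmax(theta, 0.02), 0.98)
  alpha <- sweep(alpha, 2, colSums(alpha), "/")
  list(theta = theta, alpha = alpha)
}

#' Choose the number of haplotype clusters by masked-imputation CV
#'
#' fastPHASE-style cross-validation: on a panel thinned to at least
#' `spacing` bp between SNPs, `n_sets` replicate copies are generated, each
#' masking `mask_frac` of the genotypes at random; for every K the cluster
#' model is fitted to the masked copy and the hidden genotypes are imputed
#' from the fitted model; `Wp`, the proportion of wrongly imputed genotypes,
#' is averaged over replicates and the K minimising the mean is selected.
#'
#' @param panel phased [hap_panel()] (thinned internally).
#' @param K_grid candidate cluster counts (default 5, 10, 20, 30, 40, 50).
#' @param n_sets replicate masked copies (default 5).
#' @param mask_frac fraction of genotypes masked (default 0.1; 0 is an
#'   error since nothing could be scored).
#' @param spacing minimum SNP spacing in bp (default 100 kb).
#' @param max_iter,tol,rho_init EM controls as in [hapflk()].
#' @return list with `K_star`, `wp` (tibble `K`, `set`, `wp`) and
#'   `mean_wp` (tibble `K`, `mean_wp`).
#' @export
choose_k <- function(panel, K_grid = c(5, 10, 20, 30, 40, 50), n_sets = 5,
                     mask_frac = 0.1, spacing = 1e5,
                     max_iter = 50, tol = 1e-3, rho_init = 1e-6) {
  if (mask_frac <= 0) stop("mask_frac must be positive: nothing to score",
                           call. = FALSE)
  panel <- thin_variants(panel, spacing)
  L <- n_sites(panel); n <- n_samples(panel)
  dist <- site_dists(panel$sites)
  res <- list()
  for (set in seq_len(n_sets)) {
    mask <- matrix(stats::runif(n * L) < mask_frac, nrow = n)
    masked <- panel$haplotypes
    truth_geno <- masked[seq(1, 2 * n, 2), , drop = FALSE] +
      masked[seq(2, 2 * n, 2), , drop = FALSE]
    for (i in seq_len(n)) {
      masked[c(2 * i - 1, 2 * i), mask[i, ]] <- NA_integer_
    }
    score <- !is.na(truth_geno) & mask
    for (K in K_grid) {
      base_freq <- colMeans(panel$haplotypes, na.rm = TRUE)
      init <- cluster_init(base_freq, K)
      em <- cluster_hmm_em(masked, dist, init$theta, init$alpha, rho_init,
                           pop = rep(0L, 2 * n), n_pop = 1L,
                           max_iter = max_iter, tol = tol,
                           return_gamma = TRUE)
      # per-haplotype allele posterior: sum_k gamma * theta
      pred <- matrix(0, nrow = 2 * n, ncol = L)
      for (k in seq_len(K)) {
        pred <- pred + em$gamma[[k]] * matrix(em$theta[k, ], nrow = 2 * n,
                                              ncol = L, byrow = TRUE)
      }
      imput <- (pred[seq(1, 2 * n, 2), , drop = FALSE] >= 0.5) +
        (pred[seq(2, 2 * n, 2), , drop = FALSE] >= 0.5)
      wp <- sum((imput != truth_geno)[score]) / max(sum(score), 1)
      res[[length(res) + 1]] <- tibble::tibble(K = K, set = set, wp = wp)
    }
  }
  wp <- dplyr::bind_rows(res)
  mean_wp <- wp |>
    dplyr::group_by(.data$K) |>
    dplyr::summarise(mean_wp = mean(.data$wp), .groups = "drop")
  list(K_star = mean_wp$K[which.min(mean_wp$mean_wp)], wp = wp,
       mean_wp = mean_wp)
}
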