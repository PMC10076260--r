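#' Reynolds-distance kinship model for FLK
#'
#' Pairwise population differentiation is estimated on a thinned SNP set by
#' the multi-locus ratio-of-sums Weir & Cockerham estimator and mapped to
#' the Reynolds divergence scale `D = -log(1 - t)`. A neighbour-joining tree
#' is built on `D`, midpoint-rooted, and the kinship matrix `F` is read off
#' as shared root-to-tip branch lengths (`F_ij` = length of the shared path
#' from the root to the MRCA of populations i and j; `F_ii` = the full
#' root-to-tip depth). Negative NJ branch lengths are clamped to zero.
#' With fewer than three populations a star tree is used with a warning.
#'
#' @param panel a [hap_panel()] (thin it first, e.g. with [thin_variants()]).
#' @param groups tibble `sample_id`, `group`.
#' @return a `kinship_model` list: `populations`, `D` (Reynolds distance
#'   matrix), `tree` (`phylo` or `NULL`), `F` (kinship matrix).
#' @export
build_kinship <- function(panel, groups) {
  gl <- sort(unique(groups$group))
  r <- length(gl)
  D <- matrix(0, r, r, dimnames = list(gl, gl))
  for (i in seq_len(r - 1)) {
    for (j in seq(i + 1, r)) {
      sub <- groups[groups$group %in% gl[c(i, j)], ]
      comp <- wc_fst_components(panel, sub)
      ok <- !is.na(comp$a)
      t_hat <- sum(comp$a[ok]) / sum((comp$a + comp$b + comp$c)[ok])
      t_hat <- min(max(t_hat, 0), 1 - 1e-9)
      D[i, j] <- D[j, i] <- -log(1 - t_hat)
    }
  }
  if (r < 3) {
    warning("fewer than three populations: star tree fallback")
    Fm <- diag(D[1, 2] / 2, r)
    dimnames(Fm) <- list(gl, gl)
    return(structure(list(populations = gl, D = D, tree = NULL, F = Fm),
                     class = "kinship_model"))
  }
  tree <- ape::nj(stats::as.dist(D))
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree <- phangorn::midpoint(tree)
  Fm <- tree_kinship(tree)[gl, gl]
  structure(list(populations = gl, D = D, tree = tree, F = Fm),
            class = "kinship_model")
}

#' Kinship matrix from a rooted population tree
#'
#' @param tree rooted `phylo` object with branch lengths.
#' @return matrix of shared root-to-MRCA path lengths (tip depths on the
#'   diagonal), labelled by tip.
#' @export
tree_kinship <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  dn <- ape::dist.nodes(tree)
  root <- n + 1L
  depth <- dn[root, seq_len(n)]
  Fm <- matrix(0, n, n, dimnames = list(tips, tips))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      Fm[i, j] <- (depth[i] + depth[j] - dn[i, j]) / 2
    }
  }
  Fm
}

#' @export
print.kinship_model <- function(x, ...) {
  cat(sprintf("<kinship_model> %d populations; Reynolds D range [%.4f, %.4f]\n",
              length(x$populations), min(x$D[upper.tri(x$D)]),
              max(x$D[upper.tri(x$D)])))
  invisible(x)
}

#' FLK statistic for a matrix of population allele frequencies
#'
#' For each SNP the ancestral frequency is estimated by the
#' kinship-weighted mean `p0 = (1' F^-1 p) / (1' F^-1 1)` and the statistic
#' is the quadratic form
#' `T = (p - p0 1)' [p0 (1 - p0) F]^-1 (p - p0 1)`, referred to a chi-square
#' null with `n_pop - 1` degrees of freedom. Monomorphic SNPs
#' (`p0` at 0 or 1) are `NA`. With `F = c I` this reduces to the classical
#' Lewontin-Krakauer statistic.
#'
#' @param p numeric matrix `n_pop x n_snps` of alt-allele frequencies (a
#'   vector is treated as one SNP), rows ordered like `Fm`.
#' @param Fm population kinship matrix.
#' @return tibble `flk`, `p_value` (one row per SNP).
#' @export
flk <- function(p, Fm) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 1)
  r <- nrow(Fm)
  stopifnot(nrow(p) == r)
  Finv <- solve(Fm)
  w <- Finv %*% rep(1, r)
  sw <- sum(w)
  p0 <- as.vector(crossprod(w, p)) / sw
  resid <- sweep(p, 2, p0)
  Tstat <- colSums(resid * (Finv %*% resid)) / (p0 * (1 - p0))
  bad <- p0 <= 0 | p0 >= 1 | !is.finite(Tstat)
  Tstat[bad] <- NA_real_
  tibble::tibble(flk = Tstat,
                 p_value = stats::pchisq(Tstat, df = r - 1,
                                         lower.tail = FALSE))
}

#' Population allele frequencies of a panel
#'
#' @param panel a [hap_panel()].
#' @param groups tibble `sample_id`, `group`.
#' @return matrix `n_groups x n_sites` of alt-allele frequencies over
#'   non-missing alleles, rows named and sorted by group.
#' @export
pop_freqs <- function(panel, groups) {
  gl <- sort(unique(groups$group))
  out <- t(sapply(gl, function(g)
    alt_freq(panel, sample_rows(panel, groups$sample_id[groups$group == g]))))
  rownames(out) <- gl
  out
}

#' Scale a raw statistic to a chi-square null by robust moment matching
#'
#' Estimates an effective degree of freedom `d` and scale `s` so that the
#' median and 75th percentile of the genome-wide distribution match those of
#' `s * chisq_d`, then converts values to upper-tail p-values. Robust
#' quantiles make the fit insensitive to a selected tail.
#'
#' @param x numeric vector of raw statistics (NA tolerated).
#' @return list with `p_value`, `scaled` (`x / s`), `df`, `scale`.
#' @export
chi2_scale <- function(x) {
  ok <- is.finite(x)
  med <- stats::median(x[ok]); q75 <- stats::quantile(x[ok], 0.75, names = FALSE)
  if (med <= 0 || q75 <= med) stop("degenerate statistic distribution",
                                   call. = FALSE)
  target <- q75 / med
  f <- function(d) stats::qchisq(0.75, d) / stats::qchisq(0.5, d) - target
  d <- tryCatch(stats::uniroot(f, c(0.05, 500), tol = 1e-8)$root,
                error = function(e) 1)
  s <- med / stats::qchisq(0.5, d)
  p <- rep(NA_real_, length(x))
  p[ok] <- stats::pchisq(x[ok] / s, d, lower.tail = FALSE)
  list(p_value = p, scaled = x / s, df = d, scale = s)
}
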