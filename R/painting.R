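#' Inter-site distances with chromosome breaks
#'
#' Distances between adjacent sites of a site table; the interval spanning a
#' chromosome boundary is coded -1, which the HMM layer treats as a free
#' switch (chromosomes are painted independently).
#'
#' @param sites tibble with `chrom`, `pos`.
#' @return numeric vector of length `nrow(sites) - 1`.
#' @export
site_dists <- function(sites) {
  if (nrow(sites) < 2) return(numeric(0))
  d <- diff(sites$pos)
  brk <- sites$chrom[-1] != sites$chrom[-nrow(sites)]
  d[brk] <- -1
  d
}

#' Paint one recipient haplotype against a donor panel
#'
#' Li & Stephens copying model: the hidden state is the donor haplotype being
#' copied; between adjacent sites `d` bp apart the chain switches to a
#' uniformly chosen donor with probability `1 - exp(-Ne * rho * d / N)`
#' (the self-copy keeps its `1/N` share of the switch mass); the emitted
#' allele matches the copied donor with probability `1 - Mu`. Posteriors are
#' computed by scaled forward-backward.
#'
#' @param recipient integer vector of recipient alleles (0/1/NA) over the
#'   site list.
#' @param donors integer matrix (`N` donor haplotypes x `L` sites).
#' @param dist inter-site distances from [site_dists()].
#' @param Ne recombination-scaling parameter (> 0).
#' @param Mu miscopy probability (0 < Mu < 0.5).
#' @param rho per-bp recombination rate.
#' @return list with `gamma` (`L x N` posterior copying probabilities,
#'   rows sum to 1), `loglik`, `switch_post`, `exp_miscopy`, `n_emit`.
#' @export
paint_haplotype <- function(recipient, donors, dist, Ne, Mu, rho = 1e-8) {
  stopifnot(Ne > 0, Mu > 0, Mu < 0.5)
  if (nrow(donors) == 0) stop("donor panel is empty", call. = FALSE)
  if (length(recipient) != ncol(donors)) {
    stop("recipient and donors disagree on the site list", call. = FALSE)
  }
  ls_forward_backward(donors, as.integer(recipient), dist, Ne, rho, Mu)
}

#' Fit copying parameters for one accession by EM
#'
#' Runs exactly `n_iter` expectation-maximisation iterations over both
#' haplotypes of the accession: Ne is re-solved from the expected switch
#' count (1-d root find on the monotone expected-switch curve) and Mu from
#' the expected miscopy fraction. The log-likelihood is non-decreasing
#' across iterations up to the numerical floor.
#'
#' @param recipient_haps integer matrix (2 x L): the accession's haplotypes.
#' @param donors integer matrix (N x L) of donor haplotypes.
#' @param dist inter-site distances ([site_dists()]).
#' @param rho per-bp recombination rate.
#' @param n_iter EM iteration count (default 10).
#' @param Ne0,Mu0 initial values; `Ne0 = NULL` picks a scale-aware start.
#' @return list with `Ne`, `Mu`, `loglik` (trace, length `n_iter`).
#' @export
fit_params_em <- function(recipient_haps, donors, dist, rho = 1e-8,
                          n_iter = 10, Ne0 = NULL, Mu0 = 1e-3) {
  N <- nrow(donors)
  L <- ncol(donors)
  valid <- dist > 0
  total_d <- sum(dist[valid])
  poly <- any(colSums(donors, na.rm = TRUE) %% N != 0)
  if (!poly) {
    warning("donor panel is monomorphic at every site; copying parameters ",
            "left at their initial values")
  }
  if (is.null(Ne0)) {
    Ne0 <- 0.01 * L * N / (rho * max(total_d, 1))
  }
  Ne <- Ne0; Mu <- Mu0
  trace <- numeric(n_iter)
  # identical haplotypes (fully selfed lines) contribute identical
  # expectations: compute each distinct haplotype once and weight
  hkey <- apply(recipient_haps, 1, paste, collapse = "")
  wts <- as.vector(table(hkey)[unique(hkey)])
  uniq <- recipient_haps[!duplicated(hkey), , drop = FALSE]
  for (it in seq_len(n_iter)) {
    S <- 0; mis <- 0; emit <- 0; ll <- 0
    sp_valid <- 0
    for (k in seq_len(nrow(uniq))) {
      fb <- ls_forward_backward(donors, as.integer(uniq[k, ]),
                                dist, Ne, rho, Mu)
      ll <- ll + wts[k] * fb$loglik
      sp_valid <- sp_valid + wts[k] * sum(fb$switch_post[valid])
      mis <- mis + wts[k] * fb$exp_miscopy
      emit <- emit + wts[k] * fb$n_emit
    }
    trace[it] <- ll
    if (!poly) next
    # M-step: solve sum over valid intervals of the switch curve = E[switches]
    nh <- nrow(recipient_haps)
    f <- function(log_ne) {
      nh * sum(1 - exp(-exp(log_ne) * rho * dist[valid] / N)) - sp_valid
    }
    if (sp_valid > 1e-10 && f(log(1e-6)) < 0 && f(log(1e12)) > 0) {
      Ne <- exp(stats::uniroot(f, c(log(1e-6), log(1e12)), tol = 1e-10)$root)
    }
    if (emit > 0) Mu <- min(max(mis / emit, 1e-6), 0.49)
  }
  list(Ne = Ne, Mu = Mu, loglik = trace)
}

#' Aggregate donor-level copying posteriors to donor groups
#'
#' Group probability at a SNP is the sum of the posteriors of the group's
#' member donor haplotypes, so per-SNP vectors still sum to 1.
#'
#' @param gamma `L x N` donor-haplotype posterior matrix.
#' @param donor_hap_groups character vector of length `N`: group label of
#'   each donor haplotype (column).
#' @return `L x n_groups` matrix with columns named by group.
#' @export
aggregate_groups <- function(gamma, donor_hap_groups) {
  if (anyNA(donor_hap_groups)) {
    stop("every donor haplotype must be mapped to a group", call. = FALSE)
  }
  if (length(donor_hap_groups) != ncol(gamma)) {
    stop("group vector and posterior matrix disagree on donor count",
         call. = FALSE)
  }
  groups <- sort(unique(donor_hap_groups))
  ind <- sapply(groups, function(g) as.numeric(donor_hap_groups == g))
  out <- gamma %*% ind
  colnames(out) <- groups
  out
}

#' Paint all recipient haplotypes against a donor panel
#'
#' Runs per-accession EM estimation of (Ne, Mu), then a final painting of
#' both haplotypes with the fitted parameters, aggregated to donor groups.
#'
#' @param recipients a [hap_panel()] of recipient accessions.
#' @param donors a [hap_panel()] of donor accessions (same site list).
#' @param donor_groups tibble with `sample_id`, `group` covering every donor.
#' @param rho per-bp recombination rate.
#' @param n_em_iter EM iterations per accession (default 10); 0 skips EM and
#'   uses `Ne`/`Mu` directly.
#' @param Ne,Mu fixed copying parameters used when `n_em_iter = 0` (or as EM
#'   starting values otherwise).
#' @return a `painting` object: list with `prob` (named list per recipient
#'   haplotype of `L x n_groups` posterior matrices), `sites`, `groups`,
#'   `params` (per-accession fitted Ne/Mu and final log-likelihood).
#' @export
paint_panel <- function(recipients, donors, donor_groups, rho = 1e-8,
                        n_em_iter = 10, Ne = NULL, Mu = 1e-3) {
  if (!identical(dim(recipients$haplotypes)[2], dim(donors$haplotypes)[2]) ||
      !identical(recipients$sites$pos, donors$sites$pos)) {
    stop("recipient and donor panels must share the site list", call. = FALSE)
  }
  miss <- setdiff(donors$sample_ids, donor_groups$sample_id)
  if (length(miss)) {
    stop("donors without a group assignment: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dmat <- donors$haplotypes
  hap_grp <- donor_groups$group[match(rep(donors$sample_ids, each = 2L),
                                      donor_groups$sample_id)]
  dist <- site_dists(donors$sites)
  prob <- list()
  params <- list()
  for (i in seq_along(recipients$sample_ids)) {
    sid <- recipients$sample_ids[i]
    rh <- recipients$haplotypes[c(2L * i - 1L, 2L * i), , drop = FALSE]
    if (n_em_iter > 0) {
      fit <- fit_params_em(rh, dmat, dist, rho = rho, n_iter = n_em_iter,
                           Ne0 = Ne, Mu0 = Mu)
    } else {
      stopifnot(!is.null(Ne))
      fit <- list(Ne = Ne, Mu = Mu, loglik = NA_real_)
    }
    ll <- 0
    same <- identical(rh[1, ], rh[2, ])
    for (k in 1:2) {
      if (k == 2L && same) {
        ll <- ll + fb$loglik
        prob[[paste0(sid, "_2")]] <- prob[[paste0(sid, "_1")]]
        next
      }
      fb <- paint_haplotype(rh[k, ], dmat, dist, fit$Ne, fit$Mu, rho)
      ll <- ll + fb$loglik
      prob[[paste0(sid, "_", k)]] <- aggregate_groups(fb$gamma, hap_grp)
    }
    params[[sid]] <- tibble::tibble(sample_id = sid, Ne = fit$Ne, Mu = fit$Mu,
                                    loglik = ll)
  }
  structure(list(prob = prob, sites = recipients$sites,
                 groups = sort(unique(hap_grp)),
                 params = dplyr::bind_rows(params)),
            class = "painting")
}

#' @export
print.painting <- function(x, ...) {
  cat(sprintf("<painting> %d haplotypes x %d SNPs over %d donor groups\n",
              length(x$prob), nrow(x$sites), length(x$groups)))
  invisible(x)
}

#' Tidy a painting into a long tibble
#'
#' @param x a `painting` object.
#' @param ... unused.
#' @return tibble `hap_id`, `chrom`, `pos`, one probability column per donor
#'   group.
#' @method tidy painting
#' @export
tidy.painting <- function(x, ...) {
  purrr::imap_dfr(x$prob, function(p, id) {
    dplyr::bind_cols(tibble::tibble(hap_id = id, chrom = x$sites$chrom,
                                    pos = x$sites$pos),
                     tibble::as_tibble(p))
  })
}

#' One-line summary of a painting
#' @param x a `painting` object.
#' @param ... unused.
#' @return tibble with haplotype/SNP/group counts and the Ne/Mu ranges.
#' @method glance painting
#' @export
glance.painting <- function(x, ...) {
  tibble::tibble(n_haplotypes = length(x$prob), n_snps = nrow(x$sites),
                 n_groups = length(x$groups),
                 Ne_median = stats::median(x$params$Ne),
                 Mu_median = stats::median(x$params$Mu))
}
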