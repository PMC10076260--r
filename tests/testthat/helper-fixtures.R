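# Shared fixtures, memoised so the expensive painting run happens once per
# test session.

.fixture_env <- new.env(parent = emptyenv())

# The reference synthetic study panel: two deeply diverged genepools
# (FST ~ 0.4), five donor races, 40 selfing recipients admixed 20
# generations ago with minor-ancestry fraction 0.1, on 2 x 5 Mb
# chromosomes with 3000 SNPs.
sim_fixture <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_panel(sim_config(seed = 101))
  }
  .fixture_env$sim
}

paint_fixture <- function() {
  if (is.null(.fixture_env$paint)) {
    sim <- sim_fixture()
    donors <- sim$groups[sim$groups$role == "donor", ]
    pt <- paint_panel(sim$recipient_panel, sim$donor_panel, donors,
                      n_em_iter = 10)
    wm <- assign_windows(pt, sim$chrom_lengths)
    calls <- call_genepool(wm)
    .fixture_env$paint <- list(painting = pt, windows = wm, calls = calls)
  }
  .fixture_env$paint
}

# True genepool of every SNP of one haplotype, from the truth tracts.
truth_genepool <- function(sim, hap_id, sites) {
  tr <- sim$truth[sim$truth$hap_id == hap_id, ]
  out <- rep(NA_character_, nrow(sites))
  for (j in seq_len(nrow(tr))) {
    sel <- sites$chrom == tr$chrom[j] & sites$pos >= tr$start[j] &
      sites$pos < tr$end[j]
    out[sel] <- tr$genepool[j]
  }
  out
}

# Small deterministic panel builder for unit tests.
toy_panel <- function(haps, pos = NULL, chrom = "Chr01", qual = NULL,
                      depth = NULL, gt_depth = NULL) {
  haps <- as.matrix(haps)
  L <- ncol(haps)
  if (is.null(pos)) pos <- seq(0, by = 1000, length.out = L)
  sites <- tibble::tibble(chrom = rep(chrom, length.out = L), pos = pos,
                          ref = "A", alt = "T")
  if (!is.null(qual)) sites$qual <- qual
  if (!is.null(depth)) sites$depth <- depth
  hap_panel(haps, sites, sprintf("s%02d", seq_len(nrow(haps) / 2)),
            gt_depth = gt_depth)
}

# Independent textbook implementation of the Weir & Cockerham (1984)
# per-site components, written scalar-style as an oracle.
wc_oracle_site <- function(geno_by_pop) {
  r <- length(geno_by_pop)
  n_i <- p_i <- h_i <- numeric(r)
  for (i in seq_len(r)) {
    g <- geno_by_pop[[i]]
    g <- g[!is.na(g)]
    n_i[i] <- length(g)
    p_i[i] <- sum(g) / (2 * length(g))
    h_i[i] <- mean(g == 1)
  }
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

# Exhaustive-path-enumeration oracle for the copying-model posteriors.
ls_enum_oracle <- function(donors, recip, dist, Ne, rho, mu) {
  N <- nrow(donors); L <- ncol(donors)
  s <- ifelse(dist <= 0, 1, 1 - exp(-Ne * rho * dist / N))
  em <- function(l, j) {
    if (is.na(recip[l]) || is.na(donors[j, l])) return(1)
    if (donors[j, l] == recip[l]) 1 - mu else mu
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), L)))
  post <- matrix(0, L, N); tot <- 0
  for (r in seq_len(nrow(paths))) {
    p <- em(1, paths[r, 1]) / N
    for (l in 2:L) {
      tr <- (1 - s[l - 1]) * (paths[r, l - 1] == paths[r, l]) + s[l - 1] / N
      p <- p * tr * em(l, paths[r, l])
    }
    tot <- tot + p
    for (l in 1:L) post[l, paths[r, l]] <- post[l, paths[r, l]] + p
  }
  list(gamma = post / tot, loglik = log(tot))
}

# Brute-force pairwise-difference nucleotide diversity.
pi_bruteforce <- function(h) {
  n <- nrow(h)
  tot <- 0
  for (j in seq_len(ncol(h))) {
    x <- h[, j]
    x <- x[!is.na(x)]
    if (length(x) < 2) next
    cnt <- 0; pairs <- 0
    for (u in seq_along(x)[-1]) {
      for (v in seq_len(u - 1)) {
        pairs <- pairs + 1
        cnt <- cnt + (x[u] != x[v])
      }
    }
    tot <- tot + cnt / pairs
  }
  unname(tot)
}

# Brute-force interval oracle on a bp grid: marks covered positions and
# reads off maximal runs.
merge_oracle <- function(regions, gap = 0) {
  purrr::map_dfr(split(regions, regions$chrom), function(r) {
    lim <- max(r$end) + gap + 2
    cov <- logical(lim)
    for (i in seq_len(nrow(r))) cov[(r$start[i] + 1):r$end[i]] <- TRUE
    # bridge gaps <= gap
    runs <- rle(cov)
    ends <- cumsum(runs$lengths)
    for (k in seq_along(runs$lengths)) {
      if (!runs$values[k] && runs$lengths[k] <= gap && k > 1 &&
          k < length(runs$lengths)) {
        cov[(ends[k] - runs$lengths[k] + 1):ends[k]] <- TRUE
      }
    }
    runs <- rle(cov)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    keep <- which(runs$values)
    tibble::tibble(chrom = r$chrom[1], start = starts[keep] - 1,
                   end = ends[keep])
  })
}

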