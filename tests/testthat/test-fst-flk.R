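test_that("Weir & Cockerham components match an independent implementation", {
  set.seed(51)
  # spec'd toy counts: pop1 12/8, pop2 3/17 alt alleles over 10 diploids each
  g1 <- c(rep(2L, 4), rep(1L, 4), rep(0L, 2))   # 12 alt alleles
  g2 <- c(rep(1L, 3), rep(0L, 7))               # 3 alt alleles
  h <- matrix(NA_integer_, nrow = 40, ncol = 1)
  geno <- c(g1, g2)
  for (i in seq_len(20)) {
    h[2 * i - 1, 1] <- as.integer(geno[i] >= 1)
    h[2 * i, 1] <- as.integer(geno[i] == 2)
  }
  panel <- toy_panel(h)
  grp <- tibble::tibble(sample_id = panel$sample_ids,
                        group = rep(c("p1", "p2"), each = 10))
  comp <- wc_fst_components(panel, grp)
  oracle <- wc_oracle_site(list(g1, g2))
  expect_equal(comp$a, oracle$a, tolerance = 1e-10)
  expect_equal(comp$b, oracle$b, tolerance = 1e-10)
  expect_equal(comp$c, oracle$c, tolerance = 1e-10)

  # random multi-population panels with missing data
  for (rep in 1:5) {
    r <- sample(2:4, 1)
    n <- 8
    h <- matrix(sample(c(0L, 1L, NA), 2 * n * r * 6, replace = TRUE,
                       prob = c(.45, .45, .1)), nrow = 2 * n * r)
    panel <- toy_panel(h)
    grp <- tibble::tibble(sample_id = panel$sample_ids,
                          group = rep(paste0("p", 1:r), each = n))
    comp <- wc_fst_components(panel, grp)
    for (j in 1:6) {
      geno_by_pop <- lapply(1:r, function(i) {
        rows <- sample_rows(panel, grp$sample_id[grp$group == paste0("p", i)])
        a1 <- panel$haplotypes[rows[seq(1, 2 * n, 2)], j]
        a2 <- panel$haplotypes[rows[seq(2, 2 * n, 2)], j]
        ifelse(is.na(a1) | is.na(a2), NA, a1 + a2)
      })
      o <- wc_oracle_site(geno_by_pop)
      if (!is.na(comp$a[j])) {
        expect_equal(comp$a[j], o$a, tolerance = 1e-10)
        expect_equal(comp$b[j], o$b, tolerance = 1e-10)
        expect_equal(comp$c[j], o$c, tolerance = 1e-10)
      }
    }
  }
})

test_that("fixed differences give FST 1 and identical frequencies near 0", {
  h <- rbind(matrix(0L, 20, 5), matrix(1L, 20, 5))
  panel <- toy_panel(h)
  grp <- tibble::tibble(sample_id = panel$sample_ids,
                        group = rep(c("a", "b"), each = 10))
  res <- windowed_fst(panel, grp, window_bp = 10000)
  expect_equal(res$per_site$fst_site, rep(1, 5))
  expect_equal(res$windows$fst[1], 1)
  set.seed(52)
  h2 <- matrix(rbinom(80 * 50, 1, 0.5), nrow = 80)
  p2 <- toy_panel(h2)
  g2 <- tibble::tibble(sample_id = p2$sample_ids,
                       group = rep(c("a", "b"), each = 20))
  res2 <- windowed_fst(p2, g2)
  expect_lt(abs(res2$summary$global), 0.02)
})

test_that("windowed FST is the ratio of summed components", {
  set.seed(53)
  h <- matrix(sample(0:1, 40 * 12, replace = TRUE), nrow = 40)
  panel <- toy_panel(h, pos = c(seq(0, 5500, by = 500)))
  grp <- tibble::tibble(sample_id = panel$sample_ids,
                        group = rep(c("a", "b"), each = 10))
  res <- windowed_fst(panel, grp, window_bp = 3000)
  comp <- res$per_site
  w1 <- comp[comp$pos < 3000 & !is.na(comp$a), ]
  expect_equal(res$windows$fst[1],
               sum(w1$a) / sum(w1$a + w1$b + w1$c), tolerance = 1e-12)
  expect_true(all(res$windows$n_snps >= 0))
})

test_that("FLK equals the quadratic form and reduces to Lewontin-Krakauer", {
  set.seed(54)
  r <- 4; L <- 200
  cI <- 0.08
  Fm <- diag(cI, r); dimnames(Fm) <- list(paste0("p", 1:r), paste0("p", 1:r))
  P <- matrix(runif(r * L, 0.1, 0.9), nrow = r)
  res <- flk(P, Fm)
  # star kinship: precision weights equal -> simple mean, scaled sum of squares
  p0 <- colMeans(P)
  T_manual <- colSums(sweep(P, 2, p0)^2) / (cI * p0 * (1 - p0))
  expect_equal(res$flk, T_manual, tolerance = 1e-12)
  # identical frequencies across populations -> T = 0, p = 1
  Pc <- matrix(rep(runif(L, .2, .8), each = r), nrow = r)
  resc <- flk(Pc, Fm)
  expect_equal(resc$flk, rep(0, L), tolerance = 1e-10)
  expect_equal(resc$p_value, rep(1, L), tolerance = 1e-10)
  # monomorphic SNP -> NA
  expect_true(is.na(flk(matrix(0, r, 1), Fm)$flk))
  # allele-label swap invariance
  res_sw <- flk(1 - P, Fm)
  expect_equal(res$flk, res_sw$flk, tolerance = 1e-10)
})

test_that("FLK with a general kinship matches brute-force matrix algebra", {
  set.seed(55)
  r <- 4
  A <- matrix(runif(r * r, 0, 0.05), r)
  Fm <- A %*% t(A) + diag(0.05, r)
  dimnames(Fm) <- list(paste0("p", 1:r), paste0("p", 1:r))
  P <- matrix(runif(r * 50, 0.1, 0.9), nrow = r)
  res <- flk(P, Fm)
  Finv <- solve(Fm)
  one <- rep(1, r)
  for (l in c(1, 17, 50)) {
    p <- P[, l]
    p0 <- as.numeric(t(one) %*% Finv %*% p) /
      as.numeric(t(one) %*% Finv %*% one)
    Tm <- as.numeric(t(p - p0 * one) %*% solve(p0 * (1 - p0) * Fm) %*%
                       (p - p0 * one))
    expect_equal(res$flk[l], Tm, tolerance = 1e-12)
  }
})

test_that("Reynolds kinship recovers simulated differentiation and trees", {
  set.seed(56)
  # two populations at target FST t: D ~ -log(1 - t)
  t_target <- 0.15; S <- 3000
  p <- runif(S, 0.05, 0.95)
  bn <- function() rbeta(S, p * (1 - t_target) / t_target,
                         (1 - p) * (1 - t_target) / t_target)
  p1 <- bn(); p2 <- bn()
  h <- rbind(t(sapply(1:40, function(i) rbinom(S, 1, p1))),
             t(sapply(1:40, function(i) rbinom(S, 1, p2))))
  panel <- toy_panel(h, pos = seq(0, by = 1000, length.out = S))
  grp <- tibble::tibble(sample_id = panel$sample_ids,
                        group = rep(c("a", "b"), each = 20))
  expect_warning(kin <- build_kinship(panel, grp), "star tree")
  expect_lt(abs(kin$D["a", "b"] - (-log(1 - t_target))), 0.035)

  # identical populations: D ~ 0
  p0 <- runif(500, .2, .8)
  h0 <- t(sapply(1:40, function(i) rbinom(500, 1, p0)))
  pan0 <- toy_panel(h0, pos = seq(0, by = 1000, length.out = 500))
  g0 <- tibble::tibble(sample_id = pan0$sample_ids,
                       group = rep(c("a", "b"), each = 10))
  expect_warning(k0 <- build_kinship(pan0, g0), "star tree")
  expect_lt(abs(k0$D["a", "b"]), 0.02)
})

test_that("kinship from a hand-built tree equals shared branch lengths", {
  tree <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.15,D:0.1):0.02);")
  Fm <- tree_kinship(tree)
  expect_equal(Fm["A", "A"], 0.15)
  expect_equal(Fm["B", "B"], 0.25)
  expect_equal(Fm["A", "B"], 0.05)
  expect_equal(Fm["C", "D"], 0.02)
  expect_equal(Fm["A", "C"], 0)
  expect_true(isSymmetric(Fm))
  d <- diag(Fm)
  expect_true(all(Fm <= pmin(matrix(d, 4, 4), matrix(d, 4, 4, byrow = TRUE))
                  + 1e-12))
})

test_that("chi-square scaling recovers a known null distribution", {
  set.seed(57)
  d_true <- 3; s_true <- 2.5
  x <- s_true * rchisq(5000, d_true)
  sc <- chi2_scale(x)
  expect_lt(abs(sc$df - d_true), 0.25)
  expect_lt(abs(sc$scale - s_true), 0.25)
  # p-values approximately uniform
  expect_lt(abs(mean(sc$p_value < 0.1) - 0.1), 0.02)
})
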