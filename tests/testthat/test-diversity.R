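test_that("per-site diversity matches hand-computed pairwise values", {
  # 4 haplotypes, allele counts 2/2: all 6 pairs, 4 differ -> 2/3
  h <- matrix(c(0L, 0L, 1L, 1L), ncol = 1)
  panel <- toy_panel(h)
  est <- theta_pi(panel)
  expect_equal(est$per_site$pi, 2 / 3, tolerance = 1e-15)
  # monomorphic region: 0
  h0 <- matrix(0L, nrow = 4, ncol = 3)
  expect_equal(theta_pi(toy_panel(h0))$regions$theta_pi_bp, 0)
  # 2 haplotypes differing at k of L sites: theta-pi/bp = k / L
  h2 <- rbind(c(0L, 0L, 1L, 0L, 1L), c(0L, 1L, 0L, 0L, 1L))
  p2 <- toy_panel(h2, pos = 0:4)
  reg <- tibble::tibble(chrom = "Chr01", start = 0, end = 5)
  expect_equal(theta_pi(p2, regions = reg)$regions$theta_pi_bp, 2 / 5)
})

test_that("theta-pi equals brute-force pairwise differences with missing data", {
  set.seed(81)
  for (rep in 1:4) {
    n_hap <- sample(c(6, 10, 20), 1)
    L <- 200
    h <- matrix(sample(c(0L, 1L, NA), n_hap * L, replace = TRUE,
                       prob = c(.4, .4, .2)), nrow = n_hap)
    if (n_hap %% 2) h <- h[-1, , drop = FALSE]
    panel <- toy_panel(h, pos = seq(0, by = 50, length.out = L))
    reg <- tibble::tibble(chrom = "Chr01", start = 0, end = max(panel$sites$pos) + 1)
    est <- theta_pi(panel, regions = reg)
    brute <- pi_bruteforce(panel$haplotypes)
    expect_equal(est$regions$theta_pi_bp * (max(panel$sites$pos) + 1), brute,
                 tolerance = 1e-12)
  }
})

test_that("the window track averages per-site diversity over 100-kb windows", {
  set.seed(82)
  h <- matrix(sample(0:1, 8 * 50, replace = TRUE), nrow = 8)
  panel <- toy_panel(h, pos = sort(sample.int(250e3, 50)) - 1)
  lens <- tibble::tibble(chrom = "Chr01", length = 250e3)
  est <- theta_pi(panel, chrom_lengths = lens)
  expect_identical(nrow(est$windows), 3L)
  w1 <- est$per_site[est$per_site$pos < 100e3, ]
  expect_equal(est$windows$theta_pi[1], sum(w1$pi) / 1e5, tolerance = 1e-12)
  expect_equal(est$windows$end[3], 250e3)
})

test_that("raising min_pind never adds contributing sites", {
  set.seed(83)
  h <- matrix(sample(c(0L, 1L, NA), 12 * 100, replace = TRUE,
                     prob = c(.35, .35, .3)), nrow = 12)
  panel <- toy_panel(h, pos = seq(0, by = 100, length.out = 100))
  prev <- Inf
  for (pind in c(0, 0.3, 0.6, 0.9)) {
    est <- theta_pi(panel, min_pind = pind)
    used <- est$regions$theta_pi_bp
    n_used <- sum(!is.na(est$per_site$pi) & est$per_site$pind >= pind)
    expect_lte(n_used, prev)
    prev <- n_used
  }
})

test_that("private alleles are binned by frequency and class", {
  # 6 EU + 6 AM samples
  ann <- tibble::tibble(chrom = "Chr01",
                        pos = seq(0, by = 1000, length.out = 5),
                        effect = c("missense", "synonymous", "missense",
                                   "loss_of_function", "synonymous"),
                        gene_id = paste0("g", 1:5))
  # columns: EU-private low (1/12 = 0.083 > 0.05? use 1/24 ... ) build explicitly
  eu <- rbind(c(1L, 0L, 1L, 1L, 0L),
              matrix(0L, 11, 5))
  am <- rbind(c(0L, 0L, 1L, 0L, 1L),
              c(0L, 0L, 1L, 0L, 1L),
              matrix(0L, 10, 5))
  panel <- toy_panel(rbind(eu, am), pos = ann$pos)
  groups <- tibble::tibble(sample_id = panel$sample_ids,
                           continent = rep(c("EU", "AM"), each = 6))
  res <- private_allele_spectrum(panel, groups, ann, freq_split = 0.1)
  # site 1 (missense, freq 1/12 in EU, 0 in AM): EU-private low
  # site 2: monomorphic everywhere -> private nowhere
  # site 3: segregating in both -> not private
  # site 4 (lof, EU 1/12): EU-private low, nonsynonymous
  # site 5 (syn, AM 2/12 = 0.167): AM-private medium-high
  eu_low_nonsyn <- res$spectrum$n[res$spectrum$continent == "EU" &
                                    res$spectrum$bin == "low" &
                                    res$spectrum$class == "nonsynonymous"]
  expect_identical(eu_low_nonsyn, 2L)
  am_high_syn <- res$spectrum$n[res$spectrum$continent == "AM" &
                                  res$spectrum$bin == "medium_high" &
                                  res$spectrum$class == "synonymous"]
  expect_identical(am_high_syn, 1L)
  expect_identical(sum(res$spectrum$n), 3L)
  expect_setequal(res$per_gene$gene_id, c("g1", "g4", "g5"))
})

test_that("a toy panel matches exhaustive private-allele classification", {
  set.seed(84)
  L <- 20
  h <- matrix(sample(c(0L, 1L), 24 * L, replace = TRUE, prob = c(.8, .2)),
              nrow = 24)
  ann <- tibble::tibble(chrom = "Chr01",
                        pos = seq(0, by = 1000, length.out = L),
                        effect = sample(c("synonymous", "missense",
                                          "loss_of_function", "other"),
                                        L, replace = TRUE),
                        gene_id = NA_character_)
  panel <- toy_panel(h, pos = ann$pos)
  groups <- tibble::tibble(sample_id = panel$sample_ids,
                           continent = rep(c("EU", "AM"), each = 6))
  res <- private_allele_spectrum(panel, groups, ann, freq_split = 0.05)
  manual <- 0L
  for (j in seq_len(L)) {
    f_eu <- mean(h[1:12, j]); f_am <- mean(h[13:24, j])
    cls <- ann$effect[j]
    if (cls == "other") next
    if ((f_eu > 0 && f_am == 0) || (f_am > 0 && f_eu == 0)) {
      manual <- manual + 1L
    }
  }
  expect_identical(sum(res$spectrum$n), manual)
})

test_that("genetic-load ratios and rank-sum comparisons behave", {
  # accession with 10 missense, 2 lof, 5 synonymous alt alleles
  eff <- c(rep("missense", 10), rep("loss_of_function", 2),
           rep("synonymous", 5))
  L <- length(eff)
  ann <- tibble::tibble(chrom = "Chr01",
                        pos = seq(0, by = 1000, length.out = L),
                        effect = eff)
  h <- rbind(rep(1L, L), rep(0L, L),   # accession 1: dosage 1 each
             rep(0L, L), rep(0L, L))   # accession 2: none
  panel <- toy_panel(h, pos = ann$pos)
  groups <- tibble::tibble(sample_id = panel$sample_ids, group = c("a", "b"))
  res <- genetic_load(panel, ann, groups)
  expect_equal(res$per_accession$missense_syn[1], 2.0)
  expect_equal(res$per_accession$lof_syn[1], 0.4)
  expect_true(is.na(res$per_accession$missense_syn[2]))  # 0 synonymous
  expect_error(genetic_load(panel, ann, groups[0, ]), "empty group")
})

test_that("identical load in all accessions gives p = 1", {
  eff <- c(rep("missense", 4), rep("synonymous", 4))
  ann <- tibble::tibble(chrom = "Chr01", pos = seq(0, 7000, by = 1000),
                        effect = eff)
  h <- do.call(rbind, rep(list(c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L)), 12))
  panel <- toy_panel(h, pos = ann$pos)
  groups <- tibble::tibble(sample_id = panel$sample_ids,
                           group = rep(c("a", "b"), each = 3))
  res <- genetic_load(panel, ann, groups)
  expect_true(all(res$tests$p_value == 1))
})

test_that("a simulated between-group load difference is detected", {
  set.seed(85)
  L <- 400
  eff <- sample(c("missense", "synonymous"), L, replace = TRUE)
  ann <- tibble::tibble(chrom = "Chr01",
                        pos = seq(0, by = 500, length.out = L),
                        effect = eff)
  n <- 60
  rate <- ifelse(eff == "missense", 0.05, 0.05)
  h <- matrix(0L, nrow = 2 * n, ncol = L)
  for (i in seq_len(n)) {
    boost <- if (i > 30) 2 else 1   # group B: doubled missense rate
    pr <- ifelse(eff == "missense", rate * boost, rate)
    h[2 * i - 1, ] <- rbinom(L, 1, pr)
    h[2 * i, ] <- rbinom(L, 1, pr)
  }
  panel <- toy_panel(h, pos = ann$pos)
  groups <- tibble::tibble(sample_id = panel$sample_ids,
                           group = rep(c("a", "b"), each = 30))
  res <- genetic_load(panel, ann, groups)
  p <- res$tests$p_value[res$tests$ratio == "missense_syn"]
  expect_lt(p, 0.01)
})

test_that("masked diversity reproduces the qualitative admixture ordering", {
  sim <- sim_fixture()
  pf <- paint_fixture()
  masks <- mask_introgression(sim$recipient_panel, pf$windows)
  calls <- pf$calls
  and_samples <- calls$sample_id[!calls$ambiguous & calls$call == "EU_AND"]
  lens <- sim$chrom_lengths
  unmasked <- theta_pi(sim$recipient_panel, samples = and_samples,
                       chrom_lengths = lens)
  masked <- theta_pi(masks$and_masked, samples = and_samples,
                     chrom_lengths = lens)
  # admixed unmasked diversity exceeds single-ancestry masked diversity
  expect_gt(sum(unmasked$regions$theta_pi_bp),
            sum(masked$regions$theta_pi_bp))
})
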