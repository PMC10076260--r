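# A hand-built painting object over one haplotype: per-SNP group
# probability rows supplied directly.
fake_painting <- function(prob_rows, pos, chrom = "Chr01",
                          groups = c("AM_A1", "AM_A2", "AM_A3", "AM_M1",
                                     "AM_M2"),
                          hap_id = "EU_001_1") {
  p <- do.call(rbind, prob_rows)
  colnames(p) <- groups
  structure(list(prob = stats::setNames(list(p), hap_id),
                 sites = tibble::tibble(chrom = chrom, pos = pos),
                 groups = groups,
                 params = tibble::tibble(sample_id = sub("_[12]$", "",
                                                         hap_id))),
            class = "painting")
}

chrlen <- function(len = 50000) tibble::tibble(chrom = "Chr01", length = len)

test_that("window labels follow the mean-probability >= 0.8 rule", {
  rows <- list(
    c(1, 0, 0, 0, 0),                  # win 1: pure AM_A1
    c(0.2, 0.2, 0.2, 0.2, 0.2),        # win 2: uniform -> unknown
    c(0.85, 0.05, 0.05, 0.03, 0.02),   # win 3: mean 0.85 -> AM_A1
    c(0.7, 0.1, 0.1, 0.05, 0.05),      # win 4: max 0.7 < 0.8 -> unknown
    c(0, 0, 0, 0.9, 0.1))              # win 5: AM_M1
  pt <- fake_painting(rows, pos = c(5000, 15000, 25000, 35000, 45000))
  wm <- assign_windows(pt, chrlen(), window_bp = 10000, prob = 0.8)
  expect_identical(wm$label, c("AM_A1", "unknown", "AM_A1", "unknown",
                               "AM_M1"))
  expect_identical(wm$genepool, c("AND", NA, "AND", NA, "MES"))
  expect_identical(wm$n_snps, rep(1L, 5))
})

test_that("windows tile chromosomes including the final partial window", {
  pt <- fake_painting(list(c(1, 0, 0, 0, 0)), pos = 100)
  wm <- assign_windows(pt, chrlen(34000), window_bp = 10000)
  expect_identical(nrow(wm), 4L)
  expect_identical(wm$end[4], 34000)
  expect_identical(wm$label[-1], rep("unknown", 3))  # zero-SNP windows
  # tiling count: ceil(len / window)
  expect_identical(nrow(wm), as.integer(ceiling(34000 / 10000)))
})

test_that("window means average the per-SNP probabilities", {
  rows <- list(c(0.9, 0.1, 0, 0, 0), c(0.7, 0.3, 0, 0, 0),
               c(0.8, 0.2, 0, 0, 0))
  pt <- fake_painting(rows, pos = c(1000, 4000, 9000))
  wm <- assign_windows(pt, chrlen(10000))
  expect_equal(wm$max_prob, 0.8)
  expect_identical(wm$label, "AM_A1")
})

test_that("genepool calls apply the two criteria and flag disagreement", {
  mk_map <- function(labels_by_chrom, sample_id = "EU_x") {
    purrr::imap_dfr(labels_by_chrom, function(labels, ch) {
      n <- length(labels)
      purrr::map_dfr(1:2, function(k)
        tibble::tibble(hap_id = paste0(sample_id, "_", k),
                       sample_id = sample_id, chrom = ch,
                       start = (seq_len(n) - 1) * 10000,
                       end = seq_len(n) * 10000, n_snps = 1L,
                       label = labels, max_prob = 0.9,
                       genepool = label_genepool(labels)))
    })
  }
  # 100% Andean -> EU_AND on every chromosome
  m1 <- mk_map(list(Chr01 = rep("AM_A1", 10), Chr02 = rep("AM_A2", 10)))
  c1 <- call_genepool(m1)
  expect_identical(c1$call, "EU_AND")
  expect_identical(c1$chrom_and, 2L)
  # 60% Andean windows and majority chromosomes Andean -> EU_AND
  m2 <- mk_map(list(Chr01 = c(rep("AM_A1", 6), rep("AM_M1", 4)),
                    Chr02 = c(rep("AM_A3", 6), rep("AM_M2", 4))))
  expect_identical(call_genepool(m2)$call, "EU_AND")
  # criteria disagreement -> ambiguous
  m3 <- mk_map(list(Chr01 = c(rep("AM_A1", 9), rep("AM_M1", 1)),
                    Chr02 = c(rep("AM_M1", 6), rep("AM_A1", 4)),
                    Chr03 = c(rep("AM_M1", 6), rep("AM_A1", 4))))
  c3 <- call_genepool(m3)
  expect_true(c3$ambiguous)
  expect_true(is.na(c3$call))
  # all unknown -> unassignable
  m4 <- mk_map(list(Chr01 = rep("unknown", 5)))
  expect_error(call_genepool(m4), "unassignable")
})

test_that("block extraction follows the merge, gap-join and drop rules", {
  mk_map <- function(labels, sample_id = "EU_x") {
    n <- length(labels)
    purrr::map_dfr(1:2, function(k)
      tibble::tibble(hap_id = paste0(sample_id, "_", k),
                     sample_id = sample_id, chrom = "Chr01",
                     start = (seq_len(n) - 1) * 10000,
                     end = seq_len(n) * 10000, n_snps = 1L,
                     label = labels, max_prob = 0.9,
                     genepool = label_genepool(labels)))
  }
  calls <- tibble::tibble(sample_id = "EU_x", call = "EU_AND",
                          ambiguous = FALSE)
  # [M, M, unknown, M] on an EU_AND haplotype: one 40-kb block, 3 windows
  b1 <- extract_blocks(mk_map(c("AM_M1", "AM_M1", "unknown", "AM_M2")),
                       calls)
  expect_identical(nrow(b1$blocks), 2L)  # both haplotypes
  expect_identical(b1$blocks$start[1], 0)
  expect_identical(b1$blocks$end[1], 40000)
  expect_identical(b1$blocks$n_windows[1], 3L)
  expect_identical(b1$summary$median_length[1], 40000)
  # [M, A x 6, M]: 60-kb gap > 50 kb, both singletons dropped
  b2 <- extract_blocks(mk_map(c("AM_M1", rep("AM_A1", 6), "AM_M1")), calls)
  expect_identical(nrow(b2$blocks), 0L)
  expect_true(is.na(b2$summary$median_length[1]))
  expect_identical(b2$summary$n_blocks[1], 0L)
  # [M, A x 5, M]: 50-kb gap joined, block spans 70 kb with 2 windows
  b3 <- extract_blocks(mk_map(c("AM_M1", rep("AM_A1", 5), "AM_M1")), calls)
  expect_identical(nrow(b3$blocks), 2L)
  expect_identical(b3$blocks$end[1] - b3$blocks$start[1], 70000)
  expect_identical(b3$blocks$n_windows[1], 2L)
  # all-Andean haplotype: zero blocks, median NA
  b4 <- extract_blocks(mk_map(rep("AM_A1", 8)), calls)
  expect_identical(nrow(b4$blocks), 0L)
  expect_true(is.na(b4$summary$median_length[1]))
})

test_that("ancestry masking partitions alleles and is idempotent", {
  sim <- sim_fixture()
  pf <- paint_fixture()
  panel <- sim$recipient_panel
  masks <- mask_introgression(panel, pf$windows)
  h0 <- !is.na(panel$haplotypes)
  ha <- !is.na(masks$and_masked$haplotypes)
  hm <- !is.na(masks$mes_masked$haplotypes)
  # masked panels only ever remove alleles
  expect_true(all(h0[ha]))
  expect_true(all(h0[hm]))
  # AND-kept + MES-kept + unknown-dropped partition the observed alleles
  unknown_ct <- sum(h0) - sum(ha) - sum(hm)
  expect_gte(unknown_ct, 0)
  expect_false(any(ha & hm))
  # idempotence
  again <- mask_introgression(masks$and_masked, pf$windows)
  expect_identical(again$and_masked$haplotypes, masks$and_masked$haplotypes)
})

test_that("inferred block-length median matches the truth tracts", {
  sim <- sim_fixture()
  pf <- paint_fixture()
  res <- extract_blocks(pf$windows, pf$calls)
  # truth minor-ancestry tracts for called accessions, same >= 2-window filter
  calls <- pf$calls[!pf$calls$ambiguous, ]
  truth_blocks <- sim$truth |>
    dplyr::inner_join(calls[, c("sample_id", "call")], by = "sample_id") |>
    dplyr::filter(genepool != sub("EU_", "", call),
                  end - start >= 20000)
  expect_gt(nrow(res$blocks), 0)
  ratio <- stats::median(res$blocks$length) /
    stats::median(truth_blocks$end - truth_blocks$start)
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.25)
})
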