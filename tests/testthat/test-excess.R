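test_that("excess thresholds reproduce the sample-size arithmetic", {
  thr <- excess_thresholds(71, 43)
  expect_equal(thr$F_A_reported, 0.811)
  expect_equal(thr$F_M_reported, 0.688)
  expect_equal(thr$F_A, (2 * 71 + 43) / (2 * 114), tolerance = 1e-15)
  # symmetry: equal counts give equal thresholds of 0.75
  thr2 <- excess_thresholds(10, 10)
  expect_equal(thr2$F_A, 0.75)
  expect_equal(thr2$F_M, 0.75)
  # exchange symmetry F_A(a, m) = F_M(m, a)
  expect_equal(excess_thresholds(30, 7)$F_A, excess_thresholds(7, 30)$F_M)
  # F_A >= 0.5 always (scan a grid)
  for (a in c(1, 5, 80)) {
    for (m in c(1, 12, 60)) {
      expect_gte(excess_thresholds(a, m)$F_A, 0.5)
    }
  }
  # degenerate and empty cases
  expect_warning(thr3 <- excess_thresholds(100, 0))
  expect_equal(thr3$F_A, 1.0)
  expect_error(excess_thresholds(0, 0), "no recipient")
})

make_window_map <- function(assignments, window_bp = 10000) {
  # assignments: named list sample -> list(chrom labels vectors)
  purrr::imap_dfr(assignments, function(hap_labels, sid) {
    purrr::imap_dfr(hap_labels, function(labels, k) {
      n <- length(labels)
      tibble::tibble(hap_id = paste0(sid, "_", k),
                     sample_id = sid, chrom = "Chr01",
                     start = (seq_len(n) - 1) * window_bp,
                     end = seq_len(n) * window_bp, n_snps = 1L,
                     label = labels, max_prob = 0.9,
                     genepool = label_genepool(labels))
    })
  })
}

test_that("per-SNP Fobs traces window assignments over all haplotypes", {
  # 3 accessions (6 haplotypes); windows of 10 kb; SNPs at 5 kb and 15 kb
  wm <- make_window_map(list(
    s1 = list(`1` = c("AM_A1", "AM_M1"), `2` = c("AM_A2", "unknown")),
    s2 = list(`1` = c("AM_A3", "AM_M1"), `2` = c("AM_A1", "AM_M2")),
    s3 = list(`1` = c("unknown", "AM_M1"), `2` = c("AM_M1", "AM_M1"))))
  calls <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                          call = c("EU_AND", "EU_AND", "EU_MES"),
                          ambiguous = FALSE)
  sites <- tibble::tibble(chrom = "Chr01", pos = c(5000, 15000))
  thr <- list(F_A = 0.6, F_M = 0.6, F_A_reported = 0.6, F_M_reported = 0.6)
  ex <- scan_excess(wm, sites, calls, thr)
  # SNP 1: AND on 4/6 haplotypes, 1 MES, 1 unknown
  expect_equal(ex$fobs_and[1], 4 / 6)
  expect_equal(ex$fobs_mes[1], 1 / 6)
  expect_true(ex$flag_and[1])
  # SNP 2: MES on 5/6, 1 unknown
  expect_equal(ex$fobs_mes[2], 5 / 6)
  expect_equal(ex$fobs_and[2], 0)
  expect_true(ex$flag_mes[2])
  expect_false(ex$flag_and[2])
  # Fobs_AND + Fobs_MES + unassigned = 1
  expect_true(all(ex$fobs_and + ex$fobs_mes <= 1 + 1e-12))
})

test_that("the threshold comparison is >= (strict below, flagged at)", {
  wm <- make_window_map(list(
    s1 = list(`1` = "AM_A1", `2` = "AM_A1"),
    s2 = list(`1` = "AM_A1", `2` = "AM_A1"),
    s3 = list(`1` = "AM_A1", `2` = "AM_M1"),
    s4 = list(`1` = "AM_M1", `2` = "AM_M1"),
    s5 = list(`1` = "AM_M1", `2` = "AM_M1")))
  calls <- tibble::tibble(sample_id = paste0("s", 1:5),
                          call = c("EU_AND", "EU_AND", "EU_AND",
                                   "EU_MES", "EU_MES"),
                          ambiguous = FALSE)
  sites <- tibble::tibble(chrom = "Chr01", pos = 5000)
  # Fobs_AND = 5/10 = 0.5
  ex1 <- scan_excess(wm, sites, calls,
                     list(F_A_reported = 0.5, F_M_reported = 0.9,
                          F_A = 0.5, F_M = 0.9))
  expect_true(ex1$flag_and[1])
  ex2 <- scan_excess(wm, sites, calls,
                     list(F_A_reported = 0.511, F_M_reported = 0.9,
                          F_A = 0.511, F_M = 0.9))
  expect_false(ex2$flag_and[1])
})

test_that("excess regions follow the slop/merge/support worked examples", {
  lens <- tibble::tibble(chrom = "Chr01", length = 5e6)
  # SNPs at 100 kb, 103 kb, 110 kb -> one region [97500, 112500], support 3
  r1 <- build_excess_regions(
    tibble::tibble(chrom = "Chr01", pos = c(100e3, 103e3, 110e3)), lens)
  expect_identical(nrow(r1), 1L)
  expect_equal(r1$start, 97500)
  expect_equal(r1$end, 112500)
  expect_identical(r1$n_support, 3L)
  # two isolated SNPs 1 Mb apart: support 1 each, both dropped
  r2 <- build_excess_regions(
    tibble::tibble(chrom = "Chr01", pos = c(1e6, 2e6)), lens)
  expect_identical(nrow(r2), 0L)
  # boundary clipping at the chromosome start
  r3 <- build_excess_regions(
    tibble::tibble(chrom = "Chr01", pos = c(1000, 1500, 2000)), lens)
  expect_equal(r3$start, 0)
  expect_equal(r3$end, 4500)
  # empty input
  r4 <- build_excess_regions(tibble::tibble(chrom = character(),
                                            pos = numeric()), lens)
  expect_identical(nrow(r4), 0L)
})

test_that("PAIL calls require all three evidence layers", {
  excess <- tibble::tibble(chrom = "c1", start = c(100, 5000, 9000),
                           end = c(1000, 6000, 9500), n_support = 3L)
  selection <- tibble::tibble(chrom = "c1", start = c(900, 8900),
                              end = c(1200, 9600))
  fst_top <- tibble::tibble(chrom = "c1", start = c(950, 7000),
                            end = c(1100, 7500))
  genes <- tibble::tibble(gene_id = paste0("g", 1:4),
                          chrom = "c1",
                          start = c(150, 5100, 9100, 20000),
                          end = c(400, 5200, 9200, 21000))
  res <- call_pail(excess, selection, fst_top, genes)
  # region 1: excess + selection + fst -> PAIL
  expect_true(res$regions$pail[1])
  # region 2: excess only
  expect_false(res$regions$sel_overlap[2])
  expect_false(res$regions$pail[2])
  # region 3: excess + selection but no FST outlier
  expect_true(res$regions$sel_overlap[3])
  expect_false(res$regions$pail[3])
  expect_identical(res$genes$evidence[res$genes$gene_id == "g1"], "pail")
  expect_identical(res$genes$evidence[res$genes$gene_id == "g2"],
                   "introgression_only")
  expect_false("g4" %in% res$genes$gene_id)
})

test_that("tightening thresholds never enlarges the PAIL set", {
  set.seed(71)
  excess <- tibble::tibble(chrom = "c1",
                           start = seq(0, 9e4, by = 1e4))
  excess$end <- excess$start + 8000
  excess$n_support <- sample(3:10, 10, replace = TRUE)
  selection <- tibble::tibble(chrom = "c1", start = c(5, 35, 75) * 1e3,
                              end = c(12, 48, 83) * 1e3)
  fstw <- tibble::tibble(chrom = "c1", start = seq(0, 9e4, by = 1e4))
  fstw$end <- fstw$start + 1e4
  fstw$fst <- seq(0.1, 0.9, length.out = 10)
  loose <- call_pail(excess, selection, fst_outlier_windows(fstw, 0.5), genes = tibble::tibble(
    gene_id = character(), chrom = character(), start = numeric(),
    end = numeric()))
  tight <- call_pail(excess, selection, fst_outlier_windows(fstw, 0.1), genes = tibble::tibble(
    gene_id = character(), chrom = character(), start = numeric(),
    end = numeric()))
  expect_true(all(which(tight$regions$pail) %in% which(loose$regions$pail)))
})
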