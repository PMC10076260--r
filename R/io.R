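#' Read a phased biallelic SNP VCF into a haplotype panel
#'
#' Parses a (possibly bgzipped) VCF 4.x file keeping only biallelic SNP
#' records; everything else (indels, multi-allelic records) is skipped and
#' counted. Phase is taken from the genotype separator: the panel is flagged
#' unphased if any kept genotype uses `/`. VCF coordinates are converted to
#' the package-internal 0-based convention on read.
#'
#' @param path VCF file path.
#' @param region_filter optional tibble of intervals (`chrom`, `start`, `end`,
#'   0-based half-open); only records inside are kept.
#' @return a [hap_panel()] with per-site `qual` and, when `INFO/DP` and
#'   `FORMAT/DP` are present, site and genotype depths. The number of skipped
#'   non-biallelic-SNP records is attached as attribute `n_skipped`.
#' @export
read_vcf <- function(path, region_filter = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("not a VCF: missing #CHROM header line", call. = FALSE)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L) stop("VCF has no sample columns", call. = FALSE)
  sample_ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]

  n_skipped <- 0L
  recs <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L + length(sample_ids)) {
      stop(sprintf("malformed VCF record at data line %d", i), call. = FALSE)
    }
    ref <- f[4]; alt <- f[5]
    if (nchar(ref) != 1L || nchar(alt) != 1L || alt %in% c(".", ref) ||
        grepl(",", alt, fixed = TRUE)) {
      n_skipped <- n_skipped + 1L
      next
    }
    recs[[i]] <- f
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) stop("no biallelic SNP records in VCF", call. = FALSE)

  chrom <- vapply(recs, `[`, "", 1)
  pos <- as.numeric(vapply(recs, `[`, "", 2)) - 1
  qual <- suppressWarnings(as.numeric(vapply(recs, `[`, "", 6)))
  info <- vapply(recs, `[`, "", 8)
  dp <- suppressWarnings(as.numeric(sub(".*?\\bDP=([0-9.]+).*", "\\1", info)))
  dp[!grepl("\\bDP=", info)] <- NA_real_

  fmt <- strsplit(vapply(recs, `[`, "", 9), ":", fixed = TRUE)
  L <- length(recs); n <- length(sample_ids)
  hap <- matrix(NA_integer_, nrow = 2L * n, ncol = L)
  gt_depth <- matrix(NA_real_, nrow = n, ncol = L)
  any_unphased <- FALSE; any_gt_dp <- FALSE
  for (j in seq_len(L)) {
    gt_i <- match("GT", fmt[[j]])
    dp_i <- match("DP", fmt[[j]])
    smp <- recs[[j]][-(1:9)]
    parts <- strsplit(smp, ":", fixed = TRUE)
    gt <- vapply(parts, `[`, "", gt_i)
    if (any(grepl("/", gt, fixed = TRUE) & gt != "./.")) any_unphased <- TRUE
    al <- strsplit(gt, "[/|]")
    a1 <- suppressWarnings(as.integer(vapply(al, `[`, "", 1)))
    a2 <- suppressWarnings(as.integer(vapply(al, function(x) if (length(x) > 1) x[2] else NA_character_, "")))
    hap[seq(1L, 2L * n, by = 2L), j] <- a1
    hap[seq(2L, 2L * n, by = 2L), j] <- a2
    if (!is.na(dp_i)) {
      any_gt_dp <- TRUE
      gt_depth[, j] <- suppressWarnings(as.numeric(vapply(parts, function(x)
        if (length(x) >= dp_i) x[dp_i] else NA_character_, "")))
    }
  }

  sites <- tibble::tibble(chrom = chrom, pos = pos,
                          ref = vapply(recs, `[`, "", 4),
                          alt = vapply(recs, `[`, "", 5),
                          qual = qual, depth = dp)
  keep <- rep(TRUE, L)
  if (!is.null(region_filter)) {
    keep <- purrr::map_lgl(seq_len(L), function(j) {
      any(region_filter$chrom == chrom[j] &
            region_filter$start <= pos[j] & pos[j] < region_filter$end)
    })
  }
  panel <- hap_panel(hap[, keep, drop = FALSE], sites[keep, ], sample_ids,
                     phased = !any_unphased,
                     gt_depth = if (any_gt_dp) gt_depth[, keep, drop = FALSE] else NULL)
  attr(panel, "n_skipped") <- n_skipped
  panel
}

#' Write a haplotype panel as VCF 4.2
#'
#' Positions are converted back to 1-based VCF coordinates. Missing alleles
#' are written as `.`; the genotype separator follows the panel's phase flag.
#'
#' @param panel a [hap_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  sep <- if (panel$phased) "|" else "/"
  n <- n_samples(panel)
  h <- panel$haplotypes
  a1 <- h[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  a2 <- h[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  code <- function(x) ifelse(is.na(x), ".", as.character(x))
  qual <- if ("qual" %in% names(panel$sites)) {
    ifelse(is.na(panel$sites$qual), ".", format(panel$sites$qual, trim = TRUE))
  } else rep(".", n_sites(panel))
  info <- if ("depth" %in% names(panel$sites)) {
    ifelse(is.na(panel$sites$depth), ".",
           paste0("DP=", format(panel$sites$depth, trim = TRUE)))
  } else rep(".", n_sites(panel))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=introscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$sample_ids), collapse = "\t")),
             con)
  for (j in seq_len(n_sites(panel))) {
    gts <- paste0(code(a1[, j]), sep, code(a2[, j]))
    writeLines(paste(c(panel$sites$chrom[j], panel$sites$pos[j] + 1, ".",
                       panel$sites$ref[j], panel$sites$alt[j], qual[j], ".",
                       info[j], "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a region set as BED3+
#'
#' Intervals are written in the 0-based half-open BED convention (the
#' package-internal convention, so no shift is applied), sorted by
#' `(chrom, start)`. Extra columns beyond `chrom`/`start`/`end` are appended
#' in order.
#'
#' @param regions tibble with `chrom`, `start`, `end` and optional metadata
#'   columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  regions <- tibble::as_tibble(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (nrow(regions) && any(regions$start < 0 | regions$end < 0)) {
    stop("negative coordinates are not valid in BED output", call. = FALSE)
  }
  if (nrow(regions) && any(regions$start >= regions$end)) {
    stop("empty or inverted interval (start >= end)", call. = FALSE)
  }
  regions <- dplyr::arrange(regions, .data$chrom, .data$start)
  extra <- setdiff(names(regions), c("chrom", "start", "end"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#chrom", "start", "end", extra), collapse = "\t"), con)
  if (nrow(regions)) {
    cols <- c(list(regions$chrom, format(regions$start, scientific = FALSE, trim = TRUE),
                   format(regions$end, scientific = FALSE, trim = TRUE)),
              lapply(extra, function(e) as.character(regions[[e]])))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Read a BED3+ file
#'
#' @param path BED path; `#`-prefixed lines are treated as comments (a header
#'   comment written by [write_bed()] is recognised and used for column names).
#' @return tibble with `chrom`, `start`, `end` (0-based half-open) plus any
#'   extra columns.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  nm <- c("chrom", "start", "end")
  if (length(hdr)) {
    cand <- strsplit(sub("^#", "", hdr[1]), "\t", fixed = TRUE)[[1]]
    if (length(cand) >= 3 && identical(cand[1:3], nm)) nm <- cand
  }
  if (!length(lines)) {
    out <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
    for (e in setdiff(nm, names(out))) out[[e]] <- character()
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  k <- max(lengths(f))
  if (length(nm) < k) nm <- c(nm, paste0("V", seq_len(k - length(nm)) + 3L))
  out <- tibble::as_tibble(stats::setNames(
    lapply(seq_len(k), function(i) vapply(f, function(x) x[i], "")), nm[seq_len(k)]))
  out$start <- as.numeric(out$start)
  out$end <- as.numeric(out$end)
  out
}

#' Read a tab-separated table as a tibble
#'
#' Thin wrapper used for group assignments, annotations and trait tables.
#' @param path TSV path with a header line.
#' @return tibble.
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE))
}

#' Write a tibble as a tab-separated table
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
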