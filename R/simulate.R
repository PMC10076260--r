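#' Configuration for the synthetic admixed-panel generator
#'
#' Defines the study conditions the generator emulates: two deeply diverged
#' crop genepools (Andean, Mesoamerican) each split into races by a nested,
#' smaller differentiation parameter; near-homozygous selfing lines; recent
#' admixture laying Markov ancestry tracts along recipient haplotypes; effect
#' classes per variant; and group-structured quantitative traits with
#' replicate noise.
#'
#' @param seed integer master seed; every downstream draw derives from it.
#' @param n_chrom,chrom_len_bp chromosome count and length (bp).
#' @param n_sites SNP count per chromosome.
#' @param f_divergence Balding-Nichols differentiation of each genepool from
#'   the common ancestor (realises an inter-genepool FST of about this value).
#' @param f_subgroup nested Balding-Nichols differentiation of races within a
#'   genepool.
#' @param donor_group_sizes named vector of donor counts per race; names must
#'   be the five races `AM_M1, AM_M2, AM_A1, AM_A2, AM_A3`.
#' @param n_recipients number of admixed recipient accessions.
#' @param recipient_and_frac fraction of recipients whose major ancestry is
#'   Andean.
#' @param m expected minor-ancestry genome fraction per recipient haplotype.
#' @param g age of admixture in generations.
#' @param r per-bp per-generation recombination rate.
#' @param selfing if `TRUE` both haplotypes of a line are identical
#'   (near-complete selfing, the single-seed-descent situation).
#' @param miscopy per-site allele miscopy rate when copying from a donor.
#' @param effect_props named proportions over
#'   `synonymous, missense, loss_of_function, other` for per-variant effect
#'   classes.
#' @param gene_len,gene_spacing gene model used for the annotation track (bp).
#' @param sigma2_b,sigma2_w,sigma2_e,n_reps trait model: between-group,
#'   within-group (line) and replicate-noise variances, replicates per line.
#' @param adaptive_loci optional tibble (`chrom`, `pos`, `width_bp`, `frac`,
#'   `ancestry`) of engineered adaptive-introgression loci: at each locus the
#'   given ancestry is forced onto a fraction `frac` of recipient accessions.
#'
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L, chrom_len_bp = 5e6, n_sites = 1500L,
                       f_divergence = 0.4, f_subgroup = 0.05,
                       donor_group_sizes = c(AM_M1 = 12L, AM_M2 = 12L,
                                             AM_A1 = 12L, AM_A2 = 12L,
                                             AM_A3 = 12L),
                       n_recipients = 40L, recipient_and_frac = 71 / 114,
                       m = 0.1, g = 20, r = 1e-8,
                       selfing = TRUE, miscopy = 1e-3,
                       effect_props = c(synonymous = 0.30, missense = 0.25,
                                        loss_of_function = 0.05, other = 0.40),
                       gene_len = 5000, gene_spacing = 25000,
                       sigma2_b = 2, sigma2_w = 1, sigma2_e = 1, n_reps = 3L,
                       adaptive_loci = NULL) {
  stopifnot(m >= 0, m <= 1, g >= 1, r > 0,
            sigma2_b >= 0, sigma2_w >= 0, sigma2_e >= 0, n_reps >= 1,
            all(donor_group_sizes >= 2))
  if (f_divergence <= 0 || f_divergence >= 1) {
    stop("f_divergence must lie strictly in (0, 1)", call. = FALSE)
  }
  if (f_subgroup <= 0 || f_subgroup >= 1) {
    stop("f_subgroup must lie strictly in (0, 1)", call. = FALSE)
  }
  need <- c("AM_M1", "AM_M2", "AM_A1", "AM_A2", "AM_A3")
  if (!setequal(names(donor_group_sizes), need)) {
    stop("donor_group_sizes must name exactly the five races: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

race_genepool <- function(race) {
  ifelse(startsWith(race, "AM_A") | race == "AND", "AND", "MES")
}

#' Balding-Nichols allele frequencies for the donor races
#'
#' Ancestral frequencies are uniform on (0.05, 0.95); each genepool draws its
#' frequency from `Beta(p(1-f)/f, (1-p)(1-f)/f)` around the ancestral value,
#' and each race repeats the construction around its genepool with the nested
#' `f_subgroup`.
#'
#' @param config a [sim_config()].
#' @return list with `ancestral` (vector over all sites, chromosomes
#'   concatenated), `genepool` (sites x 2 matrix, columns `AND`, `MES`) and
#'   `race` (sites x 5 matrix).
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  S <- config$n_chrom * config$n_sites
  p <- stats::runif(S, 0.05, 0.95)
  bn <- function(p, f) {
    q <- stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
    pmin(pmax(q, 0), 1)
  }
  genepool <- cbind(AND = bn(p, config$f_divergence),
                    MES = bn(p, config$f_divergence))
  races <- names(config$donor_group_sizes)
  race <- sapply(races, function(rc) {
    bn(genepool[, race_genepool(rc)], config$f_subgroup)
  })
  list(ancestral = p, genepool = genepool, race = race)
}

sim_site_table <- function(config) {
  purrr::map_dfr(seq_len(config$n_chrom), function(ci) {
    pos <- sort(sample.int(config$chrom_len_bp, config$n_sites)) - 1
    tibble::tibble(chrom = sprintf("Chr%02d", ci), pos = pos,
                   ref = "A", alt = "T")
  })
}

#' Simulate donor haplotypes for the five races
#'
#' @param config a [sim_config()].
#' @param freqs output of [simulate_frequencies()]; regenerated when `NULL`.
#' @return list with `panel` (a [hap_panel()]), `groups` (tibble `sample_id`,
#'   `group`, `genepool`, `role`) and `freqs`.
#' @export
simulate_donors <- function(config, freqs = NULL) {
  if (is.null(freqs)) freqs <- simulate_frequencies(config)
  set.seed(config$seed + 1L)
  sites <- sim_site_table(config)
  races <- names(config$donor_group_sizes)
  ids <- list(); rows <- list(); grp <- list()
  for (rc in races) {
    n_g <- config$donor_group_sizes[[rc]]
    sid <- sprintf("%s_%03d", rc, seq_len(n_g))
    f <- freqs$race[, rc]
    for (s in sid) {
      h1 <- stats::rbinom(length(f), 1L, f)
      h2 <- if (config$selfing) h1 else stats::rbinom(length(f), 1L, f)
      rows[[length(rows) + 1L]] <- h1
      rows[[length(rows) + 1L]] <- h2
    }
    ids[[rc]] <- sid
    grp[[rc]] <- tibble::tibble(sample_id = sid, group = rc,
                                genepool = race_genepool(rc), role = "donor")
  }
  panel <- hap_panel(do.call(rbind, rows), sites, unlist(ids, use.names = FALSE))
  list(panel = panel, groups = dplyr::bind_rows(grp), freqs = freqs)
}

# One haplotype's ancestry tracts along one chromosome: switch events are a
# Poisson process of rate g*r per bp; at each event the ancestry state is
# redrawn as minor with probability m, so a visible minor tract is
# exponential with rate g*r*(1-m).
sim_tracts_one <- function(len, m, g, r) {
  rate <- g * r
  brk <- numeric(0)
  x <- stats::rexp(1, rate)
  while (x < len) {
    brk <- c(brk, x)
    x <- x + stats::rexp(1, rate)
  }
  states <- stats::rbinom(length(brk) + 1L, 1L, m)  # 1 = minor ancestry
  starts <- c(0, brk); ends <- c(brk, len)
  keep <- c(TRUE, diff(states) != 0L)
  grp <- cumsum(keep)
  tibble::tibble(start = starts[keep],
                 end = vapply(split(ends, grp), max, 0),
                 minor = states[keep] == 1L)
}

#' Simulate admixed recipient accessions with known ancestry tracts
#'
#' Each recipient has a major genepool; ancestry along each haplotype follows
#' a two-state Markov tract process (switch probability over `d` bp equal to
#' `1 - exp(-g * r * d)`, minor state drawn with probability `m`). Within a
#' tract, alleles are copied from one randomly chosen donor haplotype of a
#' randomly chosen race of the tract's genepool, with a small per-site
#' miscopy rate. Under selfing the two haplotypes of a line are identical.
#' Engineered adaptive loci, if configured, overwrite the tract state of a
#' fraction of accessions before alleles are copied.
#'
#' @param config a [sim_config()].
#' @param donors output of [simulate_donors()]; regenerated when `NULL`.
#' @return list with `panel` (recipients), `truth` (tibble `hap_id`,
#'   `sample_id`, `chrom`, `start`, `end`, `race`, `genepool`), `groups`
#'   (recipient metadata incl. the true major genepool) and the donor set.
#' @export
simulate_recipients <- function(config, donors = NULL) {
  if (is.null(donors)) donors <- simulate_donors(config)
  set.seed(config$seed + 2L)
  n <- config$n_recipients
  n_and <- round(n * config$recipient_and_frac)
  major <- c(rep("AND", n_and), rep("MES", n - n_and))
  sample_ids <- sprintf("EU_%03d", seq_len(n))
  races <- split(donors$groups$sample_id, donors$groups$group)
  race_of_pool <- split(names(config$donor_group_sizes),
                        race_genepool(names(config$donor_group_sizes)))
  chroms <- unique(donors$panel$sites$chrom)
  site_pos <- split(donors$panel$sites$pos, donors$panel$sites$chrom)
  site_idx <- split(seq_len(n_sites(donors$panel)), donors$panel$sites$chrom)

  hap <- matrix(NA_integer_, nrow = 2L * n, ncol = n_sites(donors$panel))
  truth <- list()
  for (i in seq_len(n)) {
    n_hap_draw <- if (config$selfing) 1L else 2L
    for (k in seq_len(2L)) {
      if (config$selfing && k == 2L) {
        hap[2L * i, ] <- hap[2L * i - 1L, ]
        t2 <- truth[[length(truth)]]
        t2$hap_id <- paste0(sample_ids[i], "_2")
        truth[[length(truth) + 1L]] <- t2
        next
      }
      per_chrom <- list()
      for (ch in chroms) {
        tr <- sim_tracts_one(config$chrom_len_bp, config$m, config$g, config$r)
        tr$genepool <- ifelse(tr$minor, setdiff(c("AND", "MES"), major[i]),
                              major[i])
        tr$chrom <- ch
        per_chrom[[ch]] <- tr
      }
      tr <- dplyr::bind_rows(per_chrom)
      if (!is.null(config$adaptive_loci)) {
        for (j in seq_len(nrow(config$adaptive_loci))) {
          al <- config$adaptive_loci[j, ]
          if (stats::runif(1) < al$frac) {
            tr <- force_tract(tr, al$chrom, al$pos - al$width_bp / 2,
                              al$pos + al$width_bp / 2, al$ancestry,
                              config$chrom_len_bp)
          }
        }
      }
      tr$race <- vapply(tr$genepool, function(gp)
        sample(race_of_pool[[gp]], 1L), "")
      tr$hap_id <- paste0(sample_ids[i], "_", k)
      tr$sample_id <- sample_ids[i]
      # copy alleles tract by tract
      row <- 2L * i - (2L - k)
      for (j in seq_len(nrow(tr))) {
        ch <- tr$chrom[j]
        in_tr <- site_idx[[ch]][site_pos[[ch]] >= tr$start[j] &
                                  site_pos[[ch]] < tr$end[j]]
        if (!length(in_tr)) next
        donor_id <- sample(races[[tr$race[j]]], 1L)
        drow <- sample_rows(donors$panel, donor_id)[sample.int(2L, 1L)]
        al <- donors$panel$haplotypes[drow, in_tr]
        flip <- stats::runif(length(al)) < config$miscopy
        al[flip] <- 1L - al[flip]
        hap[row, in_tr] <- al
      }
      truth[[length(truth) + 1L]] <-
        tr[, c("hap_id", "sample_id", "chrom", "start", "end", "race",
               "genepool")]
    }
  }
  panel <- hap_panel(hap, donors$panel$sites, sample_ids)
  rec_groups <- tibble::tibble(sample_id = sample_ids,
                               group = paste0("EU_", major),
                               genepool = major, role = "recipient")
  list(panel = panel, truth = dplyr::bind_rows(truth), groups = rec_groups,
       donors = donors)
}

# Overwrite tract state on [start, end) with the given genepool, re-tiling
# the affected chromosome so tracts stay gap- and overlap-free.
force_tract <- function(tr, chrom, start, end, genepool, chrom_len) {
  start <- max(0, start); end <- min(chrom_len, end)
  on_chr <- tr$chrom == chrom
  keep <- tr[!on_chr, ]
  cur <- tr[on_chr, ]
  pieces <- list()
  for (j in seq_len(nrow(cur))) {
    s <- cur$start[j]; e <- cur$end[j]
    if (e <= start || s >= end) {
      pieces[[length(pieces) + 1L]] <- cur[j, ]
    } else {
      if (s < start) {
        left <- cur[j, ]; left$end <- start
        pieces[[length(pieces) + 1L]] <- left
      }
      if (e > end) {
        right <- cur[j, ]; right$start <- end
        pieces[[length(pieces) + 1L]] <- right
      }
    }
  }
  forced <- cur[1, ]
  forced$start <- start; forced$end <- end
  forced$genepool <- genepool
  forced$minor <- NA
  out <- dplyr::bind_rows(dplyr::bind_rows(pieces), forced) |>
    dplyr::arrange(.data$start)
  dplyr::bind_rows(keep, out)
}

#' Per-variant effect classes and a gene model
#'
#' Genes of length `gene_len` are tiled every `gene_spacing` bp; every variant
#' draws an effect class from `effect_props` and is mapped to its covering
#' gene (or `NA` between genes).
#'
#' @param config a [sim_config()].
#' @param panel the panel to annotate.
#' @return list with `variants` (tibble `chrom`, `pos`, `effect`, `gene_id`)
#'   and `genes` (tibble `gene_id`, `chrom`, `start`, `end`).
#' @export
simulate_annotation <- function(config, panel) {
  set.seed(config$seed + 3L)
  genes <- purrr::map_dfr(unique(panel$sites$chrom), function(ch) {
    starts <- seq(0, config$chrom_len_bp - config$gene_len,
                  by = config$gene_spacing)
    tibble::tibble(gene_id = sprintf("%s_g%04d", ch, seq_along(starts)),
                   chrom = ch, start = starts, end = starts + config$gene_len)
  })
  eff <- sample(names(config$effect_props), n_sites(panel), replace = TRUE,
                prob = config$effect_props)
  gid <- rep(NA_character_, n_sites(panel))
  for (ch in unique(panel$sites$chrom)) {
    gsub_ <- genes[genes$chrom == ch, ]
    si <- which(panel$sites$chrom == ch)
    hit <- findInterval(panel$sites$pos[si], gsub_$start)
    ok <- hit >= 1 & panel$sites$pos[si] < gsub_$end[pmax(hit, 1)]
    gid[si[ok]] <- gsub_$gene_id[hit[ok]]
  }
  list(variants = tibble::tibble(chrom = panel$sites$chrom,
                                 pos = panel$sites$pos,
                                 effect = eff, gene_id = gid),
       genes = genes)
}

#' Group-structured quantitative traits with replicates
#'
#' Each trait value is a group mean (variance `sigma2_b`), plus a line
#' deviation (`sigma2_w`), plus replicate noise (`sigma2_e`); expected
#' broad-sense heritability is
#' `(sigma2_b + sigma2_w) / (sigma2_b + sigma2_w + sigma2_e)`.
#'
#' @param config a [sim_config()].
#' @param groups tibble with `sample_id` and `group` (the structuring factor).
#' @param trait_name name for the simulated trait.
#' @return tibble `sample_id`, `group`, `trait`, `rep`, `value`.
#' @export
simulate_traits <- function(config, groups, trait_name = "trait1") {
  stopifnot(config$n_reps >= 1)
  set.seed(config$seed + 4L)
  gl <- unique(groups$group)
  mu <- stats::setNames(stats::rnorm(length(gl), 0, sqrt(config$sigma2_b)), gl)
  line <- stats::rnorm(nrow(groups), 0, sqrt(config$sigma2_w))
  tidyr::expand_grid(i = seq_len(nrow(groups)), rep = seq_len(config$n_reps)) |>
    dplyr::mutate(sample_id = groups$sample_id[.data$i],
                  group = groups$group[.data$i],
                  trait = trait_name,
                  value = mu[.data$group] + line[.data$i] +
                    stats::rnorm(dplyr::n(), 0, sqrt(config$sigma2_e))) |>
    dplyr::select("sample_id", "group", "trait", "rep", "value")
}

#' Run the whole generator
#'
#' Convenience wrapper producing donors, recipients with truth tracts,
#' annotation and traits in one call, all reproducible from
#' `(config, config$seed)`.
#'
#' @param config a [sim_config()].
#' @return list with `panel` (donors + recipients combined), `donor_panel`,
#'   `recipient_panel`, `groups` (all accessions), `truth`, `annotation`,
#'   `traits` and `chrom_lengths`.
#' @export
simulate_panel <- function(config) {
  rec <- simulate_recipients(config)
  donors <- rec$donors
  combined <- hap_panel(rbind(donors$panel$haplotypes, rec$panel$haplotypes),
                        donors$panel$sites,
                        c(donors$panel$sample_ids, rec$panel$sample_ids))
  groups <- dplyr::bind_rows(donors$groups, rec$groups)
  ann <- simulate_annotation(config, combined)
  traits <- simulate_traits(config, groups)
  list(panel = combined, donor_panel = donors$panel,
       recipient_panel = rec$panel, groups = groups, truth = rec$truth,
       annotation = ann, traits = traits,
       chrom_lengths = tibble::tibble(
         chrom = unique(combined$sites$chrom),
         length = config$chrom_len_bp))
}
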