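#' Screen out inbred populations
#'
#' Inbreeding inflates homozygosity at many loci at once, whereas null
#' alleles act locus by locus; populations in which many loci show a
#' significant heterozygote deficit are therefore flagged as inbred and
#' excluded before null-allele assessment. A population is excluded when at
#' least `min_loci` loci have positive inbreeding coefficient
#' ([fis()] > 0) and a [u_test_het_deficiency()] p-value below `alpha`.
#'
#' @param ds an [msat_dataset()].
#' @param alpha per-locus significance level, default 0.05.
#' @param min_loci exclusion threshold; default `ceiling(0.2 * n_loci)`
#'   (20% of loci or more).
#' @param n_perm permutations for the U-tests, default 10000.
#' @param seed optional integer seed.
#' @return list with `retained` and `excluded` site labels and a data frame
#'   `counts` (site, number of significantly inbred loci).
#' @export
screen_inbred_pops <- function(ds, alpha = 0.05, min_loci = NULL,
                               n_perm = 10000, seed = NULL) {
  if (is.null(min_loci)) min_loci <- ceiling(0.2 * nrow(ds$loci))
  sites <- unique(ds$meta$site)
  run_seeded(seed, {
    counts <- vapply(sites, function(s) {
      hits <- 0L
      for (loc in ds$loci$name) {
        g <- locus_pop_calls(ds, loc, s)
        if (nrow(g) < 2L) next
        f <- fis(g)
        if (is.na(f) || f <= 0) next
        ut <- u_test_het_deficiency(g, n_perm = n_perm)
        if (ut$p_value < alpha) hits <- hits + 1L
      }
      hits
    }, integer(1))
    excluded <- sites[counts >= min_loci]
    list(retained = setdiff(sites, excluded), excluded = excluded,
         counts = data.frame(site = sites, n_inbred_loci = unname(counts),
                             stringsAsFactors = FALSE))
  })
}

#' Brookfield null-allele frequency estimate
#'
#' Estimator 1 of Brookfield: \eqn{r = (H_E - H_O)/(1 + H_E)}, floored at
#' zero. Appropriate when missing data are not attributed to null-allele
#' homozygotes.
#'
#' @param h_e,h_o expected and observed heterozygosity.
#' @return estimated null-allele frequency in `[0, H_E/(1+H_E)]`.
#' @export
brookfield_r <- function(h_e, h_o) {
  pmax(0, (h_e - h_o) / (1 + h_e))
}

#' Detect a null allele at one locus in one population
#'
#' A null allele is inferred when there is a significant excess of
#' homozygotes spread evenly across the homozygote classes: for each allele
#' class, the observed homozygote count is compared with its distribution
#' under Hardy-Weinberg proportions (randomizations of the allele vector);
#' the one-sided per-class p-values are combined with
#' [fisher_combine()]. The null frequency is then estimated with
#' [brookfield_r()].
#'
#' @param g two-column matrix of allele calls.
#' @param n_perm randomizations, default 1000.
#' @param alpha significance level for the combined test, default 0.05.
#' @param seed optional integer seed.
#' @return list `significant` (logical), `r_hat`, `p_combined`, and the
#'   per-class table `classes`. Monomorphic input gives
#'   `significant = FALSE`, `r_hat = 0`. Method tag: `"mc_like"`, a
#'   reconstruction of the classic homozygote-excess scan from its verbal
#'   description.
#' @export
detect_null <- function(g, n_perm = 1000, alpha = 0.05, seed = NULL) {
  g <- drop_missing(g)
  alleles <- sort(unique(c(g[, 1], g[, 2])))
  if (length(alleles) < 2L || nrow(g) < 2L)
    return(list(significant = FALSE, r_hat = 0, p_combined = 1,
                classes = NULL, method = "mc_like"))
  a <- c(g[, 1], g[, 2])
  lev <- factor(a, levels = alleles)
  obs_hom <- as.numeric(table(factor(g[g[, 1] == g[, 2], 1],
                                     levels = alleles)))
  hits <- rep(0L, length(alleles))
  run_seeded(seed, {
    for (b in seq_len(n_perm)) {
      gs <- sample_levene(a)
      sh <- as.numeric(table(factor(gs[gs[, 1] == gs[, 2], 1],
                                    levels = alleles)))
      hits <- hits + as.integer(sh >= obs_hom)
    }
  })
  pcls <- (hits + 1) / (n_perm + 1)
  pc <- fisher_combine(pcls)
  hs <- het_stats(g)
  list(significant = pc < alpha,
       r_hat = unname(brookfield_r(hs["H_E"], hs["H_O"])),
       p_combined = pc,
       classes = data.frame(allele = alleles, observed_hom = obs_hom,
                            p = pcls),
       method = "mc_like")
}

#' Null-allele scan over loci and populations
#'
#' Runs [detect_null()] for every locus in every retained population.
#'
#' @param ds an [msat_dataset()].
#' @param pops populations to scan (default: all sites).
#' @param n_perm,alpha,seed passed to [detect_null()].
#' @return data frame with columns `locus`, `pop`, `r_hat`, `significant`.
#' @export
null_allele_cells <- function(ds, pops = NULL, n_perm = 1000, alpha = 0.05,
                              seed = NULL) {
  if (is.null(pops)) pops <- unique(ds$meta$site)
  run_seeded(seed, {
    rows <- list()
    for (loc in ds$loci$name) for (s in pops) {
      d <- detect_null(locus_pop_calls(ds, loc, s), n_perm = n_perm,
                       alpha = alpha)
      rows[[length(rows) + 1L]] <-
        data.frame(locus = loc, pop = s, r_hat = d$r_hat,
                   significant = d$significant, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Cumulative null-allele burden and rank per locus
#'
#' For each locus, sums the estimated null frequencies over the populations
#' with a significant homozygote excess (`r_cumulative`), capturing both
#' prevalence and severity, and ranks loci from worst (rank 1, largest
#' burden) to best. Tied loci (typically the zero-burden block) share the
#' first rank position of their block, as in `rank(ties.method = "min")`.
#'
#' @param cells data frame from [null_allele_cells()] (columns `locus`,
#'   `pop`, `r_hat`, `significant`).
#' @return data frame `locus`, `r_cumulative`, `null_rank`, loci in first
#'   appearance order.
#' @export
r_cumulative_rank <- function(cells) {
  stopifnot(all(c("locus", "pop", "r_hat", "significant") %in% names(cells)))
  loci <- unique(cells$locus)
  rc <- vapply(loci, function(l) {
    sel <- cells$locus == l & cells$significant
    sum(cells$r_hat[sel])
  }, numeric(1))
  data.frame(locus = loci, r_cumulative = unname(rc),
             null_rank = rank(-rc, ties.method = "min"),
             stringsAsFactors = FALSE)
}

#' Rescale a sequenced allele's repeat count to the median-sized allele
#'
#' The repeat count observed in the one directly sequenced allele is scaled
#' proportionally to the length of the median-sized allele of the gene pool:
#' `seq_repeats * median_allele_length / seq_allele_length`. This serves as
#' a per-locus proxy for mutation rate (and hence homoplasy potential),
#' since slippage rates rise with the number of contiguous repeat units.
#'
#' @param seq_repeats contiguous repeat units in the sequenced allele.
#' @param seq_allele_length bp length of the trimmed sequenced allele.
#' @param median_allele_length bp length of the median allele.
#' @return inferred repeat count of the median allele (real-valued).
#' @export
scale_repeats <- function(seq_repeats, seq_allele_length,
                          median_allele_length) {
  if (any(seq_allele_length <= 0)) stop("seq_allele_length must be positive")
  if (any(median_allele_length <= 0))
    stop("median_allele_length must be positive")
  seq_repeats * median_allele_length / seq_allele_length
}

#' Median allele length per locus
#'
#' Computed over all non-missing allele copies in the dataset (both alleles
#' of every individual). With an even number of copies the arithmetic mean
#' of the two central values is taken, so half-integer medians occur.
#'
#' @param ds an [msat_dataset()].
#' @return named numeric vector, bp per locus.
#' @export
median_allele_length <- function(ds) {
  vapply(seq_len(nrow(ds$loci)), function(j) {
    a <- c(ds$calls[, j, 1], ds$calls[, j, 2])
    stats::median(a[!is.na(a)])
  }, numeric(1)) |> stats::setNames(ds$loci$name)
}

#' Rank loci by homoplasy potential
#'
#' Descending rescaled repeat count: rank 1 = most repeat units = greatest
#' potential for alleles identical in state but not by descent. Ties share
#' their block's first rank position.
#'
#' @param median_repeats named numeric vector from [scale_repeats()].
#' @return data frame `locus`, `median_repeats`, `repeat_rank`.
#' @export
homoplasy_rank <- function(median_repeats) {
  data.frame(locus = names(median_repeats),
             median_repeats = unname(median_repeats),
             repeat_rank = rank(-median_repeats, ties.method = "min"),
             stringsAsFactors = FALSE)
}

#' Probability of identity
#'
#' Chance that two individuals drawn at random from a panmictic population
#' share the same genotype: per locus
#' \eqn{PI = 2(\sum_i p_i^2)^2 - \sum_i p_i^4}; across loci the product.
#' Allele frequencies are pooled over the whole dataset.
#'
#' @param ds an [msat_dataset()].
#' @return list with `per_locus` (named vector) and `multi_locus` (scalar).
#' @export
probability_of_identity <- function(ds) {
  per <- vapply(seq_len(nrow(ds$loci)), function(j) {
    g <- drop_missing(matrix(ds$calls[, j, ], ncol = 2))
    if (nrow(g) == 0L) return(NA_real_)
    p <- allele_freq_vector(g)
    2 * sum(p^2)^2 - sum(p^4)
  }, numeric(1))
  names(per) <- ds$loci$name
  list(per_locus = per, multi_locus = prod(per, na.rm = TRUE))
}

#' Per-locus noise report
#'
#' Combines the null-allele scan and the homoplasy proxy into one table.
#' Requires locus annotations `seq_repeats` and `seq_allele_length` in
#' `ds$loci` (or supplied via `annotations`).
#'
#' @param ds an [msat_dataset()].
#' @param cells optional precomputed [null_allele_cells()] table (e.g.
#'   restricted to outbred populations); computed over all sites otherwise.
#' @param annotations optional data frame `name`, `seq_repeats`,
#'   `seq_allele_length` overriding `ds$loci`.
#' @param median_lengths optional named vector of median allele lengths (bp);
#'   computed from the dataset by default.
#' @param n_perm,alpha,seed passed to [null_allele_cells()] when `cells` is
#'   not supplied.
#' @return data frame, one row per locus: `locus`, `r_cumulative`,
#'   `null_rank`, `median_allele_length`, `median_repeats`, `repeat_rank`.
#' @export
locus_noise_report <- function(ds, cells = NULL, annotations = NULL,
                               median_lengths = NULL, n_perm = 1000,
                               alpha = 0.05, seed = NULL) {
  ann <- if (is.null(annotations)) ds$loci else annotations
  need <- c("name", "seq_repeats", "seq_allele_length")
  if (!all(need %in% names(ann)))
    stop("locus annotations must provide ", paste(need, collapse = ", "))
  ann <- ann[match(ds$loci$name, ann$name), ]
  if (anyNA(ann$name)) stop("annotations missing for some loci")
  if (is.null(cells))
    cells <- null_allele_cells(ds, n_perm = n_perm, alpha = alpha,
                               seed = seed)
  nullr <- r_cumulative_rank(cells)
  nullr <- nullr[match(ds$loci$name, nullr$locus), ]
  ml <- if (is.null(median_lengths)) median_allele_length(ds)
        else median_lengths[ds$loci$name]
  mr <- scale_repeats(ann$seq_repeats, ann$seq_allele_length, ml)
  names(mr) <- ds$loci$name
  hr <- homoplasy_rank(mr)
  data.frame(locus = ds$loci$name,
             r_cumulative = nullr$r_cumulative,
             null_rank = nullr$null_rank,
             median_allele_length = unname(ml),
             median_repeats = hr$median_repeats,
             repeat_rank = hr$repeat_rank,
             stringsAsFactors = FALSE)
}
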