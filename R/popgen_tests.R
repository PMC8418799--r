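#' Extract one locus/one population genotype matrix
#'
#' Convenience accessor: the non-missing diploid calls (n x 2 integer matrix
#' of allele sizes) for a single locus in a single site (or the whole
#' dataset).
#'
#' @param ds an [msat_dataset()].
#' @param locus locus name.
#' @param site site label, or `NULL` for all individuals.
#' @return integer matrix with two columns, one row per scored individual.
#' @export
locus_pop_calls <- function(ds, locus, site = NULL) {
  j <- match(locus, ds$loci$name)
  if (is.na(j)) stop("unknown locus: ", locus)
  keep <- if (is.null(site)) rep(TRUE, length(ds$individuals))
          else ds$meta$site == site
  g <- ds$calls[keep, j, , drop = FALSE]
  g <- matrix(g, ncol = 2)
  g[!is.na(g[, 1]), , drop = FALSE]
}

#' Observed and unbiased expected heterozygosity
#'
#' `H_O` is the heterozygote fraction among scored genotypes; `H_E` is the
#' small-sample unbiased expected heterozygosity
#' \eqn{\frac{2n}{2n-1}(1 - \sum_i p_i^2)}.
#'
#' @param g two-column matrix of non-missing allele calls.
#' @return named numeric vector `c(H_O =, H_E =)`.
#' @export
het_stats <- function(g) {
  g <- drop_missing(g)
  n <- nrow(g)
  if (n == 0L) stop("no non-missing genotypes")
  ho <- mean(g[, 1] != g[, 2])
  p <- allele_freq_vector(g)
  he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  c(H_O = ho, H_E = he)
}

drop_missing <- function(g) {
  g <- matrix(as.integer(g), ncol = 2)
  g[stats::complete.cases(g), , drop = FALSE]
}

allele_freq_vector <- function(g) {
  a <- c(g[, 1], g[, 2])
  tab <- table(a)
  p <- as.numeric(tab) / length(a)
  names(p) <- names(tab)
  p
}

## Levene conditional log-probability of a genotype table given allele counts:
## log P = log n! + h log 2 + sum log a_k! - log (2n)! - sum log n_ij!
## where h = number of heterozygotes. Constant terms (allele counts are
## conditioned on) are retained; comparisons are within one conditional class.
levene_logprob <- function(g) {
  n <- nrow(g)
  a <- c(g[, 1], g[, 2])
  ak <- table(a)
  h <- sum(g[, 1] != g[, 2])
  key <- paste(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2]))
  nij <- table(key)
  lgamma(n + 1) + h * log(2) + sum(lgamma(ak + 1)) -
    lgamma(2 * n + 1) - sum(lgamma(nij + 1))
}

## Draw one table from the Levene distribution by permuting the allele
## vector and pairing consecutive entries.
sample_levene <- function(a) {
  a <- sample(a)
  cbind(a[seq(1, length(a), by = 2)], a[seq(2, length(a), by = 2)])
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided probability test: the p-value is the total conditional
#' (Levene) probability, given the observed allele counts, of genotype
#' tables no more probable than the observed one. For two-allele tables the
#' table space is enumerated exactly; otherwise the null distribution is
#' sampled by Monte-Carlo permutation of the allele vector (an i.i.d. draw
#' from the same conditional distribution the usual Markov-chain walk
#' targets), with add-one smoothing `(exceedances + 1)/(B + 1)`.
#'
#' @param g two-column matrix of allele calls (missing rows dropped).
#' @param n_perm Monte-Carlo sample count, default 10000.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param method `"auto"` (enumerate two-allele tables, else Monte-Carlo),
#'   `"enum"` or `"mc"`.
#' @return list of class `msat_test` with `statistic` (the observed
#'   conditional log-probability), `p_value`, `n_permutations`, `method`.
#' @export
hwe_exact <- function(g, n_perm = 10000, seed = NULL,
                      method = c("auto", "enum", "mc")) {
  method <- match.arg(method)
  g <- drop_missing(g)
  alleles <- sort(unique(c(g[, 1], g[, 2])))
  if (length(alleles) < 2L) {
    warning("monomorphic locus: HWE test undefined, p = 1")
    return(msat_test(NA_real_, 1, 0L, "hwe_exact"))
  }
  obs <- levene_logprob(g)
  tol <- 1e-9
  if (method == "enum" || (method == "auto" && length(alleles) == 2L)) {
    if (length(alleles) != 2L)
      stop("enumeration implemented for two-allele tables only")
    d <- hwe_enum_2allele(g)
    p <- sum(d$prob[d$logprob <= obs + tol])
    return(msat_test(obs, min(p, 1), 0L, "hwe_exact_enum"))
  }
  a <- c(g[, 1], g[, 2])
  hits <- 0L
  run_seeded(seed, {
    for (b in seq_len(n_perm)) {
      if (levene_logprob(sample_levene(a)) <= obs + tol) hits <- hits + 1L
    }
  })
  msat_test(obs, (hits + 1) / (n_perm + 1), n_perm, "hwe_exact_mc")
}

## Full enumeration of the two-allele conditional distribution: given allele
## counts (nA, nB), tables are indexed by the heterozygote count h, which
## shares the parity of nA and runs 0..min(nA, nB).
hwe_enum_2allele <- function(g) {
  a <- c(g[, 1], g[, 2])
  ak <- table(a)
  nA <- as.integer(ak[1]); nB <- as.integer(ak[2])
  n <- nrow(g)
  hs <- seq(nA %% 2L, min(nA, nB), by = 2L)
  logp <- vapply(hs, function(h) {
    naa <- (nA - h) / 2; nbb <- (nB - h) / 2
    lgamma(n + 1) + h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) -
      lgamma(2 * n + 1) - (lgamma(naa + 1) + lgamma(h + 1) + lgamma(nbb + 1))
  }, numeric(1))
  data.frame(h = hs, logprob = logp, prob = exp(logp))
}

msat_test <- function(statistic, p, n_perm, method) {
  structure(list(statistic = unname(statistic), p_value = unname(p),
                 n_permutations = n_perm, method = method),
            class = "msat_test")
}

#' @export
print.msat_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s)\n", x$method,
              x$statistic, x$p_value,
              if (x$n_permutations > 0)
                paste(x$n_permutations, "Monte-Carlo samples")
              else "exact"))
  invisible(x)
}

## Score statistic for heterozygote deficiency: homozygote excess per
## allele class weighted by the inverse allele frequency,
## U = sum_i (O_ii - E_ii) / p_i, with the Levene expectation
## E_ii = n_i (n_i - 1) / (2 (2n - 1)).
u_statistic <- function(g) {
  n <- nrow(g)
  a <- c(g[, 1], g[, 2])
  ak <- table(a)
  p <- as.numeric(ak) / (2 * n)
  hom <- g[g[, 1] == g[, 2], 1]
  o <- as.numeric(table(factor(hom, levels = names(ak))))
  e <- as.numeric(ak) * (as.numeric(ak) - 1) / (2 * (2 * n - 1))
  sum((o - e) / p)
}

#' U-test of heterozygote deficiency
#'
#' One-sided Monte-Carlo score test against the panmixia null: the statistic
#' weights each allele class's homozygote excess by the inverse allele
#' frequency; the p-value is the fraction of conditional (allele-permutation)
#' tables with a statistic at least as large, with add-one smoothing.
#'
#' @inheritParams hwe_exact
#' @return an `msat_test` (method `"u_test"`).
#' @export
u_test_het_deficiency <- function(g, n_perm = 10000, seed = NULL) {
  g <- drop_missing(g)
  alleles <- unique(c(g[, 1], g[, 2]))
  if (length(alleles) < 2L)
    return(msat_test(NA_real_, 1, 0L, "u_test"))
  obs <- u_statistic(g)
  a <- c(g[, 1], g[, 2])
  tol <- 1e-9
  hits <- 0L
  run_seeded(seed, {
    for (b in seq_len(n_perm)) {
      if (u_statistic(sample_levene(a)) >= obs - tol) hits <- hits + 1L
    }
  })
  msat_test(obs, (hits + 1) / (n_perm + 1), n_perm, "u_test")
}

#' Within-population inbreeding coefficient
#'
#' Small-sample form \eqn{f = 1 - H_O / H_E} with the unbiased expected
#' heterozygosity of [het_stats()]. Positive values indicate heterozygote
#' deficit relative to Hardy-Weinberg proportions.
#'
#' @param g two-column matrix of allele calls.
#' @return numeric scalar, `NA` if the locus is monomorphic.
#' @export
fis <- function(g) {
  g <- drop_missing(g)
  hs <- het_stats(g)
  if (hs["H_E"] == 0) return(NA_real_)
  unname(1 - hs["H_O"] / hs["H_E"])
}

#' Fisher's combined probability test
#'
#' \eqn{X = -2 \sum \ln p_i} referred to a chi-square distribution with
#' `2k` degrees of freedom.
#'
#' @param pvals p-values in (0, 1]; `NA`s are dropped.
#' @return combined p-value.
#' @export
fisher_combine <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0L) stop("no p-values to combine")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  x <- -2 * sum(log(pvals))
  stats::pchisq(x, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Sequential Bonferroni (Holm step-down) significance flags
#'
#' Sorts p-values ascending and rejects while
#' \eqn{p_{(i)} \le \alpha / (m - i + 1)}, stopping at the first failure.
#'
#' @param pvals numeric vector of p-values.
#' @param alpha family-wise error rate, default 0.05.
#' @return logical vector of rejections, in the input order.
#' @export
sequential_bonferroni <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0L) stop("empty p-value list")
  stats::p.adjust(pvals, method = "holm") <= alpha
}

#' Genotypic linkage-equilibrium test for a locus pair
#'
#' Within each population, a Monte-Carlo contingency test on the two-locus
#' genotype table (log-likelihood-ratio statistic, genotypes at one locus
#' permuted across individuals); per-population p-values are combined across
#' populations with [fisher_combine()]. Genotypes are never pooled across
#' sites.
#'
#' @param ds an [msat_dataset()].
#' @param locus_a,locus_b locus names.
#' @param n_perm permutations per population, default 10000.
#' @param seed optional integer seed.
#' @return an `msat_test` (method `"le_test"`), or p `NA` when no population
#'   has enough joint data.
#' @export
le_test <- function(ds, locus_a, locus_b, n_perm = 10000, seed = NULL) {
  run_seeded(seed, {
    ps <- numeric(0)
    for (s in unique(ds$meta$site)) {
      ga <- locus_pop_pair(ds, locus_a, s)
      gb <- locus_pop_pair(ds, locus_b, s)
      ok <- !is.na(ga) & !is.na(gb)
      if (sum(ok) < 2L) next
      fa <- factor(ga[ok]); fb <- factor(gb[ok])
      if (nlevels(fa) < 2L || nlevels(fb) < 2L) next
      obs <- g_statistic(table(fa, fb))
      hits <- 0L
      for (b in seq_len(n_perm)) {
        if (g_statistic(table(fa, sample(fb))) >= obs - 1e-9) hits <- hits + 1L
      }
      ps <- c(ps, (hits + 1) / (n_perm + 1))
    }
    if (length(ps) == 0L)
      msat_test(NA_real_, NA_real_, n_perm, "le_test")
    else
      msat_test(length(ps), fisher_combine(ps), n_perm, "le_test")
  })
}

## genotype-as-string vector for one locus in one site (NA when missing)
locus_pop_pair <- function(ds, locus, site) {
  j <- match(locus, ds$loci$name)
  if (is.na(j)) stop("unknown locus: ", locus)
  keep <- ds$meta$site == site
  a1 <- ds$calls[keep, j, 1]; a2 <- ds$calls[keep, j, 2]
  ifelse(is.na(a1), NA_character_, paste(a1, a2, sep = "/"))
}

g_statistic <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  idx <- tab > 0
  2 * sum(tab[idx] * log(tab[idx] / e[idx]))
}

#' All locus pairs of a dataset
#'
#' @param ds an [msat_dataset()].
#' @return two-column character matrix of the `n(n-1)/2` unordered pairs.
#' @export
locus_pairs <- function(ds) {
  nm <- ds$loci$name
  idx <- utils::combn(length(nm), 2)
  cbind(a = nm[idx[1, ]], b = nm[idx[2, ]])
}

## evaluate `expr` under an optional temporary seed (RNG state restored);
## the promise is forced in the caller's frame either way
run_seeded <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(seed, expr)
}
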