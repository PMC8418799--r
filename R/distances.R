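#' Per-population (or pooled) allele frequencies
#'
#' Frequencies over non-missing allele copies; support is the set of alleles
#' observed anywhere in the dataset at that locus, so population vectors at
#' one locus are comparable.
#'
#' @param ds an [msat_dataset()].
#' @param by `"site"` for per-population frequencies or `"pooled"` for one
#'   vector per locus over the whole dataset.
#' @return For `by = "pooled"`, a list (per locus) of named frequency
#'   vectors. For `by = "site"`, a list (per locus) of matrices
#'   (sites x alleles) of frequencies; rows of sites with no data are `NaN`.
#' @export
allele_freqs <- function(ds, by = c("site", "pooled")) {
  by <- match.arg(by)
  sites <- unique(ds$meta$site)
  out <- lapply(seq_len(nrow(ds$loci)), function(j) {
    all_a <- sort(unique(as.vector(ds$calls[, j, ])))
    if (by == "pooled") {
      a <- as.vector(ds$calls[, j, ])
      a <- a[!is.na(a)]
      tab <- table(factor(a, levels = all_a))
      p <- as.numeric(tab) / max(1, length(a))
      names(p) <- all_a
      return(p)
    }
    m <- matrix(NA_real_, length(sites), length(all_a),
                dimnames = list(sites, all_a))
    for (s in seq_along(sites)) {
      a <- as.vector(ds$calls[ds$meta$site == sites[s], j, ])
      a <- a[!is.na(a)]
      m[s, ] <- as.numeric(table(factor(a, levels = all_a))) / length(a)
    }
    m
  })
  names(out) <- ds$loci$name
  out
}

#' Cavalli-Sforza & Edwards chord distance
#'
#' \deqn{D_c = \frac{2}{\pi L} \sum_l \sqrt{2\,(1 - \sum_i \sqrt{x_{li} y_{li}})}}
#' over the `L` loci scorable in both populations. Robust for detecting
#' isolation by distance in the presence of null alleles.
#'
#' @param freqs per-site frequency list from `allele_freqs(ds, "site")`.
#' @param pop_a,pop_b site labels.
#' @return chord distance (`NA` when no locus is scorable in both).
#' @export
chord_distance <- function(freqs, pop_a, pop_b) {
  terms <- vapply(freqs, function(m) {
    x <- m[pop_a, ]; y <- m[pop_b, ]
    if (anyNA(x) || anyNA(y) || any(is.nan(x)) || any(is.nan(y)))
      return(NA_real_)
    sqrt(2 * max(0, 1 - sum(sqrt(x * y))))
  }, numeric(1))
  terms <- terms[!is.na(terms)]
  if (length(terms) == 0L) return(NA_real_)
  2 / (pi * length(terms)) * sum(terms)
}

#' Nei's standard genetic distance
#'
#' \eqn{D_s = -\ln( \bar J_{xy} / \sqrt{\bar J_x \bar J_y} )} with the gene
#' identities J averaged over loci before the log (the classic multi-locus
#' form). Increases linearly with time/geographic distance under
#' infinite-allele mutation at constant rate. Populations sharing no alleles
#' give `Inf`.
#'
#' @inheritParams chord_distance
#' @return numeric distance, possibly `Inf`.
#' @export
nei_standard <- function(freqs, pop_a, pop_b) {
  jx <- jy <- jxy <- numeric(0)
  for (m in freqs) {
    x <- m[pop_a, ]; y <- m[pop_b, ]
    if (anyNA(x) || anyNA(y) || any(is.nan(x)) || any(is.nan(y))) next
    jx <- c(jx, sum(x^2)); jy <- c(jy, sum(y^2)); jxy <- c(jxy, sum(x * y))
  }
  if (length(jx) == 0L) return(NA_real_)
  J <- mean(jxy) / sqrt(mean(jx) * mean(jy))
  if (J == 0) return(Inf)
  -log(J)
}

#' Linearized pairwise F_ST
#'
#' Multi-locus Weir-Cockerham theta for the two populations, transformed as
#' \eqn{\theta / (1 - \theta)} so that it scales linearly with distance in a
#' stepping-stone at migration-drift equilibrium. Negative theta estimates
#' are floored at zero before linearizing.
#'
#' @param ds an [msat_dataset()].
#' @param pop_a,pop_b site labels.
#' @return numeric; `Inf` when theta = 1.
#' @export
pairwise_fst_linearized <- function(ds, pop_a, pop_b) {
  th <- wc_theta(ds, sites = c(pop_a, pop_b))
  if (is.na(th)) return(NA_real_)
  th <- max(0, th)
  if (th >= 1) return(Inf)
  th / (1 - th)
}

#' Kinship similarity between two multilocus genotypes
#'
#' Per locus, the mean over the four cross-individual allele pairs of the
#' identity-in-state indicator; averaged over the loci scored in both
#' individuals (method tag `dkf_iis`).
#'
#' @param ga,gb two-column matrices of allele calls, rows = loci (aligned),
#'   `NA` for missing.
#' @return similarity in `[0, 1]`, `NA` if no shared scorable locus.
#' @export
kinship_dkf <- function(ga, gb) {
  ok <- !is.na(ga[, 1]) & !is.na(gb[, 1])
  if (!any(ok)) return(NA_real_)
  s <- (ga[ok, 1] == gb[ok, 1]) + (ga[ok, 1] == gb[ok, 2]) +
       (ga[ok, 2] == gb[ok, 1]) + (ga[ok, 2] == gb[ok, 2])
  mean(s / 4)
}

#' Proportion of shared alleles between two multilocus genotypes
#'
#' Multiset intersection of the two allele pairs at each locus (0, 1 or 2
#' shared alleles; an A/A vs A/B comparison shares one), summed over loci
#' and divided by twice the number of loci compared. Loci missing in either
#' individual are excluded from numerator and denominator.
#'
#' @inheritParams kinship_dkf
#' @return similarity in `[0, 1]`, `NA` if no shared scorable locus.
#' @export
shared_alleles_dps <- function(ga, gb) {
  ok <- !is.na(ga[, 1]) & !is.na(gb[, 1])
  if (!any(ok)) return(NA_real_)
  shared <- shared_allele_count(ga[ok, , drop = FALSE],
                                gb[ok, , drop = FALSE])
  sum(shared) / (2 * sum(ok))
}

## multiset intersection size of two sorted allele pairs, vectorized by row
shared_allele_count <- function(ga, gb) {
  ## pairs are stored sorted ascending, so the multiset intersection of
  ## {a1,a2} and {b1,b2} has a closed form
  eq11 <- ga[, 1] == gb[, 1]; eq12 <- ga[, 1] == gb[, 2]
  eq21 <- ga[, 2] == gb[, 1]; eq22 <- ga[, 2] == gb[, 2]
  ifelse(eq11 & eq22, 2L, as.integer(eq11 | eq12 | eq21 | eq22))
}

#' Lynch-Ritland pairwise relatedness
#'
#' Method-of-moments estimator using reference allele frequencies, so that a
#' shared rare allele counts as stronger evidence of identity by descent
#' than a shared common allele. With reference individual alleles (a, b) and
#' proband alleles (c, d):
#' \deqn{\hat r = \frac{p_a (S_{bc} + S_{bd}) + p_b (S_{ac} + S_{ad}) - 4 p_a p_b}
#'                     {(1 + S_{ab})(p_a + p_b) - 4 p_a p_b}}
#' Loci are combined by weights proportional to the inverse sampling
#' variance, \eqn{w = ((1 + S_{ab})(p_a + p_b) - 4 p_a p_b) / (2 p_a p_b)}.
#' The estimator is asymmetric in the two individuals, so the mean of both
#' directions is returned. Loci with zero denominator (e.g. a heterozygote
#' reference with both alleles at frequency 0.5) are skipped.
#'
#' @inheritParams kinship_dkf
#' @param freqs pooled frequency list from `allele_freqs(ds, "pooled")`,
#'   one named vector per locus (aligned with the rows of `ga`).
#' @return relatedness estimate (unbounded; ~0 for random pairs, ~0.5 for
#'   parent-offspring), `NA` if every locus is degenerate.
#' @export
lynch_ritland_r <- function(ga, gb, freqs) {
  r1 <- lr_directional(ga, gb, freqs)
  r2 <- lr_directional(gb, ga, freqs)
  if (is.na(r1) && is.na(r2)) return(NA_real_)
  mean(c(r1, r2), na.rm = TRUE)
}

## one direction: individual A is the reference (alleles a,b), B the proband
lr_directional <- function(ga, gb, freqs) {
  num <- den <- 0
  used <- FALSE
  for (l in seq_len(nrow(ga))) {
    if (is.na(ga[l, 1]) || is.na(gb[l, 1])) next
    p <- freqs[[l]]
    a <- ga[l, 1]; b <- ga[l, 2]; c_ <- gb[l, 1]; d <- gb[l, 2]
    pa <- p[as.character(a)]; pb <- p[as.character(b)]
    if (is.na(pa) || is.na(pb)) next
    sab <- as.numeric(a == b)
    sac <- as.numeric(a == c_); sad <- as.numeric(a == d)
    sbc <- as.numeric(b == c_); sbd <- as.numeric(b == d)
    denom <- (1 + sab) * (pa + pb) - 4 * pa * pb
    if (abs(denom) < 1e-12) next
    r_l <- (pa * (sbc + sbd) + pb * (sac + sad) - 4 * pa * pb) / denom
    w_l <- denom / (2 * pa * pb)
    num <- num + w_l * r_l
    den <- den + w_l
    used <- TRUE
  }
  if (!used || den == 0) return(NA_real_)
  unname(num / den)
}

#' Pairwise distance / similarity matrix
#'
#' Builds the full symmetric matrix for one metric, over sampling sites
#' (`level = "population"`: chord `"dc"`, Nei standard `"ds"`, linearized
#' F_ST `"fst_lin"`) or over individuals (`level = "individual"`: kinship
#' `"dkf"`, shared alleles `"dps"`, Lynch-Ritland relatedness `"lr"`).
#'
#' @param ds an [msat_dataset()].
#' @param metric one of `"dc"`, `"ds"`, `"fst_lin"`, `"dkf"`, `"dps"`,
#'   `"lr"`.
#' @param level `"population"` or `"individual"`; inferred from the metric
#'   when omitted.
#' @return object of class `msat_dist`: list with `labels`, `mat`
#'   (symmetric numeric matrix), `kind` (`"dissimilarity"` or
#'   `"similarity"`) and `metric`.
#' @export
distance_matrix <- function(ds, metric = c("dc", "ds", "fst_lin",
                                           "dkf", "dps", "lr"),
                            level = NULL) {
  metric <- match.arg(metric)
  pop_metrics <- c("dc", "ds", "fst_lin")
  if (is.null(level))
    level <- if (metric %in% pop_metrics) "population" else "individual"
  level <- match.arg(level, c("population", "individual"))
  if (xor(metric %in% pop_metrics, level == "population"))
    stop("metric '", metric, "' is not defined at level '", level, "'")
  kind <- if (metric %in% pop_metrics) "dissimilarity" else "similarity"

  if (level == "population") {
    labs <- unique(ds$meta$site)
    f <- allele_freqs(ds, "site")
    m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    for (i in seq_along(labs)) for (j in seq_len(i - 1L)) {
      v <- switch(metric,
                  dc = chord_distance(f, labs[i], labs[j]),
                  ds = nei_standard(f, labs[i], labs[j]),
                  fst_lin = pairwise_fst_linearized(ds, labs[i], labs[j]))
      m[i, j] <- m[j, i] <- v
    }
  } else {
    labs <- ds$individuals
    n <- length(labs)
    m <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
    f <- allele_freqs(ds, "pooled")
    vals <- if (metric == "lr") lr_all_pairs(ds, f)
            else pair_similarity_all(ds, metric)
    m[lower.tri(m)] <- vals
    m <- pmax(m, t(m), na.rm = TRUE)
    diag(m) <- vapply(seq_len(n), function(i) {
      ga <- matrix(ds$calls[i, , ], ncol = 2)
      switch(metric,
             dkf = kinship_dkf(ga, ga),
             dps = shared_alleles_dps(ga, ga),
             lr = lynch_ritland_r(ga, ga, f))
    }, numeric(1))
  }
  structure(list(labels = labs, mat = m, kind = kind, metric = metric),
            class = "msat_dist")
}

#' @export
print.msat_dist <- function(x, ...) {
  cat(sprintf("msat_dist '%s' (%s) over %d labels\n", x$metric, x$kind,
              length(x$labels)))
  invisible(x)
}

## vectorized dkf / dps over all unordered pairs, in lower.tri order
pair_similarity_all <- function(ds, metric) {
  n <- length(ds$individuals)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]          # i > j
  L <- nrow(ds$loci)
  num <- den <- numeric(length(i))
  for (l in seq_len(L)) {
    a1 <- ds$calls[, l, 1]; a2 <- ds$calls[, l, 2]
    ok <- !is.na(a1[i]) & !is.na(a1[j])
    if (!any(ok)) next
    ga <- cbind(a1[i][ok], a2[i][ok]); gb <- cbind(a1[j][ok], a2[j][ok])
    if (metric == "dps") {
      num[ok] <- num[ok] + shared_allele_count(ga, gb)
      den[ok] <- den[ok] + 2
    } else {
      s <- (ga[, 1] == gb[, 1]) + (ga[, 1] == gb[, 2]) +
           (ga[, 2] == gb[, 1]) + (ga[, 2] == gb[, 2])
      num[ok] <- num[ok] + s / 4
      den[ok] <- den[ok] + 1
    }
  }
  ifelse(den > 0, num / den, NA_real_)
}

## vectorized two-direction Lynch-Ritland over all pairs (lower.tri order)
lr_all_pairs <- function(ds, freqs) {
  n <- length(ds$individuals)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  num1 <- den1 <- num2 <- den2 <- numeric(length(i))
  for (l in seq_len(nrow(ds$loci))) {
    p <- freqs[[l]]
    a1 <- ds$calls[, l, 1]; a2 <- ds$calls[, l, 2]
    pv1 <- p[as.character(a1)]; pv2 <- p[as.character(a2)]
    ok <- !is.na(a1[i]) & !is.na(a1[j])
    if (!any(ok)) next
    ii <- i[ok]; jj <- j[ok]
    dir_acc <- function(ra1, ra2, rp1, rp2, pb1, pb2) {
      ## reference alleles ra*, reference freqs rp*, proband alleles pb*
      sab <- as.numeric(ra1 == ra2)
      sac <- as.numeric(ra1 == pb1); sad <- as.numeric(ra1 == pb2)
      sbc <- as.numeric(ra2 == pb1); sbd <- as.numeric(ra2 == pb2)
      denom <- (1 + sab) * (rp1 + rp2) - 4 * rp1 * rp2
      r_l <- (rp1 * (sbc + sbd) + rp2 * (sac + sad) - 4 * rp1 * rp2) / denom
      w_l <- denom / (2 * rp1 * rp2)
      good <- abs(denom) >= 1e-12
      list(wr = ifelse(good, w_l * r_l, 0), w = ifelse(good, w_l, 0))
    }
    d1 <- dir_acc(a1[ii], a2[ii], pv1[ii], pv2[ii], a1[jj], a2[jj])
    d2 <- dir_acc(a1[jj], a2[jj], pv1[jj], pv2[jj], a1[ii], a2[ii])
    num1[ok] <- num1[ok] + d1$wr; den1[ok] <- den1[ok] + d1$w
    num2[ok] <- num2[ok] + d2$wr; den2[ok] <- den2[ok] + d2$w
  }
  r1 <- ifelse(den1 > 0, num1 / den1, NA_real_)
  r2 <- ifelse(den2 > 0, num2 / den2, NA_real_)
  rowMeans(cbind(r1, r2), na.rm = TRUE)
}
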