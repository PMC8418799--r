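#' One-tailed Welch two-sample t-test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom;
#' alternative hypothesis `mean(a) > mean(b)` (i.e. removing loci from the
#' full set has *reduced* the mean of the metric).
#'
#' @param a,b numeric vectors (each at least 2 values).
#' @return list `t`, `df`, `p` (one-tailed).
#' @export
welch_one_tailed <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero variance in both samples")
  tt <- stats::t.test(a, b, alternative = "greater", var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Iterative worst-locus omission with a t-test stopping rule
#'
#' Removes the worst-ranked locus one at a time; after each removal the full
#' metric vector is compared with the reduced one by [welch_one_tailed()].
#' The procedure stops at the first removal count whose one-tailed p-value
#' falls below `alpha`. The entire trace is returned for audit.
#'
#' @param values named numeric vector: the per-locus noise metric.
#' @param ranks named integer vector: 1 = worst. Ties are broken by larger
#'   metric value, then by name, so the removal order is deterministic.
#' @param alpha stopping significance level, default 0.05.
#' @param max_frac maximum fraction of loci that may be removed before the
#'   search is abandoned, default 0.5.
#' @return list of class `selection_trace`: `trace` (data frame with columns
#'   `k`, `removed`, `t`, `df`, `p`), `stop_k` (`NA` if never significant),
#'   `removed` (locus names up to `stop_k`), `final_loci`.
#' @export
iterative_omit <- function(values, ranks, alpha = 0.05, max_frac = 0.5) {
  stopifnot(!is.null(names(values)), setequal(names(values), names(ranks)))
  ranks <- ranks[names(values)]
  ord <- names(values)[order(ranks, -values, names(values))]
  if (stats::var(values) == 0) {
    warning("metric is constant across loci; nothing to omit")
    return(structure(list(trace = NULL, stop_k = NA_integer_,
                          removed = character(0),
                          final_loci = names(values)),
                     class = "selection_trace"))
  }
  kmax <- floor(max_frac * length(values))
  rows <- list()
  stop_k <- NA_integer_
  for (k in seq_len(kmax)) {
    reduced <- values[setdiff(names(values), ord[seq_len(k)])]
    wt <- welch_one_tailed(values, reduced)
    rows[[k]] <- data.frame(k = k, removed = ord[k], t = wt$t, df = wt$df,
                            p = wt$p, stringsAsFactors = FALSE)
    if (wt$p < alpha) { stop_k <- k; break }
  }
  if (is.na(stop_k))
    warning("no removal count up to ", kmax,
            " achieved a significant reduction")
  trace <- do.call(rbind, rows)
  removed <- if (is.na(stop_k)) character(0) else ord[seq_len(stop_k)]
  structure(list(trace = trace, stop_k = stop_k, removed = removed,
                 final_loci = setdiff(names(values), removed)),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("selection_trace: stop at k =", x$stop_k, "\n")
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Build the low-noise dataset
#'
#' Runs [iterative_omit()] on the cumulative null-allele burden and on the
#' rescaled repeat count, removes the union of the two omission sets, and
#' re-runs both Welch comparisons plus a probability-of-identity guard
#' (checking that the discarded loci did not carry disproportionate
#' information content) on the final set.
#'
#' @param ds an [msat_dataset()].
#' @param noise per-locus table from [locus_noise_report()].
#' @param alpha stopping significance level, default 0.05.
#' @param n_omit_null,n_omit_homoplasy number of loci to drop on each axis;
#'   `NULL` (default) uses each trace's stopping index.
#' @return list: `dataset` (the reduced [msat_dataset()]), `removed`,
#'   `trace_null`, `trace_homoplasy`, `recheck_null`, `recheck_homoplasy`
#'   (Welch tests of the 33-vs-final metric vectors), `pi_check` (Welch test
#'   on per-locus PI, full vs reduced).
#' @export
build_lnds <- function(ds, noise, alpha = 0.05, n_omit_null = NULL,
                       n_omit_homoplasy = NULL) {
  vn <- stats::setNames(noise$r_cumulative, noise$locus)
  rn <- stats::setNames(noise$null_rank, noise$locus)
  vh <- stats::setNames(noise$median_repeats, noise$locus)
  rh <- stats::setNames(noise$repeat_rank, noise$locus)
  tn <- iterative_omit(vn, rn, alpha = alpha)
  th <- iterative_omit(vh, rh, alpha = alpha)
  ord_n <- names(vn)[order(rn, -vn, names(vn))]
  ord_h <- names(vh)[order(rh, -vh, names(vh))]
  kn <- if (is.null(n_omit_null)) tn$stop_k else n_omit_null
  kh <- if (is.null(n_omit_homoplasy)) th$stop_k else n_omit_homoplasy
  ## a metric that never reached a significant reduction removes nothing
  if (is.na(kn)) kn <- 0L
  if (is.na(kh)) kh <- 0L
  removed <- union(ord_n[seq_len(kn)], ord_h[seq_len(kh)])
  kept <- setdiff(noise$locus, removed)
  out <- subset_dataset(ds, loci = kept,
                        label = paste(ds$label, "LNDS"))
  safe_welch <- function(a, b) {
    tryCatch(welch_one_tailed(a, b),
             error = function(e) list(t = NA_real_, df = NA_real_,
                                      p = NA_real_))
  }
  pi_full <- probability_of_identity(ds)$per_locus
  list(dataset = out,
       removed = removed,
       trace_null = tn,
       trace_homoplasy = th,
       recheck_null = safe_welch(vn, vn[kept]),
       recheck_homoplasy = safe_welch(vh, vh[kept]),
       pi_check = safe_welch(pi_full, pi_full[kept]))
}

#' Per-locus global F_ST with descending ranks
#'
#' Weir-Cockerham theta for each locus across all sampling sites (two-level
#' variance components a, b, c summed over alleles), ranked from highest
#' (rank 1) to lowest, with the drop to the next rank
#' (`delta_fst`, used to spot natural breaks for high-signal retention).
#' Rank ties are broken by the unrounded theta, then by locus name.
#'
#' @param ds an [msat_dataset()] with at least two sites.
#' @return data frame `locus`, `fst`, `rank`, `delta_fst` (NA for the last
#'   rank), loci in input order. Loci monomorphic across all populations get
#'   `fst = NA` and are ranked last.
#' @export
per_locus_global_fst <- function(ds) {
  if (length(unique(ds$meta$site)) < 2L) stop("need >= 2 populations")
  theta <- vapply(ds$loci$name, function(l) wc_theta(ds, loci = l),
                  numeric(1))
  ord <- order(-theta, ds$loci$name, na.last = TRUE)
  rk <- integer(length(theta)); rk[ord] <- seq_along(theta)
  d <- rep(NA_real_, length(theta))
  sorted <- theta[ord]
  d[ord[-length(ord)]] <- sorted[-length(sorted)] - sorted[-1]
  data.frame(locus = ds$loci$name, fst = unname(theta), rank = rk,
             delta_fst = d, stringsAsFactors = FALSE)
}

#' Build a high-signal dataset
#'
#' Retains the `k` loci with the highest global F_ST ranks. The choice of
#' `k` is a judgement call made from the `delta_fst` column of the rank
#' table (inflection points in the rank-ordered F_ST distribution); it is a
#' parameter, not an automated break detection.
#'
#' @param ds an [msat_dataset()].
#' @param fst rank table from [per_locus_global_fst()].
#' @param k number of top-ranked loci to retain.
#' @return the reduced [msat_dataset()].
#' @export
build_hsds <- function(ds, fst, k) {
  if (k < 1L || k > nrow(fst)) stop("k out of range 1..", nrow(fst))
  keep <- fst$locus[fst$rank <= k]
  subset_dataset(ds, loci = keep, label = paste0(ds$label, " HSDS", k))
}

#' Multi-locus Weir-Cockerham theta
#'
#' Two-level (population / individual) variance components per allele per
#' locus: among-population (a), among-individual-within-population (b) and
#' within-individual (c, from observed heterozygosity); theta is the ratio
#' of the a-sum to the (a+b+c)-sum over alleles (and loci, when several are
#' given).
#'
#' @param ds an [msat_dataset()].
#' @param loci locus names to include (default all).
#' @param sites site labels to include (default all).
#' @return theta estimate (can be negative; `NA` if no informative locus).
#' @export
wc_theta <- function(ds, loci = NULL, sites = NULL) {
  if (is.null(loci)) loci <- ds$loci$name
  if (is.null(sites)) sites <- unique(ds$meta$site)
  A <- B <- C <- 0
  any_info <- FALSE
  for (l in loci) {
    comp <- wc_components(ds, l, sites)
    if (is.null(comp)) next
    any_info <- TRUE
    A <- A + sum(comp$a); B <- B + sum(comp$b); C <- C + sum(comp$c)
  }
  if (!any_info || A + B + C == 0) return(NA_real_)
  A / (A + B + C)
}

## Weir & Cockerham (1984) variance components for one locus, per allele.
## Returns NULL when < 2 populations have data or the locus is monomorphic.
wc_components <- function(ds, locus, sites) {
  j <- match(locus, ds$loci$name)
  glist <- lapply(sites, function(s) {
    g <- matrix(ds$calls[ds$meta$site == s, j, ], ncol = 2)
    g[!is.na(g[, 1]), , drop = FALSE]
  })
  glist <- glist[vapply(glist, nrow, integer(1)) > 0]
  r <- length(glist)
  if (r < 2L) return(NULL)
  alleles <- sort(unique(unlist(lapply(glist, as.vector))))
  if (length(alleles) < 2L) return(NULL)
  ni <- vapply(glist, nrow, integer(1))
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  a <- b <- cc <- numeric(length(alleles))
  for (k in seq_along(alleles)) {
    al <- alleles[k]
    pi <- vapply(glist, function(g) mean(c(g[, 1], g[, 2]) == al),
                 numeric(1))
    hi <- vapply(glist, function(g)
      mean((g[, 1] == al) != (g[, 2] == al)), numeric(1))
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a[k] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b[k] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[k] <- hbar / 2
  }
  list(a = a, b = b, c = cc, alleles = alleles)
}
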