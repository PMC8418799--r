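test_that("Welch test reproduces the four reference stopping statistics", {
  noise <- ref_noise_report()
  rcum <- setNames(noise$r_cumulative, noise$locus)
  mrep <- setNames(noise$median_repeats, noise$locus)
  null5 <- noise$locus[order(noise$null_rank, -rcum)][1:5]
  hom5 <- noise$locus[order(noise$repeat_rank)][1:5]

  w1 <- welch_one_tailed(rcum, rcum[setdiff(names(rcum), null5)])
  expect_equal(w1$t, 1.720, tolerance = 5e-4)
  expect_equal(round(w1$df), 40)

  union9 <- union(null5, hom5)
  expect_equal(length(union9), 9L)
  w3 <- welch_one_tailed(rcum, rcum[setdiff(names(rcum), union9)])
  expect_equal(w3$t, 1.520, tolerance = 5e-4)
  expect_equal(round(w3$df), 42)
  w4 <- welch_one_tailed(mrep, mrep[setdiff(names(mrep), union9)])
  expect_equal(w4$t, 1.499, tolerance = 5e-4)
  expect_equal(round(w4$df), 53)

  ## identical samples: t = 0, one-tailed p = 0.5
  w0 <- welch_one_tailed(rcum, rcum)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 0.5)
  expect_error(welch_one_tailed(c(1, 1), c(1, 1)), "zero variance")
})

test_that("iterative omission stops at the first significant reduction", {
  noise <- ref_noise_report()
  rcum <- setNames(noise$r_cumulative, noise$locus)
  nrank <- setNames(noise$null_rank, noise$locus)
  tr_null <- iterative_omit(rcum, nrank)
  expect_equal(tr_null$stop_k, 5L)
  expect_equal(sort(tr_null$removed),
               sort(c("SPB2480", "SPB1507", "SPB4155", "SPB2613",
                      "Dfr-24")))
  expect_equal(round(tr_null$trace$p[5], 3), 0.047)

  ## the repeat-count axis reaches significance one step later, at the
  ## reference stopping statistic t = 1.819 (df ~ 50)
  mrep <- setNames(noise$median_repeats, noise$locus)
  hrank <- setNames(noise$repeat_rank, noise$locus)
  tr_hom <- iterative_omit(mrep, hrank)
  expect_equal(tr_hom$stop_k, 6L)
  k <- tr_hom$stop_k
  expect_equal(tr_hom$trace$t[k], 1.819, tolerance = 5e-4)
  expect_equal(round(tr_hom$trace$df[k]), 50)
  expect_equal(round(tr_hom$trace$p[k], 3), 0.037)

  ## stopping index is invariant to positive rescaling of the metric
  tr_sc <- iterative_omit(rcum * 7.3, nrank)
  expect_equal(tr_sc$stop_k, tr_null$stop_k)
  expect_equal(tr_sc$removed, tr_null$removed)

  ## the stopping index is, by construction, the first significant step
  expect_true(all(tr_hom$trace$p[seq_len(k - 1)] >= 0.05))
  expect_lt(tr_hom$trace$p[k], 0.05)

  ## a tight cluster plus a few extreme loci stops within the outlier block
  set.seed(8)
  v <- setNames(c(10, 10.5, 11, 9.5, rep(1, 26) + runif(26, 0, 0.2)),
                paste0("l", 1:30))
  tr1 <- iterative_omit(v, setNames(rank(-v, ties.method = "first"),
                                    names(v)))
  expect_lte(tr1$stop_k, 4L)
  ## if the ranking removes the *best* loci first the mean never drops
  v2 <- setNames(seq(1, 1.1, length.out = 20), letters[1:20])
  expect_warning(tr2 <- iterative_omit(v2, setNames(rank(v2), names(v2))),
                 "no removal count")
  expect_true(is.na(tr2$stop_k))
})

test_that("low-noise dataset removes the 9-locus union, keeping 24 loci", {
  noise <- ref_noise_report()
  ## carrier dataset: genotypes are irrelevant to the locus arithmetic here
  set.seed(3)
  n <- 12
  calls <- array(sample(10:20, n * 33 * 2, replace = TRUE), c(n, 33, 2))
  ds <- toy_dataset(calls, sites = rep(c("A", "B"), each = n / 2),
                    loci = data.frame(name = noise$locus))
  res <- build_lnds(ds, noise, n_omit_null = 5, n_omit_homoplasy = 5)
  expect_equal(length(res$removed), 9L)
  expect_true("Dfr-24" %in% res$removed)  # shared by both axes
  expect_equal(nrow(res$dataset$loci), 24L)
  expect_equal(res$recheck_null$t, 1.520, tolerance = 5e-4)
  expect_equal(res$recheck_homoplasy$t, 1.499, tolerance = 5e-4)
  ## disjoint omission sets remove k1 + k2 loci
  noise2 <- noise
  noise2$repeat_rank <- rev(noise$null_rank)  # worst homoplasy != worst null
  res2 <- suppressWarnings(
    build_lnds(ds, noise2, n_omit_null = 2, n_omit_homoplasy = 2))
  expect_equal(length(res2$removed), 4L)
})

test_that("Weir-Cockerham theta matches a variance-components oracle", {
  ## oracle: literal scalar transcription of the a/b/c component formulas
  oracle_theta <- function(glist) {
    r <- length(glist)
    ni <- sapply(glist, nrow)
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    alleles <- sort(unique(unlist(glist)))
    A <- B <- C <- 0
    for (al in alleles) {
      pi <- hi <- numeric(r)
      for (k in 1:r) {
        g <- glist[[k]]
        pi[k] <- mean(c(g) == al)
        hi[k] <- mean((g[, 1] == al) != (g[, 2] == al))
      }
      pbar <- sum(ni * pi) / (r * nbar)
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / (r * nbar)
      a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
             (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
             (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      A <- A + a; B <- B + b; C <- C + cc
    }
    A / (A + B + C)
  }
  set.seed(17)
  for (rep in 1:20) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    g1 <- cbind(sample(1:2, n1, TRUE), sample(1:2, n1, TRUE))
    g2 <- cbind(sample(1:2, n2, TRUE, prob = c(0.8, 0.2)),
                sample(1:2, n2, TRUE, prob = c(0.8, 0.2)))
    if (length(unique(c(g1, g2))) < 2) next
    calls <- array(NA_integer_, c(n1 + n2, 1, 2))
    calls[, 1, 1] <- pmin(c(g1[, 1], g2[, 1]), c(g1[, 2], g2[, 2]))
    calls[, 1, 2] <- pmax(c(g1[, 1], g2[, 1]), c(g1[, 2], g2[, 2]))
    ds <- toy_dataset(calls, sites = rep(c("A", "B"), c(n1, n2)))
    expect_equal(wc_theta(ds), oracle_theta(list(g1, g2)),
                 tolerance = 1e-12)
  }
})

test_that("theta hits the boundary cases", {
  ## fixed for different alleles: complete differentiation
  calls <- array(NA_integer_, c(20, 1, 2))
  calls[1:10, 1, ] <- 1L
  calls[11:20, 1, ] <- 2L
  ds <- toy_dataset(calls, sites = rep(c("A", "B"), each = 10))
  expect_equal(wc_theta(ds), 1)
  ## identical allele frequencies with equal sizes: theta <= 0
  calls2 <- array(NA_integer_, c(8, 1, 2))
  calls2[, 1, 1] <- rep(c(1L, 1L, 2L, 2L), 2)
  calls2[, 1, 2] <- rep(c(1L, 2L, 2L, 1L), 2)
  calls2[, 1, ] <- cbind(pmin(calls2[, 1, 1], calls2[, 1, 2]),
                         pmax(calls2[, 1, 1], calls2[, 1, 2]))
  ds2 <- toy_dataset(calls2, sites = rep(c("A", "B"), each = 4))
  expect_lte(wc_theta(ds2), 0)
})

test_that("F_ST rank table orders loci and reports rank gaps", {
  ds <- sim_small()
  tab <- per_locus_global_fst(ds)
  expect_equal(sort(tab$rank), 1:12)
  ord <- order(tab$rank)
  fst_sorted <- tab$fst[ord]
  expect_true(all(diff(fst_sorted[!is.na(fst_sorted)]) <= 1e-12))
  expect_equal(tab$delta_fst[ord][1], fst_sorted[1] - fst_sorted[2],
               tolerance = 1e-12)
  ## high-signal subsets honour rank and bounds
  top3 <- build_hsds(ds, tab, 3)
  expect_equal(nrow(top3$loci), 3L)
  expect_setequal(top3$loci$name, tab$locus[tab$rank <= 3])
  expect_identical(build_hsds(ds, tab, 12)$loci$name, ds$loci$name)
  expect_error(build_hsds(ds, tab, 0), "out of range")
  expect_error(build_hsds(ds, tab, 13), "out of range")
})

test_that("reference F_ST ranks identify the published top-10 set", {
  fst <- spb_global_fst()
  top10 <- fst$locus[fst$rank <= 10]
  expect_setequal(top10, c("SPB2480", "SPB4155", "SPB2187", "SPB3731",
                           "SPB903595", "SPB1284", "SPB3013", "Dfr-17",
                           "Dfr-09", "SPB1272"))
  top19 <- fst$locus[fst$rank <= 19]
  expect_equal(length(top19), 19L)
  expect_false("SPB3702" %in% top19)  # rank 20 sits just past the break
})
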