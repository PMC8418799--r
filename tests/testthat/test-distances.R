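## two-site dataset with prescribed allele frequencies, built by explicit
## genotype construction (60 individuals per site)
freq_dataset <- function(fx, fy, n = 60) {
  draw <- function(p, n) sample(seq_along(p), n, replace = TRUE, prob = p)
  calls <- array(NA_integer_, c(2 * n, 1, 2))
  calls[1:n, 1, 1] <- draw(fx, n); calls[1:n, 1, 2] <- draw(fx, n)
  calls[n + 1:n, 1, 1] <- draw(fy, n); calls[n + 1:n, 1, 2] <- draw(fy, n)
  calls[, 1, ] <- cbind(pmin(calls[, 1, 1], calls[, 1, 2]),
                        pmax(calls[, 1, 1], calls[, 1, 2]))
  toy_dataset(calls, sites = rep(c("X", "Y"), each = n))
}

test_that("chord distance matches its closed form", {
  ## identical frequency vectors -> 0
  f <- list(L1 = rbind(X = c(0.4, 0.6), Y = c(0.4, 0.6)))
  expect_equal(chord_distance(f, "X", "Y"), 0)
  ## fixed for different alleles -> (2/pi) sqrt(2)
  f2 <- list(L1 = rbind(X = c(1, 0), Y = c(0, 1)))
  expect_equal(chord_distance(f2, "X", "Y"), 2 * sqrt(2) / pi,
               tolerance = 1e-12)
  expect_equal(chord_distance(f2, "X", "Y"), 0.9003, tolerance = 1e-4)
  ## duplicating loci leaves the mean over loci unchanged
  f3 <- list(L1 = f2$L1, L2 = f2$L1)
  expect_equal(chord_distance(f3, "X", "Y"),
               chord_distance(f2, "X", "Y"), tolerance = 1e-12)
  ## direct-summation oracle on random tables
  set.seed(21)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    x <- prop.table(runif(k)); y <- prop.table(runif(k))
    f4 <- list(A = rbind(X = x, Y = y), B = rbind(X = y, Y = x))
    oracle <- mean(c(sqrt(2 * (1 - sum(sqrt(x * y)))),
                     sqrt(2 * (1 - sum(sqrt(y * x)))))) * 2 / pi
    expect_equal(chord_distance(f4, "X", "Y"), oracle, tolerance = 1e-12)
  }
})

test_that("Nei standard distance averages gene identities before the log", {
  f <- list(L1 = rbind(X = c(0.9, 0.1), Y = c(0.1, 0.9)))
  ## J_x = J_y = 0.82, J_xy = 0.18
  expect_equal(nei_standard(f, "X", "Y"), -log(0.18 / 0.82),
               tolerance = 1e-12)
  expect_equal(nei_standard(f, "X", "Y"), 1.516, tolerance = 1e-3)
  expect_equal(nei_standard(list(L1 = rbind(X = c(0.3, 0.7),
                                            Y = c(0.3, 0.7))), "X", "Y"), 0)
  ## no shared alleles -> infinite, flagged by Inf
  f2 <- list(L1 = rbind(X = c(1, 0), Y = c(0, 1)))
  expect_true(is.infinite(nei_standard(f2, "X", "Y")))
})

test_that("linearized F_ST floors negative theta and transforms", {
  set.seed(9)
  ds <- freq_dataset(c(0.5, 0.5), c(0.5, 0.5))
  ## identical pops: theta <= 0 floored to 0
  expect_equal(pairwise_fst_linearized(ds, "X", "Y"), 0, tolerance = 0.02)
  ## fixed-different pops: theta = 1 -> infinite
  calls <- array(NA_integer_, c(8, 1, 2))
  calls[1:4, 1, ] <- 1L; calls[5:8, 1, ] <- 2L
  fixed <- toy_dataset(calls, sites = rep(c("X", "Y"), each = 4))
  expect_true(is.infinite(pairwise_fst_linearized(fixed, "X", "Y")))
  ## transform arithmetic at the weak-structure scale
  expect_equal(round(0.009 / (1 - 0.009), 5), 0.00908)
})

test_that("kinship and shared-allele similarities follow the pair rules", {
  m <- function(a, b) matrix(c(a, b), 1, 2)
  expect_equal(kinship_dkf(m(1, 1), m(1, 1)), 1)
  expect_equal(kinship_dkf(m(1, 1), m(1, 2)), 0.5)
  expect_equal(kinship_dkf(m(1, 2), m(3, 4)), 0)
  expect_equal(shared_alleles_dps(m(1, 2), m(2, 3)), 0.5)
  ## multiset rule: A/A vs A/B shares exactly one allele
  expect_equal(shared_alleles_dps(m(1, 1), m(1, 2)), 0.5)
  expect_equal(shared_alleles_dps(m(1, 2), m(1, 2)), 1)
  ## missing loci drop from numerator and denominator
  ga <- rbind(c(1, 2), c(NA, NA), c(3, 3))
  gb <- rbind(c(1, 2), c(5, 6), c(3, 4))
  expect_equal(shared_alleles_dps(ga, gb), (2 + 1) / (2 * 2))
  expect_true(is.na(shared_alleles_dps(rbind(c(NA, NA)), rbind(c(1, 2)))))
})

test_that("Lynch-Ritland relatedness follows its single-locus formula", {
  ## both individuals A/B with p_A = 0.2, p_B = 0.3 -> r = 1
  ga <- matrix(c(1, 2), 1, 2)
  freqs <- list(c("1" = 0.2, "2" = 0.3, "3" = 0.5))
  expect_equal(lynch_ritland_r(ga, ga, freqs), 1, tolerance = 1e-12)
  ## both alleles at 0.5: denominator zero, locus skipped -> NA
  freqs2 <- list(c("1" = 0.5, "2" = 0.5))
  expect_true(is.na(lynch_ritland_r(ga, ga, freqs2)))
  ## hand case: unrelated-looking homozygotes
  gb <- matrix(c(3, 3), 1, 2)
  pa <- 0.2
  num <- pa * (0 + 0) + pa * (0 + 0) - 4 * pa * pa
  den <- (1 + 1) * (pa + pa) - 4 * pa * pa
  gaa <- matrix(c(1, 1), 1, 2)
  f3 <- list(c("1" = 0.2, "3" = 0.8))
  p3 <- 0.8
  num2 <- p3 * 0 + p3 * 0 - 4 * p3 * p3
  den2 <- 2 * (p3 + p3) - 4 * p3 * p3
  expect_equal(lynch_ritland_r(gaa, gb, f3),
               mean(c(num / den, num2 / den2)), tolerance = 1e-12)
})

test_that("relatedness is near zero for random pairs, near half for parent-offspring", {
  set.seed(13)
  n <- 120; L <- 20; k <- 8
  p <- prop.table(runif(k) + 0.2)
  draw <- function(n) matrix(sample(k, n * 2, TRUE, prob = p), n, 2)
  pop <- lapply(seq_len(L), function(l) draw(n))
  calls <- array(NA_integer_, c(n, L, 2))
  for (l in seq_len(L)) {
    calls[, l, 1] <- pmin(pop[[l]][, 1], pop[[l]][, 2])
    calls[, l, 2] <- pmax(pop[[l]][, 1], pop[[l]][, 2])
  }
  ds <- toy_dataset(calls, sites = rep("A", n))
  dm <- distance_matrix(ds, "lr")
  vals <- dm$mat[lower.tri(dm$mat)]
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.05)
  ## parent-offspring pairs: child takes one allele from each of two parents
  f <- allele_freqs(ds, "pooled")
  rs <- sapply(seq_len(50), function(i) {
    pa <- matrix(calls[i, , ], ncol = 2)
    pb <- matrix(calls[i + 50, , ], ncol = 2)
    ch <- cbind(ifelse(runif(L) < 0.5, pa[, 1], pa[, 2]),
                ifelse(runif(L) < 0.5, pb[, 1], pb[, 2]))
    lynch_ritland_r(pa, ch, f)
  })
  expect_equal(mean(rs), 0.5, tolerance = 0.06)
})

test_that("distance matrices are symmetric with the right self-values", {
  ds <- sim_small()
  for (met in c("dc", "ds", "fst_lin")) {
    dm <- distance_matrix(ds, met)
    expect_equal(dm$kind, "dissimilarity")
    expect_equal(dm$mat, t(dm$mat), tolerance = 1e-12)
    expect_equal(nrow(dm$mat), 5)
  }
  sub <- subset_dataset(ds, sites = unique(ds$meta$site)[1:2])
  for (met in c("dkf", "dps", "lr")) {
    dm <- distance_matrix(sub, met)
    expect_equal(dm$kind, "similarity")
    expect_equal(dm$mat, t(dm$mat), tolerance = 1e-12)
    if (met != "lr")
      expect_true(all(dm$mat[lower.tri(dm$mat)] >= 0 &
                        dm$mat[lower.tri(dm$mat)] <= 1, na.rm = TRUE))
  }
  ## a duplicated individual has maximal self-similarity to its copy
  dup <- sub
  dup$calls[2, , ] <- dup$calls[1, , ]
  dmd <- distance_matrix(dup, "dps")
  expect_equal(dmd$mat[2, 1], 1)
  ## vectorized pair engine agrees with the scalar pair functions
  dmk <- distance_matrix(sub, "dkf")
  i <- 5; j <- 11
  expect_equal(dmk$mat[i, j],
               kinship_dkf(matrix(sub$calls[i, , ], ncol = 2),
                           matrix(sub$calls[j, , ], ncol = 2)),
               tolerance = 1e-12)
  dml <- distance_matrix(sub, "lr")
  f <- allele_freqs(sub, "pooled")
  expect_equal(dml$mat[i, j],
               lynch_ritland_r(matrix(sub$calls[i, , ], ncol = 2),
                               matrix(sub$calls[j, , ], ncol = 2), f),
               tolerance = 1e-12)
  ## metric/level mismatches are rejected
  expect_error(distance_matrix(ds, "dc", level = "individual"),
               "not defined")
})

test_that("pair counts scale as n(n-1)/2 across levels", {
  ds <- sim_small()
  n <- length(ds$individuals)
  dm <- distance_matrix(ds, "dps")
  expect_equal(sum(lower.tri(dm$mat)), n * (n - 1) / 2)
})
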