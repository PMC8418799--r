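#' Configuration for the stepping-stone forward simulator
#'
#' Demes sit on a one-dimensional line at a constant latitude, spaced
#' `deme_spacing_km` apart, so Haversine distances are near-linear in deme
#' index. Generations are non-overlapping: each one consists of sex-specific
#' natal dispersal (by default to an adjacent deme), random monogamous pairing within the
#' deme, offspring production to a constant census size, and strict stepwise
#' mutation (one repeat unit up or down with equal probability, reflecting
#' at a floor). Dispersal happens before reproduction, the condition under
#' which sex-biased movement can mask spatial structure in the dispersing
#' sex while the philopatric sex retains it.
#'
#' @param n_demes number of demes (>= 2).
#' @param N_per_deme diploid individuals per deme (even, so the two sexes
#'   can be balanced at initialisation).
#' @param n_loci number of unlinked microsatellite loci.
#' @param mutation_rate per-allele per-generation stepwise mutation
#'   probability.
#' @param m_female,m_male per-generation probability that an individual of
#'   that sex moves to an adjacent deme (edge demes have one neighbour;
#'   movers there go inward).
#' @param null_freq per-locus probability that an allele lineage is
#'   non-amplifying, applied when rendering the final census (scalar or
#'   vector of length `n_loci`).
#' @param n_generations generations to simulate.
#' @param seed integer seed; all stochastic draws flow from it.
#' @param deme_spacing_km spacing between adjacent demes, default 150 km
#'   (sites of a regional survey hundreds of km apart).
#' @param founder_repeats initial repeat count of every allele, default 20.
#' @param repeat_floor smallest permitted repeat count, default 5.
#' @param motif_bp repeat unit length in bp, default 2; allele size in bp is
#'   `100 + motif_bp * repeats`.
#' @param n_sample individuals sampled per deme into the output dataset,
#'   default 28 (a field sample, much smaller than the deme census).
#' @param disp_steps_female,disp_steps_male mean dispersal distance of a
#'   mover, in deme steps (shifted-geometric step count, direction random).
#'   The default 1 gives strictly adjacent-deme migration; values above 1
#'   model occasional long-range (e.g. wind-assisted) dispersal.
#' @param founder_span founder alleles are drawn uniformly from
#'   `founder_repeats` plus/minus `founder_span` repeat units, representing
#'   standing variation of the ancestral pool; default 5 (about 11 alleles
#'   per locus).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_demes = 9, N_per_deme = 400, n_loci = 33,
                       mutation_rate = 5e-4, m_female = 0.2, m_male = 0.2,
                       null_freq = 0, n_generations = 100, seed = 1,
                       deme_spacing_km = 150, founder_repeats = 20,
                       repeat_floor = 5, motif_bp = 2,
                       n_sample = 28, disp_steps_female = 1,
                       disp_steps_male = 1, founder_span = 5) {
  rates <- c(mutation_rate, m_female, m_male, null_freq)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (n_demes < 2L) stop("need at least 2 demes")
  if (N_per_deme %% 2L != 0L) stop("N_per_deme must be even")
  if (length(null_freq) == 1L) null_freq <- rep(null_freq, n_loci)
  if (length(null_freq) != n_loci)
    stop("null_freq must be scalar or length n_loci")
  structure(list(n_demes = as.integer(n_demes),
                 N_per_deme = as.integer(N_per_deme),
                 n_loci = as.integer(n_loci),
                 mutation_rate = mutation_rate,
                 m_female = m_female, m_male = m_male,
                 null_freq = null_freq,
                 n_generations = as.integer(n_generations),
                 seed = as.integer(seed),
                 deme_spacing_km = deme_spacing_km,
                 founder_repeats = as.integer(founder_repeats),
                 repeat_floor = as.integer(repeat_floor),
                 motif_bp = as.integer(motif_bp),
                 n_sample = as.integer(n_sample),
                 disp_steps_female = disp_steps_female,
                 disp_steps_male = disp_steps_male,
                 founder_span = as.integer(founder_span)),
            class = "sim_config")
}

#' Run the forward-time stepping-stone simulation
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_result`: `dataset` (an [msat_dataset()] with
#'   demes as sites on a constant-latitude line) and `truth` (the config).
#'   Null alleles are carried as a hidden allele state and rendered when
#'   sampling: null/visible genotypes appear as homozygotes for the visible
#'   allele, null/null genotypes as missing.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, sim_run(cfg))
}

sim_run <- function(cfg) {
  n_total <- cfg$n_demes * cfg$N_per_deme
  L <- cfg$n_loci
  ## state: repeat counts, one matrix column pair per locus; founders draw
  ## alleles from a common pool (standing variation, panmictic ancestry)
  A <- matrix(sample(seq(max(cfg$repeat_floor,
                              cfg$founder_repeats - cfg$founder_span),
                          cfg$founder_repeats + cfg$founder_span),
                     n_total * 2L * L, replace = TRUE),
              n_total, 2 * L)
  deme <- rep(seq_len(cfg$n_demes), each = cfg$N_per_deme)
  sex <- rep(c("male", "female"), length.out = n_total)

  for (gen in seq_len(cfg$n_generations)) {
    ## 1. pairing and reproduction to constant deme census
    newA <- matrix(0L, n_total, 2 * L)
    new_deme <- rep(seq_len(cfg$n_demes), each = cfg$N_per_deme)
    row0 <- 0L
    for (d in seq_len(cfg$n_demes)) {
      males <- which(deme == d & sex == "male")
      females <- which(deme == d & sex == "female")
      if (length(males) == 0L || length(females) == 0L) {
        warning("sex missing in deme ", d, " at generation ", gen,
                "; pairing resampled from the whole population")
        if (length(males) == 0L) males <- which(sex == "male")
        if (length(females) == 0L) females <- which(sex == "female")
      }
      ## monogamous pairs; offspring numbers multinomial over pairs
      ## (Poisson-equivalent under constant total)
      np <- min(length(males), length(females))
      mo <- sample(males)[seq_len(np)]
      fo <- sample(females)[seq_len(np)]
      pair <- sample.int(np, cfg$N_per_deme, replace = TRUE)
      rows <- row0 + seq_len(cfg$N_per_deme)
      odd <- seq(1L, 2L * L, by = 2L)
      ## per offspring x locus: which of the parent's two allele columns
      from_f <- matrix(rep(odd, each = cfg$N_per_deme) +
                         (stats::runif(cfg$N_per_deme * L) < 0.5),
                       cfg$N_per_deme, L)
      from_m <- matrix(rep(odd, each = cfg$N_per_deme) +
                         (stats::runif(cfg$N_per_deme * L) < 0.5),
                       cfg$N_per_deme, L)
      ## maternal allele into column 2l-1, paternal into 2l
      newA[rows, odd] <- matrix(A[cbind(rep(fo[pair], times = L),
                                        as.vector(from_f))],
                                cfg$N_per_deme, L)
      newA[rows, odd + 1L] <- matrix(A[cbind(rep(mo[pair], times = L),
                                             as.vector(from_m))],
                                     cfg$N_per_deme, L)
      row0 <- row0 + cfg$N_per_deme
    }
    A <- newA
    deme <- new_deme
    sex <- ifelse(stats::runif(n_total) < 0.5, "male", "female")
    ## 2. stepwise mutation, reflecting at the size floor
    if (cfg$mutation_rate > 0) {
      mut <- which(stats::runif(length(A)) < cfg$mutation_rate)
      if (length(mut)) {
        step <- sample(c(-1L, 1L), length(mut), replace = TRUE)
        A[mut] <- A[mut] + step
        A[mut][A[mut] < cfg$repeat_floor] <- cfg$repeat_floor + 1L
      }
    }
    ## 3. natal migration of the newborn cohort, sex-specific, to an
    ## adjacent deme (edge movers go inward). Dispersal precedes the next
    ## round of mating, so the final census consists of individuals that
    ## may have dispersed but have not yet reproduced.
    pm <- ifelse(sex == "male", cfg$m_male, cfg$m_female)
    move <- stats::runif(n_total) < pm
    if (any(move)) {
      mean_steps <- ifelse(sex[move] == "male", cfg$disp_steps_male,
                           cfg$disp_steps_female)
      steps <- 1L + stats::rgeom(sum(move), prob = 1 / mean_steps)
      dir <- sample(c(-1L, 1L), sum(move), replace = TRUE)
      nd <- deme[move] + dir * steps
      ## reflect single-step edge moves inward, clamp long-range ones
      nd[steps == 1L & nd < 1L] <- 2L
      nd[steps == 1L & nd > cfg$n_demes] <- cfg$n_demes - 1L
      nd <- pmin(pmax(nd, 1L), cfg$n_demes)
      deme[move] <- nd
    }
  }
  sim_render(cfg, A, deme, sex)
}

## render the final census into an msat_dataset, applying null alleles
sim_render <- function(cfg, A, deme, sex) {
  keep <- unlist(lapply(seq_len(cfg$n_demes), function(d) {
    cand <- which(deme == d)
    if (length(cand) <= cfg$n_sample) cand else sample(cand, cfg$n_sample)
  }))
  A <- A[keep, , drop = FALSE]
  deme <- deme[keep]; sex <- sex[keep]
  n <- length(keep)
  L <- cfg$n_loci
  calls <- array(NA_integer_, c(n, L, 2))
  for (l in seq_len(L)) {
    sz1 <- 100L + cfg$motif_bp * A[, 2 * l - 1L]
    sz2 <- 100L + cfg$motif_bp * A[, 2 * l]
    calls[, l, 1] <- sz1
    calls[, l, 2] <- sz2
  }
  ids <- sprintf("d%02d_i%03d", deme, seq_len(n))
  lat <- 35
  lon_step <- cfg$deme_spacing_km / (111.19 * cos(lat * pi / 180))
  meta <- data.frame(id = ids, site = sprintf("deme%02d", deme), sex = sex,
                     lat = lat, lon = (deme - 1) * lon_step,
                     stringsAsFactors = FALSE)
  loci <- data.frame(name = sprintf("L%02d", seq_len(L)),
                     motif = strrep("A", cfg$motif_bp),
                     stringsAsFactors = FALSE)
  ds <- msat_dataset(calls, ids, loci, meta, label = "sim")
  for (l in seq_len(L)) {
    if (cfg$null_freq[l] > 0)
      ds <- apply_nulls(ds, ds$loci$name[l], cfg$null_freq[l])
  }
  structure(list(dataset = ds, truth = cfg), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result:\n")
  print(x$dataset)
  invisible(x)
}

#' Inject null alleles at a locus
#'
#' Each allele copy at the locus is independently relabelled as
#' non-amplifying with probability `r_true`. A null/visible genotype is
#' rendered as an apparent homozygote for the visible allele; a null/null
#' genotype becomes missing. With `r_true = 0` the dataset is returned
#' unchanged.
#'
#' @param ds an [msat_dataset()].
#' @param locus locus name.
#' @param r_true true null-allele frequency, in `[0, 0.5]`.
#' @param seed optional integer seed.
#' @return the modified [msat_dataset()].
#' @export
apply_nulls <- function(ds, locus, r_true, seed = NULL) {
  if (r_true < 0 || r_true > 0.5) stop("r_true must lie in [0, 0.5]")
  if (r_true == 0) return(ds)
  j <- match(locus, ds$loci$name)
  if (is.na(j)) stop("unknown locus: ", locus)
  run_seeded(seed, {
    n <- length(ds$individuals)
    null1 <- stats::runif(n) < r_true
    null2 <- stats::runif(n) < r_true
    a1 <- ds$calls[, j, 1]; a2 <- ds$calls[, j, 2]
    both <- null1 & null2
    a1[null1 & !null2] <- a2[null1 & !null2]
    a2[null2 & !null1] <- a1[null2 & !null1]
    a1[both] <- NA_integer_; a2[both] <- NA_integer_
    ds$calls[, j, 1] <- pmin(a1, a2)
    ds$calls[, j, 2] <- pmax(a1, a2)
    ds
  })
}
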