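## Shared fixture builders. Everything is generated in code; the only
## stored data are the bundled reference-survey CSVs shipped with the
## package.

## genotype matrix from counts of unordered pairs, e.g. geno_mat(AA = 5, AB = 2)
geno_mat <- function(...) {
  cts <- c(...)
  rows <- lapply(names(cts), function(nm) {
    al <- match(strsplit(nm, "")[[1]], LETTERS)
    matrix(rep(al, cts[[nm]]), ncol = 2, byrow = TRUE)
  })
  do.call(rbind, rows)
}

## tiny hand-built dataset: n individuals per site, explicit calls
toy_dataset <- function(calls, sites, sexes = NULL, loci = NULL,
                        lat = NULL, lon = NULL) {
  n <- dim(calls)[1]
  ids <- sprintf("i%02d", seq_len(n))
  if (is.null(sexes)) sexes <- rep("unknown", n)
  if (is.null(loci)) loci <- data.frame(name = sprintf("L%d", seq_len(dim(calls)[2])))
  if (is.null(lat)) lat <- rep(35, n)
  if (is.null(lon)) lon <- as.numeric(factor(sites))
  meta <- data.frame(id = ids, site = sites, sex = sexes, lat = lat,
                     lon = lon)
  msat_dataset(calls, ids, loci, meta)
}

## small cached simulated dataset shared across test files
sim_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_demes = 5, N_per_deme = 60, n_loci = 12,
                        n_generations = 40, n_sample = 20, seed = 2024)
      cache <<- suppressWarnings(simulate_dataset(cfg))$dataset
    }
    cache
  }
})

## reference-survey vectors used in several files
ref_noise_report <- function() {
  ann <- spb_locus_annotations()
  summ <- spb_null_summary()
  mr <- scale_repeats(ann$seq_repeats, ann$seq_allele_length,
                      ann$median_allele_length)
  names(mr) <- ann$name
  hr <- homoplasy_rank(mr)
  data.frame(locus = ann$name,
             r_cumulative = summ$r_cumulative[match(ann$name, summ$locus)],
             null_rank = summ$null_rank[match(ann$name, summ$locus)],
             median_allele_length = ann$median_allele_length,
             median_repeats = hr$median_repeats,
             repeat_rank = hr$repeat_rank)
}
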