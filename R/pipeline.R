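#' Run the full screening and isolation-by-distance pipeline
#'
#' Orchestrates the analysis end to end on one dataset: null-allele scan
#' over outbred populations, homoplasy proxy, low-noise and high-signal
#' locus subsets, sex partitions, and the Mantel isolation-by-distance
#' battery for every requested dataset variant. With both locus-subset
#' strategies and both sexes present this yields the full 12-variant grid
#' (4 locus sets x 3 sex partitions).
#'
#' @param ds an [msat_dataset()] (e.g. from [read_genepop()] or
#'   [simulate_dataset()]).
#' @param annotations locus annotation data frame (`name`, `seq_repeats`,
#'   `seq_allele_length`) for the homoplasy proxy; default `ds$loci` if it
#'   carries those columns, otherwise the homoplasy axis is skipped and
#'   locus subsets use the null axis only.
#' @param hsds_k integer vector: sizes of high-signal subsets to build,
#'   default `c(10, 19)`.
#' @param alpha significance level used throughout, default 0.05.
#' @param n_perm_null randomizations per null-allele test, default 1000.
#' @param n_perm_inbred permutations per U-test in the inbred-population
#'   screen, default 1000.
#' @param n_perm_mantel Mantel permutations, default 999.
#' @param sex_partitions character subset of `c("m+f", "m", "f")`.
#' @param seed integer seed governing every stochastic stage, default 1.
#' @param out_dir optional directory; when given, all tables are written
#'   there as TSV (with a header comment recording package version and
#'   seed) and their MD5 hashes recorded in the manifest.
#' @return list of class `msat_pipeline`: `screen` (inbred-population
#'   screen), `noise` (per-locus noise report), `fst` (per-locus F_ST rank
#'   table), `variants` (named list of [msat_dataset()]s), `ibd` (combined
#'   Mantel table over variants and metrics), `manifest` (config echo,
#'   versions, timings, file hashes).
#' @export
run_all <- function(ds, annotations = NULL, hsds_k = c(10, 19),
                    alpha = 0.05, n_perm_null = 1000, n_perm_inbred = 1000,
                    n_perm_mantel = 999,
                    sex_partitions = c("m+f", "m", "f"), seed = 1,
                    out_dir = NULL) {
  stopifnot(inherits(ds, "msat_dataset"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
  }
  if (is.null(annotations) &&
      all(c("seq_repeats", "seq_allele_length") %in% names(ds$loci)))
    annotations <- ds$loci
  if (!nzchar(ds$label)) ds$label <- "ADS"

  withr::with_seed(seed, {
    screen <- screen_inbred_pops(ds, alpha = alpha, n_perm = n_perm_inbred)
    tick("inbred_screen")
    cells <- null_allele_cells(ds, pops = screen$retained,
                               n_perm = n_perm_null, alpha = alpha)
    tick("null_scan")

    have_hom <- !is.null(annotations)
    if (have_hom) {
      noise <- locus_noise_report(ds, cells = cells,
                                  annotations = annotations)
      lnds <- build_lnds(ds, noise, alpha = alpha)
    } else {
      noise <- r_cumulative_rank(cells)
      vn <- stats::setNames(noise$r_cumulative, noise$locus)
      rn <- stats::setNames(noise$null_rank, noise$locus)
      tr <- iterative_omit(vn, rn, alpha = alpha)
      lnds <- list(dataset = subset_dataset(ds, loci = tr$final_loci,
                                            label = paste(ds$label, "LNDS")),
                   removed = tr$removed, trace_null = tr)
    }
    tick("locus_noise")

    fst <- per_locus_global_fst(ds)
    variants <- list(ADS = ds, LNDS = lnds$dataset)
    for (k in hsds_k) {
      variants[[paste0("HSDS", k)]] <- build_hsds(ds, fst, k)
    }
    tick("fst_rank")

    ## sex partitions: individuals of unknown sex are dropped from m / f
    expand <- list()
    for (nm in names(variants)) for (sp in sex_partitions) {
      v <- variants[[nm]]
      dsv <- switch(sp,
        "m+f" = v,
        "m" = try(subset_dataset(v, sex = "male",
                                 label = paste(nm, "m")), silent = TRUE),
        "f" = try(subset_dataset(v, sex = "female",
                                 label = paste(nm, "f")), silent = TRUE))
      if (inherits(dsv, "try-error")) next
      if (sp == "m+f") dsv$label <- paste(nm, "m+f")
      expand[[dsv$label]] <- dsv
    }

    ibd <- do.call(rbind, lapply(expand, function(v) {
      if (length(unique(v$meta$site)) < 4L) return(NULL)
      ibd_battery(v, n_perm = n_perm_mantel)
    }))
    rownames(ibd) <- NULL
    tick("ibd")
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("msatIBD")),
    seed = seed, alpha = alpha,
    n_perm = c(null = n_perm_null, inbred = n_perm_inbred,
               mantel = n_perm_mantel),
    n_individuals = length(ds$individuals), n_loci = nrow(ds$loci),
    timings_sec = unlist(timings), hashes = NULL)

  out <- list(screen = screen, noise = noise, fst = fst,
              variants = expand, ibd = ibd, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stage <- function(df, name) {
      p <- file.path(out_dir, paste0(name, ".tsv"))
      con <- file(p, "w")
      writeLines(sprintf("# msatIBD %s seed=%d",
                         manifest$package_version, seed), con)
      utils::write.table(df, con, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      close(con)
      p
    }
    paths <- c(write_stage(out$noise, "locus_noise"),
               write_stage(out$fst, "fst_ranks"),
               write_stage(out$ibd, "ibd_mantel"),
               write_stage(screen$counts, "inbred_screen"))
    out$manifest$hashes <- tools::md5sum(paths)
  }
  class(out) <- "msat_pipeline"
  out
}

#' @export
print.msat_pipeline <- function(x, ...) {
  cat("msat_pipeline:", length(x$variants), "dataset variants,",
      nrow(x$ibd), "Mantel rows\n")
  invisible(x)
}
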