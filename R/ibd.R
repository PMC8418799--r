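#' Great-circle geographic distance matrix
#'
#' Haversine distances (mean Earth radius 6371.0088 km) between sampling
#' sites (one representative coordinate per site, the first individual's)
#' or between individuals. All members of a site share the trap coordinate,
#' so individual-level matrices contain zero within-site distances; these
#' are retained, not jittered.
#'
#' @param meta metadata data frame (`id`, `site`, `sex`, `lat`, `lon`).
#' @param level `"population"` or `"individual"`.
#' @return object of class `msat_dist` (kind `"dissimilarity"`, metric
#'   `"km"`), distances in km.
#' @export
haversine_matrix <- function(meta, level = c("population", "individual")) {
  level <- match.arg(level)
  if (level == "population") {
    first <- !duplicated(meta$site)
    labs <- meta$site[first]
    pts <- cbind(meta$lon[first], meta$lat[first])
  } else {
    labs <- meta$id
    pts <- cbind(meta$lon, meta$lat)
  }
  m <- geosphere::distm(pts, fun = geosphere::distHaversine) / 1000
  ## geosphere's default radius is 6378137 m; rescale to the mean radius
  m <- m * (6371.0088 / 6378.137)
  dimnames(m) <- list(labs, labs)
  structure(list(labels = labs, mat = m, kind = "dissimilarity",
                 metric = "km"),
            class = "msat_dist")
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation between the off-diagonal entries of a genetic and a
#' geographic matrix, with significance from permutations of one matrix's
#' label order. Testing is one-tailed in the direction isolation by
#' distance predicts: positive correlation for dissimilarity metrics,
#' negative for similarity metrics (relatedness decays with distance). The
#' regression slope of genetic on geographic distance is also reported.
#'
#' @param genetic an `msat_dist` (from [distance_matrix()]).
#' @param geo an `msat_dist` in km (from [haversine_matrix()]) with the same
#'   labels.
#' @param n_perm permutations, default 999.
#' @param seed optional integer seed.
#' @param tail `"auto"` (from `genetic$kind`), `"positive"` or
#'   `"negative"`.
#' @return list of class `mantel_result`: `r`, `slope`, `p`, `n_perm`,
#'   `tail`.
#' @export
mantel_ibd <- function(genetic, geo, n_perm = 999, seed = NULL,
                       tail = c("auto", "positive", "negative")) {
  tail <- match.arg(tail)
  if (tail == "auto")
    tail <- if (genetic$kind == "similarity") "negative" else "positive"
  if (!identical(as.character(genetic$labels), as.character(geo$labels)))
    stop("label mismatch between genetic and geographic matrices")
  n <- length(genetic$labels)
  if (n < 4L) stop("need at least 4 labels for a Mantel test")
  G <- genetic$mat; D <- geo$mat
  lt <- lower.tri(G)
  ok <- is.finite(G[lt]) & is.finite(D[lt])
  if (!any(ok)) stop("no finite pairs")
  gv <- G[lt][ok]; dv <- D[lt][ok]
  if (stats::sd(gv) == 0 || stats::sd(dv) == 0)
    stop("constant matrix: Mantel correlation undefined")
  r_obs <- stats::cor(gv, dv)
  slope <- stats::cov(gv, dv) / stats::var(dv)
  hits <- 0L
  run_seeded(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      gp <- G[perm, perm][lt][ok]
      rp <- suppressWarnings(stats::cor(gp, dv))
      if (is.na(rp)) next
      if (tail == "positive" && rp >= r_obs - 1e-12) hits <- hits + 1L
      if (tail == "negative" && rp <= r_obs + 1e-12) hits <- hits + 1L
    }
  })
  structure(list(r = r_obs, slope = slope, p = (hits + 1) / (n_perm + 1),
                 n_perm = n_perm, tail = tail),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, slope = %.3g, one-tailed (%s) p = %.4g [%d permutations]\n",
              x$r, x$slope, x$tail, x$p, x$n_perm))
  invisible(x)
}

#' Battery of isolation-by-distance tests
#'
#' Runs [mantel_ibd()] for each requested metric at its natural level
#' (population-based: chord, Nei standard, linearized F_ST;
#' individual-based: kinship, shared alleles, Lynch-Ritland relatedness)
#' against Haversine geographic distances.
#'
#' @param ds an [msat_dataset()].
#' @param metrics metric names (see [distance_matrix()]); default all six.
#' @param n_perm permutations per test, default 999.
#' @param seed optional integer seed.
#' @return data frame: `dataset`, `metric`, `level`, `kind`, `r`, `slope`,
#'   `p`.
#' @export
ibd_battery <- function(ds, metrics = c("dc", "ds", "fst_lin",
                                        "dkf", "dps", "lr"),
                        n_perm = 999, seed = NULL) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  run_seeded(seed, {
    rows <- lapply(metrics, function(mt) {
      gm <- distance_matrix(ds, mt)
      lvl <- if (mt %in% c("dc", "ds", "fst_lin")) "population"
             else "individual"
      geo <- haversine_matrix(ds$meta, lvl)
      res <- mantel_ibd(gm, geo, n_perm = n_perm)
      data.frame(dataset = ds$label, metric = mt, level = lvl,
                 kind = gm$kind, r = res$r, slope = res$slope, p = res$p,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
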