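#' Assemble a validated microsatellite dataset
#'
#' The central container of the package: diploid allele-size calls
#' (integer base pairs) for a set of individuals at a set of loci, together
#' with per-individual metadata (sampling site, sex, coordinates).
#'
#' @param calls integer array of dimension `c(n_individuals, n_loci, 2)`
#'   holding allele sizes in bp, `NA` for missing. Half-missing calls
#'   (one allele `NA`) are promoted to fully missing with a warning, matching
#'   the whole-genotype missing convention of GenePop's `000` code. The two
#'   alleles of each call are stored sorted ascending; heterozygosity never
#'   depends on their order.
#' @param individuals character vector of unique individual ids
#'   (`dim(calls)[1]` long).
#' @param loci data frame with at least a `name` column; optionally `motif`,
#'   `seq_repeats` (contiguous repeat units in the directly sequenced allele)
#'   and `seq_allele_length` (bp of the trimmed sequenced allele), as used by
#'   the homoplasy proxy.
#' @param meta data frame with columns `id`, `site`, `sex`
#'   (one of `"male"`, `"female"`, `"unknown"`), `lat`, `lon`; exactly one row
#'   per genotyped individual.
#' @param label free-text label for the dataset variant (e.g. `"ADS m+f"`).
#'
#' @return An object of class `msat_dataset`: a list with elements `calls`,
#'   `individuals`, `loci`, `meta`, `label`.
#' @export
msat_dataset <- function(calls, individuals, loci, meta, label = "") {
  if (length(dim(calls)) != 3L || dim(calls)[3] != 2L)
    stop("`calls` must be an n_individuals x n_loci x 2 array")
  storage.mode(calls) <- "integer"
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (is.null(loci$name)) stop("`loci` needs a `name` column")
  loci$name <- as.character(loci$name)
  if (anyDuplicated(loci$name)) stop("duplicate locus names")
  individuals <- as.character(individuals)
  if (length(individuals) != dim(calls)[1])
    stop("length(individuals) != nrow(calls)")
  if (nrow(loci) != dim(calls)[2]) stop("nrow(loci) != ncol(calls)")
  if (anyDuplicated(individuals)) stop("duplicate individual ids")
  if (any(calls <= 0, na.rm = TRUE)) stop("allele sizes must be positive")

  half <- is.na(calls[, , 1]) != is.na(calls[, , 2])
  if (any(half)) {
    warning(sum(half), " half-missing call(s) promoted to fully missing")
    calls[, , 1][half] <- NA_integer_
    calls[, , 2][half] <- NA_integer_
  }
  ## unordered pair convention: sorted ascending
  lo <- pmin(calls[, , 1], calls[, , 2])
  hi <- pmax(calls[, , 1], calls[, , 2])
  calls[, , 1] <- lo
  calls[, , 2] <- hi
  dimnames(calls) <- list(individuals, loci$name, c("a1", "a2"))

  meta <- validate_meta(meta)
  if (!setequal(meta$id, individuals))
    stop("metadata ids do not match genotyped individuals")
  meta <- meta[match(individuals, meta$id), , drop = FALSE]
  rownames(meta) <- NULL
  if (length(unique(meta$site)) < 1L) stop("site set is empty")

  structure(list(calls = calls, individuals = individuals, loci = loci,
                 meta = meta, label = label),
            class = "msat_dataset")
}

#' @export
print.msat_dataset <- function(x, ...) {
  cat("msat_dataset", if (nzchar(x$label)) paste0("'", x$label, "'"), "\n")
  cat("  ", length(x$individuals), "individuals,", nrow(x$loci), "loci,",
      length(unique(x$meta$site)), "sites\n")
  miss <- mean(is.na(x$calls[, , 1]))
  cat(sprintf("  missing calls: %.1f%%; sexes: %s\n", 100 * miss,
              paste(names(table(x$meta$sex)), table(x$meta$sex),
                    sep = "=", collapse = " ")))
  invisible(x)
}

validate_meta <- function(meta) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("id", "site", "sex", "lat", "lon")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  meta$id <- as.character(meta$id)
  meta$site <- as.character(meta$site)
  if (anyDuplicated(meta$id))
    stop("duplicate ids in metadata: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  meta$sex <- normalize_sex(meta$sex)
  meta$lat <- as.numeric(meta$lat)
  meta$lon <- as.numeric(meta$lon)
  if (any(is.na(meta$lat)) || any(meta$lat < -90 | meta$lat > 90))
    stop("latitude out of range [-90, 90]")
  if (any(is.na(meta$lon)) || any(meta$lon < -180 | meta$lon > 180))
    stop("longitude out of range [-180, 180]")
  meta[, need]
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("m", "male")] <- "male"
  out[x %in% c("f", "female")] <- "female"
  out
}

#' Read a per-individual metadata table
#'
#' Delimited text with header `id,site,sex,lat,lon`. Sex labels are
#' normalized: `m`/`male` and `f`/`female` (any case, surrounding whitespace
#' ignored) map to `"male"`/`"female"`, anything else to `"unknown"`.
#'
#' @param path path to a CSV (or other `sep`-delimited) file.
#' @param sep field separator, default `","`.
#' @return data frame with columns `id`, `site`, `sex`, `lat`, `lon`.
#' @export
read_metadata <- function(path, sep = ",") {
  meta <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, strip.white = TRUE)
  validate_meta(meta)
}

#' Read a GenePop genotype file
#'
#' Supports the standard dialect: a title line, locus names (one per line or
#' comma-separated), `Pop` separators, and per-individual lines
#' `id , a1a2 a1a2 ...` with 2- or 3-digit-per-allele codes (auto-detected
#' from code width). `00`/`000` denotes a missing allele; a genotype is
#' treated as missing if either allele is missing.
#'
#' Allele codes are taken as allele sizes in bp unless a sidecar code table
#' (as written by [write_genepop()]) is supplied, in which case codes are
#' mapped back through it.
#'
#' @param path GenePop file.
#' @param meta optional metadata data frame or file path ([read_metadata()]
#'   format). If omitted, placeholder metadata is synthesised: sites from the
#'   Pop blocks (named after each block's last individual id, the GenePop
#'   convention, falling back to `pop1..popK` on clashes), sex unknown,
#'   coordinates 0.
#' @param sidecar optional path to a code-to-bp sidecar TSV.
#' @param label dataset label.
#' @return an [msat_dataset()].
#' @export
read_genepop <- function(path, meta = NULL, sidecar = NULL, label = "") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("GenePop file too short")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' separator found")
  header <- lines[2:(first_pop - 1)]
  locus_names <- trimws(unlist(strsplit(header, ",")))
  locus_names <- locus_names[nzchar(locus_names)]
  if (length(locus_names) < 1L) stop("no locus names found")

  ids <- character(); pop_of <- integer(); geno_rows <- list()
  pop_idx <- 0L
  for (i in seq(first_pop, length(lines))) {
    if (is_pop[i]) { pop_idx <- pop_idx + 1L; next }
    ln <- lines[i]
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L)
      stop("line ", i, ": expected 'id , genotypes' but found no comma")
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(codes) != length(locus_names))
      stop("line ", i, ": ", length(codes), " genotype field(s) for ",
           length(locus_names), " loci")
    width <- unique(nchar(codes))
    if (length(width) != 1L || !width %in% c(4L, 6L))
      stop("line ", i, ": unknown allele-code width (",
           paste(unique(nchar(codes)), collapse = ","),
           "); expected 4 or 6 characters per genotype")
    half <- width / 2L
    a1 <- as.integer(substr(codes, 1L, half))
    a2 <- as.integer(substr(codes, half + 1L, width))
    if (anyNA(a1) || anyNA(a2)) stop("line ", i, ": non-numeric allele code")
    a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
    ids <- c(ids, id); pop_of <- c(pop_of, pop_idx)
    geno_rows[[length(geno_rows) + 1L]] <- rbind(a1, a2)
  }
  n <- length(ids)
  if (n == 0L) stop("no individuals found")
  if (anyDuplicated(ids))
    ids <- make.unique(ids, sep = "_")
  L <- length(locus_names)
  calls <- array(NA_integer_, c(n, L, 2))
  for (j in seq_len(n)) {
    calls[j, , 1] <- geno_rows[[j]][1, ]
    calls[j, , 2] <- geno_rows[[j]][2, ]
  }

  if (!is.null(sidecar)) {
    map <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    calls[] <- map$size_bp[match(calls, map$code)]
  }

  ## site label per pop block: GenePop names a pop by its last individual id
  pop_names <- vapply(seq_len(max(pop_of)), function(k) {
    ids[max(which(pop_of == k))]
  }, character(1))
  if (anyDuplicated(pop_names)) pop_names <- paste0("pop", seq_along(pop_names))

  if (is.null(meta)) {
    meta <- data.frame(id = ids, site = pop_names[pop_of], sex = "unknown",
                       lat = 0, lon = 0, stringsAsFactors = FALSE)
  } else if (is.character(meta) && length(meta) == 1L) {
    meta <- read_metadata(meta)
  }
  msat_dataset(calls, ids, data.frame(name = locus_names), meta, label)
}

#' Write a dataset in GenePop format
#'
#' Emits the 3-digit-per-allele dialect, one `Pop` block per site (in order
#' of first appearance), with raw allele sizes in bp as codes. Allele sizes
#' above 999 do not fit the dialect; recode them (e.g. subtract a per-locus
#' offset) before writing. A sidecar TSV mapping codes to bp sizes can be
#' written alongside so that files remain self-describing.
#'
#' @param ds an [msat_dataset()].
#' @param path output file.
#' @param sidecar optional path for a code-to-bp sidecar TSV.
#' @param title title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(ds, path, sidecar = NULL, title = NULL) {
  stopifnot(inherits(ds, "msat_dataset"))
  if (length(ds$individuals) == 0L) stop("empty dataset")
  if (any(ds$calls > 999L, na.rm = TRUE))
    stop("allele sizes > 999 bp cannot be written in the 3-digit dialect; ",
         "recode alleles (e.g. subtract a per-locus offset) first")
  if (is.null(title))
    title <- paste("msatIBD dataset", ds$label)
  out <- c(title, ds$loci$name)
  code <- function(x) sprintf("%03d", ifelse(is.na(x), 0L, x))
  for (s in unique(ds$meta$site)) {
    out <- c(out, "Pop")
    for (j in which(ds$meta$site == s)) {
      g <- paste0(code(ds$calls[j, , 1]), code(ds$calls[j, , 2]))
      out <- c(out, paste(ds$individuals[j], ",", paste(g, collapse = " ")))
    }
  }
  writeLines(out, path)
  if (!is.null(sidecar)) {
    sizes <- sort(unique(as.vector(ds$calls)))
    utils::write.table(data.frame(code = sizes, size_bp = sizes),
                       sidecar, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Subset a dataset by loci, sites and/or sex
#'
#' Retains the original ordering of loci and individuals; subsetting is
#' idempotent and the axes commute.
#'
#' @param ds an [msat_dataset()].
#' @param loci character vector of locus names to retain (default all).
#' @param sites character vector of site labels to retain (default all).
#' @param sex `"male"` or `"female"` to retain one sex (default all).
#' @param label label for the derived dataset; defaults to the parent label.
#' @return an [msat_dataset()].
#' @export
subset_dataset <- function(ds, loci = NULL, sites = NULL, sex = NULL,
                           label = NULL) {
  stopifnot(inherits(ds, "msat_dataset"))
  keep_l <- seq_len(nrow(ds$loci))
  if (!is.null(loci)) {
    bad <- setdiff(loci, ds$loci$name)
    if (length(bad))
      stop("unknown locus name(s): ", paste(bad, collapse = ", "),
           "; known: ", paste(ds$loci$name, collapse = ", "))
    keep_l <- which(ds$loci$name %in% loci)
  }
  keep_i <- rep(TRUE, length(ds$individuals))
  if (!is.null(sites)) {
    bad <- setdiff(sites, unique(ds$meta$site))
    if (length(bad))
      stop("unknown site label(s): ", paste(bad, collapse = ", "),
           "; known: ", paste(unique(ds$meta$site), collapse = ", "))
    keep_i <- keep_i & ds$meta$site %in% sites
  }
  if (!is.null(sex)) {
    sex <- match.arg(sex, c("male", "female", "unknown"))
    keep_i <- keep_i & ds$meta$sex == sex
  }
  if (!any(keep_i)) stop("subset removes every individual")
  msat_dataset(ds$calls[keep_i, keep_l, , drop = FALSE],
               ds$individuals[keep_i],
               ds$loci[keep_l, , drop = FALSE],
               ds$meta[keep_i, , drop = FALSE],
               label = if (is.null(label)) ds$label else label)
}
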