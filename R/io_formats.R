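# SCAT-dialect genotype and site file handling.
#
# The genotype dialect: whitespace-delimited, two consecutive lines per
# individual.  Each line is "<id> <site_index> <allele at locus 1> ... ",
# -999 marks a missing allele, site_index -1 marks an unknown-origin sample.
# Haploid pseudo-loci (the mtDNA haplogroup "eleventh locus") carry their
# allele on the first line and -999 on the second.

MISSING_SENTINEL <- -999L

#' Integer codes used for the mtDNA haplogroup pseudo-locus
#'
#' Fixed so that written genotype files are bit-reproducible: 1a=1, 1b=2,
#' 2a=3, 2b=4, 2c=5.  The label `"unknown"` maps to the missing sentinel.
#'
#' @export
HAPLOGROUP_CODES <- c("1a" = 1L, "1b" = 2L, "2a" = 3L, "2b" = 4L, "2c" = 5L)

#' Default name of the haplogroup pseudo-locus
#' @export
HAPLOGROUP_LOCUS <- "mtDNA"

#' Construct a genotype table
#'
#' The central container for multilocus genotypes: an ordered set of samples,
#' each with one allele pair per diploid (STRP) locus and optionally one
#' allele at haploid pseudo-loci.  Missing alleles are stored as `NA` and
#' serialized as -999.
#'
#' @param ids character vector of unique sample identifiers.
#' @param site_index integer vector; index (>= 1) of the sampling site for
#'   georeferenced samples, -1 for unknown-origin samples.
#' @param a1,a2 integer matrices (`length(ids)` x `length(loci)`) of allele
#'   sizes (base pairs) or `NA`; `a2` is ignored (forced `NA`) for haploid
#'   loci.
#' @param loci character vector of locus names.
#' @param ploidy integer vector per locus, 2 for STRP loci, 1 for the
#'   haplogroup pseudo-locus.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(ids, site_index, a1, a2, loci,
                           ploidy = rep(2L, length(loci))) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  n <- length(ids)
  L <- length(loci)
  a1 <- matrix(as.integer(a1), n, L)
  a2 <- matrix(as.integer(a2), n, L)
  ploidy <- as.integer(ploidy)
  if (length(ploidy) != L || !all(ploidy %in% c(1L, 2L)))
    stop("ploidy must be 1 or 2 per locus")
  a1[!is.na(a1) & a1 == MISSING_SENTINEL] <- NA_integer_
  a2[!is.na(a2) & a2 == MISSING_SENTINEL] <- NA_integer_
  a2[, ploidy == 1L] <- NA_integer_
  bad <- which(!is.na(a1) & a1 <= 0L)
  if (length(bad)) stop("allele sizes must be positive integers")
  bad <- which(!is.na(a2) & a2 <= 0L)
  if (length(bad)) stop("allele sizes must be positive integers")
  structure(
    list(ids = ids, site_index = as.integer(site_index),
         a1 = a1, a2 = a2, loci = as.character(loci), ploidy = ploidy),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples, %d loci (%d diploid, %d haploid)\n",
              length(x$ids), length(x$loci), sum(x$ploidy == 2L),
              sum(x$ploidy == 1L)))
  cat(sprintf("  unknown-origin samples: %d\n", sum(x$site_index == -1L)))
  invisible(x)
}

#' Number of samples in a genotype table
#' @param table a `genotype_table`.
#' @export
n_samples <- function(table) length(table$ids)

#' Per-sample count of fully typed loci
#'
#' A locus counts as typed only if no allele at it is missing.  By default
#' only diploid (STRP) loci are counted, matching the suitability filter.
#'
#' @param table a `genotype_table`.
#' @param strp_only count only diploid loci (default `TRUE`).
#' @return integer vector named by sample id.
#' @export
typed_locus_counts <- function(table, strp_only = TRUE) {
  keep <- if (strp_only) table$ploidy == 2L else rep(TRUE, length(table$loci))
  a1 <- table$a1[, keep, drop = FALSE]
  a2 <- table$a2[, keep, drop = FALSE]
  hap <- table$ploidy[keep] == 1L
  ok <- !is.na(a1) & (!is.na(a2) | rep(hap, each = nrow(a1)))
  stats::setNames(as.integer(rowSums(ok)), table$ids)
}

#' Subset a genotype table by sample
#' @param table a `genotype_table`.
#' @param i logical, integer or character (id) index.
#' @export
subset_samples <- function(table, i) {
  if (is.character(i)) i <- match(i, table$ids)
  genotype_table(table$ids[i], table$site_index[i],
                 table$a1[i, , drop = FALSE], table$a2[i, , drop = FALSE],
                 table$loci, table$ploidy)
}

#' Parse a SCAT-dialect genotype file
#'
#' Two consecutive whitespace-delimited lines per individual, each
#' `<id> <site_index> <one allele per locus>`; both lines of a pair must
#' agree on id and site index.  -999 is the missing sentinel; site index -1
#' flags unknown origin.
#'
#' @param file path, connection, or a character vector of lines (given as
#'   `text = ...`).
#' @param text optional character vector of lines, used instead of `file`.
#' @param loci optional locus names; defaults to `L1..Lk`.
#' @param haploid character vector of locus names to treat as haploid
#'   pseudo-loci (their second-line allele must be -999).
#' @return A [genotype_table()].
#' @export
parse_scat_genotypes <- function(file = NULL, text = NULL, loci = NULL,
                                 haploid = character()) {
  lines <- if (!is.null(text)) text else readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 2L != 0L)
    stop("malformed genotype file: odd number of non-empty lines (",
         length(lines), "); every individual needs exactly two lines")
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  nt <- lengths(toks)
  if (length(unique(nt)) > 1L)
    stop("inconsistent token counts across lines (first offending line: ",
         which(nt != nt[1L])[1L], ")")
  if (nt[1L] < 3L) stop("each line needs id, site index and >= 1 allele")
  L <- nt[1L] - 2L
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  if (length(loci) != L) stop("loci has length ", length(loci),
                              " but file carries ", L, " loci")
  ploidy <- ifelse(loci %in% haploid, 1L, 2L)
  n <- length(lines) %/% 2L
  i1 <- seq(1L, by = 2L, length.out = n)
  parse_alleles <- function(row, lineno) {
    v <- suppressWarnings(as.integer(row))
    bad <- is.na(v) & !(row %in% c("NA"))
    if (any(bad))
      stop("non-integer allele token '", row[bad][1L], "' on line ", lineno)
    v
  }
  ids <- character(n); site <- integer(n)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(n)) {
    t1 <- toks[[i1[j]]]; t2 <- toks[[i1[j] + 1L]]
    if (t1[1L] != t2[1L])
      stop("pairing error: lines ", i1[j], "/", i1[j] + 1L,
           " have mismatched ids '", t1[1L], "' vs '", t2[1L], "'")
    if (t1[2L] != t2[2L])
      stop("pairing error: lines ", i1[j], "/", i1[j] + 1L,
           " have mismatched site indices for id '", t1[1L], "'")
    ids[j] <- t1[1L]
    s <- suppressWarnings(as.integer(t1[2L]))
    if (is.na(s)) stop("non-integer site index on line ", i1[j])
    site[j] <- s
    a1[j, ] <- parse_alleles(t1[-(1:2)], i1[j])
    a2[j, ] <- parse_alleles(t2[-(1:2)], i1[j] + 1L)
  }
  genotype_table(ids, site, a1, a2, loci, ploidy)
}

#' Write a genotype table in the SCAT dialect
#'
#' Inverse of [parse_scat_genotypes()]: `parse(write(x))` reproduces `x`
#' exactly (locus names are not stored in the file and must be re-supplied).
#'
#' @param table a `genotype_table`.
#' @param file path or connection; if `NULL`, the lines are returned.
#' @export
write_scat_genotypes <- function(table, file = NULL) {
  fmt <- function(m) {
    m[is.na(m)] <- MISSING_SENTINEL
    m
  }
  a1 <- fmt(table$a1); a2 <- fmt(table$a2)
  n <- n_samples(table)
  lines <- character(2L * n)
  for (j in seq_len(n)) {
    pre <- paste(table$ids[j], table$site_index[j])
    lines[2L * j - 1L] <- paste(pre, paste(a1[j, ], collapse = " "))
    lines[2L * j]      <- paste(pre, paste(a2[j, ], collapse = " "))
  }
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Apply the locus-count suitability filter
#'
#' A genotype profile is suitable for assignment only if it is fully typed at
#' `min_loci` or more STRP loci.  The haplogroup pseudo-locus never counts
#' toward the threshold (the filter is applied before haplogroup encoding).
#'
#' @param table a `genotype_table`.
#' @param min_loci minimum number of typed STRP loci (default 6).
#' @return list with elements `table` (kept samples) and `excluded`
#'   (character vector of excluded ids).
#' @export
filter_suitable <- function(table, min_loci = 6L) {
  stopifnot(min_loci >= 1L)
  if (n_samples(table) == 0L) {
    warning("empty genotype table")
    return(list(table = table, excluded = character()))
  }
  cnt <- typed_locus_counts(table, strp_only = TRUE)
  keep <- cnt >= min_loci
  list(table = subset_samples(table, which(keep)),
       excluded = table$ids[!keep])
}

#' Encode mtDNA haplogroup labels as a haploid pseudo-locus
#'
#' Appends one haploid locus whose allele is the fixed integer code of each
#' sample's haplogroup ([HAPLOGROUP_CODES]); `"unknown"` becomes missing and
#' never contributes to likelihoods.
#'
#' @param table a `genotype_table` without a haplogroup locus.
#' @param labels named character vector, sample id -> label in
#'   `c(names(HAPLOGROUP_CODES), "unknown")`.  Every table id must appear.
#' @param locus_name name for the pseudo-locus.
#' @export
encode_haplogroup_locus <- function(table, labels,
                                    locus_name = HAPLOGROUP_LOCUS) {
  if (locus_name %in% table$loci)
    stop("table already carries a '", locus_name, "' pseudo-locus")
  miss <- setdiff(table$ids, names(labels))
  if (length(miss))
    stop("no haplogroup label for sample(s): ", paste(miss, collapse = ", "))
  lab <- as.character(labels[table$ids])
  bad <- !(lab %in% c(names(HAPLOGROUP_CODES), "unknown"))
  if (any(bad)) stop("unrecognised haplogroup label: ", lab[bad][1L])
  code <- unname(HAPLOGROUP_CODES[lab])   # unknown -> NA
  genotype_table(table$ids, table$site_index,
                 cbind(table$a1, code),
                 cbind(table$a2, NA_integer_),
                 c(table$loci, locus_name),
                 c(table$ploidy, 1L))
}

#' Decode the haplogroup pseudo-locus back to labels
#'
#' Exact inverse of [encode_haplogroup_locus()].
#'
#' @param table a `genotype_table` with a haplogroup pseudo-locus.
#' @param locus_name name of the pseudo-locus.
#' @return named character vector id -> label ("unknown" for missing).
#' @export
decode_haplogroup_locus <- function(table, locus_name = HAPLOGROUP_LOCUS) {
  k <- match(locus_name, table$loci)
  if (is.na(k)) stop("no '", locus_name, "' locus in table")
  code <- table$a1[, k]
  inv <- stats::setNames(names(HAPLOGROUP_CODES), HAPLOGROUP_CODES)
  lab <- ifelse(is.na(code), "unknown", inv[as.character(code)])
  stats::setNames(unname(lab), table$ids)
}

# ---------------------------------------------------------------------------
# Sampling sites

#' Construct a sampling-site table
#'
#' Georeferenced reference sites with a three-way biogeographic zone label
#' (North of the river barrier, Transition/contact zone, South).  The
#' two-way region used for region-level accuracy scoring is derived from the
#' zone; the Transition zone maps to a configurable region (default North).
#'
#' @param code site codes (short text, e.g. "MTCM").
#' @param index unique contiguous integer indices starting at 1.
#' @param lat,lon decimal degrees WGS84.
#' @param zone one of "North", "Transition", "South" per site.
#' @return data.frame of class `sampling_sites` with a derived `region`
#'   column.
#' @export
sampling_sites <- function(code, index, lat, lon, zone) {
  index <- as.integer(index)
  if (anyDuplicated(index) || !setequal(index, seq_along(index)))
    stop("site indices must be unique and contiguous from 1")
  if (!all(zone %in% c("North", "Transition", "South")))
    stop("zone must be North, Transition or South")
  if (any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("coordinates out of range")
  df <- data.frame(code = as.character(code), index = index,
                   lat = as.numeric(lat), lon = as.numeric(lon),
                   zone = as.character(zone), stringsAsFactors = FALSE)
  df <- df[order(df$index), , drop = FALSE]
  rownames(df) <- NULL
  df$region <- site_region(df$zone)
  class(df) <- c("sampling_sites", "data.frame")
  df
}

#' Map zone labels to two-way region labels
#' @param zone character vector of zone labels.
#' @param transition_region region the Transition zone is scored in.
#' @export
site_region <- function(zone, transition_region = "North") {
  ifelse(zone == "Transition", transition_region, zone)
}

#' Read a sampling-site file
#'
#' One line per site: `code index latitude longitude zone`.
#'
#' @param file path or connection.
#' @export
read_sampling_sites <- function(file) {
  df <- utils::read.table(file, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("code", "index", "lat", "lon", "zone"))
  sampling_sites(df$code, df$index, df$lat, df$lon, df$zone)
}

#' Write a sampling-site file
#' @param sites a `sampling_sites` table.
#' @param file path or connection.
#' @export
write_sampling_sites <- function(sites, file) {
  lines <- sprintf("%s %d %.6f %.6f %s", sites$code, sites$index,
                   sites$lat, sites$lon, sites$zone)
  writeLines(lines, file)
  invisible(lines)
}
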