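# Seeded synthetic landscapes with the statistical structure the assignment
# model assumes: spatially autocorrelated allele frequencies over scattered
# sites, a river-barrier latent shift with a linear transition (contact)
# zone, barrier-correlated mtDNA haplogroups, and per-locus missingness.

KM_PER_DEG_LAT <- 111.19

#' Configuration of a synthetic landscape
#'
#' Defaults emulate the reference panel the model was designed for: 10
#' sites across a Cameroon-sized rectangle, 10 STRP loci with spatially
#' autocorrelated frequencies (decay range 150 km), a river barrier at
#' mid-latitude with a 100 km transition zone, a strong (+3 latent units)
#' cross-barrier shift, 5% per-locus missingness, and haplogroups matching
#' the barrier side with probability 0.95.
#'
#' @param n_sites number of reference sites (>= 2).
#' @param samples_per_site georeferenced samples per site.
#' @param n_loci number of diploid STRP loci.
#' @param alleles_per_locus alleles segregating per locus.
#' @param alpha_true decay range (km) of the latent covariance.
#' @param beta_sill_true,tau2_true latent sill and nugget variance.
#' @param barrier constant latitude of the river barrier, or a data.frame
#'   (`lat`, `lon`) polyline read as latitude-as-a-function-of-longitude.
#' @param barrier_shift latent mean offset added north of the barrier to one
#'   randomly chosen allele per locus.
#' @param transition_width km over which the shift tapers linearly.
#' @param missing_rate i.i.d. probability that a sample-locus is missing.
#' @param haplogroup_fidelity probability a sample's haplogroup matches its
#'   barrier side.
#' @param lat_range,lon_range map rectangle (decimal degrees).
#' @param seed RNG seed; everything downstream is deterministic in it.
#' @export
landscape_config <- function(n_sites = 10L, samples_per_site = 10L,
                             n_loci = 10L, alleles_per_locus = 5L,
                             alpha_true = 150, beta_sill_true = 1,
                             tau2_true = 0.1, barrier = 4.5,
                             barrier_shift = 3, transition_width = 100,
                             missing_rate = 0.05,
                             haplogroup_fidelity = 0.95,
                             lat_range = c(2, 7), lon_range = c(9, 14),
                             seed = 1L) {
  stopifnot(n_sites >= 2L, samples_per_site >= 0L, n_loci >= 1L,
            alleles_per_locus >= 2L, alpha_true > 0, beta_sill_true >= 0,
            tau2_true > 0, transition_width > 0,
            missing_rate >= 0, missing_rate <= 1,
            haplogroup_fidelity >= 0, haplogroup_fidelity <= 1)
  as.list(environment())
}

barrier_lat_at <- function(barrier, lon) {
  if (is.numeric(barrier) && length(barrier) == 1L)
    return(rep(barrier, length(lon)))
  stats::approx(barrier$lon, barrier$lat, xout = lon, rule = 2L)$y
}

# Signed km north (+) of the barrier.
barrier_signed_km <- function(barrier, lat, lon)
  (lat - barrier_lat_at(barrier, lon)) * KM_PER_DEG_LAT

# Linear taper: 0 south of the transition zone, 1 north of it.
barrier_taper <- function(d_km, width) pmin(1, pmax(0, d_km / width + 0.5))

draw_haplogroups <- function(side_north, fidelity) {
  n <- length(side_north)
  flip <- stats::runif(n) < (1 - fidelity)
  eff <- xor(side_north, flip)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (eff[i])
      sample(c("1a", "1b"), 1L, prob = c(0.25, 0.75))
    else
      sample(c("2a", "2b", "2c"), 1L, prob = c(0.3, 0.2, 0.5))
  }
  out
}

#' Simulate a georeferenced synthetic landscape
#'
#' Site coordinates are scattered uniformly over the map rectangle; per
#' locus-allele latent fields are drawn from a multivariate normal with the
#' exponential-decay covariance; `barrier_shift` is added to one allele per
#' locus north of the barrier (tapered across the transition zone);
#' frequencies arise from the same softmax transform the model uses;
#' diploid genotypes are sampled under Hardy-Weinberg equilibrium;
#' haplogroups follow the barrier side with probability
#' `haplogroup_fidelity`; missingness is i.i.d.  Fully seeded.
#'
#' @param cfg a [landscape_config()].
#' @return list with `table` (genotype_table of georeferenced samples),
#'   `sites`, `haplogroups` (named id -> label), `truth` (true per-site
#'   frequency matrix, allele universe, per-sample metadata), `boundary`
#'   (map rectangle polygon, padded), and `config`.
#' @export
simulate_landscape <- function(cfg = landscape_config()) {
  set.seed(cfg$seed)
  S <- cfg$n_sites; L <- cfg$n_loci; A <- cfg$alleles_per_locus
  lat <- stats::runif(S, cfg$lat_range[1L], cfg$lat_range[2L])
  lon <- stats::runif(S, cfg$lon_range[1L], cfg$lon_range[2L])
  d_km <- barrier_signed_km(cfg$barrier, lat, lon)
  zone <- ifelse(abs(d_km) < cfg$transition_width / 2, "Transition",
                 ifelse(d_km > 0, "North", "South"))
  sites <- sampling_sites(sprintf("ST%02d", seq_len(S)), seq_len(S),
                          lat, lon, zone)

  universe <- lapply(seq_len(L), function(l)
    as.integer(100 + 10 * (l - 1) + 2 * (0:(A - 1))))
  K <- L * A
  D <- site_distance_matrix(sites)
  Sigma <- cfg$beta_sill_true * exp(-D / cfg$alpha_true) +
    diag(cfg$tau2_true, S)
  Lc <- tryCatch(t(chol(Sigma)),
                 error = function(e) stop("degenerate covariance: ",
                                          conditionMessage(e)))
  taper <- barrier_taper(d_km, cfg$transition_width)
  shifted_allele <- sample.int(A, L, replace = TRUE)
  latent <- matrix(0, S, K)
  for (k in seq_len(K)) latent[, k] <- as.numeric(Lc %*% stats::rnorm(S))
  for (l in seq_len(L))
    latent[, (l - 1L) * A + shifted_allele[l]] <-
      latent[, (l - 1L) * A + shifted_allele[l]] + cfg$barrier_shift * taper

  freqs <- latent
  for (l in seq_len(L)) {
    k <- (l - 1L) * A + seq_len(A)
    freqs[, k] <- t(apply(latent[, k, drop = FALSE], 1L, latent_to_freq))
  }
  colnames(freqs) <- unlist(lapply(seq_len(L), function(l)
    paste0("L", l, ":", universe[[l]])))
  rownames(freqs) <- sites$code

  n <- S * cfg$samples_per_site
  ids <- sprintf("G%03d", seq_len(n))
  site_of <- rep(seq_len(S), each = cfg$samples_per_site)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    s <- site_of[i]
    for (l in seq_len(L)) {
      k <- (l - 1L) * A + seq_len(A)
      g <- sample(universe[[l]], 2L, replace = TRUE, prob = freqs[s, k])
      a1[i, l] <- g[1L]; a2[i, l] <- g[2L]
    }
  }
  miss <- matrix(stats::runif(n * L) < cfg$missing_rate, n, L)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  tab <- genotype_table(ids, site_of, a1, a2, paste0("L", seq_len(L)))
  hg <- stats::setNames(draw_haplogroups(d_km[site_of] > 0,
                                         cfg$haplogroup_fidelity), ids)
  pad <- 0.5
  boundary <- boundary_polygon(
    lat = c(cfg$lat_range[1L] - pad, cfg$lat_range[1L] - pad,
            cfg$lat_range[2L] + pad, cfg$lat_range[2L] + pad),
    lon = c(cfg$lon_range[1L] - pad, cfg$lon_range[2L] + pad,
            cfg$lon_range[2L] + pad, cfg$lon_range[1L] - pad))
  truth <- list(freqs = freqs, universe = universe,
                shifted_allele = shifted_allele,
                samples = data.frame(id = ids, site_index = site_of,
                                     site = sites$code[site_of],
                                     lat = sites$lat[site_of],
                                     lon = sites$lon[site_of],
                                     north = d_km[site_of] > 0,
                                     stringsAsFactors = FALSE))
  list(table = tab, sites = sites, haplogroups = hg, truth = truth,
       boundary = boundary, config = cfg)
}

#' Draw unknown-origin query samples from the true site frequencies
#'
#' Fresh genotypes per site (no missingness), marked unknown (site index
#' -1), plus an answer key that assignment code must never see.
#'
#' @param landscape result of [simulate_landscape()].
#' @param n_per_site queries per site.
#' @param seed RNG seed.
#' @return list `table` (queries), `haplogroups`, `key` (data.frame `id`,
#'   `site_index`, `site`, `lat`, `lon`).
#' @export
sample_unknowns <- function(landscape, n_per_site, seed = 1L) {
  set.seed(seed)
  cfg <- landscape$config
  S <- cfg$n_sites; L <- cfg$n_loci; A <- cfg$alleles_per_locus
  universe <- landscape$truth$universe
  freqs <- landscape$truth$freqs
  n <- S * n_per_site
  if (n == 0L)
    return(list(table = genotype_table(character(), integer(),
                                       matrix(NA_integer_, 0, L),
                                       matrix(NA_integer_, 0, L),
                                       paste0("L", seq_len(L))),
                haplogroups = stats::setNames(character(), character()),
                key = data.frame(id = character(), site_index = integer(),
                                 site = character(), lat = numeric(),
                                 lon = numeric())))
  ids <- sprintf("U%03d", seq_len(n))
  site_of <- rep(seq_len(S), each = n_per_site)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    s <- site_of[i]
    for (l in seq_len(L)) {
      k <- (l - 1L) * A + seq_len(A)
      g <- sample(universe[[l]], 2L, replace = TRUE, prob = freqs[s, k])
      a1[i, l] <- g[1L]; a2[i, l] <- g[2L]
    }
  }
  d_km <- barrier_signed_km(cfg$barrier, landscape$sites$lat[site_of],
                            landscape$sites$lon[site_of])
  hg <- stats::setNames(draw_haplogroups(d_km > 0, cfg$haplogroup_fidelity),
                        ids)
  tab <- genotype_table(ids, rep(-1L, n), a1, a2, paste0("L", seq_len(L)))
  key <- data.frame(id = ids, site_index = site_of,
                    site = landscape$sites$code[site_of],
                    lat = landscape$sites$lat[site_of],
                    lon = landscape$sites$lon[site_of],
                    stringsAsFactors = FALSE)
  list(table = tab, haplogroups = hg, key = key)
}

#' Write a landscape as a fixture bundle of plain-text files
#'
#' Emits `genotypes.txt` (SCAT dialect), `sites.txt`, `boundary.txt` (one
#' `lat lon` vertex per line), `haplogroups.tsv`, and, when `unknowns` is
#' given, `unknown_genotypes.txt` plus `answer_key.tsv`.  Regenerating the
#' bundle from the same seed is byte-identical; the bundle round-trips
#' losslessly through the parsers.
#'
#' @param landscape result of [simulate_landscape()].
#' @param dir output directory (created).
#' @param unknowns optional result of [sample_unknowns()].
#' @return invisible character vector of files written.
#' @export
write_fixture_bundle <- function(landscape, dir, unknowns = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(genotypes = file.path(dir, "genotypes.txt"),
             sites = file.path(dir, "sites.txt"),
             boundary = file.path(dir, "boundary.txt"),
             haplogroups = file.path(dir, "haplogroups.tsv"))
  write_scat_genotypes(landscape$table, files["genotypes"])
  write_sampling_sites(landscape$sites, files["sites"])
  writeLines(sprintf("%.6f %.6f", landscape$boundary$lat,
                     landscape$boundary$lon), files["boundary"])
  hg <- landscape$haplogroups
  writeLines(c("id\thaplogroup", sprintf("%s\t%s", names(hg), hg)),
             files["haplogroups"])
  if (!is.null(unknowns)) {
    files <- c(files, unknown_genotypes = file.path(dir, "unknown_genotypes.txt"),
               answer_key = file.path(dir, "answer_key.tsv"))
    write_scat_genotypes(unknowns$table, files["unknown_genotypes"])
    k <- unknowns$key
    writeLines(c("id\tsite_index\tsite\tlat\tlon",
                 sprintf("%s\t%d\t%s\t%.6f\t%.6f", k$id, k$site_index,
                         k$site, k$lat, k$lon)),
               files["answer_key"])
  }
  invisible(files)
}

#' Read a boundary polygon file (one `lat lon` vertex per line)
#' @param file path.
#' @export
read_boundary_polygon <- function(file) {
  df <- utils::read.table(file, header = FALSE,
                          col.names = c("lat", "lon"))
  boundary_polygon(df$lat, df$lon)
}
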