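# SAM and CAM assignment of unknown-origin genotypes: SAM scores every
# sampled reference site by posterior mean genotype log-likelihood with a
# multi-run consensus; CAM runs a Metropolis random walk over candidate
# coordinates constrained to a habitat boundary polygon.

#' Construct and validate a boundary polygon
#'
#' @param lat,lon ordered vertex coordinates in decimal degrees; the polygon
#'   may be explicitly closed (first == last) or implicitly closed.
#' @return object of class `boundary_polygon` (data.frame `lat`, `lon`,
#'   without a duplicated closing vertex).
#' @export
boundary_polygon <- function(lat, lon) {
  stopifnot(length(lat) == length(lon))
  n <- length(lat)
  if (n > 1L && lat[1L] == lat[n] && lon[1L] == lon[n]) {
    lat <- lat[-n]; lon <- lon[-n]; n <- n - 1L
  }
  if (nrow(unique(cbind(lat, lon))) < 3L)
    stop("a boundary polygon needs >= 3 distinct vertices")
  poly <- data.frame(lat = as.numeric(lat), lon = as.numeric(lon))
  if (polygon_self_intersects(poly))
    stop("boundary polygon is self-intersecting")
  class(poly) <- c("boundary_polygon", "data.frame")
  poly
}

# Proper-crossing test between non-adjacent edges.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  x <- poly$lon; y <- poly$lat
  nxt <- c(seq_len(n)[-1L], 1L)
  seg_cross <- function(i, j) {
    p1 <- c(x[i], y[i]); p2 <- c(x[nxt[i]], y[nxt[i]])
    p3 <- c(x[j], y[j]); p4 <- c(x[nxt[j]], y[nxt[j]])
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
      (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
       ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent around the wrap
      if (seg_cross(i, j)) return(TRUE)
    }
  }
  FALSE
}

#' Bundled study-area boundary polygon (Nigeria and Cameroon)
#'
#' The habitat polygon enclosing all ten reference sampling sites and the
#' known chimpanzee habitat across Nigeria and Cameroon, used for the
#' primary CAM assignments.
#'
#' @export
study_area_polygon <- function() {
  boundary_polygon(
    lat = c(9.01, 7.80, 6.03, 3.73, 1.71, 2.26, 3.96, 4.42, 6.22, 6.47, 9.01),
    lon = c(2.79, 15.50, 14.54, 15.32, 16.16, 9.83, 9.17, 5.84, 4.88, 2.78,
            2.79))
}

#' Bundled boundary polygon of the P. t. troglodytes range
#'
#' The wider central-African range polygon used for the follow-up CAM test
#' of samples placed in southern Cameroon (with western-Nigeria samples as
#' negative controls).
#'
#' @export
troglodytes_range_polygon <- function() {
  boundary_polygon(
    lat = c(3.76, 4.29, 4.48, 4.14, 3.98, 1.66, -0.57, -2.16, -4.33, -5.96,
            -4.48, -3.45, -1.87, -0.79, 0.35, 2.21, 3.13, 3.76),
    lon = c(9.61, 11.29, 13.63, 16.30, 18.59, 18.10, 17.73, 16.32, 15.26,
            12.43, 11.85, 10.57, 9.33, 8.92, 9.48, 9.91, 9.99, 9.61))
}

#' Point-in-polygon test (even-odd rule, boundary counts as inside)
#'
#' @param lat,lon coordinates (vectorised).
#' @param poly a [boundary_polygon()].
#' @return logical vector.
#' @export
point_in_polygon <- function(lat, lon, poly) {
  if (!inherits(poly, "boundary_polygon")) poly <- boundary_polygon(poly$lat, poly$lon)
  pip_cpp(as.numeric(lat), as.numeric(lon), poly$lat, poly$lon)
}

#' Smoothed assignment (SAM) of one sample to the reference sites
#'
#' For each fitted run, every site is scored by the mean over that run's
#' retained draws of the query's genotype log-likelihood under the site's
#' allele frequencies.  The per-run best site is the argmax; the consensus
#' is the majority across runs, ties broken by the highest mean
#' log-likelihood ratio over all runs.
#'
#' @param table a `genotype_table` containing the query.
#' @param i query sample index or id.
#' @param surface a `frequency_surface` fitted *without* the query (for
#'   cross-validation the leave-one-out refit is mandatory).
#' @return object of class `sam_assignment`: `scores` (runs x sites mean
#'   log-likelihoods), `mean_ll` (per site, across runs), `llr` (per site,
#'   mean log-likelihood ratio vs the best alternative site), `best_run`
#'   (site code per run), `consensus`, `agreement`.
#' @export
sam_assign <- function(table, i, surface) {
  qc <- query_count_vector(table, i, surface$universe)
  if (qc$typed == 0L) stop("query has no typed loci")
  sc <- sam_scores_cpp(surface$latent, dim(surface$latent), qc$q,
                       surface$locus_of, length(surface$universe))
  sc <- sc + qc$het_const
  S <- ncol(sc)
  codes <- surface$sites$code
  runs <- sort(unique(surface$run))
  per_run <- matrix(vapply(runs, function(r)
    colMeans(sc[surface$run == r, , drop = FALSE]), numeric(S)),
    nrow = length(runs), ncol = S, byrow = TRUE,
    dimnames = list(paste0("run", runs), codes))
  mean_ll <- colMeans(per_run)
  llr <- vapply(seq_len(S), function(s)
    if (S == 1L) 0 else mean_ll[s] - max(mean_ll[-s]), 0)
  names(llr) <- codes
  best_run <- codes[apply(per_run, 1L, which.max)]
  tab <- table(factor(best_run, levels = codes))
  top <- names(tab)[tab == max(tab)]
  consensus <- if (length(top) == 1L) top else top[which.max(llr[top])]
  structure(list(id = if (is.character(i)) i else table$ids[i],
                 scores = per_run, mean_ll = mean_ll, llr = llr,
                 best_run = best_run, consensus = consensus,
                 agreement = as.integer(max(tab))),
            class = "sam_assignment")
}

#' @export
print.sam_assignment <- function(x, ...) {
  cat(sprintf("sam_assignment %s -> %s (%d/%d runs agree, LLR %.2f)\n",
              x$id, x$consensus, x$agreement, nrow(x$scores),
              x$llr[x$consensus]))
  invisible(x)
}

#' Continuous assignment (CAM) of one sample inside a boundary polygon
#'
#' Per run, a Metropolis random walk over candidate coordinates: proposals
#' are spherical-Gaussian steps (step size adapted to 20-50% acceptance
#' during burn-in, then frozen), proposals outside the boundary are
#' rejected, and the acceptance ratio uses the genotype log-likelihood at
#' allele frequencies kriged from a posterior surface draw (draws cycled
#' along the chain).  Retained states from all runs are pooled.
#'
#' @inheritParams sam_assign
#' @param boundary a [boundary_polygon()].
#' @param cfg an [mcmc_config()] for the location chain; defaults to the
#'   surface's own configuration.
#' @param step_init initial proposal standard deviation in degrees.
#' @param zones optional named list of zone [boundary_polygon()]s used to
#'   label the median point estimate.
#' @param n_confidence number of posterior-weighted confidence draws.
#' @return object of class `cam_assignment`: pooled `chain` (lat/lon
#'   matrix, `runs * iterations` rows), `median` point estimate,
#'   `confidence` draws, `zone` of the median (or `NA`), acceptance rates.
#' @export
cam_assign <- function(table, i, surface, boundary, cfg = NULL,
                       step_init = 0.5, zones = NULL, n_confidence = 100L) {
  if (is.null(cfg)) cfg <- surface$cfg
  qc <- query_count_vector(table, i, surface$universe)
  if (qc$typed == 0L) stop("query has no typed loci")
  id <- if (is.character(i)) i else table$ids[i]
  D <- site_distance_matrix(surface$sites)
  s0 <- derive_seed(cfg$seed, id_hash(id))
  chains <- vector("list", cfg$runs)
  accept <- numeric(cfg$runs)
  for (r in seq_len(cfg$runs)) {
    set.seed(derive_seed(s0, r))
    res <- cam_run_cpp(surface$latent, dim(surface$latent), surface$mu,
                       surface$hyper, qc$q, surface$locus_of,
                       length(surface$universe), surface$sites$lat,
                       surface$sites$lon, D, boundary$lat, boundary$lon,
                       cfg$burn_in, cfg$iterations, cfg$thinning, step_init)
    chains[[r]] <- res$chain
    accept[r] <- res$accept
  }
  chain <- do.call(rbind, chains)
  colnames(chain) <- c("lat", "lon")
  med <- median_point(chain)
  zone <- if (is.null(zones)) NA_character_ else
    zone_of(med[1L], med[2L], zones, strict = FALSE)
  conf <- confidence_draws(chain, n = n_confidence,
                           seed = derive_seed(s0, 9999L))
  structure(list(id = id, chain = chain, median = med, confidence = conf,
                 zone = zone, accept = accept,
                 run = rep(seq_len(cfg$runs), each = cfg$iterations)),
            class = "cam_assignment")
}

#' @export
print.cam_assignment <- function(x, ...) {
  cat(sprintf("cam_assignment %s -> (%.5f, %.5f)%s; %d retained points\n",
              x$id, x$median[1L], x$median[2L],
              if (is.na(x$zone)) "" else paste0(" [", x$zone, "]"),
              nrow(x$chain)))
  invisible(x)
}

#' Component-wise median of a coordinate chain
#'
#' @param chain matrix (or data.frame) with columns lat, lon.
#' @return numeric `c(lat, lon)` (even counts averaged per component).
#' @export
median_point <- function(chain) {
  chain <- as.matrix(chain)
  if (nrow(chain) == 0L) stop("empty chain")
  c(lat = stats::median(chain[, 1L]), lon = stats::median(chain[, 2L]))
}

#' Posterior-weighted confidence draws from a CAM chain
#'
#' The retained chain is already posterior-weighted, so confidence draws
#' are uniform with-replacement resamples of its coordinates.
#'
#' @param chain matrix with columns lat, lon.
#' @param n number of draws (default 100).
#' @param seed RNG seed.
#' @export
confidence_draws <- function(chain, n = 100L, seed = 1L) {
  chain <- as.matrix(chain)
  if (nrow(chain) == 0L) stop("empty chain")
  set.seed(seed)
  chain[sample.int(nrow(chain), n, replace = TRUE), , drop = FALSE]
}

#' Zone membership of a coordinate
#'
#' @param lat,lon coordinate.
#' @param zones named list of [boundary_polygon()]s.
#' @param strict error when the point is in no zone (default) instead of
#'   returning `NA`.
#' @return zone name of the first containing polygon.
#' @export
zone_of <- function(lat, lon, zones, strict = TRUE) {
  for (z in names(zones))
    if (point_in_polygon(lat, lon, zones[[z]])) return(z)
  if (strict) stop("point (", lat, ", ", lon, ") lies in no zone polygon")
  NA_character_
}

#' Write SAM assignments as a tab-separated table
#' @param assignments list of `sam_assignment` objects.
#' @param file path or connection.
#' @export
write_sam_table <- function(assignments, file) {
  rows <- lapply(assignments, function(a) {
    cbind(data.frame(id = a$id, consensus = a$consensus,
                     agreement = a$agreement),
          as.data.frame(t(a$mean_ll)))
  })
  out <- do.call(rbind, rows)
  utils::write.table(format(out, digits = 10), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write CAM point estimates (and companion confidence draws) as TSV
#' @param assignments list of `cam_assignment` objects.
#' @param file path for the per-sample median table.
#' @param confidence_file optional path for the pooled confidence draws.
#' @export
write_cam_table <- function(assignments, file, confidence_file = NULL) {
  out <- do.call(rbind, lapply(assignments, function(a)
    data.frame(id = a$id, lat = sprintf("%.6f", a$median[1L]),
               lon = sprintf("%.6f", a$median[2L]), zone = a$zone)))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(confidence_file)) {
    cd <- do.call(rbind, lapply(assignments, function(a)
      data.frame(id = a$id, lat = sprintf("%.6f", a$confidence[, 1L]),
                 lon = sprintf("%.6f", a$confidence[, 2L]))))
    utils::write.table(cd, confidence_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(out)
}
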