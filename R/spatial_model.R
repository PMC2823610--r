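# The probabilistic core: distance-decay covariance over sampling sites,
# latent Gaussian fields transformed to allele frequencies, multilocus
# genotype likelihoods, and MCMC posterior sampling of frequency surfaces.

EARTH_RADIUS_KM <- 6371.0

#' Great-circle (haversine) distance in kilometres
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @param radius Earth radius in km (default 6371.0).
#' @return distance(s) in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2,
                            radius = EARTH_RADIUS_KM) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range: |lat| <= 90, |lon| <= 180 required")
  r <- pi / 180
  dlat <- (lat2 - lat1) * r / 2
  dlon <- (lon2 - lon1) * r / 2
  a <- sin(dlat)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon)^2
  2 * radius * asin(pmin(1, sqrt(a)))
}

#' Parameters of the spatial frequency surface
#'
#' Exponential distance-decay covariance with a nugget:
#' `C(d) = beta_sill * exp(-d / alpha) + tau2 * [d == 0]`.
#' `alpha` (km) controls how fast correlations between allele frequencies
#' decay with distance; `beta_sill` scales the latent variance; `tau2`
#' captures site-level noise and keeps the matrix positive definite.
#'
#' @param alpha decay range in km (> 0).
#' @param beta_sill covariance scale (> 0).
#' @param tau2 nugget variance (>= 0).
#' @export
surface_params <- function(alpha = 200, beta_sill = 1, tau2 = 0.1) {
  if (alpha <= 0 || beta_sill <= 0) stop("alpha and beta_sill must be > 0")
  if (tau2 < 0) stop("tau2 must be >= 0")
  structure(list(alpha = alpha, beta_sill = beta_sill, tau2 = tau2),
            class = "surface_params")
}

#' Distance-decay covariance matrix over sites
#'
#' @param sites a `sampling_sites` table (or any data.frame with `lat`,
#'   `lon`).
#' @param params a [surface_params()].
#' @return symmetric positive-definite matrix
#'   `C[i,j] = beta_sill * exp(-d_ij/alpha) + tau2 * [i == j]`.
#' @export
covariance_matrix <- function(sites, params) {
  stopifnot(inherits(params, "surface_params"), nrow(sites) >= 1L)
  D <- site_distance_matrix(sites)
  params$beta_sill * exp(-D / params$alpha) + diag(params$tau2, nrow(D))
}

site_distance_matrix <- function(sites) {
  n <- nrow(sites)
  D <- matrix(0, n, n)
  if (n > 1L) for (i in seq_len(n - 1L)) {
    d <- great_circle_km(sites$lat[i], sites$lon[i],
                         sites$lat[(i + 1L):n], sites$lon[(i + 1L):n])
    D[i, (i + 1L):n] <- d
    D[(i + 1L):n, i] <- d
  }
  D
}

#' Transform latent field values to allele frequencies
#'
#' Overflow-guarded softmax: strictly positive frequencies summing to one,
#' invariant to adding a constant to all latent values.
#'
#' @param latent numeric vector of latent values for one locus at one
#'   location (>= 2 alleles).
#' @export
latent_to_freq <- function(latent) {
  if (length(latent) < 2L) stop("a locus needs >= 2 alleles")
  e <- exp(latent - max(latent))
  e / sum(e)
}

#' Multilocus genotype log-likelihood under given allele frequencies
#'
#' Hardy-Weinberg genotype probabilities: homozygote `p^2`, heterozygote
#' `2 p q`; a haploid pseudo-locus contributes `p`.  Missing loci contribute
#' zero (the empty product).
#'
#' @param alleles list with one element per locus: an integer pair (diploid),
#'   a single integer (haploid), or `NULL`/`NA` for missing.
#' @param freqs list parallel to `alleles`: named numeric frequency vectors
#'   (names = allele sizes).
#' @return log-probability (0 when every locus is missing).
#' @export
genotype_loglik <- function(alleles, freqs) {
  stopifnot(length(alleles) == length(freqs))
  ll <- 0
  for (l in seq_along(alleles)) {
    a <- alleles[[l]]
    if (is.null(a) || all(is.na(a))) next
    if (any(is.na(a))) next                 # half-missing locus: skip
    f <- freqs[[l]]
    p <- f[as.character(a)]
    if (any(is.na(p)))
      stop("no frequency for allele ", a[is.na(p)][1L], " at locus ", l)
    if (length(a) == 2L) {
      ll <- ll + if (a[1L] == a[2L]) 2 * log(p[1L]) else
        log(2) + log(p[1L]) + log(p[2L])
    } else {
      ll <- ll + log(p[1L])
    }
  }
  unname(ll)
}

#' Extract one sample's alleles as a per-locus list
#' @param table a `genotype_table`.
#' @param i sample index or id.
#' @export
record_alleles <- function(table, i) {
  if (is.character(i)) i <- match(i, table$ids)
  lapply(seq_along(table$loci), function(l) {
    if (table$ploidy[l] == 1L) {
      a <- table$a1[i, l]
      if (is.na(a)) NULL else a
    } else {
      a <- c(table$a1[i, l], table$a2[i, l])
      if (any(is.na(a))) NULL else a
    }
  })
}

#' MCMC run configuration
#'
#' Defaults follow the published protocol: thinning 500, burn-in 1,000
#' cycles, 2,000 retained iterations per run, 5 independent runs.
#'
#' @param thinning keep every `thinning`-th proposal cycle.
#' @param burn_in discarded initial cycles per run.
#' @param iterations retained states per run.
#' @param runs independent chains (distinct derived seeds).
#' @param seed master seed; per-run seeds derive deterministically from it.
#' @export
mcmc_config <- function(thinning = 500L, burn_in = 1000L, iterations = 2000L,
                        runs = 5L, seed = 1L) {
  v <- c(thinning, burn_in, iterations, runs)
  if (any(v < 1L)) stop("all MCMC settings must be positive")
  structure(list(thinning = as.integer(thinning), burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations), runs = as.integer(runs),
                 seed = as.integer(seed)), class = "mcmc_config")
}

#' Reduced MCMC settings for desk-scale testing
#'
#' Scaled-down settings (thinning 1, burn-in 200, 400 retained iterations,
#' 2 runs) used where the full protocol would be needlessly slow; accuracy
#' claims tested under these settings are correspondingly coarse.
#'
#' @inheritParams mcmc_config
#' @export
reduced_mcmc_config <- function(seed = 1L, burn_in = 200L, iterations = 400L,
                                runs = 2L, thinning = 1L) {
  mcmc_config(thinning = thinning, burn_in = burn_in, iterations = iterations,
              runs = runs, seed = seed)
}

#' Priors for the surface model hyperparameters
#'
#' `mu ~ N(0, mu_sd^2)` per locus-allele; `log alpha ~ N(log 200 km, 1)`;
#' `log beta_sill`, `log tau2 ~ N(0, 1)`.  All configurable.
#'
#' @param mu_sd,log_alpha_mean,log_alpha_sd,log_beta_mean,log_beta_sd
#'   prior location/scale parameters.
#' @param log_tau2_mean,log_tau2_sd nugget prior (log scale).
#' @export
surface_priors <- function(mu_sd = 3, log_alpha_mean = log(200),
                           log_alpha_sd = 1, log_beta_mean = 0,
                           log_beta_sd = 1, log_tau2_mean = 0,
                           log_tau2_sd = 1) {
  list(mu_sd = mu_sd, log_alpha_mean = log_alpha_mean,
       log_alpha_sd = log_alpha_sd, log_beta_mean = log_beta_mean,
       log_beta_sd = log_beta_sd, log_tau2_mean = log_tau2_mean,
       log_tau2_sd = log_tau2_sd)
}

# Deterministic per-run / per-sample seed derivation; stays within 32-bit
# signed integer range.
derive_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 1000003) * 1009 +
                (as.numeric(k) %% 65521) * 9973) %% 2147483647)
}

# Stable non-negative hash of a sample id, for order-independent per-sample
# seed derivation in cross-validation.
id_hash <- function(id) {
  v <- utf8ToInt(id)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  as.integer(h)
}

#' The allele universe of a genotype table
#'
#' Every allele observed anywhere in the table (including unknown-origin
#' samples) gets a latent dimension at every site, so private alleles of
#' queries never produce minus-infinity likelihoods.
#'
#' @param table a `genotype_table`.
#' @return list per locus of sorted unique allele sizes.
#' @export
allele_universe <- function(table) {
  lapply(seq_along(table$loci), function(l) {
    a <- c(table$a1[, l], if (table$ploidy[l] == 2L) table$a2[, l])
    sort(unique(a[!is.na(a)]))
  })
}

# Flattened column bookkeeping for a universe: K columns, one per
# locus-allele; returns locus_of (1-based) and column names.
universe_columns <- function(table, universe) {
  A <- lengths(universe)
  if (any(A < 2L))
    stop("locus '", table$loci[which(A < 2L)[1L]],
         "' has fewer than 2 observed alleles")
  list(locus_of = rep(seq_along(universe), A),
       names = unlist(lapply(seq_along(universe), function(l)
         paste0(table$loci[l], ":", universe[[l]]))),
       K = sum(A))
}

# Site x column allele-count matrix from georeferenced samples.  A diploid
# locus contributes only when fully typed (both alleles present).
allele_count_matrix <- function(table, sites, universe) {
  uc <- universe_columns(table, universe)
  S <- nrow(sites)
  cnt <- matrix(0, S, uc$K, dimnames = list(sites$code, uc$names))
  offs <- c(0L, cumsum(lengths(universe)))
  for (i in seq_len(n_samples(table))) {
    s <- table$site_index[i]
    if (s < 1L) next
    for (l in seq_along(table$loci)) {
      if (table$ploidy[l] == 1L) {
        a <- table$a1[i, l]
        if (is.na(a)) next
        k <- offs[l] + match(a, universe[[l]])
        cnt[s, k] <- cnt[s, k] + 1
      } else {
        a1 <- table$a1[i, l]; a2 <- table$a2[i, l]
        if (is.na(a1) || is.na(a2)) next
        k1 <- offs[l] + match(a1, universe[[l]])
        k2 <- offs[l] + match(a2, universe[[l]])
        cnt[s, k1] <- cnt[s, k1] + 1
        cnt[s, k2] <- cnt[s, k2] + 1
      }
    }
  }
  cnt
}

# Query count vector over universe columns plus the heterozygote log(2)
# constant; loci with unseen alleles raise an error.
query_count_vector <- function(table, i, universe) {
  if (is.character(i)) i <- match(i, table$ids)
  uc <- universe_columns(table, universe)
  offs <- c(0L, cumsum(lengths(universe)))
  q <- numeric(uc$K)
  het_const <- 0
  typed <- 0L
  for (l in seq_along(table$loci)) {
    if (table$ploidy[l] == 1L) {
      a <- table$a1[i, l]
      if (is.na(a)) next
      k <- offs[l] + match(a, universe[[l]])
      if (is.na(k)) stop("allele ", a, " at locus ", table$loci[l],
                         " is outside the fitted allele universe")
      q[k] <- q[k] + 1
      typed <- typed + 1L
    } else {
      a1 <- table$a1[i, l]; a2 <- table$a2[i, l]
      if (is.na(a1) || is.na(a2)) next
      k1 <- offs[l] + match(a1, universe[[l]])
      k2 <- offs[l] + match(a2, universe[[l]])
      if (is.na(k1) || is.na(k2))
        stop("allele at locus ", table$loci[l],
             " is outside the fitted allele universe")
      q[k1] <- q[k1] + 1
      q[k2] <- q[k2] + 1
      if (a1 != a2) het_const <- het_const + log(2)
      typed <- typed + 1L
    }
  }
  list(q = q, het_const = het_const, typed = typed)
}

#' Fit posterior allele-frequency surfaces by MCMC
#'
#' Metropolis-within-Gibbs sampler: site-block random-walk proposals per
#' locus-allele latent field, random walks for the per-column means `mu` and
#' (optionally) log-scale random walks for `alpha`, `beta_sill` and `tau2`.
#' Each of `cfg$runs` chains uses a seed derived deterministically from
#' `cfg$seed`; draws are bit-reproducible given `(seed, run)`.
#'
#' @param table a `genotype_table`; samples with `site_index >= 1` provide
#'   counts, unknown-origin samples only widen the allele universe.
#' @param sites a `sampling_sites` table covering all site indices used.
#' @param cfg an [mcmc_config()].
#' @param priors a [surface_priors()] list.
#' @param universe optional allele universe (default: from `table`); pass
#'   the universe of the full dataset when fitting leave-one-out subsets.
#' @param fix_params optional [surface_params()]: hold `alpha`, `beta_sill`,
#'   `tau2` fixed instead of sampling them.
#' @return object of class `frequency_surface` holding the retained latent
#'   draws (`S x K x n_draws` array), per-draw `mu` and hyperparameters, the
#'   run index of every draw, and the fit metadata.
#' @export
fit_surfaces_mcmc <- function(table, sites, cfg = mcmc_config(),
                              priors = surface_priors(), universe = NULL,
                              fix_params = NULL) {
  stopifnot(inherits(cfg, "mcmc_config"))
  if (is.null(universe)) universe <- allele_universe(table)
  uc <- universe_columns(table, universe)
  counts <- allele_count_matrix(table, sites, universe)
  D <- site_distance_matrix(sites)
  sample_hyper <- is.null(fix_params)
  init <- if (sample_hyper)
    surface_params(exp(priors$log_alpha_mean), exp(priors$log_beta_mean),
                   exp(priors$log_tau2_mean))
  else fix_params

  runs <- vector("list", cfg$runs)
  for (r in seq_len(cfg$runs)) {
    set.seed(derive_seed(cfg$seed, r))
    runs[[r]] <- fit_run_cpp(counts, uc$locus_of, length(universe), D,
                             cfg$burn_in, cfg$iterations, cfg$thinning,
                             sample_hyper, init$alpha, init$beta_sill,
                             init$tau2, priors)
  }
  latent <- array(unlist(lapply(runs, `[[`, "latent")),
                  dim = c(nrow(counts), uc$K, cfg$iterations * cfg$runs))
  dimnames(latent) <- list(sites$code, uc$names, NULL)
  mu <- do.call(rbind, lapply(runs, `[[`, "mu"))
  hyper <- do.call(rbind, lapply(runs, `[[`, "hyper"))
  colnames(hyper) <- c("alpha", "beta_sill", "tau2")
  acc <- do.call(rbind, lapply(runs, `[[`, "accept"))
  colnames(acc) <- c("latent", "mu", "hyper")
  if (any(acc[, "latent"] < 0.05 | acc[, "latent"] > 0.95))
    warning("latent-field acceptance rate outside [0.05, 0.95] after ",
            "burn-in; inspect surface$accept and consider longer burn-in")
  structure(list(
    sites = sites, loci = table$loci, ploidy = table$ploidy,
    universe = universe, locus_of = uc$locus_of, col_names = uc$names,
    latent = latent, mu = mu, hyper = hyper,
    run = rep(seq_len(cfg$runs), each = cfg$iterations),
    cfg = cfg, priors = priors, fixed = !sample_hyper, accept = acc),
    class = "frequency_surface")
}

#' @export
print.frequency_surface <- function(x, ...) {
  cat(sprintf(paste0("frequency_surface: %d sites, %d loci (%d allele ",
                     "columns), %d draws over %d runs\n"),
              nrow(x$sites), length(x$loci), dim(x$latent)[2L],
              dim(x$latent)[3L], x$cfg$runs))
  cat(sprintf("  posterior median alpha %.1f km, beta_sill %.3f, tau2 %.3f\n",
              stats::median(x$hyper[, 1L]), stats::median(x$hyper[, 2L]),
              stats::median(x$hyper[, 3L])))
  invisible(x)
}

#' Allele frequencies at the anchor sites for one posterior draw
#'
#' @param surface a `frequency_surface`.
#' @param draw draw index.
#' @return `S x K` matrix; within each locus the columns of every row sum
#'   to 1.
#' @export
surface_freqs <- function(surface, draw) {
  X <- surface$latent[, , draw, drop = FALSE][, , 1L]
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  out <- X
  for (l in seq_along(surface$universe)) {
    k <- which(surface$locus_of == l)
    out[, k] <- t(apply(X[, k, drop = FALSE], 1L, latent_to_freq))
  }
  dimnames(out) <- list(surface$sites$code, surface$col_names)
  out
}

#' Conditional (kriged) latent values at an arbitrary coordinate
#'
#' Standard conditional-normal mean of the latent field at a query location
#' given the anchor values of one posterior draw, under that draw's
#' covariance parameters.  Deterministic given the draw.
#'
#' @param surface a `frequency_surface`.
#' @param draw draw index.
#' @param lat,lon query coordinate in decimal degrees.
#' @return named numeric vector of K latent values.
#' @export
krige_latent <- function(surface, draw, lat, lon) {
  stopifnot(is.finite(lat), is.finite(lon))
  sites <- surface$sites
  alpha <- surface$hyper[draw, 1L]; beta <- surface$hyper[draw, 2L]
  tau2 <- surface$hyper[draw, 3L]
  Sig <- beta * exp(-site_distance_matrix(sites) / alpha) +
    diag(tau2, nrow(sites))
  d <- great_circle_km(lat, lon, sites$lat, sites$lon)
  cc <- beta * exp(-d / alpha)
  X <- surface$latent[, , draw, drop = FALSE][, , 1L]
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  mu <- surface$mu[draw, ]
  w <- solve(Sig, cc)
  stats::setNames(mu + as.numeric(crossprod(X - rep(1, nrow(X)) %o% mu, w)),
                  surface$col_names)
}

#' Allele frequencies at an arbitrary coordinate for one draw
#' @inheritParams krige_latent
#' @return list per locus of named frequency vectors.
#' @export
freqs_at <- function(surface, draw, lat, lon) {
  latq <- krige_latent(surface, draw, lat, lon)
  lapply(seq_along(surface$universe), function(l) {
    k <- which(surface$locus_of == l)
    stats::setNames(latent_to_freq(latq[k]), surface$universe[[l]])
  })
}

#' Save a fitted surface (with manifest) to a single archive file
#'
#' @param surface a `frequency_surface`.
#' @param path output `.rds` path.
#' @export
save_surface <- function(surface, path) {
  surface$manifest <- list(
    seed = surface$cfg$seed, cfg = unclass(surface$cfg),
    created = "geoassign", content_hash = surface_hash(surface))
  saveRDS(surface, path)
  invisible(path)
}

surface_hash <- function(surface) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(surface$latent, surface$mu, surface$hyper), f)
  unname(tools::md5sum(f))
}

#' Load a surface saved by [save_surface()]
#' @param path `.rds` path.
#' @export
load_surface <- function(path) readRDS(path)
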