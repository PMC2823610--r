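test_that("great-circle distances behave at the poles of the formula", {
  expect_equal(great_circle_km(4.5, 9.5, 4.5, 9.5), 0)
  expect_equal(great_circle_km(0, 0, 0, 180), pi * 6371.0)
  expect_error(great_circle_km(91, 0, 0, 0), "out of range")
  expect_error(great_circle_km(0, 0, 0, 181), "out of range")
})

test_that("covariance_matrix is exponential decay plus nugget and is PD", {
  sites <- sampling_sites(c("AA", "BB", "CC"), 1:3, c(4, 5, 6), c(9, 10, 11),
                          rep("North", 3))
  p <- surface_params(alpha = 150, beta_sill = 2, tau2 = 0.3)
  C <- covariance_matrix(sites, p)
  expect_equal(diag(C), rep(2.3, 3))
  d12 <- great_circle_km(4, 9, 5, 10)
  expect_equal(C[1, 2], 2 * exp(-d12 / 150))
  # entries decay monotonically with distance
  d13 <- great_circle_km(4, 9, 6, 11)
  expect_lt(C[1, 3], C[1, 2])
  # positive definiteness on random site sets (dense eigensolve oracle)
  set.seed(4)
  rs <- sampling_sites(sprintf("S%02d", 1:10), 1:10, runif(10, 2, 7),
                       runif(10, 9, 14), rep("North", 10))
  ev <- eigen(covariance_matrix(rs, p), symmetric = TRUE, only.values = TRUE)
  expect_true(all(ev$values > 0))
  expect_error(surface_params(alpha = -1), "must be > 0")
})

test_that("latent_to_freq is a shift-invariant softmax", {
  expect_equal(latent_to_freq(rep(0, 4)), rep(0.25, 4))
  expect_equal(latent_to_freq(c(0, log(2))), c(1 / 3, 2 / 3))
  x <- c(-1.2, 0.4, 2.2)
  expect_equal(latent_to_freq(x), latent_to_freq(x + 57.3))
  expect_equal(sum(latent_to_freq(c(1000, 1001, 999))), 1)  # overflow guard
  expect_error(latent_to_freq(0.5), "2 alleles")
})

test_that("genotype_loglik follows Hardy-Weinberg per locus", {
  f2 <- list(c("100" = 0.5, "102" = 0.5))
  expect_equal(genotype_loglik(list(c(100L, 102L)), f2), log(0.5))
  expect_equal(genotype_loglik(list(NULL), f2), 0)
  f3 <- list(c("100" = 0.2, "102" = 0.3, "104" = 0.5))
  expect_equal(genotype_loglik(list(c(100L, 104L)), f3), log(0.2))  # 2*.2*.5
  expect_equal(genotype_loglik(list(c(100L, 100L)), f3), 2 * log(0.2))
  # haploid pseudo-locus contributes p, not p^2
  expect_equal(genotype_loglik(list(104L), f3), log(0.5))
  # permutation invariance in locus order
  al <- list(c(100L, 102L), 104L)
  fr <- list(f2[[1]], f3[[1]])
  expect_equal(genotype_loglik(al, fr), genotype_loglik(rev(al), rev(fr)))
  # monotone in each observed allele's frequency
  lo <- genotype_loglik(list(c(100L, 100L)),
                        list(c("100" = 0.1, "102" = 0.9)))
  hi <- genotype_loglik(list(c(100L, 100L)),
                        list(c("100" = 0.6, "102" = 0.4)))
  expect_gt(hi, lo)
  expect_error(genotype_loglik(list(c(100L, 106L)), f3), "no frequency")
})

test_that("one-site posterior mean frequency matches the count fraction", {
  fx <- one_site_fixture()
  surf <- fit_surfaces_mcmc(fx$table, fx$sites,
                            reduced_mcmc_config(seed = 2))
  p1 <- vapply(seq_len(dim(surf$latent)[3]), function(d)
    surface_freqs(surf, d)[1, 1], 0)
  expect_lt(abs(mean(p1) - 12 / 16), 0.05)
})

test_that("posterior draws are bit-reproducible given seed and run", {
  fx <- one_site_fixture()
  cfg <- mcmc_config(thinning = 1, burn_in = 50, iterations = 50, runs = 2,
                     seed = 33)
  s1 <- fit_surfaces_mcmc(fx$table, fx$sites, cfg)
  s2 <- fit_surfaces_mcmc(fx$table, fx$sites, cfg)
  expect_identical(s1$latent, s2$latent)
  expect_identical(s1$hyper, s2$hyper)
  expect_identical(s1$mu, s2$mu)
})

test_that("frequencies sum to one at every site and draw", {
  ls <- simulate_landscape(landscape_config(n_sites = 4, samples_per_site = 4,
                                            n_loci = 3, alleles_per_locus = 3,
                                            seed = 8))
  surf <- fit_surfaces_mcmc(ls$table, ls$sites,
                            mcmc_config(thinning = 1, burn_in = 50,
                                        iterations = 40, runs = 1, seed = 5))
  for (d in c(1L, 20L, 40L)) {
    fr <- surface_freqs(surf, d)
    for (l in 1:3) {
      k <- which(surf$locus_of == l)
      expect_true(all(abs(rowSums(fr[, k]) - 1) < 1e-9))
      expect_true(all(fr[, k] > 0))
    }
  }
})

test_that("cross-site frequency differences cover zero when sites are equal", {
  # two sites simulated with identical frequencies; scaled down from the
  # 20-replicate design to 10 seeded replicates for runtime
  hits <- 0L
  for (rep in 1:10) {
    set.seed(100 + rep)
    n <- 15L
    a1 <- matrix(sample(c(100L, 102L), 2 * n, TRUE, prob = c(0.6, 0.4)),
                 2 * n, 1)
    a2 <- matrix(sample(c(100L, 102L), 2 * n, TRUE, prob = c(0.6, 0.4)),
                 2 * n, 1)
    tab <- genotype_table(sprintf("S%d", 1:(2 * n)),
                          rep(1:2, each = n), a1, a2, "L1")
    sites <- sampling_sites(c("AA", "BB"), 1:2, c(4, 6), c(9, 13),
                            rep("North", 2))
    surf <- fit_surfaces_mcmc(tab, sites,
                              mcmc_config(thinning = 1, burn_in = 150,
                                          iterations = 300, runs = 1,
                                          seed = 200 + rep))
    diffs <- vapply(seq_len(300), function(d) {
      fr <- surface_freqs(surf, d)
      fr[1, 1] - fr[2, 1]
    }, 0)
    ci <- quantile(diffs, c(0.025, 0.975))
    if (ci[1] <= 0 && 0 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("distant sites decorrelate as alpha decreases", {
  set.seed(9)
  n <- 4L   # light data so the spatial prior dominates
  a1 <- matrix(sample(c(100L, 102L), 2 * n, TRUE), 2 * n, 1)
  a2 <- matrix(sample(c(100L, 102L), 2 * n, TRUE), 2 * n, 1)
  tab <- genotype_table(sprintf("S%d", 1:(2 * n)), rep(1:2, each = n),
                        a1, a2, "L1")
  sites <- sampling_sites(c("AA", "BB"), 1:2, c(2, 7), c(9, 14),
                          rep("North", 2))   # ~ 780 km apart
  cors <- vapply(c(20, 300, 5000), function(alpha) {
    surf <- fit_surfaces_mcmc(tab, sites,
                              mcmc_config(thinning = 5, burn_in = 200,
                                          iterations = 400, runs = 1,
                                          seed = 77),
                              fix_params = surface_params(alpha = alpha,
                                                          beta_sill = 1,
                                                          tau2 = 0.01))
    cor(surf$latent[1, 1, ], surf$latent[2, 1, ])
  }, 0)
  expect_lt(cors[1], cors[2])
  expect_lt(cors[2], cors[3])
})

test_that("kriging interpolates anchors and reverts to the mean far away", {
  sites <- sampling_sites(c("AA", "BB", "CC"), 1:3, c(4, 5, 6), c(9, 10, 11),
                          rep("North", 3))
  X <- matrix(c(1, 2, 3, -1, 0, 1), 3, 2)
  surf <- fake_surface(X, mu = c(0.5, 0.5), alpha = 200, beta = 1, tau2 = 0,
                       sites = sites)
  # query on an anchor with zero nugget returns the anchor values
  expect_equal(unname(krige_latent(surf, 1, 5, 10)), X[2, ], tolerance = 1e-8)
  # far query (d >> alpha) returns mu
  expect_equal(unname(krige_latent(surf, 1, -60, 120)), c(0.5, 0.5),
               tolerance = 1e-6)
  # three anchors: matches a direct solve of the conditional system
  surf2 <- fake_surface(X, mu = c(0.2, -0.3), alpha = 150, beta = 1.4,
                        tau2 = 0.2, sites = sites)
  q <- c(4.7, 10.2)
  d <- great_circle_km(q[1], q[2], sites$lat, sites$lon)
  Sig <- 1.4 * exp(-as.matrix(dist(cbind(sites$lat, sites$lon))) * 0) # placeholder
  D <- outer(seq_len(3), seq_len(3), Vectorize(function(i, j)
    great_circle_km(sites$lat[i], sites$lon[i], sites$lat[j], sites$lon[j])))
  Sig <- 1.4 * exp(-D / 150) + diag(0.2, 3)
  cc <- 1.4 * exp(-d / 150)
  expected <- c(0.2, -0.3) + t(X - rep(1, 3) %o% c(0.2, -0.3)) %*%
    solve(Sig, cc)
  expect_equal(unname(krige_latent(surf2, 1, q[1], q[2])),
               as.numeric(expected), tolerance = 1e-10)
})

test_that("posterior alpha recovers the simulation truth within a factor 3", {
  ok <- 0L
  for (rep in 1:10) {
    ls <- simulate_landscape(landscape_config(
      n_sites = 8, samples_per_site = 8, n_loci = 5, alleles_per_locus = 4,
      alpha_true = 150, barrier_shift = 0, seed = 300 + rep))
    surf <- fit_surfaces_mcmc(ls$table, ls$sites,
                              reduced_mcmc_config(seed = 400 + rep))
    med <- median(surf$hyper[, "alpha"])
    if (med > 50 && med < 450) ok <- ok + 1L
  }
  expect_gte(ok, 8L)
})

test_that("surfaces save and load with a content-hash manifest", {
  fx <- one_site_fixture()
  surf <- fit_surfaces_mcmc(fx$table, fx$sites,
                            mcmc_config(thinning = 1, burn_in = 20,
                                        iterations = 20, runs = 1, seed = 3))
  f <- withr::local_tempfile(fileext = ".rds")
  save_surface(surf, f)
  back <- load_surface(f)
  expect_identical(back$latent, surf$latent)
  expect_equal(back$manifest$seed, 3)
  expect_match(back$manifest$content_hash, "^[0-9a-f]{32}$")
})
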