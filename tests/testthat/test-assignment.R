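test_that("boundary polygons validate their vertex lists", {
  expect_error(boundary_polygon(c(1, 1, 1), c(2, 2, 2)), "distinct")
  # bow-tie self-intersection
  expect_error(boundary_polygon(c(0, 1, 0, 1), c(0, 1, 1, 0)),
               "self-intersecting")
  closed <- boundary_polygon(c(0, 0, 1, 0), c(0, 1, 1, 0))
  open <- boundary_polygon(c(0, 0, 1), c(0, 1, 1))
  expect_equal(nrow(closed), 3L)
  expect_equal(closed$lat, open$lat)
  # both bundled polygons are valid
  expect_s3_class(study_area_polygon(), "boundary_polygon")
  expect_s3_class(troglodytes_range_polygon(), "boundary_polygon")
})

test_that("point_in_polygon handles interior, exterior and boundary", {
  poly <- study_area_polygon()
  expect_true(point_in_polygon(5.00, 9.50, poly))
  expect_false(point_in_polygon(20.0, 0.0, poly))
  # a polygon vertex itself counts as inside
  expect_true(point_in_polygon(poly$lat[3], poly$lon[3], poly))
  sq <- boundary_polygon(c(0, 0, 2, 2), c(0, 2, 2, 0))
  expect_true(point_in_polygon(0, 1, sq))   # edge midpoint
  expect_true(all(point_in_polygon(c(1, 0.5), c(1, 1.5), sq)))
  expect_false(point_in_polygon(2.0001, 1, sq))
})

test_that("SAM assigns held-out samples perfectly with disjoint alleles", {
  fx <- disjoint_fixture()
  cfg <- mcmc_config(thinning = 1, burn_in = 100, iterations = 200, runs = 2,
                     seed = 6)
  universe <- allele_universe(fx$table)
  for (i in c(1L, 5L, 9L, 16L)) {
    rest <- subset_samples(fx$table, -i)
    surf <- fit_surfaces_mcmc(rest, fx$sites, cfg, universe = universe)
    a <- sam_assign(fx$table, i, surf)
    expect_equal(a$consensus, fx$sites$code[fx$table$site_index[i]])
    expect_equal(a$agreement, 2L)
  }
})

test_that("SAM with a single reference site is the trivial argmax", {
  fx <- one_site_fixture()
  surf <- fit_surfaces_mcmc(fx$table, fx$sites,
                            mcmc_config(thinning = 1, burn_in = 30,
                                        iterations = 30, runs = 2, seed = 4))
  a <- sam_assign(fx$table, 1, surf)
  expect_equal(a$consensus, "ONLY")
  expect_equal(unname(a$llr["ONLY"]), 0)
  expect_equal(a$agreement, 2L)
})

test_that("SAM consensus is invariant to run order", {
  fx <- disjoint_fixture()
  cfg <- mcmc_config(thinning = 1, burn_in = 60, iterations = 100, runs = 3,
                     seed = 15)
  surf <- fit_surfaces_mcmc(subset_samples(fx$table, -2L), fx$sites, cfg,
                            universe = allele_universe(fx$table))
  a1 <- sam_assign(fx$table, 2L, surf)
  # permute the runs of the surface
  perm <- c(3L, 1L, 2L)
  idx <- order(match(surf$run, perm))
  surf2 <- surf
  surf2$latent <- surf$latent[, , idx, drop = FALSE]
  surf2$mu <- surf$mu[idx, , drop = FALSE]
  surf2$hyper <- surf$hyper[idx, , drop = FALSE]
  surf2$run <- rep(1:3, each = sum(surf$run == 1L))
  a2 <- sam_assign(fx$table, 2L, surf2)
  expect_equal(a2$consensus, a1$consensus)
  expect_equal(sort(unname(a2$mean_ll)), sort(unname(a1$mean_ll)))
  expect_error(sam_assign(
    genotype_table("empty", -1L, matrix(NA_integer_, 1, 2),
                   matrix(NA_integer_, 1, 2), c("L1", "L2")),
    1L, surf), "no typed loci")
})

cam_cfg <- function(seed) mcmc_config(thinning = 1, burn_in = 150,
                                      iterations = 300, runs = 2, seed = seed)

test_that("CAM chains stay inside the boundary and are deterministic", {
  fx <- disjoint_fixture()
  boundary <- boundary_polygon(c(1, 1, 8, 8), c(8, 14, 14, 8))
  surf <- fit_surfaces_mcmc(subset_samples(fx$table, -1L), fx$sites,
                            cam_cfg(10), universe = allele_universe(fx$table))
  a <- cam_assign(fx$table, 1L, surf, boundary, cfg = cam_cfg(10))
  expect_equal(nrow(a$chain), 600L)
  expect_true(all(point_in_polygon(a$chain[, 1], a$chain[, 2], boundary)))
  b <- cam_assign(fx$table, 1L, surf, boundary, cfg = cam_cfg(10))
  expect_identical(a$chain, b$chain)
  expect_identical(a$median, b$median)
  expect_identical(a$confidence, b$confidence)
})

test_that("CAM median converges into a shrunken boundary disc", {
  fx <- disjoint_fixture()
  # boundary reduced to a small square around site AA (6, 10)
  disc <- boundary_polygon(c(5.8, 5.8, 6.2, 6.2), c(9.8, 10.2, 10.2, 9.8))
  surf <- fit_surfaces_mcmc(subset_samples(fx$table, -1L), fx$sites,
                            cam_cfg(12), universe = allele_universe(fx$table))
  a <- cam_assign(fx$table, 1L, surf, disc, cfg = cam_cfg(12),
                  step_init = 0.05)
  expect_true(point_in_polygon(a$median[1], a$median[2], disc))
})

test_that("a sample drawn at a site is placed near that site by CAM", {
  # synthetic landscape, held-out samples: median within 2 * alpha of truth
  # in >= 80% of replicates (scaled to 5 landscape seeds for runtime)
  ok <- 0L
  for (rep in 1:5) {
    ls <- simulate_landscape(landscape_config(
      n_sites = 8, samples_per_site = 8, n_loci = 8, alleles_per_locus = 4,
      alpha_true = 150, seed = 500 + rep))
    cfg <- reduced_mcmc_config(seed = 600 + rep)
    unk <- sample_unknowns(ls, 1L, seed = 700 + rep)
    qid <- unk$key$id[1]
    all_tab <- genotype_table(
      c(ls$table$ids, unk$table$ids),
      c(ls$table$site_index, unk$table$site_index),
      rbind(ls$table$a1, unk$table$a1), rbind(ls$table$a2, unk$table$a2),
      ls$table$loci, ls$table$ploidy)
    surf <- fit_surfaces_mcmc(all_tab, ls$sites, cfg)
    a <- cam_assign(all_tab, qid, surf, ls$boundary, cfg = cfg)
    err <- great_circle_km(a$median[1], a$median[2],
                           unk$key$lat[1], unk$key$lon[1])
    if (err < 2 * 150) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("median_point is the component-wise median", {
  expect_equal(median_point(cbind(c(1, 2, 3), c(1, 2, 3))),
               c(lat = 2, lon = 2))
  expect_equal(median_point(cbind(c(0, 0), c(0, 10))), c(lat = 0, lon = 5))
  set.seed(12)
  ch <- cbind(runif(10001), runif(10001))
  expect_equal(unname(median_point(ch)),
               c(sort(ch[, 1])[5001], sort(ch[, 2])[5001]))
  expect_error(median_point(ch[0, ]), "empty")
})

test_that("confidence draws resample the chain with replacement", {
  one <- matrix(c(4.5, 9.5), 1, 2)
  d <- confidence_draws(one, n = 100, seed = 2)
  expect_equal(nrow(unique(d)), 1L)
  ch <- cbind(c(1, 1, 2), c(5, 5, 6))   # state (1,5) has weight 2/3
  d2 <- confidence_draws(ch, n = 10000, seed = 3)
  expect_true(all(d2[, 1] %in% ch[, 1]))
  expect_lt(abs(mean(d2[, 1] == 1) - 2 / 3), 0.05)
})

test_that("zone_of picks the first containing polygon", {
  zones <- default_zone_polygons()
  expect_equal(zone_of(5.7, 10.9, zones), "North")
  expect_equal(zone_of(5.4, 11.7, zones), "Transition")
  expect_equal(zone_of(3.5, 12.5, zones), "South")
  expect_error(zone_of(40, 40, zones), "no zone")
  expect_true(is.na(zone_of(40, 40, zones, strict = FALSE)))
})
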