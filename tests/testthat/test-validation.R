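test_that("summarize_confusion scores locations and regions per row", {
  sites <- example_sites()
  # identity matrix: everything perfect
  m <- diag(5L, 10L)
  dimnames(m) <- list(sites$code, sites$code)
  cs <- summarize_confusion(m, sites)
  expect_true(all(cs$row_location_pct == 100L))
  expect_true(all(cs$row_region_pct == 100L))
  expect_equal(cs$overall_location_pct, 100L)
  # row sums and the location <= region inequality on random matrices
  set.seed(44)
  for (rep in 1:5) {
    r <- matrix(rpois(100, 1.5), 10, 10, dimnames = list(sites$code,
                                                         sites$code))
    cs <- summarize_confusion(r, sites)
    expect_equal(unname(cs$row_total), rowSums(r), ignore_attr = TRUE)
    ok <- cs$row_total > 0
    expect_true(all(cs$row_location_pct[ok] <= cs$row_region_pct[ok]))
  }
})

test_that("summarize_confusion accepts assignment data frames", {
  sites <- example_sites()
  df <- data.frame(true_site = c("MTCM", "MTCM", "DJBR"),
                   assigned_site = c("MTCM", "MSSE", "CMNP"))
  cs <- summarize_confusion(df, sites)
  expect_equal(unname(cs$counts["MTCM", "MSSE"]), 1L)
  expect_equal(unname(cs$row_location_pct["MTCM"]), 50L)
  expect_equal(unname(cs$row_region_pct["DJBR"]), 100L)  # CMNP is also South
})

test_that("distance quantiles invert the empirical CDF without interpolation", {
  est <- data.frame(id = paste0("s", 1:10), lat = 0,
                    lon = (1:10) * 50 / 111.19495)
  tru <- data.frame(id = paste0("s", 1:10), lat = 0, lon = 0)
  q <- distance_quantiles(est, tru, probs = c(0.3, 0.5, 0.8))
  expect_equal(unname(round(q)), c(150, 250, 400))
  # all-zero errors
  q0 <- distance_quantiles(tru, tru)
  expect_equal(unname(q0), c(0, 0, 0))
  # monotone non-decreasing in q, and equal to a sort-based oracle
  set.seed(3)
  e2 <- data.frame(id = paste0("x", 1:37), lat = runif(37, -5, 5),
                   lon = runif(37, -5, 5))
  t2 <- data.frame(id = paste0("x", 1:37), lat = runif(37, -5, 5),
                   lon = runif(37, -5, 5))
  probs <- seq(0.05, 0.95, by = 0.1)
  q2 <- distance_quantiles(e2, t2, probs)
  expect_true(all(diff(q2) >= 0))
  errs <- sort(great_circle_km(e2$lat, e2$lon, t2$lat, t2$lon))
  expect_equal(unname(q2), errs[ceiling(probs * 37)])
  expect_error(distance_quantiles(e2, data.frame(id = "zz", lat = 0, lon = 0)),
               "no shared ids")
})

test_that("zone containment walks the great-circle segment", {
  zones <- list(
    main = boundary_polygon(c(0, 0, 10, 10), c(0, 10, 10, 0)),
    other = boundary_polygon(c(0, 0, 10, 10), c(10, 20, 20, 10)))
  expect_true(zone_containment(c(5, 5), c(5, 5), zones))
  expect_false(zone_containment(c(5, 15), c(5, 5), zones))  # endpoint fails
  # concave notch: both endpoints inside, the segment clips the notch
  notched <- list(z = boundary_polygon(
    lat = c(0, 0, 3, 3, 0.3, 0.3, 3, 3),
    lon = c(0, 10, 10, 5.5, 5.5, 4.5, 4.5, 0)))
  expect_true(point_in_polygon(0.5, 1, notched$z))
  expect_true(point_in_polygon(0.5, 9, notched$z))
  got <- zone_containment(c(0.5, 1), c(0.5, 9), notched)
  pts <- great_circle_points(0.5, 1, 0.5, 9, 10001)
  oracle <- all(oracle_pip(pts[, 1], pts[, 2], notched$z))
  expect_identical(got, oracle)
  expect_false(got)
  expect_error(zone_containment(c(5, 5), c(50, 50), zones), "no zone")
})

test_that("mtDNA concordance tallies match a brute-force count", {
  regions <- setNames(rep("North", 4), paste0("s", 1:4))
  hg <- setNames(rep("1b", 4), paste0("s", 1:4))
  r <- mtdna_concordance(regions, hg)
  expect_equal(r$pct_excl_transition, 100L)
  r2 <- mtdna_concordance(setNames(c("North", "South"), c("a", "b")),
                          setNames(c("1b", "1b"), c("a", "b")))
  expect_equal(r2$pct_excl_transition, 50L)
  # randomized labels vs brute force
  set.seed(10)
  ids <- paste0("q", 1:40)
  regions <- setNames(sample(c("North", "South", "Transition"), 40, TRUE), ids)
  hg <- setNames(sample(c(names(HAPLOGROUP_CODES), "unknown"), 40, TRUE), ids)
  r3 <- mtdna_concordance(regions, hg)
  known <- hg != "unknown"
  expd <- ifelse(substr(hg, 1, 1) == "1", "North", "South")
  keep <- known & regions != "Transition"
  expect_equal(r3$concordant_excl_transition,
               sum(regions[keep] == expd[keep]))
  expect_equal(r3$n_incl_transition, sum(known))
  expect_error(mtdna_concordance(regions, setNames(rep("unknown", 40), ids)),
               "unknown haplogroup")
})

test_that("the Welch test matches its closed form and is symmetric", {
  x <- c(0.9, 0.8, 0.85); y <- c(0.1, 0.2, 0.15)
  got <- negative_control_test(x, y)
  ref <- oracle_welch(x, y)
  expect_equal(got$t, ref$t)
  expect_equal(got$df, ref$df)
  expect_equal(got$p, ref$p)
  # and against the stats implementation
  tt <- t.test(x, y)
  expect_equal(got$t, unname(tt$statistic))
  expect_equal(got$p, tt$p.value)
  # identical groups
  expect_equal(negative_control_test(x, x)$t, 0)
  # swapping flips t, p unchanged
  sw <- negative_control_test(y, x)
  expect_equal(sw$t, -got$t)
  expect_equal(sw$p, got$p)
  # degenerate zero-variance groups
  expect_equal(negative_control_test(c(1, 1), c(1, 1))$p, 1)
  expect_equal(negative_control_test(c(1, 1), c(0, 0))$p, 0)
  expect_error(negative_control_test(1, c(1, 2)), ">= 2")
})

test_that("loocv runs one refit-assign cycle per sample, order-independently", {
  fx <- disjoint_fixture(n_per_site = 3L)
  cfg <- mcmc_config(thinning = 1, burn_in = 60, iterations = 100, runs = 2,
                     seed = 9)
  cv <- loocv(fx$table, fx$sites, "SAM", cfg)
  expect_equal(nrow(cv), 6L)
  # disjoint-allele two-site landscape: 100% accuracy
  expect_true(all(cv$assigned_site == cv$true_site))
  # dataset ordering must not matter (per-sample seeds derive from ids)
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  cv2 <- loocv(subset_samples(fx$table, perm), fx$sites, "SAM", cfg)
  cv2 <- cv2[match(cv$id, cv2$id), ]
  expect_equal(cv2$assigned_site, cv$assigned_site)
})

test_that("CAM loocv returns coordinate estimates for every sample", {
  fx <- disjoint_fixture(n_per_site = 2L)
  cfg <- mcmc_config(thinning = 1, burn_in = 60, iterations = 80, runs = 2,
                     seed = 13)
  boundary <- boundary_polygon(c(1, 1, 8, 8), c(8, 14, 14, 8))
  cv <- loocv(fx$table, fx$sites, "CAM", cfg, boundary = boundary)
  expect_equal(nrow(cv), 4L)
  expect_true(all(point_in_polygon(cv$est_lat, cv$est_lon, boundary)))
  expect_error(loocv(fx$table, fx$sites, "CAM", cfg), "boundary")
})

test_that("SAM carries no information without spatial structure", {
  # beta_sill ~ 0 and no barrier: all sites share one frequency surface.
  # Accuracy must not exceed chance (1/n_sites); it sits slightly *below*
  # chance because the held-out genotype is removed from its own site's
  # allele counts (the usual leave-one-out artifact), so the two-sided
  # comparison is deliberately one-sided here.  Assigned sites must also be
  # near-uniform.
  ls <- simulate_landscape(landscape_config(
    n_sites = 4, samples_per_site = 50, n_loci = 3, alleles_per_locus = 3,
    beta_sill_true = 1e-6, tau2_true = 1e-6, barrier_shift = 0, seed = 42))
  cfg <- mcmc_config(thinning = 1, burn_in = 80, iterations = 150, runs = 1,
                     seed = 42)
  cv <- suppressWarnings(loocv(ls$table, ls$sites, "SAM", cfg))
  correct <- sum(cv$assigned_site == cv$true_site)
  p_above <- binom.test(correct, nrow(cv), p = 1 / 4,
                        alternative = "greater")$p.value
  expect_gt(p_above, 0.05)
  counts <- table(factor(cv$assigned_site, levels = ls$sites$code))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("validation reports assemble and serialise", {
  sites <- example_sites()
  m <- diag(3L, 10L)
  dimnames(m) <- list(sites$code, sites$code)
  rep <- validation_report(
    confusion = summarize_confusion(m, sites),
    quantiles = c(q30 = 93, q50 = 157, q80 = 254),
    zone_containment_pct = 85L,
    concordance = mtdna_concordance(setNames("North", "a"),
                                    setNames("1b", "a")),
    negative_control = negative_control_test(c(0.9, 0.8), c(0.1, 0.2)))
  d <- withr::local_tempdir()
  write_validation_report(rep, d)
  expect_true(all(file.exists(file.path(d, c("confusion.tsv", "quantiles.tsv",
                                             "summary.txt")))))
  expect_equal(nrow(read.delim(file.path(d, "confusion.tsv"))), 10L)
})
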