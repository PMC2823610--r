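# Shared in-code fixtures.

# A one-site table with allele counts (12, 4) at a single diploid locus.
one_site_fixture <- function() {
  a1 <- matrix(c(rep(100L, 4), rep(100L, 4)), 8, 1)
  a2 <- matrix(c(rep(100L, 4), rep(102L, 4)), 8, 1)
  list(table = genotype_table(sprintf("S%d", 1:8), rep(1L, 8), a1, a2, "L1"),
       sites = sampling_sites("ONLY", 1L, 4.5, 9.5, "North"))
}

# Two sites with disjoint allele sets: assignments must be unambiguous.
disjoint_fixture <- function(n_per_site = 8L, seed = 21L) {
  set.seed(seed)
  n <- 2L * n_per_site
  site <- rep(1:2, each = n_per_site)
  pool <- list(c(100L, 102L), c(110L, 112L))
  a1 <- matrix(0L, n, 2); a2 <- matrix(0L, n, 2)
  for (l in 1:2) {
    a1[, l] <- vapply(site, function(s) sample(pool[[s]], 1L), 0L)
    a2[, l] <- vapply(site, function(s) sample(pool[[s]], 1L), 0L)
  }
  list(table = genotype_table(sprintf("S%02d", 1:n), site, a1, a2,
                              c("L1", "L2")),
       sites = sampling_sites(c("AA", "BB"), 1:2, c(6, 3), c(10, 12),
                              c("North", "South")))
}

# Hand-constructed surface with a single draw, for deterministic kriging
# checks and flat-likelihood CAM chains.
fake_surface <- function(latent, mu, alpha, beta, tau2, sites) {
  K <- ncol(latent)
  structure(list(
    sites = sites, loci = "L1", ploidy = 2L,
    universe = list(100L + 2L * seq_len(K) - 2L),
    locus_of = rep(1L, K), col_names = paste0("L1:", seq_len(K)),
    latent = array(latent, dim = c(nrow(latent), K, 1L)),
    mu = matrix(mu, 1L, K),
    hyper = matrix(c(alpha, beta, tau2), 1L, 3L,
                   dimnames = list(NULL, c("alpha", "beta_sill", "tau2"))),
    run = 1L, cfg = mcmc_config(seed = 1), fixed = TRUE),
    class = "frequency_surface")
}
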