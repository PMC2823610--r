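# Independent oracles used to check package primitives.  These deliberately
# use different algorithms from the implementation they check.

# Winding-number point-in-polygon (implementation uses even-odd ray
# casting).  Boundary points count as inside, matching the package rule.
oracle_pip <- function(lat, lon, poly) {
  x <- poly$lon; y <- poly$lat
  n <- length(x)
  vapply(seq_along(lat), function(ii) {
    px <- lon[ii]; py <- lat[ii]
    wn <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      cross <- (x[j] - x[i]) * (py - y[i]) - (y[j] - y[i]) * (px - x[i])
      if (cross == 0 &&
          px >= min(x[i], x[j]) && px <= max(x[i], x[j]) &&
          py >= min(y[i], y[j]) && py <= max(y[i], y[j]))
        return(TRUE)
      if (y[i] <= py) {
        if (y[j] > py && cross > 0) wn <- wn + 1
      } else {
        if (y[j] <= py && cross < 0) wn <- wn - 1
      }
    }
    wn != 0
  }, TRUE)
}

# Textbook haversine with the atan2 formulation (implementation uses asin).
oracle_haversine <- function(lat1, lon1, lat2, lon2, R = 6371.0) {
  r <- pi / 180
  dphi <- (lat2 - lat1) * r
  dlmb <- (lon2 - lon1) * r
  a <- sin(dphi / 2)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlmb / 2)^2
  2 * R * atan2(sqrt(a), sqrt(1 - a))
}

# Hand-written Welch two-sample t (implementation is also closed form, but
# this copy is derived independently and cross-checked against stats::t.test
# in the tests).
oracle_welch <- function(x, y) {
  sx <- var(x) / length(x); sy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df <- (sx + sy)^2 / (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Kruskal MST cost on a distance matrix.
oracle_mst_cost <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(0)
  e <- which(upper.tri(D), arr.ind = TRUE)
  e <- e[order(D[e]), , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  cost <- 0; cnt <- 0L
  for (r in seq_len(nrow(e))) {
    a <- find(e[r, 1L]); b <- find(e[r, 2L])
    if (a != b) {
      parent[a] <- b
      cost <- cost + D[e[r, 1L], e[r, 2L]]
      cnt <- cnt + 1L
      if (cnt == n - 1L) break
    }
  }
  cost
}

# Exhaustive Steiner-tree cost for binary terminal sequences: minimum MST
# cost over terminals plus any subset of up to (n - 2) added 0/1 vectors.
oracle_steiner_cost <- function(term) {
  m <- ncol(term)
  all_pts <- as.matrix(expand.grid(rep(list(0:1), m)))
  key <- function(M) apply(M, 1L, paste, collapse = "")
  cand <- all_pts[!(key(all_pts) %in% key(term)), , drop = FALSE]
  hd <- function(M) as.matrix(dist(M, method = "manhattan"))
  best <- Inf
  max_add <- min(nrow(term) - 2L, nrow(cand))
  for (sz in 0:max_add) {
    combs <- if (sz == 0L) list(integer(0)) else
      asplit(utils::combn(nrow(cand), sz), 2L)
    for (cc in combs)
      best <- min(best, oracle_mst_cost(hd(rbind(term,
                                                 cand[cc, , drop = FALSE]))))
  }
  best
}

# 0/1 matrix row -> A/T sequence string.
binseq <- function(v) paste(c("A", "T")[v + 1L], collapse = "")

# Weir-Cockerham multiallelic theta (FST) between two groups of diploid
# genotypes given as a genotype_table and a logical group indicator.
oracle_wc_fst <- function(table, in_group1) {
  num <- 0; den <- 0
  r <- 2
  for (l in which(table$ploidy == 2L)) {
    a1 <- table$a1[, l]; a2 <- table$a2[, l]
    ok <- !is.na(a1) & !is.na(a2)
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    for (al in alleles) {
      n_i <- p_i <- h_i <- numeric(2)
      for (g in 1:2) {
        sel <- ok & (if (g == 1) in_group1 else !in_group1)
        n_i[g] <- sum(sel)
        if (n_i[g] == 0) next
        p_i[g] <- (sum(a1[sel] == al) + sum(a2[sel] == al)) / (2 * n_i[g])
        h_i[g] <- mean((a1[sel] == al) != (a2[sel] == al))
      }
      if (any(n_i == 0)) next
      nbar <- mean(n_i)
      nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                hbar / 4) / (nbar - 1))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# A small deterministic genotype table for IO tests.
make_random_table <- function(n = 20L, L = 4L, seed = 7L, haploid_last = TRUE) {
  set.seed(seed)
  loci <- paste0("L", seq_len(L))
  ploidy <- rep(2L, L)
  if (haploid_last) ploidy[L] <- 1L
  sizes <- lapply(seq_len(L), function(l) 100L + 10L * l + 2L * (0:3))
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    a1[, l] <- sample(sizes[[l]], n, replace = TRUE)
    a2[, l] <- if (ploidy[l] == 2L) sample(sizes[[l]], n, replace = TRUE)
      else NA_integer_
    miss <- runif(n) < 0.15
    a1[miss, l] <- NA_integer_
    if (ploidy[l] == 2L) a2[miss, l] <- NA_integer_
  }
  genotype_table(sprintf("S%02d", seq_len(n)),
                 sample(c(-1L, 1L, 2L, 3L), n, replace = TRUE),
                 a1, a2, loci, ploidy)
}
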