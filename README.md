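# geoassign

Geographic-origin inference for individuals of unknown provenance from
multilocus microsatellite (STRP) genotypes and mitochondrial haplogroups —
the wildlife-forensics problem of placing, say, a rescued chimpanzee of
unknown capture location onto a map, given a panel of georeferenced
reference genotypes from known sampling sites.

## Who this is for

Conservation geneticists and wildlife-forensics labs with:

* a panel of georeferenced diploid STRP genotype profiles from reference
  sites (SCAT-dialect genotype files: two lines per individual, one allele
  per locus per line, `-999` missing, site index `-1` = unknown origin);
* query genotypes of unknown origin;
* optionally, aligned mtDNA HVRI sequences whose haplogroup clusters carry
  additional geographic signal.

## The model

Reference allele counts at `S` sites are smoothed through a latent Gaussian
field per locus-allele with an exponential distance-decay covariance

```
C(d) = beta_sill * exp(-d / alpha) + tau2 * [d == 0]      (d in km)
```

where `alpha` (km) controls how fast allele-frequency correlations decay
with distance, `beta_sill` is the sill and `tau2` a nugget.  Latent values
map to allele frequencies by a softmax, genotypes enter through
Hardy–Weinberg likelihoods (`p^2`, `2pq`; a haploid haplogroup pseudo-locus
contributes `p`), and a Metropolis-within-Gibbs sampler draws posterior
frequency surfaces.  Two assignment modes consume the posterior:

* **SAM** (smoothed assignment method): scores every sampled site by the
  posterior-mean genotype log-likelihood of the query, with a consensus
  across independent runs (ties broken by the highest mean log-likelihood
  ratio).
* **CAM** (continuous assignment method): a Metropolis random walk over
  candidate coordinates constrained to a habitat boundary polygon, with
  frequencies kriged from the posterior surfaces; reports the
  component-wise median of the pooled coordinate chain plus 100
  posterior-weighted confidence draws.

A validation suite mirrors the standard evaluation of such pipelines:
leave-one-out cross-validation with confusion matrices and location/region
accuracies, empirical distance quantiles of assignment error, zone
containment of error segments, mtDNA–assignment concordance, and a Welch
*t* negative-control boundary test.  A fully seeded synthetic-landscape
generator (spatially autocorrelated frequencies, a river-barrier latent
shift with a transition zone, barrier-linked haplogroups, missingness)
makes every stage testable offline.

## Worked example

Simulate the default synthetic landscape (10 sites x 10 samples x 10 STRP
loci, barrier shift 3, haplogroups encoded as an eleventh locus),
cross-validate SAM, then assign a fresh unknown:

```r
library(geoassign)
ls  <- simulate_landscape(landscape_config(seed = 1))
tab <- encode_haplogroup_locus(ls$table, ls$haplogroups)
cfg <- reduced_mcmc_config(seed = 1)   # thinning 1, burn-in 200, 400 iter, 2 runs
cv  <- loocv(tab, ls$sites, "SAM", cfg)
summarize_confusion(cv, ls$sites)
```

```
     ST01 ST02 ST03 ST04 ST05 ST06 ST07 ST08 ST09 ST10 Location% Region%
ST01   10    0    0    0    0    0    0    0    0    0       100     100
ST02    1    9    0    0    0    0    0    0    0    0        90     100
...
ST10    0    0    0    0    3    0    0    0    0    7        70     100
overall: location 80%, region 100% (n = 100 tallied)
```

Rows are true sites, columns assigned sites; the diagonal share is the
location accuracy and `Region%` scores only which side of the river barrier
a sample was placed on — location errors concentrate between nearby
same-region sites, region calls are essentially perfect, matching the
behaviour expected of spatially smoothed assignment.

```r
unk  <- sample_unknowns(ls, 1, seed = 2)
qtab <- encode_haplogroup_locus(unk$table, unk$haplogroups)
all_tab <- genotype_table(c(tab$ids, qtab$ids),
                          c(tab$site_index, qtab$site_index),
                          rbind(tab$a1, qtab$a1), rbind(tab$a2, qtab$a2),
                          tab$loci, tab$ploidy)
surf <- fit_surfaces_mcmc(all_tab, ls$sites, cfg)
sam_assign(all_tab, "U001", surf)
cam_assign(all_tab, "U001", surf, ls$boundary, cfg = cfg)
```

```
sam_assignment U001 -> ST02 (2/2 runs agree, LLR 0.52)
cam_assignment U001 -> (2.93794, 9.95569); 800 retained points
```

The true origin of `U001` is `ST01` at (3.3275, 10.0299): SAM picked the
neighbouring same-region site (a typical location-level miss), while the
CAM median lands about 45 km from the true origin — the continuous estimate
does not depend on the sampling-site grid.

Bundled example data: `example_sam_confusion()` (a published-style 10-site
cross-validation confusion matrix), `example_cam_estimates()` (origin
estimates for 46 rescue-centre chimpanzees), `study_area_polygon()` and
`troglodytes_range_polygon()` (habitat boundary polygons), and
`default_zone_polygons()` (approximate North/Transition/South zones).

## Command line

```sh
Rscript inst/cli/geoassign.R simulate --config cfg.json --seed 4 --out out/
Rscript inst/cli/geoassign.R sam      --config cfg.json --out out/
Rscript inst/cli/geoassign.R reproduce-synthetic --config cfg.json --out out/
```

Every output directory receives a `manifest.json` with the config echo,
seed and content hashes; identical config + seed reproduces byte-identical
outputs.

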