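# Bundled example data: a published-style cross-validation confusion matrix
# over the ten Cameroon/Nigeria reference sites, origin estimates for 46
# rescue-centre chimpanzees of unknown provenance, and approximate default
# zone polygons.

#' The ten reference sampling sites of the example study design
#'
#' Site codes, indices, zone labels and *approximate, synthetic*
#' coordinates: the original site coordinates are not published, so these
#' are representative stand-ins near each named locality, suitable for
#' examples and synthetic benchmarks but not for reproducing published
#' distances.
#'
#' @export
example_sites <- function() {
  sampling_sites(
    code = c("ISFR", "GGNP", "AKZN", "CRNP", "MSSE", "MTCM", "MANB", "DEFR",
             "CMNP", "DJBR"),
    index = 1:10,
    lat = c(7.45, 7.33, 6.25, 5.75, 5.45, 4.20, 4.85, 3.55, 2.55, 3.15),
    lon = c(5.15, 11.58, 10.10, 8.85, 9.75, 9.17, 11.45, 9.85, 10.35, 12.85),
    zone = c("North", "North", "North", "North", "North", "North",
             "Transition", "South", "South", "South"))
}

#' Example SAM cross-validation confusion matrix
#'
#' Counts of leave-one-out SAM assignments (rows = true site, columns =
#' assigned site) for 86 georeferenced chimpanzee genotype profiles across
#' the ten example sites, plus the per-site counts of 46 unknown-origin
#' rescue-centre queries in the `unknown_queries` attribute.
#'
#' @return integer matrix with site-code dimnames.
#' @export
example_sam_confusion <- function() {
  df <- utils::read.delim(system.file("extdata", "sam_confusion_example.tsv",
                                      package = "geoassign"),
                          check.names = FALSE)
  m <- as.matrix(df[, 2:11])
  rownames(m) <- df$true_site
  storage.mode(m) <- "integer"
  attr(m, "unknown_queries") <- stats::setNames(as.integer(df$unknown_queries),
                                                df$true_site)
  m
}

#' Example origin estimates for 46 unknown-provenance chimpanzees
#'
#' Per-sample mtDNA haplogroup, consensus SAM site and region, and CAM
#' median coordinate estimate (decimal degrees) with its zone label.
#'
#' @return data.frame with columns `id`, `haplogroup`, `sam_site`,
#'   `sam_region`, `cam_lat`, `cam_lon`, `cam_region`.
#' @export
example_cam_estimates <- function() {
  utils::read.delim(system.file("extdata", "cam_estimates_example.tsv",
                                package = "geoassign"),
                    stringsAsFactors = FALSE)
}

#' Approximate default zone polygons for the example study area
#'
#' Rough rectangles (an L-shape for the North) around the coordinate
#' clusters of the example CAM estimates; the true biogeographic zone
#' boundaries are not published, so these are *approximate* configuration
#' defaults meant to be replaced by user-supplied polygons.
#'
#' @return named list of [boundary_polygon()]s: `North`, `Transition`,
#'   `South`.
#' @export
default_zone_polygons <- function() {
  list(
    North = boundary_polygon(
      lat = c(2.0, 2.0, 4.6, 4.6, 6.2, 6.2, 4.6, 4.6, 10.0, 10.0),
      lon = c(2.5, 10.0, 10.0, 11.3, 11.3, 12.2, 12.2, 19.0, 19.0, 2.5)),
    Transition = boundary_polygon(
      lat = c(4.6, 6.2, 6.2, 4.6), lon = c(11.3, 11.3, 12.2, 12.2)),
    South = boundary_polygon(
      lat = c(-6.0, 4.6, 4.6, -6.0), lon = c(10.0, 10.0, 19.0, 19.0)))
}
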