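#' Region nest density with provenance
#'
#' Resolves the nest density (mean and 5-95\% interval, nests/m^2) used for
#' a region: a posterior prediction from the rock-size model when the mean
#' rock diameter is known, otherwise a fixed override rule with a zero-width
#' interval. The study used two such overrides: Kongsfjorden at 1 nest/m^2
#' (a conservative average of neighbouring regions) and Sjuoyane at
#' 0.2 nest/m^2 (the lowest density documented for morphologically similar
#' colonies).
#'
#' @param region region label.
#' @param mean_rock_diameter_m mean rock diameter in m, or NA when unknown.
#' @param posterior a \code{\link{fit_density_model}} result (required when
#'   a rock diameter is given).
#' @param overrides data.frame with columns \code{region} and
#'   \code{density}; consulted when no diameter is available. Defaults to
#'   the study's two fixed rules.
#' @return data.frame row: \code{region, density_mean, density_low,
#'   density_high, provenance}.
#' @export
assign_region_density <- function(region, mean_rock_diameter_m = NA,
                                  posterior = NULL,
                                  overrides = default_density_overrides()) {
  if (!is.na(mean_rock_diameter_m)) {
    if (is.null(posterior)) stop("posterior required to predict from a rock diameter")
    p <- predict_density(posterior, mean_rock_diameter_m)
    return(data.frame(region = region, density_mean = p$mean,
                      density_low = p$cri_low, density_high = p$cri_high,
                      provenance = "model", stringsAsFactors = FALSE))
  }
  hit <- overrides[overrides$region == region, , drop = FALSE]
  if (nrow(hit) == 0)
    stop(sprintf("unresolvable region '%s': no rock diameter and no override rule",
                 region))
  d <- hit$density[1]
  data.frame(region = region, density_mean = d, density_low = d,
             density_high = d, provenance = "fixed", stringsAsFactors = FALSE)
}

#' Fixed-density override rules used in the study
#'
#' @return data.frame of region-level fixed nest densities (nests/m^2).
#' @export
default_density_overrides <- function() {
  data.frame(region = c("Kongsfjorden", "Sjuoyane"),
             density = c(1.0, 0.2), stringsAsFactors = FALSE)
}

#' Per-patch nest count estimate
#'
#' Multiplies a slope-corrected patch area by the region's nest density
#' bounds: mean/low/high nests are \code{area * density_mean/low/high}.
#' Counts stay in floating point; rounding happens only when reports are
#' rendered.
#'
#' @param patch_id identifier.
#' @param region region label.
#' @param corrected_area_m2 slope-corrected area (m^2, >= 0).
#' @param density a row as returned by \code{\link{assign_region_density}}.
#' @return data.frame row: \code{patch_id, region, corrected_area_m2,
#'   nests_mean, nests_low, nests_high}.
#' @export
patch_nest_estimate <- function(patch_id, region, corrected_area_m2, density) {
  if (!is.finite(corrected_area_m2) || corrected_area_m2 < 0)
    stop("corrected_area_m2 must be finite and non-negative")
  data.frame(patch_id = patch_id, region = region,
             corrected_area_m2 = corrected_area_m2,
             nests_mean = corrected_area_m2 * density$density_mean,
             nests_low = corrected_area_m2 * density$density_low,
             nests_high = corrected_area_m2 * density$density_high,
             stringsAsFactors = FALSE)
}

#' Breeding pairs of a cliff colony from bird counts
#'
#' For colonies on vertical cliffs where rock-size densities do not apply,
#' pairs are estimated from birds counted near the cliff:
#' \code{pairs = birds / (2 * attendance)}, i.e. the count is scaled up to
#' the total number of adults by the colony-attendance fraction and halved
#' to pairs. At the mid chick-rearing attendance of 0.5 (half the nesting
#' adults present), 500 observed birds give 500 pairs.
#'
#' @param birds_observed birds counted (>= 0).
#' @param attendance_fraction fraction of nesting adults present, in (0, 1].
#' @return estimated pairs, rounded to the nearest integer.
#' @export
cliff_colony_estimate <- function(birds_observed, attendance_fraction = 0.5) {
  if (birds_observed < 0) stop("birds_observed must be non-negative")
  if (attendance_fraction <= 0 || attendance_fraction > 1)
    stop("attendance_fraction must lie in (0, 1]")
  round(birds_observed / (2 * attendance_fraction))
}

#' Aggregate patch estimates into a census report
#'
#' Sums nest counts (mean and both interval bounds independently, matching
#' the study's table arithmetic) by region and in total, and computes the
#' summary statistics reported alongside: mean patch area, mean nests per
#' patch (total divided by number of colonies, truncated), and colony
#' counts.
#'
#' @param patches data.frame of \code{\link{patch_nest_estimate}} rows;
#'   optionally with an \code{n_colonies} column when rows are already
#'   region aggregates (defaults to 1 per row).
#' @return an object of class \code{census_report}: list with
#'   \code{per_region} (data.frame), \code{total_mean/low/high},
#'   \code{n_colonies}, \code{mean_patch_area_m2},
#'   \code{mean_nests_per_patch}.
#' @export
aggregate_census <- function(patches) {
  patches <- as.data.frame(patches)
  if (nrow(patches) == 0) stop("empty patch list")
  if (anyDuplicated(patches$patch_id))
    stop("duplicate patch_id in patch list")
  if (is.null(patches$n_colonies)) patches$n_colonies <- 1L
  agg <- stats::aggregate(
    patches[, c("n_colonies", "nests_mean", "nests_low", "nests_high")],
    by = list(region = patches$region), FUN = sum)
  agg <- agg[order(agg$region), , drop = FALSE]
  rownames(agg) <- NULL
  total_mean <- sum(patches$nests_mean)
  total_low <- sum(patches$nests_low)
  total_high <- sum(patches$nests_high)
  n_col <- sum(patches$n_colonies)
  mean_area <- if (!is.null(patches$corrected_area_m2))
    mean(patches$corrected_area_m2) else NA_real_
  structure(list(per_region = agg,
                 total_mean = total_mean, total_low = total_low,
                 total_high = total_high,
                 n_colonies = n_col,
                 mean_patch_area_m2 = mean_area,
                 mean_nests_per_patch = floor(total_mean / n_col)),
            class = "census_report")
}

#' @export
print.census_report <- function(x, ...) {
  cat("Colony census report\n")
  pr <- x$per_region
  pr$nests_mean <- round(pr$nests_mean)
  pr$nests_low <- round(pr$nests_low)
  pr$nests_high <- round(pr$nests_high)
  print(pr, row.names = FALSE)
  cat(sprintf("Total: %d (5-95%% CI %d-%d) pairs over %d colonies; mean %d nests/patch\n",
              round(x$total_mean), round(x$total_low), round(x$total_high),
              x$n_colonies, x$mean_nests_per_patch))
  invisible(x)
}

#' Share of the world breeding population
#'
#' Expresses a census total (mean with 5-95\% bounds) as a percentage of the
#' world population bracket: the low share divides the census lower bound by
#' the world upper bound, the high share divides the census upper bound by
#' the world lower bound, and the mid share averages the census mean over
#' both world bounds. All reported to one decimal.
#'
#' @param total_mean,total_low,total_high census totals (pairs).
#' @param world_low,world_high world population bracket (pairs), e.g. the
#'   37-40 million global little auk estimate.
#' @return named numeric: \code{low, mid, high} percentages.
#' @export
global_share <- function(total_mean, total_low, total_high,
                         world_low = 37e6, world_high = 40e6) {
  if (world_low <= 0 || world_high <= 0 || world_low > world_high)
    stop("world bounds must be positive with low <= high")
  c(low = round(total_low / world_high * 100, 1),
    mid = round(mean(c(total_mean / world_high, total_mean / world_low)) * 100, 1),
    high = round(total_high / world_low * 100, 1))
}

#' The Spitsbergen little auk colony census table
#'
#' The region-level results of the 2009-2015 W/NW Spitsbergen colony
#' surveys: colony counts, the nest density applied (model prediction,
#' fixed rule, or cliff count), and predicted pairs with 5-95\% bounds.
#' Shipped with the package as its worked reference dataset.
#'
#' @return data.frame with one row per surveyed site.
#' @export
spitsbergen_census <- function() {
  path <- system.file("extdata", "spitsbergen_colony_census.csv",
                      package = "aukcensus", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
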