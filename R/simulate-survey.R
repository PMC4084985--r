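#' Ground truth for the synthetic haul-seine survey
#'
#' Parameter set driving [simulate_survey()]. Presence of adults in a
#' haul follows a Bernoulli(logit-linear) model; positive catches follow
#' a rounded lognormal. Effects are additive on the respective link
#' scales (log-odds for presence, log fish-per-haul for positive catch).
#'
#' Defaults mirror the structure the standardization model is built to
#' detect: presence responds to year, concentrated region, spawning
#' season and temperature bin; positive catch responds to year, region
#' and bottom vegetation.
#'
#' @param years survey years.
#' @param year_logit,year_log per-year additive effects (recycled to
#'   `length(years)`).
#' @param region_logit,region_log effect of the concentrated region.
#' @param season_logit log-odds shift inside the spawning season
#'   (April-September).
#' @param temp_logit_per_bin log-odds shift per 2.5 degree C temperature
#'   bin above the coldest observed bin.
#' @param vegetation_log log-mean shift when bottom vegetation present.
#' @param presence_intercept baseline log-odds of a positive haul.
#' @param positive_meanlog,positive_sdlog lognormal parameters of the
#'   positive catch.
#' @param hotspot_centers matrix (rows = hotspots) of planar coordinates
#'   (m) of concentration centers.
#' @param hotspot_radius_m radius within which a grid is truly
#'   "concentrated".
#' @param grid_cell_m survey grid cell size in meters (one nautical
#'   mile).
#' @return list of class `survey_truth`.
#' @export
survey_truth <- function(years = 1996:2001,
                         year_logit = seq(0.5, -0.5,
                                          length.out = length(years)),
                         year_log = seq(0.4, -0.4,
                                        length.out = length(years)),
                         region_logit = 1.2, region_log = 0.6,
                         season_logit = 0.8,
                         temp_logit_per_bin = 0.15,
                         vegetation_log = 0.4,
                         presence_intercept = -1.4,
                         positive_meanlog = 1.0, positive_sdlog = 0.8,
                         hotspot_centers = rbind(c(4500, 4500),
                                                 c(14500, 13000)),
                         hotspot_radius_m = 2.2 * 1852,
                         grid_cell_m = 1852) {
  stopifnot(positive_sdlog > 0, nrow(hotspot_centers) >= 1)
  structure(list(
    years = years,
    year_logit = rep_len(year_logit, length(years)),
    year_log = rep_len(year_log, length(years)),
    region_logit = region_logit, region_log = region_log,
    season_logit = season_logit,
    temp_logit_per_bin = temp_logit_per_bin,
    vegetation_log = vegetation_log,
    presence_intercept = presence_intercept,
    positive_meanlog = positive_meanlog, positive_sdlog = positive_sdlog,
    hotspot_centers = hotspot_centers,
    hotspot_radius_m = hotspot_radius_m,
    grid_cell_m = grid_cell_m), class = "survey_truth")
}

#' Simulate a stratified-random haul-seine survey
#'
#' Generates one haul record per (year, month, haul) with covariates and
#' a zero-inflated adult count: presence is Bernoulli on the logit scale,
#' and conditional on presence the count is a rounded lognormal forced to
#' be at least 1. Temperature follows an annual sinusoid, salinity a
#' west-east gradient, and vegetation is a fixed per-grid property.
#'
#' @param truth a [survey_truth()] object.
#' @param n_grids number of square survey grids (laid out on a
#'   near-square lattice); must be >= 4.
#' @param years years to survey (default: `truth$years`; must be a
#'   subset of it, length >= 2).
#' @param hauls_per_month hauls per calendar month per year.
#' @param seed integer RNG seed.
#' @return list with `hauls` (data.frame: `haul_id`, `date`, `grid_id`,
#'   `x`, `y`, `adult_count`, `temperature_c`, `salinity_ppt`,
#'   `bottom_vegetation`, `year`, `month`, `season`,
#'   `region_true`) and `truth` (the input truth augmented with
#'   `grid_truth`, the per-grid concentrated labels).
#' @export
simulate_survey <- function(truth, n_grids = 100, years = truth$years,
                            hauls_per_month = 10, seed = 1) {
  stopifnot(inherits(truth, "survey_truth"), n_grids >= 4,
            length(years) >= 2, all(years %in% truth$years))
  set.seed(child_seed(seed, 0))
  side <- ceiling(sqrt(n_grids))
  cell <- truth$grid_cell_m
  gx <- ((seq_len(n_grids) - 1) %% side + 0.5) * cell
  gy <- ((seq_len(n_grids) - 1) %/% side + 0.5) * cell
  d2hot <- sapply(seq_len(nrow(truth$hotspot_centers)), function(h)
    sqrt((gx - truth$hotspot_centers[h, 1])^2 +
         (gy - truth$hotspot_centers[h, 2])^2))
  concentrated <- apply(d2hot <= truth$hotspot_radius_m, 1, any)
  grid_truth <- data.frame(grid_id = sprintf("G%03d", seq_len(n_grids)),
                           x = gx, y = gy, concentrated = concentrated,
                           vegetation = runif(n_grids) < 0.5)

  des <- expand.grid(year = years, month = 1:12,
                     haul = seq_len(hauls_per_month))
  n <- nrow(des)
  gi <- sample.int(n_grids, n, replace = TRUE)
  day <- sample.int(28, n, replace = TRUE)
  date <- as.Date(sprintf("%d-%02d-%02d", des$year, des$month, day))
  doy <- doy_of(date)
  temp <- 22 + 8 * sin(2 * pi * (doy - 110) / 365.25) + rnorm(n, 0, 1.5)
  sal <- 20 + 14 * (gx[gi] / max(gx)) + rnorm(n, 0, 2)
  sal <- pmin(pmax(sal, 2), 38)
  veg <- grid_truth$vegetation[gi]
  conc <- grid_truth$concentrated[gi]
  spawn <- des$month >= 4 & des$month <= 9
  yi <- match(des$year, truth$years)
  tb <- floor(temp / 2.5)
  tb <- tb - min(tb)
  eta_p <- truth$presence_intercept + truth$year_logit[yi] +
    truth$region_logit * conc + truth$season_logit * spawn +
    truth$temp_logit_per_bin * tb
  p <- plogis(eta_p)
  if (all(p == 0))
    stop("degenerate truth: presence probability is zero everywhere")
  present <- rbinom(n, 1, p) == 1
  mu <- truth$positive_meanlog + truth$year_log[yi] +
    truth$region_log * conc + truth$vegetation_log * veg
  count <- integer(n)
  count[present] <- pmax(1L, as.integer(round(
    rlnorm(sum(present), mu[present], truth$positive_sdlog))))

  hauls <- data.frame(
    haul_id = sprintf("H%05d", seq_len(n)),
    date = date,
    grid_id = grid_truth$grid_id[gi],
    x = gx[gi] + runif(n, -cell / 2, cell / 2),
    y = gy[gi] + runif(n, -cell / 2, cell / 2),
    adult_count = count,
    temperature_c = round(temp, 1),
    salinity_ppt = round(sal, 1),
    bottom_vegetation = veg,
    year = des$year,
    month = des$month,
    season = factor(ifelse(spawn, "spawning", "non-spawning"),
                    levels = c("non-spawning", "spawning")),
    region_true = factor(ifelse(conc, "concentrated", "not"),
                         levels = c("not", "concentrated")),
    stringsAsFactors = FALSE)
  truth$grid_truth <- grid_truth
  list(hauls = hauls[order(hauls$date, hauls$haul_id), ], truth = truth)
}
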