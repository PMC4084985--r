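# shared builders and independent oracles for the test suite

EST <- "Etc/GMT+5"

est <- function(x) as.POSIXct(x, tz = EST)

# minimal two-receiver deployment on the x axis (ids 9 and 10)
tiny_deployments <- function() {
  data.frame(receiver_id = c(9L, 10L), easting = c(0, 100),
             northing = c(0, 0), zone = c(2L, 2L),
             core_array = c(TRUE, TRUE))
}

det_row <- function(tag, recv, ts) {
  data.frame(tag_id = tag, receiver_id = as.integer(recv),
             timestamp = est(ts), stringsAsFactors = FALSE)
}

# random detection table over a receiver set and a date span
random_detections <- function(n, receivers, tags, start, days, seed) {
  set.seed(seed)
  data.frame(
    tag_id = sample(tags, n, replace = TRUE),
    receiver_id = sample(receivers, n, replace = TRUE),
    timestamp = est(start) + runif(n, 0, days * 86400))
}

# brute-force Mann-Whitney U: count pairwise wins + half-ties
brute_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
  u
}

# winding-number point-in-polygon (independent of the ray-casting
# implementation in the package)
winding_inside <- function(px, py, vx, vy) {
  n <- length(vx)
  wn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cross <- (vx[j] - vx[i]) * (py - vy[i]) - (px - vx[i]) * (vy[j] - vy[i])
    if (vy[i] <= py) {
      if (vy[j] > py && cross > 0) wn <- wn + 1
    } else {
      if (vy[j] <= py && cross < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# attach true region labels from simulate_survey ground truth
with_true_region <- function(sim) {
  h <- sim$hauls
  gt <- sim$truth$grid_truth
  conc <- gt$concentrated[match(h$grid_id, gt$grid_id)]
  h$region <- factor(ifelse(conc, "concentrated", "not"),
                     levels = c("not", "concentrated"))
  h
}

# daily presence table built straight from simulator truth (zone 2 on
# present days), for series-level oracles that bypass the acoustic layer
truth_daily_table <- function(truth_daily) {
  d <- truth_daily[truth_daily$present, c("tag_id", "date")]
  d$zone <- 2L
  d$spawning_site <- TRUE
  d
}
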