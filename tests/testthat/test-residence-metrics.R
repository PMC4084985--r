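daily_from <- function(tag, dates, zone) {
  data.frame(tag_id = tag, date = as.Date(dates), zone = as.integer(zone),
             spawning_site = as.integer(zone) %in% c(2L, 3L))
}

test_that("daily presence deduplicates hourly positions", {
  pos <- data.frame(tag_id = "A",
                    bin_start = est("2007-06-14 10:00:00") +
                      c(0, 1, 2, 3, 4) * 3600,
                    zone = c(2L, 2L, 2L, 2L, 7L))
  d <- daily_presence(pos)
  expect_equal(nrow(d), 2)  # one row per zone that day
  expect_setequal(d$zone, c(2L, 7L))
  expect_equal(d$spawning_site, d$zone %in% c(2, 3))
  # random table: row set equals the distinct-triples oracle
  set.seed(3)
  pos2 <- data.frame(tag_id = sample(c("A", "B"), 200, TRUE),
                     bin_start = est("2007-06-01 00:00:00") +
                       sample(0:500, 200, TRUE) * 3600,
                     zone = sample(1:7, 200, TRUE))
  d2 <- daily_presence(pos2)
  oracle <- unique(data.frame(tag_id = pos2$tag_id,
                              date = as.Date(format(pos2$bin_start,
                                                    tz = EST, "%Y-%m-%d")),
                              zone = pos2$zone))
  expect_equal(nrow(d2), nrow(oracle))
})

test_that("residence summary reproduces the published arithmetic", {
  # DD(A)=43 over 6/4-8/19 (the printed 2007 example): TP 77, RI 55.8
  set.seed(11)
  span <- seq(as.Date("2007-06-04"), as.Date("2007-08-19"), by = "day")
  dates <- c(span[1], span[length(span)],
             sample(span[2:(length(span) - 1)], 41))
  rs <- residence_summary(daily_from("T1", dates, 2))
  a <- rs[rs$scope == "array", ]
  expect_equal(a$dd, 43L)
  expect_equal(a$tp, 77L)
  expect_equal(a$ri, 55.8)
  # 2009 multi-year example: 3/21-9/20 spans 184 d
  rs2 <- residence_summary(daily_from("T2", c("2009-03-21", "2009-09-20"),
                                      4))
  expect_equal(rs2[rs2$scope == "array", "tp"], 184L)
  # degenerate single date
  rs3 <- residence_summary(daily_from("T3", "2007-07-01", 2))
  expect_true(all(rs3$tp == 1 & rs3$dd == 1 & rs3$ri == 100))
  expect_false(any(rs3$eligible))
})

test_that("residence metrics are invariant to a constant date shift", {
  set.seed(4)
  dates <- as.Date("2007-06-01") + sample(0:90, 30)
  a <- residence_summary(daily_from("A", dates, 2))
  b <- residence_summary(daily_from("A", dates + 17, 2))
  expect_equal(a[c("dd", "tp", "ri")], b[c("dd", "tp", "ri")])
})

test_that("residence recovery from simulated detections is exact", {
  # near-certain detection: every true presence day yields positions
  tr <- telemetry_truth(detection_steepness = 0.5, spurious_rate = 0)
  tags <- make_tags(n_v9 = 0, n_v13 = 6,
                    implant_time = est("2007-04-01 18:00:00"))
  dr <- as.Date(c("2007-05-01", "2007-07-31"))
  sim <- simulate_telemetry(tr, tags = tags, control_tags = NULL,
                            date_range = dr, seed = 19)
  pos <- estimate_positions(sim$detections, default_deployments(),
                            zone_map = default_zone_map())
  daily <- daily_presence(pos)
  rs <- residence_summary(daily)
  td <- sim$truth_daily[sim$truth_daily$present, ]
  for (tg in unique(td$tag_id)) {
    truth_dates <- td$date[td$tag_id == tg]
    a <- rs[rs$scope == "array" & rs$tag_id == tg, ]
    expect_equal(a$dd, length(unique(truth_dates)))
    expect_equal(a$first_date, min(truth_dates))
    expect_equal(a$tp,
                 as.integer(max(truth_dates) - min(truth_dates)) + 1L)
  }
})

test_that("RI correlation matches the covariance-formula oracle", {
  res <- table1_to_residences()
  rc <- ri_correlation(res, min_dates = 4)
  expect_equal(rc$n, 38)
  # independent textbook formula on the same eligible pairs
  a <- res[res$scope == "array", ]
  s <- res[res$scope == "spawning_site", ]
  m <- merge(a, s, by = c("tag_id", "year"), suffixes = c("_a", "_ss"))
  m <- m[!is.na(m$ri_a) & !is.na(m$ri_ss) & m$dd_ss >= 4, ]
  x <- m$ri_a; y <- m$ri_ss
  r_hand <- (mean(x * y) - mean(x) * mean(y)) /
    sqrt((mean(x^2) - mean(x)^2) * (mean(y^2) - mean(y)^2))
  expect_equal(rc$r, r_hand, tolerance = 1e-12)
  # affine rescaling of both RI columns leaves r unchanged
  res2 <- res
  arr <- res2$scope == "array"
  res2$ri[arr] <- 3 * res2$ri[arr] + 7
  res2$ri[!arr] <- 0.5 * res2$ri[!arr] - 2
  expect_equal(ri_correlation(res2, 4)$r, rc$r, tolerance = 1e-12)
  # perfect agreement and perfect anti-order
  mk <- function(ra, rs_) rbind(
    data.frame(tag_id = c("a", "b", "c"), year = 1, scope = "array",
               dd = 9, ri = ra, ri_raw = ra),
    data.frame(tag_id = c("a", "b", "c"), year = 1,
               scope = "spawning_site", dd = 9, ri = rs_, ri_raw = rs_))
  expect_equal(ri_correlation(mk(c(1, 2, 3), c(1, 2, 3)))$r, 1)
  expect_equal(ri_correlation(mk(c(1, 2, 3), c(3, 2, 1)))$r, -1)
})

test_that("Mann-Whitney U matches the pairwise-count oracle", {
  # identical samples: U = n1*n2/2 by symmetry
  u0 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(u0$u, 4.5)
  # complete separation
  u1 <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(sort(c(u1$u, u1$u_other)), c(0, 4))
  # random samples with ties vs brute force
  set.seed(8)
  for (k in 1:5) {
    x <- sample(1:10, 8, replace = TRUE)
    y <- sample(1:10, 7, replace = TRUE)
    u <- mann_whitney_u(x, y)
    expect_equal(u$u, brute_u(x, y))
    expect_equal(u$u + u$u_other, 56)
    expect_true(u$p_normal_approx >= 0 && u$p_normal_approx <= 1)
  }
})

test_that("zone relocation tables count bins and normalize rows", {
  set.seed(2)
  pos <- data.frame(tag_id = sample(c("A", "B"), 300, TRUE),
                    bin_start = est("2007-06-01 00:00:00") +
                      sample(0:2000, 300) * 3600,
                    zone = sample(1:7, 300, TRUE))
  zrt <- zone_relocation_table(pos)
  expect_true(all(abs(rowSums(zrt$counts / rowSums(zrt$counts)) - 1) <
                  1e-9))
  expect_equal(sum(zrt$counts), 300L)
  # order invariance
  zrt2 <- zone_relocation_table(pos[sample(nrow(pos)), ])
  expect_identical(zrt$counts, zrt2$counts)
  # fixture proportions: zone-7 share of 2007 relocations
  t2 <- load_table2_fixture()
  expect_equal(round(t2["2007", "7"] / sum(t2["2007", ]), 3), 0.324)
})

test_that("chi-square against expected proportions matches the formula", {
  expect_equal(chisq_equal_distribution(c(5, 5, 5))$statistic, 0)
  x10 <- chisq_equal_distribution(c(10, 0))
  expect_equal(x10$statistic, 10)
  expect_equal(x10$df, 1)
  set.seed(14)
  for (k in 1:5) {
    cnt <- sample(5:60, 4)
    p <- c(0.1, 0.2, 0.3, 0.4)
    got <- chisq_equal_distribution(cnt, p)
    e <- sum(cnt) * p
    expect_equal(got$statistic, sum((cnt - e)^2 / e))
    expect_equal(got$df, 3)
  }
})

test_that("relocation proportion series tracks the active denominator", {
  tags <- make_tags(n_v9 = 0, n_v13 = 3,
                    implant_time = est("2007-04-01 18:00:00"))
  d <- rbind(daily_from(tags$tag_id[1], "2007-06-10", 2),
             daily_from(tags$tag_id[2], "2007-06-10", 2),
             daily_from(tags$tag_id[3], "2007-06-10", 3))
  ser <- relocation_proportion_series(d, tags,
                                      dates = as.Date(c("2007-06-10",
                                                        "2007-06-11")))
  expect_equal(ser$prop_spawning_site, c(1, 0))
  expect_equal(ser$prop_other, c(0, 0))
  expect_equal(ser$n_active, c(3L, 3L))
  expect_true(all(ser$lunar_deg >= 0 & ser$lunar_deg < 360))
})

test_that("a lunar-driven series peaks at the semi-lunar period", {
  # strong semi-lunar truth, no seasonal trend; series built from truth
  tr <- telemetry_truth(doy_amplitude = 0, lunar_amplitude = 2,
                        sex_effect = 0, random_intercept_sd = 0.2,
                        baseline = -0.5)
  tags <- make_tags(n_v9 = 0, n_v13 = 30,
                    implant_time = est("2007-03-25 18:00:00"))
  dates <- seq(as.Date("2007-04-01"), as.Date("2007-09-15"), by = "day")
  rec <- simulate_presence_records(tr, tags, dates, seed = 6)
  daily <- data.frame(tag_id = rec$tag_id[rec$present == 1],
                      date = rec$date[rec$present == 1],
                      zone = 2L, spawning_site = TRUE)
  ser <- relocation_proportion_series(daily, tags, dates = dates)
  y <- ser$prop_spawning_site - mean(ser$prop_spawning_site)
  # periodogram oracle via fft; dominant short period near 29.53/2 d
  pw <- Mod(fft(y))^2
  n <- length(y)
  freq <- (seq_len(n) - 1) / n
  short <- which(freq > 1 / 25 & freq < 0.5)
  peak_period <- 1 / freq[short[which.max(pw[short])]]
  expect_gt(peak_period, 13)
  expect_lt(peak_period, 17)
})

test_that("monthly zone profiles are proper per-month distributions", {
  set.seed(21)
  d <- data.frame(tag_id = sample(c("A", "B"), 120, TRUE),
                  date = as.Date("2007-05-01") + sample(0:120, 120, TRUE),
                  zone = sample(c(2L, 3L, 7L), 120, TRUE))
  d$spawning_site <- d$zone %in% c(2L, 3L)
  d <- unique(d)
  mp <- monthly_zone_profile(d)
  sums <- aggregate(prop ~ tag_id + year + month, mp, sum)
  expect_true(all(abs(sums$prop - 1) < 1e-9))
  # group-count oracle on one cell
  cell <- mp[mp$tag_id == "A" & mp$month == 6 & mp$zone == 2, ]
  if (nrow(cell) == 1) {
    o <- d[d$tag_id == "A" & format(d$date, "%m") == "06", ]
    expect_equal(cell$prop, mean(o$zone == 2))
  }
  # single-zone fish: degenerate profile
  solo <- daily_from("S", c("2007-06-01", "2007-06-02"), 7)
  ms <- monthly_zone_profile(solo)
  expect_equal(ms$prop, 1)
})
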