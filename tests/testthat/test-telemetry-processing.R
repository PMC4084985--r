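test_that("spurious filter removes exactly the daily core singletons", {
  dep <- tiny_deployments()
  d <- rbind(det_row("A", 9, "2007-06-14 10:00:00"),      # singleton -> out
             det_row("B", 9, "2007-06-14 10:00:00"),      # pair -> kept
             det_row("B", 10, "2007-06-14 11:00:00"),
             det_row("A", 9, "2007-06-15 10:00:00"),      # next day pair
             det_row("A", 10, "2007-06-15 10:05:00"))
  fs <- filter_spurious(d, dep)
  expect_equal(nrow(fs$removed), 1)
  expect_equal(fs$removed$tag_id, "A")
  expect_equal(as.character(as.Date(fs$removed$timestamp)), "2007-06-14")
  expect_equal(nrow(fs$kept) + nrow(fs$removed), nrow(d))
})

test_that("spurious filter matches a brute-force per-tag-per-day oracle", {
  dep <- default_deployments()
  d <- random_detections(500, dep$receiver_id, paste0("T", 1:6),
                         "2007-06-01 00:00:00", days = 10, seed = 31)
  d <- d[order(d$tag_id, d$timestamp), ]
  fs <- filter_spurious(d, dep)
  # oracle: exhaustive group-and-count on (tag, EST day) over core array
  core <- dep$receiver_id[dep$core_array]
  day <- format(d$timestamp, tz = EST, "%Y-%m-%d")
  is_core <- d$receiver_id %in% core
  expect_removed <- logical(nrow(d))
  for (tg in unique(d$tag_id)) for (dy in unique(day)) {
    i <- which(d$tag_id == tg & day == dy & is_core)
    if (length(i) == 1) expect_removed[i] <- TRUE
  }
  expect_equal(sort(as.numeric(fs$removed$timestamp)),
               sort(as.numeric(d$timestamp[expect_removed])))
  expect_equal(nrow(fs$kept), sum(!expect_removed))
})

test_that("post-release split partitions at the 48 h boundary", {
  tags <- make_tags(n_v9 = 1, n_v13 = 0,
                    implant_time = est("2007-06-14 12:00:00"))
  t0 <- tags$implant_time[1]
  d <- data.frame(tag_id = tags$tag_id[1], receiver_id = 9L,
                  timestamp = t0 + c(47.9, 48.1) * 3600)
  sp <- split_post_release(d, tags)
  expect_equal(nrow(sp$post_release), 1)
  expect_equal(nrow(sp$study), 1)
  expect_lt(as.numeric(sp$post_release$timestamp - t0, units = "hours"), 48)

  # random partition sizes against a direct timestamp comparison
  dd <- random_detections(300, c(9L, 10L), tags$tag_id,
                          "2007-06-14 12:00:00", days = 6, seed = 7)
  sp2 <- split_post_release(dd, tags)
  oracle_post <- sum(as.numeric(dd$timestamp) < as.numeric(t0) + 48 * 3600)
  expect_equal(nrow(sp2$post_release), oracle_post)
  expect_equal(nrow(sp2$study), nrow(dd) - oracle_post)

  tags$implant_time[1] <- NA
  expect_error(split_post_release(d, tags), "implant_time")
})

test_that("censoring drops detections after the censor date only", {
  tags <- make_tags(n_v9 = 1, n_v13 = 1,
                    implant_time = est("2009-04-01 12:00:00"))
  tags$censor_date[1] <- as.Date("2009-06-10")  # the tag-26 pattern
  d <- rbind(det_row(tags$tag_id[1], 9, "2009-06-09 10:00:00"),
             det_row(tags$tag_id[1], 9, "2009-06-10 23:00:00"),
             det_row(tags$tag_id[1], 9, "2009-06-11 01:00:00"),
             det_row(tags$tag_id[2], 9, "2009-06-30 01:00:00"))
  out <- apply_censoring(d, tags)
  kept_days <- as.character(as.Date(format(out$timestamp, tz = EST,
                                           "%Y-%m-%d")))
  expect_false(any(out$tag_id == tags$tag_id[1] &
                   kept_days > "2009-06-10"))
  expect_equal(sum(out$tag_id == tags$tag_id[1]), 2)  # 9th and 10th kept
  # no censor date: untouched
  expect_equal(nrow(apply_censoring(d, within(tags, censor_date <- NA))),
               nrow(d))
})

test_that("stationary tags are flagged at immobility onset", {
  mk <- function(tag, recv, dates) {
    do.call(rbind, lapply(dates, function(dt)
      det_row(tag, recv, paste(dt, "08:00:00"))))
  }
  dead_days <- as.character(seq(as.Date("2007-07-01"), by = "day",
                                length.out = 20))
  dead <- mk("DEAD", 14, dead_days)
  # a moving tag sweeps receivers 3..19
  move <- do.call(rbind, lapply(seq_along(dead_days), function(i)
    det_row("MOVE", 3 + (i %% 17), paste(dead_days[i], "09:00:00"))))
  fl <- flag_stationary(rbind(dead, move), min_days = 14,
                        receiver_spread = 2)
  expect_equal(fl$tag_id, "DEAD")
  expect_equal(fl$onset_date, as.Date("2007-07-01"))
  expect_equal(fl$run_days, 20)

  # two adjacent receivers alternating still count with spread = 2
  alt <- do.call(rbind, lapply(seq_along(dead_days), function(i)
    det_row("ALT", c(9L, 10L)[1 + i %% 2], paste(dead_days[i], "07:00:00"))))
  fl2 <- flag_stationary(alt, min_days = 14, receiver_spread = 2)
  expect_equal(fl2$tag_id, "ALT")
})

test_that("weighted-means positions match hand-computed oracles", {
  dep <- default_deployments()
  # all detections on receiver 14: position is receiver 14 itself
  d14 <- do.call(rbind, lapply(0:6, function(m)
    det_row("A", 14, sprintf("2007-06-14 10:%02d:00", m))))
  p <- estimate_positions(d14, dep)
  expect_equal(nrow(p), 1)
  expect_equal(p$easting, dep$easting[dep$receiver_id == 14])
  expect_equal(p$mean_receiver_number, 14)
  expect_equal(p$n_detections, 7L)

  # 3 detections at (0,0) receiver 9 and 1 at (100,0) receiver 10
  tiny <- tiny_deployments()
  d <- rbind(det_row("A", 9, "2007-06-14 10:01:00"),
             det_row("A", 9, "2007-06-14 10:02:00"),
             det_row("A", 9, "2007-06-14 10:03:00"),
             det_row("A", 10, "2007-06-14 10:04:00"))
  p2 <- estimate_positions(d, tiny)
  expect_equal(p2$easting, 25.0)
  expect_equal(p2$mean_receiver_number, 9.25)
})

test_that("positions are translation-equivariant and inside the hull", {
  dep <- default_deployments()
  d <- random_detections(400, dep$receiver_id, c("A", "B"),
                         "2007-06-01 00:00:00", days = 2, seed = 5)
  p <- estimate_positions(d, dep)
  dep2 <- dep
  dep2$easting <- dep$easting + 250
  dep2$northing <- dep$northing - 125
  p2 <- estimate_positions(d, dep2)
  expect_equal(p2$easting, p$easting + 250)
  expect_equal(p2$northing, p$northing - 125)
  expect_true(all(p$easting >= min(dep$easting) &
                  p$easting <= max(dep$easting)))
  expect_true(all(p$northing >= min(dep$northing) &
                  p$northing <= max(dep$northing)))
})

test_that("zone assignment matches an independent geometric oracle", {
  zm <- default_zone_map()
  dep <- default_deployments()
  # receivers land in their own zones
  expect_equal(assign_zone(dep$easting, dep$northing, zm), dep$zone)
  # boundary point resolves deterministically to the nearest centroid
  b1 <- assign_zone(160, 0, zm)
  expect_identical(b1, assign_zone(160, 0, zm))
  expect_true(b1 %in% c(2L, 3L))

  set.seed(77)
  px <- runif(1000, -700, 1600)
  py <- runif(1000, -150, 650)
  got <- assign_zone(px, py, zm)
  zones <- sort(unique(zm$polygons$zone))
  for (k in seq_along(px)) {
    inside <- vapply(zones, function(z) {
      v <- zm$polygons[zm$polygons$zone == z, ]
      winding_inside(px[k], py[k], v$x, v$y)
    }, TRUE)
    if (sum(inside) == 1)
      expect_equal(got[k], zones[which(inside)])
  }
})

test_that("control-tag audit recovers error and detection rates", {
  tr <- telemetry_truth()
  dep <- data.frame(receiver_id = 1L, easting = 0, northing = 0,
                    zone = 2L, core_array = TRUE)
  ctl <- data.frame(control_id = "C0", easting = 0, northing = 0,
                    zone = 2L, delay_s = 60)
  tags <- make_tags(n_v9 = 1, n_v13 = 0,
                    implant_time = est("2007-06-01 00:00:00"))
  tags$censor_date <- as.Date("2007-05-01")
  sim <- simulate_telemetry(tr, deployments = dep, tags = tags,
                            control_tags = ctl,
                            date_range = as.Date(c("2007-06-01",
                                                   "2007-06-03")),
                            seed = 21)
  period <- c(est("2007-06-01 00:00:00"), est("2007-06-04 00:00:00"))
  aud <- audit_control_tags(sim$detections, ctl, dep, period = period)
  # co-located receiver: zero positioning error; detection rate matches
  # the single-ping probability at distance zero
  p0 <- detection_probability(0, tr)
  expect_equal(aud$mean_error_m, 0)
  n <- sim$control_expected$expected
  expect_lt(abs(aud$detection_rate - p0), 3 * sqrt(p0 * (1 - p0) / n))

  # thin to 50%: detection rate halves (binomial oracle)
  set.seed(9)
  keep <- runif(nrow(sim$detections)) < 0.5
  aud2 <- audit_control_tags(sim$detections[keep, ], ctl, dep,
                             period = period)
  expect_lt(abs(aud2$detection_rate - 0.5 * p0), 3 * sqrt(0.25 / n))
})
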