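#' Ground truth for the synthetic telemetry array
#'
#' Parameters of the daily spawning-site presence process and the
#' detection model used by [simulate_telemetry()]. Daily presence of fish
#' `i` on date `d` is Bernoulli with
#' `logit p = baseline + sex_effect*[male] +
#'  doy_amplitude*cos(2*pi*(doy - doy_peak)/365.25) +
#'  lunar_amplitude*cos(2*theta) + b_i`,
#' where `theta` is the lunar phase in radians (so the semi-lunar term
#' peaks at both new and full moon) and `b_i ~ N(0, random_intercept_sd)`.
#'
#' Detection of a single ping by a receiver at distance `d` m is
#' `plogis(detection_steepness * (detection_halfrange_m - d))`, i.e. 50%
#' at the half-range (85 m by default, the consistent-detection range
#' established by long-term range testing at the site). That 50%
#' range is the only calibrated point; the slope is a free parameter.
#'
#' @param doy_amplitude,doy_peak cyclic seasonal effect (log-odds
#'   amplitude; peak day of year, default early July).
#' @param lunar_amplitude log-odds amplitude of the semi-lunar effect.
#' @param sex_effect male minus female log-odds difference.
#' @param random_intercept_sd SD of per-fish random intercepts (log-odds).
#' @param baseline log-odds of presence for an average female at the
#'   seasonal/lunar zero point.
#' @param detection_halfrange_m distance at which single-ping detection
#'   probability is 0.5.
#' @param detection_steepness logistic slope per meter.
#' @param spurious_rate expected stray single detections per tag-day.
#' @param site_bins_mean,refuge_bins_mean mean number of occupied hourly
#'   bins per present day at the spawning site (within 1400-2000 h) and
#'   in the refuge zone (other hours).
#' @return list of class `telemetry_truth`.
#' @export
telemetry_truth <- function(doy_amplitude = 1.5, doy_peak = 182,
                            lunar_amplitude = 0.8, sex_effect = 1.0,
                            random_intercept_sd = 0.8, baseline = -1.0,
                            detection_halfrange_m = 85,
                            detection_steepness = 0.05,
                            spurious_rate = 0.02,
                            site_bins_mean = 2.6, refuge_bins_mean = 3) {
  stopifnot(detection_halfrange_m > 0, random_intercept_sd >= 0)
  structure(list(doy_amplitude = doy_amplitude, doy_peak = doy_peak,
                 lunar_amplitude = lunar_amplitude, sex_effect = sex_effect,
                 random_intercept_sd = random_intercept_sd,
                 baseline = baseline,
                 detection_halfrange_m = detection_halfrange_m,
                 detection_steepness = detection_steepness,
                 spurious_rate = spurious_rate,
                 site_bins_mean = site_bins_mean,
                 refuge_bins_mean = refuge_bins_mean),
            class = "telemetry_truth")
}

#' Single-ping detection probability at distance
#'
#' @param distance_m distance(s) in meters.
#' @param truth a [telemetry_truth()] object.
#' @return probabilities in (0, 1); 0.5 at `detection_halfrange_m`.
#' @export
detection_probability <- function(distance_m, truth) {
  plogis(truth$detection_steepness *
           (truth$detection_halfrange_m - distance_m))
}

# logit of daily presence for given covariates and random intercept
presence_logit <- function(truth, male, doy, lunar_deg, b) {
  truth$baseline + truth$sex_effect * male +
    truth$doy_amplitude * cos(2 * pi * (doy - truth$doy_peak) / 365.25) +
    truth$lunar_amplitude * cos(2 * lunar_deg * pi / 180) + b
}

#' Simulate detections from the acoustic array
#'
#' For every tag and day inside its activity window (annual duty cycle,
#' battery horizon, censor date), true spawning-site presence is drawn
#' from the logistic daily model of [telemetry_truth()]. Present fish
#' occupy a small number of hourly bins at the spawning site (zones 2-3)
#' during 1400-2000 h and at the refuge zone (receiver 23 area) during
#' other hours; absent fish are outside the array and yield no detections
#' except injected spurious singletons. Within each occupied bin the tag
#' emits `floor(3600 / mean inter-ping delay)` pings; every ping is
#' detected by every receiver independently with probability
#' [detection_probability()] of the fish-receiver distance. Control tags
#' ping on a fixed 60 s schedule from their true positions (detections of
#' one ping share a timestamp across receivers).
#'
#' Each fish consumes its own random-number stream split from `seed`, so
#' adding fish does not perturb the draws of others.
#'
#' @param truth a [telemetry_truth()] object.
#' @param deployments receiver table, see [default_deployments()].
#' @param tags tag metadata, see [make_tags()].
#' @param control_tags control-tag table ([default_control_tags()]) or
#'   `NULL` to skip control transmissions.
#' @param date_range `Date` vector of length 2 (inclusive).
#' @param seed integer master seed.
#' @return list with `detections` (tag_id, receiver_id, timestamp; sorted),
#'   `truth_daily` (tag_id, date, active, present, p_true, b) and
#'   `control_expected` (expected transmissions per control tag).
#' @export
simulate_telemetry <- function(truth, deployments = default_deployments(),
                               tags = make_tags(),
                               control_tags = default_control_tags(),
                               date_range, seed = 1) {
  stopifnot(inherits(truth, "telemetry_truth"), nrow(deployments) > 0,
            nrow(tags) > 0, all(!is.na(tags$sex)),
            all(!is.na(tags$tag_model)))
  date_range <- as.Date(date_range)
  if (length(date_range) != 2 || anyNA(date_range) ||
      date_range[2] < date_range[1])
    stop("date_range must be two ordered dates")
  days <- seq(date_range[1], date_range[2], by = "day")
  core <- deployments[deployments$zone %in% c(2L, 3L), ]
  refuge <- deployments[deployments$receiver_id == 23L, ]
  if (nrow(refuge) == 0) refuge <- deployments[deployments$zone == 7L, ][1, ]
  lun <- lunar_phase(days)
  doy <- doy_of(days)
  day_sec <- as.numeric(as.POSIXct(paste(days), tz = EST_TZ))

  det_list <- list()
  truth_list <- list()
  for (i in seq_len(nrow(tags))) {
    tg <- tags[i, ]
    set.seed(child_seed(seed, i))
    b <- rnorm(1, 0, truth$random_intercept_sd)
    active <- tag_active_on(days, tg) &
      days >= est_date(tg$implant_time)
    p <- plogis(presence_logit(truth, tg$sex == "M", doy, lun, b))
    present <- active & (runif(length(days)) < p)
    truth_list[[i]] <- data.frame(tag_id = tg$tag_id, date = days,
                                  active = active, present = present,
                                  p_true = ifelse(active, p, 0), b = b)
    pres_idx <- which(present)
    if (length(pres_idx) > 0) {
      np <- length(pres_idx)
      n_site <- 1L + rbinom(np, 4, (truth$site_bins_mean - 1) / 4)
      n_ref <- rbinom(np, 6, truth$refuge_bins_mean / 6)
      hours <- unlist(lapply(seq_len(np), function(k) {
        c(sample(14:19, n_site[k]),
          if (n_ref[k] > 0) sample(c(6:13, 20:23), n_ref[k]) else integer())
      }))
      day_of_bin <- rep(pres_idx, n_site + n_ref)
      at_site <- unlist(lapply(seq_len(np), function(k)
        rep(c(TRUE, FALSE), c(n_site[k], n_ref[k]))))
      nb <- length(hours)
      core_row <- sample.int(nrow(core), nb, replace = TRUE)
      fx <- ifelse(at_site, core$easting[core_row], refuge$easting[1]) +
        rnorm(nb, 0, 20)
      fy <- ifelse(at_site, core$northing[core_row], refuge$northing[1]) +
        rnorm(nb, 0, 20)
      n_pings <- floor(3600 / ((tg$delay_min_s + tg$delay_max_s) / 2))
      dmat <- sqrt(outer(fx, deployments$easting, "-")^2 +
                   outer(fy, deployments$northing, "-")^2)
      pmat <- detection_probability(dmat, truth)
      pmat[pmat < 1e-4] <- 0
      cnt <- matrix(rbinom(length(pmat), n_pings, pmat), nrow = nb)
      idx <- which(cnt > 0, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        nrep <- cnt[idx]
        bi <- rep(idx[, 1], nrep)
        rec <- rep(deployments$receiver_id[idx[, 2]], nrep)
        t0 <- day_sec[day_of_bin[bi]] + hours[bi] * 3600
        det_list[[length(det_list) + 1]] <-
          list(tag_id = rep(tg$tag_id, length(bi)), receiver_id = rec,
               t = t0 + runif(length(bi), 0, 3600))
      }
    }
    # spurious singletons on active days without real site presence
    sp_idx <- which(active & !present)
    if (truth$spurious_rate > 0 && length(sp_idx) > 0) {
      nsp <- rpois(length(sp_idx), truth$spurious_rate)
      keep <- which(nsp > 0)
      if (length(keep) > 0) {
        di <- rep(sp_idx[keep], nsp[keep])
        rr <- core$receiver_id[sample.int(nrow(core), length(di),
                                          replace = TRUE)]
        det_list[[length(det_list) + 1]] <-
          list(tag_id = rep(tg$tag_id, length(di)), receiver_id = rr,
               t = day_sec[di] + runif(length(di), 0, 86400))
      }
    }
  }

  control_expected <- NULL
  if (!is.null(control_tags) && nrow(control_tags) > 0) {
    t_start <- as.POSIXct(paste(date_range[1]), tz = EST_TZ)
    t_end <- as.POSIXct(paste(date_range[2]), tz = EST_TZ) + 86400
    for (k in seq_len(nrow(control_tags))) {
      ct <- control_tags[k, ]
      set.seed(child_seed(seed, 100000 + k))
      pt <- seq(t_start, t_end - ct$delay_s, by = ct$delay_s)
      dvec <- sqrt((deployments$easting - ct$easting)^2 +
                   (deployments$northing - ct$northing)^2)
      pr <- detection_probability(dvec, truth)
      near <- which(pr >= 1e-4)
      for (r in near) {
        hit <- runif(length(pt)) < pr[r]
        if (any(hit))
          det_list[[length(det_list) + 1]] <-
            list(tag_id = rep(ct$control_id, sum(hit)),
                 receiver_id = rep(deployments$receiver_id[r], sum(hit)),
                 t = as.numeric(pt[hit]))
      }
    }
    control_expected <- data.frame(
      control_id = control_tags$control_id,
      expected = as.numeric(difftime(t_end, t_start, units = "secs")) /
        control_tags$delay_s)
  }

  if (length(det_list) > 0) {
    dt <- data.table::rbindlist(det_list)
    data.table::setorder(dt, tag_id, t, receiver_id)
    detections <- data.frame(
      tag_id = dt$tag_id, receiver_id = dt$receiver_id,
      timestamp = as.POSIXct(dt$t, origin = "1970-01-01", tz = EST_TZ))
  } else {
    detections <- data.frame(tag_id = character(), receiver_id = integer(),
                             timestamp = as.POSIXct(character(),
                                                    tz = EST_TZ))
  }
  list(detections = detections,
       truth_daily = do.call(rbind, truth_list),
       control_expected = control_expected)
}

#' Simulate daily presence records directly (model level)
#'
#' Fast-path generator that skips the detection layer: draws the daily
#' presence outcome of the [telemetry_truth()] logistic model for every
#' tag and date, returning ready-to-fit presence records. Used for
#' model-level calibration checks where the acoustic layer is irrelevant.
#'
#' @param truth a [telemetry_truth()] object.
#' @param tags tag metadata ([make_tags()]).
#' @param dates `Date` vector of study dates.
#' @param seed integer seed.
#' @return data.frame with `tag_id`, `date`, `present`, `sex`,
#'   `total_length_mm`, `doy`, `lunar_deg`, `year`, `b`.
#' @export
simulate_presence_records <- function(truth, tags, dates, seed = 1) {
  stopifnot(inherits(truth, "telemetry_truth"), length(dates) > 0)
  dates <- as.Date(dates)
  lun <- lunar_phase(dates)
  doy <- doy_of(dates)
  out <- lapply(seq_len(nrow(tags)), function(i) {
    set.seed(child_seed(seed, i))
    b <- rnorm(1, 0, truth$random_intercept_sd)
    p <- plogis(presence_logit(truth, tags$sex[i] == "M", doy, lun, b))
    data.frame(tag_id = tags$tag_id[i], date = dates,
               present = as.integer(runif(length(dates)) < p),
               sex = tags$sex[i],
               total_length_mm = tags$total_length_mm[i],
               doy = doy, lunar_deg = lun, year = year_of(dates), b = b)
  })
  do.call(rbind, out)
}
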