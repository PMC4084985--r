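#' @import data.table
NULL

utils::globalVariables(c(
  "tag_id", "receiver_id", "timestamp", "bin_start", "n_det", "easting",
  "northing", "zone", "date", "scope", "J", ".N", ".SD", "N",
  "mean_receiver_number", "n_detections", "present", "core", "n_core", "t"))

#' Remove spurious single detections
#'
#' A detection is spurious when it is the only core-array detection of
#' its transmitter within a 24 h period: isolated pings are more likely
#' code collisions or noise than a fish. With `window = "day"` (default)
#' the period is the local EST calendar day; `window = "rolling"` removes
#' core detections with no other core detection of the same tag within
#' 24 h either side.
#'
#' @param detections detection table (`tag_id`, `receiver_id`,
#'   `timestamp`), sorted.
#' @param deployments receiver table with `core_array` flag.
#' @param window `"day"` or `"rolling"`.
#' @return list with `kept` and `removed` detection tables; the two
#'   partition the input exactly.
#' @export
filter_spurious <- function(detections, deployments, window = c("day", "rolling")) {
  window <- match.arg(window)
  if (nrow(detections) == 0)
    return(list(kept = detections, removed = detections))
  core_ids <- deployments$receiver_id[deployments$core_array]
  is_core <- detections$receiver_id %in% core_ids
  drop <- rep(FALSE, nrow(detections))
  if (window == "day") {
    # EST calendar day without per-row timezone formatting: shift epoch
    # seconds by the fixed -5 h offset and floor to days
    day <- floor((as.numeric(detections$timestamp) - 5 * 3600) / 86400)
    dt <- data.table(i = seq_len(nrow(detections)),
                     tag_id = detections$tag_id, day = day, core = is_core)
    dt[, n_core := sum(core), by = .(tag_id, day)]
    drop <- dt$core & dt$n_core == 1L
  } else {
    ci <- which(is_core)
    if (length(ci) > 0) {
      ct <- as.numeric(detections$timestamp[ci])
      tg <- detections$tag_id[ci]
      o <- order(tg, ct)
      ct <- ct[o]; tg <- tg[o]
      n <- length(ci)
      prev_same <- c(FALSE, tg[-1] == tg[-n] & (ct[-1] - ct[-n]) <= 86400)
      next_same <- c(prev_same[-1], FALSE)
      iso <- !prev_same & !next_same
      drop[ci[o][iso]] <- TRUE
    }
  }
  list(kept = detections[!drop, , drop = FALSE],
       removed = detections[drop, , drop = FALSE])
}

#' Split detections into post-release and study periods
#'
#' Behavior in the first hours after surgery can reflect handling stress
#' rather than normal movement, so detections within `window_h` hours of
#' each tag's implantation are analyzed separately. The study period
#' starts at `implant_time + window_h` (detections at exactly the
#' boundary belong to the study period).
#'
#' @param detections detection table.
#' @param tags tag metadata with `implant_time` for every tag present.
#' @param window_h post-release window in hours.
#' @return list with `post_release` and `study` tables.
#' @export
split_post_release <- function(detections, tags, window_h = 48) {
  it <- tags$implant_time[match(detections$tag_id, tags$tag_id)]
  if (anyNA(it) && nrow(detections) > 0) {
    missing <- unique(detections$tag_id[is.na(it)])
    stop("no implant_time for tag(s): ", paste(missing, collapse = ", "))
  }
  post <- as.numeric(detections$timestamp) < as.numeric(it) + window_h * 3600
  list(post_release = detections[post, , drop = FALSE],
       study = detections[!post, , drop = FALSE])
}

#' Drop detections after a tag's censor date
#'
#' Tags that stop moving for an extended period indicate death or tag
#' loss; their detections after the recorded `censor_date` (inclusive of
#' that date itself) are removed.
#'
#' @param detections detection table.
#' @param tags tag metadata with optional `censor_date`.
#' @return filtered detection table.
#' @export
apply_censoring <- function(detections, tags) {
  cd <- tags$censor_date[match(detections$tag_id, tags$tag_id)]
  keep <- is.na(cd) | est_date(detections$timestamp) <= cd
  detections[keep, , drop = FALSE]
}

#' Flag stationary tags as mortality/tag-loss candidates
#'
#' Scans each tag's daily detection history for runs of consecutive days
#' on which the tag was detected only on a narrow, fixed set of receivers
#' (receiver-number range at most `receiver_spread`). Runs of at least
#' `min_days` days are flagged with their onset date, supporting the
#' manual mortality call that precedes [apply_censoring()].
#'
#' @param detections detection table.
#' @param min_days minimum run length in days.
#' @param receiver_spread maximum receiver-number range within the run.
#' @return data.frame `tag_id`, `onset_date`, `run_days`, `receivers`.
#' @export
flag_stationary <- function(detections, min_days = 14, receiver_spread = 2) {
  out <- list()
  for (tg in unique(detections$tag_id)) {
    sub <- detections[detections$tag_id == tg, ]
    day <- est_date(sub$timestamp)
    per_day <- split(sub$receiver_id, as.character(day))
    ds <- as.Date(names(per_day))
    o <- order(ds); ds <- ds[o]; per_day <- per_day[o]
    i <- 1
    while (i <= length(ds)) {
      j <- i
      rmin <- min(per_day[[i]]); rmax <- max(per_day[[i]])
      while (j < length(ds) && ds[j + 1] == ds[j] + 1) {
        nmin <- min(rmin, min(per_day[[j + 1]]))
        nmax <- max(rmax, max(per_day[[j + 1]]))
        if (nmax - nmin + 1 > receiver_spread) break
        rmin <- nmin; rmax <- nmax; j <- j + 1
      }
      if (j - i + 1 >= min_days)
        out[[length(out) + 1]] <- data.frame(
          tag_id = tg, onset_date = ds[i], run_days = j - i + 1,
          receivers = paste(rmin, rmax, sep = "-"))
      i <- j + 1
    }
  }
  if (length(out) == 0)
    return(data.frame(tag_id = character(), onset_date = as.Date(character()),
                      run_days = integer(), receivers = character()))
  do.call(rbind, out)
}

#' Weighted-means hourly positions
#'
#' Collapses detections into clock-aligned hourly bins `[HH:00, HH+1:00)`
#' (EST) per tag. The position for a bin is the detection-count-weighted
#' mean of the coordinates of the receivers that logged the tag in that
#' bin; the second location measure is the detection-count-weighted mean
#' receiver number.
#'
#' @param detections detection table.
#' @param deployments receiver table with coordinates.
#' @param zone_map optional zone geometry (see [default_zone_map()]); if
#'   supplied, a `zone` column is attached via [assign_zone()].
#' @param bin_hours bin width in hours (default 1).
#' @return data.frame `tag_id`, `bin_start`, `easting`, `northing`,
#'   `mean_receiver_number`, `n_detections` (and `zone` if mapped),
#'   one row per non-empty bin.
#' @export
estimate_positions <- function(detections, deployments, zone_map = NULL,
                               bin_hours = 1) {
  stopifnot(all(detections$receiver_id %in% deployments$receiver_id))
  dt <- data.table(tag_id = detections$tag_id,
                   receiver_id = detections$receiver_id,
                   t = as.numeric(detections$timestamp))
  w <- bin_hours * 3600
  dt[, bin_start := floor(t / w) * w]
  cnt <- dt[, .N, by = .(tag_id, bin_start, receiver_id)]
  dep <- data.table(receiver_id = deployments$receiver_id,
                    easting = deployments$easting,
                    northing = deployments$northing)
  cnt <- dep[cnt, on = "receiver_id"]
  pos <- cnt[, .(easting = sum(easting * N) / sum(N),
                 northing = sum(northing * N) / sum(N),
                 mean_receiver_number = sum(receiver_id * N) / sum(N),
                 n_detections = sum(N)),
             by = .(tag_id, bin_start)]
  setorder(pos, tag_id, bin_start)
  out <- as.data.frame(pos)
  out$bin_start <- as.POSIXct(out$bin_start, origin = "1970-01-01",
                              tz = EST_TZ)
  if (!is.null(zone_map))
    out$zone <- assign_zone(out$easting, out$northing, zone_map)
  out
}

# even-odd ray casting; vertices in order, implicitly closed
point_in_poly <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

#' Assign positions to detection zones
#'
#' Returns the zone whose polygon contains each position. Positions
#' outside every polygon (or on shared boundaries, where containment is
#' ambiguous) are resolved deterministically to the zone with the nearest
#' polygon centroid.
#'
#' @param x,y position coordinates (meters).
#' @param zone_map zone geometry, see [default_zone_map()].
#' @return integer vector of zones.
#' @export
assign_zone <- function(x, y, zone_map = default_zone_map()) {
  polys <- zone_map$polygons
  zones <- sort(unique(polys$zone))
  hit <- matrix(FALSE, length(x), length(zones))
  cx <- numeric(length(zones)); cy <- numeric(length(zones))
  for (k in seq_along(zones)) {
    v <- polys[polys$zone == zones[k], ]
    hit[, k] <- point_in_poly(x, y, v$x, v$y)
    cx[k] <- mean(v$x); cy[k] <- mean(v$y)
  }
  nhit <- rowSums(hit)
  out <- integer(length(x))
  one <- nhit == 1
  out[one] <- zones[apply(hit[one, , drop = FALSE], 1, which.max)]
  amb <- !one
  if (any(amb)) {
    d2 <- outer(x[amb], cx, "-")^2 + outer(y[amb], cy, "-")^2
    out[amb] <- zones[apply(d2, 1, which.min)]
  }
  out
}

#' Audit positioning error and detection rate with control tags
#'
#' Compares hourly weighted-means positions of fixed control tags with
#' their true deployment positions. The audited error is the easting
#' error (the informative axis for this west-east channel array); a full
#' Euclidean error is also reported. The detection rate is the number of
#' distinct received transmissions (unique ping timestamps) divided by
#' the number expected from the fixed delay over `period`.
#'
#' @param detections detection table containing control-tag ids.
#' @param control_tags control-tag table with true positions.
#' @param deployments receiver table.
#' @param period POSIXct length-2 monitoring interval used for expected
#'   transmissions; defaults to each tag's detection span.
#' @return data.frame `control_id`, `zone`, `n_bins`, `mean_error_m`,
#'   `se_error_m`, `fraction_gt_200m`, `mean_error_euclid_m`,
#'   `detection_rate`.
#' @export
audit_control_tags <- function(detections, control_tags, deployments,
                               period = NULL) {
  out <- list()
  for (k in seq_len(nrow(control_tags))) {
    ct <- control_tags[k, ]
    sub <- detections[detections$tag_id == ct$control_id, , drop = FALSE]
    if (nrow(sub) == 0) next
    pos <- estimate_positions(sub, deployments)
    err_e <- abs(pos$easting - ct$easting)
    err_2 <- sqrt((pos$easting - ct$easting)^2 +
                  (pos$northing - ct$northing)^2)
    if (is.null(period)) {
      span <- as.numeric(diff(range(sub$timestamp))) + ct$delay_s
      expected <- span / ct$delay_s
    } else {
      expected <- as.numeric(difftime(period[2], period[1], units = "secs")) /
        ct$delay_s
    }
    detected <- length(unique(as.numeric(sub$timestamp)))
    out[[k]] <- data.frame(
      control_id = ct$control_id,
      zone = if ("zone" %in% names(ct)) ct$zone else NA_integer_,
      n_bins = nrow(pos),
      mean_error_m = mean(err_e),
      se_error_m = sd(err_e) / sqrt(length(err_e)),
      fraction_gt_200m = mean(err_e > 200),
      mean_error_euclid_m = mean(err_2),
      detection_rate = min(1, detected / expected))
  }
  do.call(rbind, out)
}
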