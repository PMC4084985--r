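#' Default synthetic receiver array
#'
#' A 42-receiver planar layout mirroring the monitored inlet: receivers
#' 1-2 in the gulf west of the inlet (zone 1), the 17-receiver core array
#' (receivers 3-19, overlapping ranges) covering the spawning site
#' (zones 2-3) along the beach, transit receivers in zone 4, a shallow
#' refuge area north of the channel (zone 7, containing receiver 23) and
#' estuarine receivers in zones 5-6. Coordinates are planar meters
#' (UTM-like); no geodesy.
#'
#' @return `data.frame` with columns `receiver_id`, `easting`,
#'   `northing`, `zone`, `core_array`.
#' @export
default_deployments <- function() {
  d <- rbind(
    data.frame(receiver_id = 1:2,
               easting = c(-560, -360), northing = c(0, 0), zone = 1L),
    # core array, zone 2: staggered double row off the beach (beach at y=150)
    data.frame(receiver_id = c(3L, 5L, 7L, 9L, 11L),
               easting = c(-140, -70, 0, 70, 140), northing = 100, zone = 2L),
    data.frame(receiver_id = c(4L, 6L, 8L, 10L),
               easting = c(-105, -35, 35, 105), northing = 0, zone = 2L),
    # core array, zone 3
    data.frame(receiver_id = c(12L, 14L, 16L, 18L),
               easting = c(200, 280, 360, 440), northing = 100, zone = 3L),
    data.frame(receiver_id = c(13L, 15L, 17L, 19L),
               easting = c(240, 320, 400, 470), northing = 0, zone = 3L),
    # transit zone between inlet and refuge
    data.frame(receiver_id = c(20L, 21L, 24L, 25L),
               easting = c(520, 600, 680, 760),
               northing = c(60, 120, 40, 100), zone = 4L),
    # northern refuge behind the barrier island
    data.frame(receiver_id = c(22L, 23L, 39L, 40L, 41L, 42L),
               easting = c(560, 620, 500, 700, 600, 520),
               northing = c(300, 380, 450, 470, 520, 560), zone = 7L),
    data.frame(receiver_id = 26:31,
               easting = c(850, 930, 1010, 1090, 880, 1060),
               northing = c(0, 80, 0, 80, -80, -80), zone = 5L),
    data.frame(receiver_id = 32:38,
               easting = c(1200, 1280, 1360, 1440, 1520, 1250, 1470),
               northing = c(0, 70, 0, 70, 0, -80, -80), zone = 6L))
  d <- d[order(d$receiver_id), ]
  d$core_array <- d$receiver_id >= 3L & d$receiver_id <= 19L
  rownames(d) <- NULL
  d
}

#' Default zone geometry
#'
#' Seven rectangular zone polygons matching [default_deployments()]:
#' zones 1-6 run west (gulf) to east (inner estuary) along the channel and
#' zone 7 is the shallow refuge north of the channel. Supplied as a config
#' artifact: any polygon set (columns `zone`, `x`, `y`, vertices in order)
#' plus a receiver-to-zone lookup can be substituted.
#'
#' @return list with `polygons` (data.frame `zone`, `x`, `y`) and
#'   `receiver_zone` (named integer vector keyed by receiver id).
#' @export
default_zone_map <- function() {
  rect <- function(zone, x0, x1, y0, y1)
    data.frame(zone = zone, x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  polys <- rbind(rect(1L, -700, -160, -150, 150),
                 rect(2L, -160, 160, -150, 150),
                 rect(3L, 160, 480, -150, 150),
                 rect(4L, 480, 800, -150, 200),
                 rect(5L, 800, 1150, -150, 150),
                 rect(6L, 1150, 1600, -150, 150),
                 rect(7L, 400, 800, 200, 650))
  dep <- default_deployments()
  list(polygons = polys,
       receiver_zone = setNames(dep$zone, dep$receiver_id))
}

#' Default control tags
#'
#' Three fixed-position reference transmitters with a 60 s fixed delay,
#' used to audit detection rate and positioning error: one mid-way between
#' receivers 9 and 10 in the pass (zone 2), one in zone 5 and one in
#' zone 6 adjacent to a receiver.
#'
#' @return `data.frame` with `control_id`, `easting`, `northing`, `zone`,
#'   `delay_s`.
#' @export
default_control_tags <- function() {
  data.frame(control_id = c("C2", "C5", "C6"),
             easting = c(105, 950, 1350),
             northing = c(60, 20, 20),
             zone = c(2L, 5L, 6L),
             delay_s = 60)
}

#' Build a tag metadata table
#'
#' Synthetic transmitter metadata mirroring the tagging design: V9 tags
#' (149 d battery, 15-45 s random inter-pulse delay, unrestricted annual
#' window) and V13 tags (three seasons, active 22 March through
#' 20 September each year, 30-90 s delay).
#'
#' @param n_v9,n_v13 number of tags of each model.
#' @param implant_time implantation instant (POSIXct EST or coercible);
#'   all tags share it unless a vector is given.
#' @param sex_ratio proportion female; sexes are assigned deterministically
#'   in alternation to hit the ratio.
#' @param tl_range total-length range (mm) spread evenly across tags.
#' @return `data.frame` with columns `tag_id`, `sex`, `total_length_mm`,
#'   `tag_model`, `implant_time`, `battery_days`, `active_start_md`,
#'   `active_end_md` (month*100+day annual activity window),
#'   `delay_min_s`, `delay_max_s`, `censor_date`.
#' @export
make_tags <- function(n_v9 = 20, n_v13 = 11,
                      implant_time = parse_est("2007-06-14 20:00:00"),
                      sex_ratio = 0.5, tl_range = c(495, 792)) {
  n <- n_v9 + n_v13
  stopifnot(n > 0)
  # deterministic assignment: alternate at 50:50, otherwise block layout
  if (sex_ratio == 0.5) {
    sex <- rep(c("F", "M"), length.out = n)
  } else {
    nf <- round(sex_ratio * n)
    sex <- c(rep("F", nf), rep("M", n - nf))
  }
  model <- c(rep("V9", n_v9), rep("V13", n_v13))
  data.frame(
    tag_id = sprintf("T%02d", seq_len(n)),
    sex = sex,
    total_length_mm = round(seq(tl_range[1], tl_range[2], length.out = n)),
    tag_model = model,
    implant_time = rep(as.POSIXct(implant_time, tz = EST_TZ),
                       length.out = n),
    battery_days = ifelse(model == "V9", 149, 540),
    active_start_md = ifelse(model == "V9", 101L, 322L),
    active_end_md = ifelse(model == "V9", 1231L, 920L),
    delay_min_s = ifelse(model == "V9", 15, 30),
    delay_max_s = ifelse(model == "V9", 45, 90),
    censor_date = as.Date(NA),
    stringsAsFactors = FALSE)
}

# Is calendar date d inside a tag's annual activity window (MMDD ints)
# and within battery life from implantation?
tag_active_on <- function(d, tags) {
  md <- month_of(d) * 100L + as.integer(format(d, "%d"))
  implant_d <- est_date(tags$implant_time)
  in_window <- md >= tags$active_start_md & md <= tags$active_end_md
  # V13 battery budget is spread over three seasonal windows; model it as a
  # 3-year horizon. V9 runs continuously from implantation.
  horizon <- ifelse(tags$tag_model == "V13", 3 * 365.25, tags$battery_days)
  alive <- d >= implant_d & as.numeric(d - implant_d) <= horizon
  not_censored <- is.na(tags$censor_date) | d <= tags$censor_date
  in_window & alive & not_censored
}
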