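#' Collapse hourly positions to daily zone presence
#'
#' One row per (tag, date, zone) with any zone-labelled hourly position
#' on that local date. The spawning-site flag marks zones 2-3.
#'
#' @param positions zone-labelled position table from
#'   [estimate_positions()].
#' @return data.frame `tag_id`, `date`, `zone`, `spawning_site`.
#' @export
daily_presence <- function(positions) {
  stopifnot("zone" %in% names(positions))
  d <- unique(data.frame(tag_id = positions$tag_id,
                         date = est_date(positions$bin_start),
                         zone = positions$zone))
  d$spawning_site <- d$zone %in% c(2L, 3L)
  d <- d[order(d$tag_id, d$date, d$zone), ]
  rownames(d) <- NULL
  d
}

#' Residence index from days detected and a detection span
#'
#' `TP` is the total period of detection, counted inclusively from the
#' first to the last detection date (`last - first + 1`); `RI` is the
#' residence index `100 * DD / TP` where `DD` is the number of distinct
#' detection dates.
#'
#' @param dd days detected.
#' @param first_date,last_date first and last detection dates.
#' @return data.frame with `tp` (days) and `ri` (percent, unrounded).
#' @export
residence_index <- function(dd, first_date, last_date) {
  tp <- as.integer(as.Date(last_date) - as.Date(first_date)) + 1L
  data.frame(tp = tp, ri = 100 * dd / tp)
}

#' Per fish-year residence summary
#'
#' Summarizes a daily presence table into one row per (tag, year, scope),
#' where scope is the whole array or the spawning site (zones 2-3): first
#' and last detection dates, days detected (DD), total period (TP,
#' inclusive span) and residence index (RI = 100*DD/TP). `ri` is rounded
#' to one decimal for display; `ri_raw` keeps full precision. Fish are
#' flagged eligible when detected on at least `min_dates` dates.
#'
#' @param daily daily presence table from [daily_presence()].
#' @param min_dates eligibility threshold on DD.
#' @return data.frame `tag_id`, `year`, `scope`, `first_date`,
#'   `last_date`, `dd`, `tp`, `ri`, `ri_raw`, `eligible`.
#' @export
residence_summary <- function(daily, min_dates = 5) {
  stopifnot(nrow(daily) > 0)
  one_scope <- function(d, scope) {
    if (nrow(d) == 0) return(NULL)
    dd <- unique(d[c("tag_id", "date")])
    dd$year <- year_of(dd$date)
    agg <- aggregate(date ~ tag_id + year, dd, function(x)
      c(first = min(x), last = max(x), n = length(unique(x))))
    m <- agg$date
    out <- data.frame(tag_id = agg$tag_id, year = agg$year, scope = scope,
                      first_date = as.Date(m[, "first"],
                                           origin = "1970-01-01"),
                      last_date = as.Date(m[, "last"], origin = "1970-01-01"),
                      dd = as.integer(m[, "n"]))
    ri <- residence_index(out$dd, out$first_date, out$last_date)
    out$tp <- ri$tp
    out$ri <- round(ri$ri, 1)
    out$ri_raw <- ri$ri
    out$eligible <- out$dd >= min_dates
    out
  }
  res <- rbind(one_scope(daily, "array"),
               one_scope(daily[daily$spawning_site, , drop = FALSE],
                         "spawning_site"))
  res <- res[order(res$scope, res$year, res$tag_id), ]
  rownames(res) <- NULL
  res
}

#' Correlation between whole-array and spawning-site residence indices
#'
#' Pairs RI over the two scopes by fish-year and reports the Pearson
#' correlation over eligible pairs. Eligibility follows the spawning-site
#' days-detected threshold (`min_dates`, default 4, which reproduces the
#' published 38-pair set).
#'
#' @param residences a [residence_summary()]-shaped table, or the
#'   packaged fixture via [load_table1_fixture()] reshaped with
#'   [table1_to_residences()].
#' @param min_dates minimum spawning-site DD for a pair to enter.
#' @return list with `r` (Pearson), `n` (pairs), `p_value`.
#' @export
ri_correlation <- function(residences, min_dates = 4) {
  a <- residences[residences$scope == "array", ]
  s <- residences[residences$scope == "spawning_site", ]
  m <- merge(a, s, by = c("tag_id", "year"), suffixes = c("_a", "_ss"))
  m <- m[!is.na(m$ri_a) & !is.na(m$ri_ss) & m$dd_ss >= min_dates, ]
  ct <- cor.test(m$ri_a, m$ri_ss, method = "pearson")
  list(r = unname(ct$estimate), n = nrow(m), p_value = ct$p.value)
}

#' Reshape the packaged residence fixture to summary form
#'
#' @param t1 fixture table from [load_table1_fixture()].
#' @return long residence table matching [residence_summary()] columns.
#' @export
table1_to_residences <- function(t1 = load_table1_fixture()) {
  rbind(
    data.frame(tag_id = as.character(t1$tag), year = t1$year,
               scope = "array", first_date = t1$first_a,
               last_date = t1$last_a, dd = t1$dd_a, tp = t1$tp_a,
               ri = t1$ri_a, ri_raw = t1$ri_a,
               eligible = !is.na(t1$dd_a) & t1$dd_a >= 5),
    data.frame(tag_id = as.character(t1$tag), year = t1$year,
               scope = "spawning_site", first_date = t1$first_ss,
               last_date = t1$last_ss, dd = t1$dd_ss, tp = t1$tp_ss,
               ri = t1$ri_ss, ri_raw = t1$ri_ss,
               eligible = !is.na(t1$dd_ss) & t1$dd_ss >= 5))
}

#' Mann-Whitney rank test between two samples
#'
#' U statistic with midrank handling of ties and a two-sided p-value from
#' the tie-corrected normal approximation (no continuity correction).
#' Both orientations of U are reported (`u + u_other = n1*n2`).
#'
#' @param x,y numeric samples.
#' @return list `u`, `u_other`, `n1`, `n2`, `p_normal_approx`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  u <- unname(wt$statistic)
  list(u = u, u_other = length(x) * length(y) - u,
       n1 = length(x), n2 = length(y),
       p_normal_approx = wt$p.value)
}

#' Year-by-zone relocation table
#'
#' Counts hourly position bins per year and zone, with row-normalized
#' proportions (3 decimals for display, matching the published layout).
#'
#' @param positions zone-labelled position table.
#' @return list with integer matrix `counts` (years x zones), matrix
#'   `proportions`, and `totals` per year.
#' @export
zone_relocation_table <- function(positions) {
  stopifnot("zone" %in% names(positions))
  yr <- year_of(est_date(positions$bin_start))
  counts <- table(factor(yr), factor(positions$zone, levels = 1:7))
  counts <- unclass(counts)
  storage.mode(counts) <- "integer"
  props <- round(counts / rowSums(counts), 3)
  list(counts = counts, proportions = props, totals = rowSums(counts))
}

#' Chi-square test of detections against expected zone proportions
#'
#' @param counts vector of per-zone totals (>= 2 cells).
#' @param expected_props expected proportions (default equal).
#' @return list `statistic`, `df`, `p_value`.
#' @export
chisq_equal_distribution <- function(counts,
                                     expected_props = rep(1 / length(counts),
                                                          length(counts))) {
  stopifnot(length(counts) >= 2, all(counts >= 0))
  ht <- suppressWarnings(chisq.test(counts, p = expected_props))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Daily proportion of tagged fish relocated, by zone group
#'
#' For every study date: the fraction of active, uncensored tags detected
#' in the spawning site (zones 2-3) and in non-spawning-site zones (4-7).
#' The denominator counts tags whose annual duty cycle and battery window
#' cover the date and that are not yet censored. Lunar phase is attached
#' per date.
#'
#' @param daily daily presence table ([daily_presence()]).
#' @param tags tag metadata.
#' @param dates optional `Date` vector of output dates (default: span of
#'   `daily`).
#' @return data.frame `date`, `n_active`, `prop_spawning_site`,
#'   `prop_other`, `lunar_deg`.
#' @export
relocation_proportion_series <- function(daily, tags, dates = NULL) {
  if (is.null(dates))
    dates <- seq(min(daily$date), max(daily$date), by = "day")
  act <- vapply(dates, function(d) sum(tag_active_on(d, tags)), 0)
  ss <- daily[daily$spawning_site, ]
  ot <- daily[daily$zone %in% 4:7, ]
  n_ss <- vapply(dates, function(d)
    length(unique(ss$tag_id[ss$date == d])), 0)
  n_ot <- vapply(dates, function(d)
    length(unique(ot$tag_id[ot$date == d])), 0)
  data.frame(date = dates, n_active = as.integer(act),
             prop_spawning_site = ifelse(act > 0, n_ss / act, 0),
             prop_other = ifelse(act > 0, n_ot / act, 0),
             lunar_deg = lunar_phase(dates))
}

#' Per-fish monthly zone profile
#'
#' Proportion of daily zone relocations by zone for each (tag, month);
#' proportions sum to 1 within months having any detection.
#'
#' @param daily daily presence table.
#' @return data.frame `tag_id`, `year`, `month`, `zone`, `prop`, `n`.
#' @export
monthly_zone_profile <- function(daily) {
  d <- daily
  d$year <- year_of(d$date)
  d$month <- month_of(d$date)
  agg <- aggregate(list(n = rep(1, nrow(d))),
                   d[c("tag_id", "year", "month", "zone")], sum)
  tot <- aggregate(list(tot = agg$n), agg[c("tag_id", "year", "month")], sum)
  m <- merge(agg, tot)
  m$prop <- m$n / m$tot
  m <- m[order(m$tag_id, m$year, m$month, m$zone),
         c("tag_id", "year", "month", "zone", "prop", "n")]
  rownames(m) <- NULL
  m
}
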