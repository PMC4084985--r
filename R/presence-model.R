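SYNODIC_DAYS <- 29.530588853
# reference new moon: 2000-01-06 18:14 UTC
LUNAR_EPOCH <- as.POSIXct("2000-01-06 18:14:00", tz = "UTC")

#' Lunar phase as a continuous 0-360 degree covariate
#'
#' Mean-synodic-month phase angle: 0/360 at new moon, 180 at full moon.
#' Computed as `360 * ((days since the 2000-01-06 18:14 UTC new moon)
#' mod 29.530588853) / 29.530588853`, evaluated at local noon (EST) of
#' the date. Accurate to within a few degrees of almanac lunations over
#' the supported 1990-2050 span.
#'
#' @param date `Date` vector (or coercible).
#' @return numeric degrees in `[0, 360)`.
#' @export
lunar_phase <- function(date) {
  date <- as.Date(date)
  if (any(!is.na(date) & (date < as.Date("1990-01-01") |
                          date > as.Date("2050-12-31"))))
    stop("date outside supported 1990-2050 span")
  t <- as.POSIXct(paste(date, "12:00:00"), tz = EST_TZ)
  d <- as.numeric(difftime(t, LUNAR_EPOCH, units = "days"))
  360 * ((d %% SYNODIC_DAYS) / SYNODIC_DAYS)
}

#' Build daily presence records for the spawning-site model
#'
#' One record per active, uncensored tag per spawning-season date
#' (April-September) inside `dates`: `present = 1` iff the tag has at
#' least one hourly position in the spawning-site zones with bin start
#' within the diel spawning window (default 1400-2000 h, half-open).
#' Sex, sex-specific size (total length centered within sex), day of
#' year, lunar phase and year are attached.
#'
#' @param positions zone-labelled hourly positions
#'   ([estimate_positions()]).
#' @param tags tag metadata.
#' @param dates `Date` vector of candidate dates (default: span of
#'   `positions`).
#' @param window integer hours `c(from, to)`, half-open `[from, to)`.
#' @param zones spawning-site zones.
#' @param season_months months retained (April-September).
#' @return data.frame `tag_id`, `date`, `present`, `sex`,
#'   `total_length_mm`, `size_m`, `size_f`, `doy`, `lunar_deg`, `year`.
#' @export
build_presence_records <- function(positions, tags, dates = NULL,
                                   window = c(14, 20), zones = c(2L, 3L),
                                   season_months = 4:9) {
  stopifnot("zone" %in% names(positions))
  if (is.null(dates)) {
    d0 <- est_date(positions$bin_start)
    dates <- seq(min(d0), max(d0), by = "day")
  }
  dates <- dates[month_of(dates) %in% season_months]
  hr <- as.integer(format(positions$bin_start, tz = EST_TZ, "%H"))
  hit <- positions[positions$zone %in% zones &
                   hr >= window[1] & hr < window[2], ]
  hit_key <- unique(paste(hit$tag_id, est_date(hit$bin_start)))
  out <- list()
  for (i in seq_len(nrow(tags))) {
    tg <- tags[i, ]
    act <- dates[tag_active_on(dates, tg) &
                 dates >= est_date(tg$implant_time)]
    if (length(act) == 0) next
    out[[length(out) + 1]] <- data.frame(
      tag_id = tg$tag_id, date = act,
      present = as.integer(paste(tg$tag_id, act) %in% hit_key),
      sex = tg$sex, total_length_mm = tg$total_length_mm)
  }
  rec <- do.call(rbind, out)
  if (is.null(rec) || nrow(rec) == 0)
    stop("no active tag-dates in the requested range")
  rec$sex <- factor(rec$sex, levels = c("F", "M"))
  mu <- tapply(rec$total_length_mm, rec$sex, mean)
  rec$size_m <- ifelse(rec$sex == "M",
                       rec$total_length_mm - mu["M"], 0)
  rec$size_f <- ifelse(rec$sex == "F",
                       rec$total_length_mm - mu["F"], 0)
  rec$doy <- doy_of(rec$date)
  rec$lunar_deg <- lunar_phase(rec$date)
  rec$year <- year_of(rec$date)
  rownames(rec) <- NULL
  rec
}

#' Cyclic cubic regression spline basis
#'
#' Evaluates a cyclic cubic regression spline basis with `n_knots`
#' evenly spaced knots over `[0, period]`, together with its
#' second-derivative roughness penalty. Inputs are wrapped modulo the
#' period, so rows for `x` and `x + period` are identical and the fitted
#' function matches in value and first derivative at the period ends.
#'
#' @param x evaluation points.
#' @param period cycle length (365.25 for day of year, 360 for lunar
#'   phase).
#' @param n_knots number of knots (>= 4).
#' @return list with `basis` (matrix, `length(x)` rows), `penalty`
#'   (symmetric non-negative-definite matrix) and `knots`.
#' @export
cyclic_basis <- function(x, period, n_knots = 10) {
  stopifnot(n_knots >= 4, period > 0)
  xw <- x %% period
  knots <- seq(0, period, length.out = n_knots)
  sm <- mgcv::smoothCon(mgcv::s(xx, bs = "cc", k = n_knots),
                        data = data.frame(xx = xw),
                        knots = list(xx = knots),
                        absorb.cons = FALSE)[[1]]
  list(basis = sm$X, penalty = sm$S[[1]], knots = sm$xp)
}

#' Fit the binomial additive mixed model of spawning-site presence
#'
#' Penalized-likelihood fit of
#' `present ~ sex + size_m + size_f + s(doy, cc) + s(lunar, cc) +
#'  (1 | tag)` with a logit link: cyclic cubic regression splines for day
#' of year (period 365.25) and lunar phase (period 360), sex-specific
#' linear size slopes, and a per-fish random intercept in its
#' mixed-model (ridge) representation. Smoothing parameters and the
#' random-intercept variance are selected by REML. Approximate Wald
#' p-values per term come from the mgcv summary.
#'
#' @param records presence records from [build_presence_records()] or
#'   [simulate_presence_records()].
#' @param knots_doy,knots_lunar basis dimensions of the two cyclic
#'   smooths.
#' @param use_size include the sex-specific size slopes (dropped
#'   automatically when sizes are constant within sex).
#' @return object of class `presence_fit`: list with `gam` (the mgcv
#'   fit), `sex_contrast` (+/- SE), `random_intercept_sd`, `edf`,
#'   `p_values`, `separation` flag and `n`.
#' @export
fit_binomial_amm <- function(records, knots_doy = 10, knots_lunar = 8,
                             use_size = TRUE) {
  stopifnot(all(records$present %in% 0:1))
  if (length(unique(records$present)) < 2)
    stop("both outcome classes required")
  rec <- records
  rec$sex <- factor(rec$sex, levels = c("F", "M"))
  if (length(unique(rec$tag_id[rec$sex == "M"])) < 2 ||
      length(unique(rec$tag_id[rec$sex == "F"])) < 2)
    stop("need at least two fish of each sex")
  rec$tag_f <- factor(rec$tag_id)
  if (!all(c("size_m", "size_f") %in% names(rec))) {
    mu <- tapply(rec$total_length_mm, rec$sex, mean)
    rec$size_m <- ifelse(rec$sex == "M", rec$total_length_mm - mu["M"], 0)
    rec$size_f <- ifelse(rec$sex == "F", rec$total_length_mm - mu["F"], 0)
  }
  sizes_ok <- use_size && sd(rec$size_m) > 0 && sd(rec$size_f) > 0
  fixed <- if (sizes_ok) "sex + size_m + size_f" else "sex"
  fml <- as.formula(paste(
    "present ~", fixed,
    "+ s(doy, bs = 'cc', k =", knots_doy, ")",
    "+ s(lunar_deg, bs = 'cc', k =", knots_lunar, ")",
    "+ s(tag_f, bs = 're')"))
  # complete-separation screen: a sex with all-0 or all-1 outcomes
  tab <- table(rec$sex, rec$present)
  separation <- any(tab == 0)
  fit <- mgcv::gam(fml, family = binomial(), data = rec, method = "REML",
                   knots = list(doy = c(0, 365.25), lunar_deg = c(0, 360)))
  sm <- summary(fit)
  b <- coef(fit)
  re_i <- grep("^s\\(tag_f\\)", names(b))
  sex_i <- which(names(b) == "sexM")
  pt <- sm$s.table[, "p-value"]
  names(pt) <- rownames(sm$s.table)
  pv <- c(sm$p.table[, "Pr(>|z|)"], pt)
  structure(list(
    gam = fit,
    sex_contrast = unname(b[sex_i]),
    sex_contrast_se = sqrt(diag(vcov(fit)))[sex_i],
    random_intercept_sd = if (length(re_i)) sd(b[re_i]) else 0,
    edf = setNames(sm$s.table[, "edf"], rownames(sm$s.table)),
    p_values = pv,
    separation = separation,
    converged = fit$converged,
    n = nrow(rec)), class = "presence_fit")
}

#' Population-level presence predictions
#'
#' Inverse-logit predictions with the per-fish random intercept set to
#' zero (the random-effect smooth is excluded from the linear predictor).
#'
#' @param fit a `presence_fit`.
#' @param covariates data.frame with `sex`, `doy`, `lunar_deg` (and
#'   `size_m`, `size_f`, defaulting to 0).
#' @return numeric probabilities in (0, 1).
#' @export
predict_presence <- function(fit, covariates) {
  nd <- covariates
  if (!"size_m" %in% names(nd)) nd$size_m <- 0
  if (!"size_f" %in% names(nd)) nd$size_f <- 0
  nd$sex <- factor(nd$sex, levels = c("F", "M"))
  nd$tag_f <- factor(fit$gam$model$tag_f[1],
                     levels = levels(fit$gam$model$tag_f))
  as.numeric(predict(fit$gam, newdata = nd, type = "response",
                     exclude = "s(tag_f)"))
}

#' Evaluate a fitted cyclic smooth on a grid
#'
#' @param fit a `presence_fit`.
#' @param term `"doy"` or `"lunar_deg"`.
#' @param n grid size.
#' @return data.frame `x`, `value` (link-scale smooth contribution).
#' @export
smooth_curve <- function(fit, term = c("doy", "lunar_deg"), n = 361) {
  term <- match.arg(term)
  period <- if (term == "doy") 365.25 else 360
  grid <- seq(0, period, length.out = n)
  nd <- data.frame(doy = if (term == "doy") grid else 180,
                   lunar_deg = if (term == "lunar_deg") grid else 90,
                   sex = factor("F", levels = c("F", "M")),
                   size_m = 0, size_f = 0,
                   tag_f = factor(fit$gam$model$tag_f[1],
                                  levels = levels(fit$gam$model$tag_f)))
  pm <- predict(fit$gam, newdata = nd, type = "terms")
  col <- grep(term, colnames(pm), fixed = TRUE)
  data.frame(x = grid, value = as.numeric(pm[, col]))
}
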