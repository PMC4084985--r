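#' @importFrom stats aggregate coef cor.test chisq.test lm glm predict
#'   quantile rbinom rlnorm rnorm rpois runif rt sd setNames plogis qlogis pnorm
#'   binomial vcov AIC as.formula median complete.cases wilcox.test
#' @importFrom utils read.csv write.csv head
NULL

# Fixed-offset Eastern Standard Time, year-round (no DST). "Etc/GMT+5" is
# the POSIX sign convention for UTC-5.
EST_TZ <- "Etc/GMT+5"

#' Parse timestamps in fixed-offset Eastern Standard Time
#'
#' Accepts ISO-8601 (`2007-06-14 15:30:00`) and US-style
#' (`6/14/2007 15:30:00`) timestamps. All times are interpreted as EST
#' (UTC-5) year-round with no daylight-saving adjustment, so hour binning
#' is reproducible across the season.
#'
#' @param x character vector of timestamps.
#' @return `POSIXct` vector in the `Etc/GMT+5` timezone; `NA` where
#'   unparseable.
#' @export
parse_est <- function(x) {
  x <- as.character(x)
  fmts <- c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d", "%m/%d/%Y %H:%M:%OS", "%m/%d/%Y %H:%M", "%m/%d/%Y")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = EST_TZ)
  for (f in fmts) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(x[miss], format = f, tz = EST_TZ)
  }
  out
}

#' Parse dates, accepting ISO and M/D/YYYY
#'
#' @param x character vector of dates.
#' @return `Date` vector.
#' @export
parse_date_flex <- function(x) {
  x <- as.character(x)
  out <- as.Date(rep(NA_character_, length(x)))
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  us <- !iso & grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x)
  out[us] <- as.Date(x[us], format = "%m/%d/%Y")
  out
}

# Floor a POSIXct to its clock-aligned hourly bin start [HH:00, HH+1:00).
hour_floor <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 3600) * 3600,
             origin = "1970-01-01", tz = EST_TZ)
}

# Local (EST) calendar date of a timestamp. EST is a fixed UTC-5 offset,
# so the date is pure arithmetic on epoch seconds (no tz formatting).
est_date <- function(t) {
  if (inherits(t, "Date")) return(t)
  as.Date(floor((as.numeric(t) - 5 * 3600) / 86400), origin = "1970-01-01")
}

# Day of year / year helpers on Date input.
doy_of <- function(d) as.integer(format(d, "%j"))
year_of <- function(d) as.integer(format(d, "%Y"))
month_of <- function(d) as.integer(format(d, "%m"))

# Spawning season: April through September.
in_spawning_season <- function(d) month_of(d) >= 4L & month_of(d) <= 9L

# Derive a 32-bit safe child seed from a master seed and a stream index.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + 7919 * as.numeric(k)) %% 2147483647)
}
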