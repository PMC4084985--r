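#' Read a detection table from CSV
#'
#' Parses a receiver-export-style CSV holding one row per received
#' transmitter ping. Column names are matched case-insensitively against
#' common aliases (`timestamp`/`datetime`/`date_time`, `receiver`/
#' `receiver_id`, `transmitter`/`tag`/`tag_id`). Timestamps are interpreted
#' as fixed-offset EST (UTC-5, no daylight saving) and the table is sorted
#' by tag then time.
#'
#' @param path path to a CSV file with a header row.
#' @param deployments receiver deployment table (see
#'   [default_deployments()]); detections on receivers absent from it are
#'   a hard error.
#' @return `data.frame` with columns `tag_id` (character), `receiver_id`
#'   (integer) and `timestamp` (POSIXct, EST), sorted by `(tag_id,
#'   timestamp)`.
#' @export
read_detections <- function(path, deployments) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(raw))
  pick <- function(aliases, what) {
    i <- which(nm %in% aliases)
    if (length(i) == 0)
      stop("no column for ", what, " in ", path, call. = FALSE)
    raw[[i[1]]]
  }
  ts_raw <- pick(c("timestamp", "datetime", "date_time", "date and time"),
                 "timestamp")
  recv <- pick(c("receiver", "receiver_id", "vr2"), "receiver")
  tag <- pick(c("transmitter", "tag", "tag_id"), "transmitter")
  ts <- parse_est(ts_raw)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    stop("malformed timestamp on data row(s) ",
         paste(head(bad, 5), collapse = ", "),
         " (e.g. '", ts_raw[bad[1]], "')", call. = FALSE)
  }
  recv <- as.integer(recv)
  unknown <- setdiff(unique(recv), deployments$receiver_id)
  if (length(unknown) > 0)
    stop("unknown receiver_id: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- data.frame(tag_id = as.character(tag), receiver_id = recv,
                    timestamp = ts, stringsAsFactors = FALSE)
  out[order(out$tag_id, out$timestamp, out$receiver_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Write any pipeline table to CSV
#'
#' RFC-4180 CSV with a header row; timestamps are serialized in EST and
#' dates in ISO-8601 so that a write/read round trip is lossless.
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  y <- x
  for (j in seq_along(y)) {
    if (inherits(y[[j]], "POSIXct"))
      y[[j]] <- format(y[[j]], tz = EST_TZ, "%Y-%m-%d %H:%M:%S")
    else if (inherits(y[[j]], "Date"))
      y[[j]] <- format(y[[j]], "%Y-%m-%d")
  }
  write.csv(y, path, row.names = FALSE)
  invisible(path)
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "spawnsite")
  if (p == "") p <- file.path("inst", "extdata", file)  # pre-install use
  p
}

#' Packaged per-fish-year residence summary fixture
#'
#' The printed per-fish-year relocation summary for the 30 tagged fish:
#' days detected (DD), first/last detection dates, total period (TP) and
#' residence index (RI) for the whole array (`_a`) and the spawning site
#' (`_ss`, zones 2-3). 46 rows: 30 fish-years in 2007, 9 in 2008, 7 in
#' 2009. Fish that died in 2009 carry `censored = TRUE` and `NA` metrics.
#'
#' @return `data.frame` with columns `year`, `tag`, `tl_mm`, `sex`,
#'   `dd_a`, `first_a`, `last_a`, `tp_a`, `ri_a`, `dd_ss`, `first_ss`,
#'   `last_ss`, `tp_ss`, `ri_ss`, `multiyear`, `censored`.
#' @export
load_table1_fixture <- function() {
  x <- read.csv(fixture_path("table1_residence.csv"),
                stringsAsFactors = FALSE, na.strings = ".")
  for (col in c("first_a", "last_a", "first_ss", "last_ss"))
    x[[col]] <- parse_date_flex(x[[col]])
  for (col in c("dd_a", "tp_a", "dd_ss", "tp_ss"))
    x[[col]] <- as.integer(x[[col]])
  x$sex <- factor(x$sex, levels = c("F", "M"))
  x
}

#' Packaged year-by-zone relocation count fixture
#'
#' Hourly-bin relocation counts of all tagged fish by year (2007-2009)
#' and detection zone (1-7), as printed. Zones 2-3 are the spawning site.
#'
#' @param long if `TRUE` return the long `(year, zone, count)` form;
#'   otherwise a 3 x 7 year-by-zone matrix.
#' @return data.frame or integer matrix.
#' @export
load_table2_fixture <- function(long = FALSE) {
  x <- read.csv(fixture_path("table2_relocations.csv"))
  if (long) return(x)
  m <- with(x, tapply(count, list(year, zone), sum))
  storage.mode(m) <- "integer"
  m
}
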