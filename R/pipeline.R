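#' Default pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]: seeds, synthetic
#' truths, array geometry, model windows and hyperparameters. Any element
#' can be overridden via `...`.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed for every stochastic stage.
#' @param ... overrides for individual elements.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "results", seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = seed,
    survey_truth = survey_truth(),
    survey_n_grids = 100,
    survey_hauls_per_month = 10,
    telemetry_truth = telemetry_truth(),
    tags = make_tags(n_v9 = 20, n_v13 = 11),
    date_range = as.Date(c("2007-06-14", "2007-09-30")),
    window = c(14, 20),
    zones = c(2L, 3L),
    knots_doy = 10,
    knots_lunar = 8,
    kde_bandwidth = 2 * 1852,
    kde_contour = 0.5,
    n_draws = 10000)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), f)
  unname(tools::md5sum(f))
}

write_stage <- function(x, path, hash, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# spawnsite config_hash=%s seed=%d", hash, seed), con)
  close(con)
  y <- x
  for (j in seq_along(y)) {
    if (inherits(y[[j]], "POSIXct"))
      y[[j]] <- format(y[[j]], tz = EST_TZ, "%Y-%m-%d %H:%M:%S")
    else if (inherits(y[[j]], "Date"))
      y[[j]] <- format(y[[j]], "%Y-%m-%d")
  }
  suppressWarnings(write.table(y, path, sep = ",", row.names = FALSE,
                               append = TRUE, qmethod = "double"))
  path
}

#' Read a stage output written by [run_pipeline()]
#'
#' @param path CSV path with a provenance comment header.
#' @return data.frame; attribute `provenance` carries the header line.
#' @export
read_stage <- function(path) {
  hdr <- readLines(path, n = 1)
  x <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(x, "provenance") <- hdr
  x
}

#' Run the full synthetic analysis pipeline
#'
#' Stages: simulate the survey and telemetry streams, process detections
#' (spurious filter, post-release split, censoring, positions, zones,
#' control audit), compute residence metrics and relocation tables, fit
#' the presence model, and standardize survey catch rates. All stage
#' outputs are written to `config$out_dir` as CSV with a provenance
#' header (config hash + seed); a JSON manifest lists the artifacts.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return (invisibly) list with the manifest and in-memory stage
#'   results.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed
  say <- function(...) if (!quiet) message(sprintf(...))
  art <- character()
  put <- function(x, name) {
    p <- file.path(config$out_dir, name)
    write_stage(x, p, hash, seed)
    art[[length(art) + 1]] <<- p
    p
  }

  say("stage 1/5: simulating survey and telemetry")
  sv <- simulate_survey(config$survey_truth, config$survey_n_grids,
                        hauls_per_month = config$survey_hauls_per_month,
                        seed = seed)
  put(sv$hauls, "hauls.csv")
  dep <- default_deployments()
  zm <- default_zone_map()
  tel <- simulate_telemetry(config$telemetry_truth, dep, config$tags,
                            default_control_tags(), config$date_range,
                            seed = seed)
  put(tel$detections, "detections.csv")
  say("  %d hauls, %d detections", nrow(sv$hauls), nrow(tel$detections))

  say("stage 2/5: processing telemetry")
  fs <- filter_spurious(tel$detections, dep)
  say("  spurious filter: %d in -> %d kept + %d removed",
      nrow(tel$detections), nrow(fs$kept), nrow(fs$removed))
  fish_det <- fs$kept[fs$kept$tag_id %in% config$tags$tag_id, ]
  sp <- split_post_release(fish_det, config$tags)
  say("  post-release split: %d post-release, %d study",
      nrow(sp$post_release), nrow(sp$study))
  study <- apply_censoring(sp$study, config$tags)
  pos <- estimate_positions(study, dep, zone_map = zm)
  put(pos, "positions.csv")
  ctl_det <- fs$kept[fs$kept$tag_id %in% default_control_tags()$control_id, ]
  audit <- audit_control_tags(ctl_det, default_control_tags(), dep)
  if (!is.null(audit)) put(audit, "control_audit.csv")

  say("stage 3/5: residence metrics")
  daily <- daily_presence(pos)
  res <- residence_summary(daily)
  put(res, "residence_summary.csv")
  zrt <- zone_relocation_table(pos)
  put(render_zone_table(zrt), "zone_relocations.csv")
  ser <- relocation_proportion_series(daily, config$tags)
  put(ser, "relocation_series.csv")

  say("stage 4/5: presence model")
  rec <- build_presence_records(pos, config$tags, window = config$window,
                                zones = config$zones)
  pf <- fit_binomial_amm(rec, config$knots_doy, config$knots_lunar)
  put(data.frame(term = names(pf$p_values), p_value = pf$p_values),
      "presence_model_terms.csv")
  put(smooth_curve(pf, "doy"), "smooth_doy.csv")
  put(smooth_curve(pf, "lunar_deg"), "smooth_lunar.csv")

  say("stage 5/5: CPUE standardization")
  cls <- kde_region_classify(sv$hauls, config$kde_bandwidth,
                             config$kde_contour)
  put(as.data.frame(cls), "regions.csv")
  hauls_r <- apply_region(sv$hauls, cls)
  hf <- fit_hurdle_stepwise(hauls_r)
  idx <- combine_monte_carlo(marginal_means(hf$binomial$model),
                             marginal_means(hf$lognormal$model),
                             sigma2 = hf$sigma2,
                             n_draws = config$n_draws, seed = seed)
  put(idx$summary, "index_summary.csv")

  manifest <- list(config_hash = hash, seed = seed,
                   package_version = as.character(
                     utils::packageVersion("spawnsite")),
                   artifacts = unlist(art))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, survey = sv, telemetry = tel,
                 positions = pos, residence = res, zone_table = zrt,
                 presence_fit = pf, hurdle = hf, index = idx,
                 audit = audit, series = ser))
}

#' Render a year-by-zone relocation table in the published layout
#'
#' Counts with row-normalized proportions (3 decimals) and year totals,
#' plus an all-years total row.
#'
#' @param zrt output of [zone_relocation_table()].
#' @return data.frame with `year`, one column per zone count, `total`
#'   and per-zone proportion columns.
#' @export
render_zone_table <- function(zrt) {
  cnt <- zrt$counts
  tot_row <- colSums(cnt)
  cnt_all <- rbind(cnt, Total = tot_row)
  props <- round(cnt_all / rowSums(cnt_all), 3)
  out <- data.frame(year = rownames(cnt_all), cnt_all,
                    total = rowSums(cnt_all),
                    check.names = FALSE)
  names(out)[2:8] <- paste0("zone", 1:7)
  prop_df <- as.data.frame(props)
  names(prop_df) <- paste0("prop_zone", 1:7)
  cbind(out, prop_df)
}

#' Render a per-fish-year residence table in the published layout
#'
#' Wide per-fish-year rows with DD, first/last date, TP and RI for the
#' whole array and the spawning site.
#'
#' @param residences [residence_summary()] output.
#' @param tags optional tag metadata to attach sex and size.
#' @return data.frame, one row per fish-year.
#' @export
render_residence_table <- function(residences, tags = NULL) {
  a <- residences[residences$scope == "array", ]
  s <- residences[residences$scope == "spawning_site", ]
  m <- merge(a, s, by = c("tag_id", "year"), suffixes = c("_a", "_ss"),
             all.x = TRUE)
  out <- data.frame(year = m$year, tag = m$tag_id,
                    dd_a = m$dd_a, first_a = m$first_date_a,
                    last_a = m$last_date_a, tp_a = m$tp_a, ri_a = m$ri_a,
                    dd_ss = m$dd_ss, first_ss = m$first_date_ss,
                    last_ss = m$last_date_ss, tp_ss = m$tp_ss,
                    ri_ss = m$ri_ss)
  if (!is.null(tags)) {
    i <- match(out$tag, tags$tag_id)
    out <- cbind(out[1:2], tl_mm = tags$total_length_mm[i],
                 sex = tags$sex[i], out[-(1:2)])
  }
  out[order(out$year, out$tag), ]
}
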