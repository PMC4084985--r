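#' Bin a continuous covariate into fixed-width half-open bins
#'
#' Bins are `[k*width, (k+1)*width)`; a value on a boundary belongs to
#' the upper bin. Used to free temperature and salinity from a linear
#' constraint in the catch-rate models (2.5 degree C / 2.5 ppt bins).
#'
#' @param values numeric vector.
#' @param width bin width (> 0).
#' @return ordered factor whose labels are bin midpoints; attribute
#'   `breaks` holds the bin edges.
#' @export
bin_covariate <- function(values, width = 2.5) {
  stopifnot(width > 0)
  k <- floor(values / width)
  lev <- seq(min(k, na.rm = TRUE), max(k, na.rm = TRUE))
  f <- factor(k, levels = lev, labels = sprintf("%g", (lev + 0.5) * width),
              ordered = TRUE)
  attr(f, "breaks") <- c(lev, max(lev) + 1) * width
  f
}

#' Classify survey grids into concentrated vs other regions by KDE
#'
#' A two-dimensional Gaussian kernel density estimate over haul locations
#' (weighted by nominal CPUE, i.e. the adult count per haul, unless
#' `weighted = FALSE`, in which case only positive-catch locations enter
#' unweighted) is evaluated at each surveyed grid center. Grids inside
#' the highest-density region enclosing `contour_level` of the total
#' density mass are labelled concentrated.
#'
#' @param hauls haul table ([simulate_survey()]).
#' @param bandwidth kernel SD in meters (default two grid widths).
#' @param contour_level fraction of density mass enclosed (0-1).
#' @param weighted weight the KDE by adult count.
#' @return `data.frame` (class `region_classification`): `grid_id`, `x`,
#'   `y`, `density`, `region` (factor `not`/`concentrated`); attributes
#'   `bandwidth`, `contour_level`.
#' @export
kde_region_classify <- function(hauls, bandwidth = 2 * 1852,
                                contour_level = 0.5, weighted = TRUE) {
  if (all(hauls$adult_count == 0))
    stop("all hauls have zero catch; cannot classify regions")
  grids <- aggregate(cbind(x, y) ~ grid_id, hauls, mean)
  if (weighted) {
    src <- hauls[hauls$adult_count > 0, ]
    w <- src$adult_count
  } else {
    src <- hauls[hauls$adult_count > 0, ]
    w <- rep(1, nrow(src))
  }
  # edge-corrected weighted product-Gaussian KDE at the grid centers:
  # divide by the kernel mass falling inside the survey extent so that
  # grids near the boundary are not spuriously down-weighted
  xr <- range(hauls$x); yr <- range(hauls$y)
  edge <- function(g, lo, hi) pnorm(hi, g, bandwidth) - pnorm(lo, g, bandwidth)
  dens <- vapply(seq_len(nrow(grids)), function(g) {
    sum(w * exp(-((grids$x[g] - src$x)^2 + (grids$y[g] - src$y)^2) /
                  (2 * bandwidth^2))) /
      (edge(grids$x[g], xr[1], xr[2]) * edge(grids$y[g], yr[1], yr[2]))
  }, 0)
  if (contour_level >= 1) {
    # limiting contour: everything carrying any density mass
    conc <- dens > 0
  } else {
    ord <- order(dens, decreasing = TRUE)
    cum <- cumsum(dens[ord]) / sum(dens)
    k <- which(cum >= contour_level - 1e-12)[1]
    conc <- logical(nrow(grids))
    conc[ord[seq_len(k)]] <- TRUE
  }
  out <- data.frame(grid_id = grids$grid_id, x = grids$x, y = grids$y,
                    density = dens / sum(dens),
                    region = factor(ifelse(conc, "concentrated", "not"),
                                    levels = c("not", "concentrated")))
  attr(out, "bandwidth") <- bandwidth
  attr(out, "contour_level") <- contour_level
  class(out) <- c("region_classification", class(out))
  out
}

#' Attach region labels to hauls
#'
#' @param hauls haul table.
#' @param classification output of [kde_region_classify()].
#' @return hauls with a `region` factor column.
#' @export
apply_region <- function(hauls, classification) {
  hauls$region <- classification$region[match(hauls$grid_id,
                                              classification$grid_id)]
  hauls
}

# merge ordered-factor levels holding fewer than min_n observations into
# their populated neighbor (standard practice for binned covariates in
# CPUE standardization, where near-empty bins make cells unestimable)
lump_sparse_bins <- function(f, min_n = 10) {
  f <- droplevels(factor(f, ordered = TRUE))
  repeat {
    cnt <- table(f)
    if (length(cnt) <= 2 || min(cnt) >= min_n) break
    i <- which.min(cnt)
    j <- if (i == 1) 2 else if (i == length(cnt)) i - 1 else
      if (cnt[i - 1] <= cnt[i + 1]) i - 1 else i + 1
    lev <- levels(f)
    lev[i] <- lev[j]
    levels(f) <- lev
    f <- droplevels(f)
  }
  factor(as.character(f))
}

# model frame shared by the two hurdle submodels
hurdle_frame <- function(hauls, bin_width = 2.5, min_bin_n = 10) {
  stopifnot("region" %in% names(hauls))
  data.frame(
    presence = as.integer(hauls$adult_count > 0),
    count = hauls$adult_count,
    year = factor(hauls$year),
    month = factor(hauls$month),
    region = factor(hauls$region),
    season = factor(hauls$season),
    temp_bin = lump_sparse_bins(bin_covariate(hauls$temperature_c,
                                              bin_width), min_bin_n),
    sal_bin = lump_sparse_bins(bin_covariate(hauls$salinity_ppt,
                                             bin_width), min_bin_n),
    vegetation = factor(hauls$bottom_vegetation, levels = c(FALSE, TRUE),
                        labels = c("absent", "present")))
}

# one greedy forward-AIC pass; year always retained
forward_aic <- function(frame, response, fitter, candidates) {
  terms <- "year"
  fit <- fitter(paste(response, "~ year"), frame)
  aic <- AIC(fit)
  trace <- data.frame(step = 0L, added = "year", aic = aic)
  repeat {
    addable <- setdiff(candidates, terms)
    # month and season alias each other; interaction needs both parents
    if ("month" %in% terms) addable <- setdiff(addable, "season")
    if ("season" %in% terms) addable <- setdiff(addable, "month")
    if (!all(c("region", "season") %in% terms))
      addable <- setdiff(addable, "region:season")
    if (length(addable) == 0) break
    cand_fits <- lapply(addable, function(tm) {
      tryCatch(fitter(paste(response, "~", paste(c(terms, tm),
                                                 collapse = " + ")), frame),
               error = function(e) NULL)
    })
    ok <- !vapply(cand_fits, is.null, TRUE)
    if (!any(ok)) break
    aics <- rep(Inf, length(addable))
    aics[ok] <- vapply(cand_fits[ok], AIC, 0)
    best <- which.min(aics)
    if (aics[best] >= aic) break
    terms <- c(terms, addable[best])
    fit <- cand_fits[[best]]
    aic <- aics[best]
    trace <- rbind(trace, data.frame(step = nrow(trace),
                                     added = addable[best], aic = aic))
  }
  list(model = fit, terms = terms, aic = aic, trace = trace)
}

#' Fit the two-part hurdle model with forward-AIC selection
#'
#' Part 1 models the probability that a haul catches any adults
#' (binomial, logit link); part 2 models the log of the positive count
#' (Gaussian on the log scale, i.e. lognormal with identity link on the
#' log response). Each submodel starts from year-only (year is always
#' retained, to provide the annual index) and greedily adds the
#' candidate term that most reduces AIC until no addition reduces it.
#' Month and season are treated as aliases: whichever enters first
#' blocks the other. The region-by-season interaction is only offered
#' once both parents are in.
#'
#' @param hauls haul table with a `region` column (see
#'   [apply_region()]).
#' @param candidates candidate terms beyond year.
#' @param bin_width temperature/salinity bin width.
#' @param min_bin_n temperature/salinity bins with fewer hauls are pooled
#'   into their neighbor before fitting.
#' @return object of class `hurdle_fit`: list with `binomial` and
#'   `lognormal` sublists (`model`, `terms`, `aic`, `trace`), `frame`
#'   and `sigma2` (lognormal residual variance).
#' @export
fit_hurdle_stepwise <- function(hauls,
                                candidates = c("month", "region", "season",
                                               "region:season", "temp_bin",
                                               "sal_bin", "vegetation"),
                                bin_width = 2.5, min_bin_n = 10) {
  fr <- hurdle_frame(hauls, bin_width, min_bin_n)
  if (length(unique(fr$year)) < 2) stop("need at least two year levels")
  if (!any(fr$presence == 1) || !any(fr$presence == 0))
    stop("hurdle model needs both zero and positive hauls")
  bin <- forward_aic(fr, "presence",
                     function(f, d) glm(as.formula(f), binomial(), data = d),
                     candidates)
  pos_fr <- fr[fr$presence == 1, , drop = FALSE]
  pos_fr <- droplevels(pos_fr)
  pos_fr$logcount <- log(pos_fr$count)
  logn <- forward_aic(pos_fr, "logcount",
                      function(f, d) lm(as.formula(f), data = d),
                      candidates)
  structure(list(binomial = bin, lognormal = logn, frame = fr,
                 sigma2 = summary(logn$model)$sigma^2),
            class = "hurdle_fit")
}

#' Year-specific marginal means on the link scale
#'
#' Covariate-adjusted per-year estimates from a fitted submodel,
#' averaging predictions over a balanced reference grid (equal weight to
#' every level of every other factor), with standard errors from the
#' coefficient covariance and the submodel's residual degrees of
#' freedom.
#'
#' @param submodel a fitted `glm`/`lm` from [fit_hurdle_stepwise()]
#'   (e.g. `fit$binomial$model`).
#' @return data.frame `year`, `estimate`, `se`, `df` (link scale).
#' @export
marginal_means <- function(submodel) {
  em <- emmeans::emmeans(submodel, "year")
  s <- as.data.frame(em)
  est_col <- if ("emmean" %in% names(s)) "emmean" else "estimate"
  data.frame(year = as.character(s$year),
             estimate = s[[est_col]],
             se = s$SE,
             df = rep(stats::df.residual(submodel), nrow(s)))
}

#' Combine hurdle submodels into annual index distributions
#'
#' For each year, draws `n_draws` Student-t realizations around each
#' submodel's marginal mean (scaled by its SE, with the submodel's
#' residual df capped at 200), back-transforms (inverse logit for the
#' presence part; `exp(mu + sigma2/2)` lognormal mean correction for the
#' positive part) and multiplies the parts into standardized
#' fish-per-haul index draws.
#'
#' @param binomial_mm,lognormal_mm [marginal_means()] tables for the
#'   same set of years.
#' @param sigma2 lognormal submodel residual variance (0 disables the
#'   half-variance correction).
#' @param n_draws draws per year.
#' @param seed integer seed.
#' @param lognormal_correction apply the `exp(sigma2/2)` mean
#'   correction.
#' @return object of class `standardized_index`: list with `draws`
#'   (n_draws x years matrix) and `summary` (per-year mean, median,
#'   2.5/97.5 percentiles).
#' @export
combine_monte_carlo <- function(binomial_mm, lognormal_mm, sigma2 = 0,
                                n_draws = 10000, seed = 1,
                                lognormal_correction = TRUE) {
  if (!setequal(binomial_mm$year, lognormal_mm$year))
    stop("year sets differ between submodels")
  yrs <- sort(unique(binomial_mm$year))
  bi <- binomial_mm[match(yrs, binomial_mm$year), ]
  lo <- lognormal_mm[match(yrs, lognormal_mm$year), ]
  set.seed(child_seed(seed, 424243))
  corr <- if (lognormal_correction) sigma2 / 2 else 0
  draws <- sapply(seq_along(yrs), function(k) {
    b <- bi$estimate[k] + bi$se[k] * rt(n_draws, min(bi$df[k], 200))
    l <- lo$estimate[k] + lo$se[k] * rt(n_draws, min(lo$df[k], 200))
    plogis(b) * exp(l + corr)
  })
  colnames(draws) <- yrs
  summ <- data.frame(
    year = yrs,
    mean = colMeans(draws),
    median = apply(draws, 2, median),
    lwr = apply(draws, 2, quantile, 0.025),
    upr = apply(draws, 2, quantile, 0.975))
  structure(list(draws = draws, summary = summ),
            class = "standardized_index")
}
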