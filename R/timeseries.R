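#' A per-sampler darkening time series
#'
#' Ordered (exposure time, delta-PI) observations for one sampler. The first
#' point is the sampler's own baseline and must have `delta_pi = 0`;
#' original samplers start at exposure time 0, while a replacement sampler
#' (deployed mid-campaign to probe saturation) starts at its deployment time
#' on the campaign clock, still with `delta_pi = 0`.
#'
#' @param sampler_id,location_id Identifiers.
#' @param exposure_time Strictly increasing numeric vector of observation
#'   times (days in field mode, minutes in lab mode).
#' @param delta_pi Numeric vector of delta-PI values, same length.
#' @param role `"original"` or `"replacement"`.
#' @param time_unit Unit label carried on the series (`"days"` or
#'   `"minutes"`); rates are reported per this unit and never silently
#'   converted.
#' @return An object of class `delta_series`.
#' @export
#' @examples
#' delta_series("S1", "L1", c(0, 33, 55), c(0, -440, -720))
delta_series <- function(sampler_id, location_id, exposure_time, delta_pi,
                         role = c("original", "replacement"),
                         time_unit = "days") {
  role <- match.arg(role)
  if (length(exposure_time) != length(delta_pi)) {
    stop_input("exposure_time and delta_pi must have equal length.")
  }
  if (length(exposure_time) < 1L) stop_input("A series needs at least one point.")
  if (any(diff(exposure_time) <= 0)) {
    stop_input("exposure_time must be strictly increasing.")
  }
  if (delta_pi[1] != 0) {
    stop_input("The first (baseline) point of a series must have delta_pi 0.")
  }
  if (role == "original" && exposure_time[1] != 0) {
    stop_input("An original sampler's series must start at exposure time 0.")
  }
  structure(
    list(
      sampler_id = sampler_id, location_id = location_id, role = role,
      time_unit = time_unit,
      data = tibble(
        exposure_time = as.numeric(exposure_time),
        delta_pi = as.numeric(delta_pi)
      )
    ),
    class = "delta_series"
  )
}

#' @export
print.delta_series <- function(x, ...) {
  cat(sprintf(
    "<delta_series> sampler '%s' (%s) at location '%s': %d points over %g %s\n",
    x$sampler_id, x$role, x$location_id, nrow(x$data),
    diff(range(x$data$exposure_time)), x$time_unit
  ))
  invisible(x)
}

## delta_pi observed at exactly time t, or NA if the sampler was not imaged
## at t.
series_value_at <- function(series, t) {
  i <- which(series$data$exposure_time == t)
  if (length(i) == 0L) NA_real_ else series$data$delta_pi[i[1]]
}

#' Interval and whole-period rates of change in reflectance
#'
#' For each consecutive pair of observations, the rate
#' `(delta_pi[i+1] - delta_pi[i]) / (t[i+1] - t[i])` in PI per time unit,
#' plus the whole-period rate (last minus first observation over the total
#' elapsed time). Rates are negative while the sampler darkens.
#'
#' @param series A [delta_series()] with at least two points.
#' @return A list with `intervals` (tibble: `t_start`, `t_end`, `rate`) and
#'   `whole_period` (single rate), both in PI per `time_unit`.
#' @export
interval_rates <- function(series) {
  stopifnot(inherits(series, "delta_series"))
  d <- series$data
  if (nrow(d) < 2L) stop_input("Need at least two points to compute rates.")
  dt <- diff(d$exposure_time)
  if (any(dt == 0)) stop_input("Duplicate observation times give degenerate intervals.")
  list(
    intervals = tibble(
      t_start = head(d$exposure_time, -1),
      t_end = tail(d$exposure_time, -1),
      rate = diff(d$delta_pi) / dt
    ),
    whole_period = (d$delta_pi[nrow(d)] - d$delta_pi[1]) /
      (d$exposure_time[nrow(d)] - d$exposure_time[1])
  )
}

#' Ordinary least-squares fit of darkening versus exposure time
#'
#' Fits `delta_pi ~ exposure_time` by OLS. Under sustained, roughly constant
#' exposure, darkening is near-linear in time and the fit's slope estimates
#' the darkening rate; the coefficient of determination quantifies how
#' consistent the rate was over the deployment.
#'
#' @param series A [delta_series()] with at least three points.
#' @return An object of class `linear_fit`: `slope` (PI per time unit),
#'   `intercept` (PI), `r_squared`, `n_points`, and the underlying `lm` fit
#'   (`model`).
#' @export
fit_linear_darkening <- function(series) {
  stopifnot(inherits(series, "delta_series"))
  d <- series$data
  if (nrow(d) < 3L) stop_input("Need at least three points for a linear fit.")
  if (length(unique(d$exposure_time)) < 2L) {
    stop_input("All observation times identical: design matrix is rank-deficient.")
  }
  fit <- lm(delta_pi ~ exposure_time, data = d)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((d$delta_pi - mean(d$delta_pi))^2)
  structure(
    list(
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
      n_points = nrow(d), model = fit
    ),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "<linear_fit> slope %.3g PI/unit, intercept %.3g PI, R^2 %.3f (n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n_points
  ))
  invisible(x)
}

#' Lower limit of detection of a cohort, in deployment time
#'
#' The shortest deployment after which every sampler in the cohort shows a
#' measurable change in reflectance: the earliest observed sampling time `t`
#' such that all samplers with an observation at `t` satisfy
#' `|delta_pi| >= threshold_percent/100 * max_value` (1% of full scale, 41
#' PI, by default). Ragged sampling grids are allowed; each candidate time
#' is judged on the samplers actually observed then.
#'
#' @param cohort List of [delta_series()].
#' @param threshold_percent Measurable-change threshold in percent of full
#'   scale; 0 accepts any sampler at the first post-baseline time.
#' @param max_value Full-scale pixel value.
#' @return The earliest qualifying sampling time, or `NA` if the threshold
#'   is never reached by all samplers simultaneously.
#' @export
lower_lod_time <- function(cohort, threshold_percent = 1, max_value = 4095L) {
  if (length(cohort) == 0L) stop_input("Empty cohort.")
  threshold_pi <- threshold_percent / 100 * max_value
  times <- sort(unique(unlist(lapply(cohort, function(s) s$data$exposure_time))))
  times <- times[times > min(vapply(cohort, function(s) s$data$exposure_time[1], numeric(1)))]
  for (t in times) {
    vals <- vapply(cohort, series_value_at, numeric(1), t = t)
    vals <- vals[!is.na(vals)]
    if (length(vals) > 0 && all(abs(vals) >= threshold_pi)) {
      return(t)
    }
  }
  NA_real_
}

#' Saturation assessment via a replacement sampler
#'
#' Once an exposure surface saturates it stops darkening despite continued
#' exposure. The field probe for this is to deploy a fresh replacement
#' sampler beside the long-exposed ones: over the same window, a saturated
#' site shows near-zero change on the continuing samplers but a large change
#' on the replacement. The rule implemented here fires when (i) the mean
#' continuing change is within `continuing_tolerance` of zero, (ii) the
#' replacement change is itself measurable (at least `measurable_threshold`
#' PI), and (iii) the ratio of the two magnitudes reaches `ratio_threshold`.
#' All three quantities are reported regardless of the verdict.
#'
#' @param continuing List of [delta_series()] exposed since baseline, each
#'   observed at both window endpoints.
#' @param replacement A [delta_series()] with role `"replacement"`, starting
#'   (delta-PI 0) at the window start.
#' @param window Numeric `c(t_start, t_end)` on the campaign clock.
#' @param ratio_threshold Minimum `|replacement| / |continuing|` ratio
#'   (default 10).
#' @param continuing_tolerance Maximum `|mean continuing change|` still
#'   regarded as "no longer darkening" (default 41 PI, the 1% threshold).
#' @param measurable_threshold Minimum `|replacement change|` (default 41 PI).
#' @param epsilon Floor for the ratio denominator (default 1 PI), avoiding
#'   division by ~0 when continuing samplers are flat.
#' @return An object of class `saturation_assessment` with `location_id`,
#'   `window`, `continuing_change`, `replacement_change`, `ratio`, and
#'   `saturated`.
#' @export
#' @examples
#' cont <- lapply(c("A", "B"), function(id) {
#'   delta_series(id, "L7", c(0, 118, 173), c(0, -2900, -2860))
#' })
#' rep1 <- delta_series("C", "L7", c(118, 173), c(0, -2100), role = "replacement")
#' assess_saturation(cont, rep1, window = c(118, 173))
assess_saturation <- function(continuing, replacement, window,
                              ratio_threshold = 10, continuing_tolerance = 41,
                              measurable_threshold = 41, epsilon = 1) {
  if (length(continuing) == 0L) stop_input("Need at least one continuing series.")
  stopifnot(inherits(replacement, "delta_series"))
  if (length(window) != 2L || window[2] <= window[1]) {
    stop_input("window must be c(t_start, t_end) with t_end > t_start.")
  }
  changes <- vapply(continuing, function(s) {
    v0 <- series_value_at(s, window[1])
    v1 <- series_value_at(s, window[2])
    if (is.na(v0) || is.na(v1)) {
      stop_input(sprintf(
        "Continuing series '%s' is not observed at both window endpoints.",
        s$sampler_id
      ))
    }
    v1 - v0
  }, numeric(1))
  r0 <- series_value_at(replacement, window[1])
  r1 <- series_value_at(replacement, window[2])
  if (is.na(r0) || is.na(r1)) {
    stop_input("Replacement series is not observed at both window endpoints.")
  }
  if (r0 != 0) {
    stop_input("Replacement series must start with delta_pi 0 at the window start.")
  }
  continuing_change <- mean(changes)
  replacement_change <- r1 - r0
  ratio <- abs(replacement_change) / max(abs(continuing_change), epsilon)
  structure(
    list(
      location_id = continuing[[1]]$location_id, window = window,
      continuing_change = continuing_change,
      replacement_change = replacement_change, ratio = ratio,
      saturated = abs(continuing_change) <= continuing_tolerance &&
        abs(replacement_change) >= measurable_threshold &&
        ratio >= ratio_threshold
    ),
    class = "saturation_assessment"
  )
}

#' @export
print.saturation_assessment <- function(x, ...) {
  cat(sprintf(
    "<saturation_assessment> location '%s', window [%g, %g]: continuing %.4g PI, replacement %.4g PI, ratio %.3g -> %s\n",
    x$location_id, x$window[1], x$window[2], x$continuing_change,
    x$replacement_change, x$ratio,
    if (x$saturated) "SATURATED" else "not saturated"
  ))
  invisible(x)
}

#' Cohort summary of darkening rates over a period
#'
#' Computes each sampler's interval rate over `period` (endpoint-to-endpoint
#' change divided by elapsed time) and summarises the cohort by the median
#' and interquartile range, using the linear-interpolation quantile
#' definition.
#'
#' @param cohort List of [delta_series()], each observed at both period
#'   endpoints.
#' @param period Numeric `c(t_start, t_end)`.
#' @return A list with `rates` (tibble: `sampler_id`, `rate`), `median`, and
#'   `iqr` (`c(lower, upper)`, the 25th and 75th percentiles).
#' @export
period_rate_summary <- function(cohort, period) {
  if (length(cohort) == 0L) stop_input("Empty cohort.")
  if (length(period) != 2L || period[2] <= period[1]) {
    stop_input("period must be c(t_start, t_end) with t_end > t_start (empty period).")
  }
  rates <- dplyr::bind_rows(lapply(cohort, function(s) {
    v0 <- series_value_at(s, period[1])
    v1 <- series_value_at(s, period[2])
    if (is.na(v0) || is.na(v1)) {
      return(tibble(sampler_id = character(), rate = numeric()))
    }
    tibble(sampler_id = s$sampler_id, rate = (v1 - v0) / (period[2] - period[1]))
  }))
  if (nrow(rates) == 0L) {
    stop_input("No sampler in the cohort is observed at both period endpoints.")
  }
  qs <- quantile(rates$rate, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(rates = rates, median = qs[2], iqr = c(qs[1], qs[3]))
}

#' Assemble delta series from a table of delta records
#'
#' Groups a delta-record table (as produced by [delta_pi()] or
#' [measure_campaign()]) by sampler and returns one [delta_series()] per
#' sampler, ordered by exposure time.
#'
#' @param records Tibble with columns `sampler_id`, `location_id`,
#'   `exposure_time`, `delta_pi`, and optionally `role`.
#' @param time_unit Time unit carried on each series.
#' @return A named list of [delta_series()] (names are sampler ids).
#' @export
build_delta_series <- function(records, time_unit = "days") {
  if (nrow(records) == 0L) stop_input("Empty record table.")
  if (!"role" %in% names(records)) records$role <- "original"
  split_ids <- unique(records$sampler_id)
  out <- lapply(split_ids, function(id) {
    r <- records[records$sampler_id == id, ]
    r <- r[order(r$exposure_time), ]
    delta_series(
      sampler_id = id, location_id = r$location_id[1],
      exposure_time = r$exposure_time, delta_pi = r$delta_pi,
      role = r$role[1], time_unit = time_unit
    )
  })
  setNames(out, split_ids)
}
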