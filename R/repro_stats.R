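#' Pearson and Spearman correlation between replicate measurements
#'
#' Thin, validated wrappers around the sample product-moment correlation and
#' its rank version (ties receive average ranks), used to quantify agreement
#' between co-located samplers.
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  check_cor_input(x, y)
  cor(x, y, method = "pearson")
}

#' @rdname pearson_r
#' @export
spearman_s <- function(x, y) {
  check_cor_input(x, y)
  cor(x, y, method = "spearman")
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y must have equal length.")
  if (length(x) < 3L) stop_input("Need at least 3 observations for a correlation.")
  if (anyNA(x) || anyNA(y)) stop_input("Missing values are not allowed.")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_input("Correlation undefined: one of the vectors has zero variance.")
  }
  invisible(TRUE)
}

#' Coefficient of variation of replicate measurements
#'
#' Sample standard deviation (n - 1 denominator) divided by the absolute
#' mean, in percent. Replicate counts in this method are small (2-3
#' co-located samplers), hence the sample standard deviation.
#'
#' @param values Numeric vector of at least 2 replicate delta-PI values with
#'   nonzero mean.
#' @return CV in percent (absolute value).
#' @export
#' @examples
#' cv_replicates(c(-90, -100, -110)) # 10
cv_replicates <- function(values) {
  if (length(values) < 2L) stop_input("Need at least 2 replicates for a CV.")
  m <- mean(values)
  if (m == 0) stop_input("CV undefined: replicate mean is 0.")
  sd(values) / abs(m) * 100
}

#' RMSE of replicates relative to their replicate mean
#'
#' Pools, over all replicate sets, each value's deviation from its own set
#' mean, and returns the root of the mean squared deviation — a precision
#' (reproducibility) metric for co-located samplers. For a pair this equals
#' half the absolute difference. The relative version divides by the
#' absolute grand mean of all values (the reported percentages are positive
#' although darkening means are negative).
#'
#' @param sets A list of numeric vectors (each a replicate set, n >= 2), or
#'   a single numeric vector (one set).
#' @return A list with `rmse` (PI units) and `rmse_over_mean` (percent).
#' @export
#' @examples
#' rmse_vs_replicate_mean(list(c(-400, -480), c(-100, -100)))$rmse # 28.28
rmse_vs_replicate_mean <- function(sets) {
  if (is.numeric(sets)) sets <- list(sets)
  if (length(sets) == 0L) stop_input("Empty input: no replicate sets.")
  for (s in sets) {
    if (length(s) < 2L) stop_input("Every replicate set needs n >= 2.")
  }
  deviations <- unlist(lapply(sets, function(s) s - mean(s)))
  all_values <- unlist(sets)
  rmse <- sqrt(mean(deviations^2))
  grand <- mean(all_values)
  list(
    rmse = rmse,
    rmse_over_mean = if (grand == 0) NA_real_ else rmse / abs(grand) * 100
  )
}

#' Agreement between paired samplers, overall and by group
#'
#' For each group of pairs: the number of pairs, the mean delta-PI over all
#' values, Pearson and Spearman correlation between the A and B member
#' vectors, and the RMSE relative to the pair means (with its relative
#' version). Grouping is either `"all"` (one group), `"by_date"` (one group
#' per sampling date), or `"by_quintile"`: all pairs pooled, ranked by pair
#' mean delta-PI and split into 5 equal-count groups (ties and remainders
#' resolved by stable input order, so group sizes differ by at most one).
#'
#' Groups with fewer than 3 pairs, or with zero variance in either member
#' vector, get `NA` correlations (with a warning for the former).
#'
#' @param pairs Tibble with columns `delta_a`, `delta_b`, `date`, and
#'   optionally `location_id`.
#' @param grouping `"all"`, `"by_date"`, or `"by_quintile"`.
#' @param n_quantile_groups Number of quantile groups (default 5).
#' @return A tibble with one row per group: `grouping`, `group`, `n_pairs`,
#'   `mean_delta_pi`, `pearson_r`, `spearman_s`, `rmse`, `rmse_over_mean`.
#' @export
agreement_by_group <- function(pairs, grouping = c("all", "by_date", "by_quintile"),
                               n_quantile_groups = 5L) {
  grouping <- match.arg(grouping)
  if (nrow(pairs) == 0L) stop_input("Empty pair table.")
  groups <- switch(grouping,
    all = list(all = seq_len(nrow(pairs))),
    by_date = split(seq_len(nrow(pairs)), pairs$date),
    by_quintile = {
      pair_mean <- (pairs$delta_a + pairs$delta_b) / 2
      ord <- order(pair_mean) # stable: ties keep input (location) order
      cuts <- floor(seq(0, nrow(pairs), length.out = n_quantile_groups + 1))
      g <- lapply(seq_len(n_quantile_groups), function(k) {
        ord[(cuts[k] + 1):cuts[k + 1]]
      })
      setNames(g, paste0("Q", seq_len(n_quantile_groups)))
    }
  )
  dplyr::bind_rows(lapply(names(groups), function(gname) {
    idx <- groups[[gname]]
    a <- pairs$delta_a[idx]
    b <- pairs$delta_b[idx]
    err <- rmse_vs_replicate_mean(mapply(c, a, b, SIMPLIFY = FALSE))
    r <- s <- NA_real_
    if (length(idx) < 3L) {
      warn(sprintf(
        "Group '%s' has only %d pair(s); correlations skipped.", gname, length(idx)
      ))
    } else if (sd(a) == 0 || sd(b) == 0) {
      # zero-variance group: correlation reported as not-available
    } else {
      r <- pearson_r(a, b)
      s <- spearman_s(a, b)
    }
    tibble(
      grouping = grouping, group = gname, n_pairs = length(idx),
      mean_delta_pi = mean(c(a, b)), pearson_r = r, spearman_s = s,
      rmse = err$rmse, rmse_over_mean = err$rmse_over_mean
    )
  }))
}

#' Decompose delta-PI variability among and within locations
#'
#' Three unweighted mean coefficients of variation characterising what the
#' method can distinguish:
#' \describe{
#'   \item{among_location_cv}{per sampling date, the CV across location mean
#'     delta-PI values, averaged over dates — spatial contrast between
#'     locations;}
#'   \item{within_location_cv}{per location, the CV across its per-date
#'     means, averaged over locations — temporal evolution at one place;}
#'   \item{replicate_cv}{per location-date, the CV across co-located
#'     replicates, averaged over all location-dates — measurement
#'     precision.}
#' }
#' A useful passive method shows among > within > replicate. The baseline
#' time-point (all delta-PI identically 0) is excluded.
#'
#' @param records Tibble with columns `location_id`, `sampler_id`,
#'   `exposure_time`, `delta_pi`; needs >= 2 locations, >= 2 post-baseline
#'   dates, and >= 2 replicates per location.
#' @return A list with `among_location_cv`, `within_location_cv`,
#'   `replicate_cv`, all in percent.
#' @export
variability_decomposition <- function(records) {
  records <- records[records$exposure_time > 0, ]
  if (nrow(records) == 0L) stop_input("No post-baseline records.")
  if (length(unique(records$location_id)) < 2L) {
    stop_input("Need at least 2 locations for the decomposition.")
  }
  if (length(unique(records$exposure_time)) < 2L) {
    stop_input("Need at least 2 post-baseline sampling dates.")
  }
  reps_per_loc <- tapply(
    records$sampler_id, records$location_id,
    function(s) length(unique(s))
  )
  if (any(reps_per_loc < 2L)) {
    stop_input("Need at least 2 replicate samplers per location.")
  }

  loc_date_means <- records |>
    dplyr::group_by(.data$location_id, .data$exposure_time) |>
    dplyr::summarise(mean_delta = mean(.data$delta_pi), .groups = "drop")

  among_by_date <- loc_date_means |>
    dplyr::group_by(.data$exposure_time) |>
    dplyr::summarise(cv = cv_replicates(.data$mean_delta), .groups = "drop")
  within_by_loc <- loc_date_means |>
    dplyr::group_by(.data$location_id) |>
    dplyr::summarise(cv = cv_replicates(.data$mean_delta), .groups = "drop")
  rep_by_cell <- records |>
    dplyr::group_by(.data$location_id, .data$exposure_time) |>
    dplyr::summarise(cv = cv_replicates(.data$delta_pi), .groups = "drop")

  list(
    among_location_cv = mean(among_by_date$cv),
    within_location_cv = mean(within_by_loc$cv),
    replicate_cv = mean(rep_by_cell$cv)
  )
}
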