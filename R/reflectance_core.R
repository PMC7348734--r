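#' Summarise one surface at one time-point
#'
#' Bundles the mean pixel intensity (PI) of one surface's ROI at one imaging
#' time-point with the metadata needed to pair it correctly: surface role,
#' exposure time, frame count, and the full-scale value of the pixel scale.
#'
#' @param surface_id Identifier of the physical surface (sampler id or
#'   reference id).
#' @param role `"sample"` (passively exposed) or `"reference"` (unexposed).
#' @param t Exposure time of the imaging session (days in field campaigns,
#'   minutes in laboratory runs); must be `>= 0`.
#' @param mean_pi Mean pixel intensity in `[0, max_value]` (unrounded).
#' @param n_frames Number of frames pooled into `mean_pi`.
#' @param max_value Full-scale pixel value (4095 for 12-bit data).
#' @return A one-row tibble of class `intensity_summary`.
#' @export
intensity_summary <- function(surface_id, role, t, mean_pi, n_frames = 20L,
                              max_value = 4095L) {
  role <- match.arg(role, c("sample", "reference"))
  if (t < 0) stop_input("Exposure time must be >= 0.")
  if (mean_pi < 0 || mean_pi > max_value) {
    stop_range(sprintf("mean_pi %.2f outside [0, %d].", mean_pi, max_value))
  }
  out <- tibble(
    surface_id = surface_id, role = role, t = as.numeric(t),
    mean_pi = as.numeric(mean_pi), n_frames = as.integer(n_frames),
    max_value = as.integer(max_value)
  )
  class(out) <- c("intensity_summary", class(out))
  out
}

#' Change in reflectance of a passively exposed sampler (delta-PI)
#'
#' The method's core metric: the change in mean pixel intensity of the
#' sample surface between baseline (t = 0) and exposure time T, doubly
#' referenced,
#'
#' \deqn{\Delta PI = (PI_{S,T} - PI_{R,T}) - (PI_{S,0} - PI_{R,0}),}
#'
#' where S is the exposed sample and R the unexposed reference imaged in the
#' same session. Referencing each sample against its own baseline removes
#' filter-to-filter differences in baseline reflectance; referencing against
#' the in-session reference removes session-to-session differences in overall
#' lightbox brightness (any additive shift common to both surfaces cancels
#' exactly). Negative values mean darkening; 0 means no change; -max_value
#' means a change from perfect white to perfect black.
#'
#' @param sample_baseline,reference_baseline [intensity_summary()] rows of
#'   the sample and reference at t = 0 (the two must share the same `t`).
#' @param sample_at_T,reference_at_T [intensity_summary()] rows at exposure
#'   time T (same `t` for both).
#' @param sampler_id,location_id Identifiers copied into the output record;
#'   default to the sample surface's id and `NA`.
#' @return A one-row tibble (a delta record) with `sampler_id`,
#'   `location_id`, `exposure_time`, `delta_pi` (PI units) and
#'   `delta_percent` (`delta_pi / max_value * 100`).
#' @export
#' @examples
#' s0 <- intensity_summary("S1", "sample", 0, 3900)
#' r0 <- intensity_summary("REF", "reference", 0, 3950)
#' sT <- intensity_summary("S1", "sample", 33, 2800)
#' rT <- intensity_summary("REF", "reference", 33, 3940)
#' delta_pi(s0, r0, sT, rT)$delta_pi # -1090
delta_pi <- function(sample_baseline, reference_baseline, sample_at_T,
                     reference_at_T, sampler_id = sample_baseline$surface_id,
                     location_id = NA_character_) {
  if (sample_baseline$role != "sample" || sample_at_T$role != "sample" ||
    reference_baseline$role != "reference" || reference_at_T$role != "reference") {
    stop_pairing("Surface roles do not match the sample/reference pairing.")
  }
  if (sample_baseline$t != reference_baseline$t) {
    stop_pairing("Baseline sample and reference summaries have different times.")
  }
  if (sample_at_T$t != reference_at_T$t) {
    stop_pairing("At-T sample and reference summaries have different times.")
  }
  mv <- c(
    sample_baseline$max_value, reference_baseline$max_value,
    sample_at_T$max_value, reference_at_T$max_value
  )
  if (length(unique(mv)) != 1L) {
    stop_range("All four summaries must share the same full-scale value.")
  }
  d <- (sample_at_T$mean_pi - reference_at_T$mean_pi) -
    (sample_baseline$mean_pi - reference_baseline$mean_pi)
  tibble(
    sampler_id = sampler_id, location_id = location_id,
    exposure_time = sample_at_T$t, delta_pi = d,
    delta_percent = pi_to_percent(d, mv[1])
  )
}

#' Convert a change in pixel intensity to percent of full scale
#'
#' @param delta_pi Change in PI units; `|delta_pi|` must not exceed
#'   `max_value`.
#' @param max_value Full-scale pixel value (4095 for 12-bit data).
#' @return `delta_pi / max_value * 100`.
#' @export
#' @examples
#' pi_to_percent(-41) # about -1%
pi_to_percent <- function(delta_pi, max_value = 4095L) {
  if (any(abs(delta_pi) > max_value)) {
    stop_range("`|delta_pi|` exceeds the full-scale value.")
  }
  delta_pi / max_value * 100
}

#' @rdname pi_to_percent
#' @param percent Change expressed in percent of full scale.
#' @export
percent_to_pi <- function(percent, max_value = 4095L) {
  if (any(abs(percent) > 100)) stop_range("`|percent|` exceeds 100.")
  percent / 100 * max_value
}

#' Is a change in reflectance measurable?
#'
#' A change counts as measurable when its magnitude reaches
#' `threshold_percent` of full scale — by default 1%, i.e. 41 PI on the
#' 12-bit scale, the threshold used to define the method's lower limit of
#' detection.
#'
#' @inheritParams pi_to_percent
#' @param threshold_percent Positive threshold in percent of full scale.
#' @return Logical, `TRUE` iff `|delta_pi| >= threshold_percent/100 *
#'   max_value`.
#' @export
is_measurable_change <- function(delta_pi, threshold_percent = 1,
                                 max_value = 4095L) {
  if (threshold_percent <= 0) stop_input("threshold_percent must be > 0.")
  abs(delta_pi) >= threshold_percent / 100 * max_value
}

#' Mean pixel intensities of every surface in a session
#'
#' Applies [extract_roi_mean()] to every layout entry and returns the
#' corresponding [intensity_summary()] rows — the glue between raw images
#' and the delta-PI computation.
#'
#' @param stack A [frame_stack()].
#' @param layout A [surface_layout()].
#' @param t Exposure time of this session.
#' @return A tibble with one `intensity_summary` row per surface.
#' @export
summarize_session <- function(stack, layout, t) {
  dplyr::bind_rows(lapply(seq_len(nrow(layout)), function(i) {
    intensity_summary(
      surface_id = layout$surface_name[i], role = layout$role[i], t = t,
      mean_pi = extract_roi_mean(stack, layout[i, ]),
      n_frames = n_frames(stack), max_value = stack$max_value
    )
  }))
}
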