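#' Saturating darkening model of a passively exposed surface
#'
#' The simulator's forward model for how a white filter surface darkens with
#' cumulative particle deposition. The surface's true mean pixel intensity
#' at time t is
#'
#' \deqn{PI(t) = PI_{sat} + (PI_0 - PI_{sat}) e^{-k D(t)},}
#'
#' with cumulative dose \eqn{D(t) = \int_0^t v_d C(\tau) d\tau}: deposition
#' velocity `v_d` times airborne concentration `C`. This is the simplest
#' monotone form consistent with the two regimes the method must handle —
#' near-linear darkening at low cumulative dose (initial rate
#' \eqn{k (PI_0 - PI_{sat}) v_d C}) and a plateau (saturation) at high dose.
#' Dose units are arbitrary but consistent: `k`, `v_d` and `C` only ever
#' enter as a product, since no calibration to mass concentration exists.
#'
#' @param pi_0 Baseline surface PI (near full scale for white filters).
#' @param pi_sat Saturation floor PI (`0 <= pi_sat < pi_0`).
#' @param k Darkening rate constant per unit dose (`>= 0`).
#' @param v_d Deposition velocity (arbitrary units).
#' @param concentration Default concentration: a scalar (constant in time)
#'   or a function of time.
#' @return An object of class `darkening_model`.
#' @export
darkening_model <- function(pi_0 = 3900, pi_sat = 500, k = 0.00155, v_d = 1,
                            concentration = 1) {
  if (!(pi_sat >= 0 && pi_sat < pi_0)) stop_input("Need 0 <= pi_sat < pi_0.")
  if (k < 0) stop_input("k must be >= 0.")
  structure(
    list(
      pi_0 = pi_0, pi_sat = pi_sat, k = k, v_d = v_d,
      concentration = concentration
    ),
    class = "darkening_model"
  )
}

#' @rdname darkening_model
#' @details `lab_darkening_model()` parameterises the same form for
#'   laboratory smoke-chamber conditions: an initial darkening rate of
#'   4.2 PI per minute at unit concentration (`k = 4.2 / (pi_0 - pi_sat)`
#'   per minute).
#' @export
lab_darkening_model <- function(pi_0 = 3900, pi_sat = 500) {
  darkening_model(pi_0 = pi_0, pi_sat = pi_sat, k = 4.2 / (pi_0 - pi_sat))
}

## Cumulative dose D(t) = integral of v_d * C.
cumulative_dose <- function(model, t, concentration = model$concentration) {
  if (is.function(concentration)) {
    vapply(t, function(ti) {
      if (ti == 0) {
        return(0)
      }
      model$v_d * stats::integrate(concentration, 0, ti)$value
    }, numeric(1))
  } else {
    model$v_d * concentration * t
  }
}

#' True (noise-free) surface PI at an exposure time
#'
#' @param model A [darkening_model()].
#' @param t Exposure time(s), `>= 0`.
#' @param concentration Overrides the model's concentration (scalar or
#'   function of time).
#' @return Surface PI value(s); strictly decreasing in `t` when `k > 0` and
#'   the concentration is positive.
#' @export
#' @examples
#' m <- darkening_model()
#' true_surface_pi(m, c(0, 33, 258))
true_surface_pi <- function(model, t, concentration = model$concentration) {
  stopifnot(inherits(model, "darkening_model"))
  if (any(t < 0)) stop_input("t must be >= 0.")
  model$pi_sat + (model$pi_0 - model$pi_sat) *
    exp(-model$k * cumulative_dose(model, t, concentration))
}

#' Lightbox noise model
#'
#' The disturbance structure of real lightbox sessions: a per-session
#' additive brightness offset and multiplicative gain shared by every
#' surface in the photo (lighting drift between imaging time-points — the
#' disturbance the double-referenced delta-PI is designed to cancel),
#' per-frame multiplicative flicker, and additive per-pixel sensor noise.
#' All draws are reproducible from `seed`.
#'
#' @param session_offset_sd SD of the per-session additive offset b (PI).
#' @param session_gain_sd SD of `log(g)` for the per-session gain g
#'   (lognormal, so g > 0).
#' @param flicker_sd SD of the per-frame multiplicative flicker factor
#'   around 1.
#' @param pixel_sd SD of additive per-pixel noise (PI).
#' @param seed Integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(session_offset_sd = 15, session_gain_sd = 0.002,
                        flicker_sd = 0.005, pixel_sd = 8, seed = 1L) {
  if (any(c(session_offset_sd, session_gain_sd, flicker_sd, pixel_sd) < 0)) {
    stop_input("Noise standard deviations must be >= 0.")
  }
  structure(
    list(
      session_offset_sd = session_offset_sd,
      session_gain_sd = session_gain_sd, flicker_sd = flicker_sd,
      pixel_sd = pixel_sd, seed = as.integer(seed)
    ),
    class = "noise_model"
  )
}

#' Default two-surface layout for simulated lightbox frames
#'
#' Sample and reference surfaces side by side in the centre of the field of
#' view, mirroring the physical imaging arrangement.
#'
#' @param frame_dim `c(rows, cols)` of the simulated frames.
#' @param roi_side ROI side length in pixels (odd; default 49).
#' @return A [surface_layout()].
#' @export
default_layout <- function(frame_dim = c(256, 256), roi_side = 49L) {
  mid_row <- floor(frame_dim[1] / 2)
  quarter <- floor(frame_dim[2] / 4)
  if (roi_side > quarter * 2 - 2) {
    stop_layout("roi_side too large for frame_dim: the two ROIs would overlap.")
  }
  surface_layout(tibble(
    surface_name = c("sample", "reference"),
    role = c("sample", "reference"),
    roi_center_row = c(mid_row, mid_row),
    roi_center_col = c(quarter, 3 * quarter),
    roi_side_pixels = as.integer(roi_side)
  ))
}

## Round half away from zero, deterministically across platforms.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Render one simulated imaging session
#'
#' Builds a multi-frame grayscale stack in which each layout ROI is filled
#' with its surface's true PI, background pixels take a mid-gray backdrop
#' value (so ROI mis-specification is visible in tests), and the noise
#' model is applied as
#' `pixel = clip(round(g * f_j * pi + b + pixel_noise), 0, max_value)`
#' with session gain g, session offset b and per-frame flicker `f_j`.
#' Rounding is half-away-from-zero. Identical inputs and seed give
#' bit-identical stacks.
#'
#' @param surface_pis Named numeric vector of true surface PI values; names
#'   must match the layout's `surface_name`s.
#' @param layout A [surface_layout()].
#' @param n_frames Number of frames (default 20).
#' @param noise A [noise_model()].
#' @param frame_dim `c(rows, cols)` of each frame.
#' @param backdrop Background PI outside all ROIs.
#' @param bit_depth Bits per pixel (default 12; full scale `2^bit_depth-1`).
#' @param session_offset,session_gain Fix the session offset/gain instead of
#'   drawing them from `noise` (used to probe drift behaviour).
#' @param quantize If `FALSE`, skip rounding and clipping and return
#'   continuous pixel values (diagnostic mode for closed-form noise
#'   analyses; such stacks cannot be written to disk losslessly).
#' @param seed Seed for this session's draws; `NULL` uses the current RNG
#'   state (as during campaign generation). Defaults to `noise$seed`.
#' @param session_id Session identifier stored on the stack.
#' @return A [frame_stack()].
#' @export
render_session <- function(surface_pis, layout, n_frames = 20L,
                           noise = noise_model(), frame_dim = c(256, 256),
                           backdrop = 2000, bit_depth = 12L,
                           session_offset = NULL, session_gain = NULL,
                           quantize = TRUE, seed = noise$seed,
                           session_id = NA_character_) {
  max_value <- bitwShiftL(1L, as.integer(bit_depth)) - 1L
  if (any(surface_pis < 0) || any(surface_pis > max_value)) {
    stop_range("Surface PI values must lie in [0, max_value].")
  }
  if (!all(layout$surface_name %in% names(surface_pis))) {
    stop_layout("`surface_pis` must name every layout surface.")
  }
  render <- function() {
    base <- matrix(backdrop, frame_dim[1], frame_dim[2])
    fake_stack <- list(frames = array(0L, c(1L, frame_dim)))
    for (i in seq_len(nrow(layout))) {
      idx <- roi_indices(fake_stack, layout[i, ])
      base[idx$rows, idx$cols] <- surface_pis[[layout$surface_name[i]]]
    }
    b <- if (is.null(session_offset)) {
      rnorm(1, 0, noise$session_offset_sd)
    } else {
      session_offset
    }
    g <- if (is.null(session_gain)) {
      exp(rnorm(1, 0, noise$session_gain_sd))
    } else {
      session_gain
    }
    f <- pmax(1 + rnorm(n_frames, 0, noise$flicker_sd), 0.01)
    arr <- outer(g * f, base) + b
    if (noise$pixel_sd > 0) {
      arr <- arr + array(
        rnorm(length(arr), 0, noise$pixel_sd),
        dim(arr)
      )
    }
    if (quantize) {
      arr <- pmin(pmax(round_half_away(arr), 0), max_value)
      frame_stack(arr, bit_depth = bit_depth, session_id = session_id)
    } else {
      # continuous diagnostic stack: same shape, double pixels, no clipping
      structure(
        list(
          frames = arr, bit_depth = as.integer(bit_depth),
          max_value = max_value, session_id = session_id, capture_label = ""
        ),
        class = "frame_stack"
      )
    }
  }
  if (is.null(seed)) render() else withr::with_seed(seed, render())
}

#' Design of a simulated monitoring campaign
#'
#' Describes the deployment the simulator emulates. The defaults mirror a
#' long-term indoor field study: 20 locations with paired (duplicate)
#' samplers, imaged at baseline and on days 33, 55, 90, 118, 173, 209 and
#' 258, 20 frames per session. Between-location differences in exposure are
#' drawn as lognormal concentration multipliers; co-located replicates get
#' a small lognormal deposition multiplier of their own, so replicate
#' disagreement scales with the signal. Optionally a fresh replacement
#' sampler is deployed mid-campaign at the highest-concentration location
#' (the saturation probe).
#'
#' @param n_locations Number of locations.
#' @param samplers_per_location Co-located replicate samplers per location.
#' @param sampling_times Imaging times including baseline 0 (days in field
#'   mode, minutes in lab mode).
#' @param time_unit `"days"` or `"minutes"`.
#' @param concentrations Optional explicit per-location concentrations
#'   (length `n_locations`); `NULL` draws them.
#' @param concentration_median,concentration_sdlog Median and log-SD of the
#'   lognormal between-location concentration distribution.
#' @param replicate_sdlog Log-SD of the per-sampler deposition multiplier
#'   (replicate-level variability).
#' @param reference_pi True PI of the unexposed reference surface.
#' @param baseline_pi_sd SD of per-filter baseline PI around the model's
#'   `pi_0` (filter-to-filter manufacturing variation).
#' @param n_frames Frames per session.
#' @param frame_dim Simulated frame size, `c(rows, cols)`.
#' @param roi_side ROI side length (odd).
#' @param backdrop Background PI outside the ROIs.
#' @param include_replacement Deploy a replacement sampler?
#' @param replacement_start_index Index into `sampling_times` at which the
#'   replacement is deployed (its baseline).
#' @return An object of class `campaign_design`.
#' @export
campaign_design <- function(n_locations = 20L, samplers_per_location = 2L,
                            sampling_times = c(0, 33, 55, 90, 118, 173, 209, 258),
                            time_unit = "days", concentrations = NULL,
                            concentration_median = 1,
                            concentration_sdlog = 1.1,
                            replicate_sdlog = 0.11, reference_pi = 3950,
                            baseline_pi_sd = 20, n_frames = 20L,
                            frame_dim = c(256, 256), roi_side = 49L,
                            backdrop = 2000, include_replacement = TRUE,
                            replacement_start_index = 5L) {
  if (sampling_times[1] != 0 || any(diff(sampling_times) <= 0)) {
    stop_input("sampling_times must start at 0 and be strictly increasing.")
  }
  if (!is.null(concentrations) && length(concentrations) != n_locations) {
    stop_input("`concentrations` must have one value per location.")
  }
  if (include_replacement &&
    (replacement_start_index < 2L ||
      replacement_start_index >= length(sampling_times))) {
    stop_input("replacement_start_index must point inside the campaign.")
  }
  structure(
    list(
      n_locations = as.integer(n_locations),
      samplers_per_location = as.integer(samplers_per_location),
      sampling_times = sampling_times, time_unit = time_unit,
      concentrations = concentrations,
      concentration_median = concentration_median,
      concentration_sdlog = concentration_sdlog,
      replicate_sdlog = replicate_sdlog, reference_pi = reference_pi,
      baseline_pi_sd = baseline_pi_sd, n_frames = as.integer(n_frames),
      frame_dim = frame_dim, roi_side = as.integer(roi_side),
      backdrop = backdrop, include_replacement = include_replacement,
      replacement_start_index = as.integer(replacement_start_index)
    ),
    class = "campaign_design"
  )
}

#' @rdname campaign_design
#' @details `lab_study_design()` mirrors a laboratory smoke-chamber run:
#'   one "location" (the chamber) with triplicate samplers imaged every 5
#'   minutes for 85 minutes, no between-location spread and no replacement
#'   sampler. Pair it with [lab_darkening_model()].
#' @export
lab_study_design <- function() {
  campaign_design(
    n_locations = 1L, samplers_per_location = 3L,
    sampling_times = seq(0, 85, by = 5), time_unit = "minutes",
    concentration_sdlog = 0, replicate_sdlog = 0.1,
    include_replacement = FALSE
  )
}

#' Generate a full synthetic imaging campaign
#'
#' Writes one multi-frame TIFF per sampler per sampling time (each photo
#' containing the sampler surface and the unexposed reference side by
#' side), plus the layout file, a campaign manifest, the simulation
#' configuration, and a ground-truth table of true PI / true delta-PI /
#' true initial darkening rate per observation — so pipeline estimates can
#' be checked against known truth. Output is deterministic given the seed.
#'
#' @param design A [campaign_design()].
#' @param model A [darkening_model()]; per-location concentrations from the
#'   design scale its dose rate.
#' @param noise A [noise_model()].
#' @param out_dir Output directory (created if needed).
#' @param seed Campaign seed (defaults to `noise$seed`).
#' @return Invisibly, a list with `dir`, `manifest` (tibble: `sampler_id`,
#'   `location_id`, `role`, `exposure_time`, `n_frames`, `path`),
#'   `ground_truth` (tibble incl. `true_pi`, `true_delta_pi`,
#'   `true_initial_rate`), `layout`, `design`, `model`, `noise`.
#' @export
generate_campaign <- function(design, model = darkening_model(),
                              noise = noise_model(), out_dir,
                              seed = noise$seed) {
  stopifnot(inherits(design, "campaign_design"), inherits(model, "darkening_model"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_input(sprintf("Cannot create '%s'.", out_dir))

  withr::with_seed(seed, {
    conc <- design$concentrations
    if (is.null(conc)) {
      conc <- exp(rnorm(
        design$n_locations, log(design$concentration_median),
        design$concentration_sdlog
      ))
    }
    loc_ids <- sprintf("L%02d", seq_len(design$n_locations))

    samplers <- dplyr::bind_rows(lapply(seq_len(design$n_locations), function(l) {
      dplyr::bind_rows(lapply(seq_len(design$samplers_per_location), function(s) {
        tibble(
          sampler_id = sprintf("%s_S%d", loc_ids[l], s),
          location_id = loc_ids[l], role = "original",
          concentration = conc[l] * exp(rnorm(1, 0, design$replicate_sdlog)),
          pi_0 = model$pi_0 + rnorm(1, 0, design$baseline_pi_sd),
          deployed_at = 0
        )
      }))
    }))
    if (design$include_replacement) {
      l <- which.max(conc)
      samplers <- dplyr::bind_rows(samplers, tibble(
        sampler_id = sprintf("%s_R1", loc_ids[l]),
        location_id = loc_ids[l], role = "replacement",
        concentration = conc[l] * exp(rnorm(1, 0, design$replicate_sdlog)),
        pi_0 = model$pi_0 + rnorm(1, 0, design$baseline_pi_sd),
        deployed_at = design$sampling_times[design$replacement_start_index]
      ))
    }

    layout <- default_layout(design$frame_dim, design$roi_side)
    manifest <- list()
    truth <- list()
    for (i in seq_len(nrow(samplers))) {
      sm <- samplers[i, ]
      m_i <- darkening_model(
        pi_0 = sm$pi_0, pi_sat = model$pi_sat, k = model$k, v_d = model$v_d,
        concentration = sm$concentration
      )
      times <- design$sampling_times[design$sampling_times >= sm$deployed_at]
      pi_dep <- true_surface_pi(m_i, 0)
      for (t in times) {
        pi_t <- true_surface_pi(m_i, t - sm$deployed_at)
        sid <- sprintf("%s_t%03d", sm$sampler_id, t)
        stack <- render_session(
          c(sample = pi_t, reference = design$reference_pi),
          layout = layout, n_frames = design$n_frames, noise = noise,
          frame_dim = design$frame_dim, backdrop = design$backdrop,
          seed = NULL, session_id = sid
        )
        rel <- paste0(sid, ".tif")
        write_frame_stack(stack, file.path(out_dir, rel))
        manifest[[sid]] <- tibble(
          sampler_id = sm$sampler_id, location_id = sm$location_id,
          role = sm$role, exposure_time = t, n_frames = design$n_frames,
          path = rel
        )
        truth[[sid]] <- tibble(
          sampler_id = sm$sampler_id, location_id = sm$location_id,
          role = sm$role, exposure_time = t, true_pi = pi_t,
          true_delta_pi = pi_t - pi_dep,
          true_initial_rate = -m_i$k * m_i$v_d * sm$concentration *
            (sm$pi_0 - model$pi_sat),
          concentration = sm$concentration
        )
      }
    }
    manifest <- dplyr::bind_rows(manifest)
    truth <- dplyr::bind_rows(truth)

    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    write.csv(truth, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
    write_surface_layout(layout, file.path(out_dir, "layout.yaml"))
    yaml::write_yaml(
      list(
        design = design[setdiff(names(design), "concentrations")],
        model = unclass(model)[c("pi_0", "pi_sat", "k", "v_d")],
        noise = unclass(noise), seed = seed
      ),
      file.path(out_dir, "config.yaml")
    )

    invisible(list(
      dir = out_dir, manifest = manifest, ground_truth = truth,
      layout = layout, design = design, model = model, noise = noise
    ))
  })
}
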