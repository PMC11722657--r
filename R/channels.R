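#' Multimodal channel registry
#'
#' Fixed registry of the 15 sensor channels recorded per driving session:
#' 4 physiological (electrodermal activity, heart rate, respiration rate,
#' perinasal perspiration) followed by 11 non-physiological (gaze X/Y,
#' left/right pupil diameter, and six vehicle-telemetry channels, plus a
#' facial-emotion scalar). The row order of this registry defines the row
#' order of every aligned matrix and window tensor in the package.
#'
#' @return A data.frame with columns `name`, `rate_hz`, `modality`
#'   (`"phys"`/`"nonphys"`) and `unit`, 15 rows, physiological rows first.
#' @export
#' @examples
#' channel_registry()
channel_registry <- function() {
  data.frame(
    name = c(
      "eda", "hr", "resp", "persp",
      "gaze_x", "gaze_y", "pupil_left", "pupil_right",
      "speed", "accel", "brake", "steer", "lane_offset", "lane_pos",
      "emotion"
    ),
    rate_hz = c(
      25, 1, 1, 7.5,
      25, 25, 25, 25,
      58.8, 58.8, 58.8, 58.8, 58.8, 58.8,
      15
    ),
    modality = c(rep("phys", 4), rep("nonphys", 11)),
    unit = c(
      "uS", "bpm", "breaths/min", "au",
      "deg", "deg", "mm", "mm",
      "km/h", "m/s^2", "frac", "deg", "m", "m",
      "au"
    ),
    stringsAsFactors = FALSE
  )
}

# Per-channel generative settings used by simulate_cohort(): a stationary
# baseline, a latent-ability shift on the mean, AR(1) noise whose scale
# shrinks exponentially with the relevant latent dimension (so low ability
# produces erratic signals), and transient event bumps.
# mean_coef rows are the per-dimension (decision, control, psych) mean shifts.
channel_effects <- function() {
  reg <- channel_registry()
  eff <- data.frame(
    name = reg$name,
    base = c(5, 75, 16, 1,
             0, 0, 4, 4,
             70, 0, 0, 0, 0, 1.8,
             0.5),
    noise_sd = c(0.3, 2, 1, 0.1,
                 1, 1, 0.2, 0.2,
                 3, 0.5, 0.2, 0.1, 0.4, 0.3,
                 0.15),
    # which latent dimension scales the AR noise (1 decision, 2 control, 3 psych)
    noise_dim = c(3, 3, 3, 3,
                  1, 1, 1, 1,
                  2, 2, 2, 2, 2, 2,
                  3),
    bump_amp = c(1.0, 8, 2, 0.3,
                 1.5, 0, 0.5, 0.5,
                 -15, 1.5, 1.0, 0, 0, 0,
                 0.3),
    stringsAsFactors = FALSE
  )
  # additive mean shift per unit (effect_size * latent dim)
  eff$mean_decision <- c(0, 0, 0, 0, 0, 0, 0.1, 0.1, 0, 0, 0, 0, 0, 0, 0)
  eff$mean_control  <- c(0, 0, 0, 0, 0, 0, 0, 0, 0.5, 0, 0, 0, -0.05, 0, 0)
  eff$mean_psych    <- c(-0.4, -3, -1, -0.2, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, -0.1)
  eff
}

# events that add a bump to a given channel
bump_event_types <- function(name) {
  switch(name,
    eda = c("secondary_task", "emergency"),
    hr = "emergency",
    resp = "secondary_task",
    persp = "emergency",
    gaze_x = "secondary_task",
    pupil_left = "secondary_task",
    pupil_right = "secondary_task",
    speed = c("intersection", "emergency"),
    accel = "emergency",
    brake = c("intersection", "emergency"),
    emotion = "secondary_task",
    character(0)
  )
}
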