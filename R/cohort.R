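#' Configuration for a synthetic driving cohort
#'
#' Defines the study conditions the simulator reproduces: two age groups
#' (young/old) split into counterbalancing groups A and B, session duration,
#' the strength with which the latent per-driver ability shapes both the
#' task-performance indicators and the sensor statistics, and the native
#' sampling rate of each of the 15 channels.
#'
#' @param n_young,n_old Drivers per age group (defaults 34 + 34, the cohort
#'   size the simulator emulates).
#' @param duration_s Session length in seconds.
#' @param effect_size Unitless, `>= 0`. Scales the influence of the latent
#'   ability on indicators and channel statistics; 0 removes the planted
#'   signal entirely.
#' @param indicator_noise_sd Standard deviation of the noise added on the
#'   linear predictor of every task-performance indicator.
#' @param group_a_rt_offset Additive emergency reaction-time bias (seconds)
#'   applied to counterbalance group A, emulating the extra task that group
#'   performed; removed downstream by [compensate_reaction_times()].
#' @param missing_rate Fraction `[0, 1)` of interior samples replaced by
#'   missing markers in every channel.
#' @param channel_rates Named numeric vector of sampling rates in Hz;
#'   defaults to `channel_registry()$rate_hz`.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_young = 34, n_old = 34, duration_s = 300,
                          effect_size = 1, indicator_noise_sd = 0.3,
                          group_a_rt_offset = 0.3, missing_rate = 0,
                          channel_rates = NULL, seed = 1L) {
  reg <- channel_registry()
  if (is.null(channel_rates)) {
    channel_rates <- stats::setNames(reg$rate_hz, reg$name)
  }
  cfg <- list(
    n_young = n_young, n_old = n_old, duration_s = duration_s,
    effect_size = effect_size, indicator_noise_sd = indicator_noise_sd,
    group_a_rt_offset = group_a_rt_offset, missing_rate = missing_rate,
    channel_rates = channel_rates, seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid cohort config field '", field, "': ", msg, call. = FALSE)
  }
  chk(is.numeric(cfg$n_young) && cfg$n_young >= 0 && cfg$n_young == round(cfg$n_young),
      "n_young", "must be a nonnegative integer")
  chk(is.numeric(cfg$n_old) && cfg$n_old >= 0 && cfg$n_old == round(cfg$n_old),
      "n_old", "must be a nonnegative integer")
  chk(cfg$n_young + cfg$n_old >= 4, "n_young", "cohort must have at least 4 drivers")
  chk(is.numeric(cfg$duration_s) && cfg$duration_s >= 1, "duration_s", "must be >= 1 second")
  chk(is.numeric(cfg$effect_size) && cfg$effect_size >= 0, "effect_size", "must be >= 0")
  chk(is.numeric(cfg$indicator_noise_sd) && cfg$indicator_noise_sd >= 0,
      "indicator_noise_sd", "must be >= 0")
  chk(is.numeric(cfg$missing_rate) && cfg$missing_rate >= 0 && cfg$missing_rate < 1,
      "missing_rate", "must lie in [0, 1)")
  chk(all(cfg$channel_rates > 0), "channel_rates", "all rates must be > 0")
  chk(setequal(names(cfg$channel_rates), channel_registry()$name),
      "channel_rates", "must name exactly the 15 registry channels")
  invisible(cfg)
}

# weights combining the three latent dimensions into the overall latent
# ability; same values as default_weight_model() so label recovery by the
# scoring pipeline is an identifiable target.
latent_overall_weights <- function() {
  c(decision = 0.3898, control = 0.3182, psych = 0.2920)
}

#' Simulate a driving cohort
#'
#' Draws per-driver latent abilities (decision, control, psych) from a
#' correlated trivariate Gaussian (pairwise correlation 0.3), then generates
#' one task-performance record and one multi-rate 15-channel session
#' recording per driver. Indicator means shift monotonically with the latent
#' dimensions scaled by `effect_size` (higher decision ability raises
#' secondary-task accuracy, higher control ability lowers emergency reaction
#' time, ...), and channel statistics shift with ability as well (lower
#' control ability raises lane-offset variance; lower psych ability raises
#' the EDA baseline). Counterbalance group A receives the configured
#' additive emergency reaction-time offset.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort` with elements `profiles` (data.frame:
#'   driver_id, age_group, counterbalance_group, latent decision/control/
#'   psych, latent_overall), `records` (data.frame of the ten raw
#'   task-performance indicators), `recordings` (list of session recordings,
#'   each a list with `driver_id`, `channels` — per channel a list with
#'   `time_s` and `value` at native rate — and `event_log`), and `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_young = 2, n_old = 2, duration_s = 30))
#' coh$profiles
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_young + config$n_old
  es <- config$effect_size

  # latent abilities: trivariate Gaussian, corr 0.3
  Sigma <- matrix(0.3, 3, 3); diag(Sigma) <- 1
  A <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(Sigma)
  colnames(A) <- c("decision", "control", "psych")
  w <- latent_overall_weights()
  profiles <- data.frame(
    driver_id = sprintf("D%03d", seq_len(n)),
    age_group = rep(c("young", "old"), c(config$n_young, config$n_old)),
    counterbalance_group = rep_len(c("A", "B"), n),
    decision = A[, 1], control = A[, 2], psych = A[, 3],
    latent_overall = as.numeric(A %*% w),
    stringsAsFactors = FALSE
  )

  records <- simulate_records(profiles, es, config$indicator_noise_sd,
                              config$group_a_rt_offset)
  events <- session_events(config$duration_s)
  recordings <- lapply(seq_len(n), function(i) {
    simulate_recording(profiles$driver_id[i], A[i, ], es, config, events)
  })
  if (config$missing_rate > 0) {
    recordings <- lapply(recordings, function(r) {
      inject_missingness(r, config$missing_rate)
    })
  }
  structure(list(profiles = profiles, records = records,
                 recordings = recordings, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("synthetic driving cohort:", nrow(x$profiles), "drivers,",
      x$config$duration_s, "s sessions, effect size", x$config$effect_size, "\n")
  invisible(x)
}

# linear/thresholded link functions from latent ability to the ten
# task-performance indicators (decision a1, control a2, psych a3)
simulate_records <- function(profiles, es, noise_sd, group_a_rt_offset) {
  n <- nrow(profiles)
  a1 <- profiles$decision; a2 <- profiles$control; a3 <- profiles$psych
  eps <- function() stats::rnorm(n, 0, noise_sd)
  # scale of the latent-plus-noise predictor; discretization thresholds are
  # placed relative to it so binary/ordinal class balance does not depend on
  # effect_size (and effect_size = 0 leaves pure, balanced noise)
  s <- sqrt(es^2 + noise_sd^2)
  rec <- data.frame(
    driver_id = profiles$driver_id,
    avoid_count = pmax(0, round(12 + 1.5 * (es * a1 + eps()))),
    secondary_accuracy = stats::plogis(0.5 + 0.1 * (es * a1 + eps())),
    anticipation_correct = as.integer(es * a1 + eps() > 0),
    emergency_rt_s = exp(0.4 - 0.06 * (es * a2 - eps())),
    collision_extent = {
      u <- -(es * a2 + eps())
      as.integer(u > -0.43 * s) + as.integer(u > 0.43 * s)
    },
    secondary_rt_s = exp(0.9 - 0.05 * (es * a2 - eps())),
    line_cross = as.integer(-(es * a2 + eps()) > 0.25 * s),
    nasa_score = 50 - 5 * (es * a3 - eps()),
    anxiety_score = 40 - 4 * (es * a3 - eps()),
    ab_personality_score = 30 + 3 * (es * a3 + eps()),
    stringsAsFactors = FALSE
  )
  isA <- profiles$counterbalance_group == "A"
  rec$emergency_rt_s[isA] <- rec$emergency_rt_s[isA] + group_a_rt_offset
  rec
}

# scripted event schedule shared by all drivers (same simulated drive)
session_events <- function(duration_s) {
  ev <- list()
  add <- function(type, onsets, dur) {
    onsets <- onsets[onsets + dur <= duration_s]
    if (!length(onsets)) return()
    ev[[length(ev) + 1L]] <<- data.frame(
      event_type = type, onset_s = onsets, offset_s = onsets + dur,
      stringsAsFactors = FALSE)
  }
  add("secondary_task", seq(30, max(30, duration_s - 20), by = 60), 10)
  add("intersection", seq(90, max(90, duration_s - 15), by = 120), 6)
  add("emergency", floor(0.65 * duration_s), 3)
  if (!length(ev)) {
    return(data.frame(event_type = character(0), onset_s = numeric(0),
                      offset_s = numeric(0)))
  }
  out <- do.call(rbind, ev)
  out[order(out$onset_s), , drop = FALSE]
}

# AR(1) noise with stationary sd 1
ar1_noise <- function(n, phi = 0.9) {
  innov <- stats::rnorm(n, 0, sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

simulate_recording <- function(driver_id, a, es, config, events) {
  eff <- channel_effects()
  channels <- vector("list", nrow(eff))
  names(channels) <- eff$name
  for (j in seq_len(nrow(eff))) {
    nm <- eff$name[j]
    rate <- config$channel_rates[[nm]]
    nsamp <- floor(config$duration_s * rate)
    t <- (seq_len(nsamp) - 1) / rate
    mean_shift <- es * (eff$mean_decision[j] * a[1] +
                        eff$mean_control[j] * a[2] +
                        eff$mean_psych[j] * a[3])
    sd_eff <- eff$noise_sd[j] * exp(-0.35 * es * a[eff$noise_dim[j]])
    x <- eff$base[j] + mean_shift + sd_eff * ar1_noise(nsamp)
    if (eff$bump_amp[j] != 0) {
      types <- bump_event_types(nm)
      sel <- events[events$event_type %in% types, , drop = FALSE]
      for (k in seq_len(nrow(sel))) {
        on <- sel$onset_s[k]; off <- sel$offset_s[k]
        idx <- which(t >= on & t < off)
        if (length(idx)) {
          phase <- (t[idx] - on) / (off - on)
          x[idx] <- x[idx] + eff$bump_amp[j] * 0.5 * (1 - cos(2 * pi * phase))
        }
      }
    }
    channels[[j]] <- list(time_s = t, value = x)
  }
  list(driver_id = driver_id, channels = channels, event_log = events)
}

#' Replace a fraction of interior samples by missing markers
#'
#' Marks approximately `rate` of the interior samples of every channel as
#' missing (`NA`). The first and last sample of each channel are always
#' kept so that interpolation downstream is well defined.
#'
#' @param rec A session recording (element of `cohort$recordings`).
#' @param rate Fraction in `[0, 1)`.
#' @param seed Optional integer seed for the Bernoulli drop pattern.
#' @return The recording with `NA` values injected.
#' @export
inject_missingness <- function(rec, rate, seed = NULL) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("missing rate must lie in [0, 1)", call. = FALSE)
  }
  if (rate == 0) return(rec)
  if (!is.null(seed)) set.seed(seed)
  rec$channels <- lapply(rec$channels, function(ch) {
    n <- length(ch$value)
    if (n > 2) {
      drop <- stats::runif(n - 2) < rate
      ch$value[c(FALSE, drop, FALSE)] <- NA_real_
    }
    ch
  })
  rec
}
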