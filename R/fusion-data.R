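#' Synthetic windows whose label depends on a cross-modal interaction
#'
#' Generates a window set in which each subject carries two latent factors,
#' one expressed only in the physiological rows (1-4) and one only in the
#' non-physiological rows (5-15). The four-level label is the joint sign
#' pattern of the two factors (`2 * (u_p > 0) + (u_np > 0)`): each modality
#' alone carries one bit, so no single-modality reader can do better than
#' half the classes, and the classes {0,3} vs {1,2} are exactly the sign of
#' the cross-modal product `u_p * u_np`. This probes how well an
#' architecture combines both modalities and is used to order the ablation
#' variants.
#'
#' Each window row is a baseline 0.5 plus a level shift encoding the
#' modality's latent factor, a slow sinusoidal carrier, and white noise,
#' clipped to [0, 1] like preprocessed sensor windows.
#'
#' @param n_subjects Number of subjects.
#' @param windows_per_subject Windows generated per subject.
#' @param width Window width in samples (default 60 = one 60 s window at
#'   1 Hz).
#' @param effect_size Scales the latent level shift relative to the noise.
#' @param noise_sd White-noise standard deviation.
#' @param seed Integer seed.
#' @return A labeled `window_set` with 15-row windows.
#' @export
simulate_fusion_windows <- function(n_subjects = 32, windows_per_subject = 12,
                                    width = 60, effect_size = 3,
                                    noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  # balanced design: subjects are spread evenly over the four sign
  # quadrants, with magnitudes bounded away from the ambiguous origin
  quad <- sample(rep_len(0:3, n_subjects))
  up <- ifelse(quad >= 2, 1, -1) * (0.3 + abs(stats::rnorm(n_subjects)))
  un <- ifelse(quad %% 2 == 1, 1, -1) * (0.3 + abs(stats::rnorm(n_subjects)))
  labels_subj <- quad
  m <- n_subjects * windows_per_subject
  w <- array(0, c(15, width, m))
  t <- seq_len(width)
  carrier <- 0.05 * sin(2 * pi * t / width)
  amp <- 0.05 * effect_size
  k <- 0L
  for (s in seq_len(n_subjects)) {
    for (j in seq_len(windows_per_subject)) {
      k <- k + 1L
      phys <- 0.5 + amp * tanh(up[s]) + carrier
      nonp <- 0.5 + amp * tanh(un[s]) + carrier
      win <- rbind(matrix(rep(phys, each = 4), 4, width),
                   matrix(rep(nonp, each = 11), 11, width))
      win <- win + matrix(stats::rnorm(15 * width, 0, noise_sd), 15, width)
      w[, , k] <- pmin(1, pmax(0, win))
    }
  }
  window_set(w,
             labels = rep(labels_subj, each = windows_per_subject),
             subject_ids = rep(sprintf("S%03d", seq_len(n_subjects)),
                               each = windows_per_subject),
             window_len_s = width, step_s = width)
}
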