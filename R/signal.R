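#' Trim the session start and impute missing samples
#'
#' Drops the first `trim_s` seconds of every channel (the asynchronous
#' start-up period of multi-sensor rigs), shifts timestamps so the trimmed
#' recording starts at 0, linearly interpolates interior missing values and
#' fills leading/trailing missing values with the nearest valid sample.
#'
#' @param rec A session recording.
#' @param trim_s Seconds to drop from the start (>= 0).
#' @return The cleaned recording.
#' @export
trim_and_impute <- function(rec, trim_s = 0) {
  if (trim_s < 0) stop("trim_s must be >= 0", call. = FALSE)
  nms <- names(rec$channels)
  rec$channels <- lapply(nms, function(nm) {
    ch <- rec$channels[[nm]]
    keep <- ch$time_s >= trim_s
    t <- ch$time_s[keep] - trim_s
    v <- ch$value[keep]
    if (!length(v) || all(is.na(v))) {
      stop("channel '", nm, "' has no valid samples after trimming",
           call. = FALSE)
    }
    if (anyNA(v)) {
      ok <- which(!is.na(v))
      v <- stats::approx(t[ok], v[ok], xout = t, rule = 2)$y
    }
    list(time_s = t, value = v)
  })
  names(rec$channels) <- nms
  if (!is.null(rec$event_log) && nrow(rec$event_log)) {
    ev <- rec$event_log
    ev$onset_s <- ev$onset_s - trim_s
    ev$offset_s <- ev$offset_s - trim_s
    rec$event_log <- ev[ev$offset_s > 0, , drop = FALSE]
  }
  rec
}

#' Min-max normalize a recording to [0, 1]
#'
#' Per channel, `x' = (x - x_min) / (x_max - x_min)`. With `params = NULL`
#' the extrema are taken from the recording itself (per-recording scope);
#' passing parameters fitted on training recordings (per-training-set scope,
#' see [fit_normalization()]) reuses them verbatim, which avoids information
#' leakage into held-out subjects. A constant channel maps to all-zero;
#' values outside a supplied range are clipped to [0, 1].
#'
#' @param rec A cleaned session recording.
#' @param params Optional `normalization_params`.
#' @return List with `rec` (normalized) and `params` (the parameters used).
#' @export
minmax_normalize <- function(rec, params = NULL) {
  scope <- if (is.null(params)) "per_recording" else params$scope
  if (is.null(params)) {
    rng <- lapply(rec$channels, function(ch) range(ch$value))
    params <- structure(list(
      x_min = vapply(rng, `[`, numeric(1), 1),
      x_max = vapply(rng, `[`, numeric(1), 2),
      scope = scope), class = "normalization_params")
  }
  nms <- names(rec$channels)
  rec$channels <- lapply(nms, function(nm) {
    ch <- rec$channels[[nm]]
    lo <- params$x_min[[nm]]; hi <- params$x_max[[nm]]
    if (hi > lo) {
      ch$value <- pmin(1, pmax(0, (ch$value - lo) / (hi - lo)))
    } else {
      ch$value <- rep(0, length(ch$value))
    }
    ch
  })
  names(rec$channels) <- nms
  list(rec = rec, params = params)
}

#' Fit training-set normalization parameters
#'
#' Per-channel global minima/maxima over a set of (training) recordings, for
#' leakage-free per-training-set normalization scope.
#'
#' @param recordings List of cleaned session recordings.
#' @return A `normalization_params` with scope `"per_training_set"`.
#' @export
fit_normalization <- function(recordings) {
  nms <- names(recordings[[1]]$channels)
  x_min <- stats::setNames(rep(Inf, length(nms)), nms)
  x_max <- stats::setNames(rep(-Inf, length(nms)), nms)
  for (rec in recordings) {
    for (nm in nms) {
      r <- range(rec$channels[[nm]]$value)
      x_min[nm] <- min(x_min[nm], r[1])
      x_max[nm] <- max(x_max[nm], r[2])
    }
  }
  structure(list(x_min = x_min, x_max = x_max, scope = "per_training_set"),
            class = "normalization_params")
}

#' Resample all channels to a common grid
#'
#' Channels faster than the target rate are aggregated by the mean within
#' each target-grid bin; channels slower than the target rate are linearly
#' interpolated. The output matrix is truncated to the shortest channel so
#' all 15 rows share one time axis (physiological rows first, registry
#' order).
#'
#' @param rec A cleaned, imputed session recording.
#' @param target_rate Common rate in Hz (default 1).
#' @param label Optional ability label carried along with the matrix.
#' @return An `aligned_matrix`: list with `driver_id`, `values` (15 x T),
#'   `rate_hz`, `label`.
#' @export
resample_align <- function(rec, target_rate = 1, label = NA_integer_) {
  if (target_rate <= 0) stop("target_rate must be > 0", call. = FALSE)
  rows <- lapply(names(rec$channels), function(nm) {
    ch <- rec$channels[[nm]]
    n <- length(ch$value)
    native <- if (n >= 2) (n - 1) / (ch$time_s[n] - ch$time_s[1]) else 0
    if (n >= 2 && native >= target_rate) {
      bin <- floor(ch$time_s * target_rate)
      agg <- rowsum(ch$value, bin)
      cnt <- rowsum(rep(1, n), bin)
      as.numeric(agg / cnt)
    } else {
      grid <- seq(0, max(ch$time_s), by = 1 / target_rate)
      stats::approx(ch$time_s, ch$value, xout = grid, rule = 2)$y
    }
  })
  T_len <- min(vapply(rows, length, integer(1)))
  values <- do.call(rbind, lapply(rows, function(r) r[seq_len(T_len)]))
  rownames(values) <- names(rec$channels)
  structure(list(driver_id = rec$driver_id, values = values,
                 rate_hz = target_rate, label = label),
            class = "aligned_matrix")
}

#' Cut an aligned matrix into overlapping windows
#'
#' Sliding windows of length `L_s` seconds stepped by `S_s` seconds over the
#' aligned 15-row matrix; the count is `floor((T - L) / S) + 1`. The
#' driver's label is replicated onto every window; windows are half-open
#' `[start, start + L)` and indexed from the recording start.
#'
#' @param aligned An `aligned_matrix`.
#' @param L_s Window length in seconds.
#' @param S_s Step in seconds (> 0).
#' @param label Label replicated to all windows (default: the aligned
#'   matrix's own label).
#' @return A `window_set`: `windows` (H x W x m array), `labels`,
#'   `subject_ids`, `window_len_s`, `step_s`.
#' @export
make_windows <- function(aligned, L_s, S_s, label = aligned$label) {
  rate <- aligned$rate_hz
  Tn <- ncol(aligned$values)
  Lw <- round(L_s * rate)
  Sw <- round(S_s * rate)
  if (Sw <= 0) stop("step S_s must be > 0", call. = FALSE)
  if (Lw > Tn) stop("window length ", L_s, " s exceeds recording duration ",
                    Tn / rate, " s", call. = FALSE)
  m <- floor((Tn - Lw) / Sw) + 1L
  H <- nrow(aligned$values)
  w <- array(NA_real_, c(H, Lw, m))
  for (i in seq_len(m)) {
    start <- (i - 1L) * Sw
    w[, , i] <- aligned$values[, (start + 1L):(start + Lw)]
  }
  window_set(w, labels = rep(label, m),
             subject_ids = rep(aligned$driver_id, m),
             window_len_s = L_s, step_s = S_s)
}

#' Construct a window set
#'
#' @param windows H x W x m array of windows (H = 15 registry channels).
#' @param labels Integer labels, one per window.
#' @param subject_ids Subject id per window.
#' @param window_len_s,step_s Window geometry in seconds.
#' @return A `window_set`.
#' @export
window_set <- function(windows, labels, subject_ids, window_len_s, step_s) {
  m <- dim(windows)[3]
  stopifnot(length(labels) == m, length(subject_ids) == m)
  structure(list(windows = windows, labels = labels,
                 subject_ids = subject_ids,
                 window_len_s = window_len_s, step_s = step_s),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat("window set:", d[3], "windows of", d[1], "x", d[2], "from",
      length(unique(x$subject_ids)), "subjects\n")
  if (!all(is.na(x$labels))) {
    cat("label counts:\n"); print(table(x$labels))
  }
  invisible(x)
}

#' Concatenate window sets
#'
#' @param ... `window_set` objects with identical window geometry.
#' @return A single `window_set`.
#' @export
combine_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "window_set")) {
    sets <- sets[[1]]
  }
  d <- dim(sets[[1]]$windows)[1:2]
  for (s in sets) stopifnot(all(dim(s$windows)[1:2] == d))
  m <- sum(vapply(sets, function(s) dim(s$windows)[3], integer(1)))
  w <- array(NA_real_, c(d, m))
  at <- 0L
  for (s in sets) {
    k <- dim(s$windows)[3]
    w[, , at + seq_len(k)] <- s$windows
    at <- at + k
  }
  window_set(w, unlist(lapply(sets, `[[`, "labels")),
             unlist(lapply(sets, `[[`, "subject_ids")),
             sets[[1]]$window_len_s, sets[[1]]$step_s)
}

#' Split a window into its physiological and non-physiological images
#'
#' Rows 1-4 of a 15-row window are the physiological channels, rows 5-15 the
#' non-physiological channels (registry order).
#'
#' @param window A 15 x W matrix.
#' @return List with `phys` (4 x W) and `nonphys` (11 x W).
#' @export
split_modalities <- function(window) {
  if (nrow(window) != 15) {
    stop("window must have 15 rows (registry order), got ", nrow(window),
         call. = FALSE)
  }
  list(phys = window[1:4, , drop = FALSE],
       nonphys = window[5:15, , drop = FALSE])
}

#' Preprocess a whole cohort into a labeled window set
#'
#' Runs trim/impute, min-max normalization, resampling to the common grid
#' and windowing for every driver, attaching the driver's ability label to
#' all of their windows.
#'
#' @param cohort A `cohort`.
#' @param labels Data.frame with `driver_id` and `label` (e.g. from
#'   [label_drivers()]).
#' @param trim_s,target_rate,L_s,S_s Preprocessing settings (defaults: no
#'   trim, 1 Hz grid, 60 s windows, 5 s step).
#' @param norm_params Optional `normalization_params` for per-training-set
#'   scope; NULL normalizes per recording.
#' @return A `window_set` over all drivers.
#' @export
build_window_set <- function(cohort, labels, trim_s = 0, target_rate = 1,
                             L_s = 60, S_s = 5, norm_params = NULL) {
  lab <- stats::setNames(labels$label, labels$driver_id)
  sets <- lapply(cohort$recordings, function(rec) {
    rec <- trim_and_impute(rec, trim_s)
    rec <- minmax_normalize(rec, norm_params)$rec
    al <- resample_align(rec, target_rate, label = lab[[rec$driver_id]])
    make_windows(al, L_s, S_s)
  })
  combine_window_sets(sets)
}

#' Subject-wise train/test split of a window set
#'
#' Splits at the subject level so no subject contributes windows to both
#' sides.
#'
#' @param ws A `window_set`.
#' @param test_fraction Fraction of subjects held out.
#' @param seed Integer seed for the subject draw.
#' @return List with `train` and `test` window sets and the id vectors.
#' @export
subject_split <- function(ws, test_fraction = 0.2, seed = 1L) {
  subj <- unique(ws$subject_ids)
  set.seed(seed)
  n_test <- max(1L, round(length(subj) * test_fraction))
  test_subj <- sample(subj, n_test)
  list(train = subset_windows(ws, !(ws$subject_ids %in% test_subj)),
       test = subset_windows(ws, ws$subject_ids %in% test_subj),
       train_subjects = setdiff(subj, test_subj), test_subjects = test_subj)
}

subset_windows <- function(ws, keep) {
  idx <- which(keep)
  window_set(ws$windows[, , idx, drop = FALSE], ws$labels[idx],
             ws$subject_ids[idx], ws$window_len_s, ws$step_s)
}
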