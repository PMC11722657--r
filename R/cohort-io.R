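#' Write a cohort to disk as CSV + JSON manifest
#'
#' Writes `recordings.csv` (long format: driver_id, time_s, channel, value),
#' `performance.csv` (one row per driver, the ten raw indicators),
#' `profiles.csv`, `events.csv` and `manifest.json` (config echo, channel
#' registry, seed). Missing samples are written as empty fields.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- data.table::rbindlist(lapply(cohort$recordings, function(rec) {
    data.table::rbindlist(lapply(names(rec$channels), function(nm) {
      ch <- rec$channels[[nm]]
      data.table::data.table(driver_id = rec$driver_id, time_s = ch$time_s,
                             channel = nm, value = ch$value)
    }))
  }))
  data.table::fwrite(long, file.path(dir, "recordings.csv"), na = "")
  data.table::fwrite(cohort$records, file.path(dir, "performance.csv"), na = "")
  data.table::fwrite(cohort$profiles, file.path(dir, "profiles.csv"), na = "")
  ev <- data.table::rbindlist(lapply(cohort$recordings, function(rec) {
    if (!nrow(rec$event_log)) return(NULL)
    data.table::data.table(driver_id = rec$driver_id, rec$event_log)
  }))
  if (is.null(ev) || !nrow(ev)) {
    ev <- data.table::data.table(driver_id = character(0),
                                 event_type = character(0),
                                 onset_s = numeric(0), offset_s = numeric(0))
  }
  data.table::fwrite(ev, file.path(dir, "events.csv"), na = "")
  manifest <- list(
    n_drivers = nrow(cohort$profiles),
    n_channels = length(channel_registry()$name),
    channels = stats::setNames(as.list(cohort$config$channel_rates),
                               names(cohort$config$channel_rates)),
    config = cohort$config[c("n_young", "n_old", "duration_s", "effect_size",
                             "indicator_noise_sd", "group_a_rt_offset",
                             "missing_rate", "seed")]
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  dt <- data.table::fread(path, na.strings = "")
  miss <- setdiff(required, names(dt))
  if (length(miss)) {
    stop("parse error in ", basename(path), " (line 1): missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dt
}

check_numeric_col <- function(dt, col, file) {
  v <- dt[[col]]
  if (is.numeric(v) || is.logical(v)) return(invisible())
  bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))[1]
  stop("parse error in ", file, " (line ", bad + 1L, "): non-numeric value '",
       v[bad], "' in column ", col, call. = FALSE)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the CSV files and `manifest.json`.
#' @return A `cohort` list (profiles, records, recordings, config echo).
#'   Round-trips [write_cohort()] output up to float formatting (< 1e-9).
#' @export
read_cohort <- function(dir) {
  long <- read_csv_checked(file.path(dir, "recordings.csv"),
                           c("driver_id", "time_s", "channel", "value"))
  for (col in c("time_s", "value")) {
    check_numeric_col(long, col, "recordings.csv")
  }
  records <- read_csv_checked(file.path(dir, "performance.csv"),
                              c("driver_id", indicator_names()))
  profiles <- read_csv_checked(file.path(dir, "profiles.csv"),
                               c("driver_id", "age_group", "counterbalance_group"))
  events <- read_csv_checked(file.path(dir, "events.csv"),
                             c("driver_id", "event_type", "onset_s", "offset_s"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ids <- unique(long$driver_id)
  reg_order <- channel_registry()$name
  recordings <- lapply(ids, function(id) {
    sub <- long[long$driver_id == id, ]
    chans <- lapply(reg_order, function(nm) {
      s <- sub[sub$channel == nm, ]
      list(time_s = s$time_s, value = s$value)
    })
    names(chans) <- reg_order
    ev <- events[events$driver_id == id, c("event_type", "onset_s", "offset_s")]
    list(driver_id = id, channels = chans,
         event_log = as.data.frame(ev))
  })
  structure(list(profiles = as.data.frame(profiles),
                 records = as.data.frame(records),
                 recordings = recordings,
                 config = manifest$config),
            class = "cohort")
}

indicator_names <- function() {
  c("avoid_count", "secondary_accuracy", "anticipation_correct",
    "emergency_rt_s", "collision_extent", "secondary_rt_s", "line_cross",
    "nasa_score", "anxiety_score", "ab_personality_score")
}
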