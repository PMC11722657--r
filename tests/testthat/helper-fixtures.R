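# small in-code fixtures shared across test files

# a hand-built recording with a few channels (names need not be the full
# registry for the channel-level signal ops)
toy_recording <- function(channels) {
  list(driver_id = "T001", channels = channels,
       event_log = data.frame(event_type = character(0), onset_s = numeric(0),
                              offset_s = numeric(0)))
}

toy_channel <- function(values, rate = 1) {
  list(time_s = (seq_along(values) - 1) / rate, value = values)
}

# performance records with exactly controlled indicator values
toy_records <- function(n = 12, seed = 1) {
  set.seed(seed)
  data.frame(
    driver_id = sprintf("D%03d", seq_len(n)),
    avoid_count = rpois(n, 8),
    secondary_accuracy = runif(n, 0.3, 0.9),
    anticipation_correct = rbinom(n, 1, 0.5),
    emergency_rt_s = runif(n, 0.8, 2.5),
    collision_extent = sample(0:2, n, replace = TRUE),
    secondary_rt_s = runif(n, 1.5, 4),
    line_cross = rbinom(n, 1, 0.3),
    nasa_score = runif(n, 20, 80),
    anxiety_score = runif(n, 10, 70),
    ab_personality_score = runif(n, 10, 50),
    stringsAsFactors = FALSE
  )
}

# component matrix with prescribed oriented z values (bypasses standardize)
toy_component_matrix <- function(values_by_dim) {
  nms <- names(drivecog::dimension_map())
  dm <- drivecog::dimension_map()
  n <- length(values_by_dim)
  z <- matrix(0, n, length(nms), dimnames = list(sprintf("D%03d", seq_len(n)), nms))
  for (i in seq_len(n)) {
    for (nm in nms) z[i, nm] <- values_by_dim[[i]][[dm[[nm]]]]
  }
  structure(list(driver_ids = rownames(z), components = z,
                 orientation = drivecog::default_orientation()),
            class = "component_matrix")
}

# tiny model config used where the architecture itself is under test
tiny_config <- function(variant = "dual_branch_aff", D = 16, L = 1, heads = 2,
                        dropout = 0) {
  fusion_model_config(variant, embed_dim = D, n_layers = L, n_heads = heads,
                      dropout = dropout)
}

random_window_batch <- function(B = 4, width = 60, seed = 1) {
  set.seed(seed)
  array(runif(15 * width * B), c(15, width, B))
}
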