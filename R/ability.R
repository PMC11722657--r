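#' Mapping of the ten cognitive components onto the three ability dimensions
#'
#' The ten task-performance indicators group into three dimensions of
#' driving-related cognitive ability: cognitive decision-making (attention
#' allocation = secondary-task avoidance count, working memory =
#' secondary-task accuracy, anticipation = traffic-signal anticipation),
#' vehicle control (reaction = emergency reaction time, judgment = collision
#' extent, processing speed = secondary-task reaction time, perception =
#' line crossing) and psychological regulation (stress resistance = NASA
#' workload score, anxiety level, Type A/B personality score).
#'
#' @return Named character vector: indicator name -> dimension
#'   (`"decision"`, `"control"`, `"psych"`).
#' @export
dimension_map <- function() {
  c(avoid_count = "decision", secondary_accuracy = "decision",
    anticipation_correct = "decision",
    emergency_rt_s = "control", collision_extent = "control",
    secondary_rt_s = "control", line_cross = "control",
    nasa_score = "psych", anxiety_score = "psych",
    ab_personality_score = "psych")
}

#' Default component orientation
#'
#' Sign applied to each standardized component so that larger always means
#' better ability: both reaction times, collision extent, line crossing,
#' NASA workload and anxiety are higher-is-worse and get sign -1.
#'
#' @return Named numeric vector of +1/-1 over the ten components.
#' @export
default_orientation <- function() {
  o <- stats::setNames(rep(1, 10), indicator_names())
  o[c("emergency_rt_s", "secondary_rt_s", "collision_extent",
      "line_cross", "nasa_score", "anxiety_score")] <- -1
  o
}

#' Compensate the group-A emergency reaction-time bias
#'
#' Counterbalance group A performed an extra task during the emergency
#' scenario, biasing its reaction times upward. The default mode computes
#' the compensation as the difference of the two group means,
#' `CRT = mean(RT_A) - mean(RT_B)`, and subtracts it from every group-A
#' reaction time. `mode = "literal_eq2"` instead uses the group-sum
#' difference divided by the total number of drivers,
#' `CRT = (sum(RT_A) - sum(RT_B)) / N`, applied the same way.
#'
#' @param records Task-performance data.frame with `driver_id` and
#'   `emergency_rt_s`.
#' @param group_map Named character vector driver_id -> "A"/"B".
#' @param mode `"mean_difference"` (default) or `"literal_eq2"`.
#' @return List with `records` (adjusted) and `adjustment` (crt, rta, rtb,
#'   n_total, mode).
#' @export
compensate_reaction_times <- function(records, group_map,
                                      mode = c("mean_difference", "literal_eq2")) {
  mode <- match.arg(mode)
  unknown <- setdiff(records$driver_id, names(group_map))
  if (length(unknown)) {
    stop("driver(s) missing from group_map: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  grp <- group_map[records$driver_id]
  rt <- records$emergency_rt_s
  if (!any(grp == "A") || !any(grp == "B")) {
    stop("both counterbalance groups must be non-empty", call. = FALSE)
  }
  if (any(rt <= 0)) stop("reaction times must be positive", call. = FALSE)
  rta <- mean(rt[grp == "A"])
  rtb <- mean(rt[grp == "B"])
  n_total <- length(rt)
  crt <- switch(mode,
    mean_difference = rta - rtb,
    literal_eq2 = (sum(rt[grp == "A"]) - sum(rt[grp == "B"])) / n_total
  )
  records$emergency_rt_s[grp == "A"] <- rt[grp == "A"] - crt
  list(records = records,
       adjustment = list(crt = crt, rta = rta, rtb = rtb,
                         n_total = n_total, mode = mode))
}

#' Encode raw task-performance records as a numeric component matrix
#'
#' Continuous indicators pass through; binary indicators (anticipation
#' correctness, line crossing) map to 0/1 ("no collision" style encoding),
#' the ordinal collision extent maps to 0/1/2. Logical columns are accepted
#' and coerced.
#'
#' @param records Data.frame with `driver_id` and the ten indicator columns.
#' @return Numeric matrix, one row per driver, 10 named columns; rownames
#'   are driver ids.
#' @export
encode_components <- function(records) {
  nms <- indicator_names()
  miss <- setdiff(nms, names(records))
  if (length(miss)) {
    stop("records missing indicator column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- matrix(NA_real_, nrow(records), length(nms),
              dimnames = list(records$driver_id, nms))
  domains <- list(anticipation_correct = 0:1, line_cross = 0:1,
                  collision_extent = 0:2)
  for (nm in nms) {
    v <- records[[nm]]
    if (is.logical(v)) v <- as.numeric(v)
    if (!is.numeric(v)) {
      stop("indicator ", nm, " is not numeric", call. = FALSE)
    }
    if (nm %in% names(domains)) {
      bad <- which(!(v %in% domains[[nm]]))
      if (length(bad)) {
        stop("out-of-domain value for driver ", records$driver_id[bad[1]],
             ", field ", nm, ": ", v[bad[1]], call. = FALSE)
      }
    }
    if (anyNA(v)) {
      stop("missing value for driver ",
           records$driver_id[which(is.na(v))[1]], ", field ", nm,
           call. = FALSE)
    }
    m[, nm] <- v
  }
  m
}

#' Standardize and orient the component matrix
#'
#' Column-wise z-scores `Z = (X - mean) / sd` (sample sd, divisor n-1), then
#' multiplied by the orientation sign of each component so that larger
#' oriented values always mean better ability. A constant column (sd 0) is
#' set to all-zero with a warning.
#'
#' @param mat Numeric matrix from [encode_components()].
#' @param orientation Named +1/-1 vector; defaults to [default_orientation()].
#' @return A `component_matrix`: list with `driver_ids`, `components`
#'   (oriented z-score matrix) and `orientation`.
#' @export
standardize_components <- function(mat, orientation = default_orientation()) {
  if (nrow(mat) < 2) stop("need at least 2 rows to standardize", call. = FALSE)
  miss <- setdiff(colnames(mat), names(orientation))
  if (length(miss)) {
    stop("orientation missing for component(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  z <- mat
  for (j in seq_len(ncol(mat))) {
    s <- stats::sd(mat[, j])
    if (s == 0) {
      warning("component '", colnames(mat)[j],
              "' is constant; standardized column set to zero")
      z[, j] <- 0
    } else {
      z[, j] <- (mat[, j] - mean(mat[, j])) / s
    }
    z[, j] <- z[, j] * orientation[[colnames(mat)[j]]]
  }
  structure(list(driver_ids = rownames(mat), components = z,
                 orientation = orientation[colnames(mat)]),
            class = "component_matrix")
}

#' Shipped default dimension weights
#'
#' The default weight model assigns the three ability dimensions the weights
#' W = (0.3898, 0.3182, 0.2920) for decision-making, vehicle control and
#' psychological regulation respectively (summing to 1), reflecting their
#' relative importance for driving safety.
#'
#' @return A `weight_model` with only the `weights` slot populated.
#' @export
default_weight_model <- function() {
  structure(list(loadings = NULL, variance_ratios = NULL, k_components = NULL,
                 weights = c(decision = 0.3898, control = 0.3182, psych = 0.2920),
                 raw_weights = NULL, normalized = TRUE),
            class = "weight_model")
}

#' Fit PCA-based dimension weights
#'
#' Runs principal component analysis on the oriented standardized component
#' matrix (its covariance equals the component correlation matrix). Each
#' component's raw weight aggregates its loading magnitudes over the first K
#' principal components weighted by each component's share of total
#' variance, `w_i = sum_k |L_ik| * V_k` (the magnitude reading keeps the
#' importance of a variable from cancelling across oppositely-signed
#' loadings). Loadings' signs are also fixed so each principal component's
#' largest-magnitude loading is positive. The three dimension weights are
#' the means of `w_i` over each dimension's components, normalized to
#' sum 1.
#'
#' @param cm A `component_matrix`.
#' @param k_components Number of principal components K; default: smallest K
#'   with cumulative variance ratio >= 0.8.
#' @return A `weight_model` with loadings, variance ratios, raw per-component
#'   weights and the normalized 3-vector of dimension weights.
#' @export
fit_pca_weights <- function(cm, k_components = NULL) {
  z <- cm$components
  if (nrow(z) < 10) stop("need at least 10 drivers to fit weights", call. = FALSE)
  p <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  L <- p$rotation
  ev <- p$sdev^2
  V <- ev / sum(ev)
  # sign convention: largest-|loading| entry of each PC positive
  for (k in seq_len(ncol(L))) {
    i <- which.max(abs(L[, k]))
    if (L[i, k] < 0) L[, k] <- -L[, k]
  }
  if (is.null(k_components)) {
    k_components <- which(cumsum(V) >= 0.8)[1]
  }
  if (is.null(k_components) || is.na(k_components) || k_components < 1) {
    stop("k_components must be >= 1", call. = FALSE)
  }
  k_components <- min(k_components, ncol(L))
  K <- seq_len(k_components)
  raw <- as.numeric(abs(L[, K, drop = FALSE]) %*% V[K])
  names(raw) <- rownames(L)
  dm <- dimension_map()[names(raw)]
  dims <- c("decision", "control", "psych")
  wdim <- vapply(dims, function(d) mean(raw[dm == d]), numeric(1))
  wdim <- wdim / sum(wdim)
  structure(list(loadings = L, variance_ratios = V,
                 k_components = k_components, weights = wdim,
                 raw_weights = raw, normalized = TRUE),
            class = "weight_model")
}

#' @export
print.weight_model <- function(x, ...) {
  cat("ability dimension weights:\n")
  print(round(x$weights, 4))
  if (!is.null(x$k_components)) {
    cat("fitted by PCA with K =", x$k_components, "components\n")
  } else {
    cat("(shipped default weights)\n")
  }
  invisible(x)
}

#' Compute composite ability scores
#'
#' Each dimension score is the mean of that dimension's oriented z-scored
#' components; the composite `Score = sum_i W_i * dim_i` weights the three
#' dimension scores.
#'
#' @param cm A `component_matrix`.
#' @param weight_model A `weight_model` (default: [default_weight_model()]).
#' @return Data.frame: driver_id, dim_decision, dim_control, dim_psych, score.
#' @export
compute_scores <- function(cm, weight_model = default_weight_model()) {
  dm <- dimension_map()[colnames(cm$components)]
  dims <- c("decision", "control", "psych")
  ds <- vapply(dims, function(d) {
    cols <- which(dm == d)
    if (!length(cols)) stop("dimension '", d, "' has no components", call. = FALSE)
    rowMeans(cm$components[, cols, drop = FALSE])
  }, numeric(nrow(cm$components)))
  if (is.null(dim(ds))) ds <- matrix(ds, nrow = 1, dimnames = list(NULL, dims))
  w <- weight_model$weights[dims]
  data.frame(driver_id = cm$driver_ids,
             dim_decision = ds[, "decision"],
             dim_control = ds[, "control"],
             dim_psych = ds[, "psych"],
             score = as.numeric(ds %*% w),
             stringsAsFactors = FALSE)
}

#' Fit Gaussian-rule quartile thresholds for the composite score
#'
#' Thresholds `Q_i = mean + sd * z_pi` with `z_pi` the standard-normal
#' quantiles at p = 0.25, 0.50, 0.75 (so Q2 always equals the mean).
#'
#' @param scores Numeric vector of composite scores, or the data.frame from
#'   [compute_scores()].
#' @return A `label_thresholds` list: q1, q2, q3, mu, sigma, z_percentiles,
#'   score_min, score_max.
#' @export
fit_thresholds <- function(scores) {
  if (is.data.frame(scores)) scores <- scores$score
  if (length(scores) < 8) stop("need at least 8 scores", call. = FALSE)
  mu <- mean(scores)
  sigma <- stats::sd(scores)
  if (sigma == 0) stop("degenerate cohort: score standard deviation is 0",
                       call. = FALSE)
  zp <- stats::qnorm(c(0.25, 0.5, 0.75))
  q <- mu + sigma * zp
  structure(list(q1 = q[1], q2 = q[2], q3 = q[3], mu = mu, sigma = sigma,
                 z_percentiles = zp, score_min = min(scores),
                 score_max = max(scores)),
            class = "label_thresholds")
}

#' Rank-based inverse-normal transform
#'
#' Optional pre-transform mapping scores to normal quantiles of their
#' mid-ranks (Blom-style offset 0.5/n), for cohorts whose composite scores
#' are far from Gaussian.
#'
#' @param scores Numeric vector.
#' @return Transformed vector on the standard-normal scale.
#' @export
rank_inverse_normal <- function(scores) {
  n <- length(scores)
  stats::qnorm((rank(scores, ties.method = "average") - 0.5) / n)
}

#' Assign four-level ability labels
#'
#' Maps each score to a grade: 0 "Insufficient" on `[min, Q1)`, 1 "Fair" on
#' `[Q1, Q2)`, 2 "Good" on `[Q2, Q3)`, 3 "Excellent" on `[Q3, max]`.
#' Intervals are left-closed: a score exactly on a threshold goes to the
#' higher class.
#'
#' @param scores Numeric vector or the data.frame from [compute_scores()].
#' @param thresholds A `label_thresholds` from [fit_thresholds()].
#' @return Data.frame: driver_id (if available), score, label (0-3),
#'   grade_name.
#' @export
assign_labels <- function(scores, thresholds) {
  ids <- NULL
  if (is.data.frame(scores)) {
    ids <- scores$driver_id
    scores <- scores$score
  }
  q <- c(thresholds$q1, thresholds$q2, thresholds$q3)
  if (is.unsorted(q)) stop("thresholds must be ordered q1 <= q2 <= q3",
                           call. = FALSE)
  label <- findInterval(scores, q)
  grades <- c("Insufficient", "Fair", "Good", "Excellent")
  out <- data.frame(score = scores, label = label,
                    grade_name = grades[label + 1L],
                    stringsAsFactors = FALSE)
  if (!is.null(ids)) out <- cbind(data.frame(driver_id = ids,
                                             stringsAsFactors = FALSE), out)
  out
}

#' Full labelling pipeline on task-performance records
#'
#' Convenience wrapper: reaction-time compensation, encoding,
#' standardization, weighting (shipped default weights or a fresh PCA fit),
#' threshold fitting and label assignment.
#'
#' @param records Task-performance data.frame.
#' @param group_map Named driver_id -> "A"/"B" map for reaction-time
#'   compensation, or NULL to skip compensation.
#' @param weights `"default"` or `"fit"`.
#' @param orientation Component orientation map.
#' @return List: labels (data.frame), scores, thresholds, weight_model,
#'   adjustment.
#' @export
label_drivers <- function(records, group_map = NULL,
                          weights = c("default", "fit"),
                          orientation = default_orientation()) {
  weights <- match.arg(weights)
  adj <- NULL
  if (!is.null(group_map)) {
    comp <- compensate_reaction_times(records, group_map)
    records <- comp$records
    adj <- comp$adjustment
  }
  cm <- standardize_components(encode_components(records), orientation)
  wm <- if (weights == "fit") fit_pca_weights(cm) else default_weight_model()
  sc <- compute_scores(cm, wm)
  th <- fit_thresholds(sc)
  list(labels = assign_labels(sc, th), scores = sc, thresholds = th,
       weight_model = wm, adjustment = adj)
}
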