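#' Leave-one-subject-out folds
#'
#' One fold per subject: that subject's windows form the test set, everyone
#' else's the training set, preventing identity leakage.
#'
#' @param subject_ids Character vector of unique subject ids.
#' @return A `fold_spec`: list of folds, each with `train` and `test` ids.
#' @export
loso_folds <- function(subject_ids) {
  if (anyDuplicated(subject_ids)) {
    stop("duplicate subject ids", call. = FALSE)
  }
  if (length(subject_ids) < 2) stop("need at least 2 subjects", call. = FALSE)
  folds <- lapply(subject_ids, function(s) {
    list(train = setdiff(subject_ids, s), test = s)
  })
  structure(folds, class = "fold_spec")
}

#' Subject-grouped holdout folds
#'
#' Partitions subjects into `k` groups; each fold tests one group. `k = 1`
#' gives a single holdout split with `test_fraction` of subjects.
#'
#' @param subject_ids Unique subject ids.
#' @param k Number of folds.
#' @param test_fraction Held-out fraction when `k = 1`.
#' @param seed Integer seed for the assignment.
#' @return A `fold_spec`.
#' @export
holdout_folds <- function(subject_ids, k = 1, test_fraction = 0.25, seed = 1L) {
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids", call. = FALSE)
  set.seed(seed)
  if (k == 1) {
    n_test <- max(1L, round(length(subject_ids) * test_fraction))
    test <- sample(subject_ids, n_test)
    folds <- list(list(train = setdiff(subject_ids, test), test = test))
  } else {
    grp <- sample(rep_len(seq_len(k), length(subject_ids)))
    folds <- lapply(seq_len(k), function(g) {
      list(train = subject_ids[grp != g], test = subject_ids[grp == g])
    })
  }
  structure(folds, class = "fold_spec")
}

#' Class-stratified holdout fold
#'
#' Builds a single train/test fold holding out `test_per_class` subjects of
#' every label, so the test set always contains all classes. Assumes each
#' subject carries one label (the window-set convention).
#'
#' @param ws A labeled `window_set`.
#' @param test_per_class Held-out subjects per class.
#' @return A `fold_spec` with one fold.
#' @export
stratified_holdout_fold <- function(ws, test_per_class = 2) {
  first <- !duplicated(ws$subject_ids)
  subj <- ws$subject_ids[first]
  lab <- ws$labels[first]
  test <- unlist(lapply(split(subj, lab), utils::head, test_per_class))
  structure(list(list(train = setdiff(subj, test), test = unname(test))),
            class = "fold_spec")
}

#' Classification metrics and confusion matrix
#'
#' Accuracy is the fraction of correct predictions (the confusion-matrix
#' trace over the total, equal to the one-vs-rest micro form). Per-class
#' precision, recall and `F1 = 2PR / (P + R)` are computed one-vs-rest with
#' zero-division guarded to 0; macro-F1 averages F1 over `classes`.
#'
#' @param truth,pred Integer label vectors of equal length.
#' @param classes Class set; defaults to the sorted union of observed
#'   labels. Pass `0:3` for the four ability grades.
#' @return An `evaluation_report`: `acc`, `f1` (macro), `micro_f1`,
#'   `per_class` (P/R/F1/TP/TN/FP/FN), `confusion` (rows = truth),
#'   `confusion_norm` (row-normalized), `n`.
#' @export
compute_metrics <- function(truth, pred, classes = NULL) {
  if (length(truth) == 0) stop("empty input", call. = FALSE)
  if (length(truth) != length(pred)) stop("length mismatch", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  f <- factor(truth, levels = classes)
  p <- factor(pred, levels = classes)
  cm <- table(truth = f, predicted = p)
  n <- length(truth)
  acc <- sum(diag(cm)) / n
  per <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    tn <- n - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1, TP = tp, TN = tn, FP = fp,
      FN = fn)
  })
  per <- do.call(rbind, per)
  rownames(per) <- as.character(classes)
  rs <- rowSums(cm)
  cm_norm <- sweep(cm, 1, ifelse(rs > 0, rs, 1), "/")
  structure(list(acc = acc, f1 = mean(per[, "f1"]), micro_f1 = acc,
                 per_class = per, confusion = unclass(cm),
                 confusion_norm = unclass(cm_norm), n = n,
                 classes = classes),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("n = %d  ACC = %.4f  macro-F1 = %.4f\n", x$n, x$acc, x$f1))
  cat("confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Cross-validated evaluation of one model configuration
#'
#' Trains on each fold's training subjects and predicts its test subjects;
#' all test predictions are pooled and scored once (per-fold reports are
#' also returned). A model never sees any window of its fold's test
#' subjects.
#'
#' @param ws A labeled `window_set`.
#' @param config A [fusion_model_config()].
#' @param tc A [train_config()].
#' @param folds A `fold_spec` (default: LOSO over the subjects of `ws`).
#' @return List with `report` (pooled `evaluation_report`), `per_fold`,
#'   `truth`, `pred`.
#' @export
evaluate_model <- function(ws, config, tc = train_config(), folds = NULL) {
  if (is.null(folds)) folds <- loso_folds(unique(ws$subject_ids))
  truth <- integer(0)
  pred <- integer(0)
  per_fold <- list()
  for (i in seq_along(folds)) {
    fold <- folds[[i]]
    stopifnot(length(intersect(fold$train, fold$test)) == 0)
    tr <- subset_windows(ws, ws$subject_ids %in% fold$train)
    te <- subset_windows(ws, ws$subject_ids %in% fold$test)
    model <- train_model(tr, config, tc)
    p <- predict_model(model, te)
    truth <- c(truth, as.integer(te$labels))
    pred <- c(pred, p$labels)
    per_fold[[i]] <- compute_metrics(as.integer(te$labels), p$labels,
                                     classes = 0:(config$n_classes - 1))
  }
  list(report = compute_metrics(truth, pred,
                                classes = 0:(config$n_classes - 1)),
       per_fold = per_fold, truth = truth, pred = pred)
}

#' Ablation harness over the three model variants
#'
#' Trains and evaluates each variant on identical folds and seeds, in the
#' layout baseline / + dual-branch / + dual-branch + AFF.
#'
#' @param ws A labeled `window_set`.
#' @param variants Character vector of variants to compare.
#' @param seeds Integer seeds; each is used for every variant.
#' @param folds A `fold_spec` shared by all cells.
#' @param tc A [train_config()] (its seed is overridden per cell).
#' @param config_fn Function(variant) returning the model config; defaults
#'   to scaled-down geometry shared across variants.
#' @return An `ablation_report`: `cells` (data.frame variant x seed with acc
#'   and macro F1), `summary` (per-variant mean/sd), `reports`.
#' @export
run_ablation <- function(ws, variants = c("baseline", "dual_branch",
                                          "dual_branch_aff"),
                         seeds = 1:3, folds = NULL, tc = train_config(),
                         config_fn = NULL) {
  if (length(seeds) < 1) stop("need at least 1 seed", call. = FALSE)
  if (length(variants) < 2) stop("need at least 2 variants", call. = FALSE)
  if (is.null(folds)) folds <- loso_folds(unique(ws$subject_ids))
  if (is.null(config_fn)) {
    config_fn <- function(variant) {
      fusion_model_config(variant, embed_dim = 32, n_layers = 2, n_heads = 2)
    }
  }
  cells <- list()
  reports <- list()
  for (v in variants) {
    for (s in seeds) {
      tcs <- tc
      tcs$seed <- as.integer(s)
      res <- tryCatch(
        evaluate_model(ws, config_fn(v), tcs, folds),
        error = function(e) e
      )
      key <- paste(v, s, sep = "_seed")
      if (inherits(res, "error")) {
        cells[[key]] <- data.frame(variant = v, seed = s, acc = NA_real_,
                                   f1 = NA_real_,
                                   error = conditionMessage(res))
      } else {
        cells[[key]] <- data.frame(variant = v, seed = s,
                                   acc = res$report$acc, f1 = res$report$f1,
                                   error = NA_character_)
        reports[[key]] <- res$report
      }
    }
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  summ <- do.call(rbind, lapply(split(cells, cells$variant), function(d) {
    data.frame(variant = d$variant[1], mean_acc = mean(d$acc),
               sd_acc = stats::sd(d$acc), mean_f1 = mean(d$f1),
               sd_f1 = stats::sd(d$f1))
  }))
  summ <- summ[match(variants, summ$variant), ]
  rownames(summ) <- NULL
  structure(list(cells = cells, summary = summ, reports = reports,
                 seeds = seeds, variants = variants),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("ablation over", length(x$seeds), "seed(s):\n")
  print(x$summary, digits = 4)
  invisible(x)
}
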