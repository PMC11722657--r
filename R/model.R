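#' Configuration of one Transformer encoder branch
#'
#' A branch tiles its channel-by-time input image into `patch_h` x `patch_w`
#' patches, linearly projects each patch to `embed_dim` dimensions, prepends
#' a learned class token, adds fixed sinusoidal positional encoding and runs
#' `n_layers` pre-norm encoder blocks (multi-head self-attention +
#' feed-forward, residual connections, dropout after each feed-forward
#' linear layer and after the attention projection).
#'
#' @param patch_h,patch_w Patch height (channels) and width (time steps).
#'   Defaults: 4 x 4 (physiological image), 11 x 4 (non-physiological),
#'   15 x 15 (single-branch baseline).
#' @param embed_dim Token dimension D (default 128), divisible by `n_heads`.
#' @param n_layers Number of encoder blocks (default 12).
#' @param n_heads Attention heads (default 8).
#' @param ffn_ratio Feed-forward hidden width as a multiple of D (default 4).
#' @param dropout Dropout rate during training (default 0.2).
#' @param positional Add the sinusoidal positional encoding (default TRUE;
#'   disabling it makes the encoder permutation-equivariant over patches).
#' @return A list of class `branch_config`.
#' @export
branch_config <- function(patch_h = 4, patch_w = 4, embed_dim = 128,
                          n_layers = 12, n_heads = 8, ffn_ratio = 4,
                          dropout = 0.2, positional = TRUE) {
  if (embed_dim %% n_heads != 0) {
    stop("embed_dim must be divisible by n_heads", call. = FALSE)
  }
  if (n_layers < 0) stop("n_layers must be >= 0", call. = FALSE)
  structure(list(patch_h = patch_h, patch_w = patch_w, embed_dim = embed_dim,
                 n_layers = n_layers, n_heads = n_heads,
                 ffn_ratio = ffn_ratio, dropout = dropout,
                 positional = positional),
            class = "branch_config")
}

#' Configuration of the full prediction model
#'
#' Three variants mirror the ablation design: `"baseline"` is a single
#' encoder on the whole 15-row window image (15 x 15 patches);
#' `"dual_branch"` runs separate physiological (4-row) and non-physiological
#' (11-row) encoders and concatenates their class-token features before the
#' linear head; `"dual_branch_aff"` fuses the two class-token features with
#' the attentional feature fusion gate instead of concatenation.
#'
#' @param variant One of `"dual_branch_aff"`, `"dual_branch"`, `"baseline"`.
#' @param embed_dim,n_layers,n_heads,ffn_ratio,dropout Shared encoder
#'   settings (paper-scale defaults 128 / 12 / 8 / 4 / 0.2).
#' @param aff_bottleneck_ratio Channel bottleneck ratio r of the fusion gate
#'   (default 4).
#' @param n_classes Number of ability grades (default 4).
#' @param phys_patch,nonphys_patch,baseline_patch Patch geometries
#'   `c(height, width)` for the three images.
#' @return A list of class `fusion_model_config`.
#' @export
fusion_model_config <- function(variant = c("dual_branch_aff", "dual_branch",
                                            "baseline"),
                                embed_dim = 128, n_layers = 12, n_heads = 8,
                                ffn_ratio = 4, dropout = 0.2,
                                aff_bottleneck_ratio = 4, n_classes = 4,
                                phys_patch = c(4, 4), nonphys_patch = c(11, 4),
                                baseline_patch = c(15, 15)) {
  variant <- match.arg(variant)
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  mk <- function(p) branch_config(p[1], p[2], embed_dim, n_layers, n_heads,
                                  ffn_ratio, dropout)
  cfg <- list(variant = variant, n_classes = n_classes,
              aff_bottleneck_ratio = aff_bottleneck_ratio,
              fusion = switch(variant, dual_branch_aff = "aff",
                              dual_branch = "concat", baseline = "none"))
  if (variant == "baseline") {
    cfg$baseline_branch <- mk(baseline_patch)
  } else {
    cfg$phys_branch <- mk(phys_patch)
    cfg$nonphys_branch <- mk(nonphys_patch)
  }
  structure(cfg, class = "fusion_model_config")
}

#' Training configuration
#'
#' Adam with betas (0.9, 0.999), initial learning rate 6e-4 and a step-decay
#' schedule (multiply by `gamma` every `step` epochs; defaults step 1,
#' gamma 0.5), batch size 128.
#'
#' @param lr Initial learning rate (> 0).
#' @param gamma Decay factor in (0, 1].
#' @param step Epochs between decays.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param seed Integer seed for weight init, shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 6e-4, gamma = 0.5, step = 1, batch_size = 128,
                         epochs = 10, seed = 1L) {
  if (lr <= 0) stop("lr must be > 0", call. = FALSE)
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]", call. = FALSE)
  structure(list(lr = lr, gamma = gamma, step = step, batch_size = batch_size,
                 epochs = epochs, seed = as.integer(seed),
                 beta1 = 0.9, beta2 = 0.999),
            class = "train_config")
}

# ---- parameter initialisation ------------------------------------------

init_branch_params <- function(cfg) {
  D <- cfg$embed_dim
  p_dim <- cfg$patch_h * cfg$patch_w
  Dh <- cfg$ffn_ratio * D
  blocks <- lapply(seq_len(cfg$n_layers), function(l) {
    list(ln1_g = rep(1, D), ln1_b = rep(0, D),
         Wq = init_linear(D, D), bq = rep(0, D),
         Wk = init_linear(D, D), bk = rep(0, D),
         Wv = init_linear(D, D), bv = rep(0, D),
         Wo = init_linear(D, D), bo = rep(0, D),
         ln2_g = rep(1, D), ln2_b = rep(0, D),
         W1 = init_linear(D, Dh), b1 = rep(0, Dh),
         W2 = init_linear(Dh, D), b2 = rep(0, D))
  })
  list(Wp = init_linear(p_dim, D), bp = rep(0, D),
       cls = stats::rnorm(D, 0, 0.02), blocks = blocks)
}

init_aff_params <- function(D, r) {
  Dr <- max(1L, D %/% r)
  list(Wl1 = init_linear(D, Dr), bl1 = rep(0, Dr),
       Wl2 = init_linear(Dr, D), bl2 = rep(0, D),
       Wg1 = init_linear(D, Dr), bg1 = rep(0, Dr),
       Wg2 = init_linear(Dr, D), bg2 = rep(0, D))
}

#' Initialise model parameters
#'
#' Fan-in scaled Gaussian init (sd 1/sqrt(fan_in)) for the projection
#' matrices, sd 0.02 for the class token, sd 0.01 for the classification
#' head (so initial predictions are near-uniform), zeros for biases,
#' ones/zeros for layer-norm gains/offsets.
#'
#' @param config A [fusion_model_config()].
#' @param seed Integer seed.
#' @return Nested list of parameter arrays.
#' @export
init_model <- function(config, seed = 1L) {
  set.seed(seed)
  D <- head_input_dim(config)
  if (config$variant == "baseline") {
    params <- list(branch = init_branch_params(config$baseline_branch))
  } else {
    params <- list(phys = init_branch_params(config$phys_branch),
                   nonphys = init_branch_params(config$nonphys_branch))
    if (config$fusion == "aff") {
      params$aff <- init_aff_params(config$phys_branch$embed_dim,
                                    config$aff_bottleneck_ratio)
    }
  }
  # small head init: initial predictions near-uniform (loss ~ log n_classes)
  params$head <- list(W = init_mat(D, config$n_classes, sd = 0.01),
                      b = rep(0, config$n_classes))
  params
}

head_input_dim <- function(config) {
  if (config$variant == "baseline") {
    config$baseline_branch$embed_dim
  } else if (config$fusion == "concat") {
    2L * config$phys_branch$embed_dim
  } else {
    config$phys_branch$embed_dim
  }
}

# ---- patch embedding ----------------------------------------------------

patch_index <- function(H, W, ph, pw) {
  n_ph <- H %/% ph
  n_pw <- W %/% pw
  P <- n_ph * n_pw
  idx <- matrix(0L, P, ph * pw)
  for (p in seq_len(P)) {
    r <- (p - 1L) %% n_ph + 1L
    cc <- (p - 1L) %/% n_ph + 1L
    idx[p, ] <- as.integer(outer((r - 1L) * ph + seq_len(ph),
                                 ((cc - 1L) * pw + seq_len(pw) - 1L) * H, "+"))
  }
  idx
}

check_patch_dims <- function(H, W, cfg) {
  if (H %% cfg$patch_h != 0 || W %% cfg$patch_w != 0) {
    stop("image ", H, " x ", W, " is not divisible by patch ",
         cfg$patch_h, " x ", cfg$patch_w, call. = FALSE)
  }
}

# imgs: (H, W, B) array -> (B*P) x p_dim matrix, rows sample-major
patchify <- function(imgs, ph, pw) {
  d <- dim(imgs)
  H <- d[1]; W <- d[2]; B <- d[3]
  idx <- patch_index(H, W, ph, pw)
  P <- nrow(idx)
  img_mat <- matrix(imgs, H * W, B)
  out <- matrix(0, B * P, ph * pw)
  for (b in seq_len(B)) {
    v <- img_mat[, b]
    out[((b - 1) * P + 1):(b * P), ] <- matrix(v[idx], nrow(idx), ncol(idx))
  }
  out
}

#' Embed an image into a token sequence
#'
#' Tiles the image into patches, projects each patch to the embedding
#' dimension, prepends the class token at index 1 and adds the fixed
#' sinusoidal positional encoding (class token gets position 0).
#'
#' @param image H x W numeric matrix.
#' @param cfg A [branch_config()] whose patch size divides the image.
#' @param params Optional branch parameter list; a deterministic default
#'   (seed 0) is created when omitted.
#' @return `(n_patches + 1) x embed_dim` token matrix.
#' @export
embed_patches <- function(image, cfg, params = NULL) {
  check_patch_dims(nrow(image), ncol(image), cfg)
  if (is.null(params)) {
    set.seed(0)
    params <- init_branch_params(cfg)
  }
  imgs <- array(image, c(nrow(image), ncol(image), 1))
  tok <- add_bias(patchify(imgs, cfg$patch_h, cfg$patch_w) %*% params$Wp,
                  params$bp)
  X <- rbind(params$cls, tok)
  if (cfg$positional) X <- X + pe_sinusoidal(nrow(X), cfg$embed_dim)
  unname(X)
}

# run the encoder blocks over the (B*T) x D token matrix
run_blocks <- function(X, prm, cfg, B, T, training, keep_cache) {
  caches <- if (keep_cache) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    res <- block_forward(X, prm$blocks[[l]], cfg$n_heads, cfg$dropout,
                         B, T, training, keep_cache)
    X <- res$X
    if (keep_cache) caches[[l]] <- res$cache
  }
  list(X = X, caches = caches)
}

#' Encode a token sequence and return the class-token feature
#'
#' Runs the pre-norm encoder blocks (multi-head self-attention +
#' feed-forward, each with residual addition) over one token sequence and
#' returns the class-token row of the final layer output. A zero-depth
#' configuration returns the class token unchanged.
#'
#' @param tokens `T x embed_dim` matrix from [embed_patches()].
#' @param cfg The [branch_config()].
#' @param params Branch parameters (deterministic default when omitted).
#' @return Numeric vector of length `embed_dim`.
#' @export
encode_branch <- function(tokens, cfg, params = NULL) {
  if (is.null(params)) {
    set.seed(0)
    params <- init_branch_params(cfg)
  }
  out <- run_blocks(tokens, params, cfg, B = 1L, T = nrow(tokens),
                    training = FALSE, keep_cache = FALSE)
  if (any(!is.finite(out$X))) stop("non-finite activations in encoder",
                                   call. = FALSE)
  out$X[1, ]
}

# full branch forward on an (H, W, B) image array
branch_forward <- function(imgs, prm, cfg, training, keep_cache) {
  d <- dim(imgs)
  check_patch_dims(d[1], d[2], cfg)
  B <- d[3]
  patches <- patchify(imgs, cfg$patch_h, cfg$patch_w)
  P <- nrow(patches) / B
  T <- P + 1L
  D <- cfg$embed_dim
  tok <- add_bias(patches %*% prm$Wp, prm$bp)
  cls_rows <- (seq_len(B) - 1L) * T + 1L
  tok_rows <- as.vector(outer(2:T, (seq_len(B) - 1L) * T, "+"))
  X <- matrix(0, B * T, D)
  X[cls_rows, ] <- matrix(prm$cls, B, D, byrow = TRUE)
  X[tok_rows, ] <- tok
  if (cfg$positional) {
    X <- X + pe_sinusoidal(T, D)[rep(seq_len(T), B), ]
  }
  enc <- run_blocks(X, prm, cfg, B, T, training, keep_cache)
  cache <- NULL
  if (keep_cache) {
    cache <- list(patches = patches, blocks = enc$caches, B = B, T = T,
                  cls_rows = cls_rows, tok_rows = tok_rows)
  }
  list(cls = enc$X[cls_rows, , drop = FALSE], cache = cache)
}

branch_backward <- function(dcls, cache, prm, cfg) {
  B <- cache$B; T <- cache$T
  D <- cfg$embed_dim
  dX <- matrix(0, B * T, D)
  dX[cache$cls_rows, ] <- dcls
  gblocks <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    res <- block_backward(dX, cache$blocks[[l]], prm$blocks[[l]], cfg$n_heads)
    dX <- res$dX
    gblocks[[l]] <- res$grads
  }
  dtok <- dX[cache$tok_rows, , drop = FALSE]
  list(Wp = crossprod(cache$patches, dtok), bp = colSums(dtok),
       cls = colSums(dX[cache$cls_rows, , drop = FALSE]), blocks = gblocks)
}

# ---- attentional feature fusion ----------------------------------------

aff_forward <- function(xp, xnp, prm, keep_cache = FALSE) {
  u <- xp + xnp
  L1 <- add_bias(u %*% prm$Wl1, prm$bl1)
  R1 <- pmax(L1, 0)
  Lo <- add_bias(R1 %*% prm$Wl2, prm$bl2)
  ubar <- matrix(rowMeans(u), nrow(u), ncol(u))
  G1 <- add_bias(ubar %*% prm$Wg1, prm$bg1)
  Rg <- pmax(G1, 0)
  Go <- add_bias(Rg %*% prm$Wg2, prm$bg2)
  m <- 1 / (1 + exp(-(Lo + Go)))
  z <- m * xp + (1 - m) * xnp
  cache <- NULL
  if (keep_cache) {
    cache <- list(u = u, L1 = L1, R1 = R1, G1 = G1, Rg = Rg, ubar = ubar,
                  m = m, xp = xp, xnp = xnp)
  }
  list(z = z, mask = m, cache = cache)
}

aff_backward <- function(dz, cache, prm) {
  D <- ncol(dz)
  m <- cache$m
  dm <- dz * (cache$xp - cache$xnp)
  dxp <- dz * m
  dxnp <- dz * (1 - m)
  dpre <- dm * m * (1 - m)
  dWl2 <- crossprod(cache$R1, dpre); dbl2 <- colSums(dpre)
  dL1 <- (dpre %*% t(prm$Wl2)) * (cache$L1 > 0)
  dWl1 <- crossprod(cache$u, dL1); dbl1 <- colSums(dL1)
  du <- dL1 %*% t(prm$Wl1)
  dWg2 <- crossprod(cache$Rg, dpre); dbg2 <- colSums(dpre)
  dG1 <- (dpre %*% t(prm$Wg2)) * (cache$G1 > 0)
  dWg1 <- crossprod(cache$ubar, dG1); dbg1 <- colSums(dG1)
  dubar <- dG1 %*% t(prm$Wg1)
  du <- du + matrix(rowSums(dubar) / D, nrow(dz), D)
  list(dxp = dxp + du, dxnp = dxnp + du,
       grads = list(Wl1 = dWl1, bl1 = dbl1, Wl2 = dWl2, bl2 = dbl2,
                    Wg1 = dWg1, bg1 = dbg1, Wg2 = dWg2, bg2 = dbg2))
}

#' Attentional feature fusion of two feature vectors
#'
#' Computes `u = x_p + x_np`, builds a sigmoid attention mask from the sum
#' of a local channel bottleneck of `u` and the same bottleneck applied to
#' the channel-mean broadcast of `u`, and returns the convex combination
#' `z = m * x_p + (1 - m) * x_np`. Every mask component lies strictly in
#' (0, 1), so each output component lies between the corresponding inputs.
#'
#' @param x_p,x_np Feature vectors (or B x D matrices) of equal dimension.
#' @param params Fusion parameters; a deterministic default (seed 0) is
#'   created when omitted.
#' @param bottleneck_ratio Channel bottleneck ratio r (default 4).
#' @return Fused vector/matrix with the mask attached as attribute `"mask"`.
#' @export
fuse_aff <- function(x_p, x_np, params = NULL, bottleneck_ratio = 4) {
  vec <- is.null(dim(x_p))
  if (vec) {
    x_p <- matrix(x_p, 1)
    x_np <- matrix(x_np, 1)
  }
  if (!all(dim(x_p) == dim(x_np))) {
    stop("fused features must have equal dimensions", call. = FALSE)
  }
  if (is.null(params)) {
    set.seed(0)
    params <- init_aff_params(ncol(x_p), bottleneck_ratio)
  }
  out <- aff_forward(x_p, x_np, params)
  z <- out$z
  mask <- out$mask
  if (vec) {
    z <- as.numeric(z)
    mask <- as.numeric(mask)
  }
  attr(z, "mask") <- mask
  z
}

# ---- full model ---------------------------------------------------------

#' Forward pass of the prediction model
#'
#' Splits the 15-row window batch into its modalities (dual variants) or
#' feeds it whole (baseline), encodes, fuses and applies the linear head.
#'
#' @param imgs `15 x W x B` array (a `window_set$windows` slice).
#' @param params Model parameters from [init_model()] or a trained model.
#' @param config The [fusion_model_config()].
#' @param training Apply dropout (TRUE during optimisation only).
#' @param keep_cache Keep intermediate activations for the backward pass.
#' @return List with `logits` (B x n_classes) and `cache`.
#' @export
model_forward <- function(imgs, params, config, training = FALSE,
                          keep_cache = FALSE) {
  if (length(dim(imgs)) != 3) stop("imgs must be an (H, W, B) array",
                                   call. = FALSE)
  cache <- list()
  if (config$variant == "baseline") {
    br <- branch_forward(imgs, params$branch, config$baseline_branch,
                         training, keep_cache)
    feat <- br$cls
    cache$branch <- br$cache
  } else {
    bp <- branch_forward(imgs[1:4, , , drop = FALSE], params$phys,
                         config$phys_branch, training, keep_cache)
    bn <- branch_forward(imgs[5:15, , , drop = FALSE], params$nonphys,
                         config$nonphys_branch, training, keep_cache)
    cache$phys <- bp$cache
    cache$nonphys <- bn$cache
    if (config$fusion == "aff") {
      af <- aff_forward(bp$cls, bn$cls, params$aff, keep_cache)
      feat <- af$z
      cache$aff <- af$cache
    } else {
      feat <- cbind(bp$cls, bn$cls)
    }
  }
  logits <- add_bias(feat %*% params$head$W, params$head$b)
  if (any(!is.finite(logits))) stop("non-finite logits", call. = FALSE)
  if (keep_cache) cache$feat <- feat
  list(logits = logits, cache = if (keep_cache) cache else NULL)
}

model_backward <- function(dlogits, cache, params, config) {
  grads <- list()
  dfeat <- dlogits %*% t(params$head$W)
  grads$head <- list(W = crossprod(cache$feat, dlogits),
                     b = colSums(dlogits))
  if (config$variant == "baseline") {
    grads$branch <- branch_backward(dfeat, cache$branch, params$branch,
                                    config$baseline_branch)
  } else {
    D <- config$phys_branch$embed_dim
    if (config$fusion == "aff") {
      ab <- aff_backward(dfeat, cache$aff, params$aff)
      grads$aff <- ab$grads
      dp <- ab$dxp
      dn <- ab$dxnp
    } else {
      dp <- dfeat[, 1:D, drop = FALSE]
      dn <- dfeat[, (D + 1):(2 * D), drop = FALSE]
    }
    grads$phys <- branch_backward(dp, cache$phys, params$phys,
                                  config$phys_branch)
    grads$nonphys <- branch_backward(dn, cache$nonphys, params$nonphys,
                                     config$nonphys_branch)
  }
  # reorder to match params layout
  grads[names(params)]
}

#' Count learnable parameters
#'
#' @param x A parameter list, a `trained_model`, or a
#'   [fusion_model_config()] (initialised with seed 0 and counted).
#' @return Integer count of learnable scalars.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "fusion_model_config")) x <- init_model(x, seed = 0)
  if (inherits(x, "trained_model")) x <- x$params
  tree_sum(length, x)
}

# encoder-only count (class token + patch embedding + blocks) of all branches
encoder_parameter_count <- function(config) {
  params <- init_model(config, seed = 0)
  branches <- intersect(names(params), c("branch", "phys", "nonphys"))
  sum(vapply(params[branches], function(p) tree_sum(length, p), numeric(1)))
}

#' Train the prediction model
#'
#' Minimises cross-entropy with Adam and a step-decay learning-rate
#' schedule; epoch `e` uses `lr * gamma^floor((e - 1) / step)`. One seed
#' drives weight initialisation, shuffling and dropout, so runs are
#' reproducible on one machine.
#'
#' @param ws A `window_set` with integer labels `0..n_classes-1`.
#' @param config A [fusion_model_config()].
#' @param tc A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A `trained_model`: config, params, per-epoch `log` (epoch, loss,
#'   acc, lr), `parameter_count`.
#' @export
train_model <- function(ws, config, tc = train_config(), verbose = FALSE) {
  y <- as.integer(ws$labels)
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (any(y < 0 | y >= config$n_classes)) {
    stop("labels must lie in 0..", config$n_classes - 1, call. = FALSE)
  }
  arr <- ws$windows
  n <- dim(arr)[3]
  set.seed(tc$seed)
  params <- init_model(config, seed = tc$seed)
  state <- adam_init(params)
  log <- data.frame(epoch = integer(0), loss = numeric(0), acc = numeric(0),
                    lr = numeric(0))
  for (e in seq_len(tc$epochs)) {
    lr_e <- tc$lr * tc$gamma^((e - 1) %/% tc$step)
    idx <- sample.int(n)
    losses <- c()
    correct <- 0L
    for (start in seq(1, n, by = tc$batch_size)) {
      bidx <- idx[start:min(start + tc$batch_size - 1, n)]
      xb <- arr[, , bidx, drop = FALSE]
      fw <- model_forward(xb, params, config, training = TRUE,
                          keep_cache = TRUE)
      ce <- cross_entropy(fw$logits, y[bidx])
      if (!is.finite(ce$loss)) {
        stop("non-finite training loss at epoch ", e, call. = FALSE)
      }
      losses <- c(losses, ce$loss)
      correct <- correct +
        sum(max.col(fw$logits, ties.method = "first") - 1L == y[bidx])
      grads <- model_backward(ce$dlogits, fw$cache, params, config)
      upd <- adam_step(params, grads, state, lr_e, tc$beta1, tc$beta2)
      params <- upd$params
      state <- upd$state
    }
    log <- rbind(log, data.frame(epoch = e, loss = mean(losses),
                                 acc = correct / n, lr = lr_e))
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f acc %.3f lr %.2e",
                      e, mean(losses), correct / n, lr_e))
    }
  }
  structure(list(config = config, params = params, log = log,
                 parameter_count = count_parameters(params)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat("trained", x$config$variant, "model:",
      format(x$parameter_count, big.mark = ","), "parameters,",
      nrow(x$log), "epochs; final loss",
      signif(x$log$loss[nrow(x$log)], 4), "\n")
  invisible(x)
}

#' Predict labels for a window set
#'
#' Evaluation-mode forward pass (dropout off, deterministic) in batches.
#'
#' @param model A `trained_model`.
#' @param ws A `window_set` (labels may be missing/NA).
#' @param batch_size Evaluation batch size.
#' @return List with `labels` (predicted 0-based classes) and `probs`.
#' @export
predict_model <- function(model, ws, batch_size = 256) {
  arr <- ws$windows
  n <- dim(arr)[3]
  probs <- matrix(0, n, model$config$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    bidx <- start:min(start + batch_size - 1, n)
    fw <- model_forward(arr[, , bidx, drop = FALSE], model$params,
                        model$config, training = FALSE)
    probs[bidx, ] <- softmax_rows(fw$logits)
  }
  list(labels = max.col(probs, ties.method = "first") - 1L, probs = probs)
}
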