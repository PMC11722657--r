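test_that("patch embedding yields the expected token grids", {
  D <- 32
  phys_cfg <- branch_config(4, 4, embed_dim = D, n_layers = 1, n_heads = 2)
  tok <- embed_patches(matrix(rnorm(4 * 60), 4, 60), phys_cfg)
  expect_equal(dim(tok), c(16, D))  # 15 patches + class token

  np_cfg <- branch_config(11, 4, embed_dim = D, n_layers = 1, n_heads = 2)
  expect_equal(nrow(embed_patches(matrix(rnorm(11 * 60), 11, 60), np_cfg)), 16)

  base_cfg <- branch_config(15, 15, embed_dim = D, n_layers = 1, n_heads = 2)
  expect_equal(nrow(embed_patches(matrix(rnorm(15 * 60), 15, 60), base_cfg)), 5)

  expect_error(embed_patches(matrix(0, 5, 60), phys_cfg), "not divisible")
})

test_that("the encoder returns the class-token feature with the right properties", {
  # output dimensionality equals the embedding dimension under the
  # paper-scale defaults (128, 12 layers, 8 heads)
  cfg <- branch_config(4, 4)
  set.seed(1)
  tok <- embed_patches(matrix(rnorm(4 * 60), 4, 60), cfg)
  feat <- encode_branch(tok, cfg)
  expect_length(feat, 128)
  expect_true(all(is.finite(feat)))

  # zero-depth encoder: class token passes through unchanged
  cfg0 <- branch_config(4, 4, embed_dim = 16, n_layers = 0, n_heads = 2)
  tok0 <- embed_patches(matrix(rnorm(4 * 8), 4, 8), cfg0)
  expect_equal(encode_branch(tok0, cfg0), tok0[1, ])

  # without positional encoding, permuting the non-class tokens leaves the
  # class feature unchanged (attention is permutation-invariant)
  cfgp <- branch_config(4, 4, embed_dim = 16, n_layers = 2, n_heads = 2,
                        dropout = 0, positional = FALSE)
  set.seed(2)
  tokp <- embed_patches(matrix(rnorm(4 * 12), 4, 12), cfgp)
  perm <- c(1, 1 + sample(nrow(tokp) - 1))
  expect_equal(encode_branch(tokp[perm, ], cfgp), encode_branch(tokp, cfgp),
               tolerance = 1e-12)
})

test_that("encoder blocks with zeroed output weights are the identity map", {
  cfg <- branch_config(4, 4, embed_dim = 16, n_layers = 3, n_heads = 2,
                       dropout = 0)
  set.seed(3)
  params <- drivecog:::init_branch_params(cfg)
  for (l in seq_along(params$blocks)) {
    params$blocks[[l]]$Wo[] <- 0
    params$blocks[[l]]$bo[] <- 0
    params$blocks[[l]]$W2[] <- 0
    params$blocks[[l]]$b2[] <- 0
  }
  tok <- embed_patches(matrix(rnorm(4 * 8), 4, 8), cfg, params)
  expect_equal(encode_branch(tok, cfg, params), tok[1, ])
})

test_that("attentional feature fusion is a strict convex gate", {
  D <- 16
  set.seed(4)
  v <- rnorm(D)
  z <- fuse_aff(v, v)
  expect_equal(as.numeric(z), v)  # equal inputs are fixed points

  # zeroed fusion weights force the symmetric mask 0.5
  prm <- drivecog:::init_aff_params(D, 4)
  prm <- lapply(prm, function(p) { p[] <- 0; p })
  xp <- rnorm(D); xnp <- rnorm(D)
  z0 <- fuse_aff(xp, xnp, params = prm)
  expect_equal(attr(z0, "mask"), rep(0.5, D))
  expect_equal(as.numeric(z0), (xp + xnp) / 2)

  # over 1000 random pairs: mask in (0,1), output between the inputs
  set.seed(5)
  for (i in 1:1000) {
    xp <- rnorm(D, sd = 2); xnp <- rnorm(D, sd = 2)
    z <- fuse_aff(xp, xnp)
    m <- attr(z, "mask")
    expect_true(all(m > 0 & m < 1))
    expect_true(all(as.numeric(z) >= pmin(xp, xnp) - 1e-12))
    expect_true(all(as.numeric(z) <= pmax(xp, xnp) + 1e-12))
  }

  expect_error(fuse_aff(rnorm(4), rnorm(5)), "equal dimensions")
})

test_that("forward passes have the contracted shapes and eval determinism", {
  for (variant in c("baseline", "dual_branch", "dual_branch_aff")) {
    cfg <- tiny_config(variant, D = 16, L = 1)
    params <- init_model(cfg, seed = 6)
    imgs <- random_window_batch(B = 7, seed = variant == "baseline")
    out <- model_forward(imgs, params, cfg)
    expect_equal(dim(out$logits), c(7, 4))
    probs <- exp(out$logits) / rowSums(exp(out$logits))
    expect_equal(rowSums(probs), rep(1, 7), tolerance = 1e-6)

    # dropout off at evaluation: repeated passes are bit-identical
    out2 <- model_forward(imgs, params, cfg)
    expect_identical(out$logits, out2$logits)

    # duplicated inputs give duplicated logit rows
    dup <- imgs[, , c(1, 1, 2), drop = FALSE]
    ld <- model_forward(dup, params, cfg)$logits
    expect_equal(ld[1, ], ld[2, ])
  }
})

test_that("analytic gradients match finite differences on a small model", {
  cfg <- fusion_model_config("dual_branch_aff", embed_dim = 8, n_layers = 1,
                             n_heads = 2, dropout = 0,
                             phys_patch = c(2, 4), nonphys_patch = c(11, 4))
  set.seed(7)
  imgs <- array(runif(15 * 8 * 2), c(15, 8, 2))
  y <- c(0L, 3L)
  params <- init_model(cfg, seed = 8)
  fw <- model_forward(imgs, params, cfg, keep_cache = TRUE)
  ce <- drivecog:::cross_entropy(fw$logits, y)
  grads <- drivecog:::model_backward(ce$dlogits, fw$cache, params, cfg)

  flatten <- function(x, prefix = character(0)) {
    if (is.list(x)) {
      nms <- names(x)
      if (is.null(nms)) nms <- as.character(seq_along(x))
      out <- list()
      for (i in seq_along(x)) {
        out <- c(out, flatten(x[[i]], c(prefix, nms[i])))
      }
      out
    } else {
      setNames(list(x), paste(prefix, collapse = "/"))
    }
  }
  setv <- function(p, path, k, delta) {
    i <- suppressWarnings(as.integer(path[1]))
    key <- if (is.na(i)) path[1] else i
    if (length(path) == 1) {
      p[[key]][k] <- p[[key]][k] + delta
    } else {
      p[[key]] <- setv(p[[key]], path[-1], k, delta)
    }
    p
  }
  loss_at <- function(p) {
    drivecog:::cross_entropy(model_forward(imgs, p, cfg)$logits, y)$loss
  }
  pf <- flatten(params)
  gf <- flatten(grads)
  expect_identical(names(pf), names(gf))
  eps <- 1e-5
  set.seed(9)
  for (nm in names(pf)) {
    k <- sample(length(pf[[nm]]), 1)
    path <- strsplit(nm, "/", fixed = TRUE)[[1]]
    fd <- (loss_at(setv(params, path, k, eps)) -
           loss_at(setv(params, path, k, -eps))) / (2 * eps)
    an <- gf[[nm]][k]
    expect_lt(abs(fd - an), 1e-6 + 1e-3 * (abs(fd) + abs(an)))
  }
})

test_that("every learnable tensor receives gradient and both modalities matter", {
  cfg <- tiny_config("dual_branch_aff", D = 16, L = 1)
  params <- init_model(cfg, seed = 10)
  imgs <- random_window_batch(B = 6, seed = 11)
  y <- c(0L, 1L, 2L, 3L, 0L, 1L)
  fw <- model_forward(imgs, params, cfg, keep_cache = TRUE)
  ce <- drivecog:::cross_entropy(fw$logits, y)
  grads <- drivecog:::model_backward(ce$dlogits, fw$cache, params, cfg)
  leaf_ok <- drivecog:::tree_map(function(g) any(g != 0), grads)
  expect_true(all(unlist(leaf_ok)))

  # perturbing only the physiological rows changes the dual-branch logits
  imgs2 <- imgs
  imgs2[1:4, , ] <- imgs2[1:4, , ] + 0.3
  expect_false(isTRUE(all.equal(model_forward(imgs2, params, cfg)$logits,
                                fw$logits)))

  # the baseline is architecturally distinct from the dual variants
  cfg_b <- tiny_config("baseline", D = 16, L = 1)
  params_b <- init_model(cfg_b, seed = 10)
  expect_false(isTRUE(all.equal(model_forward(imgs, params_b, cfg_b)$logits,
                                fw$logits)))
})

test_that("parameter counts scale as the architecture dictates", {
  # paper-scale geometry: the dual encoder stack is ~2x one encoder
  dual <- fusion_model_config("dual_branch_aff")
  single <- fusion_model_config("baseline")
  ratio <- drivecog:::encoder_parameter_count(dual) /
    drivecog:::encoder_parameter_count(single)
  expect_gte(ratio, 1.8)
  expect_lte(ratio, 2.2)

  # zero-depth model: patch embedding + class token + head only
  cfg0 <- fusion_model_config("baseline", embed_dim = 16, n_layers = 0,
                              n_heads = 2, baseline_patch = c(15, 15))
  D <- 16
  expected <- (15 * 15 * D + D) + D + (D * 4 + 4)
  expect_equal(count_parameters(cfg0), expected)

  # doubling the depth doubles the per-block parameter mass exactly
  cnt <- function(L) count_parameters(
    fusion_model_config("baseline", embed_dim = 16, n_layers = L, n_heads = 2))
  expect_equal(cnt(4) - cnt(0), 2 * (cnt(2) - cnt(0)))
})

test_that("training reduces the loss and follows the step-decay schedule", {
  ws <- simulate_fusion_windows(n_subjects = 20, windows_per_subject = 10,
                                effect_size = 3, seed = 12)
  cfg <- fusion_model_config("dual_branch_aff", embed_dim = 32, n_layers = 2,
                             n_heads = 2)
  tc <- train_config(batch_size = 32, epochs = 10, gamma = 0.9, seed = 1)
  model <- train_model(ws, cfg, tc)
  log <- model$log
  expect_equal(nrow(log), 10)
  expect_gt(log$acc[10], 0.25)           # above 4-class chance
  expect_lt(log$loss[10], log$loss[1])
  expect_equal(log$lr, 6e-4 * 0.9^(0:9))
  expect_equal(model$parameter_count, count_parameters(model$params))

  # the paper-default schedule: lr halves every epoch from 6e-4
  tc_halving <- train_config(epochs = 3)
  expect_equal(tc_halving$lr * tc_halving$gamma^(0:2), 6e-4 * 0.5^(0:2))

  # near-uniform initial predictions: first-batch loss is about ln 4
  params <- init_model(cfg, seed = 2)
  l0 <- drivecog:::cross_entropy(
    model_forward(ws$windows[, , 1:40], params, cfg)$logits,
    as.integer(ws$labels[1:40]))$loss
  expect_equal(l0, log(4), tolerance = 0.05)

  # degenerate training sets are rejected
  ws1 <- drivecog:::subset_windows(ws, ws$labels == 0)
  expect_error(train_model(ws1, cfg, tc), "single class")

  # seeded training is reproducible
  m2 <- train_model(ws, cfg, tc)
  expect_identical(model$params, m2$params)
})
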