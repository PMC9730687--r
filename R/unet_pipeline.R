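#' Training configuration for the two-stage segmentation network
#'
#' Two presets are provided. `"desk"` (default) is a small configuration
#' meant to run in seconds on one CPU: 64 x 64 x 16 inputs, a 2-level 3D
#' U-Net with 8 base filters, 5 epochs, Adam at learning rate 0.003 (the
#' full-scale rate of 0.01 is unstable for so small a network and dataset).
#' `"full"` records a full-scale training recipe (224 x 224 x 64 inputs, 300
#' epochs, batch size 2, Adam at learning rate 0.01, Dice loss, skew/shear
#' augmentation of 0-5 degrees and translation of -0.1 to 0.1 of the
#' extent); it is a configuration record, not something to train on a
#' laptop. Both presets share the optimizer and loss.
#'
#' @param preset `"desk"` or `"full"`.
#' @param ... Named overrides of any field (`input_shape`, `epochs`,
#'   `learning_rate`, `batch_size`, `base_filters`, `seed`,
#'   `skew_range_deg`, `shear_range_deg`, `translation_range`,
#'   `dice_smooth`).
#' @return A `train_config` list.
#' @export
train_config <- function(preset = c("desk", "full"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    input_shape = if (preset == "desk") c(64L, 64L, 16L) else c(224L, 224L, 64L),
    epochs = if (preset == "desk") 5L else 300L,
    optimizer = "adam",
    learning_rate = if (preset == "desk") 0.003 else 0.01,
    batch_size = 2L,
    base_filters = if (preset == "desk") 8L else 16L,
    loss = "dice",
    dice_smooth = 1e-5,
    skew_range_deg = c(0, 5),
    shear_range_deg = c(0, 5),
    translation_range = c(-0.1, 0.1),
    seed = 0L)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  cfg$input_shape <- as.integer(cfg$input_shape)
  if (any(cfg$input_shape %% 2L != 0L))
    stop("input_shape must be divisible by the network downsampling factor (2)")
  structure(cfg, class = "train_config")
}

#' Preprocess an intensity volume for the network
#'
#' Trilinear resize to the target shape followed by z-score intensity
#' normalization over all voxels. A constant volume (zero standard
#' deviation) becomes all zeros, with a warning. Applying the function twice
#' at a fixed shape is a no-op up to numerical tolerance.
#'
#' @param volume 3D numeric array.
#' @param input_shape Integer length-3 target shape.
#' @return 3D numeric array of shape `input_shape`, mean 0 and sd 1 (unless
#'   constant).
#' @export
preprocess_volume <- function(volume, input_shape) {
  if (length(dim(volume)) != 3L) stop("preprocess expects a 3D volume")
  v <- resize_trilinear(volume, as.integer(input_shape))
  s <- stats::sd(as.vector(v))
  if (!is.finite(s) || s == 0) {
    warning("constant volume: z-score undefined, returning zeros")
    return(array(0, dim = dim(v)))
  }
  (v - mean(v)) / s
}

# --- resampling -------------------------------------------------------------

# Separable linear resize; axis coordinates follow the pixel-center
# convention, so identical in/out sizes reproduce the input exactly.
resize_trilinear <- function(x, new_dim) {
  for (a in 1:3) x <- resize_axis(x, a, new_dim[a], nearest = FALSE)
  x
}

resize_nearest <- function(x, new_dim) {
  for (a in 1:3) x <- resize_axis(x, a, new_dim[a], nearest = TRUE)
  x
}

resize_axis <- function(x, axis, new_n, nearest) {
  d <- dim(x)
  if (d[axis] == new_n) return(x)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  src <- (seq_len(new_n) - 0.5) * d[axis] / new_n + 0.5
  if (nearest) {
    i <- pmin(pmax(round(src), 1L), d[axis])
    out <- m[i, , drop = FALSE]
  } else {
    i0 <- pmin(pmax(floor(src), 1L), d[axis])
    i1 <- pmin(i0 + 1L, d[axis])
    w <- pmin(pmax(src - i0, 0), 1)
    out <- m[i0, , drop = FALSE] * (1 - w) + m[i1, , drop = FALSE] * w
  }
  dim(out) <- c(new_n, dp[2], dp[3])
  aperm(out, order(perm))
}

#' Randomly skew, shear and translate a volume/mask pair
#'
#' Samples a through-plane skew angle and an in-plane shear angle uniformly
#' from their ranges (each applied with a random sign), plus a per-axis
#' translation as a fraction of the volume extent, and applies the same
#' spatial transform to both inputs. The intensity volume is resampled
#' trilinearly; the mask with nearest-neighbour interpolation, so it stays
#' a label image. Voxels mapped from outside the volume are 0. Consumes the
#' caller's RNG stream: seed before calling for reproducibility.
#'
#' @param volume 3D numeric array.
#' @param mask 3D array of the same shape.
#' @param skew_range_deg,shear_range_deg Length-2 degree ranges (default
#'   0-5).
#' @param translation_range Length-2 fraction-of-extent range (default
#'   -0.1 to 0.1).
#' @param slice_axis Through-plane axis the skew tilts about (default 3).
#' @return List with `volume`, `mask` and the sampled `transform`
#'   parameters.
#' @export
augment_case <- function(volume, mask,
                         skew_range_deg = c(0, 5),
                         shear_range_deg = c(0, 5),
                         translation_range = c(-0.1, 0.1),
                         slice_axis = 3) {
  d <- dim(volume)
  if (!identical(d, dim(mask))) stop("volume and mask shapes differ")
  skew <- stats::runif(1, skew_range_deg[1], skew_range_deg[2]) *
    sample(c(-1, 1), 1)
  shear <- stats::runif(1, shear_range_deg[1], shear_range_deg[2]) *
    sample(c(-1, 1), 1)
  trans <- stats::runif(3, translation_range[1], translation_range[2]) * d

  inplane <- setdiff(1:3, slice_axis)
  A <- diag(3)
  A[inplane[1], inplane[2]] <- tan(shear * pi / 180)   # in-plane shear
  A[inplane[1], slice_axis] <- tan(skew * pi / 180)    # through-plane skew
  Ainv <- solve(A)

  ctr <- (d + 1) / 2
  coords <- cbind(
    rep.int(seq_len(d[1]), d[2] * d[3]),
    rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
    rep(seq_len(d[3]), each = d[1] * d[2]))
  src <- sweep(coords, 2L, ctr + trans, `-`) %*% t(Ainv)
  src <- sweep(src, 2L, ctr, `+`)

  list(volume = resample_at(volume, src, nearest = FALSE),
       mask = resample_at(mask, src, nearest = TRUE),
       transform = list(skew_deg = skew, shear_deg = shear,
                        translation_voxels = trans))
}

# Gather values of x at fractional coordinates (rows of src), zero outside.
resample_at <- function(x, src, nearest) {
  d <- dim(x)
  out <- numeric(nrow(src))
  if (nearest) {
    i <- round(src)
    ok <- i[, 1] >= 1 & i[, 1] <= d[1] & i[, 2] >= 1 & i[, 2] <= d[2] &
      i[, 3] >= 1 & i[, 3] <= d[3]
    lin <- i[ok, 1] + (i[ok, 2] - 1) * d[1] + (i[ok, 3] - 1) * d[1] * d[2]
    out[ok] <- x[lin]
  } else {
    ok <- src[, 1] >= 1 & src[, 1] <= d[1] & src[, 2] >= 1 &
      src[, 2] <= d[2] & src[, 3] >= 1 & src[, 3] <= d[3]
    so <- src[ok, , drop = FALSE]
    io <- pmin(pmax(floor(so), 1), rep(d - 1L, each = nrow(so)))
    dim(io) <- dim(so)
    fo <- so - io
    acc <- numeric(sum(ok))
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- (if (cx) fo[, 1] else 1 - fo[, 1]) *
           (if (cy) fo[, 2] else 1 - fo[, 2]) *
           (if (cz) fo[, 3] else 1 - fo[, 3])
      lin <- (io[, 1] + cx) + (io[, 2] + cy - 1) * d[1] +
        (io[, 3] + cz - 1) * d[1] * d[2]
      acc <- acc + w * x[lin]
    }
    out[ok] <- acc
  }
  array(out, dim = d)
}

# --- 3D U-Net built from per-offset matrix products -------------------------
#
# Feature maps are stored as V x C matrices (V voxels, column-major order of
# the 3D grid). A 3x3x3 convolution is 27 gemms: for each neighbourhood
# offset, gather the shifted feature matrix (zero-padded via a sentinel row)
# and multiply by that offset's Cin x Cout weight slice. This keeps all the
# arithmetic in BLAS while staying dependency-free.

offset_table <- function() as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))

# For each of the 27 offsets, the gather map out-voxel -> in-voxel linear
# index (V + 1 for out of bounds). Cached per grid shape.
.shift_cache <- new.env(parent = emptyenv())

shift_maps <- function(d) {
  key <- paste(d, collapse = "x")
  if (!is.null(.shift_cache[[key]])) return(.shift_cache[[key]])
  V <- prod(d)
  coords <- cbind(
    rep.int(seq_len(d[1]), d[2] * d[3]),
    rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
    rep(seq_len(d[3]), each = d[1] * d[2]))
  offs <- offset_table()
  maps <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2L, offs[o, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- rep.int(V + 1L, V)
    lin[ok] <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    maps[[o]] <- lin
  }
  res <- list(maps = maps, neg = match(
    apply(-offs, 1, paste, collapse = ","),
    apply(offs, 1, paste, collapse = ",")))
  .shift_cache[[key]] <- res
  res
}

conv_init <- function(cin, cout) {
  # He-style initialization for ReLU blocks
  sd <- sqrt(2 / (27 * cin))
  list(W = lapply(1:27, function(o)
    matrix(stats::rnorm(cin * cout, sd = sd), cin, cout)),
    b = numeric(cout))
}

conv_forward <- function(x, d, layer) {
  sm <- shift_maps(d)
  xz <- rbind(x, 0)
  out <- matrix(rep(layer$b, each = nrow(x)), nrow(x))
  for (o in 1:27) out <- out + xz[sm$maps[[o]], , drop = FALSE] %*% layer$W[[o]]
  out
}

conv_backward <- function(dY, x, d, layer) {
  sm <- shift_maps(d)
  xz <- rbind(x, 0)
  dYz <- rbind(dY, 0)
  dW <- vector("list", 27)
  dX <- matrix(0, nrow(x), ncol(x))
  for (o in 1:27) {
    xs <- xz[sm$maps[[o]], , drop = FALSE]
    dW[[o]] <- crossprod(xs, dY)
    dX <- dX + dYz[sm$maps[[sm$neg[o]]], , drop = FALSE] %*% t(layer$W[[o]])
  }
  list(dW = dW, db = colSums(dY), dX = dX)
}

relu <- function(x) { x[x < 0] <- 0; x }

pool_maps <- function(d) {
  dp <- d %/% 2L
  corners <- as.matrix(expand.grid(cx = 0:1, cy = 0:1, cz = 0:1))
  lapply(seq_len(8), function(k) {
    i <- 2L * rep.int(seq_len(dp[1]), dp[2] * dp[3]) - 1L + corners[k, 1]
    j <- 2L * rep.int(rep(seq_len(dp[2]), each = dp[1]), dp[3]) - 1L + corners[k, 2]
    l <- 2L * rep(seq_len(dp[3]), each = dp[1] * dp[2]) - 1L + corners[k, 3]
    i + (j - 1L) * d[1] + (l - 1L) * d[1] * d[2]
  })
}

maxpool_forward <- function(x, d) {
  pm <- pool_maps(d)
  Vp <- prod(d %/% 2L)
  C <- ncol(x)
  stack <- vapply(pm, function(m) x[m, , drop = FALSE],
                  matrix(0, Vp, C))            # Vp x C x 8
  flat <- matrix(stack, nrow = Vp * C)
  argmax <- max.col(flat, ties.method = "first")
  out <- matrix(flat[cbind(seq_len(Vp * C), argmax)], Vp, C)
  list(out = out, argmax = argmax, d_in = d)
}

maxpool_backward <- function(dY, pool) {
  pm <- pool_maps(pool$d_in)
  Vp <- nrow(dY); C <- ncol(dY)
  dX <- matrix(0, prod(pool$d_in), C)
  rows <- ((seq_len(Vp * C) - 1L) %% Vp) + 1L
  cols <- ((seq_len(Vp * C) - 1L) %/% Vp) + 1L
  for (k in 1:8) {
    sel <- pool$argmax == k
    if (!any(sel)) next
    dX[cbind(pm[[k]][rows[sel]], cols[sel])] <-
      dX[cbind(pm[[k]][rows[sel]], cols[sel])] + dY[sel]
  }
  dX
}

upsample_map <- function(d_small) {
  d <- d_small * 2L
  i <- (rep.int(seq_len(d[1]), d[2] * d[3]) + 1L) %/% 2L
  j <- (rep.int(rep(seq_len(d[2]), each = d[1]), d[3]) + 1L) %/% 2L
  l <- (rep(seq_len(d[3]), each = d[1] * d[2]) + 1L) %/% 2L
  i + (j - 1L) * d_small[1] + (l - 1L) * d_small[1] * d_small[2]
}

unet_init <- function(base_filters, seed) {
  F1 <- base_filters
  with_local_seed(seed, list(
    enc1a = conv_init(1L, F1),  enc1b = conv_init(F1, F1),
    bot1  = conv_init(F1, 2L * F1), bot2 = conv_init(2L * F1, 2L * F1),
    dec1a = conv_init(3L * F1, F1), dec1b = conv_init(F1, F1),
    out = list(W = matrix(stats::rnorm(F1, sd = sqrt(2 / F1)), F1, 1),
               b = 0)))
}

unet_forward <- function(x, d, params) {
  c1a <- relu(conv_forward(x, d, params$enc1a))
  c1b <- relu(conv_forward(c1a, d, params$enc1b))
  pl <- maxpool_forward(c1b, d)
  dp <- d %/% 2L
  b1 <- relu(conv_forward(pl$out, dp, params$bot1))
  b2 <- relu(conv_forward(b1, dp, params$bot2))
  um <- upsample_map(dp)
  up <- b2[um, , drop = FALSE]
  cat1 <- cbind(c1b, up)
  d1a <- relu(conv_forward(cat1, d, params$dec1a))
  d1b <- relu(conv_forward(d1a, d, params$dec1b))
  logit <- d1b %*% params$out$W + params$out$b
  prob <- 1 / (1 + exp(-logit))
  list(prob = prob,
       cache = list(x = x, d = d, dp = dp, c1a = c1a, c1b = c1b, pl = pl,
                    b1 = b1, b2 = b2, um = um, cat1 = cat1, d1a = d1a,
                    d1b = d1b, prob = prob))
}

unet_backward <- function(dprob, params, cache) {
  d <- cache$d; dp <- cache$dp
  dlogit <- dprob * cache$prob * (1 - cache$prob)
  g <- list()
  g$out <- list(W = crossprod(cache$d1b, dlogit), b = sum(dlogit))
  dd1b <- (dlogit %*% t(params$out$W)) * (cache$d1b > 0)
  bk <- conv_backward(dd1b, cache$d1a, d, params$dec1b)
  g$dec1b <- list(W = bk$dW, b = bk$db)
  dd1a <- bk$dX * (cache$d1a > 0)
  bk <- conv_backward(dd1a, cache$cat1, d, params$dec1a)
  g$dec1a <- list(W = bk$dW, b = bk$db)
  F1 <- ncol(cache$c1b)
  dc1b_skip <- bk$dX[, seq_len(F1), drop = FALSE]
  dup <- bk$dX[, F1 + seq_len(2L * F1), drop = FALSE]
  db2 <- rowsum(dup, cache$um) * (cache$b2 > 0)
  bk <- conv_backward(db2, cache$b1, dp, params$bot2)
  g$bot2 <- list(W = bk$dW, b = bk$db)
  db1 <- bk$dX * (cache$b1 > 0)
  bk <- conv_backward(db1, cache$pl$out, dp, params$bot1)
  g$bot1 <- list(W = bk$dW, b = bk$db)
  dpool <- bk$dX
  dc1b <- maxpool_backward(dpool, cache$pl) + dc1b_skip
  dc1b <- dc1b * (cache$c1b > 0)
  bk <- conv_backward(dc1b, cache$c1a, d, params$enc1b)
  g$enc1b <- list(W = bk$dW, b = bk$db)
  dc1a <- bk$dX * (cache$c1a > 0)
  bk <- conv_backward(dc1a, cache$x, d, params$enc1a)
  g$enc1a <- list(W = bk$dW, b = bk$db)
  g
}

dice_loss <- function(prob, target, smooth = 1e-5) {
  num <- 2 * sum(prob * target) + smooth
  den <- sum(prob) + sum(target) + smooth
  loss <- 1 - num / den
  dprob <- -(2 * target * den - num) / den^2
  list(loss = loss, dprob = matrix(dprob, ncol = 1))
}

# Recursive Adam over the nested parameter list.
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.numeric(p)) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    } else {
      if (!is.null(names(p))) { g <- g[names(p)]; m <- m[names(p)]; v <- v[names(p)] }
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    }
  }
  if (is.null(state)) {
    zero <- function(p) if (is.numeric(p)) p * 0 else lapply(p, zero)
    state <- list(m = zero(params), v = zero(params))
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v))
}

sum_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.numeric(a)) a + b else Map(sum_grads, a, b)
}

scale_grads <- function(a, s) {
  if (is.numeric(a)) a * s else lapply(a, scale_grads, s)
}

#' Train one segmentation stage
#'
#' Seeded training of the 3D U-Net (two resolution levels with a skip
#' connection, ReLU blocks, sigmoid output) on intensity-volume / binary-
#' mask pairs, minimizing soft Dice loss with Adam. Volumes are resized and
#' z-score normalized to `cfg$input_shape`; masks are nearest-resized.
#' Gradients are averaged over each mini-batch. The returned loss history
#' is the per-epoch mean batch loss.
#'
#' @param cases List of cases, each a list with `volume` (3D numeric array)
#'   and `mask` (3D binary array of the same shape).
#' @param cfg A [train_config()].
#' @return A `unet_model`: `params`, `loss_history`, `cfg`.
#' @export
train_stage <- function(cases, cfg = train_config()) {
  stopifnot(length(cases) >= 2L)
  if (cfg$batch_size > length(cases))
    stop("batch_size larger than the dataset")
  d <- cfg$input_shape
  V <- prod(d)
  prepped <- lapply(cases, function(cs) {
    list(x = matrix(as.vector(preprocess_volume(cs$volume, d)), V, 1),
         y = matrix(as.vector(resize_nearest((cs$mask > 0) * 1, d)), V, 1))
  })
  params <- unet_init(cfg$base_filters, cfg$seed)
  state <- NULL
  t <- 0L
  loss_history <- numeric(cfg$epochs)
  batches <- split(seq_along(prepped),
                   ceiling(seq_along(prepped) / cfg$batch_size))
  for (ep in seq_len(cfg$epochs)) {
    ep_losses <- numeric(0)
    for (bt in batches) {
      gsum <- NULL
      bloss <- 0
      for (i in bt) {
        fw <- unet_forward(prepped[[i]]$x, d, params)
        dl <- dice_loss(fw$prob, prepped[[i]]$y, cfg$dice_smooth)
        if (!is.finite(dl$loss)) stop("NaN loss during training")
        bloss <- bloss + dl$loss
        gsum <- sum_grads(gsum, unet_backward(dl$dprob, params, fw$cache))
      }
      gsum <- scale_grads(gsum, 1 / length(bt))
      t <- t + 1L
      upd <- adam_step(params, gsum, state, cfg$learning_rate, t)
      params <- upd$params
      state <- upd$state
      ep_losses <- c(ep_losses, bloss / length(bt))
    }
    loss_history[ep] <- mean(ep_losses)
  }
  structure(list(params = params, loss_history = loss_history, cfg = cfg),
            class = "unet_model")
}

unet_predict_prob <- function(model, volume) {
  d <- model$cfg$input_shape
  x <- matrix(as.vector(preprocess_volume(volume, d)), prod(d), 1)
  prob <- unet_forward(x, d, model$params)$prob
  array(prob, dim = d)
}

#' Two-stage liver-then-lesion prediction
#'
#' Stage 1 segments the liver from the full volume (probability threshold
#' 0.5). The input is then masked to the predicted liver region and passed
#' to stage 2, whose thresholded output is intersected with the liver mask,
#' so the predicted tumour is a subset of the predicted liver by
#' construction. An empty stage-1 prediction short-circuits to an empty
#' tumour mask with a warning.
#'
#' @param dwi 3D numeric intensity volume.
#' @param liver_model,lesion_model `unet_model`s from [train_stage()].
#' @param spacing Voxel spacing in mm of `dwi` (default isotropic 1 mm),
#'   attached to the returned masks.
#' @return List with `liver` and `tumor` [label_volume]s on the grid of
#'   `dwi`.
#' @export
predict_two_stage <- function(dwi, liver_model, lesion_model,
                              spacing = c(1, 1, 1)) {
  stopifnot(inherits(liver_model, "unet_model"),
            inherits(lesion_model, "unet_model"))
  d0 <- dim(dwi)
  liver_prob <- resize_trilinear(unet_predict_prob(liver_model, dwi), d0)
  liver_mask <- (liver_prob >= 0.5) * 1L
  if (!any(liver_mask > 0L)) {
    warning("stage-1 liver prediction is empty: returning empty tumour mask")
    tumor_mask <- array(0L, dim = d0)
  } else {
    masked <- dwi * (liver_mask > 0L)
    tumor_prob <- resize_trilinear(unet_predict_prob(lesion_model, masked), d0)
    tumor_mask <- ((tumor_prob >= 0.5) & (liver_mask > 0L)) * 1L
  }
  list(liver = label_volume(array(as.integer(liver_mask), d0), spacing),
       tumor = label_volume(array(as.integer(tumor_mask), d0), spacing))
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("unet_model (%s preset): input %s, %d base filters, %d epochs\n",
              x$cfg$preset, paste(x$cfg$input_shape, collapse = "x"),
              x$cfg$base_filters, x$cfg$epochs))
  cat(sprintf("  loss history: %s\n",
              paste(sprintf("%.4f", x$loss_history), collapse = " -> ")))
  invisible(x)
}
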