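# Minimal convolutional network engine for slice-wise dose prediction.
# Feature maps are arrays of dim (H, W, C, N); conv kernels live in src/.
# Only what the residual encoder-decoder needs: 3x3/1x1 convolutions
# (stride 1 or 2, zero padding), ReLU, nearest x2 upsampling, additive
# skips, MSE loss, Adam.

conv_param <- function(k, cin, cout, stride = 1L) {
  w <- matrix(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
              nrow = k * k * cin, ncol = cout)
  list(w = w, b = numeric(cout), k = as.integer(k), stride = as.integer(stride),
       cin = as.integer(cin), cout = as.integer(cout))
}

conv_fwd_p <- function(p, x) {
  conv2d_fwd(x, p$w, p$b, p$k, as.integer((p$k - 1) / 2), p$stride)
}

conv_bwd_p <- function(p, x, dy) {
  conv2d_bwd(x, p$w, dy, p$k, as.integer((p$k - 1) / 2), p$stride)
}

# Leaky ReLU (slope 0.01 on the negative side): keeps every unit trainable,
# avoiding the whole-network collapse plain ReLU can hit on unlucky inits.
relu_fwd <- function(x) {
  neg <- x < 0
  x[neg] <- 0.01 * x[neg]
  x
}

relu_bwd <- function(dy, y) {
  neg <- y < 0
  dy[neg] <- 0.01 * dy[neg]
  dy
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  o1 <- seq(1, d[1], by = 2); o2 <- seq(2, d[1], by = 2)
  p1 <- seq(1, d[2], by = 2); p2 <- seq(2, d[2], by = 2)
  dy[o1, p1, , , drop = FALSE] + dy[o2, p1, , , drop = FALSE] +
    dy[o1, p2, , , drop = FALSE] + dy[o2, p2, , , drop = FALSE]
}

# Residual block: y = relu(x + conv_b(relu(conv_a(x)))), channels preserved.
resblock_fwd <- function(pa, pb, x) {
  t1 <- conv_fwd_p(pa, x)
  a1 <- relu_fwd(t1)
  s <- conv_fwd_p(pb, a1) + x
  y <- relu_fwd(s)
  list(y = y, x = x, a1 = a1, cache_y = y)
}

resblock_bwd <- function(pa, pb, cache, dy) {
  ds <- relu_bwd(dy, cache$cache_y)
  gb <- conv_bwd_p(pb, cache$a1, ds)
  da1 <- relu_bwd(gb$dx, cache$a1)
  ga <- conv_bwd_p(pa, cache$x, da1)
  list(dx = ga$dx + ds,
       grads = list(a = list(w = ga$dw, b = ga$db),
                    b = list(w = gb$dw, b = gb$db)))
}

#' Build a residual encoder-decoder dose-prediction model
#'
#' A fully convolutional network mapping three anatomy channels (normalized
#' CT, structure label map, distance-to-target map) to one dose channel,
#' slice by slice. The encoder halves the in-plane resolution at each level
#' with stride-2 convolutions; the decoder mirrors it with nearest-neighbour
#' upsampling and additive skip connections; one residual block per
#' resolution level on each path. Two presets are provided: `"full"`
#' (3 levels, 16 base channels — intended for real cohorts) and `"reduced"`
#' (2 levels, 8 base channels — trainable on a CPU in minutes). Input
#' in-plane sizes must be divisible by the downsampling factor
#' `2^levels`. Parameter initialization is fully determined by `seed`.
#'
#' @param preset `"reduced"` or `"full"`.
#' @param seed integer seed for weight initialization.
#' @param in_channels number of input channels (default 3).
#' @return An object of class `dose_model`.
#' @export
build_model <- function(preset = c("reduced", "full"), seed = 1,
                        in_channels = 3L) {
  preset <- match.arg(preset)
  levels <- if (preset == "full") 3L else 2L
  base <- if (preset == "full") 16L else 8L
  ch <- base * 2^(0:levels)

  set.seed(seed)
  params <- list(stem = conv_param(3, in_channels, ch[1]))
  for (l in 0:levels) {
    params[[paste0("enc", l, "a")]] <- conv_param(3, ch[l + 1], ch[l + 1])
    params[[paste0("enc", l, "b")]] <- conv_param(3, ch[l + 1], ch[l + 1])
  }
  for (l in seq_len(levels)) {
    params[[paste0("down", l)]] <- conv_param(3, ch[l], ch[l + 1], stride = 2L)
  }
  for (l in seq_len(levels)) {
    params[[paste0("up", l)]] <- conv_param(3, ch[l + 1], ch[l])
    params[[paste0("dec", l, "a")]] <- conv_param(3, ch[l], ch[l])
    params[[paste0("dec", l, "b")]] <- conv_param(3, ch[l], ch[l])
  }
  params$head <- conv_param(1, ch[1], 1L)

  structure(list(params = params, preset = preset, levels = levels,
                 base = base, seed = seed, in_channels = as.integer(in_channels),
                 down_factor = 2L^levels, norm = NULL),
            class = "dose_model")
}

#' @export
print.dose_model <- function(x, ...) {
  cat(sprintf("<dose_model> preset '%s', %d levels, %d base channels, %d parameters\n",
              x$preset, x$levels, x$base, n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters of a dose model
#' @param model a [build_model()] object.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$w) + length(p$b), numeric(1)))
}

check_inplane <- function(model, d) {
  f <- model$down_factor
  if (d[1] %% f != 0 || d[2] %% f != 0) {
    stop(sprintf("in-plane size %dx%d is not divisible by the downsampling factor %d",
                 d[1], d[2], f), call. = FALSE)
  }
}

net_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  L <- model$levels
  check_inplane(model, dim(x))
  cache <- list()

  t_stem <- conv_fwd_p(p$stem, x)
  a <- relu_fwd(t_stem)
  if (keep_cache) cache$stem <- list(x = x, y = a)

  enc <- vector("list", L + 1)
  e_prev <- a
  enc_caches <- vector("list", L + 1)
  down_caches <- vector("list", L)
  for (l in 0:L) {
    if (l > 0) {
      td <- conv_fwd_p(p[[paste0("down", l)]], e_prev)
      ad <- relu_fwd(td)
      if (keep_cache) down_caches[[l]] <- list(x = e_prev, y = ad)
      e_prev <- ad
    }
    rb <- resblock_fwd(p[[paste0("enc", l, "a")]], p[[paste0("enc", l, "b")]],
                       e_prev)
    enc[[l + 1]] <- rb$y
    if (keep_cache) enc_caches[[l + 1]] <- rb
    e_prev <- rb$y
  }

  h <- enc[[L + 1]]
  up_caches <- vector("list", L)
  dec_caches <- vector("list", L)
  for (l in L:1) {
    hu <- upsample2(h)
    tu <- conv_fwd_p(p[[paste0("up", l)]], hu)
    su <- tu + enc[[l]]
    au <- relu_fwd(su)
    if (keep_cache) up_caches[[l]] <- list(x = hu, y = au)
    rb <- resblock_fwd(p[[paste0("dec", l, "a")]], p[[paste0("dec", l, "b")]],
                       au)
    if (keep_cache) dec_caches[[l]] <- rb
    h <- rb$y
  }

  y <- conv_fwd_p(p$head, h)
  if (keep_cache) {
    cache$enc <- enc_caches; cache$down <- down_caches
    cache$up <- up_caches; cache$dec <- dec_caches
    cache$head_x <- h
  }
  list(y = y, cache = if (keep_cache) cache else NULL)
}

net_backward <- function(model, cache, dy) {
  p <- model$params
  L <- model$levels
  grads <- list()

  gh <- conv_bwd_p(p$head, cache$head_x, dy)
  grads$head <- list(w = gh$dw, b = gh$db)
  dh <- gh$dx

  denc <- vector("list", L + 1)  # gradient flowing into each encoder output

  # Decoder, in reverse order of application (l = 1 was applied last).
  # Iteration l consumes dh (gradient w.r.t. its residual-block output) and
  # emits the gradient w.r.t. its input: the previous decoder stage's output
  # for l < L, or the bottleneck encoder output for l = L.
  for (l in 1:L) {
    rb <- resblock_bwd(p[[paste0("dec", l, "a")]], p[[paste0("dec", l, "b")]],
                       cache$dec[[l]], dh)
    grads[[paste0("dec", l, "a")]] <- rb$grads$a
    grads[[paste0("dec", l, "b")]] <- rb$grads$b
    dsu <- relu_bwd(rb$dx, cache$up[[l]]$y)
    # su = conv(up_l, hu) + enc[[l]]: gradient splits to conv and skip
    denc[[l]] <- dsu
    gu <- conv_bwd_p(p[[paste0("up", l)]], cache$up[[l]]$x, dsu)
    grads[[paste0("up", l)]] <- list(w = gu$dw, b = gu$db)
    dh <- upsample2_bwd(gu$dx)
  }
  denc[[L + 1]] <- dh

  # encoder path, top (bottleneck) down to full resolution
  dflow <- denc[[L + 1]]
  for (l in L:0) {
    rb <- resblock_bwd(p[[paste0("enc", l, "a")]], p[[paste0("enc", l, "b")]],
                       cache$enc[[l + 1]], dflow)
    grads[[paste0("enc", l, "a")]] <- rb$grads$a
    grads[[paste0("enc", l, "b")]] <- rb$grads$b
    dflow <- rb$dx
    if (l > 0) {
      dad <- relu_bwd(dflow, cache$down[[l]]$y)
      gd <- conv_bwd_p(p[[paste0("down", l)]], cache$down[[l]]$x, dad)
      grads[[paste0("down", l)]] <- list(w = gd$dw, b = gd$db)
      dflow <- gd$dx
      if (!is.null(denc[[l]])) dflow <- dflow + denc[[l]]
    }
  }

  da <- relu_bwd(dflow, cache$stem$y)
  gs <- conv_bwd_p(p$stem, cache$stem$x, da)
  grads$stem <- list(w = gs$dw, b = gs$db)
  grads
}

# Global-norm gradient clipping: rescales all gradients so their joint
# L2 norm is at most `max_norm`, guarding the occasional exploding step.
clip_grads <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g$w^2) + sum(g$b^2),
                           numeric(1))))
  if (is.finite(total) && total > max_norm) {
    sc <- max_norm / total
    grads <- lapply(grads, function(g) list(w = g$w * sc, b = g$b * sc))
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) list(mw = p$w * 0, vw = p$w * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$w
    s$vw <- beta2 * s$vw + (1 - beta2) * g$w^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[nm]]$w <- params[[nm]]$w - lr * (s$mw / c1) / (sqrt(s$vw / c2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

#' Train a dose model on assembled samples
#'
#' Minimizes the mean squared error between predicted and target normalized
#' dose slices with Adam. Shuffling is seeded, so a rerun with identical
#' inputs and seed reproduces the loss trajectory exactly.
#'
#' @param model a [build_model()] object.
#' @param x input array of dim (H, W, channels, n_slices).
#' @param y target array of dim (H, W, 1, n_slices).
#' @param epochs number of passes over the data.
#' @param batch_size minibatch size (slices).
#' @param lr Adam learning rate; with the step schedule this is the initial
#'   rate.
#' @param lr_schedule `"step"` (default) divides the rate by 5 for the last
#'   quarter of the epochs, which settles the high-gradient hotspot region;
#'   `"constant"` keeps `lr` throughout.
#' @param clip_norm global L2 gradient-norm ceiling (clipping guards the
#'   occasional exploding minibatch step); `Inf` disables it.
#' @param seed integer seed for minibatch shuffling.
#' @return The model with trained parameters and a `loss` element (mean
#'   epoch losses).
#' @export
train_model <- function(model, x, y, epochs = 10, batch_size = 8, lr = 4e-3,
                        lr_schedule = c("step", "constant"), clip_norm = 0.5,
                        seed = 1) {
  stopifnot(length(dim(x)) == 4, length(dim(y)) == 4,
            dim(x)[4] == dim(y)[4])
  lr_schedule <- match.arg(lr_schedule)
  n <- dim(x)[4]
  state <- adam_init(model$params)
  losses <- numeric(epochs)
  t_step <- 0
  for (ep in seq_len(epochs)) {
    lr_ep <- if (lr_schedule == "step" && ep > 0.75 * epochs) lr / 5 else lr
    set.seed(seed + ep)
    ord <- sample.int(n)
    batch_losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[, , , idx, drop = FALSE]
      fwd <- net_forward(model, xb, keep_cache = TRUE)
      resid <- fwd$y - yb
      batch_losses <- c(batch_losses, mean(resid^2))
      dy <- 2 * resid / length(resid)
      grads <- net_backward(model, fwd$cache, dy)
      grads <- clip_grads(grads, clip_norm)
      t_step <- t_step + 1
      upd <- adam_step(model$params, grads, state, lr_ep, t_step)
      model$params <- upd$params
      state <- upd$state
    }
    losses[ep] <- mean(batch_losses)
  }
  model$loss <- losses
  model
}

net_predict <- function(model, x, batch_size = 16) {
  n <- dim(x)[4]
  out <- array(0, c(dim(x)[1], dim(x)[2], 1, n))
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    out[, , , idx] <- net_forward(model, x[, , , idx, drop = FALSE])$y
  }
  out
}
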