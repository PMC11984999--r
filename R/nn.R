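# Dense conv-net engine: hand-rolled forward/backward over the im2col
# kernels in src/nn_ops.cpp, with an Adam optimizer operating on named
# parameter lists. Parameter lists are plain lists of numeric arrays, which
# is what makes FedAvg merging a one-liner.

he_init <- function(fan_in, dims) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Adam optimizer state for a parameter list
#' @param params named list of numeric arrays.
#' @return optimizer state (first/second moments and step counter).
#' @keywords internal
adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  list(m = zeros, v = zeros, t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

grads_zero <- function(params) lapply(params, function(p) p * 0)
grads_add <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}
grads_scale <- function(a, s) lapply(a, function(g) g * s)

as_cube <- function(x) if (length(dim(x)) == 3) x else array(x, c(dim(x), 1))

conv_fwd <- function(x, params, nm, cache) {
  r <- conv3x3_forward(as_cube(x), params[[paste0(nm, "_W")]],
                       params[[paste0(nm, "_b")]])
  if (!is.null(cache)) {
    cache[[nm]] <- list(cols = r$cols, cin = dim(as_cube(x))[3])
  }
  list(out = r$out, cache = cache)
}

conv_bwd <- function(dout, params, nm, cache, grads) {
  r <- conv3x3_backward(as_cube(dout), cache[[nm]]$cols,
                        params[[paste0(nm, "_W")]], cache[[nm]]$cin)
  grads[[paste0(nm, "_W")]] <- r$dw
  grads[[paste0(nm, "_b")]] <- as.vector(r$db)
  list(dx = r$dx, grads = grads)
}

upsample2 <- function(x) {
  x <- as_cube(x)
  x[rep(seq_len(dim(x)[1]), each = 2), rep(seq_len(dim(x)[2]), each = 2), ,
    drop = FALSE]
}

downsum2 <- function(d) {
  d <- as_cube(d)
  h <- dim(d)[1] / 2; w <- dim(d)[2] / 2
  i1 <- seq(1, 2 * h, 2); i2 <- i1 + 1; j1 <- seq(1, 2 * w, 2); j2 <- j1 + 1
  d[i1, j1, , drop = FALSE] + d[i2, j1, , drop = FALSE] +
    d[i1, j2, , drop = FALSE] + d[i2, j2, , drop = FALSE]
}

## ---------------------------------------------------------------- UNet ----

#' UNet architecture configuration
#'
#' A compact encoder-decoder: `depth` pooling levels with two 3x3
#' convolutions per level, channel width doubling per level from `base`,
#' nearest-neighbour upsampling with skip concatenation, and a 3x3 output
#' head producing one logit map. Input height and width must be divisible
#' by `2^depth`.
#'
#' @param depth number of down/up levels (default 2 at desk scale).
#' @param base channels at the first level (default 8).
#' @param in_channels input channels (1 for mammograms).
#' @return list of class `fm_unet_config`.
#' @export
unet_config <- function(depth = 2L, base = 8L, in_channels = 1L) {
  structure(list(depth = as.integer(depth), base = as.integer(base),
                 in_channels = as.integer(in_channels),
                 channels = as.integer(base * 2^(0:depth))),
            class = "fm_unet_config")
}

unet_init_params <- function(cfg, seed = 1L) {
  withr::with_seed(seed, {
    p <- list()
    ch <- cfg$channels
    addc <- function(p, nm, cin, cout) {
      p[[paste0(nm, "_W")]] <- he_init(9 * cin, c(9 * cin, cout))
      p[[paste0(nm, "_b")]] <- rep(0, cout)
      p
    }
    cin <- cfg$in_channels
    for (i in seq_len(cfg$depth)) {
      p <- addc(p, sprintf("enc%d_c1", i), cin, ch[i])
      p <- addc(p, sprintf("enc%d_c2", i), ch[i], ch[i])
      cin <- ch[i]
    }
    p <- addc(p, "bott_c1", ch[cfg$depth], ch[cfg$depth + 1])
    p <- addc(p, "bott_c2", ch[cfg$depth + 1], ch[cfg$depth + 1])
    for (i in rev(seq_len(cfg$depth))) {
      up_ch <- if (i == cfg$depth) ch[cfg$depth + 1] else ch[i + 1]
      p <- addc(p, sprintf("dec%d_c1", i), up_ch + ch[i], ch[i])
      p <- addc(p, sprintf("dec%d_c2", i), ch[i], ch[i])
    }
    p <- addc(p, "out", ch[1], 1L)
    p
  })
}

unet_forward <- function(params, cfg, x, want_cache = FALSE) {
  cache <- if (want_cache) list() else NULL
  x <- as_cube(x)
  if (any(dim(x)[1:2] %% 2^cfg$depth != 0))
    stop_fm("input %dx%d not divisible by 2^depth = %d",
            dim(x)[1], dim(x)[2], 2^cfg$depth)
  acts <- list()
  skips <- list()
  cur <- x
  for (i in seq_len(cfg$depth)) {
    r <- conv_fwd(cur, params, sprintf("enc%d_c1", i), cache); cache <- r$cache
    a1 <- pmax(r$out, 0)
    r <- conv_fwd(a1, params, sprintf("enc%d_c2", i), cache); cache <- r$cache
    a2 <- pmax(r$out, 0)
    skips[[i]] <- a2
    pl <- maxpool2_forward(a2)
    acts[[sprintf("enc%d_a1", i)]] <- a1
    acts[[sprintf("enc%d_a2", i)]] <- a2
    if (want_cache) cache[[sprintf("pool%d_idx", i)]] <- pl$idx
    cur <- pl$out
  }
  r <- conv_fwd(cur, params, "bott_c1", cache); cache <- r$cache
  b1 <- pmax(r$out, 0)
  r <- conv_fwd(b1, params, "bott_c2", cache); cache <- r$cache
  b2 <- pmax(r$out, 0)
  acts$bott_a1 <- b1; acts$bott_a2 <- b2
  cur <- b2
  for (i in rev(seq_len(cfg$depth))) {
    up <- upsample2(cur)
    cat_in <- array(c(up, skips[[i]]),
                    c(dim(up)[1], dim(up)[2], dim(up)[3] + dim(skips[[i]])[3]))
    if (want_cache) cache[[sprintf("dec%d_upch", i)]] <- dim(up)[3]
    r <- conv_fwd(cat_in, params, sprintf("dec%d_c1", i), cache); cache <- r$cache
    d1 <- pmax(r$out, 0)
    r <- conv_fwd(d1, params, sprintf("dec%d_c2", i), cache); cache <- r$cache
    d2 <- pmax(r$out, 0)
    acts[[sprintf("dec%d_a1", i)]] <- d1
    acts[[sprintf("dec%d_a2", i)]] <- d2
    cur <- d2
  }
  r <- conv_fwd(cur, params, "out", cache); cache <- r$cache
  logits <- r$out[, , 1]
  list(logits = logits, cache = cache, acts = acts)
}

# Dice + binary cross-entropy loss on logits; returns loss, soft dice and
# the gradient wrt logits.
seg_loss_grad <- function(logits, truth) {
  p <- 1 / (1 + exp(-logits))
  n <- length(p)
  eps <- 1e-7
  bce <- -mean(truth * log(p + eps) + (1 - truth) * log(1 - p + eps))
  s_inter <- sum(p * truth); s_p <- sum(p); s_t <- sum(truth)
  dice <- (2 * s_inter + 1) / (s_p + s_t + 1)
  loss <- bce + (1 - dice)
  dbce_dp <- (p - truth) / (p * (1 - p) + eps) / n
  ddice_dp <- (2 * truth * (s_p + s_t + 1) - (2 * s_inter + 1)) /
    (s_p + s_t + 1)^2
  dp <- dbce_dp - ddice_dp        # d(loss)/dp
  dlogits <- dp * p * (1 - p)
  list(loss = loss, dice = dice, dlogits = dlogits)
}

unet_backward <- function(params, cfg, fwd, dlogits) {
  grads <- list()
  cache <- fwd$cache
  acts <- fwd$acts
  dskips <- list()
  r <- conv_bwd(array(dlogits, c(dim(dlogits), 1)), params, "out", cache, grads)
  grads <- r$grads
  d <- r$dx
  # decoder backward: level 1 (full resolution, last in forward) first
  for (i in seq_len(cfg$depth)) {
    d <- d * (acts[[sprintf("dec%d_a2", i)]] > 0)
    r <- conv_bwd(d, params, sprintf("dec%d_c2", i), cache, grads)
    grads <- r$grads
    d <- r$dx * (acts[[sprintf("dec%d_a1", i)]] > 0)
    r <- conv_bwd(d, params, sprintf("dec%d_c1", i), cache, grads)
    grads <- r$grads
    dcat <- r$dx
    upch <- cache[[sprintf("dec%d_upch", i)]]
    dskips[[i]] <- dcat[, , upch + seq_len(dim(dcat)[3] - upch), drop = FALSE]
    # gradient wrt whatever was upsampled: decoder level i+1's output, or
    # the bottleneck output when i == depth
    d <- downsum2(dcat[, , seq_len(upch), drop = FALSE])
  }
  d <- d * (acts$bott_a2 > 0)
  r <- conv_bwd(d, params, "bott_c2", cache, grads); grads <- r$grads
  d <- r$dx * (acts$bott_a1 > 0)
  r <- conv_bwd(d, params, "bott_c1", cache, grads); grads <- r$grads
  d <- r$dx  # gradient wrt pooled output of encoder level `depth`
  # encoder backward, deepest level first
  for (i in rev(seq_len(cfg$depth))) {
    d <- maxpool2_backward(as_cube(d), cache[[sprintf("pool%d_idx", i)]])
    d <- d + dskips[[i]]
    d <- d * (acts[[sprintf("enc%d_a2", i)]] > 0)
    r <- conv_bwd(d, params, sprintf("enc%d_c2", i), cache, grads)
    grads <- r$grads
    d <- r$dx * (acts[[sprintf("enc%d_a1", i)]] > 0)
    r <- conv_bwd(d, params, sprintf("enc%d_c1", i), cache, grads)
    grads <- r$grads
    d <- r$dx  # for i > 1 this is the pooled output of level i-1
  }
  grads
}

## ----------------------------------------------------------- classifier ----

#' Compact CNN classifier configuration
#'
#' Convolution-ReLU-maxpool blocks followed by global average pooling and a
#' linear head — a communication-light architecture whose parameter count is
#' independent of the input resolution (any input divisible by
#' `2^length(channels)` works).
#'
#' @param channels widths of the conv blocks (default `c(8, 16, 32)`).
#' @param n_classes output classes (default 5, BIRADS 1-5).
#' @param in_channels input channels.
#' @return list of class `fm_cnn_config`.
#' @export
cnn_config <- function(channels = c(8L, 16L, 32L), n_classes = 5L,
                       in_channels = 1L) {
  if (n_classes < 2) stop_fm("n_classes must be >= 2")
  structure(list(channels = as.integer(channels),
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels)),
            class = "fm_cnn_config")
}

cnn_init_params <- function(cfg, seed = 1L) {
  withr::with_seed(seed, {
    p <- list()
    cin <- cfg$in_channels
    for (i in seq_along(cfg$channels)) {
      p[[sprintf("conv%d_W", i)]] <- he_init(9 * cin,
                                             c(9 * cin, cfg$channels[i]))
      p[[sprintf("conv%d_b", i)]] <- rep(0, cfg$channels[i])
      cin <- cfg$channels[i]
    }
    p$head_W <- he_init(cin, c(cin, cfg$n_classes))
    p$head_b <- rep(0, cfg$n_classes)
    p
  })
}

cnn_forward <- function(params, cfg, x, want_cache = FALSE) {
  cache <- if (want_cache) list() else NULL
  acts <- list()
  cur <- as_cube(x)
  if (any(dim(cur)[1:2] %% 2^length(cfg$channels) != 0))
    stop_fm("input %dx%d not divisible by 2^n_blocks = %d",
            dim(cur)[1], dim(cur)[2], 2^length(cfg$channels))
  for (i in seq_along(cfg$channels)) {
    r <- conv_fwd(cur, params, sprintf("conv%d", i), cache); cache <- r$cache
    a <- pmax(r$out, 0)
    acts[[sprintf("a%d", i)]] <- a
    pl <- maxpool2_forward(a)
    if (want_cache) cache[[sprintf("pool%d_idx", i)]] <- pl$idx
    cur <- pl$out
  }
  feat <- apply(cur, 3, mean)              # global average pooling
  logits <- as.vector(feat %*% params$head_W) + params$head_b
  if (want_cache) {
    cache$feat <- feat
    cache$map_dim <- dim(cur)
  }
  list(logits = logits, cache = cache, acts = acts)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# cross-entropy loss for one image; label is 1-based class index
cnn_loss_grad <- function(params, cfg, x, label) {
  fwd <- cnn_forward(params, cfg, x, want_cache = TRUE)
  p <- softmax(fwd$logits)
  loss <- -log(max(p[label], 1e-12))
  dlogits <- p
  dlogits[label] <- dlogits[label] - 1
  grads <- list()
  grads$head_W <- outer(fwd$cache$feat, dlogits)
  grads$head_b <- dlogits
  dfeat <- as.vector(params$head_W %*% dlogits)
  md <- fwd$cache$map_dim
  dmap <- array(rep(dfeat, each = md[1] * md[2]) / (md[1] * md[2]), md)
  d <- dmap
  for (i in rev(seq_along(cfg$channels))) {
    d <- maxpool2_backward(as_cube(d), fwd$cache[[sprintf("pool%d_idx", i)]])
    d <- d * (fwd$acts[[sprintf("a%d", i)]] > 0)
    r <- conv_bwd(d, params, sprintf("conv%d", i), fwd$cache, grads)
    grads <- r$grads
    d <- r$dx
  }
  list(loss = loss, probs = p, grads = grads)
}

n_params <- function(params) sum(vapply(params, length, 0L))
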