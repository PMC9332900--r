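## Compact CPU conv-net machinery: Unet generator and convolutional
## discriminator with hand-derived backpropagation over the Rcpp kernels,
## plus the Adam optimizer. Tensors are (H, W, C, N) arrays.

.conv <- function(x, w, b, stride = 1L, pad = 1L)
  .cppConvForward(x, dim(x), w, dim(w), b, as.integer(stride), as.integer(pad))
.convBw <- function(x, w, dy, stride = 1L, pad = 1L)
  .cppConvBackward(x, dim(x), w, dim(w), dy, as.integer(stride),
                   as.integer(pad))
.upconv <- function(x, w, b) .cppUpconvForward(x, dim(x), w, dim(w), b)
.upconvBw <- function(x, w, dy) .cppUpconvBackward(x, dim(x), w, dim(w), dy)

.chanRep <- function(a, dm) rep(rep(a, each = dm[1] * dm[2]), times = dm[4])

.actForward <- function(x, kind, slope = NULL) {
  if (kind == "relu") return(pmax(x, 0))
  if (kind == "lrelu") return(ifelse(x > 0, x, slope[1] * x))
  av <- .chanRep(slope, dim(x))           # prelu, learned per-channel slope
  ifelse(x > 0, x, av * x)
}

.actBackward <- function(x, dy, kind, slope = NULL) {
  if (kind == "relu") return(list(dx = dy * (x > 0)))
  if (kind == "lrelu")
    return(list(dx = ifelse(x > 0, dy, slope[1] * dy)))
  dm <- dim(x)
  av <- .chanRep(slope, dm)
  neg <- x <= 0
  dx <- dy
  dx[neg] <- dy[neg] * av[neg]
  contrib <- array(0, dm)
  contrib[neg] <- dy[neg] * x[neg]
  da <- apply(contrib, 3, sum)
  list(dx = dx, da = da)
}

.heInit <- function(kh, kw, cin, cout)
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))

#' Unet generator architecture description
#'
#' The generator operates on the bicubic-initialized HR grid and is fully
#' convolutional: a contraction path of paired 3x3 convolutions with
#' downsampling, a bottleneck, and an expansion path of 2x2 transposed
#' convolutions with skip concatenation, closed by a linear 1x1 convolution.
#' Two variants are supported: ReLU activations with max-pooling (the
#' Unet-only model) and parametric ReLU with strided-convolution
#' downsampling (the GAN generator variant).
#'
#' @param depth number of contraction levels (input sizes must be
#'   divisible by \code{2^depth}).
#' @param baseChannels channel count of the first level; doubles per level.
#' @param inChannels input channels: 1 for the metabolic map alone, 1 + P
#'   when P prior images are stacked (the two-input method).
#' @param activation \code{"relu"} or \code{"prelu"}.
#' @param downsampling \code{"maxpool"} or \code{"strided"}.
#' @param init \code{"identity"} (default) threads a delta-kernel path for
#'   the first input channel through the level-1 encoder/decoder so the
#'   freshly built network maps a non-negative input to itself exactly;
#'   training then learns corrections to the bicubic initialization, which
#'   converges far faster than learning the full mapping from
#'   \code{"he"}-only initialization.
#' @param seed seed for weight initialization.
#' @return classed parameter list.
#' @export
unetSpec <- function(depth = 3L, baseChannels = 8L, inChannels = 1L,
                     activation = c("relu", "prelu"),
                     downsampling = c("maxpool", "strided"),
                     init = c("identity", "he"), seed = 1L) {
  structure(list(depth = as.integer(depth),
                 baseChannels = as.integer(baseChannels),
                 inChannels = as.integer(inChannels),
                 activation = match.arg(activation),
                 downsampling = match.arg(downsampling),
                 init = match.arg(init),
                 seed = as.integer(seed)),
            class = "UnetSpec")
}

#' Build (initialize) a Unet generator
#'
#' Allocates He-initialized weights for the architecture described by the
#' spec. The final 1x1 convolution has no activation; with zero final-layer
#' weights the network output equals the final bias map. Deterministic
#' given \code{spec$seed}.
#'
#' @param spec a [unetSpec()].
#' @return a \code{UnetModel}: list with \code{spec} and \code{params}.
#' @export
buildGenerator <- function(spec) {
  stopifnot(inherits(spec, "UnetSpec"))
  .withSeed(spec$seed, {
    p <- list()
    d <- spec$depth
    ch <- spec$baseChannels * 2^(seq_len(d + 1L) - 1L)  # level channels + bottleneck
    cin <- spec$inChannels
    prelu <- spec$activation == "prelu"
    for (l in seq_len(d)) {
      p[[sprintf("enc%d_a_w", l)]] <- .heInit(3, 3, cin, ch[l])
      p[[sprintf("enc%d_a_b", l)]] <- numeric(ch[l])
      p[[sprintf("enc%d_b_w", l)]] <- .heInit(3, 3, ch[l], ch[l])
      p[[sprintf("enc%d_b_b", l)]] <- numeric(ch[l])
      if (prelu) {
        p[[sprintf("enc%d_a_p", l)]] <- rep(0.25, ch[l])
        p[[sprintf("enc%d_b_p", l)]] <- rep(0.25, ch[l])
      }
      if (spec$downsampling == "strided") {
        p[[sprintf("down%d_w", l)]] <- .heInit(3, 3, ch[l], ch[l])
        p[[sprintf("down%d_b", l)]] <- numeric(ch[l])
        if (prelu) p[[sprintf("down%d_p", l)]] <- rep(0.25, ch[l])
      }
      cin <- ch[l]
    }
    cb <- ch[d + 1L]
    p$bott_a_w <- .heInit(3, 3, ch[d], cb); p$bott_a_b <- numeric(cb)
    p$bott_b_w <- .heInit(3, 3, cb, cb);    p$bott_b_b <- numeric(cb)
    if (prelu) { p$bott_a_p <- rep(0.25, cb); p$bott_b_p <- rep(0.25, cb) }
    up_in <- cb
    for (l in rev(seq_len(d))) {
      p[[sprintf("up%d_w", l)]] <- .heInit(2, 2, up_in, ch[l]) *
        sqrt((3 * 3) / (2 * 2))  # keep He scale for the 2x2 kernel
      p[[sprintf("up%d_b", l)]] <- numeric(ch[l])
      p[[sprintf("dec%d_a_w", l)]] <- .heInit(3, 3, 2L * ch[l], ch[l])
      p[[sprintf("dec%d_a_b", l)]] <- numeric(ch[l])
      p[[sprintf("dec%d_b_w", l)]] <- .heInit(3, 3, ch[l], ch[l])
      p[[sprintf("dec%d_b_b", l)]] <- numeric(ch[l])
      if (prelu) {
        p[[sprintf("dec%d_a_p", l)]] <- rep(0.25, ch[l])
        p[[sprintf("dec%d_b_p", l)]] <- rep(0.25, ch[l])
      }
      up_in <- ch[l]
    }
    p$final_w <- .heInit(1, 1, ch[1L], 1L)
    p$final_b <- 0
    if (identical(spec$init, "identity")) {
      # delta-kernel pass-through of input channel 1 along the level-1
      # chain: exact identity on non-negative inputs (metabolite maps are),
      # for both ReLU and PReLU activations
      p$enc1_a_w[, , , 1] <- 0; p$enc1_a_w[2, 2, 1, 1] <- 1
      p$enc1_b_w[, , , 1] <- 0; p$enc1_b_w[2, 2, 1, 1] <- 1
      nch <- ch[1L]
      p$dec1_a_w[, , , 1] <- 0; p$dec1_a_w[2, 2, nch + 1L, 1] <- 1
      p$dec1_b_w[, , , 1] <- 0; p$dec1_b_w[2, 2, 1, 1] <- 1
      p$final_w[] <- 0; p$final_w[1, 1, 1, 1] <- 1
    }
    structure(list(spec = spec, params = p), class = "UnetModel")
  })
}

# Generator forward pass; returns list(y, cache) when keepCache.
.unetForward <- function(model, x, keepCache = FALSE) {
  spec <- model$spec; p <- model$params
  d <- spec$depth
  dm <- dim(x)
  if (length(dm) == 3L) { dim(x) <- c(dm, 1L); dm <- dim(x) }
  if (dm[3] != spec$inChannels)
    stop(sprintf("input has %d channels; model expects %d", dm[3],
                 spec$inChannels))
  if (any(dm[1:2] %% 2^d != 0L))
    stop(sprintf("input size %dx%d not divisible by 2^depth = %d",
                 dm[1], dm[2], 2^d))
  act <- spec$activation
  cache <- list()
  skips <- vector("list", d)
  cur <- x
  for (l in seq_len(d)) {
    za <- .conv(cur, p[[sprintf("enc%d_a_w", l)]], p[[sprintf("enc%d_a_b", l)]])
    aa <- .actForward(za, act, p[[sprintf("enc%d_a_p", l)]])
    zb <- .conv(aa, p[[sprintf("enc%d_b_w", l)]], p[[sprintf("enc%d_b_b", l)]])
    ab <- .actForward(zb, act, p[[sprintf("enc%d_b_p", l)]])
    if (spec$downsampling == "maxpool") {
      pl <- .cppMaxpoolForward(ab, dim(ab))
      nxt <- pl$y
      if (keepCache) cache[[sprintf("pool%d", l)]] <- pl$idx
    } else {
      zd <- .conv(ab, p[[sprintf("down%d_w", l)]], p[[sprintf("down%d_b", l)]],
                  stride = 2L)
      nxt <- .actForward(zd, act, p[[sprintf("down%d_p", l)]])
      if (keepCache) cache[[sprintf("downz%d", l)]] <- zd
    }
    skips[[l]] <- ab
    if (keepCache) {
      cache[[sprintf("encin%d", l)]] <- cur
      cache[[sprintf("encza%d", l)]] <- za
      cache[[sprintf("encaa%d", l)]] <- aa
      cache[[sprintf("enczb%d", l)]] <- zb
      cache[[sprintf("skip%d", l)]] <- ab
    }
    cur <- nxt
  }
  zba <- .conv(cur, p$bott_a_w, p$bott_a_b)
  aba <- .actForward(zba, act, p$bott_a_p)
  zbb <- .conv(aba, p$bott_b_w, p$bott_b_b)
  abb <- .actForward(zbb, act, p$bott_b_p)
  if (keepCache) {
    cache$bottin <- cur; cache$bottza <- zba; cache$bottaa <- aba
    cache$bottzb <- zbb
  }
  cur <- abb
  for (l in rev(seq_len(d))) {
    up <- .upconv(cur, p[[sprintf("up%d_w", l)]], p[[sprintf("up%d_b", l)]])
    skip <- skips[[l]]
    nch <- dim(up)[3]
    cc <- array(0, dim = c(dim(up)[1:2], 2L * nch, dim(up)[4]))
    cc[, , seq_len(nch), ] <- up
    cc[, , nch + seq_len(nch), ] <- skip
    za <- .conv(cc, p[[sprintf("dec%d_a_w", l)]], p[[sprintf("dec%d_a_b", l)]])
    aa <- .actForward(za, act, p[[sprintf("dec%d_a_p", l)]])
    zb <- .conv(aa, p[[sprintf("dec%d_b_w", l)]], p[[sprintf("dec%d_b_b", l)]])
    ab <- .actForward(zb, act, p[[sprintf("dec%d_b_p", l)]])
    if (keepCache) {
      cache[[sprintf("upin%d", l)]] <- cur
      cache[[sprintf("cc%d", l)]] <- cc
      cache[[sprintf("decza%d", l)]] <- za
      cache[[sprintf("decaa%d", l)]] <- aa
      cache[[sprintf("deczb%d", l)]] <- zb
      cache[[sprintf("decab%d", l)]] <- ab
    }
    cur <- ab
  }
  y <- .conv(cur, p$final_w, p$final_b, pad = 0L)
  if (keepCache) cache$finin <- cur
  if (keepCache) list(y = y, cache = cache) else y
}

# Backward pass: gradients of all parameters plus the input gradient.
.unetBackward <- function(model, cache, dy) {
  spec <- model$spec; p <- model$params
  d <- spec$depth; act <- spec$activation
  g <- list()
  bw <- .convBw(cache$finin, p$final_w, dy, pad = 0L)
  g$final_w <- bw$dw; g$final_b <- bw$db
  cur <- bw$dx
  for (l in seq_len(d)) {     # decoder, shallow -> deep
    ab <- .actBackward(cache[[sprintf("deczb%d", l)]], cur, act,
                       p[[sprintf("dec%d_b_p", l)]])
    if (!is.null(ab$da)) g[[sprintf("dec%d_b_p", l)]] <- ab$da
    bw <- .convBw(cache[[sprintf("decaa%d", l)]],
                  p[[sprintf("dec%d_b_w", l)]], ab$dx)
    g[[sprintf("dec%d_b_w", l)]] <- bw$dw
    g[[sprintf("dec%d_b_b", l)]] <- bw$db
    aa <- .actBackward(cache[[sprintf("decza%d", l)]], bw$dx, act,
                       p[[sprintf("dec%d_a_p", l)]])
    if (!is.null(aa$da)) g[[sprintf("dec%d_a_p", l)]] <- aa$da
    bw <- .convBw(cache[[sprintf("cc%d", l)]],
                  p[[sprintf("dec%d_a_w", l)]], aa$dx)
    g[[sprintf("dec%d_a_w", l)]] <- bw$dw
    g[[sprintf("dec%d_a_b", l)]] <- bw$db
    nch <- dim(bw$dx)[3] %/% 2L
    dup <- bw$dx[, , seq_len(nch), , drop = FALSE]
    dskip <- bw$dx[, , nch + seq_len(nch), , drop = FALSE]
    ubw <- .upconvBw(cache[[sprintf("upin%d", l)]],
                     p[[sprintf("up%d_w", l)]], dup)
    g[[sprintf("up%d_w", l)]] <- ubw$dw
    g[[sprintf("up%d_b", l)]] <- ubw$db
    cur <- ubw$dx
    g[[sprintf(".skip%d", l)]] <- dskip   # stashed for the encoder sweep
  }
  bb <- .actBackward(cache$bottzb, cur, act, p$bott_b_p)
  if (!is.null(bb$da)) g$bott_b_p <- bb$da
  bw <- .convBw(cache$bottaa, p$bott_b_w, bb$dx)
  g$bott_b_w <- bw$dw; g$bott_b_b <- bw$db
  ba <- .actBackward(cache$bottza, bw$dx, act, p$bott_a_p)
  if (!is.null(ba$da)) g$bott_a_p <- ba$da
  bw <- .convBw(cache$bottin, p$bott_a_w, ba$dx)
  g$bott_a_w <- bw$dw; g$bott_a_b <- bw$db
  cur <- bw$dx
  for (l in rev(seq_len(d))) {   # encoder, deep -> shallow
    skipDim <- dim(cache[[sprintf("skip%d", l)]])
    if (spec$downsampling == "maxpool") {
      dab <- .cppMaxpoolBackward(cache[[sprintf("pool%d", l)]], cur, skipDim)
    } else {
      da <- .actBackward(cache[[sprintf("downz%d", l)]], cur, act,
                         p[[sprintf("down%d_p", l)]])
      if (!is.null(da$da)) g[[sprintf("down%d_p", l)]] <- da$da
      bw <- .convBw(cache[[sprintf("skip%d", l)]],
                    p[[sprintf("down%d_w", l)]], da$dx, stride = 2L)
      g[[sprintf("down%d_w", l)]] <- bw$dw
      g[[sprintf("down%d_b", l)]] <- bw$db
      dab <- bw$dx
    }
    dab <- dab + g[[sprintf(".skip%d", l)]]
    g[[sprintf(".skip%d", l)]] <- NULL
    ab <- .actBackward(cache[[sprintf("enczb%d", l)]], dab, act,
                       p[[sprintf("enc%d_b_p", l)]])
    if (!is.null(ab$da)) g[[sprintf("enc%d_b_p", l)]] <- ab$da
    bw <- .convBw(cache[[sprintf("encaa%d", l)]],
                  p[[sprintf("enc%d_b_w", l)]], ab$dx)
    g[[sprintf("enc%d_b_w", l)]] <- bw$dw
    g[[sprintf("enc%d_b_b", l)]] <- bw$db
    aa <- .actBackward(cache[[sprintf("encza%d", l)]], bw$dx, act,
                       p[[sprintf("enc%d_a_p", l)]])
    if (!is.null(aa$da)) g[[sprintf("enc%d_a_p", l)]] <- aa$da
    bw <- .convBw(cache[[sprintf("encin%d", l)]],
                  p[[sprintf("enc%d_a_w", l)]], aa$dx)
    g[[sprintf("enc%d_a_w", l)]] <- bw$dw
    g[[sprintf("enc%d_a_b", l)]] <- bw$db
    cur <- bw$dx
  }
  g$.input <- cur
  g
}

#' Discriminator architecture description
#'
#' Eight 3x3 convolutional layers whose kernel counts grow from 64 to 512,
#' with stride-2 reductions at every channel doubling, followed by two
#' dense layers and a sigmoid head giving a probability in (0, 1).
#' Leaky-ReLU activations (slope 0.2) are used throughout the body.
#'
#' @param inputSize square input patch size; must be divisible by the
#'   stride chain implied by \code{channels}.
#' @param inChannels input image channels.
#' @param channels kernel counts of the 8 convolutional layers.
#' @param denseWidth width of the first dense layer.
#' @param seed initialization seed.
#' @return classed parameter list.
#' @export
discriminatorSpec <- function(inputSize = 64L, inChannels = 1L,
                              channels = c(64, 64, 128, 128, 256, 256,
                                           512, 512),
                              denseWidth = 1024L, seed = 1L) {
  channels <- as.integer(channels)
  strides <- c(1L, ifelse(channels[-1] > channels[-length(channels)], 2L, 1L))
  red <- prod(strides)
  if (inputSize %% red != 0L)
    stop(sprintf("input size %d incompatible with stride chain (reduction %d)",
                 inputSize, red))
  structure(list(inputSize = as.integer(inputSize),
                 inChannels = as.integer(inChannels), channels = channels,
                 strides = strides, denseWidth = as.integer(denseWidth),
                 leakySlope = 0.2, seed = as.integer(seed)),
            class = "DiscriminatorSpec")
}

#' Build (initialize) a discriminator
#'
#' @param spec a [discriminatorSpec()].
#' @return a \code{DiscriminatorModel}: list with \code{spec}, \code{params}.
#' @export
buildDiscriminator <- function(spec) {
  stopifnot(inherits(spec, "DiscriminatorSpec"))
  .withSeed(spec$seed, {
    p <- list()
    cin <- spec$inChannels
    sz <- spec$inputSize
    for (i in seq_along(spec$channels)) {
      p[[sprintf("conv%d_w", i)]] <- .heInit(3, 3, cin, spec$channels[i])
      p[[sprintf("conv%d_b", i)]] <- numeric(spec$channels[i])
      cin <- spec$channels[i]
      sz <- sz %/% spec$strides[i]
    }
    flat <- sz * sz * cin
    p$fc1_w <- matrix(stats::rnorm(flat * spec$denseWidth,
                                   sd = sqrt(2 / flat)), flat)
    p$fc1_b <- numeric(spec$denseWidth)
    p$fc2_w <- matrix(stats::rnorm(spec$denseWidth, sd = sqrt(1 / spec$denseWidth)))
    p$fc2_b <- 0
    structure(list(spec = spec, params = p), class = "DiscriminatorModel")
  })
}

# Discriminator forward; returns scores in (0,1), logits, optional cache.
.discForward <- function(model, x, keepCache = FALSE) {
  spec <- model$spec; p <- model$params
  dm <- dim(x)
  if (length(dm) == 3L) { dim(x) <- c(dm, 1L); dm <- dim(x) }
  if (dm[1] != spec$inputSize || dm[2] != spec$inputSize)
    stop(sprintf("discriminator expects %dx%d input patches", spec$inputSize,
                 spec$inputSize))
  sl <- spec$leakySlope
  cache <- list(); cur <- x
  for (i in seq_along(spec$channels)) {
    z <- .conv(cur, p[[sprintf("conv%d_w", i)]], p[[sprintf("conv%d_b", i)]],
               stride = spec$strides[i])
    a <- .actForward(z, "lrelu", sl)
    if (keepCache) {
      cache[[sprintf("in%d", i)]] <- cur
      cache[[sprintf("z%d", i)]] <- z
    }
    cur <- a
  }
  dmc <- dim(cur)
  N <- dmc[4]
  flat <- matrix(cur, nrow = prod(dmc[1:3]), ncol = N)
  z1 <- crossprod(p$fc1_w, flat) + p$fc1_b          # denseWidth x N
  a1 <- ifelse(z1 > 0, z1, sl * z1)
  logit <- as.numeric(crossprod(p$fc2_w, a1) + p$fc2_b)
  score <- 1 / (1 + exp(-logit))
  if (keepCache) {
    cache$flat <- flat; cache$flatDim <- dmc; cache$fcz1 <- z1; cache$fca1 <- a1
    list(score = score, logit = logit, cache = cache)
  } else list(score = score, logit = logit)
}

# Backward from d(loss)/d(logit); returns param grads and input gradient.
.discBackward <- function(model, cache, dlogit) {
  spec <- model$spec; p <- model$params
  sl <- spec$leakySlope
  g <- list()
  N <- length(dlogit)
  g$fc2_w <- matrix(cache$fca1 %*% dlogit, ncol = 1)
  g$fc2_b <- sum(dlogit)
  da1 <- p$fc2_w %*% matrix(dlogit, nrow = 1)       # denseWidth x N
  dz1 <- ifelse(cache$fcz1 > 0, da1, sl * da1)
  g$fc1_w <- cache$flat %*% t(dz1)
  g$fc1_b <- rowSums(dz1)
  dflat <- p$fc1_w %*% dz1
  cur <- array(dflat, dim = cache$flatDim)
  for (i in rev(seq_along(spec$channels))) {
    dz <- ifelse(cache[[sprintf("z%d", i)]] > 0, cur, sl * cur)
    bw <- .convBw(cache[[sprintf("in%d", i)]], p[[sprintf("conv%d_w", i)]],
                  dz, stride = spec$strides[i])
    g[[sprintf("conv%d_w", i)]] <- bw$dw
    g[[sprintf("conv%d_b", i)]] <- bw$db
    cur <- bw$dx
  }
  g$.input <- cur
  g
}

## ---- Adam ----

.adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
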