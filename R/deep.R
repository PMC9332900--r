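## Training loops (Unet with pure-MSE loss; GAN fine-tuning with
## adversarial loss), the perceptual loss, SR prediction for the three
## deep-learning method variants, and checkpoint I/O.

#' Training configuration
#'
#' Defaults record the full-scale training schedule (batch 16, Adam with
#' learning rate 1e-4, 20k iterations for the Unet; for GAN fine-tuning use
#' [ganConfig()], which switches the learning rate from 1e-5 to 1e-6 at
#' half the run and keeps Adam momenta (0.9, 0.999)). Desk-scale runs
#' shrink \code{iterations} and the network spec, not the recipe.
#'
#' @param lambda adversarial weight; 0 means pure-MSE (Unet-only) training.
#' @param batchSize minibatch size.
#' @param iterations iteration budget (an explicit budget replaces "until
#'   convergence"; combine with \code{patience} for early stopping).
#' @param learningRate scalar, or a function(iteration) -> rate.
#' @param beta1,beta2 Adam momentum terms.
#' @param cropSize random-crop size in LR voxels (\code{NULL}: no crop).
#' @param flip random mirror flips during augmentation. Off by default:
#'   array reversal does not commute with the k-space truncation operator
#'   (the LR and HR grids reflect about continuous centers offset by half
#'   an LR voxel minus half an HR voxel), so flipped pairs pose a slightly
#'   shifted inverse problem and measurably slow convergence.
#' @param generator a [unetSpec()].
#' @param discriminator a [discriminatorSpec()] (GAN only).
#' @param freezeDiscriminator if TRUE the discriminator is never updated
#'   (with \code{lambda = 0} this reduces GAN training to Unet training).
#' @param patience early-stop patience in validation checks (\code{NULL}
#'   disables early stopping).
#' @param logEvery iterations between log rows / validation checks.
#' @param checkpointDir if non-NULL, periodic checkpoints are written here.
#' @param seed seed for minibatch sampling and augmentation.
#' @return classed parameter list.
#' @export
trainConfig <- function(lambda = 0, batchSize = 16L, iterations = 20000L,
                        learningRate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                        cropSize = 16L, flip = FALSE,
                        generator = unetSpec(),
                        discriminator = NULL,
                        freezeDiscriminator = FALSE, patience = NULL,
                        logEvery = 50L, checkpointDir = NULL, seed = 1L) {
  if (lambda < 0) stop("'lambda' must be >= 0")
  structure(list(lambda = lambda, batchSize = as.integer(batchSize),
                 iterations = as.integer(iterations),
                 learningRate = learningRate, beta1 = beta1, beta2 = beta2,
                 cropSize = cropSize, flip = flip, generator = generator,
                 discriminator = discriminator,
                 freezeDiscriminator = freezeDiscriminator,
                 patience = patience, logEvery = as.integer(logEvery),
                 checkpointDir = checkpointDir, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' GAN fine-tuning configuration (full-scale schedule)
#'
#' Convenience wrapper over [trainConfig()] with the GAN schedule: 20k
#' iterations at learning rate 1e-5 for the first half and 1e-6 for the
#' second, Adam momenta (0.9, 0.999), batch 16, adversarial weight
#' \code{lambda}.
#'
#' @param lambda adversarial weight (> 0 for true GAN training; the
#'   adversarial weight has no canonical value, so a small
#'   SRGAN-lineage default is used).
#' @param iterations total iterations (rate switches at the midpoint).
#' @param ... further arguments passed to [trainConfig()].
#' @export
ganConfig <- function(lambda = 1e-3, iterations = 20000L, ...) {
  half <- iterations / 2
  trainConfig(lambda = lambda, iterations = iterations,
              learningRate = function(it) if (it <= half) 1e-5 else 1e-6,
              ...)
}

.lrAt <- function(rate, it) if (is.function(rate)) rate(it) else rate

.modelOf <- function(x) {
  if (inherits(x, "TrainedNetwork")) x$model
  else if (inherits(x, "UnetModel")) x
  else stop("expected a UnetModel or TrainedNetwork")
}

# Precompute per-pair HR-grid channel stacks: the full-image bicubic ISR
# (so training inputs match test-time inputs, with no crop-edge
# interpolation artifacts) plus stacked priors for two-input models.
.prepStacks <- function(pairs, inCh) {
  lapply(pairs, function(p) {
    fac <- dim(p@hr@data)[1] %/% dim(p@lr@data)[1]
    chans <- list(bicubicUpsample(p@lr@data, fac))
    if (inCh > 1L) {
      pri <- priorMaps(p)
      if (is.null(pri))
        stop("two-input model requires pairs carrying prior images")
      chans <- c(chans, lapply(pri@images, function(im) im@data))
      if (length(chans) != inCh)
        stop(sprintf("model expects %d input channels, pair provides %d",
                     inCh, length(chans)))
    }
    list(x = array(unlist(chans), dim = c(dim(p@hr@data), length(chans))),
         t = p@hr@data, fac = fac)
  })
}

# Assemble one flip/crop-augmented minibatch from precomputed stacks.
# Crop origins are drawn on the LR grid (HR origin = fac x LR origin).
# Consumes the current RNG stream (one flip pair + one origin per sample).
.assembleBatch <- function(stacks, idx, cfg) {
  nCh <- dim(stacks[[1]]$x)[3]
  cs <- cfg$cropSize
  xs <- vector("list", length(idx))
  ts <- vector("list", length(idx))
  for (q in seq_along(idx)) {
    st <- stacks[[idx[q]]]
    x <- st$x; t <- st$t
    flips <- if (cfg$flip) stats::runif(2) < 0.5 else c(FALSE, FALSE)
    if (flips[1]) { x <- x[rev(seq_len(nrow(x))), , , drop = FALSE]
                    t <- t[rev(seq_len(nrow(t))), , drop = FALSE] }
    if (flips[2]) { x <- x[, rev(seq_len(ncol(x))), , drop = FALSE]
                    t <- t[, rev(seq_len(ncol(t))), drop = FALSE] }
    if (!is.null(cs)) {
      fac <- st$fac
      nLR <- dim(t) %/% fac
      if (any(cs > nLR)) stop("crop window larger than the LR image")
      o <- vapply(nLR - cs, function(m)
        if (m > 0) sample.int(m + 1L, 1L) - 1L else 0L, 0L)
      s1 <- fac * o[1] + seq_len(fac * cs)
      s2 <- fac * o[2] + seq_len(fac * cs)
      x <- x[s1, s2, , drop = FALSE]
      t <- t[s1, s2, drop = FALSE]
    }
    xs[[q]] <- x
    ts[[q]] <- t
  }
  hw <- dim(xs[[1]])[1:2]
  list(x = array(unlist(xs), dim = c(hw, nCh, length(idx))),
       t = array(unlist(ts), dim = c(hw, 1L, length(idx))))
}

# Mean over the pairs of per-voxel MSE validation error (no augmentation).
.validationMSE <- function(model, stacks) {
  tot <- 0
  for (st in stacks) {
    y <- .unetForward(model, st$x)
    tot <- tot + mean((as.vector(y) - as.vector(st$t))^2)
  }
  tot / length(stacks)
}

#' Perceptual loss (MSE plus adversarial term)
#'
#' The training cost: the mean over the batch of the per-sample sum of
#' squared differences plus \code{lambda} times the non-saturating
#' adversarial term \code{-log D(G(.))}. With \code{lambda = 0} this is the
#' pure MSE cost used for Unet-only training.
#'
#' @param hrTruth,srPred numeric arrays; either single images or batches
#'   with samples along the last dimension (ndim > 2).
#' @param discScore discriminator score(s) in (0, 1), one per sample
#'   (ignored when \code{lambda = 0}).
#' @param lambda adversarial weight (>= 0).
#' @return scalar loss.
#' @export
perceptualLoss <- function(hrTruth, srPred, discScore = NULL, lambda = 0) {
  if (lambda < 0) stop("'lambda' must be >= 0")
  hrTruth <- as.array(hrTruth); srPred <- as.array(srPred)
  if (!identical(dim(hrTruth), dim(srPred))) stop("shape mismatch")
  nd <- length(dim(hrTruth))
  N <- if (nd > 2L) dim(hrTruth)[nd] else 1L
  se <- (hrTruth - srPred)^2
  perSample <- if (N == 1L) sum(se)
  else apply(se, nd, sum)
  adv <- 0
  if (lambda > 0) {
    if (is.null(discScore)) stop("'discScore' needed when lambda > 0")
    if (any(discScore <= 0 | discScore >= 1))
      stop("'discScore' must lie strictly in (0, 1)")
    adv <- lambda * (-log(discScore))
  }
  mean(perSample + adv)
}

#' Train the Unet generator with pure MSE loss
#'
#' Minibatch Adam training of the generator on bicubic-initialized inputs
#' against HR ground truth, with flip/crop augmentation. Requires
#' \code{lambda = 0}. Deterministic given the config seed (fixed thread
#' settings assumed; single-threaded BLAS gives bit reproducibility).
#'
#' @param pairs list of \linkS4class{TrainingPair}s (the training split).
#' @param cfg a [trainConfig()] with \code{lambda = 0}.
#' @param init optional pre-built \code{UnetModel} to start from (default:
#'   a fresh [buildGenerator()] from \code{cfg$generator}).
#' @param validationPairs optional held-out pairs for early stopping.
#' @return a \code{TrainedNetwork}: list with \code{model}, \code{loss}
#'   (per-iteration trace), \code{log} (data.frame), \code{config}.
#' @export
trainUnet <- function(pairs, cfg = trainConfig(), init = NULL,
                      validationPairs = NULL) {
  if (cfg$lambda != 0)
    stop("trainUnet is pure-MSE training; use trainGAN for lambda > 0")
  model <- if (is.null(init)) buildGenerator(cfg$generator) else .modelOf(init)
  res <- .trainLoop(pairs, cfg, model, disc = NULL, validationPairs)
  structure(list(model = res$model, loss = res$gLoss, log = res$log,
                 config = cfg), class = "TrainedNetwork")
}

#' Fine-tune the generator adversarially (GAN)
#'
#' Alternating discriminator/generator updates of the saddle-point
#' objective: the discriminator maximizes \code{log D(real) +
#' log(1 - D(fake))}, the generator minimizes MSE plus the non-saturating
#' adversarial term \code{-lambda log D(fake)}. The generator starts from
#' the pretrained Unet. With \code{lambda = 0} and a frozen discriminator
#' the loop is identical to [trainUnet()] (bit-for-bit on the same seed).
#' Discriminator score saturation (collapse) is reported as a warning and
#' training continues.
#'
#' @param pairs training pairs.
#' @param pretrained pretrained generator (\code{TrainedNetwork} or
#'   \code{UnetModel}).
#' @param cfg a [trainConfig()]/[ganConfig()] carrying a
#'   \code{discriminator} spec when updates are not frozen.
#' @param validationPairs optional held-out pairs (logged only).
#' @return a \code{TrainedNetwork} with additional trace columns
#'   (discriminator loss, real/fake scores).
#' @export
trainGAN <- function(pairs, pretrained, cfg = ganConfig(),
                     validationPairs = NULL) {
  model <- .modelOf(pretrained)
  disc <- NULL
  if (!cfg$freezeDiscriminator) {
    if (cfg$lambda <= 0)
      stop("GAN training with live discriminator requires lambda > 0")
    if (is.null(cfg$discriminator))
      stop("cfg$discriminator spec required")
    disc <- buildDiscriminator(cfg$discriminator)
  }
  res <- .trainLoop(pairs, cfg, model, disc = disc, validationPairs)
  structure(list(model = res$model, discriminator = res$disc,
                 loss = res$gLoss, dLoss = res$dLoss,
                 scoreReal = res$scoreReal, scoreFake = res$scoreFake,
                 log = res$log, config = cfg), class = "TrainedNetwork")
}

# Shared minibatch loop. disc = NULL means no discriminator at all (pure
# Unet path); in that case the RNG stream is exactly the Unet stream.
.trainLoop <- function(pairs, cfg, model, disc = NULL,
                       validationPairs = NULL) {
  stacks <- .prepStacks(pairs, cfg$generator$inChannels)
  valStacks <- if (!is.null(validationPairs))
    .prepStacks(validationPairs, cfg$generator$inChannels)
  set.seed(cfg$seed)
  stG <- .adamInit(model$params)
  stD <- if (!is.null(disc)) .adamInit(disc$params)
  n <- length(pairs)
  gLoss <- numeric(cfg$iterations)
  dLoss <- sR <- sF <- rep(NA_real_, cfg$iterations)
  logRows <- list()
  bestVal <- Inf; sinceBest <- 0L
  collapsed <- FALSE
  for (it in seq_len(cfg$iterations)) {
    lr <- .lrAt(cfg$learningRate, it)
    idx <- sample.int(n, cfg$batchSize, replace = TRUE)
    b <- .assembleBatch(stacks, idx, cfg)
    N <- dim(b$x)[4]
    if (!is.null(disc)) {
      # discriminator step on real HR vs current generator output
      fake <- .unetForward(model, b$x)
      fr <- .discForward(disc, b$t, keepCache = TRUE)
      ff <- .discForward(disc, fake, keepCache = TRUE)
      sR[it] <- mean(fr$score); sF[it] <- mean(ff$score)
      eps <- 1e-12
      dLoss[it] <- -mean(log(pmax(fr$score, eps))) -
        mean(log(pmax(1 - ff$score, eps)))
      gr <- .discBackward(disc, fr$cache, -(1 - fr$score) / N)
      gf <- .discBackward(disc, ff$cache, ff$score / N)
      for (nm in names(disc$params)) gr[[nm]] <- gr[[nm]] + gf[[nm]]
      up <- .adamStep(disc$params, gr, stD, lr, cfg$beta1, cfg$beta2)
      disc$params <- up$params; stD <- up$state
      if (!collapsed && it >= 50L) {
        win <- max(1L, it - 49L):it
        if (all(sF[win] < 1e-3) || all(sF[win] > 1 - 1e-3)) {
          warning("discriminator scores saturated (possible collapse); ",
                  "training continues")
          collapsed <- TRUE
        }
      }
    }
    # generator step
    fwd <- .unetForward(model, b$x, keepCache = TRUE)
    resid <- fwd$y - b$t
    mse <- sum(resid^2) / N
    dy <- 2 * resid / N
    advLoss <- 0
    if (!is.null(disc) && cfg$lambda > 0) {
      fg <- .discForward(disc, fwd$y, keepCache = TRUE)
      advLoss <- cfg$lambda * mean(-log(pmax(fg$score, 1e-12)))
      gAdv <- .discBackward(disc, fg$cache,
                            -cfg$lambda * (1 - fg$score) / N)
      dy <- dy + gAdv$.input
    }
    gLoss[it] <- mse + advLoss
    if (!is.finite(gLoss[it]))
      stop(sprintf("non-finite training loss at iteration %d (lr=%g)",
                   it, lr))
    grads <- .unetBackward(model, fwd$cache, dy)
    up <- .adamStep(model$params, grads, stG, lr, cfg$beta1, cfg$beta2)
    model$params <- up$params; stG <- up$state
    if (it %% cfg$logEvery == 0L || it == cfg$iterations) {
      val <- if (!is.null(valStacks))
        .validationMSE(model, valStacks) else NA_real_
      logRows[[length(logRows) + 1L]] <-
        data.frame(iteration = it, lr = lr, gLoss = gLoss[it],
                   dLoss = dLoss[it], scoreReal = sR[it], scoreFake = sF[it],
                   valMSE = val)
      if (!is.null(cfg$checkpointDir)) {
        dir.create(cfg$checkpointDir, recursive = TRUE, showWarnings = FALSE)
        saveNetworkParams(model, file.path(cfg$checkpointDir,
                                           sprintf("ckpt_%06d.rds", it)))
      }
      if (!is.null(cfg$patience) && !is.na(val)) {
        if (val < bestVal - 1e-12) { bestVal <- val; sinceBest <- 0L }
        else sinceBest <- sinceBest + 1L
        if (sinceBest >= cfg$patience) {
          gLoss <- gLoss[seq_len(it)]
          dLoss <- dLoss[seq_len(it)]; sR <- sR[seq_len(it)]
          sF <- sF[seq_len(it)]
          break
        }
      }
    }
  }
  list(model = model, disc = disc, gLoss = gLoss, dLoss = dLoss,
       scoreReal = sR, scoreFake = sF,
       log = do.call(rbind, logRows))
}

#' Super-resolve an LR map with a trained network
#'
#' Runs the requested deep-learning method variant:
#' \describe{
#'   \item{dl1}{generator on the bicubic-initialized map alone.}
#'   \item{dl2}{dl1 followed by FNLM reinterpolation with prior MRI.}
#'   \item{dl3}{generator on the channel-stacked bicubic map and priors
#'     (requires a model built with \code{inChannels = 1 + P}).}
#' }
#' The output is clipped to be non-negative.
#'
#' @param model trained generator (\code{TrainedNetwork} or
#'   \code{UnetModel}).
#' @param lr LR \linkS4class{MetabolicMap} or array.
#' @param prior \linkS4class{PriorImages} on the HR grid (methods 2 and 3).
#' @param method \code{"dl1"}, \code{"dl2"} or \code{"dl3"}.
#' @param factor upsampling factor.
#' @param h FNLM bandwidth for method 2.
#' @return SR map of the same kind as \code{lr} (tier \code{"SR"}).
#' @export
predictSR <- function(model, lr, prior = NULL, method = c("dl1", "dl2", "dl3"),
                      factor = 4L, h = 0.4) {
  method <- match.arg(method)
  model <- .modelOf(model)
  inCh <- model$spec$inChannels
  if (method %in% c("dl2", "dl3") && is.null(prior))
    stop(sprintf("method '%s' requires prior images", method))
  if (method == "dl3" && inCh < 2L)
    stop("method 'dl3' needs a model trained with stacked prior channels")
  if (method %in% c("dl1", "dl2") && inCh != 1L)
    stop(sprintf("method '%s' needs a single-input model (inChannels = 1)",
                 method))
  isr <- bicubicUpsample(.asArr(lr), factor)
  chans <- list(isr)
  if (method == "dl3") {
    chans <- c(chans, lapply(prior@images, function(im) im@data))
    if (length(chans) != inCh)
      stop(sprintf("model expects %d channels, got %d", inCh, length(chans)))
  }
  x <- array(unlist(chans), dim = c(dim(isr), length(chans), 1L))
  y <- .unetForward(model, x)
  out <- pmax(array(y, dim = dim(isr)), 0)
  if (method == "dl2")
    out <- .asArr(fnlmReinterpolate(out, prior, h = h))
  res <- .likeMap(lr, out, tier = "SR")
  if (is(res, "MetabolicMap")) res@voxelSize <- res@voxelSize / factor
  res
}

#' Save network parameters to a checkpoint file
#'
#' Checkpoints are self-describing (format tag, version, full architecture
#' spec) and restore bit-exactly.
#'
#' @param model a \code{UnetModel}, \code{DiscriminatorModel} or
#'   \code{TrainedNetwork}.
#' @param path output file path.
#' @export
saveNetworkParams <- function(model, path) {
  model <- if (inherits(model, "TrainedNetwork")) model$model else model
  saveRDS(list(format = "MetaboSR-checkpoint", version = 1L,
               class = class(model)[1], spec = model$spec,
               params = model$params), path)
  invisible(path)
}

#' Load network parameters from a checkpoint file
#' @param path checkpoint written by [saveNetworkParams()].
#' @return the restored model.
#' @export
loadNetworkParams <- function(path) {
  ck <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read checkpoint '", path, "': ", conditionMessage(e)))
  if (!identical(ck$format, "MetaboSR-checkpoint"))
    stop("not a MetaboSR checkpoint: ", path)
  structure(list(spec = ck$spec, params = ck$params), class = ck$class)
}
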