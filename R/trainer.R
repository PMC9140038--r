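#' Training configuration
#'
#' @param epochs number of training periods; within each, the (augmented)
#'   frame pool of the sequence is reshuffled and traversed.
#' @param steps_per_epoch gradient steps per epoch. Each step draws one
#'   batch: two distinct frames from the pool, labelled fixed and moving.
#' @param learning_rate Adam step size.
#' @param optimizer currently `"adam"`.
#' @param loss a [loss_config()].
#' @param augmentation list with `per_frame_copies` (photometric copies of
#'   each frame added to the pool, regenerated every epoch) and optionally
#'   `magnitudes` (see [upsample_sequence()]).
#' @param mode `"rgb"` trains three branches, one per colour plane;
#'   `"red"`, `"green"`, `"blue"` and `"grayscale"` train a single branch on
#'   that plane (grayscale uses the 0.299/0.587/0.114 luminance weighting).
#' @param widths channel widths passed to [build_branch()].
#' @param seed master seed covering initialization, augmentation, pair
#'   sampling and noise; equal seeds give identical runs.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 420L, steps_per_epoch = 1000L,
                         learning_rate = 1e-4, optimizer = "adam",
                         loss = loss_config(),
                         augmentation = list(per_frame_copies = 1L),
                         mode = c("rgb", "red", "green", "blue", "grayscale"),
                         widths = c(16, 32, 32, 32, 32, 32, 32, 16),
                         seed = 1L) {
  mode <- match.arg(mode)
  if (epochs < 1L || steps_per_epoch < 1L)
    stop("epochs and steps_per_epoch must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (!identical(optimizer, "adam")) stop("only the adam optimizer is available", call. = FALSE)
  stopifnot(inherits(loss, "loss_config"))
  structure(list(epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 learning_rate = learning_rate, optimizer = optimizer,
                 loss = loss, augmentation = augmentation, mode = mode,
                 widths = as.integer(widths), seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' A reduced configuration for CPU-scale experiments on small (e.g. 64 x 64)
#' sequences: 14 epochs of 90 steps with a learning rate of 1e-3 and one
#' photometric copy per frame. Completes in a few minutes on one CPU core
#' while recovering the rigid misalignments of the default phantom; the
#' raised learning rate compensates for the much shorter schedule relative
#' to the full-scale defaults.
#'
#' @param ... overrides forwarded to [train_config()].
#' @return a [train_config()].
#' @export
desk_profile <- function(...) {
  args <- list(...)
  defaults <- list(epochs = 14L, steps_per_epoch = 90L, learning_rate = 1e-3,
                   augmentation = list(per_frame_copies = 1L))
  do.call(train_config, utils::modifyList(defaults, args))
}

# Split an RGB frame into the channel planes the given mode trains on.
channels_for_mode <- function(frame, mode) {
  switch(mode,
    rgb = lapply(1:3, function(ch) frame[, , ch]),
    red = list(frame[, , 1]),
    green = list(frame[, , 2]),
    blue = list(frame[, , 3]),
    grayscale = list(luminance(frame))
  )
}

adam_init <- function(layers) {
  lapply(layers, function(l) list(
    mw = array(0, dim(l$w)), vw = array(0, dim(l$w)),
    mb = numeric(length(l$b)), vb = numeric(length(l$b))
  ))
}

adam_step <- function(branch, state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (nm in names(branch$layers)) {
    g <- grads[[nm]]
    s <- state[[nm]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$w
    s$vw <- beta2 * s$vw + (1 - beta2) * g$w^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    branch$layers[[nm]]$w <- branch$layers[[nm]]$w -
      lr * (s$mw / corr1) / (sqrt(s$vw / corr2) + eps)
    branch$layers[[nm]]$b <- branch$layers[[nm]]$b -
      lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    state[[nm]] <- s
  }
  list(branch = branch, state = state)
}

#' Train the registration network on one time sequence
#'
#' Unsupervised per-sequence training: at every step two distinct frames are
#' drawn from the current epoch's augmented pool (one labelled fixed, one
#' moving; batch size one). In `rgb` mode the pair is split into R, G and B
#' channel pairs routed to the three branches, whose losses (similarity plus
#' weighted smoothness) are aggregated before the parameter update;
#' single-channel modes train exactly one branch. Each epoch regenerates the
#' photometric augmentations and reshuffles the pool; the moving frame walks
#' the shuffled pool cyclically so all frames are visited. The trainer sees
#' only the frames and the configuration - never ground-truth masks or
#' transforms.
#'
#' @param sequence a `time_sequence`/`phantom_sequence` or plain list of
#'   `H x W x 3` frames, all the same size, at a resolution divisible by 16.
#' @param config a [train_config()] (see [desk_profile()] for CPU scale).
#' @return an object of class `training_run`: list with `model` (an
#'   `rgb_registrar` or single `branch_network`), `log` (one row per step:
#'   epoch, step, per-channel similarity and smoothness losses, total), and
#'   `config`.
#' @export
train_on_sequence <- function(sequence, config = desk_profile()) {
  stopifnot(inherits(config, "train_config"))
  frames <- as_frame_list(sequence)
  if (length(frames) < 2L) stop("a sequence needs at least 2 frames", call. = FALSE)
  dims <- lapply(frames, function(f) dim(f)[1:2])
  if (length(unique(dims)) != 1L)
    stop("all frames must have identical dimensions", call. = FALSE)
  H <- dims[[1]][1]
  W <- dims[[1]][2]
  mode <- config$mode
  n_ch <- if (mode == "rgb") 3L else 1L
  copies <- config$augmentation$per_frame_copies %||% 0L
  mags <- config$augmentation$magnitudes

  with_seed(config$seed, {
    if (mode == "rgb") {
      model <- build_rgb_registrar(H, W, config$widths,
                                   seed = sample.int(1e6, 1))
      branches <- unclass(model)[c("r", "g", "b")]
    } else {
      branches <- list(build_branch(H, W, config$widths,
                                    seed = sample.int(1e6, 1)))
    }
    states <- lapply(branches, function(b) adam_init(b$layers))

    n_steps <- config$epochs * config$steps_per_epoch
    log <- data.frame(epoch = integer(n_steps), step = integer(n_steps),
                      similarity = numeric(n_steps),
                      smoothness = numeric(n_steps),
                      total = numeric(n_steps))
    sim_ch <- matrix(0, n_steps, n_ch)
    row <- 0L
    for (epoch in seq_len(config$epochs)) {
      pool_seed <- sample.int(.Machine$integer.max, 1)
      pool <- if (copies > 0) {
        if (is.null(mags)) upsample_sequence(frames, copies, seed = pool_seed)$frames
        else upsample_sequence(frames, copies, seed = pool_seed,
                               magnitudes = mags)$frames
      } else frames
      npool <- length(pool)
      order <- sample(npool)
      pos <- 0L
      for (step in seq_len(config$steps_per_epoch)) {
        pos <- pos + 1L
        if (pos > npool) {
          order <- sample(npool)
          pos <- 1L
        }
        mi <- order[pos]
        fi <- sample(seq_len(npool)[-mi], 1)
        fch <- channels_for_mode(pool[[fi]], mode)
        mch <- channels_for_mode(pool[[mi]], mode)
        row <- row + 1L
        tot_sim <- 0
        tot_smooth <- 0
        for (b in seq_len(n_ch)) {
          x0 <- array(c(fch[[b]], mch[[b]]), c(H, W, 2))
          cache <- branch_forward(branches[[b]], x0, want_cache = TRUE)
          u <- cache$field
          warped <- warp_bilinear_fw_cpp(mch[[b]], u)
          sim <- similarity_loss(fch[[b]], warped, config$loss)
          smo <- smoothness_loss(u)
          if (!is.finite(sim) || !is.finite(smo))
            stop(sprintf("non-finite loss at epoch %d step %d (sim=%g, smooth=%g)",
                         epoch, step, sim, smo), call. = FALSE)
          gimg <- similarity_grad(fch[[b]], warped, config$loss)
          dim(gimg) <- c(H, W)
          gfield <- warp_bilinear_bw_cpp(mch[[b]], u, gimg)$gfield +
            config$loss$lambda_smooth * smoothness_grad(u)
          grads <- branch_backward(branches[[b]], cache, gfield)
          upd <- adam_step(branches[[b]], states[[b]], grads,
                           config$learning_rate, row)
          branches[[b]] <- upd$branch
          states[[b]] <- upd$state
          tot_sim <- tot_sim + sim
          tot_smooth <- tot_smooth + smo
          sim_ch[row, b] <- sim
        }
        log$epoch[row] <- epoch
        log$step[row] <- step
        log$similarity[row] <- tot_sim
        log$smoothness[row] <- tot_smooth
        log$total[row] <- tot_sim + config$loss$lambda_smooth * tot_smooth
      }
    }
    if (mode == "rgb") {
      colnames(sim_ch) <- c("similarity_r", "similarity_g", "similarity_b")
      log <- cbind(log, as.data.frame(sim_ch))
      model[c("r", "g", "b")] <- branches
    } else {
      model <- branches[[1]]
    }
    structure(list(model = model, log = log, config = config, mode = mode),
              class = "training_run")
  })
}

#' @export
print.training_run <- function(x, ...) {
  first <- mean(x$log$total[x$log$epoch == 1])
  last <- mean(x$log$total[x$log$epoch == max(x$log$epoch)])
  cat(sprintf("training_run (%s): %d epochs x %d steps; mean total loss %.3g -> %.3g\n",
              x$mode, x$config$epochs, x$config$steps_per_epoch, first, last))
  invisible(x)
}

#' Write a per-step training log to CSV
#'
#' @param run a `training_run`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_training_log <- function(run, path) {
  stopifnot(inherits(run, "training_run"))
  utils::write.csv(run$log, path, row.names = FALSE)
  invisible(path)
}
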