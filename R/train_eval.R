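# Training (ADAM + binary cross-entropy on the three overlapping binary
# masks), prediction and dice-coefficient evaluation.

#' Training configuration
#'
#' @param epochs Number of passes over the training split.
#' @param batch_size Cases per optimizer step (gradients are accumulated
#'   within a batch; the reference protocol uses 1).
#' @param learning_rate ADAM step size.
#' @param train_fraction Fraction of cases used for training; the rest
#'   form the validation split.
#' @param threshold Probability cut for binarizing predictions.
#' @param seed Seed controlling the split and the per-epoch case order.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 1L,
                         learning_rate = 1e-4, train_fraction = 0.8,
                         threshold = 0.5, seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              learning_rate = learning_rate, train_fraction = train_fraction,
              threshold = threshold, seed = as.integer(seed))
  if (cfg$epochs < 1L || cfg$batch_size < 1L) stop("epochs and batch_size must be >= 1")
  if (cfg$learning_rate < 0) stop("learning_rate must be nonnegative")
  if (cfg$train_fraction <= 0 || cfg$train_fraction > 1)
    stop("train_fraction must lie in (0, 1]")
  if (cfg$threshold < 0 || cfg$threshold > 1) stop("threshold must lie in [0, 1]")
  structure(cfg, class = "train_config")
}

#' Binary cross-entropy loss
#'
#' Mean over all voxels and channels of `-(t log p + (1-t) log(1-p))`.
#' Probabilities are clamped to `[1e-7, 1-1e-7]` before taking logs so
#' that float-saturated sigmoid outputs stay finite.
#'
#' @param pred Probability array.
#' @param target Binary array of the same shape (a [mask_stack] is
#'   accepted for either argument).
#' @return Nonnegative scalar.
#' @export
bce_loss <- function(pred, target) {
  if (inherits(pred, "mask_stack")) pred <- pred$data
  if (inherits(target, "mask_stack")) target <- target$data
  if (!identical(dim(pred), dim(target))) stop("bce_loss: shape mismatch")
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Dice similarity coefficient
#'
#' `2 |A n B| / (|A| + |B|)` for two binary masks of identical shape; two
#' empty masks score 1 (perfect agreement on the absence of foreground).
#'
#' @param ms Machine segmentation (binary array or [mask_stack] channel).
#' @param gt Ground truth, same shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(ms, gt) {
  if (!identical(dim(ms) %||% length(ms), dim(gt) %||% length(gt)))
    stop("dice_coefficient: shape mismatch")
  if (!all(ms %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stop("dice_coefficient: masks must be binary")
  s <- sum(ms) + sum(gt)
  if (s == 0) return(1)
  2 * sum(ms * gt) / s
}

adam_init <- function(params) {
  zeros <- rapply(params, function(x) x * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (blk in names(params)) {
    for (nm in names(params[[blk]])) {
      g <- grads[[blk]][[nm]]
      m <- beta1 * state$m[[blk]][[nm]] + (1 - beta1) * g
      v <- beta2 * state$v[[blk]][[nm]] + (1 - beta2) * g * g
      state$m[[blk]][[nm]] <- m
      state$v[[blk]][[nm]] <- v
      params[[blk]][[nm]] <- params[[blk]][[nm]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (blk in names(b)) for (nm in names(b[[blk]]))
    a[[blk]][[nm]] <- a[[blk]][[nm]] + b[[blk]][[nm]]
  a
}

#' Train a network
#'
#' Runs `epochs` passes of ADAM on the binary cross-entropy between the
#' sigmoid outputs and the three mask channels.  The dataset is split
#' into training/validation by `train_fraction` under `config$seed`; the
#' per-epoch case order is reshuffled with a seed derived from
#' `seed + epoch`, so loss traces are reproducible and epoch-prefix
#' stable.  The parameters achieving the best mean validation dice are
#' kept alongside the final ones.
#'
#' @param model A [znet_model].
#' @param dataset List of `list(stack=, masks=)` pairs.
#' @param config A [train_config].
#' @param verbose Print one line per epoch.
#' @return List with `model` (final weights), `best_model` (best
#'   validation dice; equals `model` when there is no validation split)
#'   and `history` (data.frame, one row per epoch).
#' @export
train_znet <- function(model, dataset, config = train_config(),
                       verbose = FALSE) {
  stopifnot(inherits(model, "znet_model"), inherits(config, "train_config"))
  n <- length(dataset)
  if (n == 0L) stop("empty dataset")
  set.seed(config$seed)
  perm <- sample.int(n)
  n_train <- max(1L, round(config$train_fraction * n))
  train_idx <- perm[seq_len(n_train)]
  val_idx <- if (n_train < n) perm[(n_train + 1L):n] else integer(0)

  state <- adam_init(model$params)
  hist <- vector("list", config$epochs)
  best <- list(dice = -Inf, params = model$params, buffers = model$buffers)

  for (ep in seq_len(config$epochs)) {
    set.seed(config$seed + 1000L * ep)
    order_ep <- train_idx[sample.int(n_train)]
    losses <- numeric(0)
    acc <- NULL
    in_batch <- 0L
    for (ii in order_ep) {
      pair <- dataset[[ii]]
      x <- pair$stack$data
      t <- pair$masks$data
      fwd <- znet_forward(model, x, training = TRUE)
      model$buffers <- fwd$buffers
      loss <- bce_loss(fwd$prob, t)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", ep,
             " on case '", pair$stack$case_id, "'; aborting")
      }
      losses <- c(losses, loss)
      dlogits <- (fwd$prob - t) / length(t)
      acc <- grads_add(acc, znet_backward(model, fwd, dlogits))
      in_batch <- in_batch + 1L
      if (in_batch == config$batch_size) {
        if (config$batch_size > 1L) {
          acc <- rapply(acc, function(g) g / in_batch, how = "replace")
        }
        st <- adam_step(model$params, acc, state, config$learning_rate)
        model$params <- st$params
        state <- st$state
        acc <- NULL
        in_batch <- 0L
      }
    }
    if (in_batch > 0L) {   # trailing partial batch
      acc <- rapply(acc, function(g) g / in_batch, how = "replace")
      st <- adam_step(model$params, acc, state, config$learning_rate)
      model$params <- st$params
      state <- st$state
    }
    vd <- c(wt = NA_real_, tc = NA_real_, et = NA_real_)
    if (length(val_idx) > 0L) {
      dd <- sapply(val_idx, function(ii) {
        pred <- predict_case(model, dataset[[ii]]$stack, config$threshold)
        gt <- dataset[[ii]]$masks$data
        c(dice_coefficient(pred$data[1, , , ], gt[1, , , ]),
          dice_coefficient(pred$data[2, , , ], gt[2, , , ]),
          dice_coefficient(pred$data[3, , , ], gt[3, , , ]))
      })
      vd <- c(wt = mean(dd[1, ]), tc = mean(dd[2, ]), et = mean(dd[3, ]))
      if (mean(vd) > best$dice) {
        best <- list(dice = mean(vd), params = model$params,
                     buffers = model$buffers)
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, loss = mean(losses),
                             val_dice_wt = vd[["wt"]],
                             val_dice_tc = vd[["tc"]],
                             val_dice_et = vd[["et"]])
    if (verbose) {
      message(sprintf("epoch %3d  loss %.5f  val WT %.3f", ep,
                      mean(losses), vd[["wt"]]))
    }
  }
  history <- do.call(rbind, hist)
  best_model <- if (is.finite(best$dice)) {
    structure(list(config = model$config, params = best$params,
                   buffers = best$buffers), class = "znet_model")
  } else model
  list(model = model, best_model = best_model, history = history)
}

#' Predict the three masks for one case
#'
#' Forward pass in evaluation mode (batch-norm running statistics),
#' then per-channel thresholding: voxels with probability `>= threshold`
#' become 1.  Channels are binarized independently, so a predicted stack
#' is not forced to satisfy the ET <= TC <= WT nesting that ground-truth
#' stacks obey.
#'
#' @param model A [znet_model].
#' @param stack A [modality_stack] whose grid is divisible by
#'   `2^depth`.
#' @param threshold Probability cut in `[0, 1]`.
#' @return A [mask_stack] (nesting not enforced).
#' @export
predict_case <- function(model, stack, threshold = 0.5) {
  stopifnot(inherits(model, "znet_model"), inherits(stack, "modality_stack"))
  fwd <- znet_forward(model, stack$data, training = FALSE)
  bin <- array(as.numeric(fwd$prob >= threshold), dim = dim(fwd$prob))
  structure(list(data = bin, case_id = stack$case_id), class = "mask_stack")
}

#' Evaluate a model over labeled cases
#'
#' Per-case dice for WT, TC and ET, the three region means, and the
#' overall mean defined as the arithmetic mean of the region means
#' (the "Avg." convention of segmentation leaderboards).
#'
#' @param model A [znet_model].
#' @param cases List of `list(stack=, masks=)` pairs, all labeled.
#' @param config A [train_config] (supplies the threshold).
#' @return An object of class `dice_report` with `per_case` (data.frame),
#'   `region_means` (named numeric) and `overall_mean`.
#' @export
evaluate_dataset <- function(model, cases, config = train_config()) {
  if (length(cases) == 0L) stop("empty case list")
  rows <- lapply(cases, function(pair) {
    if (is.null(pair$masks)) stop("evaluate_dataset requires ground-truth masks")
    pred <- predict_case(model, pair$stack, config$threshold)
    gt <- pair$masks$data
    data.frame(case_id = pair$stack$case_id,
               wt = dice_coefficient(pred$data[1, , , ], gt[1, , , ]),
               tc = dice_coefficient(pred$data[2, , , ], gt[2, , , ]),
               et = dice_coefficient(pred$data[3, , , ], gt[3, , , ]))
  })
  per_case <- do.call(rbind, rows)
  dice_report(per_case)
}

#' Assemble a dice report from per-case values
#'
#' @param per_case data.frame with columns `case_id`, `wt`, `tc`, `et`.
#' @export
dice_report <- function(per_case) {
  stopifnot(all(c("case_id", "wt", "tc", "et") %in% names(per_case)))
  region_means <- c(wt = mean(per_case$wt), tc = mean(per_case$tc),
                    et = mean(per_case$et))
  structure(list(per_case = per_case, region_means = region_means,
                 overall_mean = mean(region_means)),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat("<dice_report> ", nrow(x$per_case), " case(s)\n", sep = "")
  cat(sprintf("  mean dice  WT %.3f  TC %.3f  ET %.3f  overall %.3f\n",
              x$region_means[["wt"]], x$region_means[["tc"]],
              x$region_means[["et"]], x$overall_mean))
  invisible(x)
}

overlay_rgb <- function(base, mask, col) {
  r <- base; g <- base; b <- base
  w <- mask > 0
  r[w] <- 0.4 * base[w] + 0.6 * col[1]
  g[w] <- 0.4 * base[w] + 0.6 * col[2]
  b[w] <- 0.4 * base[w] + 0.6 * col[3]
  rst <- array(0, dim = c(ncol(base), nrow(base), 3))
  rst[, , 1] <- t(r); rst[, , 2] <- t(g); rst[, , 3] <- t(b)
  rst
}

#' Export a three-panel overlay image
#'
#' Writes a PNG of one axial slice: ground truth (green) over the Flair
#' channel, prediction (red) over the same slice, and their agreement map
#' (yellow = both, green = ground truth only, red = prediction only).
#' The whole-tumor channel is displayed.
#'
#' @param stack A [modality_stack].
#' @param gt,pred [mask_stack]s on the same grid.
#' @param slice_index Axial slice (third spatial axis), 1-based.
#' @param path Output PNG path.
#' @export
export_overlay <- function(stack, gt, pred, slice_index, path) {
  ns <- dim(stack$data)[4]
  if (slice_index < 1 || slice_index > ns)
    stop("slice_index out of range 1..", ns)
  base <- stack$data[1, , , slice_index]
  gts <- gt$data[1, , , slice_index]
  prs <- pred$data[1, , , slice_index]
  both <- gts * prs
  r <- base; g <- base; b <- base
  idx <- both > 0
  r[idx] <- 0.4 * base[idx] + 0.6; g[idx] <- 0.4 * base[idx] + 0.6
  idx <- (gts * (1 - prs)) > 0
  g[idx] <- 0.4 * base[idx] + 0.6
  idx <- (prs * (1 - gts)) > 0
  r[idx] <- 0.4 * base[idx] + 0.6
  panel3 <- array(0, dim = c(ncol(base), nrow(base), 3))
  panel3[, , 1] <- t(r); panel3[, , 2] <- t(g); panel3[, , 3] <- t(b)

  grDevices::png(path, width = 960, height = 340)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  panels <- list(`ground truth` = overlay_rgb(base, gts, c(0, 1, 0)),
                 prediction = overlay_rgb(base, prs, c(1, 0, 0)),
                 agreement = panel3)
  for (nm in names(panels)) {
    graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1), axes = FALSE,
                   xlab = "", ylab = "", asp = 1)
    graphics::rasterImage(panels[[nm]], 0, 0, 1, 1)
    graphics::title(nm)
  }
  invisible(path)
}
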