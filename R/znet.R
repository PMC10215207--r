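# The densely connected 3D encoder-decoder ("Z-net") builder.
#
# Layout for depth S and channel schedule ch[0..S]:
#   input block   : conv_block(in_channels -> ch0)           at full grid
#   encoder i     : maxpool/2 then conv_block(ch[i-1]->ch[i]) at grid /2^i
#   (deepest encoder doubles as the bottleneck)
#   decoder j=S..1: trilinear upsample x2, concatenate with the
#                   same-resolution encoder/input feature map, then
#                   conv_block(-> ch[j-1])
#   output block  : 1x1x1 convolution to out_channels, then sigmoid
#
# Every decoder stage therefore consumes ALL feature maps available at
# its spatial resolution (in a single-chain encoder there is exactly one
# per level, plus the upsampled deeper features).  Channel alignment is
# free because the concatenated width is known at build time, so no 1x1x1
# size-normalization projection is needed on the skip path; the output
# block carries the 1x1x1 convolution.

#' Architecture configuration
#'
#' @param in_channels Input channels (4 modalities by default).
#' @param out_channels Output channels (3 nested masks by default).
#' @param depth Number of encoder (= decoder) stages; the spatial grid is
#'   halved once per encoder stage, so each input dimension must be
#'   divisible by `2^depth`.
#' @param base_width Channels of the input block and first encoder stage.
#' @param width_multiplier Per-stage channel growth factor.
#' @param input_size Nominal `(D, H, W)` grid the model is intended for.
#' @return An object of class `znet_config`.
#' @export
znet_config <- function(in_channels = 4L, out_channels = 3L, depth = 4L,
                        base_width = 32L, width_multiplier = 2L,
                        input_size = c(128L, 128L, 128L)) {
  cfg <- list(in_channels = as.integer(in_channels),
              out_channels = as.integer(out_channels),
              depth = as.integer(depth),
              base_width = as.integer(base_width),
              width_multiplier = as.integer(width_multiplier),
              input_size = as.integer(input_size))
  if (cfg$depth < 1L) stop("depth must be >= 1")
  if (cfg$in_channels < 1L || cfg$out_channels < 1L)
    stop("channel counts must be >= 1")
  if (length(cfg$input_size) != 3L) stop("input_size must have length 3")
  check_grid(cfg$input_size, cfg$depth)
  structure(cfg, class = "znet_config")
}

check_grid <- function(size, depth) {
  if (any(size %% (2L^depth) != 0L)) {
    stop("input size (", paste(size, collapse = ","),
         ") must be divisible by 2^depth = ", 2L^depth)
  }
  invisible(TRUE)
}

# ch[i] for i = 0..depth (index shifted by 1 in R)
znet_channels <- function(cfg) {
  ch <- integer(cfg$depth + 1L)
  ch[1] <- cfg$base_width
  for (i in seq_len(cfg$depth)) {
    ch[i + 1] <- as.integer(cfg$base_width * cfg$width_multiplier^(i - 1L))
  }
  ch
}

# channels entering decoder stage j's conv block (upsampled + skip)
dec_in_channels <- function(cfg) {
  ch <- znet_channels(cfg)
  S <- cfg$depth
  vapply(S:1, function(j) {
    ch_up <- if (j == S) ch[S + 1] else ch[j + 1]
    as.integer(ch_up + ch[j])
  }, integer(1))
}

#' Build the network
#'
#' Instantiates all parameters (Kaiming-style normal init for
#' convolutions, unit gain / zero shift for batch normalization) under a
#' fixed seed, so two builds with the same config and seed are
#' weight-identical.
#'
#' @param config A [znet_config].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `znet_model`.
#' @export
build_znet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "znet_config"))
  set.seed(seed)
  ch <- znet_channels(config)
  S <- config$depth
  params <- list(inb = init_block_params(config$in_channels, ch[1]))
  buffers <- list(inb = init_block_buffers(ch[1]))
  for (i in seq_len(S)) {
    params[[paste0("enc", i)]] <- init_block_params(ch[i], ch[i + 1])
    buffers[[paste0("enc", i)]] <- init_block_buffers(ch[i + 1])
  }
  din <- dec_in_channels(config)
  for (k in seq_len(S)) {
    j <- S - k + 1L             # decoder stage index, deepest first
    params[[paste0("dec", j)]] <- init_block_params(din[k], ch[j])
    buffers[[paste0("dec", j)]] <- init_block_buffers(ch[j])
  }
  oc <- init_conv(ch[1], config$out_channels, 1L)
  # Output bias starts at the background prior (-3 is logit(~0.047),
  # the order of the foreground fraction in tumor volumes): with the
  # sigmoid + binary cross-entropy head this avoids spending early
  # optimizer steps on learning "mostly background" and is standard for
  # heavily class-imbalanced dense prediction.
  params$out <- list(w = oc$w, b = rep(-3, config$out_channels))
  structure(list(config = config, params = params, buffers = buffers),
            class = "znet_model")
}

#' @export
print.znet_model <- function(x, ...) {
  cfg <- x$config
  cat("<znet_model> depth ", cfg$depth, ", channels ",
      paste(znet_channels(cfg), collapse = "-"), ", ",
      cfg$in_channels, " -> ", cfg$out_channels, " channels, ",
      format(znet_num_params(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' Total trainable parameter count
#' @param model A [znet_model].
#' @export
znet_num_params <- function(model) {
  sum(rapply(model$params, length, how = "unlist"))
}

# Forward pass.  x: (C, D, H, W) array.  Returns prob (sigmoid output),
# logits, caches for backward (when training), and updated buffers.
znet_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  S <- cfg$depth
  p <- model$params
  b <- model$buffers
  d <- dim(x)
  if (length(d) != 4L || d[1] != cfg$in_channels)
    stop("input must be (", cfg$in_channels, ", D, H, W)")
  check_grid(d[2:4], S)

  caches <- list()
  fb <- block_forward(x, p$inb, b$inb, training)
  b$inb <- fb$buf
  caches$inb <- fb$cache
  e <- vector("list", S + 1L)   # e[[i+1]] = level-i features
  e[[1]] <- fb$y
  pool_idx <- vector("list", S)
  for (i in seq_len(S)) {
    pl <- cpp_maxpool2_fwd(e[[i]])
    pool_idx[[i]] <- pl$idx
    nm <- paste0("enc", i)
    fb <- block_forward(pl$out, p[[nm]], b[[nm]], training)
    b[[nm]] <- fb$buf
    caches[[nm]] <- fb$cache
    e[[i + 1]] <- fb$y
  }
  dcur <- e[[S + 1]]
  up_dims <- vector("list", S)
  cat_caches <- vector("list", S)
  for (j in S:1) {
    skip <- e[[j]]
    sd <- dim(skip)
    up_dims[[j]] <- dim(dcur)[2:4]
    up <- cpp_trilinear_fwd(dcur, sd[2:4])
    xin <- concat_channels(up, skip)
    nm <- paste0("dec", j)
    fb <- block_forward(xin, p[[nm]], b[[nm]], training)
    b[[nm]] <- fb$buf
    caches[[nm]] <- fb$cache
    cat_caches[[j]] <- dim(up)[1]
    dcur <- fb$y
  }
  logits <- cpp_conv3d_fwd(dcur, p$out$w, p$out$b, 1L)
  prob <- 1 / (1 + exp(-logits))
  list(prob = prob, logits = logits, buffers = b,
       cache = if (training) list(blocks = caches, pool_idx = pool_idx,
                                  up_dims = up_dims, up_ch = cat_caches,
                                  dlast = dcur, e_dims = lapply(e, dim))
              else NULL)
}

# Backward pass from d(loss)/d(logits).  Returns gradients with the same
# nesting as model$params.
znet_backward <- function(model, fwd, dlogits) {
  cfg <- model$config
  S <- cfg$depth
  p <- model$params
  cc <- fwd$cache
  grads <- list()

  co <- cpp_conv3d_bwd(cc$dlast, p$out$w, dlogits, 1L)
  grads$out <- list(w = co$gw, b = co$gb)
  gd <- co$gx                       # grad wrt d_0 (level-0 decoder output)
  gskip <- vector("list", S + 1L)   # grads accumulating at e[[j]]
  for (j in seq_len(S)) {
    nm <- paste0("dec", j)
    bb <- block_backward(gd, p[[nm]], cc$blocks[[nm]])
    grads[[nm]] <- bb$grads
    ch_up <- cc$up_ch[[j]]
    dcat <- bb$gx
    gup <- dcat[seq_len(ch_up), , , , drop = FALSE]
    dim(gup) <- c(ch_up, dim(dcat)[2:4])
    gsk <- dcat[ch_up + seq_len(dim(dcat)[1] - ch_up), , , , drop = FALSE]
    dim(gsk) <- c(dim(dcat)[1] - ch_up, dim(dcat)[2:4])
    gskip[[j]] <- gsk
    gd <- cpp_trilinear_bwd(gup, cc$up_dims[[j]])
  }
  gskip[[S + 1]] <- gd              # grad wrt bottleneck e[[S+1]]
  ge <- gskip[[S + 1]]
  for (i in S:1) {
    nm <- paste0("enc", i)
    bb <- block_backward(ge, p[[nm]], cc$blocks[[nm]])
    grads[[nm]] <- bb$grads
    gpool <- cpp_maxpool2_bwd(bb$gx, cc$pool_idx[[i]], cc$e_dims[[i]])
    ge <- gskip[[i]] + gpool
  }
  bb <- block_backward(ge, p$inb, cc$blocks$inb)
  grads$inb <- bb$grads
  grads
}

#' Summarize a network
#'
#' Walks the architecture symbolically (no tensor computation) and
#' reports every block's output shape at a given input grid, together
#' with the total trainable parameter count.
#'
#' @param model A [znet_model].
#' @param input_size Spatial grid; defaults to the config's.
#' @return An object of class `znet_summary` with `blocks` (data.frame)
#'   and `n_params`.
#' @export
summarize_znet <- function(model, input_size = NULL) {
  cfg <- model$config
  size <- as.integer(input_size %||% cfg$input_size)
  check_grid(size, cfg$depth)
  ch <- znet_channels(cfg)
  S <- cfg$depth
  rows <- list()
  add <- function(name, chn, sz) {
    rows[[length(rows) + 1]] <<- data.frame(
      block = name, channels = chn, d = sz[1], h = sz[2], w = sz[3])
  }
  add("input_block", ch[1], size)
  for (i in seq_len(S)) add(paste0("encoder", i), ch[i + 1], size %/% 2L^i)
  for (j in S:1) add(paste0("decoder", j), ch[j], size %/% 2L^(j - 1L))
  add("output_block", cfg$out_channels, size)
  blocks <- do.call(rbind, rows)
  structure(list(blocks = blocks, n_params = znet_num_params(model),
                 bottleneck = size %/% 2L^S),
            class = "znet_summary")
}

#' @export
print.znet_summary <- function(x, ...) {
  print(x$blocks, row.names = FALSE)
  cat("trainable parameters:", format(x$n_params, big.mark = ","), "\n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Stores config, weights, batch-norm buffers and (optionally) training
#' history in one file.
#'
#' @param model A [znet_model].
#' @param path Checkpoint file path.
#' @param history Optional training history to embed.
#' @export
save_checkpoint <- function(model, path, history = NULL) {
  saveRDS(list(config = unclass(model$config), params = model$params,
               buffers = model$buffers, history = history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(znet_config, ck$config[c("in_channels", "out_channels",
                                          "depth", "base_width",
                                          "width_multiplier", "input_size")])
  model <- structure(list(config = cfg, params = ck$params,
                          buffers = ck$buffers),
                     class = "znet_model")
  list(model = model, history = ck$history)
}
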