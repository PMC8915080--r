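#' TCN architecture description
#'
#' Describes a temporal convolutional network for sequence classification:
#' `layers` residual blocks, each containing one causal dilated convolution
#' of kernel length `2 * kernel_half_width + 1`, with the dilation doubling
#' after every convolutional layer (`d_l = 2^(l-1)` by default, continuing
#' across block boundaries), followed by an average-over-time (`"aot"`) or
#' attention (`"att"`) pooling head and a softmax classifier over
#' `n_labels` gestures.
#'
#' @param layers Number of convolutional layers `L` (one per residual
#'   block).
#' @param filters Filter counts per layer, recycled to length `L`.
#' @param n_labels Number of gesture classes `G`.
#' @param channels Number of input channels `C`.
#' @param kernel_half_width Half-width `p`; the kernel has `2p + 1` taps.
#' @param dilations Dilation schedule; default `2^(l-1)`.
#' @param head `"aot"` or `"att"`.
#' @param dropout_rate Dropout probability applied after each convolution
#'   during training, in `[0, 1)`.
#' @param activation `"relu"` (default) or `"linear"`; the linear mode turns
#'   the branch into a pure linear filter, which is useful for analysing
#'   receptive-field extent.
#' @return An object of class `tcn_config`.
#' @examples
#' cfg <- tcn_config(layers = 4, filters = 16, n_labels = 5, channels = 2)
#' receptive_field(cfg, rate = 100)
#' @export
tcn_config <- function(layers, filters, n_labels, channels,
                       kernel_half_width = 1L, dilations = NULL,
                       head = c("aot", "att"), dropout_rate = 0.05,
                       activation = c("relu", "linear")) {
  head <- match.arg(head)
  activation <- match.arg(activation)
  if (!is_count(layers)) stopf("'layers' must be a positive integer")
  L <- as.integer(layers)
  filters <- as.integer(rep_len(filters, L))
  if (any(filters < 1L)) stopf("all filter counts must be >= 1")
  if (!is_count(kernel_half_width, min = 0L))
    stopf("'kernel_half_width' must be a non-negative integer")
  dilations <- as.integer(dilations %||% 2L^(seq_len(L) - 1L))
  if (length(dilations) != L || any(dilations < 1L))
    stopf("'dilations' must hold one dilation >= 1 per layer")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stopf("'dropout_rate' must lie in [0, 1)")
  structure(list(layers = L, filters = filters,
                 n_labels = as.integer(n_labels),
                 channels = as.integer(channels),
                 kernel_half_width = as.integer(kernel_half_width),
                 dilations = dilations, head = head,
                 dropout_rate = dropout_rate, activation = activation),
            class = "tcn_config")
}

#' Standard DB1 model configurations
#'
#' The two receptive-field variants evaluated on Ninapro DB1: `"short"`
#' (4 layers, 300 ms at 100 Hz) and `"long"` (7 layers, nominally 2500 ms).
#' Filter counts are chosen so total trainable parameter counts land in the
#' tens of thousands, in line with the published model sizes.
#'
#' @param rf `"short"` (L = 4) or `"long"` (L = 7).
#' @param head `"aot"` or `"att"`.
#' @param n_labels,channels Dataset dimensions; DB1 defaults.
#' @return A [tcn_config()].
#' @export
db1_tcn_config <- function(rf = c("short", "long"), head = c("aot", "att"),
                           n_labels = 53L, channels = 10L) {
  rf <- match.arg(rf)
  head <- match.arg(head)
  if (rf == "short") {
    tcn_config(layers = 4L, filters = 80L, n_labels = n_labels,
               channels = channels, head = head)
  } else {
    tcn_config(layers = 7L, filters = 60L, n_labels = n_labels,
               channels = channels, head = head)
  }
}

#' Receptive field of a TCN configuration
#'
#' The receptive field grows by `2 p d_l` samples per convolutional layer:
#' `RF_l = RF_{l-1} + 2 p d_l` with `RF_0 = 0` and `d_1 = 1`. With
#' kernel half-width `p = 1` and doubling dilation, 4 layers at 100 Hz give
#' 30 samples = 300 ms.
#'
#' @param config A [tcn_config()], or an integer layer count (then `p` and
#'   doubling dilations come from the remaining arguments).
#' @param rate Optional sampling rate in Hz used to convert to
#'   milliseconds.
#' @param kernel_half_width,dilations Used only when `config` is a bare
#'   layer count.
#' @return List with `samples` (RF extent in samples) and `ms`
#'   (`NA` when no rate is given).
#' @export
receptive_field <- function(config, rate = NULL, kernel_half_width = 1L,
                            dilations = NULL) {
  if (inherits(config, "tcn_config")) {
    L <- config$layers
    p <- config$kernel_half_width
    d <- config$dilations
  } else {
    L <- as.integer(config)
    if (L < 0L) stopf("layer count must be >= 0")
    p <- as.integer(kernel_half_width)
    d <- as.integer(dilations %||% if (L > 0L) 2L^(seq_len(L) - 1L) else integer())
  }
  samples <- sum(2 * p * d[seq_len(L)])
  list(samples = samples,
       ms = if (is.null(rate)) NA_real_ else samples / rate * 1000)
}

block_shapes <- function(config) {
  L <- config$layers
  ntaps <- 2L * config$kernel_half_width + 1L
  kin <- c(config$channels, config$filters[-L])
  lapply(seq_len(L), function(l) {
    list(kernel = c(ntaps, kin[l], config$filters[l]),
         bias = config$filters[l],
         shortcut = if (kin[l] != config$filters[l])
           c(kin[l], config$filters[l]) else NULL)
  })
}

#' Initialize TCN parameters
#'
#' He-style initialization for convolution kernels (and the 1x1 shortcut
#' projections used when a block changes width), zero biases, and small
#' Gaussian head weights.
#'
#' @param config A [tcn_config()].
#' @param seed Optional integer seed.
#' @return An object of class `tcn_model` holding `config`, `blocks`
#'   (per-layer `kernel`, `bias`, optional `shortcut`) and `head`
#'   parameters (`W_o`, `b_o`, plus `W_a`, `b_a`, `u_a` for the attention
#'   head).
#' @export
tcn_init <- function(config, seed = NULL) {
  shapes <- block_shapes(config)
  K <- config$filters[config$layers]
  G <- config$n_labels
  model <- with_opt_seed(seed, {
    blocks <- lapply(shapes, function(sh) {
      fan_in <- sh$kernel[1L] * sh$kernel[2L]
      blk <- list(
        kernel = array(rnorm(prod(sh$kernel), sd = sqrt(2 / fan_in)), sh$kernel),
        bias = numeric(sh$bias))
      if (!is.null(sh$shortcut))
        blk$shortcut <- matrix(rnorm(prod(sh$shortcut), sd = sqrt(1 / sh$shortcut[1L])),
                               sh$shortcut[1L], sh$shortcut[2L])
      blk
    })
    head <- list(W_o = matrix(rnorm(K * G, sd = sqrt(1 / K)), K, G),
                 b_o = numeric(G))
    if (config$head == "att") {
      head$W_a <- matrix(rnorm(K * K, sd = sqrt(1 / K)), K, K)
      head$b_a <- numeric(K)
      head$u_a <- matrix(rnorm(K, sd = sqrt(1 / K)), K, 1L)
    }
    list(blocks = blocks, head = head)
  })
  structure(list(config = config, blocks = model$blocks, head = model$head),
            class = "tcn_model")
}

#' Number of trainable parameters
#' @param model A `tcn_model`.
#' @return Integer parameter count.
#' @export
tcn_n_params <- function(model) length(params_to_vector(model))

#' @export
print.tcn_model <- function(x, ...) {
  rf <- receptive_field(x$config)
  cat(sprintf("<tcn_model> L = %d conv layers, filters [%s], %s head, G = %d, C = %d\n",
              x$config$layers, paste(x$config$filters, collapse = ", "),
              toupper(x$config$head), x$config$n_labels, x$config$channels))
  cat(sprintf("  kernel length %d, dilations [%s], RF = %d samples, %d parameters\n",
              2L * x$config$kernel_half_width + 1L,
              paste(x$config$dilations, collapse = ", "),
              rf$samples, tcn_n_params(x)))
  invisible(x)
}

# --- flat parameter vector <-> nested structure (for Adam and checkpoints) ---

model_param_list <- function(model) {
  out <- list()
  for (l in seq_along(model$blocks)) {
    blk <- model$blocks[[l]]
    for (nm in names(blk)) out[[sprintf("block%d.%s", l, nm)]] <- blk[[nm]]
  }
  for (nm in names(model$head)) out[[sprintf("head.%s", nm)]] <- model$head[[nm]]
  out
}

params_to_vector <- function(model) {
  unlist(model_param_list(model), use.names = FALSE)
}

vector_to_params <- function(model, v) {
  pos <- 0L
  for (l in seq_along(model$blocks)) {
    for (nm in names(model$blocks[[l]])) {
      n <- length(model$blocks[[l]][[nm]])
      val <- v[(pos + 1L):(pos + n)]
      dim(val) <- dim(model$blocks[[l]][[nm]])
      model$blocks[[l]][[nm]] <- val
      pos <- pos + n
    }
  }
  for (nm in names(model$head)) {
    n <- length(model$head[[nm]])
    val <- v[(pos + 1L):(pos + n)]
    dim(val) <- dim(model$head[[nm]])
    model$head[[nm]] <- val
    pos <- pos + n
  }
  stopifnot(pos == length(v))
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON file holding the configuration and every
#' named parameter array with its dimensions. Loading rebuilds the model
#' and validates all parameter shapes against the configuration.
#'
#' @param model A `tcn_model`.
#' @param path File path.
#' @return `save_tcn()` the path invisibly; `load_tcn()` a `tcn_model`.
#' @export
save_tcn <- function(model, path) {
  pl <- model_param_list(model)
  jsonlite::write_json(
    list(config = unclass(model$config),
         params = lapply(pl, function(p)
           list(dim = dim(p) %||% length(p), values = as.numeric(p)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_tcn
#' @export
load_tcn <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfgl <- js$config
  config <- tcn_config(layers = cfgl$layers, filters = cfgl$filters,
                       n_labels = cfgl$n_labels, channels = cfgl$channels,
                       kernel_half_width = cfgl$kernel_half_width,
                       dilations = cfgl$dilations, head = cfgl$head,
                       dropout_rate = cfgl$dropout_rate,
                       activation = cfgl$activation)
  model <- tcn_init(config, seed = 0L)
  ref <- model_param_list(model)
  if (!identical(sort(names(ref)), sort(names(js$params))))
    stopf("checkpoint parameter names do not match the configuration")
  for (nm in names(ref)) {
    p <- js$params[[nm]]
    want <- dim(ref[[nm]]) %||% length(ref[[nm]])
    if (!identical(as.integer(p$dim), as.integer(want)))
      stopf("checkpoint shape mismatch for '%s'", nm)
    val <- as.numeric(p$values)
    dim(val) <- dim(ref[[nm]])
    ref[[nm]] <- val
  }
  v <- unlist(ref[names(model_param_list(model))], use.names = FALSE)
  vector_to_params(model, v)
}
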