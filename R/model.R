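# Public model surface: configuration, construction, forward pass,
# parameter count and receptive field.

#' Model configuration
#'
#' The default configuration reproduces the reference detector: a dual
#' input channel stem convolution (kernel 19, dense), six residual blocks
#' (channels 32/64/128, two per scale, each a depthwise kernel-19
#' convolution + instance norm + ReLU with an identity skip), kernel-1
#' stride-2 downsampling convolutions between scales, a feature pyramid
#' decoder (kernel-1 lateral convolutions to a common width, nearest
#' -neighbour top-down upsampling with addition, and a depthwise kernel-19
#' smoothing convolution per scale), and a single location head shared
#' across scales (dense kernel-5 convolution to one channel, sigmoid,
#' width-9 moving-average pool). Backbone convolutions carry no bias
#' (instance norm follows them) and instance norm carries no affine
#' parameters; with the defaults the trainable parameter count is exactly
#' 26,976.
#'
#' @param kernel_size odd kernel size of the wide convolutions (default
#'   19; 9 and 29 give the small/large-kernel ablation variants).
#' @param channels strictly increasing integer triple of residual-block
#'   widths (default `c(32, 64, 128)`).
#' @param fpn_channels common width of the pyramid decoder (default 24).
#' @param head_kernel location-head kernel size (default 5).
#' @param pool_size moving-average pool width (default 9).
#' @param in_channels 1 or 2 input channels (default 2; 1 gives the
#'   single-channel ablation variant).
#' @param depthwise use depthwise convolutions in the wide layers
#'   (default `TRUE`).
#' @return a `qrs_model_config` list.
#' @export
qrs_model_config <- function(kernel_size = 19L, channels = c(32L, 64L, 128L),
                             fpn_channels = 24L, head_kernel = 5L,
                             pool_size = 9L, in_channels = 2L,
                             depthwise = TRUE) {
  abort_if(kernel_size %% 2L == 0L, "kernel_size must be odd")
  abort_if(length(channels) != 3L || any(diff(channels) <= 0),
           "channels must be a strictly increasing triple")
  abort_if(!in_channels %in% c(1L, 2L), "in_channels must be 1 or 2")
  abort_if(head_kernel %% 2L == 0L || pool_size %% 2L == 0L,
           "head_kernel and pool_size must be odd")
  structure(list(kernel_size = as.integer(kernel_size),
                 channels = as.integer(channels),
                 fpn_channels = as.integer(fpn_channels),
                 head_kernel = as.integer(head_kernel),
                 pool_size = as.integer(pool_size),
                 in_channels = as.integer(in_channels),
                 depthwise = isTRUE(depthwise)),
            class = "qrs_model_config")
}

#' Named model presets
#'
#' `"default"` is the full-size reference model (26,976 parameters).
#' `"desk"` is a reduced-width preset (channels 8/16/32, pyramid width 8)
#' for fast CPU-only training runs on synthetic data; the architecture is
#' otherwise identical.
#'
#' @param name `"default"` or `"desk"`.
#' @return a [qrs_model_config()].
#' @export
model_preset <- function(name = c("default", "desk")) {
  name <- match.arg(name)
  switch(name,
    default = qrs_model_config(),
    desk = qrs_model_config(channels = c(8L, 16L, 32L), fpn_channels = 8L)
  )
}

#' Build a detector model
#'
#' Constructs the network described by `cfg` with uniform
#' `+-sqrt(1/fan_in)` weight initialization.
#'
#' @param cfg a [qrs_model_config()].
#' @param seed integer seed for the weight initialization, or `NULL`.
#' @return a `qrs_model` object.
#' @export
build_model <- function(cfg = qrs_model_config(), seed = NULL) {
  abort_if(!inherits(cfg, "qrs_model_config"), "cfg must be a qrs_model_config")
  params <- with_seed(seed, nn_init_params(cfg))
  structure(list(cfg = cfg, params = params), class = "qrs_model")
}

#' Number of trainable parameters
#' @param model a `qrs_model`.
#' @return integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Run the model forward
#'
#' Fully convolutional: any input length `>= 32` works. Odd lengths are
#' zero-padded on the right to a multiple of 4 internally and the outputs
#' cropped back, so the three heat maps have lengths `l`, `ceiling(l/2)`,
#' `ceiling(l/4)`.
#'
#' @param model a `qrs_model`.
#' @param signal numeric matrix `l x in_channels` (canonical, z-scored).
#' @return a `qrs_heatmaps` object: `maps` (three probability vectors in
#'   `[0, 1]`) and `fs_per_map` (250, 125, 62.5 Hz for canonical input).
#' @export
forward <- function(model, signal) {
  x <- as_signal_matrix(signal)
  out <- nn_forward(model$params, model$cfg, x, training = FALSE)
  new_heatmaps(out$maps, fs = 250)
}

new_heatmaps <- function(maps, fs = 250) {
  structure(list(maps = maps, fs_per_map = fs / c(1, 2, 4)),
            class = "qrs_heatmaps")
}

#' @export
print.qrs_heatmaps <- function(x, ...) {
  cat("<qrs_heatmaps>\n")
  for (i in 1:3) {
    cat(sprintf("  map %d: %d samples @ %g Hz, range [%.3f, %.3f]\n", i,
                length(x$maps[[i]]), x$fs_per_map[[i]],
                min(x$maps[[i]]), max(x$maps[[i]])))
  }
  invisible(x)
}

#' @export
print.qrs_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(paste0("<qrs_model> k=%d channels=%s fpn=%d in=%d %s\n",
                     "  %d trainable parameters, receptive field %.3f s\n"),
              cfg$kernel_size, paste(cfg$channels, collapse = "/"),
              cfg$fpn_channels, cfg$in_channels,
              if (cfg$depthwise) "depthwise" else "dense",
              count_parameters(x), receptive_field_s(cfg)))
  invisible(x)
}

#' Analytic receptive field of the deepest heat map
#'
#' Sums `(k - 1) * jump` along the longest path (stem and two blocks at
#' full resolution, two blocks each at half and quarter resolution, the
#' quarter-scale smoothing convolution, head convolution and pool) and
#' converts to seconds at the canonical 250 Hz rate.
#'
#' @param cfg a [qrs_model_config()].
#' @return receptive field in seconds.
#' @export
receptive_field_s <- function(cfg = qrs_model_config()) {
  k <- cfg$kernel_size
  rf <- 1 +
    (k - 1) * 1 +              # stem
    2 * (k - 1) * 1 +          # blocks at full resolution
    2 * (k - 1) * 2 +          # blocks at half resolution
    2 * (k - 1) * 4 +          # blocks at quarter resolution
    (k - 1) * 4 +              # smoothing conv at quarter resolution
    (cfg$head_kernel - 1) * 4 +
    (cfg$pool_size - 1) * 4
  rf / 250
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding the configuration and the
#' weights; `save_checkpoint` also writes the configuration as YAML next
#' to it for human inspection.
#'
#' @param model a `qrs_model`.
#' @param path checkpoint path (e.g. `model.ckpt`).
#' @return `path` (save) or the restored `qrs_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(cfg = unclass(model$cfg), params = model$params), path)
  yaml::write_yaml(unclass(model$cfg), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(qrs_model_config, obj$cfg)
  structure(list(cfg = cfg, params = obj$params), class = "qrs_model")
}
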