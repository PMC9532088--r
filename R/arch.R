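#' Architecture configuration for a dense convolutional classifier
#'
#' Describes a DenseNet-style network: a convolutional stem, dense blocks in
#' which every layer receives the concatenation of the block input and all
#' previous layers' outputs and emits `growth_rate` channels, transition
#' layers applying 1x1 channel compression followed by 2x spatial
#' downsampling, and a global-average-pool + softmax head. With
#' `fusion_enabled`, pooled Log-Gabor magnitude maps of the input image are
#' concatenated onto the feature maps at each transition output (the hybrid
#' handcrafted/learned mechanism), after per-channel standardization frozen
#' on the training split.
#'
#' @param block_sizes Integer vector, layers per dense block.
#' @param growth_rate Channels added by each dense layer (>= 1).
#' @param compression Transition channel-compression ratio in (0, 1].
#' @param stem_channels Channels produced by the stem convolution.
#' @param input_size Input image side in pixels.
#' @param num_classes Number of output classes (>= 2).
#' @param in_channels Input image channels (default 1, luminance).
#' @param stem_downsample Spatial downsampling factor applied by the stem
#'   (power of 2; default 1 for small inputs, 4 for the 224-pixel-scale
#'   shape).
#' @param fusion_enabled Concatenate Log-Gabor maps at transitions.
#' @param gabor [log_gabor_params()] used for the fused maps.
#' @param gabor_pooling `"mean_over_scales"` (one map per orientation,
#'   default) or `"none"` (all scale-orientation maps).
#' @param fusion_site `"transition"` injects after each transition output
#'   (before each subsequent dense block); `"block_input"` additionally
#'   injects before the first block.
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(block_sizes = c(2, 2, 2, 2), growth_rate = 8,
                        compression = 0.5, stem_channels = 16,
                        input_size = 64, num_classes = 8, in_channels = 1,
                        stem_downsample = 1, fusion_enabled = FALSE,
                        gabor = log_gabor_params(),
                        gabor_pooling = c("mean_over_scales", "none"),
                        fusion_site = c("transition", "block_input")) {
  gabor_pooling <- rlang::arg_match(gabor_pooling)
  fusion_site <- rlang::arg_match(fusion_site)
  stopifnot(
    "block_sizes must be a non-empty vector of positive counts" =
      length(block_sizes) >= 1 && all(vapply(block_sizes, is_count, TRUE)),
    "growth_rate must be >= 1" = is_count(growth_rate),
    "compression must be in (0, 1]" = compression > 0 && compression <= 1,
    "stem_channels must be >= 1" = is_count(stem_channels),
    "num_classes must be >= 2" = is_count(num_classes) && num_classes >= 2,
    "stem_downsample must be a power of 2" =
      is_count(stem_downsample) &&
      2^round(log2(stem_downsample)) == stem_downsample,
    inherits(gabor, "log_gabor_params")
  )
  total_down <- stem_downsample * 2^(length(block_sizes) - 1)
  if (input_size %% total_down != 0) {
    stop("input_size must be divisible by the total downsampling factor (",
         total_down, ")", call. = FALSE)
  }
  structure(
    list(block_sizes = as.integer(block_sizes),
         growth_rate = as.integer(growth_rate),
         compression = compression,
         stem_channels = as.integer(stem_channels),
         input_size = as.integer(input_size),
         num_classes = as.integer(num_classes),
         in_channels = as.integer(in_channels),
         stem_downsample = as.integer(stem_downsample),
         fusion_enabled = isTRUE(fusion_enabled),
         gabor = gabor, gabor_pooling = gabor_pooling,
         fusion_site = fusion_site),
    class = "arch_config"
  )
}

#' Preset configurations
#'
#' `arch_lite()` is the desk-trainable default: 64-pixel input, blocks
#' (2, 2, 2, 2), growth 8, stem 16 with 2x stem downsampling (dense blocks
#' then run at 32 down to 4 pixels, which keeps CPU training fast without
#' hurting accuracy on oriented textures). `arch_densenet201()` is the
#' DenseNet201-shaped configuration (224-pixel input, blocks (6, 12, 48, 32),
#' growth 32, stem 64, stem downsampling 4) used for shape-level
#' verification; its global-average-pooled feature length is 1920.
#'
#' @param num_classes Number of classes.
#' @param fusion_enabled Enable Log-Gabor fusion at transitions.
#' @param ... Passed on to [arch_config()].
#' @return An `arch_config`.
#' @export
arch_lite <- function(num_classes = 8, fusion_enabled = TRUE,
                      block_sizes = c(2, 2, 2, 2), growth_rate = 8,
                      compression = 0.5, stem_channels = 16,
                      input_size = 64, stem_downsample = 2, ...) {
  arch_config(block_sizes = block_sizes, growth_rate = growth_rate,
              compression = compression, stem_channels = stem_channels,
              input_size = input_size, stem_downsample = stem_downsample,
              num_classes = num_classes, fusion_enabled = fusion_enabled, ...)
}

#' @rdname arch_lite
#' @export
arch_densenet201 <- function(num_classes = 1000, fusion_enabled = FALSE,
                             block_sizes = c(6, 12, 48, 32),
                             growth_rate = 32, compression = 0.5,
                             stem_channels = 64, input_size = 224,
                             stem_downsample = 4, ...) {
  arch_config(block_sizes = block_sizes, growth_rate = growth_rate,
              compression = compression, stem_channels = stem_channels,
              input_size = input_size, stem_downsample = stem_downsample,
              num_classes = num_classes, fusion_enabled = fusion_enabled, ...)
}

#' Number of Log-Gabor channels injected at each fusion site
#' @param config An [arch_config()].
#' @return Integer count (0 when fusion is disabled).
#' @export
fusion_channels <- function(config) {
  if (!config$fusion_enabled) return(0L)
  switch(config$gabor_pooling,
    mean_over_scales = config$gabor$n_orientations,
    none = config$gabor$n_scales * config$gabor$n_orientations
  )
}

#' Channel and spatial-size trace of a configuration
#'
#' Pure arithmetic walk through the network: no weights are instantiated.
#' The instantiated network's tensor shapes match this trace exactly at
#' every stage.
#'
#' @param config An [arch_config()].
#' @return A tibble with columns `stage`, `type`, `in_channels`,
#'   `out_channels`, `spatial` (the stage's output spatial side).
#' @examples
#' tail(channel_trace(arch_densenet201()), 2) # 1920 pooled features
#' @export
channel_trace <- function(config) {
  stopifnot(inherits(config, "arch_config"))
  k_fuse <- fusion_channels(config)
  rows <- list()
  spatial <- config$input_size %/% config$stem_downsample
  ch <- config$stem_channels
  rows[[1]] <- list(stage = "stem", type = "stem",
                    in_channels = config$in_channels, out_channels = ch,
                    spatial = spatial)
  if (k_fuse > 0 && config$fusion_site == "block_input") {
    rows[[length(rows) + 1]] <- list(stage = "fuse0", type = "fusion",
                                     in_channels = ch,
                                     out_channels = ch + k_fuse,
                                     spatial = spatial)
    ch <- ch + k_fuse
  }
  nb <- length(config$block_sizes)
  for (b in seq_len(nb)) {
    out <- ch + config$block_sizes[b] * config$growth_rate
    rows[[length(rows) + 1]] <- list(stage = paste0("block", b),
                                     type = "dense_block", in_channels = ch,
                                     out_channels = out, spatial = spatial)
    ch <- out
    if (b < nb) {
      out <- floor(ch * config$compression)
      spatial <- spatial %/% 2L
      rows[[length(rows) + 1]] <- list(stage = paste0("transition", b),
                                       type = "transition", in_channels = ch,
                                       out_channels = out, spatial = spatial)
      ch <- out
      if (k_fuse > 0) {
        rows[[length(rows) + 1]] <- list(stage = paste0("fuse", b),
                                         type = "fusion", in_channels = ch,
                                         out_channels = ch + k_fuse,
                                         spatial = spatial)
        ch <- ch + k_fuse
      }
    }
  }
  rows[[length(rows) + 1]] <- list(stage = "global_pool", type = "gap",
                                   in_channels = ch, out_channels = ch,
                                   spatial = 1L)
  rows[[length(rows) + 1]] <- list(stage = "head", type = "softmax",
                                   in_channels = ch,
                                   out_channels = config$num_classes,
                                   spatial = 1L)
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

#' Build a network specification from a configuration
#'
#' Expands the configuration into the ordered stage list actually executed
#' by the forward pass (stem, per-layer dense-block entries, transitions
#' with fusion markers, head), each carrying its input/output channel counts
#' and spatial size, consistent with [channel_trace()]. With
#' `fusion_enabled = FALSE` this is the plain backbone;
#' `fuse_gabor_at_transitions()` re-derives the spec with fusion switched
#' on.
#'
#' @param config An [arch_config()].
#' @return An object of class `network_spec`.
#' @export
build_backbone <- function(config) {
  stopifnot(inherits(config, "arch_config"))
  trace <- channel_trace(config)
  final_ch <- trace$in_channels[trace$type == "gap"]
  structure(
    list(config = config, trace = trace, final_channels = final_ch,
         fusion_sites = sum(trace$type == "fusion")),
    class = "network_spec"
  )
}

#' @rdname build_backbone
#' @param spec A `network_spec` built without fusion.
#' @export
fuse_gabor_at_transitions <- function(spec, config = spec$config) {
  stopifnot(inherits(spec, "network_spec"))
  if (!config$fusion_enabled) return(spec)
  build_backbone(config)
}

#' @export
print.network_spec <- function(x, ...) {
  cat("Dense network spec: ", length(x$config$block_sizes), " blocks (",
      paste(x$config$block_sizes, collapse = ", "), "), growth ",
      x$config$growth_rate,
      if (x$config$fusion_enabled) ", Log-Gabor fusion" else "",
      "\n", sep = "")
  print(x$trace, n = Inf)
  invisible(x)
}
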