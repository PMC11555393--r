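#' MIFNet family configuration
#'
#' A `mifnet_config` parameterises one member of the MIFNet family: a
#' three-stage network of multi-scale interleaved-fusion (MIF) blocks
#' operating on single-channel 50x50 CT patches.  Each stage consists of a
#' 1x1 scaling convolution followed by a MIF block of three parallel
#' branches; each branch is a chain of `k` bottleneck mini-blocks whose
#' outputs are interleaved and concatenated ("channel fusion") across
#' branches after every mini-block, so that the per-branch channel count
#' grows geometrically with depth (by a factor of `fusion_channels` per
#' mini-block).
#'
#' @param stage_widths integer 3-vector; channel width set by each stage's
#'   scaling layer.  Default `c(16, 32, 64)`: the width doubles each time
#'   the feature map is down-sampled.
#' @param bottleneck_widths integer 3-vector; width of the 3x3 grouped
#'   convolution inside each stage's mini-blocks.  Default `c(4, 8, 16)`;
#'   the wide variant uses `c(8, 16, 32)`.
#' @param mini_blocks_per_stage positive integer `k`, the number of
#'   mini-blocks per branch in every stage.  Nominal depth is `3 + 6k + 1`
#'   (`k = 6` gives the depth-40 flagship).
#' @param groups integer 3-vector; group count of each stage's 3x3 grouped
#'   convolution.  Must divide that stage's bottleneck and stage widths.
#' @param fusion_channels integer `C >= 1`; how many branch outputs are
#'   concatenated to form each branch's next input (cyclic interleaving).
#'   `C = 1` disables cross-branch mixing; must not exceed the number of
#'   branches.
#' @param dropout_rates numeric 3-vector; dropout after each pooling layer.
#' @param input_size input patch side length in pixels (default 50).
#' @param input_channels number of input channels (default 1, grayscale CT).
#' @param num_classes number of output classes (default 2,
#'   benign/malignant).
#'
#' @return An object of class `mifnet_config`.
#' @examples
#' cfg <- mifnet_config(mini_blocks_per_stage = 1)
#' nominal_depth(cfg)  # 10
#' @seealso [mifnet_preset()], [assemble_mifnet()]
#' @export
mifnet_config <- function(stage_widths = c(16L, 32L, 64L),
                          bottleneck_widths = c(4L, 8L, 16L),
                          mini_blocks_per_stage = 6L,
                          groups = c(4L, 4L, 4L),
                          fusion_channels = 2L,
                          dropout_rates = c(0.1, 0.2, 0.3),
                          input_size = 50L,
                          input_channels = 1L,
                          num_classes = 2L) {
  cfg <- list(
    stage_widths = as.integer(stage_widths),
    bottleneck_widths = as.integer(bottleneck_widths),
    mini_blocks_per_stage = as.integer(mini_blocks_per_stage),
    groups = as.integer(groups),
    fusion_channels = as.integer(fusion_channels),
    branches = 3L,
    dropout_rates = as.numeric(dropout_rates),
    input_size = as.integer(input_size),
    input_channels = as.integer(input_channels),
    num_classes = as.integer(num_classes)
  )
  class(cfg) <- "mifnet_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$stage_widths) == 3L, length(cfg$bottleneck_widths) == 3L,
            length(cfg$groups) == 3L, length(cfg$dropout_rates) == 3L)
  if (cfg$mini_blocks_per_stage < 1L)
    stop("configuration error: mini_blocks_per_stage must be >= 1", call. = FALSE)
  if (cfg$fusion_channels < 1L || cfg$fusion_channels > cfg$branches)
    stop("configuration error: fusion_channels must be between 1 and the number of branches (",
         cfg$branches, ")", call. = FALSE)
  for (s in 1:3) {
    g <- cfg$groups[s]
    if (g < 1L)
      stop("configuration error: group count must be >= 1 in stage ", s, call. = FALSE)
    if (cfg$stage_widths[s] %% g != 0L)
      stop("configuration error: stage ", s, " width ", cfg$stage_widths[s],
           " is not divisible by its group count ", g, call. = FALSE)
    if (cfg$bottleneck_widths[s] %% g != 0L)
      stop("configuration error: stage ", s, " bottleneck width ",
           cfg$bottleneck_widths[s], " is not divisible by its group count ", g,
           call. = FALSE)
  }
  # every 2x2 pooling must see a map at least as large as its window
  sz <- cfg$input_size
  for (s in 1:3) {
    if (sz < 2L)
      stop("configuration error: input_size ", cfg$input_size,
           " too small to survive three pooling layers", call. = FALSE)
    sz <- ceiling((sz - 2) / 2) + 1
  }
  invisible(cfg)
}

#' Nominal depth of a MIFNet configuration
#'
#' The family's depth label counts the three scaling layers, one
#' classification layer, and six layers per mini-block stack
#' (`3 + 6k + 1`): `k` of 1, 3, 4, 5, 6, 7 give the published depths
#' 10, 22, 28, 34, 40 and 46.  Pooling layers do not count.
#'
#' @param config a [mifnet_config()].
#' @return integer depth label.
#' @export
nominal_depth <- function(config) {
  stopifnot(inherits(config, "mifnet_config"))
  3L + 6L * config$mini_blocks_per_stage + 1L
}

.preset_k <- c(mifnet10 = 1L, mifnet22 = 3L, mifnet28 = 4L,
               mifnet34 = 5L, mifnet40 = 6L, mifnet46 = 7L,
               mifnet46_wide = 7L)

#' Named MIFNet presets
#'
#' Shipped presets cover the published family: `mifnet10`, `mifnet22`,
#' `mifnet28`, `mifnet34`, `mifnet40` (the 0.7 M-parameter flagship),
#' `mifnet46`, and `mifnet46_wide` (bottleneck widths doubled to
#' (8, 16, 32)).
#'
#' @param name preset name, see Details.
#' @param ... overrides passed on to [mifnet_config()].
#' @return A [mifnet_config()].
#' @examples
#' nominal_depth(mifnet_preset("mifnet40"))  # 40
#' @export
mifnet_preset <- function(name, ...) {
  if (!name %in% names(.preset_k))
    stop("unknown preset '", name, "'; available: ",
         paste(names(.preset_k), collapse = ", "), call. = FALSE)
  args <- list(mini_blocks_per_stage = .preset_k[[name]])
  if (identical(name, "mifnet46_wide"))
    args$bottleneck_widths <- c(8L, 16L, 32L)
  args <- utils::modifyList(args, list(...))
  do.call(mifnet_config, args)
}

#' List available preset names
#' @return character vector of preset names.
#' @export
mifnet_presets <- function() names(.preset_k)

#' @export
print.mifnet_config <- function(x, ...) {
  cat("MIFNet configuration (nominal depth ", nominal_depth(x), ")\n", sep = "")
  cat("  stage widths:      ", paste(x$stage_widths, collapse = ", "), "\n")
  cat("  bottleneck widths: ", paste(x$bottleneck_widths, collapse = ", "), "\n")
  cat("  mini-blocks/stage: ", x$mini_blocks_per_stage, "\n")
  cat("  groups:            ", paste(x$groups, collapse = ", "), "\n")
  cat("  fusion channels:   ", x$fusion_channels, "\n")
  cat("  dropout:           ", paste(x$dropout_rates, collapse = ", "), "\n")
  cat("  input: ", x$input_size, "x", x$input_size, "x", x$input_channels,
      " -> ", x$num_classes, " classes\n", sep = "")
  invisible(x)
}

#' Read / write a flat key=value architecture configuration file
#'
#' The on-disk format is one `key = value` pair per line; vectors are
#' comma-separated.  Unknown keys are rejected.
#'
#' @param path file path.
#' @return [read_config()] returns a [mifnet_config()];
#'   [write_config()] returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  allowed <- names(formals(mifnet_config))
  if (any(!keys %in% allowed))
    stop("unknown config key: ", keys[!keys %in% allowed][1], call. = FALSE)
  args <- lapply(vals, function(v) as.numeric(strsplit(v, ",")[[1]]))
  names(args) <- keys
  do.call(mifnet_config, args)
}

#' @rdname read_config
#' @param config a [mifnet_config()] to serialise.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "mifnet_config"))
  keep <- setdiff(names(config), "branches")
  lines <- vapply(keep, function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}
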