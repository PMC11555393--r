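#' @title Analytic complexity accounting
#' @description
#' Output-size, jump and receptive-field propagation for convolutional
#' layer chains, plus trainable-parameter and FLOP counts over a
#' [assemble_mifnet()] layer graph.  FLOPs are counted as
#' multiply-accumulates of the convolution and dense layers for one
#' forward pass; batch normalisation, activations and pooling are counted
#' as zero (the convention is recorded in the report).
#' @name complexity
NULL

#' Spatial output size of a convolution or pooling window
#'
#' `v_out = rounding((v_in + 2p - k) / s) + 1`.  Convolutions use floor
#' rounding; the family's 2x2 stride-2 poolings use ceil rounding (which
#' is what takes a 25-pixel map to 13).
#'
#' @param v_in input side length (pixels).
#' @param kernel window side length.
#' @param padding padding per side (pixels).
#' @param stride step size.
#' @param rounding "floor" or "ceil", applied to the division.
#' @return integer output side length.
#' @examples
#' conv_output_size(50, 1, 0, 1)          # 50
#' conv_output_size(25, 2, 0, 2, "ceil")  # 13
#' @export
conv_output_size <- function(v_in, kernel, padding, stride,
                             rounding = c("floor", "ceil")) {
  rounding <- match.arg(rounding)
  stopifnot(v_in >= 1, kernel >= 1, stride >= 1, padding >= 0)
  q <- (v_in + 2 * padding - kernel) / stride
  v <- as.integer(if (rounding == "floor") floor(q) else ceiling(q)) + 1L
  if (v < 1L)
    stop("geometry error: output size ", v, " < 1 (input ", v_in,
         ", kernel ", kernel, ", stride ", stride, ")", call. = FALSE)
  v
}

#' Jump (accumulated stride) of the next layer
#'
#' The jump is the product of all step lengths so far:
#' `c_l = c_{l-1} * s`.
#' @param previous_jump jump entering the layer (>= 1).
#' @param stride the layer's stride.
#' @return the new jump.
#' @export
jump <- function(previous_jump, stride) {
  stopifnot(previous_jump >= 1, stride >= 1)
  previous_jump * stride
}

#' Receptive-field size of a layer chain
#'
#' Propagates `r_l = r_{l-1} + (k_l - 1) * prod(s_1..s_{l-1})` from
#' `r = 1`: each layer widens the field by its kernel extent scaled by
#' the accumulated stride of everything before it.  Two stacked 3x3
#' stride-1 convolutions give a receptive field of 5.
#'
#' @param layer_chain a list of `c(kernel, stride)` pairs (or a 2-column
#'   matrix, one row per layer).
#' @return integer receptive-field side length of the last layer.
#' @examples
#' receptive_field(list(c(3, 1), c(3, 1)))        # 5
#' receptive_field(list(c(3, 1), c(2, 2), c(3, 1)))  # 8
#' @export
receptive_field <- function(layer_chain) {
  rf_state(layer_chain)$r
}

#' Full (output size, jump, receptive field) propagation
#'
#' @param layer_chain as in [receptive_field()]; an element may carry a
#'   third entry of 1 to mark a ceil-mode window (unpadded, as in the
#'   family's poolings), otherwise same-padding floor geometry is used
#'   for the size propagation.
#' @param input_size optional input side length; when supplied, the
#'   output size `v` is propagated too, otherwise `v` is `NA`.
#' @return a list with `v`, `c` (jump) and `r`.
#' @export
rf_state <- function(layer_chain, input_size = NULL) {
  if (is.matrix(layer_chain))
    layer_chain <- lapply(seq_len(nrow(layer_chain)),
                          function(i) layer_chain[i, ])
  if (!length(layer_chain)) stop("empty layer chain", call. = FALSE)
  r <- 1; cjump <- 1; v <- input_size
  for (ks in layer_chain) {
    k <- ks[[1]]; s <- ks[[2]]
    ceil_pool <- length(ks) > 2 && ks[[3]] == 1
    r <- r + (k - 1) * cjump
    cjump <- jump(cjump, s)
    if (!is.null(v)) {
      v <- if (ceil_pool) conv_output_size(v, k, 0, s, "ceil")
           else conv_output_size(v, k, (k - 1) %/% 2, s, "floor")
    }
  }
  list(v = if (is.null(v)) NA_integer_ else v, c = cjump, r = as.integer(r))
}

# per-layer parameter count of one node
node_parameters <- function(node) {
  switch(node$kind,
    conv = node$kernel^2 * node$in_channels * node$out_channels /
      node$groups + if (isTRUE(node$bias)) node$out_channels else 0,
    batchnorm = if (isTRUE(node$affine)) 2 * node$channels else 0,
    dense = node$in_features * node$out_features + node$out_features,
    0)
}

#' Count trainable parameters of a layer graph
#'
#' Convolutions contribute `k^2 * in * out / groups` weights plus `out`
#' biases when biased; affine batch-norm layers contribute
#' `2 * channels` (scale and shift; the family's batch-norm layers are
#' non-affine and contribute zero); dense layers contribute
#' `in * out + out`; pooling, activations, dropout and joins are free.
#'
#' @param graph a `mifnet_graph`.
#' @return total trainable parameter count (numeric).
#' @examples
#' count_parameters(assemble_mifnet(mifnet_preset("mifnet40")))  # 715978
#' @export
count_parameters <- function(graph) {
  stopifnot(inherits(graph, "mifnet_graph"))
  sum(vapply(graph$nodes, node_parameters, 0))
}

#' Count forward-pass FLOPs of a layer graph
#'
#' Multiply-accumulate count at the stated input size:
#' `out_h * out_w * k^2 * in * out / groups` per convolution and
#' `in * out` per dense layer; batch normalisation, activations and
#' pooling are counted as zero.
#'
#' @param graph a `mifnet_graph`.
#' @param input_size input side length (defaults to the configuration's).
#' @return total multiply-accumulate count (numeric).
#' @export
count_flops <- function(graph, input_size = NULL) {
  stopifnot(inherits(graph, "mifnet_graph"))
  sh <- infer_shapes(graph, input_size)
  total <- 0
  for (node in graph$nodes) {
    total <- total + switch(node$kind,
      conv = sh$size[node$id]^2 * node$kernel^2 * node$in_channels *
        node$out_channels / node$groups,
      dense = node$in_features * node$out_features,
      0)
  }
  total
}

#' Serialized model size
#'
#' `bytes_per_parameter * parameter_count / 2^20` megabytes (default four
#' bytes per parameter, single precision).
#' @param parameter_count number of trainable parameters.
#' @param bytes_per_parameter storage width (default 4).
#' @return size in MB.
#' @examples
#' model_size_mb(262144)  # 1
#' @export
model_size_mb <- function(parameter_count, bytes_per_parameter = 4) {
  stopifnot(parameter_count >= 0)
  bytes_per_parameter * parameter_count / 2^20
}

#' Full complexity report for a network
#'
#' @param graph a `mifnet_graph` (or a [mifnet_config()], which is
#'   assembled first).
#' @param input_size input side length (defaults to the configuration's).
#' @return An object of class `mifnet_complexity`: a list with
#'   `parameter_count`, `flops`, `model_size_mb`, `model_size_bytes`,
#'   `depth` (nominal), `flop_convention`, a per-layer breakdown data
#'   frame `layers`, and `receptive_fields`, the receptive-field state at
#'   each stage boundary.
#' @examples
#' rep <- complexity_report(mifnet_preset("mifnet10"))
#' rep$parameter_count
#' @export
complexity_report <- function(graph, input_size = NULL) {
  if (inherits(graph, "mifnet_config")) graph <- assemble_mifnet(graph)
  stopifnot(inherits(graph, "mifnet_graph"))
  sh <- infer_shapes(graph, input_size)
  params <- vapply(graph$nodes, node_parameters, 0)
  flops <- vapply(graph$nodes, function(node) {
    switch(node$kind,
      conv = sh$size[node$id]^2 * node$kernel^2 * node$in_channels *
        node$out_channels / node$groups,
      dense = node$in_features * node$out_features,
      0)
  }, 0)
  layers <- data.frame(sh,
                       label = vapply(graph$nodes, function(n)
                         if (!is.null(n$label)) n$label else "", ""),
                       parameters = params, flops = flops)
  cfg <- graph$config
  report <- list(
    parameter_count = sum(params),
    flops = sum(flops),
    model_size_bytes = 4 * sum(params),
    model_size_mb = model_size_mb(sum(params)),
    depth = if (!is.null(cfg)) nominal_depth(cfg) else NA_integer_,
    flop_convention = "multiply-accumulates; conv and dense layers only",
    layers = layers,
    receptive_fields = if (!is.null(cfg)) stage_receptive_fields(cfg) else NULL
  )
  class(report) <- "mifnet_complexity"
  report
}

#' @export
print.mifnet_complexity <- function(x, ...) {
  cat(sprintf("MIFNet complexity report (nominal depth %s)\n",
              ifelse(is.na(x$depth), "?", x$depth)))
  cat(sprintf("  parameters: %s  (%.3f M)\n",
              format(x$parameter_count, big.mark = ","),
              x$parameter_count / 1e6))
  cat(sprintf("  model size: %.3f MB (4 bytes/parameter)\n", x$model_size_mb))
  cat(sprintf("  FLOPs:      %.3f x 10^8  (%s)\n", x$flops / 1e8,
              x$flop_convention))
  if (!is.null(x$receptive_fields)) {
    cat("  receptive field at stage boundaries:\n")
    for (nm in names(x$receptive_fields)) {
      st <- x$receptive_fields[[nm]]
      cat(sprintf("    %-14s v=%-3d jump=%-3d r=%d\n", nm, st$v, st$c, st$r))
    }
  }
  invisible(x)
}

#' Receptive-field state at each stage boundary
#'
#' Propagates (output size, jump, receptive field) along the deepest
#' convolutional path of the network: the scaling layer and the `k`
#' mini-blocks of each stage (each mini-block contributes a 1x1, a 3x3
#' and a 1x1 convolution), followed by the stage's 2x2 stride-2 pooling.
#'
#' @param config a [mifnet_config()].
#' @return named list of `list(v, c, r)` states after each stage's
#'   pooling.
#' @export
stage_receptive_fields <- function(config) {
  stopifnot(inherits(config, "mifnet_config"))
  chain <- list()
  out <- list()
  for (s in 1:3) {
    chain <- c(chain, list(c(1, 1)))                       # scaling conv
    for (j in seq_len(config$mini_blocks_per_stage))
      chain <- c(chain, list(c(1, 1), c(3, 1), c(1, 1)))   # mini-block
    chain <- c(chain, list(c(2, 2, 1)))                    # ceil-mode pooling
    out[[sprintf("stage%d", s)]] <-
      rf_state(chain, input_size = config$input_size)
  }
  out
}

#' Write a complexity report to disk
#'
#' Writes the per-layer breakdown as a tab-separated table and the
#' summary as JSON.
#' @param report a `mifnet_complexity` report.
#' @param path output path stem; `<path>_layers.tsv` and
#'   `<path>_summary.json` are written.
#' @return invisibly, the two paths written.
#' @export
write_complexity_report <- function(report, path) {
  stopifnot(inherits(report, "mifnet_complexity"))
  tsv <- paste0(path, "_layers.tsv")
  jsn <- paste0(path, "_summary.json")
  utils::write.table(report$layers, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  summary <- report[c("parameter_count", "flops", "model_size_mb",
                      "model_size_bytes", "depth", "flop_convention")]
  jsonlite::write_json(summary, jsn, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, jsn))
}
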