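#' @title Symbolic layer graphs
#' @description
#' A `mifnet_graph` is an ordered, acyclic list of layer nodes with
#' explicit input edges (branch splits, shortcut links and
#' concatenation-fusion joins are all edges).  Both the runnable network
#' ([init_network()], [forward()]) and the complexity accounting
#' ([count_parameters()], [count_flops()]) are derived from it.
#' @name layergraph
NULL

new_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$nodes <- list()
  b
}

add_node <- function(b, kind, inputs = integer(), ...) {
  id <- length(b$nodes) + 1L
  node <- c(list(id = id, kind = kind, inputs = as.integer(inputs)), list(...))
  b$nodes[[id]] <- node
  id
}

finish_graph <- function(b, input_id, output_id, config = NULL) {
  g <- list(nodes = b$nodes, input = input_id, output = output_id,
            config = config)
  class(g) <- "mifnet_graph"
  g
}

#' @export
print.mifnet_graph <- function(x, ...) {
  cat("MIFNet layer graph: ", length(x$nodes), " nodes\n", sep = "")
  kinds <- table(vapply(x$nodes, `[[`, "", "kind"))
  cat("  ", paste(names(kinds), kinds, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

# convenience constructors -------------------------------------------------

add_conv <- function(b, input, kernel, in_channels, out_channels,
                     groups = 1L, stride = 1L, padding = "same",
                     bias = TRUE, label = "") {
  if (in_channels %% groups != 0L || out_channels %% groups != 0L)
    stop("configuration error: conv '", label, "' channels (", in_channels,
         "->", out_channels, ") not divisible by groups ", groups,
         call. = FALSE)
  add_node(b, "conv", input, kernel = as.integer(kernel),
           stride = as.integer(stride), padding = padding,
           groups = as.integer(groups), in_channels = as.integer(in_channels),
           out_channels = as.integer(out_channels), bias = bias, label = label)
}

add_bn <- function(b, input, channels, affine = FALSE) {
  add_node(b, "batchnorm", input, channels = as.integer(channels),
           affine = affine)
}

# conv -> BN -> ReLU composite (the forward unit f(BN(x * W)))
add_cbr <- function(b, input, kernel, cin, cout, groups = 1L, relu = TRUE,
                    label = "") {
  id <- add_conv(b, input, kernel, cin, cout, groups = groups, label = label)
  id <- add_bn(b, id, cout)
  if (relu) id <- add_node(b, "relu", id)
  id
}

#' Append one bottleneck mini-block to a builder.
#'
#' The mini-block is three Conv-BN-ReLU composites: a 1x1 reduction to the
#' bottleneck width, a 3x3 grouped convolution at the bottleneck width
#' (padding "same", so the spatial size is preserved), and a 1x1 expansion
#' back to the branch width.  When the input and output widths match, an
#' identity shortcut from the mini-block input is added element-wise
#' before the final ReLU; otherwise the shortcut is dropped.
#' @noRd
append_mini_block <- function(b, input, in_channels, bottleneck,
                              out_channels, groups, label = "") {
  id <- add_cbr(b, input, 1L, in_channels, bottleneck, label = paste0(label, "/reduce"))
  id <- add_cbr(b, id, 3L, bottleneck, bottleneck, groups = groups,
                label = paste0(label, "/spatial"))
  id <- add_conv(b, id, 1L, bottleneck, out_channels, label = paste0(label, "/expand"))
  id <- add_bn(b, id, out_channels)
  if (in_channels == out_channels)
    id <- add_node(b, "add", c(input, id), channels = as.integer(out_channels))
  add_node(b, "relu", id)
}

#' Build a bottleneck mini-block as a standalone graph fragment
#'
#' @param in_channels input channel count.
#' @param bottleneck bottleneck width (the 3x3 grouped convolution runs at
#'   this width).
#' @param out_channels output channel count; an identity shortcut is
#'   included when it equals `in_channels`.
#' @param groups group count of the 3x3 convolution; must divide
#'   `bottleneck`.
#' @return A `mifnet_graph` fragment with one input and one output node.
#' @examples
#' g <- build_mini_block(16, 4, 16, 4)
#' sum(vapply(g$nodes, function(n) n$kind == "conv", TRUE))  # 3
#' @export
build_mini_block <- function(in_channels, bottleneck, out_channels, groups) {
  if (bottleneck %% groups != 0L)
    stop("configuration error: bottleneck width ", bottleneck,
         " not divisible by groups ", groups, call. = FALSE)
  b <- new_builder()
  inp <- add_node(b, "input", channels = as.integer(in_channels))
  out <- append_mini_block(b, inp, in_channels, bottleneck, out_channels,
                           groups, label = "mini")
  finish_graph(b, inp, out)
}

#' Cyclic interleaved channel fusion
#'
#' After each cascade of grouped convolutions, every branch's next input
#' is the channel-wise concatenation of `fusion_channels` consecutive
#' branch outputs, taken cyclically: branch `i` receives branches
#' `i, i+1, ..., i+C-1 (mod B)`.  With `C = 1` each branch keeps its own
#' output; with `C = B` all fused inputs are identical full
#' concatenations.  Output channel count is `C` times the per-branch
#' count.
#'
#' @param branch_outputs a list of feature maps, either numeric arrays of
#'   identical dimensions `c(h, w, channels, batch)` or integer channel
#'   counts (symbolic use).
#' @param fusion_channels integer `C` between 1 and the number of
#'   branches.
#' @return A list of the same length: fused arrays (or fused channel
#'   counts when the inputs were counts).
#' @examples
#' interleave_fuse(list(16, 16, 16), 2)  # 32 32 32
#' @export
interleave_fuse <- function(branch_outputs, fusion_channels) {
  nb <- length(branch_outputs)
  C <- as.integer(fusion_channels)
  if (C < 1L || C > nb)
    stop("fusion error: fusion_channels must be in [1, ", nb, "]", call. = FALSE)
  numeric_maps <- is.array(branch_outputs[[1]])
  if (numeric_maps) {
    dims <- lapply(branch_outputs, dim)
    ref <- dims[[1]]
    for (d in dims)
      if (!identical(d[c(1, 2)], ref[c(1, 2)]))
        stop("fusion error: branch outputs have mismatched spatial sizes",
             call. = FALSE)
  }
  lapply(seq_len(nb), function(i) {
    members <- ((i - 1L + seq_len(C) - 1L) %% nb) + 1L
    if (C == 1L) return(branch_outputs[[i]])
    if (numeric_maps) {
      abind4(branch_outputs[members])
    } else {
      sum(unlist(branch_outputs[members]))
    }
  })
}

# bind a list of [h,w,c,n] arrays along the channel axis
abind4 <- function(arrs) {
  d <- dim(arrs[[1]])
  cs <- vapply(arrs, function(a) dim(a)[3], 0)
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (a in arrs) {
    nc <- dim(a)[3]
    out[, , at + seq_len(nc), ] <- a
    at <- at + nc
  }
  out
}

#' Append one MIF block (3 branches x k mini-blocks, interleaved fusion,
#' shortcut links) to a builder; returns the merged output node id.
#' @noRd
append_mif_block <- function(b, input, stage, config) {
  w <- config$stage_widths[stage]
  bw <- config$bottleneck_widths[stage]
  g <- config$groups[stage]
  k <- config$mini_blocks_per_stage
  C <- config$fusion_channels
  nb <- config$branches
  cur <- rep(input, nb)          # node ids feeding each branch
  a <- w                         # per-branch channel count
  for (j in seq_len(k)) {
    outs <- integer(nb)
    for (i in seq_len(nb)) {
      outs[i] <- append_mini_block(b, cur[i], a, bw, a, g,
                                   label = sprintf("s%d/b%d/m%d", stage, i, j))
    }
    # channel fusion after every cascaded group convolution
    if (C == 1L) {
      cur <- outs
    } else {
      for (i in seq_len(nb)) {
        members <- ((i - 1L + seq_len(C) - 1L) %% nb) + 1L
        cur[i] <- add_node(b, "concat", outs[members],
                           channels = as.integer(C * a))
      }
      a <- C * a
    }
  }
  # merge the three branch streams element-wise
  add_node(b, "add", cur, channels = as.integer(a))
}

#' Build one MIF block as a standalone graph fragment
#'
#' Three parallel branches, each a chain of
#' `config$mini_blocks_per_stage` bottleneck mini-blocks; cyclic
#' interleaved fusion is applied after every mini-block, identity
#' shortcuts run inside each mini-block, and the block output is the
#' element-wise merge of the three branch streams.  Spatial size is
#' unchanged throughout (all convolutions use "same" padding).
#'
#' @param stage_index 1, 2 or 3.
#' @param config a [mifnet_config()].
#' @return A `mifnet_graph` fragment.
#' @export
build_mif_block <- function(stage_index, config) {
  stopifnot(inherits(config, "mifnet_config"))
  if (!stage_index %in% 1:3)
    stop("configuration error: stage_index must be 1, 2 or 3", call. = FALSE)
  b <- new_builder()
  inp <- add_node(b, "input",
                  channels = config$stage_widths[stage_index])
  out <- append_mif_block(b, inp, stage_index, config)
  finish_graph(b, inp, out, config = config)
}

#' Assemble the full MIFNet layer graph
#'
#' The network is: scaling layer (1x1 conv to the stage width) -> MIF
#' block -> pooling (2x2, stride 2, ceil mode; max pooling after stage 1,
#' average pooling after stages 2 and 3) -> dropout, repeated for the
#' three stages, followed by global average pooling, a dense
#' classification layer and softmax.  For a 50-pixel input the spatial
#' trajectory is 50 -> 25 -> 13 -> 7.
#'
#' @param config a [mifnet_config()].
#' @return A `mifnet_graph` whose `config` attribute is `config`.
#' @examples
#' g <- assemble_mifnet(mifnet_preset("mifnet10"))
#' print(g)
#' @export
assemble_mifnet <- function(config) {
  stopifnot(inherits(config, "mifnet_config"))
  validate_config(config)
  b <- new_builder()
  inp <- add_node(b, "input", channels = config$input_channels)
  id <- inp
  prev <- config$input_channels
  for (s in 1:3) {
    w <- config$stage_widths[s]
    id <- add_cbr(b, id, 1L, prev, w, label = sprintf("scale%d", s))
    id <- append_mif_block(b, id, s, config)
    poolkind <- if (s == 1L) "maxpool" else "avgpool"
    id <- add_node(b, poolkind, id, kernel = 2L, stride = 2L,
                   rounding = "ceil")
    id <- add_node(b, "dropout", id, rate = config$dropout_rates[s])
    prev <- config$stage_widths[s] *
      config$fusion_channels^config$mini_blocks_per_stage
    if (config$fusion_channels == 1L) prev <- config$stage_widths[s]
  }
  # classification head: global average pool -> dense -> softmax
  id <- add_node(b, "avgpool", id, kernel = 0L, stride = 1L,
                 rounding = "floor", global = TRUE)
  id <- add_node(b, "flatten", id)
  id <- add_node(b, "dense", id, in_features = as.integer(prev),
                 out_features = config$num_classes, bias = TRUE)
  id <- add_node(b, "softmax", id)
  finish_graph(b, inp, id, config = config)
}

# ---- structural checks ----------------------------------------------------

#' Validate the structural invariants of a layer graph
#'
#' Checks that the graph is acyclic (ids are topologically ordered by
#' construction), has exactly one input and one output, and that every
#' concatenation node's channel count equals the sum of its inputs'.
#' Returns `TRUE` invisibly or stops with a descriptive error.
#' @param graph a `mifnet_graph`.
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "mifnet_graph"))
  kinds <- vapply(graph$nodes, `[[`, "", "kind")
  if (sum(kinds == "input") != 1L)
    stop("graph error: expected exactly one input node", call. = FALSE)
  sh <- infer_shapes(graph)
  consumed <- unlist(lapply(graph$nodes, `[[`, "inputs"))
  sinks <- setdiff(seq_along(graph$nodes), consumed)
  if (length(sinks) != 1L || sinks != graph$output)
    stop("graph error: expected exactly one output node", call. = FALSE)
  for (n in graph$nodes) {
    if (any(n$inputs >= n$id))
      stop("graph error: node ", n$id, " has a non-topological edge",
           call. = FALSE)
    if (n$kind == "concat") {
      insum <- sum(sh$channels[n$inputs])
      if (insum != sh$channels[n$id])
        stop("graph error: concat node ", n$id, " channel mismatch",
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Propagate spatial size and channel count through a graph
#'
#' @param graph a `mifnet_graph`.
#' @param input_size input side length in pixels; defaults to the
#'   assembling configuration's, or 50.
#' @return A data frame with one row per node: `id`, `kind`, `size`
#'   (spatial side length) and `channels`.
#' @export
infer_shapes <- function(graph, input_size = NULL) {
  if (is.null(input_size))
    input_size <- if (!is.null(graph$config)) graph$config$input_size else 50L
  n <- length(graph$nodes)
  size <- integer(n); channels <- integer(n)
  for (node in graph$nodes) {
    i <- node$id
    ins <- node$inputs
    sz <- if (length(ins)) size[ins[1]] else NA_integer_
    ch <- if (length(ins)) channels[ins[1]] else NA_integer_
    switch(node$kind,
      input = { size[i] <- input_size; channels[i] <- node$channels },
      conv = {
        p <- if (identical(node$padding, "same")) (node$kernel - 1L) %/% 2L
             else as.integer(node$padding)
        size[i] <- conv_output_size(sz, node$kernel, p, node$stride, "floor")
        channels[i] <- node$out_channels
      },
      maxpool = ,
      avgpool = {
        if (isTRUE(node$global)) size[i] <- 1L
        else size[i] <- conv_output_size(sz, node$kernel, 0L, node$stride,
                                         node$rounding)
        channels[i] <- ch
      },
      concat = { size[i] <- sz; channels[i] <- sum(channels[ins]) },
      add = {
        if (length(unique(channels[ins])) != 1L)
          stop("graph error: add node ", i, " mixes channel counts",
               call. = FALSE)
        size[i] <- sz; channels[i] <- ch
      },
      flatten = { size[i] <- 1L; channels[i] <- sz * sz * ch },
      dense = { size[i] <- 1L; channels[i] <- node$out_features },
      { size[i] <- sz; channels[i] <- ch }  # relu, batchnorm, dropout, softmax
    )
  }
  data.frame(id = seq_len(n),
             kind = vapply(graph$nodes, `[[`, "", "kind"),
             size = size, channels = channels)
}
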