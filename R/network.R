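#' @title Runnable networks
#' @description
#' [init_network()] turns a symbolic layer graph into a runnable network:
#' Xavier-initialised weights for every convolution and dense node, plus
#' running batch-norm statistics.  [forward()] executes the graph on a
#' batch of patches.  The executor also exposes an exact backward pass
#' (used by [train()]), verified against finite differences in the test
#' suite.
#' @name network
NULL

#' Initialise a runnable MIFNet
#'
#' Convolution and dense weights are drawn from the Xavier (Glorot)
#' uniform distribution `U(-a, a)`, `a = sqrt(6 / (fan_in + fan_out))`;
#' biases start at zero and batch-norm running statistics at (0, 1).
#'
#' @param graph a `mifnet_graph` from [assemble_mifnet()], or a
#'   [mifnet_config()].
#' @param seed optional integer; when given, seeds R's RNG so that
#'   initialisation is reproducible.
#' @return An object of class `mifnet_network`.
#' @export
init_network <- function(graph, seed = NULL) {
  if (inherits(graph, "mifnet_config")) graph <- assemble_mifnet(graph)
  stopifnot(inherits(graph, "mifnet_graph"))
  if (!is.null(seed)) set.seed(seed)
  weights <- vector("list", length(graph$nodes))
  state <- vector("list", length(graph$nodes))
  for (node in graph$nodes) {
    if (node$kind == "conv") {
      cing <- node$in_channels %/% node$groups
      coutg <- node$out_channels %/% node$groups
      fan_in <- node$kernel^2 * cing
      fan_out <- node$kernel^2 * coutg
      a <- sqrt(6 / (fan_in + fan_out))
      weights[[node$id]] <- list(
        W = array(stats::runif(node$kernel^2 * cing * node$out_channels,
                               -a, a),
                  c(node$kernel, node$kernel, cing, node$out_channels)),
        b = numeric(node$out_channels))
    } else if (node$kind == "dense") {
      a <- sqrt(6 / (node$in_features + node$out_features))
      weights[[node$id]] <- list(
        W = matrix(stats::runif(node$in_features * node$out_features, -a, a),
                   node$in_features, node$out_features),
        b = numeric(node$out_features))
    } else if (node$kind == "batchnorm") {
      state[[node$id]] <- list(run_mean = numeric(node$channels),
                               run_var = rep(1, node$channels))
    }
  }
  net <- list(graph = graph, weights = weights, state = state,
              shapes = infer_shapes(graph))
  class(net) <- "mifnet_network"
  net
}

#' @export
print.mifnet_network <- function(x, ...) {
  cat("MIFNet network: ", length(x$graph$nodes), " nodes, ",
      format(count_parameters(x$graph), big.mark = ","),
      " trainable parameters\n", sep = "")
  invisible(x)
}

# coerce accepted patch containers to [H, W, C, N]
as_batch <- function(images, input_size, input_channels = 1L) {
  if (is.list(images))
    images <- simplify2array(images)
  d <- dim(images)
  if (length(d) == 2L) dim(images) <- c(d, 1L)
  d <- dim(images)
  if (length(d) == 3L) {
    images <- array(images, c(d[1], d[2], 1L, d[3]))
    d <- dim(images)
  }
  if (d[1] != input_size || d[2] != input_size || d[3] != input_channels)
    stop("shape error: expected ", input_size, "x", input_size, "x",
         input_channels, " patches, got ", d[1], "x", d[2], "x", d[3],
         call. = FALSE)
  if (!all(is.finite(images)))
    stop("data error: non-finite pixel values in batch", call. = FALSE)
  images
}

# full executor; returns node values/caches for the backward pass
net_forward <- function(net, x, training = FALSE, bn_momentum = 0.9) {
  g <- net$graph
  n <- length(g$nodes)
  values <- vector("list", n)
  caches <- vector("list", n)
  for (node in g$nodes) {
    i <- node$id
    inval <- if (length(node$inputs)) values[[node$inputs[1]]]
    switch(node$kind,
      input = { values[[i]] <- aperm(x, c(1, 2, 4, 3)) },  # to [H,W,N,C]
      conv = {
        wt <- net$weights[[i]]
        r <- conv2d_forward(inval, wt$W, wt$b, node$groups)
        values[[i]] <- r$out; caches[[i]] <- r$cache
      },
      batchnorm = {
        st <- net$state[[i]]
        r <- bn_forward(inval, training, st$run_mean, st$run_var,
                        momentum = bn_momentum)
        values[[i]] <- r$out; caches[[i]] <- r$cache
        if (training)
          net$state[[i]] <- list(run_mean = r$run_mean, run_var = r$run_var)
      },
      relu = {
        r <- relu_forward(inval)
        values[[i]] <- r$out; caches[[i]] <- r$cache
      },
      maxpool = ,
      avgpool = {
        if (isTRUE(node$global)) {
          r <- gap_forward(inval)
        } else {
          r <- pool2_forward(inval,
                             if (node$kind == "maxpool") "max" else "avg")
        }
        values[[i]] <- r$out; caches[[i]] <- r$cache
      },
      dropout = {
        r <- dropout_forward(inval, node$rate, training)
        values[[i]] <- r$out; caches[[i]] <- r$cache
      },
      concat = {
        values[[i]] <- cbind4(values[node$inputs])
      },
      add = {
        acc <- values[[node$inputs[1]]]
        for (j in node$inputs[-1]) acc <- acc + values[[j]]
        values[[i]] <- acc
      },
      flatten = {
        d <- dim(inval)            # [H, W, N, C] -> features x batch
        v <- aperm(inval, c(1, 2, 4, 3))
        dim(v) <- c(d[1] * d[2] * d[4], d[3])
        values[[i]] <- v
        caches[[i]] <- d
      },
      dense = {
        wt <- net$weights[[i]]
        r <- dense_forward(inval, wt$W, wt$b)
        values[[i]] <- r$out; caches[[i]] <- r$cache
      },
      softmax = {
        values[[i]] <- softmax_rows(inval)
      },
      stop("unknown node kind: ", node$kind))
  }
  list(values = values, caches = caches, net = net)
}

# reverse sweep from `seed_id` with gradient `seed_grad`; returns
# per-node weight gradients (list of list(W, b))
net_backward <- function(net, fw, seed_id, seed_grad) {
  g <- net$graph
  n <- length(g$nodes)
  grads <- vector("list", n)      # gradient w.r.t. each node's output
  wgrads <- vector("list", n)
  grads[[seed_id]] <- seed_grad
  accumulate <- function(id, val) {
    grads[[id]] <<- if (is.null(grads[[id]])) val else grads[[id]] + val
  }
  for (i in seq(seed_id, 1L)) {
    gr <- grads[[i]]
    if (is.null(gr)) next
    node <- g$nodes[[i]]
    switch(node$kind,
      input = { },
      conv = {
        bk <- conv2d_backward(gr, net$weights[[i]]$W, node$groups,
                              fw$caches[[i]])
        wgrads[[i]] <- list(W = bk$dW, b = bk$db)
        accumulate(node$inputs[1], bk$dx)
      },
      batchnorm = accumulate(node$inputs[1], bn_backward(gr, fw$caches[[i]])),
      relu = accumulate(node$inputs[1], relu_backward(gr, fw$caches[[i]])),
      maxpool = accumulate(node$inputs[1],
                           pool2_backward(gr, "max", fw$caches[[i]])),
      avgpool = {
        dx <- if (isTRUE(node$global)) gap_backward(gr, fw$caches[[i]])
              else pool2_backward(gr, "avg", fw$caches[[i]])
        accumulate(node$inputs[1], dx)
      },
      dropout = accumulate(node$inputs[1],
                           dropout_backward(gr, fw$caches[[i]])),
      concat = {
        at <- 0L
        for (j in node$inputs) {
          nc <- net$shapes$channels[j]
          accumulate(j, gr[, , , at + seq_len(nc), drop = FALSE])
          at <- at + nc
        }
      },
      add = for (j in node$inputs) accumulate(j, gr),
      flatten = {
        d <- fw$caches[[i]]        # original [H, W, N, C]
        dim(gr) <- c(d[1], d[2], d[4], d[3])
        accumulate(node$inputs[1], aperm(gr, c(1, 2, 4, 3)))
      },
      dense = {
        bk <- dense_backward(gr, net$weights[[i]]$W, fw$caches[[i]])
        wgrads[[i]] <- list(W = bk$dW, b = bk$db)
        accumulate(node$inputs[1], bk$dx)
      },
      softmax = stop("backward through softmax is not used; seed at the dense layer"))
    grads[i] <- list(NULL)       # free as we go (keep list length)
  }
  wgrads
}

# Batch-norm finalisation: after the weights stop moving, replace the
# exponentially-weighted running statistics (which lag the final weights)
# with the average batch statistics of a full pass over the training
# set.  Using momentum (b-1)/b on batch b accumulates the arithmetic
# mean of the per-batch means and variances.
finalize_bn_stats <- function(net, x, batch_size) {
  for (i in seq_along(net$state))
    if (!is.null(net$state[[i]]))
      net$state[[i]] <- lapply(net$state[[i]], function(v) v * 0)
  n <- dim(x)[4]
  b <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    b <- b + 1L
    idx <- start:min(start + batch_size - 1L, n)
    fw <- net_forward(net, x[, , , idx, drop = FALSE], training = TRUE,
                      bn_momentum = (b - 1) / b)
    net <- fw$net
  }
  net
}

# id of the dense classification node (softmax input)
dense_node_id <- function(graph) {
  out <- graph$nodes[[graph$output]]
  if (out$kind == "softmax") out$inputs[1] else graph$output
}

#' Run a network forward in inference mode
#'
#' Executes the layer graph on a batch of patches with dropout disabled
#' and batch normalisation using running statistics, so repeated calls
#' are bit-identical.
#'
#' @param network a `mifnet_network`.
#' @param images patches: a list of `input_size` x `input_size` matrices,
#'   an array `[size, size, n]`, or an array `[size, size, channels, n]`.
#' @return a matrix of per-class probabilities, one row per image; rows
#'   are non-negative and sum to one.
#' @export
forward <- function(network, images) {
  stopifnot(inherits(network, "mifnet_network"))
  cfg <- network$graph$config
  x <- as_batch(images, cfg$input_size, cfg$input_channels)
  fw <- net_forward(network, x, training = FALSE)
  probs <- t(fw$values[[network$graph$output]])
  colnames(probs) <- paste0("class", seq_len(ncol(probs)) - 1L)
  probs
}
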