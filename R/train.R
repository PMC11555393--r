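#' @title Training
#' @description
#' Mini-batch gradient-descent training of a runnable MIFNet with the
#' family's regime: Xavier initialisation, softmax cross-entropy loss,
#' and a choice of ADAM (the default), SGD-with-momentum or RMSprop.
#' The published regime is 50 epochs, batch size 32 and an initial
#' learning rate of 0.001; no schedule is applied (the rate is constant)
#' and there is no validation split or early stopping.
#' @name training
NULL

#' Training configuration
#'
#' @param optimizer one of "adam", "sgdm", "rmsprop".
#' @param learning_rate positive; default 0.001.  A rate of 0 is allowed
#'   (freezes the network; useful for diagnostics).
#' @param batch_size mini-batch size, default 32.
#' @param epochs number of passes over the training set, default 50.
#' @param seed integer seed controlling shuffling and dropout; also used
#'   to seed weight initialisation when [train()] receives a config or
#'   graph rather than an initialised network.
#' @param momentum SGDM momentum (default 0.9).
#' @param beta1,beta2 ADAM moment decays (defaults 0.9, 0.999).
#' @param rho RMSprop squared-gradient decay (default 0.9).
#' @return An object of class `mifnet_train_config`.
#' @export
train_config <- function(optimizer = c("adam", "sgdm", "rmsprop"),
                         learning_rate = 0.001, batch_size = 32L,
                         epochs = 50L, seed = 1L, momentum = 0.9,
                         beta1 = 0.9, beta2 = 0.999, rho = 0.9) {
  optimizer <- match.arg(optimizer)
  if (learning_rate < 0) stop("learning_rate must be >= 0", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 momentum = momentum, beta1 = beta1, beta2 = beta2,
                 rho = rho),
            class = "mifnet_train_config")
}

# one optimizer step over the per-node weight-gradient structure
make_optimizer <- function(config) {
  st <- new.env(parent = emptyenv())
  st$slot <- list()
  st$t <- 0L
  step <- function(weights, wgrads) {
    st$t <- st$t + 1L
    lr <- config$learning_rate
    for (i in seq_along(wgrads)) {
      if (is.null(wgrads[[i]])) next
      key <- as.character(i)
      for (p in c("W", "b")) {
        g <- wgrads[[i]][[p]]
        if (is.null(g)) next
        sk <- paste0(key, ".", p)
        s <- st$slot[[sk]]
        upd <- switch(config$optimizer,
          sgdm = {
            v <- if (is.null(s)) g * 0 else s$v
            v <- config$momentum * v + g
            st$slot[[sk]] <- list(v = v)
            lr * v
          },
          adam = {
            if (is.null(s)) s <- list(m = g * 0, v = g * 0)
            m <- config$beta1 * s$m + (1 - config$beta1) * g
            v <- config$beta2 * s$v + (1 - config$beta2) * g^2
            st$slot[[sk]] <- list(m = m, v = v)
            mhat <- m / (1 - config$beta1^st$t)
            vhat <- v / (1 - config$beta2^st$t)
            lr * mhat / (sqrt(vhat) + 1e-8)
          },
          rmsprop = {
            v <- if (is.null(s)) g * 0 else s$v
            v <- config$rho * v + (1 - config$rho) * g^2
            st$slot[[sk]] <- list(v = v)
            lr * g / (sqrt(v) + 1e-8)
          })
        weights[[i]][[p]] <- weights[[i]][[p]] - upd
      }
    }
    weights
  }
  step
}

# coerce a patch dataset: list(images=..., labels=0/1)
as_dataset <- function(dataset, input_size) {
  if (is.null(dataset$images) || is.null(dataset$labels))
    stop("data error: dataset must have $images and $labels", call. = FALSE)
  labels <- as.integer(dataset$labels)
  if (length(labels) == 0L) stop("data error: empty dataset", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("data error: labels must be 0 or 1", call. = FALSE)
  x <- as_batch(dataset$images, input_size)
  if (dim(x)[4] != length(labels))
    stop("data error: ", dim(x)[4], " images but ", length(labels),
         " labels", call. = FALSE)
  list(x = x, labels = labels)
}

#' Train a network
#'
#' Runs seeded mini-batch gradient descent with the configured optimizer
#' and softmax cross-entropy loss, recording training loss and
#' classification error per epoch.  All randomness (shuffling, dropout)
#' flows from `config$seed`, so identical seeds and data give identical
#' histories.
#'
#' @param network a `mifnet_network` (or a [mifnet_config()] /
#'   `mifnet_graph`, which is initialised with `config$seed`).
#' @param train_set a list with `images` (as accepted by [forward()]) and
#'   `labels` (0 = benign/negative, 1 = malignant/nodule).
#' @param config a [train_config()].
#' @return A list of class `mifnet_fit`: `network` (trained) and
#'   `history`, a data frame with `epoch`, `loss` and `error`.
#' @export
train <- function(network, train_set, config = train_config()) {
  stopifnot(inherits(config, "mifnet_train_config"))
  if (!inherits(network, "mifnet_network"))
    network <- init_network(network, seed = config$seed)
  cfg <- network$graph$config
  ds <- as_dataset(train_set, cfg$input_size)
  n <- length(ds$labels)
  dense_id <- dense_node_id(network$graph)
  step <- make_optimizer(config)
  set.seed(config$seed)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        error = numeric())
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(); nerr <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- ds$x[, , , idx, drop = FALSE]
      yb <- ds$labels[idx]
      fw <- net_forward(network, xb, training = TRUE)
      network <- fw$net                      # updated BN running stats
      logits <- fw$values[[dense_id]]
      ce <- softmax_xent(logits, yb)
      if (!is.finite(ce$loss))
        stop("divergence error: non-finite loss at epoch ", epoch,
             call. = FALSE)
      losses <- c(losses, ce$loss * length(idx))
      nerr <- nerr + sum((apply(ce$probs, 2, which.max) - 1L) != yb)
      wg <- net_backward(network, fw, dense_id, ce$dlogits)
      network$weights <- step(network$weights, wg)
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = sum(losses) / n,
                                error = nerr / n))
  }
  # finalisation pass: recompute batch-norm statistics under the final
  # weights so that inference-mode behaviour matches end-of-training
  network <- finalize_bn_stats(network, ds$x, config$batch_size)
  structure(list(network = network, history = history,
                 config = config), class = "mifnet_fit")
}

#' @export
print.mifnet_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "MIFNet fit: %d epochs (%s, lr %g); final loss %.4f, error %.2f%%\n",
    nrow(x$history), x$config$optimizer, x$config$learning_rate,
    last$loss, 100 * last$error))
  invisible(x)
}
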