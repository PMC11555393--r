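test_that("analytic gradients match finite differences", {
  cfg <- tiny_config()
  net <- init_network(cfg, seed = 3)
  set.seed(4)
  x <- array(runif(12 * 12 * 1 * 2), c(12, 12, 1, 2))
  y <- c(0L, 1L)
  dense_id <- mifnet:::dense_node_id(net$graph)
  loss_of <- function(nw) {
    fw <- mifnet:::net_forward(nw, x, training = TRUE)
    mifnet:::softmax_xent(fw$values[[dense_id]], y)$loss
  }
  fw <- mifnet:::net_forward(net, x, training = TRUE)
  ce <- mifnet:::softmax_xent(fw$values[[dense_id]], y)
  wg <- mifnet:::net_backward(net, fw, dense_id, ce$dlogits)
  eps <- 1e-5
  set.seed(5)
  conv_ids <- which(vapply(net$graph$nodes, function(n)
    n$kind %in% c("conv", "dense"), TRUE))
  # probe a few weights in every parameterised layer, first and last
  for (id in conv_ids) {
    W <- net$weights[[id]]$W
    for (flat in unique(c(1L, sample.int(length(W), 3L), length(W)))) {
      plus <- net; plus$weights[[id]]$W[flat] <- W[flat] + eps
      minus <- net; minus$weights[[id]]$W[flat] <- W[flat] - eps
      fd <- (loss_of(plus) - loss_of(minus)) / (2 * eps)
      expect_equal(wg[[id]]$W[flat], fd, tolerance = 1e-4)
    }
    b <- net$weights[[id]]$b
    plus <- net; plus$weights[[id]]$b[1] <- b[1] + eps
    minus <- net; minus$weights[[id]]$b[1] <- b[1] - eps
    fd <- (loss_of(plus) - loss_of(minus)) / (2 * eps)
    expect_equal(wg[[id]]$b[1], fd, tolerance = 1e-4)
  }
})

test_that("compiled batch-norm and pooling agree with the R reference", {
  set.seed(8)
  x <- array(rnorm(11 * 9 * 3 * 4), c(11, 9, 3, 4))   # odd sizes
  r1 <- mifnet:::bn_forward(x, TRUE, numeric(4), rep(1, 4))
  r2 <- mifnet:::bn_forward_ref(x, TRUE, numeric(4), rep(1, 4))
  expect_equal(r1$out, r2$out, tolerance = 1e-12)
  expect_equal(r1$run_mean, r2$run_mean, tolerance = 1e-12)
  expect_equal(r1$run_var, r2$run_var, tolerance = 1e-12)
  dout <- array(rnorm(length(x)), dim(x))
  expect_equal(mifnet:::bn_backward(dout, r1$cache),
               mifnet:::bn_backward_ref(dout, r2$cache),
               tolerance = 1e-12)
  for (kind in c("max", "avg")) {
    p1 <- mifnet:::pool2_forward(x, kind)
    p2 <- mifnet:::pool2_forward_ref(x, kind)
    expect_equal(p1$out, p2$out, tolerance = 1e-12)
    dpo <- array(rnorm(length(p1$out)), dim(p1$out))
    expect_equal(mifnet:::pool2_backward(dpo, kind, p1$cache),
                 mifnet:::pool2_backward_ref(dpo, kind, p2$cache),
                 tolerance = 1e-12)
  }
  # ceil-mode geometry: 11 -> 6, 9 -> 5
  expect_equal(dim(p1$out)[1:2], c(6L, 5L))
})

test_that("zeroing a branch's convolutions leaves the shortcut signal", {
  g <- build_mini_block(8, 4, 8, 2)
  net <- init_network(g, seed = 6)
  for (i in seq_along(net$weights)) {
    if (!is.null(net$weights[[i]]) && g$nodes[[i]]$kind == "conv") {
      net$weights[[i]]$W[] <- 0
      net$weights[[i]]$b[] <- 0
    }
  }
  set.seed(7)
  x <- array(runif(10 * 10 * 8 * 2), c(10, 10, 8, 2))
  fw <- mifnet:::net_forward(net, x, training = FALSE)
  add_id <- which(vapply(g$nodes, `[[`, "", "kind") == "add")
  # pre-ReLU block output equals the shortcut input exactly
  expect_equal(fw$values[[add_id]], fw$values[[g$input]])
})

test_that("softmax output is a probability distribution", {
  net <- init_network(tiny_config(), seed = 9)
  x <- array(runif(12 * 12 * 3), c(12, 12, 3))
  p <- forward(net, x)
  expect_equal(dim(p), c(3L, 2L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
})

test_that("a zeroed classification layer yields (0.5, 0.5)", {
  net <- init_network(tiny_config(), seed = 10)
  dense_id <- mifnet:::dense_node_id(net$graph)
  net$weights[[dense_id]]$W[] <- 0
  net$weights[[dense_id]]$b[] <- 0
  p <- forward(net, const_batch(2, size = 12))
  expect_equal(as.vector(p), rep(0.5, 4))
})

test_that("inference is deterministic and input shapes are checked", {
  net <- init_network(tiny_config(), seed = 11)
  set.seed(12)
  x <- array(runif(12 * 12 * 2), c(12, 12, 2))
  expect_identical(forward(net, x), forward(net, x))
  expect_error(forward(net, array(0, c(10, 10, 2))), "shape error")
  bad <- x; bad[1] <- NA
  expect_error(forward(net, bad), "non-finite")
})
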