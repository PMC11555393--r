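test_that("metric formulas match direct arithmetic", {
  perfect <- metrics_from_confusion(50, 0, 50, 0)
  expect_equal(unlist(perfect[c("acc", "f1", "prec", "sens", "spec")]),
               c(acc = 100, f1 = 100, prec = 100, sens = 100, spec = 100))
  m <- metrics_from_confusion(90, 10, 40, 10)
  expect_equal(m$acc, 100 * 130 / 150, tolerance = 1e-10)
  expect_equal(round(m$acc, 2), 86.67)
  expect_equal(m$prec, 90)
  expect_equal(m$sens, 90)
  expect_equal(m$spec, 80)
  expect_equal(m$f1, 90)
  # zero denominators are undefined, not zero
  deg <- metrics_from_confusion(0, 0, 10, 5)
  expect_true(is.na(deg$prec))
  expect_true(is.na(deg$f1))
  expect_equal(deg$spec, 100)
  expect_equal(deg$sens, 0)
  expect_error(metrics_from_confusion(0, 0, 0, 0), "no evaluated samples")
  expect_error(metrics_from_confusion(-1, 0, 1, 0), ">= 0")
})

test_that("accuracy equals p*sens + (1-p)*spec for random confusions", {
  set.seed(44)
  for (i in 1:25) {
    cts <- rpois(4, 20) + 1
    m <- metrics_from_confusion(cts[1], cts[2], cts[3], cts[4])
    p <- (cts[1] + cts[4]) / sum(cts)
    expect_equal(m$acc, p * m$sens + (1 - p) * m$spec, tolerance = 1e-10)
  }
})

test_that("evaluation is internally consistent and ties go positive", {
  net <- init_network(tiny_config(), seed = 21)
  set.seed(22)
  ds <- list(images = array(runif(12 * 12 * 20), c(12, 12, 20)),
             labels = rep(0:1, 10))
  m <- evaluate(net, ds)
  cm <- m$confusion
  expect_equal(sum(cm), 20)
  recomputed <- metrics_from_confusion(cm["tp"], cm["fp"], cm["tn"],
                                       cm["fn"])
  expect_equal(m$acc, recomputed$acc)
  expect_equal(m$spec, recomputed$spec)
  expect_equal(nrow(m$predictions), 20L)
  expect_true(all(m$predictions$confidence >= 0.5))
  # a constant-positive predictor has sens 100, spec 0
  dense_id <- mifnet:::dense_node_id(net$graph)
  net$weights[[dense_id]]$W[] <- 0
  net$weights[[dense_id]]$b <- c(-5, 5)
  mp <- evaluate(net, ds)
  expect_equal(mp$sens, 100)
  expect_equal(mp$spec, 0)
  # exactly tied probabilities predict the positive class
  net$weights[[dense_id]]$b <- c(0, 0)
  mt <- evaluate(net, ds)
  expect_true(all(mt$predictions$predicted == 1L))
  expect_error(evaluate(net, list(images = ds$images,
                                  labels = rep(2, 20))), "labels")
})

test_that("a zero learning rate freezes the loss", {
  cfg <- tiny_config()
  ds <- list(images = array(runif(12 * 12 * 16, 0, 1), c(12, 12, 16)),
             labels = rep(0:1, 8))
  fit <- train(cfg, ds, train_config(learning_rate = 0, epochs = 3,
                                     batch_size = 16, seed = 2))
  expect_lt(diff(range(fit$history$loss)), 1e-10)
})

test_that("identical seeds and data give identical histories", {
  cfg <- tiny_config()
  set.seed(23)
  ds <- list(images = array(runif(12 * 12 * 24), c(12, 12, 24)),
             labels = rep(0:1, 12))
  tc <- train_config(epochs = 2, batch_size = 8, seed = 13)
  f1 <- train(cfg, ds, tc)
  f2 <- train(cfg, ds, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$network$weights, f2$network$weights)
})

test_that("all three optimizers reduce the loss on separable patches", {
  ds <- separable_patches(24, seed = 29)
  cfg <- tiny_config(input_size = 50L)
  for (opt in c("adam", "sgdm", "rmsprop")) {
    fit <- train(cfg, ds, train_config(optimizer = opt, epochs = 3,
                                       batch_size = 16, seed = 3))
    expect_lt(fit$history$loss[3], fit$history$loss[1],
              label = paste(opt, "final loss"))
  }
})

test_that("training rejects degenerate inputs", {
  cfg <- tiny_config()
  expect_error(train(cfg, list(images = array(0, c(12, 12, 2)),
                               labels = c(0, 2)),
                     train_config(epochs = 1)), "labels")
  expect_error(train(cfg, list(images = NULL, labels = NULL),
                     train_config(epochs = 1)), "data error")
  expect_error(train_config(learning_rate = -1), "learning_rate")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(epochs = 0), "epochs")
})
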