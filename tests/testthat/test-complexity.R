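test_that("convolution output-size arithmetic covers both roundings", {
  expect_equal(conv_output_size(50, 1, 0, 1), 50L)
  expect_equal(conv_output_size(50, 3, 1, 1), 50L)       # "same" padding
  expect_equal(conv_output_size(25, 2, 0, 2, "ceil"), 13L)
  expect_equal(conv_output_size(13, 2, 0, 2, "ceil"), 7L)
  expect_equal(conv_output_size(25, 2, 0, 2, "floor"), 12L)
  expect_error(conv_output_size(2, 5, 0, 1), "geometry error")
})

test_that("jump accumulates stride products", {
  expect_equal(jump(1, 1), 1)
  expect_equal(jump(1, 2), 2)
  expect_equal(jump(jump(1, 2), 2), 4)
})

test_that("receptive-field propagation matches worked examples", {
  expect_equal(receptive_field(list(c(3, 1))), 3L)
  expect_equal(receptive_field(list(c(3, 1), c(3, 1))), 5L)
  expect_equal(receptive_field(list(c(3, 1), c(2, 2), c(3, 1))), 8L)
  expect_error(receptive_field(list()), "empty")
  st <- rf_state(list(c(3, 1), c(2, 2)), input_size = 50)
  expect_equal(st$v, 25L)
  expect_equal(st$c, 2)
})

test_that("receptive field equals the enumeration oracle on random chains", {
  for (seed in 1:20) {
    chain <- random_chain(seed)
    expect_equal(receptive_field(chain), rf_support_oracle(chain),
                 info = paste("chain seed", seed))
  }
})

test_that("receptive field is non-decreasing along any forward chain", {
  for (seed in 21:30) {
    chain <- random_chain(seed)
    rs <- vapply(seq_along(chain), function(i)
      receptive_field(chain[seq_len(i)]), 0L)
    expect_true(all(diff(rs) >= 0))
  }
})

test_that("parameter counting matches brute-force weight enumeration", {
  for (seed in 1:10) {
    g <- assemble_mifnet(random_config(seed))
    expect_equal(count_parameters(g), enumerate_weights(g),
                 info = paste("config seed", seed))
  }
})

test_that("layer-level parameter and FLOP formulas match hand counts", {
  # a single biased 1x1 conv, 1 -> 16 channels: 16 weights + 16 biases,
  # and 2500 * 16 multiply-accumulates on a 50x50 input
  b <- mifnet:::new_builder()
  inp <- mifnet:::add_node(b, "input", channels = 1L)
  cv <- mifnet:::add_conv(b, inp, 1L, 1L, 16L)
  g <- mifnet:::finish_graph(b, inp, cv)
  expect_equal(count_parameters(g), 32)
  expect_equal(count_flops(g, input_size = 50), 40000)
  # affine batch-norm contributes 2 * channels; non-affine none
  b2 <- mifnet:::new_builder()
  inp2 <- mifnet:::add_node(b2, "input", channels = 8L)
  bn_free <- mifnet:::add_bn(b2, inp2, 8L)
  bn_aff <- mifnet:::add_bn(b2, bn_free, 8L, affine = TRUE)
  g2 <- mifnet:::finish_graph(b2, inp2, bn_aff)
  expect_equal(count_parameters(g2), 16)
})

test_that("model size converts parameters at 4 bytes each", {
  expect_equal(model_size_mb(262144), 1)
  expect_equal(model_size_mb(0), 0)
  expect_equal(model_size_mb(1.394e6), 5.318, tolerance = 1e-3)
  expect_equal(model_size_mb(1e6, bytes_per_parameter = 8), 7.629,
               tolerance = 1e-3)
})

test_that("calibrated presets reproduce their frozen complexity figures", {
  # exact regression guard for the calibrated topology
  frozen <- list(
    mifnet10 = c(params = 16342, flops = 5162848),
    mifnet22 = c(params = 87742, flops = 28574368),
    mifnet28 = c(params = 178882, flops = 58403008),
    mifnet34 = c(params = 358726, flops = 117228256),
    mifnet40 = c(params = 715978, flops = 234046720),
    mifnet46 = c(params = 1428046, flops = 466851616),
    mifnet46_wide = c(params = 2500978, flops = 860032960))
  for (nm in names(frozen)) {
    g <- assemble_mifnet(mifnet_preset(nm))
    expect_equal(count_parameters(g), unname(frozen[[nm]]["params"]),
                 info = nm)
    expect_equal(count_flops(g), unname(frozen[[nm]]["flops"]), info = nm)
  }
})

test_that("complexity is monotone in depth, width, fusion and groups", {
  p_of <- function(...) {
    g <- assemble_mifnet(mifnet_config(...))
    c(count_parameters(g), count_flops(g))
  }
  # non-decreasing in the mini-block count
  pk <- sapply(1:4, function(k) p_of(mini_blocks_per_stage = k))
  expect_true(all(diff(t(pk)) > 0))
  # non-decreasing in every width entry
  expect_true(all(p_of(bottleneck_widths = c(8, 16, 32)) > p_of()))
  expect_true(all(p_of(stage_widths = c(32, 64, 128)) > p_of()))
  # non-decreasing in the fusion channel count
  pc <- sapply(1:3, function(C) p_of(fusion_channels = C))
  expect_true(all(diff(t(pc)) > 0))
  # non-increasing in every group entry (grouping compresses the model)
  pg <- sapply(c(1, 2, 4), function(g) p_of(groups = c(g, g, g)))
  expect_true(all(diff(t(pg)) < 0))
})

test_that("complexity report totals equal the per-layer breakdown sums", {
  rep <- complexity_report(mifnet_preset("mifnet10"))
  expect_equal(rep$parameter_count, sum(rep$layers$parameters))
  expect_equal(rep$flops, sum(rep$layers$flops))
  expect_equal(rep$model_size_mb, 4 * rep$parameter_count / 2^20)
  expect_equal(rep$depth, 10L)
  # receptive fields at stage boundaries are increasing
  rfs <- vapply(rep$receptive_fields, `[[`, 0L, "r")
  expect_true(all(diff(rfs) > 0))
  # report writer produces the table and the summary
  stem <- file.path(withr::local_tempdir(), "report")
  write_complexity_report(rep, stem)
  tab <- read.delim(paste0(stem, "_layers.tsv"))
  expect_equal(sum(tab$parameters), rep$parameter_count)
  js <- jsonlite::read_json(paste0(stem, "_summary.json"))
  expect_equal(js$parameter_count, rep$parameter_count)
})
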