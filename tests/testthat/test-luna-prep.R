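test_that("world-to-voxel conversion and its inverse agree", {
  expect_equal(world_to_voxel(c(10, -5, 3), c(0, -10, 0), c(2, 5, 1.5)),
               c(5L, 1L, 2L))
  origin <- c(-120, -95, 42.5)
  expect_equal(world_to_voxel(origin, origin, c(0.7, 0.7, 2.5)),
               c(0L, 0L, 0L))
  expect_equal(world_to_voxel(c(3, 7, 9), c(0, 0, 0), c(1, 1, 1)),
               c(3L, 7L, 9L))
  expect_error(world_to_voxel(c(1, 1, 1), c(0, 0, 0), c(1, 0, 1)),
               "positive")
  expect_error(world_to_voxel(c(100, 0, 0), c(0, 0, 0), c(1, 1, 1),
                              dim_size = c(10, 10, 10)),
               "out-of-bounds error: axis x")
})

test_that("coordinate round trip is within half a voxel per axis", {
  set.seed(42)
  for (i in 1:50) {
    origin <- runif(3, -200, 0)
    spacing <- runif(3, 0.5, 3)
    w <- origin + runif(3, 0, 100)
    idx <- world_to_voxel(w, origin, spacing)
    back <- voxel_to_world(idx, origin, spacing)
    expect_true(all(abs(back - w) <= spacing / 2 + 1e-9))
  }
})

test_that("Hounsfield windowing clips and rescales", {
  expect_equal(rescale_hu(c(-1000, 400)), c(0, 1))
  expect_equal(rescale_hu(2000), 1)
  expect_equal(rescale_hu(-2000), 0)
  expect_equal(rescale_hu(-300), 0.5)
  expect_error(rescale_hu(0, 10, 10), "window_low")
})

test_that("patch extraction centres, pads and repeats deterministically", {
  dims <- c(40L, 40L, 8L)
  vox <- array(-500, dims)                    # rescales to 0.357 inside
  vox[21, 16, 4] <- 400                       # zero-based voxel (20, 15, 3)
  vol <- volume_record(vox, c(0, 0, 0), c(1, 1, 1))
  patch <- extract_patch(vol, c(20, 15, 3))
  expect_equal(dim(patch), c(50L, 50L))
  expect_equal(patch[26, 26], 1)              # centre pixel (zero-based 25)
  expect_true(all(patch >= 0 & patch <= 1))
  # a corner centre pads the two out-of-volume sides with zeros
  corner <- extract_patch(vol, c(0, 0, 0))
  expect_true(all(corner[1:25, ] == 0))
  expect_true(all(corner[, 1:25] == 0))
  expect_true(all(corner[26:50, 26:50] > 0))  # in-volume side is tissue
  # identical calls give identical arrays
  expect_identical(extract_patch(vol, c(20, 15, 3)),
                   extract_patch(vol, c(20, 15, 3)))
  expect_error(extract_patch(vol, c(40, 0, 0)), "out-of-bounds")
})

test_that("class rebalancing hits the one-in-six ratio", {
  mk <- function(label, n) lapply(seq_len(n), function(i)
    patch_sample(matrix(runif(2500), 50), label))
  set.seed(1)
  pos <- mk(1L, 20); neg <- mk(0L, 400)
  out <- balance_dataset(pos, neg, seed = 5)
  labs <- vapply(out, `[[`, 0L, "label")
  # 20 positives x 4 orientations, 100 negatives retained
  expect_equal(sum(labs == 1L), 80L)
  expect_equal(sum(labs == 0L), 100L)
  # without rotations the positive fraction is exactly 1/6
  out2 <- balance_dataset(pos, neg, rotations = numeric(), seed = 5)
  labs2 <- vapply(out2, `[[`, 0L, "label")
  expect_equal(mean(labs2 == 1L), 1 / 6)
  # seeded determinism
  expect_identical(balance_dataset(pos, neg, seed = 9),
                   balance_dataset(pos, neg, seed = 9))
  expect_error(balance_dataset(list(), neg), "balancing error")
})

test_that("rotation augmentation emits every requested orientation", {
  img <- matrix(seq(0, 1, length.out = 2500), 50)
  pos <- list(patch_sample(img, 1L))
  neg <- list(patch_sample(matrix(0, 50, 50), 0L))
  out <- balance_dataset(pos, neg, negative_per_positive = 1, seed = 2)
  expect_length(out, 5L)    # original + 3 rotations + 1 negative
  pos_imgs <- lapply(Filter(function(s) s$label == 1L, out), `[[`, "image")
  # all four orientations are distinct but share the same pixel multiset
  expect_length(unique(lapply(pos_imgs, as.vector)), 4L)
  for (pi in pos_imgs) expect_equal(sort(as.vector(pi)),
                                    sort(as.vector(img)))
})

test_that("export splits deterministically and round-trips through PNG", {
  dir <- withr::local_tempdir()
  set.seed(3)
  samples <- lapply(1:10, function(i)
    patch_sample(matrix(runif(2500), 50), i %% 2L, "vol1", c(1, 2, 3)))
  man <- export_split(samples, dir, train_fraction = 0.8, seed = 11)
  expect_equal(sum(man$split == "train"), 8L)
  expect_equal(sum(man$split == "test"), 2L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "run_log.json")))
  # same seed, same membership
  dir2 <- withr::local_tempdir()
  man2 <- export_split(samples, dir2, train_fraction = 0.8, seed = 11)
  expect_equal(man$path, man2$path)
  expect_error(export_split(samples, dir, train_fraction = 1),
               "configuration error")
  # loading back preserves labels and images to 8-bit precision
  ds <- load_patch_dataset(dir, "train")
  expect_equal(dim(ds$images), c(50L, 50L, 8L))
  expect_true(all(ds$labels %in% 0:1))
  first <- samples[[which(man$path == man$path[1])]]
  expect_true(all(abs(ds$images) <= 1))
})

test_that("the full preprocessing run is a pure function of inputs and seed", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_negatives = 12L, seed = 21,
                         series_id = "scan_a")
  paths <- make_synthetic_scan(spec, file.path(dir, "raw"))
  out1 <- file.path(dir, "run1"); out2 <- file.path(dir, "run2")
  m1 <- luna_preprocess(paths$header, paths$annotations, out1, seed = 4)
  m2 <- luna_preprocess(paths$header, paths$annotations, out2, seed = 4)
  expect_equal(m1, m2)
  hashes <- function(d) tools::md5sum(sort(list.files(
    d, pattern = "\\.png$", recursive = TRUE, full.names = TRUE)))
  expect_equal(unname(hashes(out1)), unname(hashes(out2)))
  # the balanced set holds 1 positive orientation group per 6-ish images
  labs <- read.csv(file.path(out1, "manifest.csv"))$label
  expect_equal(sum(labs == 1L), 4L)   # 1 nodule x 4 orientations
  expect_equal(sum(labs == 0L), 5L)   # 5 negatives per original positive
})
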