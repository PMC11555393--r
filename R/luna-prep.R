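#' @title LUNA16-style patch preprocessing
#' @description
#' The preprocessing pipeline that turns annotated CT volumes into
#' labelled 50x50 grayscale patches: world-to-voxel coordinate
#' conversion, Hounsfield windowing to `[0, 1]`, axial patch cropping at
#' the annotation's slice, class rebalancing by seeded negative
#' undersampling plus rotation augmentation of positives, and a seeded
#' train/test export.
#' @name luna_prep
NULL

#' Convert world (mm) coordinates to voxel indices
#'
#' `index = round((world - origin) / spacing)` per axis.  Indices are
#' zero-based (the origin maps to voxel (0, 0, 0)), in (x, y, z) order.
#' When `dim_size` is supplied, out-of-range indices raise an error
#' naming the offending axis.
#'
#' @param world_xyz numeric triple, mm.
#' @param origin,spacing volume geometry, mm (spacing strictly
#'   positive).
#' @param dim_size optional integer triple of volume extents for bounds
#'   checking.
#' @return integer voxel index triple (zero-based).
#' @examples
#' world_to_voxel(c(10, -5, 3), c(0, -10, 0), c(2, 5, 1.5))  # 5 1 2
#' @export
world_to_voxel <- function(world_xyz, origin, spacing, dim_size = NULL) {
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (any(!is.finite(world_xyz)))
    stop("coordinates must be finite", call. = FALSE)
  idx <- as.integer(round((world_xyz - origin) / spacing))
  if (!is.null(dim_size)) {
    bad <- which(idx < 0L | idx >= dim_size)
    if (length(bad))
      stop("out-of-bounds error: axis ", c("x", "y", "z")[bad[1]],
           " index ", idx[bad[1]], " outside [0, ", dim_size[bad[1]] - 1L,
           "]", call. = FALSE)
  }
  idx
}

#' Inverse map: voxel indices to world coordinates
#' @param voxel_idx integer triple (zero-based).
#' @inheritParams world_to_voxel
#' @return numeric world triple, mm.
#' @export
voxel_to_world <- function(voxel_idx, origin, spacing) {
  origin + voxel_idx * spacing
}

#' Hounsfield windowing
#'
#' Clips to `[window_low, window_high]` and maps affinely to `[0, 1]`.
#' The default window of -1000 to 400 HU spans air to the soft-tissue /
#' bone boundary, the usual lung-CT choice.
#'
#' @param voxels numeric array or vector of Hounsfield units.
#' @param window_low,window_high window bounds, `window_low <
#'   window_high`.
#' @return values in `[0, 1]`, same shape as the input.
#' @examples
#' rescale_hu(c(-1000, -300, 400, 2000))  # 0.0 0.5 1.0 1.0
#' @export
rescale_hu <- function(voxels, window_low = -1000, window_high = 400) {
  if (window_low >= window_high)
    stop("window_low must be < window_high", call. = FALSE)
  (pmin(pmax(voxels, window_low), window_high) - window_low) /
    (window_high - window_low)
}

#' Extract a 50x50 axial patch around a voxel
#'
#' Crops `size` x `size` pixels from the axial slice at the centre's z
#' index, centred so that the centre voxel lands at (zero-based) pixel
#' `(size/2, size/2)`; pixels falling outside the volume are zero.
#' Intensities are Hounsfield-windowed to `[0, 1]` via [rescale_hu()].
#'
#' @param volume a [volume_record()].
#' @param center_voxel zero-based (x, y, z) index; must lie inside the
#'   volume.
#' @param size patch side length, default 50.
#' @param window_low,window_high passed to [rescale_hu()].
#' @return `size` x `size` numeric matrix in `[0, 1]` (rows = x,
#'   columns = y).
#' @export
extract_patch <- function(volume, center_voxel, size = 50L,
                          window_low = -1000, window_high = 400) {
  stopifnot(inherits(volume, "volume_record"))
  d <- dim(volume$voxels)
  cv <- as.integer(center_voxel)
  bad <- which(cv < 0L | cv >= d)
  if (length(bad))
    stop("out-of-bounds error: axis ", c("x", "y", "z")[bad[1]],
         " center ", cv[bad[1]], " outside [0, ", d[bad[1]] - 1L, "]",
         call. = FALSE)
  half <- size %/% 2L
  patch <- matrix(0, size, size)
  # zero-based pixel p maps to voxel center + (p - half)
  xs <- cv[1] + (seq_len(size) - 1L) - half
  ys <- cv[2] + (seq_len(size) - 1L) - half
  okx <- xs >= 0L & xs < d[1]
  oky <- ys >= 0L & ys < d[2]
  slice <- volume$voxels[, , cv[3] + 1L]
  patch[okx, oky] <- rescale_hu(slice[xs[okx] + 1L, ys[oky] + 1L,
                                      drop = FALSE],
                                window_low, window_high)
  patch
}

#' A labelled patch sample
#' @param image `size` x `size` matrix in `[0, 1]`.
#' @param label 0 (benign/negative) or 1 (malignant/nodule).
#' @param series_id,center_voxel provenance.
#' @return list of class `patch_sample`.
#' @export
patch_sample <- function(image, label, series_id = NA_character_,
                         center_voxel = c(NA, NA, NA)) {
  stopifnot(is.matrix(image), label %in% c(0L, 1L))
  if (min(image) < 0 || max(image) > 1)
    stop("patch values must lie in [0, 1]", call. = FALSE)
  structure(list(image = image, label = as.integer(label),
                 series_id = series_id, center_voxel = center_voxel),
            class = "patch_sample")
}

# axis-aligned rotation, counter-clockwise, in multiples of 90 degrees
rotate_image <- function(m, angle) {
  switch(as.character(angle %% 360),
         "0" = m,
         "90" = t(m)[ncol(m):1, , drop = FALSE],
         "180" = m[nrow(m):1, ncol(m):1, drop = FALSE],
         "270" = t(m)[, nrow(m):1, drop = FALSE],
         stop("rotation must be a multiple of 90 degrees", call. = FALSE))
}

#' Rebalance classes by undersampling and rotation augmentation
#'
#' Negatives are uniformly undersampled (seeded) down to
#' `negative_per_positive` per original positive — the default of 5
#' yields one nodule patch in every six images.  Each positive is
#' emitted in its original orientation plus the stated rotations.  The
#' output order is shuffled with the same seed.
#'
#' @param positives,negatives lists of [patch_sample()] objects (each
#'   class non-empty).
#' @param negative_per_positive negatives retained per original
#'   positive, default 5.
#' @param rotations angles (degrees, multiples of 90) applied to each
#'   positive in addition to the original; default `c(90, 180, 270)`.
#' @param seed integer seed fixing the undersampling and the final
#'   shuffle.
#' @return a shuffled list of `patch_sample` objects.
#' @export
balance_dataset <- function(positives, negatives, negative_per_positive = 5,
                            rotations = c(90, 180, 270), seed = 1L) {
  if (length(positives) == 0L || length(negatives) == 0L)
    stop("balancing error: both classes must be non-empty", call. = FALSE)
  set.seed(seed)
  keep <- min(length(negatives),
              as.integer(negative_per_positive * length(positives)))
  neg <- negatives[sort(sample.int(length(negatives), keep))]
  pos <- list()
  for (p in positives) {
    pos <- c(pos, list(p))
    for (ang in rotations) {
      q <- p
      q$image <- rotate_image(p$image, ang)
      pos <- c(pos, list(q))
    }
  }
  out <- c(pos, neg)
  out[sample.int(length(out))]
}

#' Seeded train/test split, written to disk
#'
#' Shuffles with `seed`, splits at `train_fraction`, and writes each
#' patch as an 8-bit grayscale PNG under `out_dir/train` and
#' `out_dir/test`, together with a `manifest.csv` (path, split, label,
#' provenance) and a `run_log.json` recording the seed and paths.
#'
#' @param samples list of [patch_sample()] objects.
#' @param out_dir output directory (created if needed).
#' @param train_fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return invisibly, the manifest data frame.
#' @export
export_split <- function(samples, out_dir, train_fraction = 0.8, seed = 1L) {
  if (length(samples) == 0L) stop("no samples to export", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("configuration error: train_fraction must be in (0, 1)",
         call. = FALSE)
  set.seed(seed)
  ord <- sample.int(length(samples))
  n_train <- round(train_fraction * length(samples))
  dir.create(file.path(out_dir, "train"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "test"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- vector("list", length(samples))
  for (i in seq_along(ord)) {
    s <- samples[[ord[i]]]
    split <- if (i <= n_train) "train" else "test"
    fname <- sprintf("patch_%05d_label%d.png", i, s$label)
    rel <- file.path(split, fname)
    png::writePNG(t(s$image), file.path(out_dir, rel))
    rows[[i]] <- data.frame(path = rel, split = split, label = s$label,
                            series_id = s$series_id,
                            center_x = s$center_voxel[1],
                            center_y = s$center_voxel[2],
                            center_z = s$center_voxel[3])
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = seed, train_fraction = train_fraction,
                            n_train = n_train,
                            n_test = length(samples) - n_train,
                            out_dir = out_dir,
                            timestamp = format(Sys.time(), tz = "UTC")),
                       file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Load an exported patch directory back as a dataset
#'
#' @param dir a directory written by [export_split()].
#' @param split "train" or "test".
#' @return a list with `images` (array `[size, size, n]`) and `labels`,
#'   as consumed by [train()] and [evaluate()].
#' @export
load_patch_dataset <- function(dir, split = c("train", "test")) {
  split <- match.arg(split)
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  manifest <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(manifest) == 0L)
    stop("no ", split, " samples in ", dir, call. = FALSE)
  imgs <- lapply(manifest$path, function(p) t(png::readPNG(file.path(dir, p))))
  list(images = simplify2array(imgs), labels = manifest$label)
}

#' Read a LUNA16-style candidate annotation table
#'
#' Comma-separated columns `seriesuid` (or `series_id`), `coordX`,
#' `coordY`, `coordZ` and `class` (0/1); an optional `diameter_mm`
#' column is carried through.
#'
#' @param path CSV path.
#' @return data frame with columns `series_id`, `x`, `y`, `z`, `label`
#'   (and `diameter` when present).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    stop("annotation file not found: ", path, call. = FALSE)
  a <- utils::read.csv(path)
  id_col <- intersect(c("seriesuid", "series_id"), names(a))[1]
  need <- c(id_col, "coordX", "coordY", "coordZ", "class")
  if (is.na(id_col) || !all(need %in% names(a)))
    stop("format error: annotation table must have seriesuid, coordX, ",
         "coordY, coordZ, class", call. = FALSE)
  out <- data.frame(series_id = as.character(a[[id_col]]),
                    x = a$coordX, y = a$coordY, z = a$coordZ,
                    label = as.integer(a$class))
  if (!all(out$label %in% c(0L, 1L)))
    stop("format error: class column must be 0/1", call. = FALSE)
  if (!all(is.finite(c(out$x, out$y, out$z))))
    stop("format error: non-finite annotation coordinates", call. = FALSE)
  if ("diameter_mm" %in% names(a)) out$diameter <- a$diameter_mm
  out
}

#' End-to-end preprocessing of annotated MetaImage volumes
#'
#' Reads every `.mhd` volume, converts its annotations to voxel indices,
#' crops Hounsfield-windowed 50x50 patches, rebalances classes
#' ([balance_dataset()]) and writes a seeded train/test split
#' ([export_split()]).  The whole run is a pure function of the input
#' files and `seed`.
#'
#' @param headers character vector of `.mhd` paths.
#' @param annotations annotation table path or data frame
#'   ([read_annotations()]).
#' @param out_dir output directory.
#' @param size patch side length, default 50.
#' @param negative_per_positive,rotations,train_fraction,seed see
#'   [balance_dataset()] and [export_split()].
#' @return invisibly, the manifest data frame.
#' @export
luna_preprocess <- function(headers, annotations, out_dir, size = 50L,
                            negative_per_positive = 5,
                            rotations = c(90, 180, 270),
                            train_fraction = 0.8, seed = 1L) {
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  pos <- list(); neg <- list()
  for (hp in headers) {
    vol <- read_metaimage(hp)
    rows <- annotations[annotations$series_id == vol$series_id, ,
                        drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      cv <- world_to_voxel(c(rows$x[r], rows$y[r], rows$z[r]),
                           vol$origin, vol$spacing,
                           dim_size = dim(vol$voxels))
      img <- extract_patch(vol, cv, size = size)
      s <- patch_sample(img, rows$label[r], vol$series_id, cv)
      if (s$label == 1L) pos <- c(pos, list(s)) else neg <- c(neg, list(s))
    }
  }
  balanced <- balance_dataset(pos, neg,
                              negative_per_positive = negative_per_positive,
                              rotations = rotations, seed = seed)
  export_split(balanced, out_dir, train_fraction = train_fraction,
               seed = seed)
}
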