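#' @title Synthetic fixtures
#' @description
#' Desk-scale stand-ins for an annotated CT archive: MetaImage volumes
#' of Gaussian lung-like background with inserted bright spheroid
#' "nodules" plus matching candidate tables (exercising the full
#' preprocessing pipeline), and direct 50x50 labelled patch sets of
#' controllable class separability (exercising training).  All
#' randomness flows from a single integer seed per call; these fixtures
#' make nodule/background discrimination learnable but do not attempt
#' anatomical realism or scanner physics.
#' @name synthetic_data
NULL

#' Specification of a synthetic CT scan
#'
#' @param volume_shape voxels per axis (x, y, z); default `c(64, 64, 16)`.
#' @param spacing mm per voxel (x, y, z); default `c(0.7, 0.7, 2.5)`.
#' @param background_mean,background_sd Gaussian background in
#'   Hounsfield units; the defaults (-800, 50) emulate aerated lung.
#' @param nodules a list of `list(center = world-mm triple, radius =
#'   mm, intensity = HU)` entries.  `intensity` is the additive
#'   amplitude of the spheroid; the default 850 lifts the plateau from
#'   -800 to about +50 HU, i.e. soft-tissue-like.  All nodules must lie
#'   inside the volume.
#' @param n_negatives number of non-nodule candidate points, sampled at
#'   least two radii away from every nodule.
#' @param seed integer fixing every random draw.
#' @param series_id identifier used for file names and annotations.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(volume_shape = c(64L, 64L, 16L),
                           spacing = c(0.7, 0.7, 2.5),
                           background_mean = -800, background_sd = 50,
                           nodules = NULL, n_negatives = 10L, seed = 1L,
                           series_id = "synthetic_scan") {
  if (is.null(nodules)) {
    mid <- (volume_shape - 1) / 2 * spacing
    nodules <- list(list(center = mid, radius = 4, intensity = 850))
  }
  extent <- volume_shape * spacing
  for (nd in nodules) {
    if (nd$radius <= 0) stop("nodule radius must be > 0", call. = FALSE)
    if (any(nd$center < 0) || any(nd$center > extent))
      stop("nodule centre outside the volume", call. = FALSE)
  }
  structure(list(volume_shape = as.integer(volume_shape),
                 spacing = as.numeric(spacing),
                 background_mean = background_mean,
                 background_sd = background_sd,
                 nodules = nodules, n_negatives = as.integer(n_negatives),
                 seed = as.integer(seed), series_id = series_id),
            class = "synthetic_spec")
}

#' Generate a synthetic MetaImage scan plus annotation table
#'
#' Writes `<series_id>.mhd` / `.raw` (MET_SHORT, origin 0) and
#' `<series_id>_annotations.csv` in the LUNA16 candidates dialect
#' (seriesuid, coordX/Y/Z, class): one class-1 row per nodule and
#' `n_negatives` class-0 rows sampled away from all nodules by at least
#' two radii.  Identical seeds give byte-identical payloads.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if needed).
#' @return list with `header`, `raw` and `annotations` paths.
#' @export
make_synthetic_scan <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  d <- spec$volume_shape
  vox <- array(stats::rnorm(prod(d), spec$background_mean,
                            spec$background_sd), d)
  # world coordinate of every voxel centre, per axis
  ax <- lapply(1:3, function(i) (seq_len(d[i]) - 1) * spec$spacing[i])
  for (nd in spec$nodules) {
    dx2 <- (ax[[1]] - nd$center[1])^2
    dy2 <- (ax[[2]] - nd$center[2])^2
    dz2 <- (ax[[3]] - nd$center[3])^2
    dist2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    vox <- vox + nd$intensity * (dist2 <= nd$radius^2)
  }
  vol <- volume_record(vox, origin = c(0, 0, 0), spacing = spec$spacing,
                       series_id = spec$series_id)
  header <- file.path(out_dir, paste0(spec$series_id, ".mhd"))
  write_metaimage(vol, header)
  # annotations: nodules first, then rejection-sampled negatives
  rows <- lapply(spec$nodules, function(nd)
    c(nd$center, 1))
  extent <- d * spec$spacing
  n_acc <- 0L; tries <- 0L
  while (n_acc < spec$n_negatives) {
    tries <- tries + 1L
    if (tries > 10000L)
      stop("could not place negatives away from nodules", call. = FALSE)
    cand <- stats::runif(3) * (extent - spec$spacing) # keep inside bounds
    ok <- all(vapply(spec$nodules, function(nd)
      sqrt(sum((cand - nd$center)^2)) >= 2 * nd$radius, TRUE))
    if (ok) {
      rows <- c(rows, list(c(cand, 0)))
      n_acc <- n_acc + 1L
    }
  }
  tab <- do.call(rbind, rows)
  ann <- data.frame(seriesuid = spec$series_id, coordX = tab[, 1],
                    coordY = tab[, 2], coordZ = tab[, 3],
                    class = as.integer(tab[, 4]))
  ann_path <- file.path(out_dir, paste0(spec$series_id,
                                        "_annotations.csv"))
  utils::write.csv(ann, ann_path, row.names = FALSE)
  list(header = header,
       raw = file.path(out_dir, paste0(spec$series_id, ".raw")),
       annotations = ann_path)
}

# soft disc indicator on a size x size grid, centre (cx, cy) in pixels
disc_mask <- function(size, cx, cy, radius) {
  g <- seq_len(size)
  d2 <- outer((g - cx)^2, (g - cy)^2, `+`)
  d2 <= radius^2
}

#' Generate a labelled 50x50 patch set of controllable separability
#'
#' Positives are Gaussian-noise backgrounds with a centred bright disc
#' (radius uniform in 4-12 px, amplitude `separation * noise_sd`);
#' negatives share the background and carry either nothing or an
#' off-centre low-amplitude distractor disc.  Values are clipped to
#' `[0, 1]`; the classes are exactly balanced, and `separation = 0`
#' makes them identically distributed.
#'
#' @param n_per_class samples per class.
#' @param separation effect size: disc amplitude in units of `noise_sd`.
#'   Default 8 (clearly learnable against the default noise).
#' @param noise_sd background noise standard deviation; default 0.05.
#' @param seed integer seed.
#' @param size patch side length, default 50.
#' @param background_mean mean background intensity, default 0.35.
#' @return list with `images` (array `[size, size, 2n]`), `labels`
#'   (0/1), and `meta` (per-sample disc parameters).
#' @export
make_patch_dataset <- function(n_per_class, separation = 8,
                               noise_sd = 0.05, seed = 1L, size = 50L,
                               background_mean = 0.35) {
  stopifnot(n_per_class >= 1, separation >= 0, noise_sd > 0)
  set.seed(seed)
  n <- 2L * n_per_class
  labels <- rep(c(1L, 0L), n_per_class)
  amp <- separation * noise_sd
  imgs <- array(0, c(size, size, n))
  meta <- data.frame(label = labels, radius = NA_real_,
                     amplitude = NA_real_, cx = NA_real_, cy = NA_real_)
  for (i in seq_len(n)) {
    img <- matrix(stats::rnorm(size * size, background_mean, noise_sd),
                  size, size)
    if (labels[i] == 1L) {
      r <- stats::runif(1, 4, 12)
      ctr <- (size + 1) / 2
      img <- img + amp * disc_mask(size, ctr, ctr, r)
      meta[i, 2:5] <- c(r, amp, ctr, ctr)
    } else if (stats::runif(1) < 0.5) {
      # off-centre, low-amplitude distractor
      r <- stats::runif(1, 2, 5)
      off <- stats::runif(2, 12, 18) * sample(c(-1, 1), 2, replace = TRUE)
      cx <- (size + 1) / 2 + off[1]; cy <- (size + 1) / 2 + off[2]
      img <- img + 0.3 * amp * disc_mask(size, cx, cy, r)
      meta[i, 2:5] <- c(r, 0.3 * amp, cx, cy)
    }
    imgs[, , i] <- pmin(pmax(img, 0), 1)
  }
  ord <- sample.int(n)
  list(images = imgs[, , ord, drop = FALSE], labels = labels[ord],
       meta = meta[ord, ])
}
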