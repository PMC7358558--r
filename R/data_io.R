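# Dataset input: MNIST IDX readers, an IDX writer for fixtures, and a
# deterministic synthetic image-classification task so every part of the
# simulator can be exercised without downloads.

.read_be_int <- function(con, path, what) {
  v <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  if (length(v) == 0) {
    stop(sprintf("truncated IDX file '%s': missing %s at byte %d",
                 path, what, seek(con)))
  }
  v
}

#' Read an MNIST-style IDX image/label pair
#'
#' Parses the big-endian IDX containers (magic 0x00000803 for images,
#' 0x00000801 for labels), scales pixel bytes by 1/255 and cross-checks
#' the sample counts of the two files.
#'
#' @param images_path path to an `idx3-ubyte` image file.
#' @param labels_path path to an `idx1-ubyte` label file.
#' @return dataset list: `images` (samples x pixels, intensities in
#'   `[0, 1]`), `labels` (0-based integers), `nrow`, `ncol`.
#' @export
read_idx <- function(images_path, labels_path) {
  con <- file(images_path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- .read_be_int(con, images_path, "magic number")
  if (magic != 0x00000803L) {
    stop(sprintf("bad image magic number 0x%08x at byte 0 of '%s'",
                 magic, images_path))
  }
  n <- .read_be_int(con, images_path, "image count")
  nr <- .read_be_int(con, images_path, "row count")
  nc <- .read_be_int(con, images_path, "column count")
  bytes <- readBin(con, "integer", n = n * nr * nc, size = 1, signed = FALSE)
  if (length(bytes) < n * nr * nc) {
    stop(sprintf("truncated IDX file '%s': expected %d pixel bytes, found %d",
                 images_path, n * nr * nc, length(bytes)))
  }
  images <- matrix(bytes / 255, nrow = n, byrow = TRUE)

  con2 <- file(labels_path, "rb")
  on.exit(close(con2), add = TRUE)
  magic2 <- .read_be_int(con2, labels_path, "magic number")
  if (magic2 != 0x00000801L) {
    stop(sprintf("bad label magic number 0x%08x at byte 0 of '%s'",
                 magic2, labels_path))
  }
  n2 <- .read_be_int(con2, labels_path, "label count")
  if (n2 != n) {
    stop(sprintf("image/label count mismatch: %d images but %d labels", n, n2))
  }
  labels <- readBin(con2, "integer", n = n2, size = 1, signed = FALSE)
  if (length(labels) < n2) {
    stop(sprintf("truncated IDX file '%s': expected %d label bytes, found %d",
                 labels_path, n2, length(labels)))
  }
  list(images = images, labels = as.integer(labels),
       nrow = nr, ncol = nc)
}

#' Write an IDX image/label pair
#'
#' Inverse of [read_idx()]; used to build small test fixtures.
#'
#' @param dataset list with `images` (intensities in `[0, 1]`), `labels`,
#'   and image dimensions `nrow`, `ncol`.
#' @param images_path,labels_path output paths.
#' @return invisibly, the two paths.
#' @export
write_idx <- function(dataset, images_path, labels_path) {
  n <- nrow(dataset$images)
  con <- file(images_path, "wb")
  writeBin(as.integer(c(0x00000803L, n, dataset$nrow, dataset$ncol)), con,
           size = 4, endian = "big")
  bytes <- as.integer(round(t(dataset$images) * 255))
  writeBin(as.raw(bytes), con)
  close(con)
  con2 <- file(labels_path, "wb")
  writeBin(as.integer(c(0x00000801L, n)), con2, size = 4, endian = "big")
  writeBin(as.raw(dataset$labels), con2)
  close(con2)
  invisible(c(images_path, labels_path))
}

#' Deterministic synthetic image-classification task
#'
#' Generates a linearly separable stand-in for a rate-coded image task:
#' each class has a fixed prototype with a disjoint bright pixel block
#' (intensity `contrast`, background 0), and samples add uniform pixel
#' noise in `[-noise, noise]`, clipped to `[0, 1]`. Balanced classes,
#' deterministic for a seed; at `noise = 0` nearest-prototype
#' classification is perfect. The default contrast and noise put the
#' ideal-device training accuracy high but below ceiling, so that device
#' non-idealities produce measurable degradation rather than disappearing
#' into a saturated task.
#'
#' @param num_classes number of classes (`<= image_side`).
#' @param image_side images are `image_side x image_side`.
#' @param samples_per_class samples per class.
#' @param noise uniform noise half-width in `[0, 1)`.
#' @param contrast prototype bright-pixel intensity in `(0, 1]`.
#' @param seed RNG seed.
#' @return dataset list: `images` (samples x pixels), `labels` (0-based),
#'   `prototypes` (classes x pixels), `nrow`, `ncol`.
#' @export
synth_dataset <- function(num_classes = 3, image_side = 8,
                          samples_per_class = 50, noise = 0.45,
                          contrast = 0.25, seed = 1L) {
  stopifnot(num_classes >= 2, image_side >= 2, samples_per_class >= 1,
            noise >= 0, noise < 1, contrast > 0, contrast <= 1,
            num_classes <= image_side)
  p <- image_side^2
  chunk <- floor(p / num_classes)
  prototypes <- matrix(0, num_classes, p)
  for (k in seq_len(num_classes)) {
    prototypes[k, ((k - 1) * chunk + 1):(k * chunk)] <- contrast
  }
  labels <- rep(seq_len(num_classes) - 1L, each = samples_per_class)
  n <- length(labels)
  with_seed(seed, {
    images <- prototypes[labels + 1L, , drop = FALSE] +
      matrix(stats::runif(n * p, -noise, noise), n, p)
    ord <- sample.int(n)
    list(images = clamp(images, 0, 1)[ord, , drop = FALSE],
         labels = labels[ord], prototypes = prototypes,
         nrow = image_side, ncol = image_side)
  })
}

#' Read a run configuration file
#'
#' Accepts YAML (section per module) or JSON; the two formats round-trip
#' losslessly through [write_run_config()].
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return nested configuration list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Write a run configuration file
#'
#' @param config nested configuration list.
#' @param path output path (`.yaml`/`.yml` or `.json`); written
#'   atomically.
#' @return invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    atomic_write(function(p) jsonlite::write_json(
      config, p, auto_unbox = TRUE, digits = NA, pretty = TRUE), path)
  } else {
    atomic_write(function(p) yaml::write_yaml(config, p), path)
  }
  invisible(path)
}

#' Default run configuration
#'
#' All module parameters at their hardware defaults, as a nested list
#' suitable for [write_run_config()].
#'
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    device = list(mode = "fitted", a_ltp = 2.270, beta_ltp = 1.60,
                  c_ltp = 0.0278, a_ltd = 1.422, beta_ltd = 8.03,
                  c_ltd = 18.25, t_max = 0.1, g_min = 0, g_max = 1),
    variation = list(sigma_p2p = 0, sigma_d2d = 0, stuck_fraction = 0,
                     rng_seed = as.integer(seed)),
    network = list(layer_sizes = c(64, 16, 3), T = 20, v_th = 0.1),
    train = list(epochs = 20, batch_size = 1, kappa_bp = 1,
                 delta_clip = 1, lambda_scale = 10, lr_schedule = list()),
    bias = list(v_s_program = -3.5, v_s_erase = 5,
                v_bg_selected_program = 2, v_bg_selected_erase = -2,
                v_unselected = 0, program_threshold = 5.5,
                erase_threshold = 7),
    dataset = list(kind = "synthetic", num_classes = 3, image_side = 8,
                   samples_per_class = 50, test_samples_per_class = 20,
                   noise = 0.45, contrast = 0.25)
  )
}

# construct module objects from a run-config list
.cfg_device <- function(rc) {
  d <- rc$device
  if (identical(d$mode, "pinned")) {
    pinned_params(d$beta_ltp, d$beta_ltd %||% d$beta_ltp,
                  t_max = d$t_max %||% 1,
                  g_min = d$g_min %||% 0, g_max = d$g_max %||% 1)
  } else {
    device_params(a_ltp = d$a_ltp, beta_ltp = d$beta_ltp, c_ltp = d$c_ltp,
                  a_ltd = d$a_ltd, beta_ltd = d$beta_ltd, c_ltd = d$c_ltd,
                  t_max = d$t_max, g_min = d$g_min, g_max = d$g_max)
  }
}

.cfg_variation <- function(rc) {
  v <- rc$variation
  variation_config(v$sigma_p2p %||% 0, v$sigma_d2d %||% 0,
                   v$stuck_fraction %||% 0, v$rng_seed %||% rc$seed %||% 1L)
}

.cfg_datasets <- function(rc) {
  d <- rc$dataset
  list(train = synth_dataset(d$num_classes, d$image_side,
                             d$samples_per_class, d$noise,
                             d$contrast %||% 0.25,
                             seed = derive_seed(rc$seed, 1L)),
       test = synth_dataset(d$num_classes, d$image_side,
                            d$test_samples_per_class %||% 20, d$noise,
                            d$contrast %||% 0.25,
                            seed = derive_seed(rc$seed, 2L)))
}
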