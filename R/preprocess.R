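# Image/mask preprocessing: max-pool downscaling, center cropping and the
# training-time augmentation recipe (horizontal flip, affine jitter, CLAHE).
#
# Images are plain numeric matrices in [0, 1], row 1 = image top, row index
# increasing inferiorly, 1-based indices.  The physical pixel size travels as
# the "spacing_cm" attribute and in the dataset manifest.

#' @importFrom EBImage affine clahe imageData
#' @importFrom stats runif rnorm
#' @importFrom utils read.csv write.csv head
NULL

#' Physical pixel spacing of an image
#' @param x image matrix.
#' @export
spacing_cm <- function(x) attr(x, "spacing_cm")

#' @rdname spacing_cm
#' @param value spacing in cm/pixel, > 0.
#' @export
`spacing_cm<-` <- function(x, value) {
  if (!is.null(value) && (!is.numeric(value) || value <= 0))
    stop("spacing must be > 0")
  attr(x, "spacing_cm") <- value
  x
}

#' Downscale an image by non-overlapping max pooling
#'
#' Each `kernel x kernel` window (stride = kernel) is replaced by its maximum,
#' preserving thin bright structures — the property that makes max pooling
#' preferable to mean pooling when shrinking radiographs containing a
#' few-pixel-wide tube.  Trailing rows/columns that do not fill a complete
#' window are dropped; pixel spacing is multiplied by the kernel size.
#'
#' @param image numeric matrix.
#' @param kernel window size, >= 1 (the study uses 3).
#' @return The pooled matrix with updated `spacing_cm`.
#' @export
downscale_maxpool <- function(image, kernel = 3) {
  if (kernel < 1 || kernel != round(kernel)) stop("`kernel` must be a positive integer")
  if (kernel > nrow(image) || kernel > ncol(image))
    stop("`kernel` (", kernel, ") exceeds image dimensions (",
         nrow(image), "x", ncol(image), ")")
  k <- as.integer(kernel)
  if (k == 1) return(image)
  nr <- nrow(image) %/% k; nc <- ncol(image) %/% k
  m <- image[seq_len(nr * k), seq_len(nc * k), drop = FALSE]
  out <- matrix(-Inf, nr, nc)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    out <- pmax(out, m[seq(di, by = k, length.out = nr),
                       seq(dj, by = k, length.out = nc), drop = FALSE])
  }
  sp <- spacing_cm(image)
  if (!is.null(sp)) spacing_cm(out) <- sp * k
  out
}

#' Crop an image (and optionally its mask) about the image center
#'
#' The `size[1] x size[2]` window is placed with top-left corner
#' `floor(dims/2) - floor(size/2)` (0-based arithmetic), i.e. centred at the
#' floor-division midpoint; the identical window is applied to the mask.  No
#' padding: the crop must fit.
#'
#' @param image numeric matrix.
#' @param mask optional binary matrix of the same shape.
#' @param size crop size, scalar or `(rows, cols)`.
#' @return `list(image, mask, offset)` where `offset = c(row, col)` is the
#'   0-based top-left corner: a tip at `(r, c)` in the original maps to
#'   `(r - offset[1], c - offset[2])` in the crop.
#' @export
center_crop <- function(image, mask = NULL, size) {
  size <- rep(as.integer(size), length.out = 2)
  d <- dim(image)
  if (any(size > d)) stop("crop size (", paste(size, collapse = "x"),
                          ") exceeds image dimensions (",
                          paste(d, collapse = "x"), ")")
  if (!is.null(mask) && !identical(dim(mask), d))
    stop("mask shape must equal image shape")
  top0 <- d %/% 2L - size %/% 2L        # 0-based top-left corner
  ri <- top0[1] + seq_len(size[1])
  ci <- top0[2] + seq_len(size[2])
  out <- image[ri, ci, drop = FALSE]
  spacing_cm(out) <- spacing_cm(image)
  list(image = out,
       mask = if (!is.null(mask)) mask[ri, ci, drop = FALSE],
       offset = top0)
}

#' Augmentation parameters
#'
#' The training-time recipe: horizontal flip with probability 0.5, then one
#' affine transform (scale uniform in 85--115%, rotation uniform in ±5
#' degrees, translation uniform in ±10% of each dimension), then CLAHE on the
#' image only (clip limit uniform in (1, 4)) with probability 0.7.  The same
#' geometric transform and the same random draws are applied to image and
#' mask; the mask is resampled nearest-neighbour and stays binary.
#'
#' @param hflip_prob probability of a horizontal flip.
#' @param scale_range uniform scale range.
#' @param rotate_deg rotation drawn uniformly in `[-rotate_deg, rotate_deg]`.
#' @param shift_frac translation drawn uniformly in
#'   `[-shift_frac, shift_frac]` of each image dimension.
#' @param clahe_clip_range uniform range for the CLAHE clip limit.
#' @param clahe_prob probability of applying CLAHE.
#' @param seed optional seed; if supplied, [augment()] re-seeds the RNG so the
#'   same parameters always produce the same transform.
#' @export
augment_params <- function(hflip_prob = 0.5, scale_range = c(0.85, 1.15),
                           rotate_deg = 5, shift_frac = 0.1,
                           clahe_clip_range = c(1, 4), clahe_prob = 0.7,
                           seed = NULL) {
  stopifnot(hflip_prob >= 0, hflip_prob <= 1, clahe_prob >= 0,
            clahe_prob <= 1, length(scale_range) == 2,
            length(clahe_clip_range) == 2, shift_frac >= 0, rotate_deg >= 0)
  structure(list(hflip_prob = hflip_prob, scale_range = scale_range,
                 rotate_deg = rotate_deg, shift_frac = shift_frac,
                 clahe_clip_range = clahe_clip_range,
                 clahe_prob = clahe_prob, seed = seed),
            class = "augment_params")
}

# 3x2 affine matrix in (row, col) index coordinates: p' = (p - c) M + c + t.
affine_matrix <- function(d, scale, theta, shift) {
  M <- scale * matrix(c(cos(theta), -sin(theta),
                        sin(theta),  cos(theta)), 2, 2, byrow = TRUE)
  cc <- (d + 1) / 2
  t <- cc - cc %*% M + shift
  rbind(M, t)
}

#' Jointly augment an image and its mask
#'
#' Draws flip / scale / rotation / shift / CLAHE from the current RNG stream
#' (or from `params$seed` when set) and applies them consistently: bilinear
#' interpolation for the image, nearest-neighbour for the mask, constant-zero
#' border fill, CLAHE (8x8 tiles) on the image only.  An all-zero mask passes
#' through with unchanged (empty) geometry.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param mask binary matrix of the same shape.
#' @param params an [augment_params()].
#' @return `list(image, mask)`; the mask is re-binarized to 0/1.
#' @export
augment <- function(image, mask, params = augment_params()) {
  if (!identical(dim(image), dim(mask))) stop("image/mask shapes differ")
  if (!is.null(params$seed)) set.seed(params$seed)
  d <- dim(image)
  do_flip <- runif(1) < params$hflip_prob
  scale <- runif(1, params$scale_range[1], params$scale_range[2])
  theta <- runif(1, -params$rotate_deg, params$rotate_deg) * pi / 180
  shift <- runif(2, -params$shift_frac, params$shift_frac) * d
  clip <- runif(1, params$clahe_clip_range[1], params$clahe_clip_range[2])
  do_clahe <- runif(1) < params$clahe_prob

  if (do_flip) {                         # flip around the vertical axis
    image <- image[, rev(seq_len(d[2])), drop = FALSE]
    mask <- mask[, rev(seq_len(d[2])), drop = FALSE]
  }
  m <- affine_matrix(d, scale, theta, shift)
  identity_tf <- scale == 1 && theta == 0 && all(shift == 0)
  if (!identity_tf) {
    image <- imageData(affine(image, m, filter = "bilinear", bg.col = 0,
                              antialias = FALSE))
    mask <- imageData(affine(mask, m, filter = "none", bg.col = 0,
                             antialias = FALSE))
  }
  if (do_clahe) {
    # CLAHE expects intensities in [0, 1]; 8x8 tile grid, 256 bins.
    image <- imageData(clahe(pmin(pmax(image, 0), 1), nx = 8, ny = 8,
                             limit = clip))
  }
  list(image = pmin(pmax(image, 0), 1), mask = (mask > 0.5) * 1)
}

# ---- manifest + PNG I/O --------------------------------------------------

#' Read or write a dataset manifest
#'
#' The manifest CSV carries one row per image with columns `image_id`,
#' `image_path`, `mask_path`, `tip_row`, `tip_col` (1-based pixel coordinates
#' of the ground-truth tube tip) and `spacing_cm` (physical pixel size).
#' Paths are stored relative to the manifest's directory and resolved on
#' read.
#'
#' @param path manifest CSV path.
#' @return A data frame with absolute `image_path` / `mask_path`.
#' @export
read_manifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "mask_path", "tip_row", "tip_col", "spacing_cm")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest is missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(man$image_id))
    man$image_id <- sub("\\.png$", "", basename(man$image_path))
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", man$image_path)
  man$image_path[rel] <- file.path(base, man$image_path[rel])
  rel <- !grepl("^(/|[A-Za-z]:)", man$mask_path)
  man$mask_path[rel] <- file.path(base, man$mask_path[rel])
  man
}

#' @rdname read_manifest
#' @param manifest manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write grayscale PNG images
#'
#' Thin wrappers over \pkg{png} keeping the `[0, 1]` intensity convention and
#' the `spacing_cm` attribute.
#'
#' @param path PNG file path.
#' @param spacing optional cm/pixel to attach on read.
#' @export
read_image_png <- function(path, spacing = NULL) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  if (!is.null(spacing)) spacing_cm(x) <- spacing
  x
}

#' @rdname read_image_png
#' @param image matrix in `[0, 1]`.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Load one manifest row as an image/mask/tip sample
#'
#' @param row one-row slice of a manifest data frame.
#' @return `list(image, mask, tip, image_id)` where `tip` is a [tip_point()].
#' @export
load_sample <- function(row) {
  img <- read_image_png(row$image_path, spacing = row$spacing_cm)
  msk <- (read_image_png(row$mask_path) > 0.5) * 1
  list(image = img, mask = msk,
       tip = tip_point(row$tip_row, row$tip_col, row$spacing_cm),
       image_id = row$image_id)
}
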