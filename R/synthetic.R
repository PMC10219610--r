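# Synthetic radiograph-like tube phantoms.
#
# Each phantom is a dark, smoothly varying background carrying a single
# bright, thin, curved tube (a quadratic Bezier from the top edge down to the
# tip), optional bright distractor artifacts, and additive Gaussian noise.
# The mask is the rasterized tube; the ground-truth tip is the mask's most
# inferior pixel under the same rule extract_tip() uses, so generator and
# evaluator agree exactly.  The geometry/contrast/imbalance regime (a tube a
# few pixels wide covering ~1% of the image) reproduces the class imbalance
# that motivates the Focal/Tversky/MCC loss comparison; no anatomical
# simulation is attempted.

#' Phantom generation parameters
#'
#' @param image_size `(rows, cols)` of the generated image.
#' @param tube_width_px integer range of tube widths (>= 1).
#' @param tube_start_col_frac range of the tube's entry column at the top
#'   edge, as a fraction of image width.
#' @param curvature control-point jitter of the quadratic curve, as a
#'   fraction of image width (larger = more bowed tubes).
#' @param tip_row_frac range of the tip row as a fraction of image height
#'   (the tube's length).
#' @param tube_contrast range of added tube intensity over the background.
#' @param background_level `c(base, amplitude)`: base intensity and the
#'   amplitude of the smooth low-frequency background variation.
#' @param noise_sigma additive Gaussian noise scale (>= 0).
#' @param distractor_count number of non-tube bright artifacts (short line
#'   segments and soft blobs).  Distractors never enter the region just above
#'   and around the tube tip, so the ground-truth tip stays unambiguous.
#' @param spacing_cm physical pixel size in cm.
#' @param seed default seed for [generate_phantom()].
#' @export
phantom_params <- function(image_size = c(96, 96), tube_width_px = c(2, 4),
                           tube_start_col_frac = c(0.35, 0.65),
                           curvature = 0.2, tip_row_frac = c(0.55, 0.9),
                           tube_contrast = c(0.35, 0.6),
                           background_level = c(0.15, 0.08),
                           noise_sigma = 0.03, distractor_count = 2,
                           spacing_cm = 0.05, seed = 1) {
  stopifnot(length(image_size) == 2, all(image_size >= 16),
            all(tube_width_px >= 1), noise_sigma >= 0,
            distractor_count >= 0, spacing_cm > 0,
            min(tip_row_frac) > 0, max(tip_row_frac) < 1,
            min(tube_start_col_frac) > 0, max(tube_start_col_frac) < 1)
  structure(list(image_size = as.integer(image_size),
                 tube_width_px = as.integer(tube_width_px),
                 tube_start_col_frac = tube_start_col_frac,
                 curvature = curvature, tip_row_frac = tip_row_frac,
                 tube_contrast = tube_contrast,
                 background_level = background_level,
                 noise_sigma = noise_sigma,
                 distractor_count = as.integer(distractor_count),
                 spacing_cm = spacing_cm, seed = as.integer(seed)),
            class = "phantom_params")
}

# 8-neighbour binary dilation by one pixel.
dilate1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ri <- pmin(pmax(seq_len(d[1]) + di, 1), d[1])
    ci <- pmin(pmax(seq_len(d[2]) + dj, 1), d[2])
    out <- pmax(out, mask[ri, ci, drop = FALSE])
  }
  out
}

#' Generate one tube phantom
#'
#' Deterministic given `seed`: the same seed always reproduces the identical
#' sample bit-for-bit.
#'
#' @param params a [phantom_params()].
#' @param seed seed for this sample (default `params$seed`).
#' @return `list(image, mask, tip, background, seed)`: image in `[0, 1]` with
#'   `spacing_cm` set, binary mask (a single 8-connected component), the
#'   ground-truth [tip_point()] (the mask's most inferior pixel), and the
#'   noise-free, tube-free background field for diagnostics.
#' @export
generate_phantom <- function(params = phantom_params(), seed = params$seed) {
  set.seed(seed)
  H <- params$image_size[1]; W <- params$image_size[2]
  width <- if (params$tube_width_px[1] == params$tube_width_px[2])
    params$tube_width_px[1] else
      sample(params$tube_width_px[1]:params$tube_width_px[2], 1)
  margin <- width + 2

  c0 <- runif(1, params$tube_start_col_frac[1],
              params$tube_start_col_frac[2]) * W
  r2 <- round(runif(1, params$tip_row_frac[1], params$tip_row_frac[2]) * H)
  c2 <- c0 + runif(1, -params$curvature, params$curvature) * W
  c1 <- (c0 + c2) / 2 + runif(1, -params$curvature, params$curvature) * W
  c0 <- min(max(c0, margin), W - margin)
  c1 <- min(max(c1, margin), W - margin)
  c2 <- min(max(c2, margin), W - margin)
  r0 <- 1; r1 <- (r0 + r2) / 2          # monotone row profile: no dip below tip

  tt <- seq(0, 1, length.out = 4L * H)
  br <- (1 - tt)^2 * r0 + 2 * tt * (1 - tt) * r1 + tt^2 * r2
  bc <- (1 - tt)^2 * c0 + 2 * tt * (1 - tt) * c1 + tt^2 * c2
  pr <- pmin(pmax(round(br), 1), H)
  pc <- pmin(pmax(round(bc), 1), W)

  mask <- matrix(0, H, W)
  rad <- width / 2
  for (di in -floor(rad):floor(rad)) for (dj in -floor(rad):floor(rad)) {
    if (di^2 + dj^2 > rad^2 + 1e-9) next
    rr <- pr + di; cc <- pc + dj
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    mask[cbind(rr[ok], cc[ok])] <- 1
  }

  # smooth low-frequency background: a few random cosine modes
  base <- params$background_level[1]; amp <- params$background_level[2]
  rn <- seq_len(H) / H; cn <- seq_len(W) / W
  bg <- matrix(0, H, W)
  for (m in 1:3) {
    fr <- runif(1, 0.5, 2); fc <- runif(1, 0.5, 2); ph <- runif(1, 0, 2 * pi)
    bg <- bg + outer(rn, cn, function(a, b) cos(2 * pi * (fr * a + fc * b) + ph))
  }
  bg <- base + amp * bg / 3

  contrast <- runif(1, params$tube_contrast[1], params$tube_contrast[2])
  feather <- dilate1(mask) - mask
  tube_field <- contrast * mask + 0.5 * contrast * feather

  # distractors: bright artifacts kept away from the tip neighbourhood
  tube_cols <- range(which(colSums(mask) > 0))
  forbidden <- function(r, c)
    r > r2 - 0.1 * H & c >= tube_cols[1] - 3 & c <= tube_cols[2] + 3
  distract <- matrix(0, H, W)
  n_placed <- 0
  while (n_placed < params$distractor_count) {
    n_placed <- n_placed + 1
    if (runif(1) < 0.5) {               # short bright line segment
      len <- runif(1, 5, 15); ang <- runif(1, 0, pi)
      rr0 <- runif(1, 5, H - 5); cc0 <- runif(1, 5, W - 5)
      s <- seq(-len / 2, len / 2, by = 0.5)
      rr <- round(rr0 + s * sin(ang)); cc <- round(cc0 + s * cos(ang))
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W & !forbidden(rr, cc)
      if (any(ok))
        distract[cbind(rr[ok], cc[ok])] <-
          pmax(distract[cbind(rr[ok], cc[ok])], runif(1, 0.25, 0.5))
    } else {                            # soft Gaussian blob
      sg <- runif(1, 2, 5); ampb <- runif(1, 0.15, 0.35)
      rr0 <- runif(1, 5, H - 5); cc0 <- runif(1, 5, W - 5)
      fld <- ampb * outer(seq_len(H), seq_len(W), function(a, b)
        exp(-((a - rr0)^2 + (b - cc0)^2) / (2 * sg^2)))
      fld[outer(seq_len(H), seq_len(W), forbidden)] <- 0
      distract <- pmax(distract, fld)
    }
  }

  noise <- if (params$noise_sigma > 0)
    matrix(rnorm(H * W, 0, params$noise_sigma), H, W) else 0
  img <- pmin(pmax(bg + tube_field + distract + noise, 0), 1)
  spacing_cm(img) <- params$spacing_cm

  tip <- extract_tip(mask, threshold = 0.5, spacing = params$spacing_cm)
  list(image = img, mask = mask, tip = tip, background = bg, seed = seed)
}

derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1009 + i * 9973) %% 2147483629)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` 8-bit PNG image/mask pairs plus the manifest CSV (columns
#' `image_id`, `image_path`, `mask_path`, `tip_row`, `tip_col`, `spacing_cm`,
#' `seed`).  Per-sample seeds are derived deterministically from `seed`, so
#' any single sample can be regenerated in isolation with
#' `generate_phantom(params, seed = manifest$seed[i])`.
#'
#' @param n number of phantoms (>= 1).
#' @param params a [phantom_params()].
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @return The manifest data frame (with paths resolved), invisibly also
#'   written to `<out_dir>/manifest.csv`.
#' @export
generate_dataset <- function(n, params = phantom_params(), out_dir,
                             seed = params$seed) {
  stopifnot(n >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- derive_seed(seed, i)
    ph <- generate_phantom(params, seed = s)
    id <- sprintf("phantom_%04d", i)
    write_image_png(ph$image, file.path(out_dir, paste0(id, ".png")))
    write_image_png(ph$mask, file.path(out_dir, paste0(id, "_mask.png")))
    rows[[i]] <- data.frame(image_id = id,
                            image_path = paste0(id, ".png"),
                            mask_path = paste0(id, "_mask.png"),
                            tip_row = ph$tip$row, tip_col = ph$tip$col,
                            spacing_cm = params$spacing_cm, seed = s,
                            stringsAsFactors = FALSE)
  }
  man <- do.call(rbind, rows)
  write_manifest(man, file.path(out_dir, "manifest.csv"))
  read_manifest(file.path(out_dir, "manifest.csv"))
}
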