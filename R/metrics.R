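# Evaluation of tube segmentation (IOU) and tip localization (Euclidean tip
# distance in cm, and PSE — the percentage of samples with error below a
# threshold).

#' Tube tip location
#'
#' @param row,col 1-based pixel coordinates of the tube's inferior endpoint.
#' @param spacing physical pixel size in cm (isotropic), > 0.
#' @param failed set for the sentinel returned when no tip could be
#'   extracted.
#' @return A `tip_point` object.
#' @export
tip_point <- function(row, col, spacing, failed = FALSE) {
  if (!failed) {
    stopifnot(is.finite(row), is.finite(col), row >= 1, col >= 1)
  }
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  structure(list(row = row, col = col, spacing = spacing,
                 failed = isTRUE(failed)),
            class = "tip_point")
}

#' @export
print.tip_point <- function(x, ...) {
  if (x$failed) cat("<tip_point> extraction failed\n")
  else cat(sprintf("<tip_point> (%g, %g), %g cm/px\n", x$row, x$col,
                   x$spacing))
  invisible(x)
}

check_binary_mask <- function(x, name) {
  if (any(x != 0 & x != 1))
    stop("`", name, "` must be binary (0/1)")
  invisible(x)
}

#' Intersection over union of two binary masks
#'
#' `|A intersect B| / |A union B|`; two empty masks agree perfectly and score
#' 1.  Identical to `1 - jaccard_loss(smooth = 0)` on hard masks.
#'
#' @param pred,truth binary matrices of equal shape.
#' @return Score in `[0, 1]`.
#' @export
iou <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("mask shapes differ")
  check_binary_mask(pred, "pred"); check_binary_mask(truth, "truth")
  inter <- sum(pred * truth)
  uni <- sum(pred) + sum(truth) - inter
  if (uni == 0) return(1)
  inter / uni
}

# 8-connected component labelling of a binary mask (breadth-first over the
# foreground only; tube masks are sparse so this is cheap).
label_components8 <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  fg <- which(mask != 0)
  if (!length(fg)) return(lab)
  nb <- c(-1L, 1L, -d[1], d[1], -d[1] - 1L, -d[1] + 1L, d[1] - 1L, d[1] + 1L)
  cur <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      rows <- (frontier - 1L) %% d[1] + 1L
      cand <- rep(frontier, each = 8L) + rep(nb, times = length(frontier))
      rr <- rep(rows, each = 8L) + rep(c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L),
                                       times = length(frontier))
      ok <- cand >= 1L & cand <= length(lab) & rr >= 1L & rr <= d[1]
      cand <- unique(cand[ok])
      cand <- cand[mask[cand] != 0 & lab[cand] == 0L]
      lab[cand] <- cur
      frontier <- cand
    }
  }
  lab
}

#' Extract the tube tip from a probability map
#'
#' Binarizes at `threshold`, keeps the largest 8-connected component, and
#' takes the most inferior pixel (maximal row index) as the tip —
#' anatomically the endotracheal tube descends the trachea, so its inferior
#' endpoint is the tip.  Row ties are broken by the lower median column.  If
#' no pixel exceeds the threshold, an explicit failure sentinel is returned
#' (downstream the distance is recorded as `Inf`), not an error.
#'
#' @param prob numeric matrix of per-pixel tube probabilities.
#' @param threshold binarization threshold in `(0, 1)`.
#' @param spacing cm per pixel carried onto the returned [tip_point()];
#'   defaults to the `spacing_cm` attribute of `prob`.
#' @return A [tip_point()] (check `$failed`).
#' @export
extract_tip <- function(prob, threshold = 0.5, spacing = spacing_cm(prob)) {
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  if (is.null(spacing)) stop("no pixel spacing supplied")
  bin <- prob > threshold
  if (!any(bin)) return(tip_point(NA, NA, spacing, failed = TRUE))
  lab <- label_components8(bin * 1)
  sizes <- tabulate(lab[lab > 0L])
  comp <- which(lab == which.max(sizes), arr.ind = TRUE)
  rmax <- max(comp[, 1])
  cols <- sort(unname(comp[comp[, 1] == rmax, 2]))
  tip_point(unname(rmax), cols[(length(cols) + 1L) %/% 2L], spacing)
}

#' Euclidean distance between two tips, in cm
#'
#' `spacing * sqrt((row2-row1)^2 + (col2-col1)^2)`.  Both points must share
#' the same pixel spacing; a failed extraction on either side yields `Inf`.
#'
#' @param pred,truth [tip_point()] objects.
#' @export
tip_distance <- function(pred, truth) {
  if (abs(pred$spacing - truth$spacing) > 1e-12)
    stop("tip points have mismatched pixel spacing")
  if (pred$failed || truth$failed) return(Inf)
  pred$spacing * sqrt((pred$row - truth$row)^2 + (pred$col - truth$col)^2)
}

#' Percentage of samples with error below a threshold (PSE)
#'
#' `100 * #(d < value) / n` over a vector of tip distances; extraction
#' failures enter as `Inf`, counting in the denominator only.  The inequality
#' is strict.
#'
#' @param distances numeric vector of tip distances in cm (may contain
#'   `Inf`).
#' @param value threshold in cm, > 0.
#' @return Percentage in `[0, 100]`.
#' @export
pse <- function(distances, value) {
  if (!length(distances)) stop("`distances` must be nonempty")
  if (value <= 0) stop("`value` must be > 0")
  if (any(is.na(distances)) || any(distances < 0))
    stop("`distances` must be nonnegative (Inf allowed for failures)")
  100 * sum(distances < value) / length(distances)
}

#' PSE at the standard thresholds
#'
#' Evaluates [pse()] at the five reporting thresholds
#' `{0.25, 0.5, 1, 1.5, 2}` cm.  Columns are nondecreasing in the threshold
#' by construction.
#'
#' @inheritParams pse
#' @param thresholds thresholds in cm.
#' @return Named numeric vector of percentages.
#' @export
pse_table <- function(distances, thresholds = c(0.25, 0.5, 1, 1.5, 2)) {
  out <- vapply(thresholds, function(v) pse(distances, v), numeric(1))
  names(out) <- paste0("lt_", thresholds)
  out
}
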