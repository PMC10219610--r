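#' @useDynLib ettseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats plogis qlogis
NULL

# ---- numerics -----------------------------------------------------------

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
log_sigmoid <- function(x) -softplus(-x)

#' Bundle logits and probabilities for the segmentation losses
#'
#' The distribution-based losses ([bce_loss()], [focal_loss()]) evaluate the
#' numerically stable fused sigmoid form and therefore want raw logits, while
#' the region-based losses and [mcc_loss()] operate on probabilities.  A
#' `prediction_batch` carries both views so any loss (and any compound of the
#' two families) can be evaluated on the same prediction.
#'
#' @param logits real-valued per-pixel scores (any array shape); probabilities
#'   are derived as `plogis(logits)`.
#' @param probs per-pixel probabilities in `[0, 1]`; logits are derived via the
#'   logit transform with probabilities clamped away from 0/1 at `1e-12`.
#'   Supply exactly one of `logits` and `probs`.
#' @return An object of class `prediction_batch` with elements `logits` and
#'   `probs` of identical shape.
#' @examples
#' p <- prediction_batch(logits = matrix(0, 4, 4))
#' range(p$probs)  # all 0.5
#' @export
prediction_batch <- function(logits = NULL, probs = NULL) {
  if (is.null(logits) == is.null(probs))
    stop("supply exactly one of `logits` and `probs`")
  if (is.null(logits)) {
    if (any(probs < 0 | probs > 1)) stop("`probs` must lie in [0, 1]")
    logits <- qlogis(pmin(pmax(probs, 1e-12), 1 - 1e-12))
    attributes(logits) <- attributes(probs)
  } else {
    if (any(!is.finite(logits))) stop("`logits` must be finite")
    probs <- plogis(logits)
    attributes(probs) <- attributes(logits)
  }
  structure(list(logits = logits, probs = probs), class = "prediction_batch")
}

# Coerce `pred` to a prediction_batch; a bare numeric array is interpreted as
# `default` ("logits" for BCE/Focal, "probs" for MCC and the region losses).
as_prediction <- function(pred, default) {
  if (inherits(pred, "prediction_batch")) return(pred)
  if (!is.numeric(pred)) stop("`pred` must be numeric or a prediction_batch")
  if (default == "logits") prediction_batch(logits = pred)
  else prediction_batch(probs = pred)
}

check_target <- function(pred, target) {
  pd <- dim(pred$probs) %||% length(pred$probs)
  td <- dim(target) %||% length(target)
  if (!identical(as.integer(pd), as.integer(td)))
    stop("prediction and target shapes differ (",
         paste(pd, collapse = "x"), " vs ", paste(td, collapse = "x"), ")")
  if (any(target != 0 & target != 1))
    stop("target must be binary (every element exactly 0 or 1)")
  invisible(target)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# View an array as (pixels, batch-elements): the last margin of a >=3-d array
# is the batch; a matrix or vector is a single element.
as_elem_matrix <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) <= 2) return(matrix(as.numeric(x), ncol = 1))
  matrix(as.numeric(x), ncol = d[length(d)])
}

reduce_loss <- function(per_pixel, reduction) {
  m <- as_elem_matrix(per_pixel)
  per_elem <- colMeans(m)
  switch(reduction,
         mean = mean(per_elem),
         sum  = sum(per_elem),
         none = per_elem,
         stop("`reduction` must be one of 'mean', 'sum', 'none'"))
}

# ---- distribution-based losses ------------------------------------------

#' Binary cross-entropy loss with fused sigmoid
#'
#' Per-pixel loss \eqn{-[p_c\, y \log\sigma(x) + (1-y)\log(1-\sigma(x))]}
#' evaluated from logits through the log-sum-exp form, so it does not overflow
#' for arbitrarily large scores.  `pos_weight` (\eqn{p_c}) rescales the
#' positive class: values above 1 trade precision for recall, which matters
#' for thin structures such as an endotracheal tube occupying ~1% of pixels.
#'
#' @param pred a [prediction_batch()] or a numeric array of logits.
#' @param target binary array of the same shape.
#' @param pos_weight positive-class weight, > 0.
#' @param reduction `"mean"` (default; mean over per-batch-element means),
#'   `"sum"`, or `"none"` (one value per batch element, the last array margin).
#' @return A numeric scalar, or a vector for `reduction = "none"`.
#' @examples
#' y <- matrix(rbinom(16, 1, 0.5), 4)
#' bce_loss(matrix(0, 4, 4), y)  # log(2)
#' @family segmentation losses
#' @export
bce_loss <- function(pred, target, pos_weight = 1, reduction = "mean") {
  pred <- as_prediction(pred, "logits")
  check_target(pred, target)
  if (!is.numeric(pos_weight) || length(pos_weight) != 1 || pos_weight <= 0)
    stop("`pos_weight` must be a single value > 0")
  x <- pred$logits
  l <- pos_weight * target * softplus(-x) + (1 - target) * softplus(x)
  reduce_loss(l, reduction)
}

#' Focal loss
#'
#' Dynamically scaled cross-entropy \eqn{-(1-p_t)^\gamma \log p_t}, where
#' \eqn{p_t} is the predicted probability of the true class.  The modulating
#' factor suppresses the contribution of well-classified pixels, concentrating
#' the gradient on hard (typically foreground) pixels under severe class
#' imbalance.  With `gamma = 0` it reduces exactly to unweighted
#' [bce_loss()].
#'
#' @inheritParams bce_loss
#' @param gamma focusing parameter, >= 0 (default 2).
#' @family segmentation losses
#' @export
focal_loss <- function(pred, target, gamma = 2, reduction = "mean") {
  pred <- as_prediction(pred, "logits")
  check_target(pred, target)
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0)
    stop("`gamma` must be a single value >= 0")
  x <- pred$logits
  log_pt <- ifelse(target == 1, log_sigmoid(x), log_sigmoid(-x))
  pt <- exp(log_pt)
  l <- -(1 - pt)^gamma * log_pt
  reduce_loss(l, reduction)
}

mcc_terms <- function(p, y) {
  list(TP = sum(p * y), FP = sum(p * (1 - y)),
       FN = sum((1 - p) * y), TN = sum((1 - p) * (1 - y)))
}

#' Matthews correlation coefficient loss
#'
#' Soft-confusion MCC: with \eqn{TP=\sum py}, \eqn{FP=\sum p(1-y)},
#' \eqn{FN=\sum(1-p)y}, \eqn{TN=\sum(1-p)(1-y)} accumulated over the whole
#' batch, \deqn{MCC = \frac{TP\,TN - FP\,FN}
#' {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN) + \epsilon}}}
#' and the loss is \eqn{1 - MCC \in [0, 2]}.  MCC is a balanced summary of
#' the full confusion matrix, informative even when one class dominates.  For
#' an all-one-class target the product under the root vanishes and the
#' \eqn{\epsilon} guard yields MCC = 0 (loss 1); this is a documented
#' degenerate value, not an error.
#'
#' @param pred a [prediction_batch()] or a numeric array of probabilities.
#' @param target binary array of the same shape.
#' @param epsilon guard added under the square root, > 0.
#' @family segmentation losses
#' @export
mcc_loss <- function(pred, target, epsilon = 1e-6) {
  pred <- as_prediction(pred, "probs")
  check_target(pred, target)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0)
    stop("`epsilon` must be a single value > 0")
  t <- mcc_terms(pred$probs, target)
  num <- t$TP * t$TN - t$FP * t$FN
  den <- sqrt((t$TP + t$FP) * (t$TP + t$FN) *
              (t$TN + t$FP) * (t$TN + t$FN) + epsilon)
  1 - num / den
}

# ---- region-based losses ------------------------------------------------

region_sums <- function(pred, target, per_image, f) {
  if (!per_image) return(f(pred, target))
  pm <- as_elem_matrix(pred); tm <- as_elem_matrix(target)
  mean(vapply(seq_len(ncol(pm)), function(k) f(pm[, k], tm[, k]), numeric(1)))
}

#' Dice loss
#'
#' `1 - (2*sum(y*p) + smooth) / (sum(y) + sum(p) + smooth)`, the soft Dice
#' overlap complement.  The smoothing constant (default 1) appears in both
#' numerator and denominator so that an exactly-correct all-background
#' prediction scores a perfect 0 rather than 0/0.
#'
#' @inheritParams mcc_loss
#' @param smooth smoothing constant, >= 0.
#' @param per_image if `TRUE`, compute the loss per batch element and average;
#'   the default pools the sums over the whole batch as one set, which
#'   stabilizes images with very small foregrounds.
#' @family segmentation losses
#' @export
dice_loss <- function(pred, target, smooth = 1, per_image = FALSE) {
  pred <- as_prediction(pred, "probs")
  check_target(pred, target)
  if (smooth < 0) stop("`smooth` must be >= 0")
  region_sums(pred$probs, target, per_image, function(p, y)
    1 - (2 * sum(y * p) + smooth) / (sum(y) + sum(p) + smooth))
}

#' Jaccard loss
#'
#' `1 - (I + smooth) / (U + smooth)` with soft intersection `I = sum(y*p)` and
#' soft union `U = sum(y) + sum(p) - I`; the direct complement of the IOU
#' score used to evaluate segmentation quality.
#'
#' @inheritParams dice_loss
#' @family segmentation losses
#' @export
jaccard_loss <- function(pred, target, smooth = 1, per_image = FALSE) {
  pred <- as_prediction(pred, "probs")
  check_target(pred, target)
  if (smooth < 0) stop("`smooth` must be >= 0")
  region_sums(pred$probs, target, per_image, function(p, y) {
    i <- sum(y * p); u <- sum(y) + sum(p) - i
    1 - (i + smooth) / (u + smooth)
  })
}

#' Tversky loss
#'
#' `1 - (TP + smooth) / (TP + alpha*FP + beta*FN + smooth)` with soft
#' confusion sums.  Unequal `alpha`/`beta` weight false positives against
#' false negatives; `beta > alpha` (default 0.3/0.7) penalizes missed tube
#' pixels harder, the usual choice for small-foreground segmentation.  With
#' `alpha = beta = 0.5` and matched smoothing it coincides with [dice_loss()].
#'
#' @inheritParams dice_loss
#' @param alpha false-positive weight, > 0.
#' @param beta false-negative weight, > 0.
#' @family segmentation losses
#' @export
tversky_loss <- function(pred, target, alpha = 0.3, beta = 0.7, smooth = 1,
                         per_image = FALSE) {
  pred <- as_prediction(pred, "probs")
  check_target(pred, target)
  if (alpha <= 0 || beta <= 0) stop("`alpha` and `beta` must be > 0")
  if (smooth < 0) stop("`smooth` must be >= 0")
  region_sums(pred$probs, target, per_image, function(p, y) {
    tp <- sum(y * p); fp <- sum((1 - y) * p); fn <- sum(y * (1 - p))
    1 - (tp + smooth) / (tp + alpha * fp + beta * fn + smooth)
  })
}

# ---- loss specifications and compounds ----------------------------------

DIST_FAMILIES <- c("bce", "focal", "mcc")
REGION_FAMILIES <- c("dice", "jaccard", "tversky")

#' Declarative specification of a single or compound loss
#'
#' @param family one of `"bce"`, `"focal"`, `"mcc"`, `"dice"`, `"jaccard"`,
#'   `"tversky"`, `"compound"`.
#' @param gamma,alpha,beta,smooth,pos_weight,epsilon hyperparameters forwarded
#'   to the member losses (see their help pages for meaning and defaults).
#' @param components for `family = "compound"`: exactly one distribution
#'   family (`bce`/`focal`/`mcc`) paired with one region family
#'   (`dice`/`jaccard`/`tversky`), in either order.
#' @param weights nonnegative mixing weights `(distribution, region)` for
#'   compound losses; default the unweighted sum `c(1, 1)`.
#' @param per_image see [dice_loss()].
#' @return A `loss_spec` object usable with [evaluate_loss()] and
#'   [make_compound_loss()].
#' @seealso [parse_loss()] for the `"mcc-tversky"` string grammar.
#' @export
loss_spec <- function(family, gamma = 2, alpha = 0.3, beta = 0.7, smooth = 1,
                      pos_weight = 1, epsilon = 1e-6, components = NULL,
                      weights = c(1, 1), per_image = FALSE) {
  family <- match.arg(family,
                      c(DIST_FAMILIES, REGION_FAMILIES, "compound"))
  if (gamma < 0) stop("`gamma` must be >= 0")
  if (alpha <= 0 || beta <= 0) stop("`alpha` and `beta` must be > 0")
  if (smooth < 0) stop("`smooth` must be >= 0")
  if (pos_weight <= 0) stop("`pos_weight` must be > 0")
  if (family == "compound") {
    if (is.null(components) || length(components) != 2)
      stop("a compound loss needs exactly two `components`")
    components <- match.arg(components, c(DIST_FAMILIES, REGION_FAMILIES),
                            several.ok = TRUE)
    d <- components[components %in% DIST_FAMILIES]
    r <- components[components %in% REGION_FAMILIES]
    if (length(d) != 1 || length(r) != 1)
      stop("compound components must pair one distribution loss (",
           paste(DIST_FAMILIES, collapse = "/"), ") with one region loss (",
           paste(REGION_FAMILIES, collapse = "/"), "), got: ",
           paste(components, collapse = ", "))
    components <- c(d, r)
    if (length(weights) != 2 || any(weights < 0))
      stop("`weights` must be two nonnegative numbers")
  } else if (!is.null(components)) {
    stop("`components` is only meaningful for family = 'compound'")
  }
  structure(list(family = family, gamma = gamma, alpha = alpha, beta = beta,
                 smooth = smooth, pos_weight = pos_weight, epsilon = epsilon,
                 components = components, weights = weights,
                 per_image = per_image),
            class = "loss_spec")
}

#' @export
print.loss_spec <- function(x, ...) {
  cat("<loss_spec>", loss_name(x), "\n")
  invisible(x)
}

#' Parse a loss name string into a loss specification
#'
#' Accepts the six single-loss names and the nine compound names written as
#' `"<distribution>-<region>"` (or with `_`), e.g. `"dice"`, `"mcc-tversky"`,
#' `"BCE_Jaccard"`.  Case-insensitive.  Extra arguments are forwarded to
#' [loss_spec()].
#'
#' @param name loss name string.
#' @param ... hyperparameters passed to [loss_spec()].
#' @export
parse_loss <- function(name, ...) {
  parts <- tolower(strsplit(gsub("_", "-", trimws(name)), "-")[[1]])
  if (length(parts) == 1) return(loss_spec(parts, ...))
  if (length(parts) == 2)
    return(loss_spec("compound", components = parts, ...))
  stop("cannot parse loss name: ", name)
}

#' @rdname parse_loss
#' @param spec a `loss_spec`.
#' @export
loss_name <- function(spec) {
  if (spec$family == "compound") paste(spec$components, collapse = "-")
  else spec$family
}

#' Names of all fifteen study losses
#'
#' The six single losses plus the nine distribution-by-region compounds.
#' @export
all_loss_names <- function() {
  c(DIST_FAMILIES, REGION_FAMILIES,
    as.vector(outer(DIST_FAMILIES, REGION_FAMILIES, paste, sep = "-")))
}

eval_single <- function(family, spec, pred, target) {
  switch(family,
         bce = bce_loss(pred, target, spec$pos_weight),
         focal = focal_loss(pred, target, spec$gamma),
         mcc = mcc_loss(pred, target, spec$epsilon),
         dice = dice_loss(pred, target, spec$smooth, spec$per_image),
         jaccard = jaccard_loss(pred, target, spec$smooth, spec$per_image),
         tversky = tversky_loss(pred, target, spec$alpha, spec$beta,
                                spec$smooth, spec$per_image))
}

#' Evaluate any loss specification
#'
#' @param spec a [loss_spec()] (or loss name string, parsed via
#'   [parse_loss()]).
#' @param pred a [prediction_batch()], or a numeric array (interpreted as
#'   logits for distribution losses and probabilities for region losses; for
#'   compound losses a bare array must be a `prediction_batch` to avoid
#'   ambiguity, unless it already is one).
#' @param target binary array.
#' @return Scalar loss value.
#' @export
evaluate_loss <- function(spec, pred, target) {
  if (is.character(spec)) spec <- parse_loss(spec)
  if (spec$family != "compound") {
    return(eval_single(spec$family, spec, pred, target))
  }
  pred <- as_prediction(pred, "logits")
  spec$weights[1] * eval_single(spec$components[1], spec, pred, target) +
    spec$weights[2] * eval_single(spec$components[2], spec, pred, target)
}

#' Build a compound (distribution + region) loss function
#'
#' Returns a callable `f(pred, target)` computing
#' `weights[1] * L_distribution + weights[2] * L_region` on the same
#' prediction.  All nine pairs of the two families are constructible.
#'
#' @param spec a [loss_spec()] with `family = "compound"`.
#' @export
make_compound_loss <- function(spec) {
  if (is.character(spec)) spec <- parse_loss(spec)
  if (spec$family != "compound")
    stop("`spec` must have family = 'compound'")
  force(spec)
  function(pred, target) evaluate_loss(spec, pred, target)
}

# ---- values + gradients (training path) ---------------------------------

# Gradient of each loss w.r.t. the logits, under "mean" reduction for the
# pixel-wise losses and the batch-as-one-set convention for the others.
# Returns list(value, grad) with grad shaped like `logits`.
loss_value_grad <- function(spec, logits, target) {
  if (is.character(spec)) spec <- parse_loss(spec)
  p <- plogis(logits)
  vg_single <- function(family) {
    switch(family,
      bce = {
        pw <- spec$pos_weight
        l <- pw * target * softplus(-logits) + (1 - target) * softplus(logits)
        g <- (-pw * target * (1 - p) + (1 - target) * p) / length(logits)
        list(value = mean(l), grad = g)
      },
      focal = {
        gam <- spec$gamma
        log_pt <- ifelse(target == 1, log_sigmoid(logits),
                         log_sigmoid(-logits))
        pt <- exp(log_pt)
        l <- -(1 - pt)^gam * log_pt
        core <- gam * pt * (1 - pt)^gam * log_pt - (1 - pt)^(gam + 1)
        g <- ifelse(target == 1, core, -core) / length(logits)
        list(value = mean(l), grad = g)
      },
      mcc = {
        y <- target
        TP <- sum(p * y); FP <- sum(p * (1 - y))
        FN <- sum((1 - p) * y); TN <- sum((1 - p) * (1 - y))
        S1 <- TP + FP; S2 <- TP + FN; S3 <- TN + FP; S4 <- TN + FN
        num <- TP * TN - FP * FN
        den <- sqrt(S1 * S2 * S3 * S4 + spec$epsilon)
        dden <- c(TP = (S2 * S3 * S4 + S1 * S3 * S4),
                  TN = (S1 * S2 * S4 + S1 * S2 * S3),
                  FP = (S2 * S3 * S4 + S1 * S2 * S4),
                  FN = (S1 * S3 * S4 + S1 * S2 * S3)) / (2 * den)
        dnum <- c(TP = TN, TN = TP, FP = -FN, FN = -FP)
        dmcc <- (dnum * den - num * dden) / den^2
        dp <- -(dmcc["TP"] * y + dmcc["FP"] * (1 - y) -
                  dmcc["FN"] * y - dmcc["TN"] * (1 - y))
        list(value = 1 - num / den, grad = dp * p * (1 - p))
      },
      dice = {
        s <- spec$smooth
        i <- sum(target * p); a <- sum(target) + sum(p)
        dp <- -(2 * target * (a + s) - (2 * i + s)) / (a + s)^2
        list(value = 1 - (2 * i + s) / (a + s), grad = dp * p * (1 - p))
      },
      jaccard = {
        s <- spec$smooth
        i <- sum(target * p); u <- sum(target) + sum(p) - i
        dp <- -(target * (u + s) - (i + s) * (1 - target)) / (u + s)^2
        list(value = 1 - (i + s) / (u + s), grad = dp * p * (1 - p))
      },
      tversky = {
        s <- spec$smooth; a <- spec$alpha; b <- spec$beta
        tp <- sum(target * p); fp <- sum((1 - target) * p)
        fn <- sum(target * (1 - p))
        den <- tp + a * fp + b * fn + s
        dden_dp <- target + a * (1 - target) - b * target
        dp <- -(target * den - (tp + s) * dden_dp) / den^2
        list(value = 1 - (tp + s) / den, grad = dp * p * (1 - p))
      })
  }
  if (spec$family != "compound") {
    out <- vg_single(spec$family)
  } else {
    d <- vg_single(spec$components[1])
    r <- vg_single(spec$components[2])
    out <- list(value = spec$weights[1] * d$value + spec$weights[2] * r$value,
                grad = spec$weights[1] * d$grad + spec$weights[2] * r$grad)
  }
  attributes(out$grad) <- attributes(logits)
  out
}
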