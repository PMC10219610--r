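# Brute-force oracles, written as plain per-pixel loops independent of the
# package's vectorized implementations, plus small fixture helpers.

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# per-pixel BCE summed then averaged
oracle_bce <- function(logits, target, pos_weight = 1) {
  tot <- 0
  for (i in seq_along(logits)) {
    s <- oracle_sigmoid(logits[i])
    tot <- tot + (-(pos_weight * target[i] * log(s) +
                      (1 - target[i]) * log(1 - s)))
  }
  tot / length(logits)
}

oracle_focal <- function(logits, target, gamma) {
  tot <- 0
  for (i in seq_along(logits)) {
    s <- oracle_sigmoid(logits[i])
    pt <- if (target[i] == 1) s else 1 - s
    tot <- tot + (-(1 - pt)^gamma * log(pt))
  }
  tot / length(logits)
}

# 2x2 confusion counts on hard predictions
oracle_confusion <- function(pred, target) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && target[i] == 1) tp <- tp + 1
    else if (pred[i] == 1 && target[i] == 0) fp <- fp + 1
    else if (pred[i] == 0 && target[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# textbook Matthews correlation from counts (0 when undefined)
oracle_phi <- function(cf) {
  den <- sqrt((cf$tp + cf$fp)) * sqrt((cf$tp + cf$fn)) *
    sqrt((cf$tn + cf$fp)) * sqrt((cf$tn + cf$fn))
  if (den == 0) return(0)
  (cf$tp * cf$tn - cf$fp * cf$fn) / den
}

oracle_soft_mcc <- function(probs, target, eps = 1e-6) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(probs)) {
    tp <- tp + probs[i] * target[i]
    fp <- fp + probs[i] * (1 - target[i])
    fn <- fn + (1 - probs[i]) * target[i]
    tn <- tn + (1 - probs[i]) * (1 - target[i])
  }
  (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn) + eps)
}

oracle_dice_loss <- function(probs, target, smooth) {
  num <- 0; dy <- 0; dp <- 0
  for (i in seq_along(probs)) {
    num <- num + probs[i] * target[i]
    dy <- dy + target[i]; dp <- dp + probs[i]
  }
  1 - (2 * num + smooth) / (dy + dp + smooth)
}

oracle_jaccard_loss <- function(probs, target, smooth) {
  inter <- 0; dy <- 0; dp <- 0
  for (i in seq_along(probs)) {
    inter <- inter + probs[i] * target[i]
    dy <- dy + target[i]; dp <- dp + probs[i]
  }
  1 - (inter + smooth) / (dy + dp - inter + smooth)
}

oracle_tversky_loss <- function(probs, target, alpha, beta, smooth) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(probs)) {
    tp <- tp + probs[i] * target[i]
    fp <- fp + probs[i] * (1 - target[i])
    fn <- fn + (1 - probs[i]) * target[i]
  }
  1 - (tp + smooth) / (tp + alpha * fp + beta * fn + smooth)
}

# random logits/targets batch of shape (r, c, 1, n)
rand_batch <- function(r = 8, c = 8, n = 2, p_fg = 0.3) {
  list(logits = array(rnorm(r * c * n, sd = 2), c(r, c, 1, n)),
       target = array(rbinom(r * c * n, 1, p_fg), c(r, c, 1, n)))
}

# small fast phantom settings for pipeline smoke tests
small_phantom_params <- function(size = 32, seed = 1) {
  phantom_params(image_size = c(size, size), tube_width_px = c(2, 3),
                 tip_row_frac = c(0.55, 0.85), seed = seed)
}

make_samples <- function(n, params, seed = 1) {
  lapply(seq_len(n), function(i) {
    ph <- generate_phantom(params, seed = seed + i)
    ph$image_id <- sprintf("s%03d", i)
    ph
  })
}
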