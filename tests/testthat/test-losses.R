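# Single and compound segmentation losses against brute-force oracles,
# closed-form identities and their documented invariants.

test_that("single losses agree with brute-force per-pixel oracles", {
  set.seed(101)
  for (rep in 1:20) {
    b <- rand_batch()
    probs <- plogis(b$logits)
    expect_lt(abs(bce_loss(b$logits, b$target, pos_weight = 2) -
                    oracle_bce(b$logits, b$target, 2)), 1e-10)
    expect_lt(abs(focal_loss(b$logits, b$target, gamma = 2) -
                    oracle_focal(b$logits, b$target, 2)), 1e-10)
    expect_lt(abs(mcc_loss(probs, b$target) -
                    (1 - oracle_soft_mcc(probs, b$target))), 1e-10)
    expect_lt(abs(dice_loss(probs, b$target, smooth = 1) -
                    oracle_dice_loss(probs, b$target, 1)), 1e-10)
    expect_lt(abs(jaccard_loss(probs, b$target, smooth = 1) -
                    oracle_jaccard_loss(probs, b$target, 1)), 1e-10)
    expect_lt(abs(tversky_loss(probs, b$target, 0.3, 0.7, smooth = 1) -
                    oracle_tversky_loss(probs, b$target, 0.3, 0.7, 1)), 1e-10)
  }
})

test_that("hand-computed example values are reproduced", {
  y <- matrix(c(1, 0, 0, 1), 2)
  # logits 0 everywhere: -log(0.5) per pixel
  expect_equal(bce_loss(matrix(0, 2, 2), y), log(2), tolerance = 1e-12)
  # saturated correct logits: essentially zero
  expect_lt(bce_loss(ifelse(y == 1, 50, -50), y), 1e-10)
  # focal at p_t = 0.5, gamma = 2: (0.5)^2 * log 2
  expect_equal(focal_loss(matrix(0, 1, 1), matrix(1, 1, 1), gamma = 2),
               0.25 * log(2), tolerance = 1e-12)
  # inverted probabilities: total disagreement, MCC -> -1
  set.seed(7)
  t8 <- matrix(rbinom(64, 1, 0.4), 8)
  expect_equal(mcc_loss(1 - t8, t8), 2, tolerance = 1e-6)
  # dice: 4 true, hard prediction overlapping 2 + 2 spurious -> 1 - 4/8
  yt <- matrix(0, 4, 4); yt[1, 1:4] <- 1
  pp <- matrix(0, 4, 4); pp[1, 1:2] <- 1; pp[3, 1:2] <- 1
  expect_equal(dice_loss(pp, yt, smooth = 0), 0.5)
  # jaccard: |I| = 2, |U| = 6
  expect_equal(jaccard_loss(pp, yt, smooth = 0), 1 - 2 / 6)
  # tversky: TP=3, FP=1, FN=2 at alpha 0.3, beta 0.7
  yt2 <- matrix(0, 4, 4); yt2[1:5] <- 1
  pt2 <- matrix(0, 4, 4); pt2[c(1, 2, 3, 6)] <- 1
  expect_equal(tversky_loss(pt2, yt2, 0.3, 0.7, smooth = 0),
               1 - 3 / (3 + 0.3 * 1 + 0.7 * 2), tolerance = 1e-12)
})

test_that("losses vanish on perfect hard predictions", {
  set.seed(11)
  y <- array(rbinom(128, 1, 0.3), c(8, 8, 1, 2))
  pred <- prediction_batch(probs = y)
  for (nm in all_loss_names())
    expect_lt(evaluate_loss(nm, pred, y), 1e-6)
  # all-background: default smoothing resolves the empty-foreground 0/0 for
  # the region losses; BCE/Focal are zero termwise
  y0 <- array(0, c(8, 8, 1, 2))
  p0 <- prediction_batch(probs = y0)
  for (nm in c("bce", "focal", "dice", "jaccard", "tversky",
               "bce-dice", "bce-jaccard", "bce-tversky",
               "focal-dice", "focal-jaccard", "focal-tversky"))
    expect_lt(evaluate_loss(nm, p0, y0), 1e-6)
  # MCC on a one-class target is the documented epsilon-guard degenerate
  # value (correlation 0, loss 1), not an error
  expect_equal(mcc_loss(y0, y0), 1, tolerance = 1e-9)
})

test_that("closed-form reduction identities hold", {
  set.seed(42)
  diffs <- replicate(200, {
    b <- rand_batch()
    abs(focal_loss(b$logits, b$target, gamma = 0) -
          bce_loss(b$logits, b$target, pos_weight = 1))
  })
  expect_lt(max(diffs), 1e-5)
  for (rep in 1:25) {
    b <- rand_batch()
    p <- plogis(b$logits)
    # tversky with alpha = beta = 1/2 and smooth s equals dice with smooth 2s
    expect_equal(tversky_loss(p, b$target, 0.5, 0.5, smooth = 0.5),
                 dice_loss(p, b$target, smooth = 1), tolerance = 1e-6)
    expect_equal(tversky_loss(p, b$target, 0.5, 0.5, smooth = 0),
                 dice_loss(p, b$target, smooth = 0), tolerance = 1e-6)
  }
})

test_that("hard-prediction mcc equals one minus the confusion-matrix phi", {
  set.seed(13)
  for (rep in 1:25) {
    pred <- matrix(rbinom(64, 1, 0.5), 8)
    targ <- matrix(rbinom(64, 1, 0.4), 8)
    phi <- oracle_phi(oracle_confusion(pred, targ))
    expect_equal(mcc_loss(pred, targ), 1 - phi, tolerance = 1e-6)
  }
})

test_that("dice and jaccard similarities obey the 2J/(1+J) relation", {
  set.seed(29)
  for (rep in 1:100) {
    pred <- matrix(rbinom(64, 1, 0.4), 8)
    targ <- matrix(rbinom(64, 1, 0.4), 8)
    if (sum(pred) + sum(targ) == 0) next
    jsim <- 1 - jaccard_loss(pred, targ, smooth = 0)
    dsim <- 1 - dice_loss(pred, targ, smooth = 0)
    expect_equal(dsim, 2 * jsim / (1 + jsim), tolerance = 1e-9)
  }
})

test_that("loss values respect their ranges and permutation invariance", {
  set.seed(3)
  for (rep in 1:20) {
    b <- rand_batch()
    p <- plogis(b$logits)
    vals <- c(bce = bce_loss(b$logits, b$target),
              focal = focal_loss(b$logits, b$target),
              mcc = mcc_loss(p, b$target),
              dice = dice_loss(p, b$target),
              jaccard = jaccard_loss(p, b$target),
              tversky = tversky_loss(p, b$target))
    expect_true(all(vals >= 0))
    expect_true(all(vals[c("dice", "jaccard", "tversky")] <= 1))
    expect_lte(vals["mcc"], 2)
    # shuffling pixels identically leaves every loss unchanged
    perm <- sample(length(b$logits))
    lp <- array(b$logits[perm], dim(b$logits))
    tp <- array(b$target[perm], dim(b$target))
    vals2 <- c(bce = bce_loss(lp, tp), focal = focal_loss(lp, tp),
               mcc = mcc_loss(plogis(lp), tp),
               dice = dice_loss(plogis(lp), tp),
               jaccard = jaccard_loss(plogis(lp), tp),
               tversky = tversky_loss(plogis(lp), tp))
    expect_equal(vals, vals2, tolerance = 1e-10)
  }
})

test_that("bce remains finite and stable at extreme logits", {
  y <- matrix(c(1, 0), 1)
  x <- matrix(c(-100, 100), 1)    # worst case: confidently wrong
  expect_true(is.finite(bce_loss(x, y)))
  expect_equal(bce_loss(x, y), 100, tolerance = 1e-9)
  expect_true(is.finite(focal_loss(x, y, gamma = 2)))
})

test_that("analytic loss gradients match finite differences", {
  set.seed(17)
  x <- array(rnorm(16), c(4, 4, 1, 1))
  y <- array(rbinom(16, 1, 0.4), c(4, 4, 1, 1))
  for (nm in c("bce", "focal", "mcc", "dice", "jaccard", "tversky",
               "bce-dice", "mcc-tversky", "focal-jaccard")) {
    spec <- parse_loss(nm)
    g <- ettseg:::loss_value_grad(spec, x, y)$grad
    for (i in c(1, 7, 16)) {
      eps <- 1e-6
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      fd <- (evaluate_loss(spec, prediction_batch(logits = xp), y) -
               evaluate_loss(spec, prediction_batch(logits = xm), y)) / (2 * eps)
      expect_equal(g[i], fd, tolerance = 1e-3,
                   label = paste("grad", nm, "at", i))
    }
  }
})

test_that("compound losses combine their components as specified", {
  set.seed(23)
  b <- rand_batch()
  pred <- prediction_batch(logits = b$logits)
  # all nine pairs are constructible
  combos <- expand.grid(d = c("bce", "focal", "mcc"),
                        r = c("dice", "jaccard", "tversky"),
                        stringsAsFactors = FALSE)
  for (q in seq_len(nrow(combos))) {
    f <- make_compound_loss(paste0(combos$d[q], "-", combos$r[q]))
    expect_true(is.finite(f(pred, b$target)))
  }
  # weights (1,0) degenerate to the distribution component
  s10 <- loss_spec("compound", components = c("bce", "dice"),
                   weights = c(1, 0))
  expect_equal(evaluate_loss(s10, pred, b$target),
               bce_loss(pred, b$target), tolerance = 1e-12)
  # unweighted sum equals independently computed components
  s11 <- loss_spec("compound", components = c("mcc", "tversky"))
  expect_equal(evaluate_loss(s11, pred, b$target),
               mcc_loss(pred, b$target) + tversky_loss(pred, b$target),
               tolerance = 1e-9)
  # region term vanishes at a perfect hard prediction
  yh <- b$target
  ph <- prediction_batch(logits = ifelse(yh == 1, 50, -50))
  expect_equal(evaluate_loss(parse_loss("bce-dice"), ph, yh),
               bce_loss(ph, yh), tolerance = 1e-10)
})

test_that("loss specifications validate their contracts", {
  expect_error(loss_spec("compound", components = c("dice", "tversky")),
               "distribution")
  expect_error(loss_spec("compound", components = c("bce", "focal")),
               "region")
  expect_error(loss_spec("compound", components = "dice"), "two")
  expect_error(loss_spec("focal", gamma = -1), "gamma")
  expect_error(loss_spec("tversky", alpha = 0), "alpha")
  expect_error(loss_spec("dice", smooth = -0.1), "smooth")
  expect_error(bce_loss(matrix(0, 2, 2), matrix(0.5, 2, 2)), "binary")
  expect_error(bce_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(tversky_loss(matrix(0.5, 2, 2), matrix(1, 2, 2), beta = -1),
               "beta")
  # string grammar
  expect_equal(loss_name(parse_loss("MCC_Tversky")), "mcc-tversky")
  expect_equal(parse_loss("dice")$family, "dice")
  expect_length(all_loss_names(), 15)
})

test_that("reduction modes are consistent", {
  set.seed(5)
  b <- rand_batch(n = 3)
  per_elem <- bce_loss(b$logits, b$target, reduction = "none")
  expect_length(per_elem, 3)
  expect_equal(mean(per_elem), bce_loss(b$logits, b$target, reduction = "mean"))
  expect_equal(sum(per_elem), bce_loss(b$logits, b$target, reduction = "sum"))
})
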