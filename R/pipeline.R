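# Training / evaluation orchestration: k-fold cross-validation splits,
# per-loss training runs with Adam, and the comparison report (per-loss IOU,
# tip distance and PSE, with group averages for the region, distribution and
# compound loss families).

#' k-fold cross-validation splits
#'
#' Shuffles the ids with `seed` and partitions them into `k` near-equal
#' blocks; fold `i` uses block `i` as test set, block `(i mod k) + 1` as
#' validation set and the remainder as training set, which at `k = 5` yields
#' the usual ~60/20/20 proportions.  Every id is tested exactly once across
#' folds.
#'
#' @param ids character or integer vector of image ids (`length(ids) >= k`).
#' @param k number of folds (>= 2).
#' @param seed shuffle seed.
#' @return List of `k` fold splits, each
#'   `list(fold_index, train_ids, val_ids, test_ids)`.
#' @export
kfold_split <- function(ids, k = 5, seed = 1) {
  if (k < 2 || k != round(k)) stop("`k` must be an integer >= 2")
  if (length(ids) < k) stop("need at least `k` ids (", length(ids),
                            " < ", k, ")")
  if (anyDuplicated(ids)) stop("`ids` must be unique")
  set.seed(seed)
  shuffled <- sample(ids)
  sizes <- rep(length(ids) %/% k, k) + (seq_len(k) <= length(ids) %% k)
  block <- rep(seq_len(k), times = sizes)
  lapply(seq_len(k), function(i) {
    v <- (i %% k) + 1L
    list(fold_index = i,
         train_ids = shuffled[block != i & block != v],
         val_ids = shuffled[block == v],
         test_ids = shuffled[block == i])
  })
}

snapshot_model <- function(model) list(params = model$params,
                                       bn_state = model$bn_state)

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

batch_tensor <- function(mats) {
  d <- dim(mats[[1]])
  array(unlist(mats, use.names = FALSE), c(d[1], d[2], 1, length(mats)))
}

#' Train a U-Net++ segmenter under a given loss
#'
#' Optimizes the model with Adam on (optionally augmented) training samples,
#' logging per-epoch mean training loss and validation IOU, and keeps the
#' weights of the epoch with the best validation IOU.  Everything — weight
#' initialization, data order, augmentation draws — is derived from `seed`,
#' so two runs with the same seed produce identical results on one CPU
#' thread.
#'
#' @param train_samples,val_samples lists of samples
#'   (`list(image, mask, tip, image_id)`, as produced by [load_sample()] or
#'   [generate_phantom()]).
#' @param loss a [loss_spec()] or loss name string.
#' @param model_config a [unetpp_config()].
#' @param epochs,batch_size,lr optimizer settings (defaults: 10 epochs,
#'   batch 4, Adam at 1e-3 — the desk-scale profile).
#' @param aug an [augment_params()] applied to training samples only, or
#'   `NULL` for none.
#' @param clip_norm global gradient-norm ceiling: if the concatenated
#'   gradient's L2 norm exceeds it, all gradients are rescaled to that norm
#'   before the Adam step (the standard guard against the occasional
#'   destabilizing step; `Inf` disables).
#' @param threshold binarization threshold for the validation IOU.
#' @param seed master seed for the run.
#' @param checkpoint_path optional path; if given, the best model is saved
#'   there with [save_checkpoint()].
#' @param verbose print per-epoch progress.
#' @return `list(model, log, loss)`: the best model, a data frame
#'   `(epoch, train_loss, val_iou)`, and the loss spec used.
#' @export
train_segmenter <- function(train_samples, val_samples, loss,
                            model_config = unetpp_config(),
                            epochs = 10, batch_size = 4, lr = 1e-3,
                            aug = NULL, clip_norm = 5, threshold = 0.5,
                            seed = 1, checkpoint_path = NULL,
                            verbose = FALSE) {
  if (is.character(loss)) loss <- parse_loss(loss)
  if (epochs < 1) stop("`epochs` must be >= 1")
  if (!length(train_samples)) stop("no training samples")
  model_config$seed <- as.integer(seed)
  model <- build_unetpp(model_config)
  opt <- adam_init(model$params)
  set.seed(seed + 1L)

  n <- length(train_samples)
  log_rows <- vector("list", epochs)
  best <- snapshot_model(model); best_iou <- -Inf; best_epoch <- 0L

  for (epoch in seq_len(epochs)) {
    ord <- sample(n)
    losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      imgs <- vector("list", length(idx)); msks <- vector("list", length(idx))
      for (q in seq_along(idx)) {
        s <- train_samples[[idx[q]]]
        if (!is.null(aug)) {
          a <- augment(s$image, s$mask, aug)
          imgs[[q]] <- a$image; msks[[q]] <- a$mask
        } else {
          imgs[[q]] <- s$image; msks[[q]] <- s$mask
        }
      }
      x <- batch_tensor(imgs); y <- batch_tensor(msks)
      fw <- unetpp_forward_full(model, x, train = TRUE)
      model$bn_state <- fw$bn_state
      nh <- length(fw$logits)
      batch_loss <- 0; dlogits <- list()
      for (h in names(fw$logits)) {
        vg <- loss_value_grad(loss, fw$logits[[h]], y)
        batch_loss <- batch_loss + vg$value / nh
        dlogits[[h]] <- vg$grad / nh
      }
      if (!is.finite(batch_loss))
        stop("non-finite loss (", loss_name(loss), ") at epoch ", epoch,
             " — aborting training")
      losses <- c(losses, batch_loss)
      grads <- unetpp_backward(model, fw, dlogits)
      if (is.finite(clip_norm)) {
        gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
        if (gn > clip_norm)
          grads <- lapply(grads, function(g) g * (clip_norm / gn))
      }
      upd <- adam_step(model$params, grads, opt, lr)
      model$params <- upd$params; opt <- upd$state
    }
    val_iou <- if (length(val_samples))
      mean(vapply(val_samples, function(s) {
        prob <- unetpp_predict(model, s$image)
        if (!all(is.finite(prob))) return(NA_real_)  # diverged weights
        iou((prob[, , 1, 1] > threshold) * 1, s$mask)
      }, numeric(1))) else NA_real_
    if (!is.na(val_iou) && val_iou > best_iou) {
      best_iou <- val_iou; best <- snapshot_model(model); best_epoch <- epoch
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch,
                                    train_loss = mean(losses),
                                    val_iou = val_iou)
    if (verbose)
      message(sprintf("[%s] epoch %d/%d loss %.4f val IOU %s",
                      loss_name(loss), epoch, epochs, mean(losses),
                      ifelse(is.na(val_iou), "NA", sprintf("%.4f", val_iou))))
  }
  if (length(val_samples)) {
    model$params <- best$params; model$bn_state <- best$bn_state
  }
  if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
  list(model = model, log = do.call(rbind, log_rows), loss = loss,
       best_epoch = best_epoch, best_val_iou = best_iou)
}

#' Evaluate a model on test samples
#'
#' For each sample: forward pass, IOU against the ground-truth mask, tip
#' extraction from the probability map, and Euclidean tip distance in cm.
#' Extraction failures are recorded (distance `Inf`), not raised.
#'
#' @param model a `unetpp` model (or a checkpoint path).
#' @param samples list of samples (see [train_segmenter()]).
#' @param threshold binarization threshold.
#' @return `list(per_image, summary)`: a per-image data frame (`image_id`,
#'   `iou`, predicted/true tip coordinates, `distance_cm`,
#'   `extraction_failed`) and a summary (`mean_iou`, `mean_distance_cm` over
#'   finite distances, `n_failed`, and the PSE table at
#'   {0.25, 0.5, 1, 1.5, 2} cm).
#' @export
evaluate_model <- function(model, samples, threshold = 0.5) {
  if (is.character(model)) model <- load_checkpoint(model)
  rows <- lapply(samples, function(s) {
    prob <- unetpp_predict(model, s$image)[, , 1, 1]
    pm <- (prob > threshold) * 1
    tp <- extract_tip(prob, threshold, spacing = s$tip$spacing)
    d <- tip_distance(tp, s$tip)
    data.frame(image_id = s$image_id %||% NA_character_,
               iou = iou(pm, s$mask),
               tip_row_pred = if (tp$failed) NA else tp$row,
               tip_col_pred = if (tp$failed) NA else tp$col,
               tip_row_true = s$tip$row, tip_col_true = s$tip$col,
               distance_cm = d, extraction_failed = tp$failed,
               stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  fin <- is.finite(per_image$distance_cm)
  list(per_image = per_image,
       summary = list(mean_iou = mean(per_image$iou),
                      mean_distance_cm = if (any(fin))
                        mean(per_image$distance_cm[fin]) else Inf,
                      n_failed = sum(per_image$extraction_failed),
                      pse = pse_table(per_image$distance_cm)))
}

loss_group <- function(name) {
  if (grepl("-", name)) "compound"
  else if (tolower(name) %in% REGION_FAMILIES) "region"
  else "distribution"
}

#' Train and compare segmentation losses across folds
#'
#' The full experiment harness: builds the k-fold splits, trains one model
#' per (loss, fold) cell, evaluates on that fold's test set and assembles the
#' comparison report — per-cell and per-loss mean IOU and tip distance, a
#' per-loss PSE table pooled over the evaluated folds, and the arithmetic
#' group averages for the region-based, distribution-based and compound
#' families.  Per-cell failures are caught, reported with the cell identity
#' and leave a partial report.
#'
#' @param manifest manifest data frame (or path to a manifest CSV).
#' @param losses character vector of loss names (see [all_loss_names()]) or
#'   list of [loss_spec()]s.
#' @param model_config a [unetpp_config()].
#' @param k number of folds in the split.
#' @param folds which folds to actually run (default all `k`).
#' @param epochs,batch_size,lr,aug,threshold as in [train_segmenter()].
#' @param extra_train optional second manifest (data frame or path) whose
#'   samples are merged into the training set of every fold — and never into
#'   validation or test — mirroring the design of augmenting a study cohort
#'   with an external public training set.
#' @param seed master seed; every cell derives its own seed from it.
#' @param out_dir optional directory for CSV outputs (`cells.csv`,
#'   `per_loss.csv`, `pse.csv`, `group_averages.csv`, `report.txt`).
#' @param verbose print progress.
#' @return A `loss_comparison` object: `cells`, `per_loss`, `pse`,
#'   `group_averages` data frames plus `errors` (character, one per failed
#'   cell).
#' @export
compare_losses <- function(manifest, losses, model_config = unetpp_config(),
                           k = 5, folds = seq_len(k), epochs = 10,
                           batch_size = 4, lr = 1e-3,
                           aug = augment_params(), threshold = 0.5,
                           extra_train = NULL, seed = 1, out_dir = NULL,
                           verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!length(losses)) stop("need at least one loss")
  specs <- lapply(losses, function(l) if (is.character(l)) parse_loss(l) else l)
  names(specs) <- vapply(specs, loss_name, character(1))
  samples <- lapply(seq_len(nrow(manifest)),
                    function(i) load_sample(manifest[i, ]))
  names(samples) <- manifest$image_id
  extra_samples <- list()
  if (!is.null(extra_train)) {
    if (is.character(extra_train)) extra_train <- read_manifest(extra_train)
    extra_samples <- lapply(seq_len(nrow(extra_train)),
                            function(i) load_sample(extra_train[i, ]))
  }
  splits <- kfold_split(manifest$image_id, k = k, seed = seed)

  cells <- list(); records <- list(); errors <- character()
  for (li in seq_along(specs)) {
    nm <- names(specs)[li]
    for (f in folds) {
      sp <- splits[[f]]
      cell_seed <- derive_seed(seed, 1000L * li + f)
      res <- tryCatch({
        tr <- train_segmenter(c(samples[sp$train_ids], extra_samples),
                              samples[sp$val_ids],
                              specs[[li]], model_config, epochs = epochs,
                              batch_size = batch_size, lr = lr,
                              aug = aug, threshold = threshold,
                              seed = cell_seed, verbose = verbose)
        evaluate_model(tr$model, samples[sp$test_ids], threshold)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors <- c(errors, sprintf("loss %s, fold %d: %s", nm, f,
                                    conditionMessage(res)))
        cells[[length(cells) + 1]] <-
          data.frame(loss = nm, fold = f, mean_iou = NA_real_,
                     mean_distance_cm = NA_real_, n_failed = NA_integer_)
        next
      }
      cells[[length(cells) + 1]] <-
        data.frame(loss = nm, fold = f, mean_iou = res$summary$mean_iou,
                   mean_distance_cm = res$summary$mean_distance_cm,
                   n_failed = res$summary$n_failed)
      records[[nm]] <- c(records[[nm]], res$per_image$distance_cm)
      if (verbose)
        message(sprintf("cell %s / fold %d: IOU %.4f, distance %.4f cm",
                        nm, f, res$summary$mean_iou,
                        res$summary$mean_distance_cm))
    }
  }
  cells <- do.call(rbind, cells)

  per_loss <- do.call(rbind, lapply(names(specs), function(nm) {
    cc <- cells[cells$loss == nm, ]
    data.frame(loss = nm, group = loss_group(nm),
               mean_iou = mean(cc$mean_iou),
               mean_distance_cm = mean(cc$mean_distance_cm),
               stringsAsFactors = FALSE)
  }))
  pse_df <- do.call(rbind, lapply(names(specs), function(nm) {
    if (is.null(records[[nm]])) return(NULL)
    cbind(data.frame(loss = nm, stringsAsFactors = FALSE),
          as.data.frame(as.list(pse_table(records[[nm]]))))
  }))
  group_averages <- do.call(rbind, lapply(split(per_loss, per_loss$group),
    function(g) data.frame(group = g$group[1],
                           mean_iou = mean(g$mean_iou),
                           mean_distance_cm = mean(g$mean_distance_cm))))
  rownames(group_averages) <- NULL

  report <- structure(list(cells = cells, per_loss = per_loss, pse = pse_df,
                           group_averages = group_averages, errors = errors),
                      class = "loss_comparison")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
    write.csv(per_loss, file.path(out_dir, "per_loss.csv"), row.names = FALSE)
    if (!is.null(pse_df))
      write.csv(pse_df, file.path(out_dir, "pse.csv"), row.names = FALSE)
    write.csv(group_averages, file.path(out_dir, "group_averages.csv"),
              row.names = FALSE)
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "report.txt"))
  }
  report
}

#' @export
print.loss_comparison <- function(x, ...) {
  cat("Loss comparison across", length(unique(x$cells$fold)), "fold(s)\n\n")
  cat("Per-loss summary (means over folds):\n")
  print(x$per_loss, row.names = FALSE, digits = 4)
  if (!is.null(x$pse)) {
    cat("\nPSE (% of test samples with tip error < threshold, cm):\n")
    print(x$pse, row.names = FALSE, digits = 4)
  }
  cat("\nGroup averages:\n")
  print(x$group_averages, row.names = FALSE, digits = 4)
  if (length(x$errors)) {
    cat("\nFailed cells:\n")
    for (e in x$errors) cat(" -", e, "\n")
  }
  invisible(x)
}

#' Desk-scale study profile
#'
#' The package's canonical end-to-end experiment: 64 synthetic 96x96 tube
#' phantoms, a depth-3 base-8 U-Net++ with deep supervision, Adam (lr 1e-3,
#' batch 4) for 10 epochs per cell, folds 1-2 of the 5-fold split, and a
#' seven-loss grid — the four headline losses (dice, focal, mcc-tversky,
#' bce-dice) plus the single-loss parents of the two compounds (bce, mcc,
#' tversky) so that compound-versus-parent comparisons can be read off the
#' same report.  [run_study()] executes it end to end; everything derives
#' deterministically from one seed.
#'
#' @return A list of settings understood by [run_study()].
#' @export
study_profile <- function() {
  list(n_phantoms = 64,
       phantom = phantom_params(),
       losses = c("bce", "dice", "focal", "mcc", "tversky",
                  "bce-dice", "mcc-tversky"),
       model = unetpp_config(depth = 3, base_channels = 8,
                             deep_supervision = TRUE),
       k = 5, folds = 1:2, epochs = 10, batch_size = 4, lr = 1e-3,
       aug = augment_params(), threshold = 0.5)
}

#' @rdname study_profile
#' @param seed master seed for dataset generation, splits and every training
#'   cell.
#' @param data_dir where to write the phantom dataset (default: a session
#'   temporary directory).
#' @param out_dir optional report output directory (see [compare_losses()]).
#' @param profile settings, defaulting to [study_profile()].
#' @param verbose print per-cell progress.
#' @export
run_study <- function(seed = 1, data_dir = NULL, out_dir = NULL,
                      profile = study_profile(), verbose = FALSE) {
  if (is.null(data_dir))
    data_dir <- file.path(tempdir(), paste0("ettseg_study_", seed))
  man <- generate_dataset(profile$n_phantoms, profile$phantom, data_dir,
                          seed = derive_seed(seed, 91))
  compare_losses(man, profile$losses, model_config = profile$model,
                 k = profile$k, folds = profile$folds,
                 epochs = profile$epochs, batch_size = profile$batch_size,
                 lr = profile$lr, aug = profile$aug,
                 threshold = profile$threshold, seed = seed,
                 out_dir = out_dir, verbose = verbose)
}
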