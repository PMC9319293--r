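#' Run the full classification pipeline on a synthetic cohort
#'
#' End-to-end study on phantoms: generate a cohort, contrast-stretch and
#' ray-cast a lesion mask per image, extract the 89-feature vectors, train
#' the three models on the 80:20 train split (with class-asymmetric
#' augmentation for the two CNN models), optimize the ensemble weights and
#' cutoff on training probabilities, and evaluate everything on the held-out
#' test split.
#'
#' Augmented variants are produced image-by-image and immediately reduced to
#' patch and resized-image tensors, so the full-resolution augmented cohort
#' is never held in memory.
#'
#' @param n_malignant,n_benign cohort class counts (defaults 124 / 76).
#' @param seed global seed; all stage seeds are derived from it by fixed
#'   offsets, so the whole run is reproducible from this one integer.
#' @param image_size_px phantom frame side (px).
#' @param use_detected_masks use the ray-cast masks (TRUE, the full
#'   pipeline) or the generator's ground-truth masks.
#' @param n_levels radiomics gray levels.
#' @param patch_epochs,head_epochs training epochs for the patch CNN and the
#'   single-image head.
#' @param patch_threshold decision threshold T for the patch model.
#' @param input_size single-image model input side.
#' @param n_trees random-forest size.
#' @param calibration `"train"`: ensemble weights are optimized on
#'   training-set probabilities (out-of-bag for the forest).
#' @return An `ebus_pipeline_result` list: per-split probability tables,
#'   the fitted models, the optimized [ensemble_config()], per-model and
#'   ensemble `eval_report`s on the test split, and mask-agreement Dice
#'   scores.
#' @export
run_pipeline <- function(n_malignant = 124L, n_benign = 76L, seed = 1L,
                         image_size_px = 388L, use_detected_masks = TRUE,
                         n_levels = 32L, patch_epochs = 8L, head_epochs = 40L,
                         patch_threshold = 0.63, input_size = 64L,
                         n_trees = 1000L, calibration = "train") {
  cohort <- generate_cohort(n_malignant, n_benign, seed = seed,
                            image_size_px = image_size_px)
  n <- length(cohort$images)
  rec <- cohort$records

  # --- masks: contrast stretch + ray-cast boundary --------------------------
  masks <- vector("list", n)
  dice <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (use_detected_masks) {
      enh <- contrast_stretch(cohort$images[[i]],
                              percentile_thresholds(cohort$images[[i]]))
      masks[[i]] <- detect_boundary(enh)
      a <- masks[[i]]$mask == 1L; b <- cohort$masks[[i]]$mask == 1L
      dice[i] <- 2 * sum(a & b) / (sum(a) + sum(b))
    } else {
      masks[[i]] <- cohort$masks[[i]]
    }
  }

  # --- model 1: radiomics + patient data ------------------------------------
  feats <- cohort_features(cohort, masks = masks, n_levels = n_levels)
  tr <- which(rec$split == "train"); te <- which(rec$split == "test")
  sel <- select_features(feats[tr, , drop = FALSE], rec$label[tr])
  rf <- train_rf(feats[tr, , drop = FALSE], rec$label[tr],
                 forest_config(n_trees = n_trees, rng_seed = seed + 101L),
                 selection = sel)
  p1_tr <- predict_p1(rf, feats[tr, , drop = FALSE], oob = identical(calibration, "train"))
  p1_te <- predict_p1(rf, feats[te, , drop = FALSE])

  # --- streamed augmentation -> patch + whole-image training tensors --------
  patch_blocks <- list(); patch_labels <- character(0)
  img_list <- list(); img_labels <- character(0)
  for (i in tr) {
    ops <- c("identity", .aug_ops[[rec$label[i]]])
    for (op in ops) {
      v <- if (op == "identity") list(image = cohort$images[[i]], mask = masks[[i]])
           else augment_one(cohort$images[[i]], masks[[i]], op)
      ps <- select_patches(v$image, v$mask)
      if (ps$n_patches > 0) {
        patch_blocks[[length(patch_blocks) + 1L]] <- patch_tensor(ps)
        patch_labels <- c(patch_labels, rep(rec$label[i], ps$n_patches))
      }
      img_list[[length(img_list) + 1L]] <- v$image
      img_labels <- c(img_labels, rec$label[i])
    }
  }
  side <- dim(patch_blocks[[1]])[1]
  n_patches <- length(patch_labels)
  Xp <- array(0, c(side, side, 3L, n_patches))
  at <- 0L
  for (b in patch_blocks) {
    k <- dim(b)[4]
    Xp[, , , at + seq_len(k)] <- b
    at <- at + k
  }

  # --- model 3: patch CNN ---------------------------------------------------
  pcnn <- build_patch_cnn(patch_cnn_config(epochs = patch_epochs,
                                           rng_seed = seed + 301L))
  pcnn <- train_patch_cnn(pcnn, Xp, patch_labels)
  p3_of <- function(idx) {
    vapply(idx, function(i) {
      ps <- select_patches(cohort$images[[i]], masks[[i]])
      if (ps$n_patches == 0L) return(NA_real_)
      aggregate_p3(classify_patches(pcnn, ps), patch_threshold)$p3
    }, numeric(1))
  }
  p3_tr <- p3_of(tr); p3_te <- p3_of(te)

  # --- model 2: frozen backbone + trained head ------------------------------
  sim <- build_single_image_model(transfer_config(input_size = input_size,
                                                  epochs = head_epochs,
                                                  rng_seed = seed + 201L))
  Xi <- image_tensor(img_list, size = input_size)
  sim <- train_single_image_model(sim, Xi, img_labels)
  p2_tr <- predict_p2(sim, image_tensor(cohort$images[tr], size = input_size))
  p2_te <- predict_p2(sim, image_tensor(cohort$images[te], size = input_size))

  # --- ensemble: grid optimization on training probabilities ----------------
  ok <- !is.na(p3_tr)
  ens <- optimize_ensemble(p1_tr[ok], p2_tr[ok], p3_tr[ok], rec$label[tr][ok])
  fused_te <- fuse_probs(p1_te, p2_te, p3_te, ens)
  y_te <- rec$label[te]

  per_model <- list(
    tabular = eval_metrics(as.integer(p1_te > 0.5), y_te, scores = p1_te),
    single_image = eval_metrics(as.integer(p2_te > 0.5), y_te, scores = p2_te),
    multi_patch = eval_metrics(
      as.integer(!is.na(p3_te) & p3_te > patch_threshold), y_te,
      scores = ifelse(is.na(p3_te), 0, p3_te)))

  structure(list(
    cohort_records = rec,
    selection = sel,
    dice = dice,
    train = data.frame(id = rec$id[tr], label = rec$label[tr],
                       p1 = p1_tr, p2 = p2_tr, p3 = p3_tr),
    test = data.frame(id = rec$id[te], label = y_te,
                      p1 = p1_te, p2 = p2_te, p3 = p3_te,
                      p = fused_te$p, class = fused_te$class),
    models = list(rf = rf, single_image = sim, patch_cnn = pcnn),
    ensemble = ens,
    ensemble_train_accuracy = attr(ens, "train_accuracy"),
    metrics = c(per_model,
                list(ensemble = eval_metrics(fused_te$class, y_te,
                                             scores = fused_te$p)))),
    class = "ebus_pipeline_result")
}

#' @export
print.ebus_pipeline_result <- function(x, ...) {
  cat("<ebus_pipeline_result>\n")
  cat(sprintf("  selected features: %d / %d\n", sum(x$selection$selected),
              nrow(x$selection)))
  cat(sprintf("  ensemble weights: (%.2f, %.2f, %.2f), cutoff %.2f\n",
              x$ensemble$weights[1], x$ensemble$weights[2],
              x$ensemble$weights[3], x$ensemble$cutoff))
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf("  %-13s test Acc %.2f%%\n", nm, m$accuracy))
  }
  invisible(x)
}
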