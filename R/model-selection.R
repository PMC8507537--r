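#' Pair-preserving subject folds for cross-validation
#'
#' Partitions subjects into `k` folds of as-equal-as-possible size; each
#' subject's lesion/healthy image pair lands in exactly one fold (pairs are
#' never split). For 34 subjects and k = 7 this gives six folds of 5
#' subjects (10 images) and one of 4 (8 images). Deterministic given
#' `seed` (uniform shuffle, then round-robin assignment).
#'
#' @param dataset A [maflim_dataset()] or an integer subject count.
#' @param k Number of folds (default 7).
#' @param seed Integer seed.
#' @return Object of class `fold_plan`: list of integer vectors of subject
#'   indices.
#' @export
make_folds <- function(dataset, k = 7L, seed = 1L) {
  n <- if (inherits(dataset, "maflim_dataset")) length(dataset)
       else as.integer(dataset)
  if (n < k) abort_config("fewer subjects than folds")
  perm <- with_local_seed(seed, sample.int(n))
  folds <- split(perm, rep_len(seq_len(k), n))
  folds <- lapply(folds, sort)
  names(folds) <- NULL
  structure(folds, class = "fold_plan", n_subjects = n, seed = seed)
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("Fold plan: %d folds over %d subjects (sizes %s; %s images)\n",
              length(x), attr(x, "n_subjects"),
              paste(sizes, collapse = "/"),
              paste(2L * sizes, collapse = "/")))
  invisible(x)
}

#' Preprocess, fit and featurize a whole cohort
#'
#' Runs the full upstream pipeline (preprocessing chain, per-pixel
#' bi-exponential fitting, 21-feature extraction) on every image of a
#' paired dataset and assembles a per-pixel feature table ready for
#' classifier training. Optionally caps the number of valid pixels kept
#' per image (deterministic subsample) to keep downstream SVM training
#' desk-scale.
#'
#' @param dataset A [maflim_dataset()] of images or scenes.
#' @param preprocess_cfg A [preprocess_config()].
#' @param fit_cfg A [biexp_config()].
#' @param max_pixels_per_image Cap on pixels kept per image (default 200);
#'   `Inf` keeps all.
#' @param seed Seed for the per-image pixel subsample.
#' @return Object of class `cohort_features`: `pixels` (data.frame with
#'   `subject`, `image`, `label`, `grade`, `row`, `col` and the 21 feature
#'   columns) and `images` (one row per image).
#' @export
cohort_features <- function(dataset,
                            preprocess_cfg = preprocess_config(),
                            fit_cfg = biexp_config(),
                            max_pixels_per_image = 200L,
                            seed = 1L) {
  pixel_rows <- list()
  image_rows <- list()
  img_i <- 0L
  for (si in seq_along(dataset$subjects)) {
    s <- dataset$subjects[[si]]
    for (side in c("lesion", "healthy")) {
      img_i <- img_i + 1L
      scn <- s[[side]]
      img <- scene_image(scn)
      irf <- scene_irf(scn)
      pp <- preprocess(img, preprocess_cfg)
      fits <- fit_image(pp$image, irf, pp$mask, fit_cfg)
      stack <- build_feature_stack(pp$image, fits, pp$mask)
      df <- as.data.frame(stack)
      if (nrow(df) > max_pixels_per_image) {
        keep <- with_local_seed(derive_seed(seed, img_i),
                                sample.int(nrow(df), max_pixels_per_image))
        df <- df[sort(keep), , drop = FALSE]
      }
      label <- if (side == "lesion") "positive" else "negative"
      grade <- if (side == "lesion") as.character(s$grade) else "Healthy"
      image_id <- sprintf("%s_%s", s$subject_id, side)
      if (nrow(df)) {
        df <- cbind(data.frame(subject = si, image = image_id,
                               label = label, grade = grade,
                               stringsAsFactors = FALSE), df)
        pixel_rows[[img_i]] <- df
      }
      image_rows[[img_i]] <- data.frame(
        subject = si, image = image_id, label = label, grade = grade,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(pixels = do.call(rbind, pixel_rows),
                 images = do.call(rbind, image_rows)),
            class = "cohort_features")
}

#' @export
print.cohort_features <- function(x, ...) {
  cat(sprintf("Cohort features: %d images, %d pixels, %d features\n",
              nrow(x$images), nrow(x$pixels),
              length(intersect(names(x$pixels), maflim_feature_names()))))
  invisible(x)
}

# Image-level scores for a set of images: train-time helper shared by SFS,
# CV and the ensemble sweep. Returns scores aligned with `images$image`.
image_scores_for <- function(model, pixels, images) {
  p <- predict(model, pixels)
  agg <- tapply(p^2, pixels$image, mean)
  as.numeric(agg[images$image])
}

#' Sequential forward feature search
#'
#' Greedy selection of up to `max_features` features from one pool
#' (spectral or time-resolved): at each step the feature whose addition
#' maximizes the training-set image-level ROC-AUC is added (AUC computed on
#' Brier-style image scores; ties broken by canonical feature order). The
#' final set is the prefix of the greedy path with the largest AUC; when
#' two prefixes tie, the smaller wins (parsimony).
#'
#' @param features A [cohort_features()] object restricted to the training
#'   images (or a full one plus `image_ids`).
#' @param model_kind Classifier kind (see [train_pixel_classifier()]).
#' @param feature_pool Candidate feature names, e.g.
#'   `maflim_feature_names("spectral")`.
#' @param max_features Maximum model size (default 3).
#' @param image_ids Optional subset of image ids to treat as the training
#'   set.
#' @return List with `selected` (character), `path` (features in greedy
#'   order) and `auc_path` (training AUC after each addition).
#' @export
sequential_forward_search <- function(features, model_kind, feature_pool,
                                      max_features = 3L,
                                      image_ids = NULL) {
  if (!length(feature_pool)) abort_config("empty feature pool")
  feature_pool <- intersect(maflim_feature_names(), feature_pool)
  pix <- features$pixels
  imgs <- features$images
  if (!is.null(image_ids)) {
    pix <- pix[pix$image %in% image_ids, , drop = FALSE]
    imgs <- imgs[imgs$image %in% image_ids, , drop = FALSE]
  }
  path <- character(0)
  auc_path <- numeric(0)
  for (step in seq_len(max_features)) {
    remaining <- setdiff(feature_pool, path)
    if (!length(remaining)) break
    best_f <- NULL; best_auc <- -Inf
    for (f in remaining) {      # canonical order; first strict max wins
      m <- train_pixel_classifier(pix, pix$label, model_kind,
                                  features = c(path, f))
      auc <- roc_auc(image_scores_for(m, pix, imgs), imgs$label)
      if (auc > best_auc + 1e-12) { best_auc <- auc; best_f <- f }
    }
    path <- c(path, best_f)
    auc_path <- c(auc_path, best_auc)
  }
  best_size <- which.max(auc_path)   # first (= smallest) maximal prefix
  list(selected = path[seq_len(best_size)], path = path,
       auc_path = auc_path)
}

#' Paired k-fold cross-validation with per-fold feature selection
#'
#' For each fold: sequential forward search and classifier training on the
#' training folds only, image-score threshold optimized on the training
#' images (constrained ROC, FPR <= 30%), then the locked fold model applied
#' unchanged to the validation images. Standardization statistics, selected
#' features and thresholds never touch validation data. Pooled validation
#' predictions give one confusion matrix. Deterministic given `seed`.
#'
#' @param features A [cohort_features()] object for the whole cohort.
#' @param model_kind Classifier kind.
#' @param feature_pool Feature pool (spectral-only or time-resolved-only).
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @param max_features Maximum model size per fold.
#' @return Object of class `maflim_cv`: `predictions` (per validation
#'   image: score, prediction, label, fold), `trace` (per fold: features,
#'   AUC path, threshold), `feature_frequency` (named counts over folds),
#'   `confusion`, `metrics`, `auc`.
#' @export
cross_validate <- function(features, model_kind, feature_pool, k = 7L,
                           seed = 1L, max_features = 3L) {
  imgs <- features$images
  pix <- features$pixels
  n_subj <- max(imgs$subject)
  plan <- make_folds(n_subj, k = k, seed = seed)
  preds <- list()
  trace <- list()
  freq <- setNames(numeric(length(feature_pool)), feature_pool)
  for (fi in seq_along(plan)) {
    val_subj <- plan[[fi]]
    tr_imgs <- imgs[!imgs$subject %in% val_subj, , drop = FALSE]
    va_imgs <- imgs[imgs$subject %in% val_subj, , drop = FALSE]
    if (length(unique(tr_imgs$label)) < 2L) {
      warning(sprintf("fold %d skipped: single-class training set", fi),
              call. = FALSE)
      next
    }
    tr_pix <- pix[pix$image %in% tr_imgs$image, , drop = FALSE]
    va_pix <- pix[pix$image %in% va_imgs$image, , drop = FALSE]
    sfs <- sequential_forward_search(
      list(pixels = tr_pix, images = tr_imgs), model_kind, feature_pool,
      max_features = max_features)
    model <- train_pixel_classifier(tr_pix, tr_pix$label, model_kind,
                                    features = sfs$selected)
    thr <- optimize_threshold(image_scores_for(model, tr_pix, tr_imgs),
                              tr_imgs$label)
    va_scores <- image_scores_for(model, va_pix, va_imgs)
    preds[[fi]] <- data.frame(
      va_imgs, score = va_scores,
      prediction = classify_image(va_scores, as.numeric(thr)),
      fold = fi, stringsAsFactors = FALSE)
    trace[[fi]] <- list(fold = fi, features = sfs$selected,
                        path = sfs$path, auc_path = sfs$auc_path,
                        threshold = as.numeric(thr))
    freq[sfs$selected] <- freq[sfs$selected] + 1
  }
  predictions <- do.call(rbind, preds)
  cm <- confusion(predictions$prediction, predictions$label,
                  predictions$grade)
  structure(list(predictions = predictions, trace = trace,
                 feature_frequency = freq, confusion = cm,
                 metrics = classification_metrics(cm),
                 auc = roc_auc(predictions$score, predictions$label),
                 model_kind = model_kind, k = k, seed = seed),
            class = "maflim_cv")
}

#' @export
print.maflim_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("%d-fold CV, %s: sensitivity %.0f%%, specificity %.0f%%, F1 %.2f, ROC-AUC %.3f\n",
              x$k, x$model_kind, 100 * m$sensitivity, 100 * m$specificity,
              m$f1, x$auc))
  top <- sort(x$feature_frequency[x$feature_frequency > 0],
              decreasing = TRUE)
  if (length(top))
    cat("  selected features (folds): ",
        paste(sprintf("%s(%d)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.maflim_cv <- function(object, ...) {
  print(object)
  print(object$confusion)
  invisible(object)
}

#' Most frequently selected features across folds
#'
#' @param cv A [cross_validate()] result.
#' @param n Number of features (default 3).
#' @return Character vector, most frequent first (ties broken by canonical
#'   feature order).
#' @export
top_features <- function(cv, n = 3L) {
  freq <- cv$feature_frequency
  ord <- order(-freq, match(names(freq), maflim_feature_names()))
  head(names(freq)[ord][freq[ord] > 0], n)
}

#' Optimize the ensemble weight by cross-validated grid search
#'
#' Runs the paired k-fold CV of the two-member ensemble for every weight
#' `w1` on the grid (default 0, 0.1, ..., 1): per fold, both members are
#' retrained on the training folds with their fixed feature sets (no
#' further feature selection), pixel posteriors are combined as
#' `w1 p_a + (1 - w1) p_b`, the image-score threshold is optimized on the
#' training images, and the locked fold ensemble is applied to the
#' validation images. The returned `w1` maximizes pooled F1 (ties: higher
#' sensitivity, then lower `w1`).
#'
#' @param features A [cohort_features()] object.
#' @param spectral_features Fixed feature set of member A (e.g. the top-3
#'   most frequent spectral features).
#' @param time_features Fixed feature set of member B.
#' @param spectral_kind,time_kind Member classifier kinds (defaults SVM and
#'   QDA).
#' @param k,seed Fold structure (must mirror the member CVs).
#' @param weights Candidate `w1` grid.
#' @return List with `w1` (selected), `metrics` (one row per candidate
#'   weight: sensitivity, specificity, F1, AUC) and `cv` (a `maflim_cv`-like
#'   record of the pooled predictions at the selected weight).
#' @export
optimize_ensemble_weight <- function(features, spectral_features,
                                     time_features,
                                     spectral_kind = "SVM",
                                     time_kind = "QDA",
                                     k = 7L, seed = 1L,
                                     weights = seq(0, 1, by = 0.1)) {
  imgs <- features$images
  pix <- features$pixels
  plan <- make_folds(max(imgs$subject), k = k, seed = seed)
  per_w_preds <- setNames(vector("list", length(weights)),
                          format(weights))
  for (fi in seq_along(plan)) {
    val_subj <- plan[[fi]]
    tr_imgs <- imgs[!imgs$subject %in% val_subj, , drop = FALSE]
    va_imgs <- imgs[imgs$subject %in% val_subj, , drop = FALSE]
    tr_pix <- pix[pix$image %in% tr_imgs$image, , drop = FALSE]
    va_pix <- pix[pix$image %in% va_imgs$image, , drop = FALSE]
    ma <- train_pixel_classifier(tr_pix, tr_pix$label, spectral_kind,
                                 features = spectral_features)
    mb <- train_pixel_classifier(tr_pix, tr_pix$label, time_kind,
                                 features = time_features)
    pa_tr <- predict(ma, tr_pix); pb_tr <- predict(mb, tr_pix)
    pa_va <- predict(ma, va_pix); pb_va <- predict(mb, va_pix)
    for (wi in seq_along(weights)) {
      w1 <- weights[wi]
      sc_tr <- tapply((w1 * pa_tr + (1 - w1) * pb_tr)^2, tr_pix$image,
                      mean)[tr_imgs$image]
      sc_va <- tapply((w1 * pa_va + (1 - w1) * pb_va)^2, va_pix$image,
                      mean)[va_imgs$image]
      thr <- optimize_threshold(as.numeric(sc_tr), tr_imgs$label)
      per_w_preds[[wi]] <- rbind(per_w_preds[[wi]], data.frame(
        va_imgs, score = as.numeric(sc_va),
        prediction = classify_image(as.numeric(sc_va), as.numeric(thr)),
        fold = fi, w1 = w1, stringsAsFactors = FALSE))
    }
  }
  metrics <- do.call(rbind, lapply(seq_along(weights), function(wi) {
    pr <- per_w_preds[[wi]]
    cm <- confusion(pr$prediction, pr$label)
    data.frame(w1 = weights[wi],
               sensitivity = sensitivity(cm),
               specificity = specificity(cm),
               f1 = f1(cm),
               auc = roc_auc(pr$score, pr$label))
  }))
  f1s <- ifelse(is.na(metrics$f1), -Inf, metrics$f1)
  sens <- ifelse(is.na(metrics$sensitivity), -Inf, metrics$sensitivity)
  ord <- order(-f1s, -sens, metrics$w1)
  best <- ord[1]
  pr <- per_w_preds[[best]]
  cm <- confusion(pr$prediction, pr$label, pr$grade)
  list(w1 = weights[best], metrics = metrics,
       cv = structure(list(predictions = pr, confusion = cm,
                           metrics = classification_metrics(cm),
                           auc = roc_auc(pr$score, pr$label),
                           model_kind = paste(spectral_kind, time_kind,
                                              sep = "-"),
                           k = k, seed = seed,
                           feature_frequency = numeric(0),
                           trace = list()),
                      class = "maflim_cv"))
}

#' Train and lock the final models on the full training set
#'
#' Retrains the spectral member, the time-resolved member and the weighted
#' ensemble on all images, optimizes each image-score threshold on the full
#' training set, and returns models that are subsequently immutable (and
#' JSON-serializable via [write_classifier()]).
#'
#' @param features A [cohort_features()] object for the full training set.
#' @param spectral_features,time_features Fixed feature sets.
#' @param w1 Ensemble weight from [optimize_ensemble_weight()].
#' @param spectral_kind,time_kind Member kinds.
#' @return List with `spectral`, `time` (pixel classifiers with thresholds
#'   set) and `ensemble` (a [maflim_ensemble()] with threshold set).
#' @export
lock_final_models <- function(features, spectral_features, time_features,
                              w1, spectral_kind = "SVM",
                              time_kind = "QDA") {
  pix <- features$pixels
  imgs <- features$images
  ma <- train_pixel_classifier(pix, pix$label, spectral_kind,
                               features = spectral_features)
  mb <- train_pixel_classifier(pix, pix$label, time_kind,
                               features = time_features)
  ma$threshold <- as.numeric(
    optimize_threshold(image_scores_for(ma, pix, imgs), imgs$label))
  mb$threshold <- as.numeric(
    optimize_threshold(image_scores_for(mb, pix, imgs), imgs$label))
  pa <- predict(ma, pix); pb <- predict(mb, pix)
  sc <- tapply((w1 * pa + (1 - w1) * pb)^2, pix$image, mean)[imgs$image]
  ens <- maflim_ensemble(ma, mb, w1)
  ens$threshold <- as.numeric(
    optimize_threshold(as.numeric(sc), imgs$label))
  list(spectral = ma, time = mb, ensemble = ens)
}
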