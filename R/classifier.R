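# ---- Gaussian discriminant internals -------------------------------------
# LDA/QDA are fitted explicitly (class means, pooled or per-class
# covariances, empirical priors) so that near-singular covariances can be
# ridge-regularized and the fitted parameters serialize to JSON. MASS::lda
# and MASS::qda are used as independent cross-checks in the test suite.

regularize_cov <- function(S) {
  p <- nrow(S)
  tr <- sum(diag(S))
  if (tr <= 0) tr <- 1
  ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) 0)
  if (min(ev) < 1e-10 * tr / p) {
    warning("near-singular covariance regularized", call. = FALSE)
    S <- S + diag(1e-6 * tr / p, p)
  }
  S
}

gauss_da_fit <- function(x, y01, pooled) {
  p <- ncol(x)
  mu <- lapply(0:1, function(k) colMeans(x[y01 == k, , drop = FALSE]))
  if (pooled) {
    S0 <- cov(x[y01 == 0, , drop = FALSE])
    S1 <- cov(x[y01 == 1, , drop = FALSE])
    n0 <- sum(y01 == 0); n1 <- sum(y01 == 1)
    S <- ((n0 - 1) * S0 + (n1 - 1) * S1) / (n0 + n1 - 2)
    sigma <- rep(list(regularize_cov(S)), 2)
  } else {
    sigma <- lapply(0:1, function(k)
      regularize_cov(cov(x[y01 == k, , drop = FALSE])))
  }
  priors <- c(mean(y01 == 0), mean(y01 == 1))
  list(mu = mu, sigma = sigma, priors = priors)
}

gauss_log_density <- function(x, mu, sigma) {
  p <- length(mu)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

gauss_da_posterior <- function(params, x) {
  l0 <- gauss_log_density(x, params$mu[[1]], params$sigma[[1]]) +
    log(params$priors[1])
  l1 <- gauss_log_density(x, params$mu[[2]], params$sigma[[2]]) +
    log(params$priors[2])
  1 / (1 + exp(l0 - l1))
}

# Quietly fit an unpenalized logistic regression; separation warnings are
# expected on well-separated synthetic data and are not informative here.
quiet_glm <- function(...) {
  withCallingHandlers(glm(...), warning = function(w) {
    if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Train a pixel-level tissue classifier
#'
#' Fits one of the four pixel classifiers on labelled per-pixel feature
#' vectors: linear discriminant analysis (LDA), quadratic discriminant
#' analysis (QDA), a linear support vector machine (L2-regularized,
#' C = 100) or logistic regression (LOGREG, unpenalized). Features are
#' z-scored using training statistics (applied identically at prediction);
#' every model exposes calibrated posterior probabilities
#' P(dysplasia/cancer | features): Gaussian posteriors with empirical class
#' priors for LDA/QDA, a Platt-style sigmoid on the decision value for the
#' SVM, and the model's own probabilities for LOGREG. Pixel labels inherit
#' the image-level histopathology label (a stated label-noise assumption:
#' no pixel-level truth exists).
#'
#' @param x Matrix or data.frame of pixel feature vectors (columns named by
#'   feature).
#' @param y Labels: logical, 0/1, or factor/character with positives
#'   `"positive"`/`"dysplasia/cancer"`/`"1"`/`TRUE`.
#' @param model_kind One of `"LDA"`, `"QDA"`, `"SVM"`, `"LOGREG"`.
#' @param features Feature subset to use (1-3 names); defaults to all
#'   columns of `x`.
#' @return Object of class `pixel_classifier`: kind, features,
#'   standardization statistics, fitted parameters and posterior
#'   calibration. The image-score threshold is unset until
#'   [optimize_threshold()] is applied.
#' @seealso [posterior_map()], [image_score()], [write_classifier()]
#' @export
train_pixel_classifier <- function(x, y,
                                   model_kind = c("LDA", "QDA", "SVM",
                                                  "LOGREG"),
                                   features = NULL) {
  model_kind <- match.arg(model_kind)
  x <- as.data.frame(x)
  if (is.null(features)) features <- names(x)
  missing_f <- setdiff(features, names(x))
  if (length(missing_f))
    abort_validation(paste0("missing feature(s): ",
                            paste(missing_f, collapse = ", ")))
  x <- as.matrix(x[, features, drop = FALSE])
  y01 <- as_label01(y)
  if (length(y01) != nrow(x))
    abort_validation("feature/label length mismatch")
  if (length(unique(y01)) < 2L)
    abort_validation("training data contains a single class")

  center <- colMeans(x)
  scale_ <- apply(x, 2L, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale_, "/")

  params <- calib <- NULL
  if (model_kind %in% c("LDA", "QDA")) {
    params <- gauss_da_fit(xs, y01, pooled = model_kind == "LDA")
  } else if (model_kind == "SVM") {
    sv <- e1071::svm(xs, factor(y01, levels = c(0, 1)),
                     kernel = "linear", cost = 100, scale = FALSE)
    w <- drop(t(sv$coefs) %*% sv$SV)
    b <- -sv$rho
    dec <- drop(xs %*% w) + b
    # orient the decision value toward the positive class (libsvm signs
    # follow the first training label, which is arbitrary here)
    if (mean(dec[y01 == 1]) < mean(dec[y01 == 0])) {
      w <- -w; b <- -b; dec <- -dec
    }
    pl <- quiet_glm(y01 ~ dec, family = binomial())
    params <- list(w = w, b = b)
    calib <- unname(coef(pl))                     # Platt intercept, slope
  } else {
    fitg <- quiet_glm(y01 ~ xs, family = binomial())
    params <- list(beta0 = unname(coef(fitg)[1]),
                   beta = unname(coef(fitg)[-1]))
    params$beta[is.na(params$beta)] <- 0
  }
  structure(list(kind = model_kind, features = features,
                 center = center, scale = scale_,
                 params = params, calib = calib,
                 threshold = NA_real_),
            class = "pixel_classifier")
}

as_label01 <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) abort_validation("numeric labels must be 0/1")
    return(as.integer(y))
  }
  y <- as.character(y)
  pos <- y %in% c("positive", "dysplasia/cancer", "lesion", "1", "TRUE")
  neg <- y %in% c("negative", "healthy", "0", "FALSE")
  if (!all(pos | neg)) abort_validation("unrecognized class labels")
  as.integer(pos)
}

#' Posterior probabilities for new pixels
#'
#' @param object A `pixel_classifier`.
#' @param newdata Matrix or data.frame containing the model's features.
#' @param ... Unused.
#' @return Numeric vector of posteriors in `[0, 1]`.
#' @export
predict.pixel_classifier <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing_f <- setdiff(object$features, names(newdata))
  if (length(missing_f))
    abort_validation(paste0("missing feature(s): ",
                            paste(missing_f, collapse = ", ")))
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  p <- switch(object$kind,
    LDA = , QDA = gauss_da_posterior(object$params, xs),
    SVM = {
      dec <- drop(xs %*% object$params$w) + object$params$b
      stats::plogis(object$calib[1] + object$calib[2] * dec)
    },
    LOGREG = stats::plogis(object$params$beta0 +
                             drop(xs %*% object$params$beta)))
  pmin(pmax(unname(p), 0), 1)
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("Pixel classifier: %s on {%s}\n", x$kind,
              paste(x$features, collapse = ", ")))
  if (is.finite(x$threshold))
    cat(sprintf("  image-score threshold: %.4f\n", x$threshold))
  invisible(x)
}

#' @export
summary.pixel_classifier <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Posterior probability map for an image
#'
#' Applies a trained pixel classifier to every valid pixel of a feature
#' stack, yielding the posterior probability of dysplasia/cancer per pixel.
#'
#' @param model A `pixel_classifier` (or `maflim_ensemble`).
#' @param stack A [build_feature_stack()] result.
#' @return Object of class `probability_map`: `p` (matrix, NA outside the
#'   valid mask) and `valid`.
#' @export
posterior_map <- function(model, stack) {
  if (inherits(model, "maflim_ensemble")) return(predict(model, stack))
  df <- as.data.frame(stack)
  p <- matrix(NA_real_, nrow(stack$valid), ncol(stack$valid))
  if (nrow(df))
    p[cbind(df$row, df$col)] <- predict(model, df)
  structure(list(p = p, valid = stack$valid), class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  v <- x$p[x$valid]
  cat(sprintf("Posterior probability map %d x %d: %d valid, mean %.3f\n",
              nrow(x$p), ncol(x$p), length(v), mean(v)))
  invisible(x)
}

#' Brier-style image-level score
#'
#' The whole-image malignancy score: the mean over valid pixels of the
#' squared pixel posterior probabilities. Lies in `[0, 1]`; monotone in
#' every pixel posterior.
#'
#' @param pmap A [posterior_map()] result, or a numeric vector of pixel
#'   posteriors.
#' @return Scalar score in `[0, 1]`.
#' @export
image_score <- function(pmap) {
  v <- if (inherits(pmap, "probability_map")) pmap$p[pmap$valid]
       else as.numeric(pmap)
  v <- v[!is.na(v)]
  if (!length(v)) abort_validation("image score undefined: no valid pixels")
  mean(v^2)
}

#' Optimize the image-score threshold on a constrained ROC
#'
#' Selects, among candidate thresholds (midpoints between sorted unique
#' scores plus sentinels below and above), the one maximizing sensitivity
#' subject to a false-positive-rate cap `1 - specificity <= max_fpr`
#' (default 30%). Ties are broken by lower FPR, then by higher threshold.
#' If no feasible threshold achieves positive sensitivity, the feasible
#' threshold with sensitivity 0 is returned with a warning.
#'
#' @param scores Numeric image-level scores.
#' @param labels Image labels (see [train_pixel_classifier()] for accepted
#'   encodings).
#' @param max_fpr Upper bound on 1 - specificity.
#' @return The selected threshold, with attributes `"sensitivity"` and
#'   `"fpr"` of its training operating point.
#' @export
optimize_threshold <- function(scores, labels, max_fpr = 0.30) {
  y <- as_label01(labels)
  if (length(unique(y)) < 2L)
    abort_validation("both classes required to optimize a threshold")
  s <- sort(unique(scores))
  cand <- c(min(s) - 1e-9,
            if (length(s) > 1L) (head(s, -1L) + s[-1L]) / 2,
            max(s) + 1e-9)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  best <- NULL
  for (th in cand) {
    pred <- as.integer(scores >= th)
    sens <- sum(pred == 1 & y == 1) / npos
    fpr <- sum(pred == 1 & y == 0) / nneg
    if (fpr > max_fpr) next
    if (is.null(best) ||
        sens > best$sens + 1e-12 ||
        (abs(sens - best$sens) <= 1e-12 &&
           (fpr < best$fpr - 1e-12 ||
              (abs(fpr - best$fpr) <= 1e-12 && th > best$th))))
      best <- list(th = th, sens = sens, fpr = fpr)
  }
  if (best$sens == 0)
    warning("no threshold attains positive sensitivity within the FPR constraint",
            call. = FALSE)
  structure(best$th, sensitivity = best$sens, fpr = best$fpr)
}

#' Classify a whole image from its score
#'
#' Positive (dysplasia/cancer) iff `score >= threshold` (inclusive).
#'
#' @param score Image-level score(s).
#' @param threshold Decision threshold.
#' @return Character vector `"positive"`/`"negative"`.
#' @export
classify_image <- function(score, threshold) {
  ifelse(score >= threshold, "positive", "negative")
}

#' Weighted combination of two posterior probability maps
#'
#' Pixel-wise convex combination `w1 * p_a + (1 - w1) * p_b` of the
#' posterior maps of the two ensemble members; both maps must share the
#' valid mask.
#'
#' @param map_a,map_b [posterior_map()] results on identical masks.
#' @param w1 Weight of `map_a`, in `[0, 1]`.
#' @return A `probability_map`.
#' @export
ensemble_posterior <- function(map_a, map_b, w1) {
  if (!is.numeric(w1) || w1 < 0 || w1 > 1)
    abort_validation("w1 must lie in [0, 1]")
  if (!identical(map_a$valid, map_b$valid))
    abort_validation("posterior maps have different valid masks")
  structure(list(p = w1 * map_a$p + (1 - w1) * map_b$p,
                 valid = map_a$valid),
            class = "probability_map")
}

#' Construct an SVM-QDA weighted-posterior ensemble
#'
#' Combines a spectral-feature member and a time-resolved-feature member by
#' a convex weighting of their posterior probability maps. The two members
#' must be trained on disjoint feature pools.
#'
#' @param model_a Spectral member (`pixel_classifier`).
#' @param model_b Time-resolved member (`pixel_classifier`).
#' @param w1 Weight of `model_a` in `[0, 1]` (`w2 = 1 - w1`).
#' @param threshold Optional image-score threshold.
#' @return Object of class `maflim_ensemble`.
#' @export
maflim_ensemble <- function(model_a, model_b, w1, threshold = NA_real_) {
  if (!is.numeric(w1) || w1 < 0 || w1 > 1)
    abort_validation("w1 must lie in [0, 1]")
  if (length(intersect(model_a$features, model_b$features)))
    abort_validation("ensemble members must use disjoint feature pools")
  structure(list(model_a = model_a, model_b = model_b,
                 w1 = w1, threshold = threshold),
            class = "maflim_ensemble")
}

#' @export
predict.maflim_ensemble <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_stack")) {
    ensemble_posterior(posterior_map(object$model_a, newdata),
                       posterior_map(object$model_b, newdata),
                       object$w1)
  } else {
    object$w1 * predict(object$model_a, newdata) +
      (1 - object$w1) * predict(object$model_b, newdata)
  }
}

#' @export
print.maflim_ensemble <- function(x, ...) {
  cat(sprintf("SVM-QDA style ensemble: w1 = %.2f (A: %s), w2 = %.2f (B: %s)\n",
              x$w1, x$model_a$kind, 1 - x$w1, x$model_b$kind))
  if (is.finite(x$threshold))
    cat(sprintf("  image-score threshold: %.4f\n", x$threshold))
  invisible(x)
}

# ---- JSON serialization ----------------------------------------------------

classifier_to_list <- function(m) {
  if (inherits(m, "maflim_ensemble")) {
    out <- list(type = "ensemble", w1 = m$w1,
                model_a = classifier_to_list(m$model_a),
                model_b = classifier_to_list(m$model_b))
    if (length(m$threshold) && is.finite(m$threshold))
      out$threshold <- m$threshold
    return(out)
  }
  out <- list(type = "pixel_classifier", kind = m$kind,
              features = m$features,
              center = as.list(m$center), scale = as.list(m$scale),
              calib = m$calib)
  if (length(m$threshold) && is.finite(m$threshold))
    out$threshold <- m$threshold
  out$params <- switch(m$kind,
    LDA = , QDA = list(mu = lapply(m$params$mu, unname),
                       sigma = lapply(m$params$sigma,
                                      function(S) unname(as.matrix(S))),
                       priors = m$params$priors),
    SVM = list(w = unname(m$params$w), b = m$params$b),
    LOGREG = m$params)
  out
}

classifier_from_list <- function(l) {
  if (identical(l$type, "ensemble")) {
    return(maflim_ensemble(classifier_from_list(l$model_a),
                           classifier_from_list(l$model_b),
                           w1 = l$w1,
                           threshold = nanull(l$threshold)))
  }
  # (thresholds are omitted from the file when unset)
  feats <- unlist(l$features)
  params <- switch(l$kind,
    LDA = , QDA = list(
      mu = lapply(l$params$mu, unlist),
      sigma = lapply(l$params$sigma, function(S)
        matrix(unlist(S), length(feats), length(feats))),
      priors = unlist(l$params$priors)),
    SVM = list(w = setNames(unlist(l$params$w), feats), b = l$params$b),
    LOGREG = list(beta0 = l$params$beta0, beta = unlist(l$params$beta)))
  structure(list(kind = l$kind, features = feats,
                 center = setNames(unlist(l$center), feats),
                 scale = setNames(unlist(l$scale), feats),
                 params = params, calib = unlist(l$calib),
                 threshold = nanull(l$threshold)),
            class = "pixel_classifier")
}

nanull <- function(x) if (is.null(x) || !length(x)) NA_real_ else as.numeric(x)

#' Serialize / restore a trained classifier as JSON
#'
#' Writes the model kind, selected features, fitted parameters, posterior
#' calibration, standardization statistics and image-score threshold.
#' Restored models predict bit-identically.
#'
#' @param model A `pixel_classifier` or `maflim_ensemble`.
#' @param path JSON file path.
#' @return `write_classifier`: `path`, invisibly. `read_classifier`: the
#'   restored model.
#' @export
write_classifier <- function(model, path) {
  # 17 significant digits make double round-trips bit-exact
  jsonlite::write_json(classifier_to_list(model), path,
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  classifier_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}
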