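# Shared fixtures, all generated in code.

# A small noiseless image whose three bands hold known bi-exponential
# decays (plus optional constant offset), for deterministic checks.
toy_image <- function(rows = 4, cols = 4, n_time = 64, dt = 0.25,
                      offset = 0, meta = list(full_scale = 1)) {
  irf <- make_irf(dt, n_time = n_time)
  pars <- list(
    b390 = list(alpha_fast = 0.55, tau_fast = 0.9, alpha_slow = 0.45,
                tau_slow = 5.0, amplitude = 0.08),
    b452 = list(alpha_fast = 0.60, tau_fast = 0.45, alpha_slow = 0.40,
                tau_slow = 3.2, amplitude = 0.10),
    b500 = list(alpha_fast = 0.55, tau_fast = 0.50, alpha_slow = 0.45,
                tau_slow = 3.0, amplitude = 0.06))
  decay <- lapply(pars, function(p) {
    y <- reconvolve(p, irf, dt, n_time) + offset
    array(rep(y, each = rows * cols), c(rows, cols, n_time))
  })
  list(image = maflim_image(decay, dt, meta), irf = irf, pars = pars)
}

# Independent dense-quadrature oracle for the reconvolution integral
# y(t_k) = integral u(s) h(t_k - s) ds, on a grid `over` times finer.
quadrature_reconvolve <- function(p, u, dt, n_time, over = 50) {
  fine_dt <- dt / over
  t_u <- (seq_along(u) - 1L) * dt
  fine_t <- seq(0, max(t_u), by = fine_dt)
  u_fine <- approx(t_u, u, xout = fine_t)$y
  h_fine <- p$alpha_fast * exp(-fine_t / p$tau_fast) +
    p$alpha_slow * exp(-fine_t / p$tau_slow)
  full <- convolve(u_fine, rev(h_fine), type = "open") * fine_dt
  full[1 + (seq_len(n_time) - 1L) * over]
}

# Brute-force AUC by explicit pair counting (ties get half credit).
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1 | labels == "positive"]
  neg <- scores[labels == 0 | labels == "negative"]
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# Brute-force constrained-threshold search over every cut point.
brute_force_threshold <- function(scores, labels, max_fpr = 0.3) {
  y <- as.integer(labels == 1 | labels == "positive")
  cand <- sort(unique(c(scores - 1e-9, scores + 1e-9,
                        min(scores) - 1, max(scores) + 1)))
  best <- NULL
  for (th in cand) {
    pred <- as.integer(scores >= th)
    sens <- sum(pred & y) / sum(y)
    fpr <- sum(pred & !y) / sum(!y)
    if (fpr > max_fpr) next
    if (is.null(best) || sens > best$sens ||
        (sens == best$sens && fpr < best$fpr))
      best <- list(sens = sens, fpr = fpr)
  }
  best
}

# Small labelled two-class pixel cloud for classifier tests.
gaussian_pixels <- function(n = 200, d = 2, delta = 3, sd1 = 1, sd2 = 1,
                            seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * d, 0, sd1), n, d),
             matrix(rnorm(n * d, delta, sd2), n, d))
  colnames(x) <- paste0("f", seq_len(d))
  list(x = as.data.frame(x), y = rep(c(0, 1), each = n))
}

# Cohort feature tables are expensive; build each once per test run.
cohort_cache <- new.env(parent = emptyenv())
cached_cohort_features <- function(effect, n_subjects = 20, seed = 11) {
  key <- paste(effect, n_subjects, seed, sep = "_")
  if (is.null(cohort_cache[[key]])) {
    ds <- generate_cohort(n_subjects, effect, seed = seed)
    cohort_cache[[key]] <- cohort_features(ds, seed = seed)
  }
  cohort_cache[[key]]
}

# A tiny synthetic feature table: image-level scores are driven by feature
# f_good; f_noise* carry nothing. Built directly so SFS oracles are exact.
toy_feature_table <- function(n_subj = 6, px_per_img = 30, seed = 17,
                              informative = "alpha_fast_452") {
  set.seed(seed)
  pixels <- list(); images <- list(); k <- 0
  for (s in seq_len(n_subj)) for (side in c("lesion", "healthy")) {
    k <- k + 1
    lab <- if (side == "lesion") "positive" else "negative"
    mu <- if (side == "lesion") 1.2 else 0
    df <- data.frame(
      subject = s, image = sprintf("S%d_%s", s, side), label = lab,
      grade = if (side == "lesion") "SCC" else "Healthy",
      row = seq_len(px_per_img), col = 1)
    df[[informative]] <- rnorm(px_per_img, mu, 1)
    df$tau_fast_390 <- rnorm(px_per_img)
    df$tau_slow_500 <- rnorm(px_per_img)
    df$tau_avg_390 <- rnorm(px_per_img)
    pixels[[k]] <- df
    images[[k]] <- df[1, c("subject", "image", "label", "grade")]
  }
  structure(list(pixels = do.call(rbind, pixels),
                 images = do.call(rbind, images)),
            class = "cohort_features")
}
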