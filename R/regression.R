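# Gaussian-process regression surrogates mapping the wearable-derivable
# feature vector [HR, CSBP, CDBP, SaO2] to one in-hospital target each.
#
# The model is an exact GP with kernel
#   k(x, x') = sigma_f^2 * exp(-||x - x'||^2 / (2 l^2)) + sigma_n^2 * 1{x = x'}
# (a constant-variance term times an isotropic squared-exponential, plus a
# noise term), fitted on z-scored features with the prior mean set to the
# training-target mean. Targets keep their physical units. Hyperparameters
# are selected by randomized search over log-uniform ranges, scored by
# 10-fold shuffled cross-validation minimizing the maximum absolute error,
# then the model is refitted on the full training set.

#' Wearable feature names (canonical column order)
#' @return Character vector.
#' @export
cr_feature_names <- function() c("HR", "CSBP", "CDBP", "SaO2")

#' In-hospital prediction targets
#' @return Character vector.
#' @export
cr_target_names <- function() c("CVP", "SV", "CO", "EF", "PaO2", "PaCO2")

#' Assemble a regression dataset from a population table
#'
#' @param subjects Population subjects data.frame (normally the accepted
#'   subset or a [split_population()] part).
#' @param target One of [cr_target_names()].
#' @param role `"train"` or `"test"` tag.
#' @return Object of class `cr_dataset`: list with `X` (n x 4 matrix),
#'   `y`, `target`, `role`.
#' @export
make_dataset <- function(subjects, target, role = "train") {
  stopifnot(target %in% cr_target_names())
  feats <- cr_feature_names()
  miss <- setdiff(c(feats, target), names(subjects))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(subjects[, feats])
  y <- subjects[[target]]
  ok <- stats::complete.cases(X) & is.finite(y)
  if (!all(ok)) {
    X <- X[ok, , drop = FALSE]
    y <- y[ok]
  }
  if (nrow(X) < 2) stop("need at least 2 complete rows")
  structure(list(X = X, y = y, target = target, role = role),
            class = "cr_dataset")
}

#' GPR tuning configuration
#'
#' @param n_iter Randomized-search iterations.
#' @param folds Cross-validation folds.
#' @param seed Seed for fold shuffling and hyperparameter draws.
#' @param signal_sd Log-uniform search range for the signal SD.
#' @param length_scale Log-uniform range for the isotropic length-scale
#'   (z-scored feature units).
#' @param noise_sd Log-uniform range for the noise SD (target units).
#' @return List of class `cr_gpr_config`.
#' @export
gpr_config <- function(n_iter = 50L, folds = 10L, seed = 1L,
                       signal_sd = c(1e-1, 1e2),
                       length_scale = c(1e-1, 1e2),
                       noise_sd = c(1e-8, 1e-1)) {
  structure(list(n_iter = as.integer(n_iter), folds = as.integer(folds),
                 seed = as.integer(seed), signal_sd = signal_sd,
                 length_scale = length_scale, noise_sd = noise_sd),
            class = "cr_gpr_config")
}

.sqdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

.JITTER <- 1e-8

# core GP fit at fixed hyperparameters on pre-scaled features
.gp_fit_core <- function(Xs, y, hyper) {
  n <- nrow(Xs)
  K <- hyper$sigma_f^2 * exp(-0.5 * .sqdist(Xs, Xs) / hyper$ell^2)
  diag(K) <- diag(K) + hyper$sigma_n^2 + .JITTER
  U <- chol(K)
  ybar <- mean(y)
  alpha <- backsolve(U, forwardsolve(t(U), y - ybar))
  list(U = U, alpha = alpha, ybar = ybar, Xs = Xs, hyper = hyper)
}

.gp_predict_core <- function(core, Xs_new, want_sd = FALSE) {
  Ks <- core$hyper$sigma_f^2 *
    exp(-0.5 * .sqdist(core$Xs, Xs_new) / core$hyper$ell^2)
  mu <- core$ybar + drop(crossprod(Ks, core$alpha))
  if (!want_sd) return(list(mean = mu))
  v <- forwardsolve(t(core$U), Ks)
  var_lat <- core$hyper$sigma_f^2 - colSums(v^2)
  var_lat[var_lat < 0] <- 0
  list(mean = mu, sd = sqrt(var_lat + core$hyper$sigma_n^2))
}

#' Fit a Gaussian-process regressor
#'
#' @param train A `cr_dataset` with at least 20 rows.
#' @param config A [gpr_config()].
#' @return Object of class `cr_gpr`: fitted hyperparameters, z-scoring
#'   statistics (training data only), Cholesky factors, and the tuning
#'   record (search draws, fold assignment seed, CV scores). A constant
#'   target yields a flagged model predicting that constant.
#' @examples
#' \donttest{
#' vp <- make_fixture_population(256, "vp1", seed = 1)
#' vp <- classify_cvrd(apply_filters(vp))
#' sp <- split_population(vp, 0.8, seed = 2)
#' m <- fit_gpr(make_dataset(sp$train, "SV"), gpr_config(n_iter = 10))
#' }
#' @export
fit_gpr <- function(train, config = gpr_config()) {
  stopifnot(inherits(train, "cr_dataset"))
  X <- train$X
  y <- train$y
  n <- nrow(X)
  if (n < 20) stop("need at least 20 training rows")
  if (stats::sd(y) == 0) {
    return(structure(list(constant = TRUE, value = y[1],
                          target = train$target,
                          feature_names = colnames(X)),
                     class = "cr_gpr"))
  }
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")

  draws <- .with_seed(config$seed, {
    data.frame(
      sigma_f = 10^stats::runif(config$n_iter,
                                log10(config$signal_sd[1]),
                                log10(config$signal_sd[2])),
      ell = 10^stats::runif(config$n_iter,
                            log10(config$length_scale[1]),
                            log10(config$length_scale[2])),
      sigma_n = 10^stats::runif(config$n_iter,
                                log10(config$noise_sd[1]),
                                log10(config$noise_sd[2]))
    )
  })
  fold <- .with_seed(config$seed + 1L,
                     sample(rep_len(seq_len(config$folds), n)))
  scores <- vapply(seq_len(config$n_iter), function(i) {
    hyper <- as.list(draws[i, ])
    errs <- vapply(seq_len(config$folds), function(f) {
      tr <- fold != f
      if (sum(tr) < 2 || sum(!tr) < 1) return(NA_real_)
      core <- tryCatch(.gp_fit_core(Xs[tr, , drop = FALSE], y[tr], hyper),
                       error = function(e) NULL)
      if (is.null(core)) return(Inf)
      pr <- .gp_predict_core(core, Xs[!tr, , drop = FALSE])
      max(abs(pr$mean - y[!tr]))
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  best <- which.min(scores)
  hyper <- as.list(draws[best, ])
  core <- .gp_fit_core(Xs, y, hyper)
  structure(list(constant = FALSE, target = train$target,
                 feature_names = colnames(X),
                 center = mu, scale = sdev, hyper = hyper, core = core,
                 y = y,
                 tuning = list(draws = draws, scores = scores, best = best,
                               folds = config$folds, seed = config$seed,
                               scoring = "max_absolute_error")),
            class = "cr_gpr")
}

#' Predict with a fitted GPR model
#'
#' @param object A `cr_gpr`.
#' @param X Matrix or data.frame with the training feature columns.
#' @param ... Unused.
#' @return data.frame with `mean` and `sd` (predictive SD including the
#'   fitted noise level), one row per input row, order preserving.
#' @export
predict.cr_gpr <- function(object, X, ...) {
  if (is.data.frame(X)) {
    miss <- setdiff(object$feature_names, names(X))
    if (length(miss)) stop("missing feature(s): ",
                           paste(miss, collapse = ", "))
    X <- as.matrix(X[, object$feature_names, drop = FALSE])
  } else {
    if (ncol(X) != length(object$feature_names)) {
      stop("feature matrix must have ", length(object$feature_names),
           " columns")
    }
    if (!is.null(colnames(X)) &&
        !identical(colnames(X), object$feature_names)) {
      stop("feature columns must be ",
           paste(object$feature_names, collapse = ", "))
    }
  }
  if (isTRUE(object$constant)) {
    return(data.frame(mean = rep(object$value, nrow(X)),
                      sd = rep(0, nrow(X))))
  }
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  pr <- .gp_predict_core(object$core, Xs, want_sd = TRUE)
  data.frame(mean = pr$mean, sd = pr$sd)
}

#' @export
print.cr_gpr <- function(x, ...) {
  if (isTRUE(x$constant)) {
    cat("<cr_gpr> constant model for", x$target, "=", x$value, "\n")
  } else {
    cat(sprintf(
      "<cr_gpr> target %s: sigma_f = %.3g, l = %.3g, sigma_n = %.3g (n = %d)\n",
      x$target, x$hyper$sigma_f, x$hyper$ell, x$hyper$sigma_n, length(x$y)))
  }
  invisible(x)
}

#' Point-prediction error metrics
#'
#' Percentage relative errors RE_j = 100 |yhat_j - y_j| / |y_j| with a
#' zero-denominator guard (|y_j| < `zero_tol` excludes the point from the
#' relative metrics; its absolute error is still reported), plus
#' R^2 = 1 - SS_res / SS_tot.
#'
#' @param y_pred Predicted values.
#' @param y_true Observed values (same length).
#' @param zero_tol Denominator guard, default 1e-6.
#' @return Object of class `cr_metrics`: list with `r2`, `max_re`, `mre`,
#'   `re` (per-point vector, `NA` where guarded), `abs_err`, `n_guarded`.
#' @export
evaluate_metrics <- function(y_pred, y_true, zero_tol = 1e-6) {
  if (length(y_pred) != length(y_true)) stop("length mismatch")
  abs_err <- abs(y_pred - y_true)
  guard <- abs(y_true) < zero_tol
  re <- ifelse(guard, NA_real_, 100 * abs_err / abs(y_true))
  ss_res <- sum((y_true - y_pred)^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  structure(list(r2 = 1 - ss_res / ss_tot,
                 max_re = if (all(guard)) NA_real_ else max(re, na.rm = TRUE),
                 mre = if (all(guard)) NA_real_ else mean(re, na.rm = TRUE),
                 re = re, abs_err = abs_err, n_guarded = sum(guard)),
            class = "cr_metrics")
}

#' @export
print.cr_metrics <- function(x, ...) {
  cat(sprintf("<cr_metrics> R2 = %.3f, maxRE = %.2f%%, MRE = %.2f%%\n",
              x$r2, x$max_re, x$mre))
  invisible(x)
}

#' Learning curve of the cross-validated maximum error
#'
#' The training set is split into shuffled CV folds once; for each requested
#' training size m, the model (at fixed hyperparameters) is fitted on a
#' seeded size-m subset of each fold's training portion and scored by the
#' maximum absolute error on that fold's full validation portion. Because
#' the validation folds are identical across sizes, scores are comparable
#' and the curve reflects the value of additional training data alone.
#'
#' @param train A `cr_dataset`.
#' @param sizes Training sizes; each must be at most the CV training-portion
#'   size, `floor(n * (folds - 1) / folds)`.
#' @param hyper Hyperparameter list (`sigma_f`, `ell`, `sigma_n`), e.g. from
#'   a fitted model's `$hyper`; when `NULL` a model is tuned on the full
#'   training set first.
#' @param config A [gpr_config()] (folds / seeds; tuning budget only used
#'   when `hyper` is `NULL`).
#' @return data.frame with `size`, `cv_max_error` (target units), and
#'   `cv_max_re` (percent, relative to the held-out targets).
#' @export
learning_curve_gpr <- function(train, sizes, hyper = NULL,
                               config = gpr_config()) {
  stopifnot(inherits(train, "cr_dataset"))
  n <- nrow(train$X)
  cap <- floor(n * (config$folds - 1) / config$folds)
  if (any(sizes > cap)) {
    stop("a requested size exceeds the cross-validation training portion (",
         cap, ")")
  }
  if (is.null(hyper)) hyper <- fit_gpr(train, config)$hyper
  mu <- colMeans(train$X)
  sdev <- apply(train$X, 2, stats::sd)
  sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(train$X, 2, mu), 2, sdev, "/")
  y <- train$y
  fold <- .with_seed(config$seed + 1L,
                     sample(rep_len(seq_len(config$folds), n)))
  errs <- array(NA_real_, c(length(sizes), config$folds, 2))
  for (f in seq_len(config$folds)) {
    tr_idx <- which(fold != f)
    va_idx <- which(fold == f)
    if (length(va_idx) < 1) next
    ord <- .with_seed(config$seed + 100L + f, sample(tr_idx))
    for (si in seq_along(sizes)) {
      take <- ord[seq_len(sizes[si])]
      core <- .gp_fit_core(Xs[take, , drop = FALSE], y[take], hyper)
      pr <- .gp_predict_core(core, Xs[va_idx, , drop = FALSE])
      ae <- abs(pr$mean - y[va_idx])
      errs[si, f, 1] <- max(ae)
      errs[si, f, 2] <- max(100 * ae / pmax(abs(y[va_idx]), 1e-6))
    }
  }
  out <- data.frame(size = sizes,
                    cv_max_error = apply(errs[, , 1, drop = FALSE], 1, mean,
                                         na.rm = TRUE),
                    cv_max_re = apply(errs[, , 2, drop = FALSE], 1, mean,
                                      na.rm = TRUE))
  rownames(out) <- NULL
  out
}
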