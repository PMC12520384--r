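# Sensitivity analysis: derivative-based local scores with ranking, and
# variance-based total-order (Sobol') indices.
#
# The local score is the dimensionless logarithmic sensitivity
#   S = (P_hat / M_hat) * dM/dP,
# with the derivative approximated by a centered finite difference at a
# relative step h (default 0.1, i.e. a 10% variation below and above the
# baseline). For M = c * P^k the score converges to k with error O(h^2) and
# is exact for quadratics.

#' Local derivative-based sensitivity score
#'
#' @param model_fn Function mapping a named parameter vector (or a
#'   `cr_params`) to a named numeric vector of outputs.
#' @param params Baseline parameter vector P-hat.
#' @param param Name of the parameter to perturb.
#' @param output Name of the output to read.
#' @param rel_step Relative step h in (0, 0.5); default 0.1.
#' @return Scalar score, or `NA` (with attribute `reason`) when the baseline
#'   output is zero or a perturbed evaluation fails.
#' @examples
#' f <- function(p) c(M = p[["P"]]^2)
#' local_sensitivity(f, c(P = 2), "P", "M")  # exactly 2
#' @export
local_sensitivity <- function(model_fn, params, param, output,
                              rel_step = 0.1) {
  stopifnot(rel_step > 0, rel_step < 0.5)
  p0 <- unclass(params)
  if (!param %in% names(p0)) stop("unknown parameter: ", param)
  M0 <- .eval_output(model_fn, params, output)
  if (!is.finite(M0)) {
    return(structure(NA_real_, reason = "model_failure_at_baseline"))
  }
  if (M0 == 0) return(structure(NA_real_, reason = "zero_baseline_output"))
  Ph <- p0[[param]]
  up <- params; up[param] <- Ph * (1 + rel_step)
  dn <- params; dn[param] <- Ph * (1 - rel_step)
  Mu <- .eval_output(model_fn, up, output)
  Md <- .eval_output(model_fn, dn, output)
  if (!is.finite(Mu) || !is.finite(Md)) {
    return(structure(NA_real_, reason = "model_failure_at_perturbed_point"))
  }
  (Ph / M0) * (Mu - Md) / (2 * rel_step * Ph)
}

.eval_output <- function(model_fn, params, output) {
  out <- tryCatch(model_fn(params), error = function(e) NULL)
  if (is.null(out)) return(NA_real_)
  out <- unlist(out)
  if (!output %in% names(out)) return(NA_real_)
  as.numeric(out[[output]])
}

#' Local sensitivity table with per-output parameter ranking
#'
#' One [local_sensitivity()] evaluation per (parameter, output) pair.
#' Per-entry failures are recorded as `NA` with a reason, not raised.
#' Rankings sort by absolute score, descending; ties break lexicographically
#' by parameter name for reproducibility.
#'
#' @inheritParams local_sensitivity
#' @param params_to_vary Character vector of parameter names.
#' @param outputs Character vector of output names.
#' @param top Number of top-ranked parameters kept per output (default 5).
#' @return Object of class `cr_sensitivity`: list with `scores` (matrix
#'   parameters x outputs), `ranking` (long data.frame), `baseline`,
#'   `rel_step`.
#' @export
sensitivity_table <- function(model_fn, params, params_to_vary, outputs,
                              rel_step = 0.1, top = 5L) {
  S <- matrix(NA_real_, length(params_to_vary), length(outputs),
              dimnames = list(params_to_vary, outputs))
  reasons <- character(0)
  for (pn in params_to_vary) {
    for (on in outputs) {
      s <- local_sensitivity(model_fn, params, pn, on, rel_step)
      S[pn, on] <- as.numeric(s)
      r <- attr(s, "reason")
      if (!is.null(r)) reasons[paste(pn, on, sep = ":")] <- r
    }
  }
  ranking <- do.call(rbind, lapply(outputs, function(on) {
    sc <- S[, on]
    ok <- !is.na(sc)
    ord <- order(-abs(sc[ok]), names(sc)[ok])
    nm <- names(sc)[ok][ord]
    n <- min(top, length(nm))
    if (n == 0) return(NULL)
    data.frame(output = on, rank = seq_len(n), parameter = nm[seq_len(n)],
               score = unname(sc[nm[seq_len(n)]]))
  }))
  structure(list(scores = S, ranking = ranking,
                 baseline = unclass(params)[params_to_vary],
                 rel_step = rel_step, failures = reasons),
            class = "cr_sensitivity")
}

#' @export
print.cr_sensitivity <- function(x, ...) {
  cat("<cr_sensitivity> ", nrow(x$scores), " parameters x ",
      ncol(x$scores), " outputs, h = ", x$rel_step, "\n", sep = "")
  print(head(x$ranking, 15))
  invisible(x)
}

#' Write / read a sensitivity report (long CSV, lossless round-trip)
#' @param x A `cr_sensitivity`.
#' @param path CSV path.
#' @return `path` invisibly; `read_sensitivity_csv` returns the long table.
#' @export
write_sensitivity_csv <- function(x, path) {
  stopifnot(inherits(x, "cr_sensitivity"))
  long <- expand.grid(parameter = rownames(x$scores),
                      output = colnames(x$scores),
                      stringsAsFactors = FALSE)
  long$score <- as.vector(x$scores)
  rk <- x$ranking
  key <- paste(long$parameter, long$output)
  rkey <- paste(rk$parameter, rk$output)
  long$rank <- rk$rank[match(key, rkey)]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensitivity_csv
#' @export
read_sensitivity_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Variance-based total-order sensitivity indices
#'
#' Two estimation routes are provided. Given a model function and a
#' parameter space, a Sobol'-sampling pick-and-freeze scheme with the Jansen
#' estimator is used (extra model runs, reference quality). Given an already
#' simulated population (a `cr_population`), a given-data estimator is used:
#' an orthonormal polynomial HDMR expansion (shifted Legendre main effects up
#' to degree 3 plus bilinear pairwise interactions) is least-squares fitted
#' to the sample and total indices are read off the coefficient variances.
#' Indices are normalized per output to sum to one; sub-threshold values are
#' a display concern only and are never dropped from the data.
#'
#' @param x A `cr_population`, or a model function `f(params) ->` named
#'   outputs when `space` and `n` are given.
#' @param space A [parameter_space()] (function route).
#' @param n Number of base samples (function route; >= 256 recommended).
#' @param outputs Output names (default: all 12 indexes for populations).
#' @param seed Seed for the sampling / scrambling.
#' @return Object of class `cr_global_indices`: list with `total`
#'   (matrix dimension x output, column-normalized), `raw` (unnormalized),
#'   `estimator`, `n`.
#' @export
global_total_indices <- function(x, space = NULL, n = NULL, outputs = NULL,
                                 seed = 1L) {
  if (inherits(x, "cr_population")) {
    .gti_given_data(x, outputs = outputs)
  } else if (is.function(x)) {
    if (is.null(space) || is.null(n)) {
      stop("the model-function route needs `space` and `n`")
    }
    .gti_jansen(x, space, n, outputs, seed)
  } else {
    stop("`x` must be a cr_population or a model function")
  }
}

.normalize_gti <- function(raw) {
  total <- raw
  for (j in seq_len(ncol(raw))) {
    cs <- sum(raw[, j])
    total[, j] <- if (is.finite(cs) && cs > 0) raw[, j] / cs else NA_real_
  }
  total
}

# Jansen pick-and-freeze estimator on scrambled-Sobol' base samples:
# ST_i = mean((f(A) - f(AB_i))^2) / (2 Var(f))
.gti_jansen <- function(model_fn, space, n, outputs, seed) {
  d <- nrow(space$dims)
  if (2 * d <= 10) {
    u <- sobol_points(n, 2L * d, seed = seed)
    A <- u[, seq_len(d), drop = FALSE]
    B <- u[, d + seq_len(d), drop = FALSE]
  } else {
    A <- sobol_points(n, d, seed = seed)
    B <- sobol_points(n, d, seed = seed + 1L)
  }
  evalu <- function(U) {
    ps <- .space_transform(space, U)
    tmpl <- unlist(model_fn(ps[[1]]))
    out <- matrix(NA_real_, length(ps), length(tmpl),
                  dimnames = list(NULL, names(tmpl)))
    for (i in seq_along(ps)) out[i, ] <- unlist(model_fn(ps[[i]]))
    out
  }
  fA <- evalu(A)
  if (is.null(outputs)) outputs <- colnames(fA)
  fA <- fA[, outputs, drop = FALSE]
  fB <- evalu(B)[, outputs, drop = FALSE]
  varf <- apply(rbind(fA, fB), 2, stats::var)
  raw <- matrix(NA_real_, d, length(outputs),
                dimnames = list(space$dims$dimension, outputs))
  for (i in seq_len(d)) {
    ABi <- A
    ABi[, i] <- B[, i]
    fABi <- evalu(ABi)[, outputs, drop = FALSE]
    raw[i, ] <- colMeans((fA - fABi)^2) / (2 * varf)
  }
  flagged <- outputs[!is.finite(varf) | varf <= 0]
  structure(list(total = .normalize_gti(raw), raw = raw,
                 estimator = "jansen_sobol", n = n, flagged = flagged),
            class = "cr_global_indices")
}

# shifted Legendre polynomials, orthonormal on U(0,1)
.legendre01 <- function(u, degree) {
  z <- 2 * u - 1
  cbind(sqrt(3) * z,
        sqrt(5) * (1.5 * z^2 - 0.5),
        sqrt(7) * (2.5 * z^3 - 1.5 * z))[, seq_len(degree), drop = FALSE]
}

.gti_given_data <- function(vp, outputs = NULL, degree = 3L) {
  if (is.null(outputs)) outputs <- cr_index_names()
  dims <- vp$space$dims$dimension
  d <- length(dims)
  U <- as.matrix(vp$subjects[, paste0("unit_", dims), drop = FALSE])
  n <- nrow(U)
  if (n < 256) stop("given-data estimator needs >= 256 samples")
  basis <- list()
  labels <- character(0)
  owner <- list()
  for (i in seq_len(d)) {
    P <- .legendre01(U[, i], degree)
    for (k in seq_len(degree)) {
      basis[[length(basis) + 1L]] <- P[, k]
      labels <- c(labels, sprintf("%s^%d", dims[i], k))
      owner[[length(owner) + 1L]] <- i
    }
  }
  if (d >= 2) {
    P1 <- vapply(seq_len(d), function(i) .legendre01(U[, i], 1L)[, 1],
                 numeric(n))
    for (i in seq_len(d - 1)) {
      for (j in (i + 1):d) {
        basis[[length(basis) + 1L]] <- P1[, i] * P1[, j]
        labels <- c(labels, sprintf("%s:%s", dims[i], dims[j]))
        owner[[length(owner) + 1L]] <- c(i, j)
      }
    }
  }
  X <- do.call(cbind, basis)
  colnames(X) <- labels
  raw <- matrix(NA_real_, d, length(outputs),
                dimnames = list(dims, outputs))
  flagged <- character(0)
  for (on in outputs) {
    y <- vp$subjects[[on]]
    ok <- is.finite(y)
    if (stats::var(y[ok]) <= 0 || sum(ok) < ncol(X) + 2) {
      flagged <- c(flagged, on)
      next
    }
    fit <- stats::lm.fit(cbind(1, X[ok, , drop = FALSE]), y[ok])
    beta <- fit$coefficients[-1]
    beta[is.na(beta)] <- 0
    # orthonormal basis: each coefficient^2 is that term's variance share
    for (i in seq_len(d)) {
      sel <- vapply(owner, function(o) i %in% o, logical(1))
      raw[i, on] <- sum(beta[sel]^2)
    }
  }
  structure(list(total = .normalize_gti(raw), raw = raw,
                 estimator = "hdmr_polynomial_given_data",
                 n = n, flagged = flagged),
            class = "cr_global_indices")
}

#' @export
print.cr_global_indices <- function(x, ...) {
  cat("<cr_global_indices> estimator:", x$estimator, " n =", x$n, "\n")
  print(round(x$total, 3))
  invisible(x)
}
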