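# Virtual-population machinery: parameter-space presets, scrambled-Sobol'
# sampling with linkage rules, population simulation, physiological
# filtering, multi-label disease classification, sampling-size convergence,
# and train/test splitting.

#' Parameter-space presets for virtual-population generation
#'
#' `"vp1"` is the 9-dimensional space: total blood volume, venous unstressed
#' volume, basal cardiac cycle linked with the vagal gain (one coordinate
#' moves both co-monotonically), baroreflex activation level, basal maximum
#' left-ventricular elastance, inspired O2 fraction, hemoglobin content,
#' maximum hemoglobin-bound CO2 concentration, and the CO2 dissociation
#' exponent. `"vp2"` is the 10-dimensional space where the three ventricular
#' elastance parameters move together as one coordinate and the
#' dissociation-curve constants are varied individually.
#'
#' @param preset `"vp1"`, `"vp2"`, or `"custom"` (then supply `dims` and
#'   `targets`).
#' @param dims For `"custom"`: data.frame with columns `dimension`, `lower`,
#'   `upper`, `unit`.
#' @param targets For `"custom"`: named list mapping each dimension to a
#'   data.frame `param`, `lower`, `upper` of linked target parameters.
#' @return Object of class `cr_space`.
#' @export
parameter_space <- function(preset = c("vp1", "vp2", "custom"),
                            dims = NULL, targets = NULL) {
  preset <- match.arg(preset)
  one <- function(param, lower, upper) {
    data.frame(param = param, lower = lower, upper = upper)
  }
  if (preset == "vp1") {
    targets <- list(
      Vtot = one("Vtot", 4373.0, 6164.4),
      Vu_ven = one("Vu_ven", 2574.9, 3629.6),
      T0_GTv = rbind(one("T0", 0.41, 0.59), one("GTv", 0.07, 0.11)),
      Pn = one("Pn", 81.9, 102.1),
      Emax_LV0 = one("Emax_LV0", 1.67, 3.11),
      FiO2 = one("FiO2", 14.7, 27.3),
      hgb = one("hgb", 0.15, 0.19),
      Csat_CO2 = one("Csat_CO2", 1.7, 2.2),
      hCO2 = one("hCO2", 1.7, 1.9)
    )
  } else if (preset == "vp2") {
    targets <- list(
      Vtot = one("Vtot", 4373.0, 6164.4),
      Vu_ven = one("Vu_ven", 2574.9, 3629.6),
      T0 = one("T0", 0.41, 0.59),
      FiO2 = one("FiO2", 14.7, 27.3),
      hgb = one("hgb", 0.15, 0.19),
      Emax_kE = rbind(one("Emax_LV0", 1.79, 2.99),
                      one("kE_LV", 0.01, 0.02),
                      one("kE_RV", 0.008, 0.014)),
      Csat_CO2 = one("Csat_CO2", 1.7, 2.2),
      hO2 = one("hO2", 0.38, 0.39),
      hCO2 = one("hCO2", 1.7, 1.9),
      kCO2 = one("kCO2", 110, 279)
    )
  } else {
    if (is.null(dims) || is.null(targets)) {
      stop("custom spaces need `dims` and `targets`")
    }
  }
  if (is.null(dims)) {
    dims <- data.frame(dimension = names(targets),
                       lower = vapply(targets, function(t) t$lower[1],
                                      numeric(1)),
                       upper = vapply(targets, function(t) t$upper[1],
                                      numeric(1)))
    rownames(dims) <- NULL
  }
  bad <- vapply(targets, function(t) any(t$lower >= t$upper), logical(1))
  if (any(bad)) stop("lower must be < upper for: ",
                     paste(names(targets)[bad], collapse = ", "))
  structure(list(preset = preset, dims = dims, targets = targets),
            class = "cr_space")
}

#' @export
print.cr_space <- function(x, ...) {
  cat("<cr_space> preset:", x$preset, "-", nrow(x$dims),
      "sampled dimensions\n")
  print(x$dims)
  invisible(x)
}

# map an n x d unit-hypercube matrix to a list of full parameter sets;
# linked targets share the coordinate co-monotonically (each target at its
# lower bound exactly when the coordinate is 0)
.space_transform <- function(space, U, base = baseline_parameters()) {
  dims <- space$dims$dimension
  stopifnot(ncol(U) == length(dims))
  lapply(seq_len(nrow(U)), function(i) {
    p <- unclass(base)
    for (j in seq_along(dims)) {
      tg <- space$targets[[dims[j]]]
      p[tg$param] <- tg$lower + U[i, j] * (tg$upper - tg$lower)
    }
    structure(p, class = "cr_params")
  })
}

#' Sample a parameter space with scrambled Sobol' points
#'
#' Low-discrepancy points in the unit hypercube are affinely mapped to each
#' dimension's range; linkage groups expand one coordinate into all member
#' parameters co-monotonically. Non-sampled parameters stay at baseline.
#'
#' @param space A [parameter_space()].
#' @param n Number of points.
#' @param seed Scramble seed (deterministic point set per seed).
#' @param base Baseline parameter set for non-sampled parameters.
#' @return List of `cr_params`, with the unit-hypercube coordinates in
#'   attribute `"unit"` (an `n x d` matrix with dimension names).
#' @export
sample_space <- function(space, n, seed = 1L,
                         base = baseline_parameters()) {
  stopifnot(inherits(space, "cr_space"), n >= 1)
  d <- nrow(space$dims)
  U <- sobol_points(n, d, seed = seed, scramble = TRUE)
  colnames(U) <- space$dims$dimension
  ps <- .space_transform(space, U, base)
  attr(ps, "unit") <- U
  attr(ps, "seed") <- seed
  ps
}

#' Simulate a virtual population
#'
#' Runs the simulator for every parameter set and collects one subject
#' record per set. Simulator failures are recorded as rejected subjects with
#' reason `integration_failure`; they never abort the population run.
#' Results are independent of evaluation order.
#'
#' @param paramsets List of parameter sets from [sample_space()].
#' @param config A [sim_config()]; with `stationarity = TRUE` the
#'   two-window deltas needed by the stationarity filter are stored.
#' @param space The originating [parameter_space()] (kept for provenance and
#'   for given-data sensitivity analysis).
#' @param simulator Simulation function `(params, config) -> cr_trace` —
#'   pluggable so that a different model implementation can be dropped in.
#' @param progress Print a dot every 64 subjects.
#' @return Object of class `cr_population`; `$subjects` is the population
#'   table (one row per subject).
#' @export
generate_population <- function(paramsets, config = sim_config("fast"),
                                space = NULL, simulator = simulate_subject,
                                progress = FALSE) {
  U <- attr(paramsets, "unit")
  seed <- attr(paramsets, "seed") %||% NA_integer_
  inames <- cr_index_names()
  rows <- lapply(seq_along(paramsets), function(i) {
    if (progress && i %% 64 == 0) cat(".")
    p <- paramsets[[i]]
    tr <- simulator(p, config)
    rec <- data.frame(sample_id = i, seed = seed)
    if (!is.null(U)) {
      for (dn in colnames(U)) rec[[paste0("unit_", dn)]] <- U[i, dn]
    }
    for (pn in cr_named_parameters()) rec[[pn]] <- unclass(p)[[pn]]
    if (inherits(tr, "cr_sim_failure")) {
      for (v in inames) rec[[v]] <- NA_real_
      rec$sim_ok <- FALSE
    } else {
      idx <- if (inherits(tr, "cr_indexset")) tr else extract_indexes(tr)
      for (v in inames) rec[[v]] <- idx[[v]]
      rec$sim_ok <- TRUE
      tr2 <- if (is.data.frame(tr)) attr(tr, "trace2") else NULL
      if (!is.null(tr2)) {
        idx2 <- extract_indexes(tr2)
        for (v in inames) {
          a <- idx[[v]]; b <- idx2[[v]]
          rec[[paste0("dabs_", v)]] <- abs(b - a)
          rec[[paste0("delta_", v)]] <-
            if (abs(a) >= 0.5) 100 * abs(b - a) / abs(a) else NA_real_
        }
      }
    }
    rec
  })
  if (progress) cat("\n")
  all_cols <- unique(unlist(lapply(rows, names)))
  subjects <- do.call(rbind, lapply(rows, function(r) {
    for (m in setdiff(all_cols, names(r))) r[[m]] <- NA_real_
    r[all_cols]
  }))
  subjects$accepted <- NA
  subjects$reasons <- NA_character_
  subjects$labels <- NA_character_
  structure(list(subjects = subjects, space = space, n = length(paramsets),
                 seed = seed, config = config),
            class = "cr_population")
}

#' @export
print.cr_population <- function(x, ...) {
  cat("<cr_population> n =", x$n)
  if (!all(is.na(x$subjects$accepted))) {
    cat(", accepted =", sum(x$subjects$accepted, na.rm = TRUE))
  }
  cat("\n")
  invisible(x)
}

#' Admissible physiological/pathological ranges for the filter
#'
#' @return data.frame with `variable`, `min`, `max`, `unit` (bounds are
#'   inclusive: a subject is rejected only when a variable falls strictly
#'   outside its range).
#' @export
filter_criteria <- function() {
  data.frame(
    variable = cr_index_names(),
    min = c(45, 84, 59, 13, 74, 0, 44, 42, 45, 80, 70, 30),
    max = c(94, 174, 110, 86, 132, 10, 128, 150, 74, 100, 110, 50),
    unit = c("beats/min", "mmHg", "mmHg", "mmHg", "mmHg", "mmHg", "mL",
             "mL/s", "%", "%", "mmHg", "mmHg")
  )
}

#' Disease classification cutoffs
#'
#' Multi-label classification of accepted subjects; all comparisons are
#' strict. The three blood-pressure rows map to the single label
#' `hypertension` (logical OR).
#'
#' @return data.frame with `variable`, `op` (`"<"` or `">"`), `cutoff`,
#'   `label`.
#' @export
cvrd_cutoffs <- function() {
  data.frame(
    variable = c("HR", "CSBP", "CDBP", "MAP", "EF", "PaCO2", "PaCO2"),
    op = c("<", ">", ">", ">", "<", "<", ">"),
    cutoff = c(60, 130, 80, 100, 50, 35, 45),
    label = c("bradycardia", "hypertension", "hypertension", "hypertension",
              "reduced cardiac function", "hyperventilation",
              "hypoventilation")
  )
}

#' Apply stationarity and range filters to a population
#'
#' The stationarity criterion: any variable whose cycle-averaged value
#' differs by more than `stationarity_tol` percent between the two save
#' windows rejects the subject; near-zero first-window means (|mean| < 0.5
#' unit) fall back to an absolute tolerance of 0.1 unit. Applied only when
#' two-window deltas are present. The range criterion: any variable strictly
#' outside its admissible range rejects the subject. Every violated
#' criterion is recorded, not just the first; filtering is idempotent.
#'
#' @param vp A `cr_population`.
#' @param criteria Range table, default [filter_criteria()].
#' @param stationarity_tol Percentage tolerance for the stationarity rule.
#' @param stationarity_abs_tol Absolute fallback tolerance (units of the
#'   variable) when the first-window mean is below 0.5 unit.
#' @return The population with `accepted` / `reasons` filled in.
#' @export
apply_filters <- function(vp, criteria = filter_criteria(),
                          stationarity_tol = 1,
                          stationarity_abs_tol = 0.1) {
  stopifnot(inherits(vp, "cr_population"))
  sub <- vp$subjects
  missing_vars <- setdiff(criteria$variable, names(sub))
  if (length(missing_vars)) {
    stop("population table lacks variable(s): ",
         paste(missing_vars, collapse = ", "))
  }
  has_deltas <- any(grepl("^delta_", names(sub)))
  reasons <- vector("list", nrow(sub))
  for (i in seq_len(nrow(sub))) {
    r <- character(0)
    if (isFALSE(sub$sim_ok[i])) {
      r <- c(r, "integration_failure")
    } else {
      for (k in seq_len(nrow(criteria))) {
        v <- criteria$variable[k]
        x <- sub[[v]][i]
        if (!is.finite(x) || x < criteria$min[k] || x > criteria$max[k]) {
          r <- c(r, paste0(v, "_range"))
        }
      }
      if (has_deltas) {
        for (v in criteria$variable) {
          dp <- sub[[paste0("delta_", v)]][i]
          da <- sub[[paste0("dabs_", v)]][i]
          viol <- if (is.finite(dp)) dp > stationarity_tol
                  else is.finite(da) && da > stationarity_abs_tol
          if (isTRUE(viol)) r <- c(r, paste0(v, "_stationarity"))
        }
      }
    }
    reasons[[i]] <- r
  }
  sub$reasons <- vapply(reasons, paste, character(1), collapse = ";")
  sub$accepted <- !nzchar(sub$reasons)
  vp$subjects <- sub
  vp
}

#' Classify accepted subjects into disease labels
#'
#' @param vp A filtered `cr_population`.
#' @param cutoffs Cutoff table, default [cvrd_cutoffs()].
#' @return The population with the `labels` column filled for accepted
#'   subjects (semicolon-joined, empty string = healthy).
#' @export
classify_cvrd <- function(vp, cutoffs = cvrd_cutoffs()) {
  stopifnot(inherits(vp, "cr_population"))
  if (all(is.na(vp$subjects$accepted))) {
    stop("run apply_filters() before classify_cvrd()")
  }
  sub <- vp$subjects
  sub$labels <- NA_character_
  for (i in which(sub$accepted)) {
    lab <- character(0)
    for (k in seq_len(nrow(cutoffs))) {
      x <- sub[[cutoffs$variable[k]]][i]
      hit <- if (cutoffs$op[k] == "<") x < cutoffs$cutoff[k]
             else x > cutoffs$cutoff[k]
      if (isTRUE(hit)) lab <- c(lab, cutoffs$label[k])
    }
    sub$labels[i] <- paste(unique(lab), collapse = ";")
  }
  vp$subjects <- sub
  vp
}

#' Summary statistics of the population indexes
#'
#' @param vp A `cr_population`.
#' @param accepted_only Restrict to accepted subjects (requires filtering).
#' @return data.frame with `variable`, `mean`, `sd`, `min`, `max`.
#' @export
population_summary <- function(vp, accepted_only = TRUE) {
  sub <- vp$subjects
  if (accepted_only) {
    if (all(is.na(sub$accepted))) stop("population is not filtered yet")
    sub <- sub[sub$accepted, , drop = FALSE]
  }
  do.call(rbind, lapply(cr_index_names(), function(v) {
    x <- sub[[v]]
    x <- x[is.finite(x)]
    data.frame(variable = v, mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x))
  }))
}

#' Sampling-size convergence errors
#'
#' Percentage error of each summary statistic at sample size n relative to
#' the largest-n reference: |e_n - e_ref| / |e_ref| * 100.
#'
#' @param stats_by_n Named list of [population_summary()] tables, names are
#'   the sample sizes.
#' @param ref Reference summary table (largest n).
#' @return Long data.frame `variable`, `statistic`, `n`, `error_pct`
#'   (`NA` with zero reference flagged in `defined`).
#' @export
convergence_errors <- function(stats_by_n, ref) {
  stats_cols <- c("mean", "sd", "min", "max")
  out <- do.call(rbind, lapply(names(stats_by_n), function(nn) {
    s <- stats_by_n[[nn]]
    do.call(rbind, lapply(seq_len(nrow(s)), function(i) {
      v <- s$variable[i]
      rrow <- ref[ref$variable == v, ]
      do.call(rbind, lapply(stats_cols, function(st) {
        e_ref <- rrow[[st]]
        defined <- is.finite(e_ref) && e_ref != 0
        data.frame(variable = v, statistic = st, n = as.integer(nn),
                   error_pct = if (defined) {
                     100 * abs(s[[st]][i] - e_ref) / abs(e_ref)
                   } else NA_real_,
                   defined = defined)
      }))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Split the accepted population into training and test sets
#'
#' Plain seeded shuffle; the training set takes `floor(fraction * N)`
#' subjects, the test set the remainder (disjoint and exhaustive).
#'
#' @param vp A filtered `cr_population` (or a subjects data.frame).
#' @param train_fraction In (0, 1); default 0.8.
#' @param seed Shuffle seed.
#' @return List with data.frames `train` and `test`.
#' @export
split_population <- function(vp, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  sub <- if (inherits(vp, "cr_population")) {
    if (all(is.na(vp$subjects$accepted))) stop("population is not filtered")
    vp$subjects[vp$subjects$accepted, , drop = FALSE]
  } else vp
  n <- nrow(sub)
  if (n < 2) stop("need at least 2 accepted subjects to split")
  perm <- .with_seed(seed, sample.int(n))
  ntr <- floor(train_fraction * n)
  list(train = sub[perm[seq_len(ntr)], , drop = FALSE],
       test = sub[perm[(ntr + 1):n], , drop = FALSE])
}

#' Write a population table to CSV (and Parquet when `arrow` is installed)
#' @param vp A `cr_population`.
#' @param path CSV output path; a sibling `.parquet` is written if possible.
#' @param parquet Also write Parquet when the `arrow` package is available.
#' @return `path` invisibly.
#' @export
write_population <- function(vp, path, parquet = FALSE) {
  utils::write.csv(vp$subjects, path, row.names = FALSE)
  if (parquet && requireNamespace("arrow", quietly = TRUE)) {
    arrow::write_parquet(vp$subjects, sub("\\.csv$", ".parquet", path))
  }
  invisible(path)
}
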