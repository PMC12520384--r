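# Configuration-driven orchestration of the full in-silico study:
# sample -> simulate (model or surrogate) -> filter -> classify ->
# sensitivity -> train -> evaluate -> propagate -> report.

#' Study configuration
#'
#' @param preset Population preset, `"vp1"` or `"vp2"`.
#' @param n Number of sampled subjects.
#' @param mode `"surrogate"` (analytic surrogate, milliseconds), `"fast"`
#'   or `"full"` (ODE simulator fidelity modes).
#' @param targets Prediction targets (default all six in-hospital
#'   variables).
#' @param seeds Named list with `sampling`, `split`, `tuning`,
#'   `propagation` integer seeds.
#' @param train_fraction Training share of the accepted population.
#' @param gpr A [gpr_config()] tuning budget.
#' @param spec An [error_spec()].
#' @param n_propagation Sobol' samples per perturbation box.
#' @param learning_sizes Training sizes for the learning curve (`NULL`
#'   skips it).
#' @param cross_preset Optional second preset evaluated with the models
#'   trained on `preset` (`NULL` skips cross-population validation).
#' @param surrogate A [surrogate_config()] used in surrogate mode.
#' @param out_dir Output directory (`NULL`: return results only).
#' @return List of class `cr_study_config`.
#' @export
study_config <- function(preset = "vp1", n = 512L, mode = "surrogate",
                         targets = cr_target_names(),
                         seeds = list(sampling = 1L, split = 2L,
                                      tuning = 3L, propagation = 4L),
                         train_fraction = 0.8,
                         gpr = gpr_config(seed = seeds$tuning),
                         spec = error_spec(), n_propagation = 256L,
                         learning_sizes = NULL, cross_preset = NULL,
                         surrogate = surrogate_config(),
                         out_dir = NULL) {
  stopifnot(mode %in% c("surrogate", "fast", "full"))
  structure(list(preset = preset, n = as.integer(n), mode = mode,
                 targets = targets, seeds = seeds,
                 train_fraction = train_fraction, gpr = gpr, spec = spec,
                 n_propagation = as.integer(n_propagation),
                 learning_sizes = learning_sizes,
                 cross_preset = cross_preset, surrogate = surrogate,
                 out_dir = out_dir),
            class = "cr_study_config")
}

#' Read / write a study configuration as YAML
#' @param path YAML file path.
#' @return `read_study_config`: a `cr_study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("preset", "n", "mode", "targets", "train_fraction",
               "n_propagation", "learning_sizes", "cross_preset",
               "out_dir")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$seeds)) args$seeds <- lapply(y$seeds, as.integer)
  if (!is.null(y$gpr)) args$gpr <- do.call(gpr_config, y$gpr)
  if (!is.null(y$spec)) args$spec <- do.call(error_spec, y$spec)
  if (!is.null(y$surrogate)) {
    args$surrogate <- do.call(surrogate_config, y$surrogate)
  }
  do.call(study_config, args)
}

#' @rdname read_study_config
#' @param config A `cr_study_config`.
#' @export
write_study_config <- function(config, path) {
  y <- unclass(config)
  y$gpr <- unclass(y$gpr)
  y$spec <- unclass(y$spec)
  y$surrogate <- unclass(y$surrogate)
  y$surrogate$noise_sd <- as.list(y$surrogate$noise_sd)
  yaml::write_yaml(y, path)
  invisible(path)
}

.build_population <- function(config) {
  if (config$mode == "surrogate") {
    make_fixture_population(config$n, config$preset,
                            config = config$surrogate,
                            seed = config$seeds$sampling)
  } else {
    space <- parameter_space(config$preset)
    ps <- sample_space(space, config$n, seed = config$seeds$sampling)
    generate_population(ps, sim_config(config$mode, stationarity = TRUE),
                        space = space)
  }
}

#' Run the full study pipeline
#'
#' Generates the population, applies the physiological filters and disease
#' classification, fits one GPR per target on the training split, evaluates
#' unperturbed and perturbed predictions on the test split, and assembles
#' the report tables (population summary, rejection/label bookkeeping,
#' global sensitivity, per-target metrics, feature-target Pearson
#' correlations on accepted subjects, optional learning curves and
#' cross-population validation). When `config$out_dir` is set every table
#' is also written to disk (CSV/JSON) together with the configuration and
#' seeds.
#'
#' @param config A [study_config()].
#' @param progress Print stage messages.
#' @return List of class `cr_study_report`.
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  stopifnot(inherits(config, "cr_study_config"))
  say <- function(...) if (progress) message(...)

  say("population [", config$preset, ", n = ", config$n, ", ",
      config$mode, "]")
  vp <- .build_population(config)
  vp <- classify_cvrd(apply_filters(vp))
  sub <- vp$subjects
  n_acc <- sum(sub$accepted)
  if (n_acc < 40) stop("too few accepted subjects (", n_acc, ")")

  reasons <- unlist(strsplit(sub$reasons[!sub$accepted], ";"))
  labels <- unlist(lapply(strsplit(sub$labels[sub$accepted], ";"),
                          function(x) if (!length(x) || !nzchar(x[1])) {
                            "healthy"
                          } else x))
  bookkeeping <- list(
    n_total = nrow(sub), n_accepted = n_acc,
    n_rejected = nrow(sub) - n_acc,
    rejection_reasons = as.data.frame(table(reason = reasons),
                                      stringsAsFactors = FALSE),
    label_counts = as.data.frame(table(label = labels),
                                 stringsAsFactors = FALSE))

  say("global sensitivity")
  gsa <- tryCatch(global_total_indices(vp), error = function(e) NULL)

  say("train/test split")
  split <- split_population(vp, config$train_fraction, config$seeds$split)

  acc <- sub[sub$accepted, ]
  cors <- do.call(rbind, lapply(cr_feature_names(), function(f) {
    data.frame(feature = f, target = config$targets,
               pearson = vapply(config$targets, function(tg)
                 stats::cor(acc[[f]], acc[[tg]]), numeric(1)))
  }))

  models <- list()
  metrics <- list()
  perturbed <- list()
  lcurves <- list()
  for (tg in config$targets) {
    say("GPR: ", tg)
    tr <- make_dataset(split$train, tg, "train")
    te <- make_dataset(split$test, tg, "test")
    m <- fit_gpr(tr, config$gpr)
    models[[tg]] <- m
    pred <- predict(m, te$X)
    metrics[[tg]] <- evaluate_metrics(pred$mean, te$y)
    perturbed[[tg]] <- propagate(m, te, config$spec,
                                 N = config$n_propagation,
                                 seed = config$seeds$propagation)
    if (!is.null(config$learning_sizes)) {
      sizes <- config$learning_sizes[config$learning_sizes <= nrow(tr$X)]
      if (length(sizes)) {
        lcurves[[tg]] <- cbind(target = tg,
                               learning_curve_gpr(tr, sizes, m$hyper,
                                                  config$gpr))
      }
    }
  }

  metric_table <- do.call(rbind, lapply(config$targets, function(tg) {
    mt <- metrics[[tg]]; pt <- perturbed[[tg]]
    data.frame(target = tg, r2 = mt$r2, max_re = mt$max_re, mre = mt$mre,
               max_repi = pt$max_repi, mrepi = pt$mrepi,
               cv_mean = pt$cv_mean, cv_sd = pt$cv_sd)
  }))

  cross <- NULL
  if (!is.null(config$cross_preset)) {
    say("cross-population validation: ", config$cross_preset)
    cfg2 <- config
    cfg2$preset <- config$cross_preset
    vp2 <- classify_cvrd(apply_filters(.build_population(cfg2)))
    acc2 <- vp2$subjects[vp2$subjects$accepted, ]
    cross <- list(
      population = vp2,
      metrics = do.call(rbind, lapply(config$targets, function(tg) {
        te2 <- make_dataset(acc2, tg, "test")
        pred <- predict(models[[tg]], te2$X)
        mt <- evaluate_metrics(pred$mean, te2$y)
        pt <- propagate(models[[tg]], te2, config$spec,
                        N = config$n_propagation,
                        seed = config$seeds$propagation)
        data.frame(target = tg, r2 = mt$r2, max_re = mt$max_re,
                   mre = mt$mre, max_repi = pt$max_repi, mrepi = pt$mrepi,
                   cv_mean = pt$cv_mean, cv_sd = pt$cv_sd)
      })))
  }

  report <- structure(list(
    config = config, population = vp, bookkeeping = bookkeeping,
    summary = population_summary(vp), global_sensitivity = gsa,
    split_sizes = c(train = nrow(split$train), test = nrow(split$test)),
    correlations = cors, models = models, metrics = metric_table,
    learning_curves = if (length(lcurves)) do.call(rbind, lcurves),
    cross = cross), class = "cr_study_report")

  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

.write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_population(report$population, file.path(dir, "population.csv"))
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  if (!is.null(report$learning_curves)) {
    utils::write.csv(report$learning_curves,
                     file.path(dir, "learning_curves.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$global_sensitivity)) {
    utils::write.csv(as.data.frame(report$global_sensitivity$total),
                     file.path(dir, "global_sensitivity.csv"))
  }
  if (!is.null(report$cross)) {
    utils::write.csv(report$cross$metrics,
                     file.path(dir, "cross_metrics.csv"), row.names = FALSE)
  }
  meta <- list(seeds = report$config$seeds,
               preset = report$config$preset, n = report$config$n,
               mode = report$config$mode,
               bookkeeping = report$bookkeeping[c("n_total", "n_accepted",
                                                  "n_rejected")],
               split_sizes = as.list(report$split_sizes),
               metrics = report$metrics)
  jsonlite::write_json(meta, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  write_study_config(report$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @export
print.cr_study_report <- function(x, ...) {
  cat("<cr_study_report> preset", x$config$preset, "n =", x$config$n,
      "(", x$bookkeeping$n_accepted, "accepted )\n")
  print(x$metrics, digits = 3)
  invisible(x)
}
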