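test_that("preset spaces have the documented dimensions and ranges", {
  vp1 <- parameter_space("vp1")
  vp2 <- parameter_space("vp2")
  expect_equal(nrow(vp1$dims), 9)
  expect_equal(nrow(vp2$dims), 10)
  expect_equal(vp1$targets$Vtot$lower, 4373.0)
  expect_equal(vp1$targets$Vtot$upper, 6164.4)
  expect_equal(vp2$targets$Emax_kE$param, c("Emax_LV0", "kE_LV", "kE_RV"))
})

test_that("sampled values stay inside their ranges and linkage is co-monotone", {
  space <- parameter_space("vp1")
  ps <- sample_space(space, 256, seed = 4)
  expect_length(ps, 256)
  vals <- t(vapply(ps, function(p) unclass(p)[c("Vtot", "T0", "GTv", "Pn")],
                   numeric(4)))
  expect_true(all(vals[, "Vtot"] >= 4373.0 & vals[, "Vtot"] <= 6164.4))
  expect_true(all(vals[, "T0"] >= 0.41 & vals[, "T0"] <= 0.59))
  expect_true(all(vals[, "GTv"] >= 0.07 & vals[, "GTv"] <= 0.11))
  # one coordinate drives both linked parameters co-monotonically
  expect_equal(stats::cor(vals[, "T0"], vals[, "GTv"]), 1, tolerance = 1e-12)
  zT0 <- (vals[, "T0"] - 0.41) / (0.59 - 0.41)
  zG <- (vals[, "GTv"] - 0.07) / (0.11 - 0.07)
  expect_equal(zT0, zG, tolerance = 1e-9)
  # non-sampled parameters stay at baseline
  expect_equal(unclass(ps[[1]])[["kE_LV"]],
               baseline_parameters()[["kE_LV"]])
  # deterministic per seed
  ps2 <- sample_space(space, 256, seed = 4)
  expect_identical(unclass(ps[[10]]), unclass(ps2[[10]]))
})

test_that("identical parameter sets give identical accepted records", {
  p <- baseline_parameters()
  cfg <- sim_config("fast", save_start = 30, save_end = 60, t_end = 60)
  vp <- generate_population(rep(list(p), 4), cfg)
  vp <- apply_filters(vp)
  expect_true(all(vp$subjects$accepted))
  idx <- vp$subjects[, cr_index_names()]
  expect_true(all(vapply(idx, function(x) length(unique(x)) == 1,
                         logical(1))))
})

test_that("a failing subject is recorded and the population completes", {
  flaky <- function(p, cfg) {
    if (unclass(p)[["Vtot"]] > 6000) {
      return(structure(list(ok = FALSE, t_fail = 1), class = "cr_sim_failure"))
    }
    surrogate_simulate(p)
  }
  ps <- list(parameter_set(Vtot = 5000), parameter_set(Vtot = 6100),
             parameter_set(Vtot = 5200))
  vp <- apply_filters(generate_population(ps, NULL, simulator = flaky))
  expect_equal(vp$subjects$sim_ok, c(TRUE, FALSE, TRUE))
  expect_equal(vp$subjects$accepted[2], FALSE)
  expect_match(vp$subjects$reasons[2], "integration_failure")
  expect_equal(nrow(vp$subjects), 3)
})

test_that("range filter applies inclusive bounds per variable", {
  vp <- make_fixture_population(8, "vp1", seed = 2)
  sub <- vp$subjects
  mid <- vapply(filter_criteria()$variable, function(v) {
    b <- filter_criteria()[filter_criteria()$variable == v, ]
    (b$min + b$max) / 2
  }, numeric(1))
  for (v in names(mid)) sub[[v]] <- mid[[v]]
  for (v in cr_index_names()) {
    sub[[paste0("delta_", v)]] <- 0.1
    sub[[paste0("dabs_", v)]] <- 0.01
  }
  sub$HR[1] <- 44.9          # below the admissible range
  sub$CVP[2] <- 0            # exactly on the inclusive bound
  sub$PaO2[3] <- 110         # exactly on the inclusive bound
  sub$delta_SV[4] <- 1.5     # stationarity drift 1.5% > 1%
  vp$subjects <- sub
  vp <- apply_filters(vp)
  expect_false(vp$subjects$accepted[1])
  expect_equal(vp$subjects$reasons[1], "HR_range")
  expect_true(vp$subjects$accepted[2])
  expect_true(vp$subjects$accepted[3])
  expect_false(vp$subjects$accepted[4])
  expect_equal(vp$subjects$reasons[4], "SV_stationarity")
  expect_true(all(vp$subjects$accepted[5:8]))
  # every violation is recorded, not only the first
  vp$subjects$HR[5] <- 200; vp$subjects$delta_CVP[5] <- 3
  vp <- apply_filters(vp)
  expect_setequal(strsplit(vp$subjects$reasons[5], ";")[[1]],
                  c("HR_range", "CVP_stationarity"))
  # idempotent
  again <- apply_filters(vp)
  expect_identical(again$subjects$reasons, vp$subjects$reasons)
})

test_that("near-zero window means fall back to the absolute tolerance", {
  vp <- make_fixture_population(2, "vp1", seed = 3)
  sub <- vp$subjects
  mid <- vapply(cr_index_names(), function(v) {
    b <- filter_criteria()[filter_criteria()$variable == v, ]
    (b$min + b$max) / 2
  }, numeric(1))
  for (v in cr_index_names()) {
    sub[[v]] <- mid[[v]]
    sub[[paste0("delta_", v)]] <- 0.1
    sub[[paste0("dabs_", v)]] <- 0.01
  }
  sub$CVP <- c(0.2, 0.2)                  # below the 0.5-unit guard
  sub$delta_CVP <- NA_real_               # percentage rule undefined
  sub$dabs_CVP <- c(0.05, 0.2)            # second exceeds 0.1 unit
  vp$subjects <- sub
  vp <- apply_filters(vp)
  expect_true(vp$subjects$accepted[1])
  expect_false(vp$subjects$accepted[2])
  expect_equal(vp$subjects$reasons[2], "CVP_stationarity")
})

test_that("classification uses strict cutoffs and allows multiple labels", {
  vp <- make_fixture_population(5, "vp1", seed = 2)
  sub <- vp$subjects
  mid <- vapply(cr_index_names(), function(v) {
    b <- filter_criteria()[filter_criteria()$variable == v, ]
    (b$min + b$max) / 2
  }, numeric(1))
  for (v in cr_index_names()) {
    sub[[v]] <- mid[[v]]
    sub[[paste0("delta_", v)]] <- 0.1
    sub[[paste0("dabs_", v)]] <- 0.01
  }
  sub$MAP <- 95; sub$CSBP <- 120; sub$CDBP <- 75; sub$HR <- 70
  sub$EF <- 60; sub$PaCO2 <- 40
  sub$CSBP[1] <- 135                       # hypertension via CSBP only
  sub$HR[2] <- 55; sub$PaCO2[2] <- 34      # bradycardia + hyperventilation
  sub$CSBP[4] <- 130; sub$CDBP[4] <- 80    # exactly at cutoffs: strict, no label
  sub$PaCO2[5] <- 46                       # hypoventilation
  vp$subjects <- sub
  vp <- classify_cvrd(apply_filters(vp))
  labs <- vp$subjects$labels
  expect_equal(labs[1], "hypertension")
  expect_setequal(strsplit(labs[2], ";")[[1]],
                  c("bradycardia", "hyperventilation"))
  expect_equal(labs[3], "")                # healthy: empty label set
  expect_equal(labs[4], "")
  expect_equal(labs[5], "hypoventilation")
})

test_that("split sizes follow the 80/20 floor rule", {
  df <- data.frame(sample_id = 1:1789, x = rnorm(1789))
  sp <- split_population(df, 0.8, seed = 1)
  expect_equal(nrow(sp$train), 1431)
  expect_equal(nrow(sp$test), 358)
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), 1:1789)
  # N = 10 at 50%
  sp2 <- split_population(data.frame(sample_id = 1:10), 0.5, seed = 3)
  expect_equal(c(nrow(sp2$train), nrow(sp2$test)), c(5, 5))
  # deterministic per seed
  sp3 <- split_population(df, 0.8, seed = 1)
  expect_identical(sp$train$sample_id, sp3$train$sample_id)
  expect_error(split_population(data.frame(sample_id = 1), 0.5, seed = 1),
               "at least 2")
})

test_that("convergence errors follow the reference-relative formula", {
  s <- function(m) data.frame(variable = "HR", mean = m, sd = 1, min = 0,
                              max = 2)
  ce <- convergence_errors(list("128" = s(10)), s(8))
  expect_equal(ce$error_pct[ce$statistic == "mean"], 25)
  ce0 <- convergence_errors(list("128" = s(8)), s(8))
  expect_equal(ce0$error_pct[ce0$statistic == "mean"], 0)
  # zero reference flagged undefined
  cz <- convergence_errors(list("128" = s(1)),
                           data.frame(variable = "HR", mean = 0, sd = 1,
                                      min = 0, max = 2))
  expect_true(is.na(cz$error_pct[cz$statistic == "mean"]))
  expect_false(cz$defined[cz$statistic == "mean"])
})

test_that("index means converge with the number of Sobol' points", {
  mk <- function(n) {
    population_summary(make_fixture_population(n, "vp1", seed = 1),
                       accepted_only = FALSE)
  }
  ce <- convergence_errors(list("128" = mk(128), "512" = mk(512),
                                "2048" = mk(2048)), mk(4096))
  m <- ce[ce$statistic == "mean", ]
  e <- split(m$error_pct, m$n)
  # the largest sample is at least as accurate as the smallest, per index
  expect_true(all(e[["2048"]] <= e[["128"]] + 1e-12))
  # and typical errors decrease monotonically
  med <- vapply(e, stats::median, numeric(1))
  expect_true(all(diff(med[order(as.integer(names(med)))]) < 0))
})

test_that("accepted-subset summaries are recomputable from rows exactly", {
  vp <- fx_vp1024()
  s <- population_summary(vp)
  acc <- vp$subjects[vp$subjects$accepted, ]
  expect_identical(s$mean[s$variable == "SV"], mean(acc$SV))
  expect_identical(s$max[s$variable == "CVP"], max(acc$CVP))
})

test_that("population table round-trips through CSV", {
  vp <- make_fixture_population(16, "vp1", seed = 5)
  vp <- classify_cvrd(apply_filters(vp))
  f <- withr::local_tempfile(fileext = ".csv")
  write_population(vp, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), 16)
  expect_equal(back$SV, vp$subjects$SV, tolerance = 1e-9)
})
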