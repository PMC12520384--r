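test_that("local score matches analytic log-derivatives", {
  lin <- function(p) c(M = 2 * p[["P"]])
  expect_equal(local_sensitivity(lin, c(P = 1), "P", "M"), 1)
  cst <- function(p) c(M = 7)
  expect_equal(local_sensitivity(cst, c(P = 1), "P", "M"), 0)
  # centered differences are exact on quadratics
  quad <- function(p) c(M = p[["P"]]^2)
  expect_equal(local_sensitivity(quad, c(P = 2), "P", "M", 0.1), 2,
                tolerance = 1e-12)
})

test_that("power-law score converges to the exponent at rate h^2", {
  pw <- function(p) c(M = 3 * p[["P"]]^1.7)
  err <- vapply(c(0.2, 0.1, 0.05), function(h) {
    abs(local_sensitivity(pw, c(P = 1.3), "P", "M", h) - 1.7)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  # quartering h by 2 should shrink the error ~4x
  expect_gt(err[1] / err[2], 3.4)
  expect_gt(err[2] / err[3], 3.4)
})

test_that("score is invariant to output rescaling and parameter units", {
  f1 <- function(p) c(M = p[["P"]]^2 + p[["P"]])
  f2 <- function(p) c(M = 500 * (p[["P"]]^2 + p[["P"]]))
  s1 <- local_sensitivity(f1, c(P = 2), "P", "M")
  s2 <- local_sensitivity(f2, c(P = 2), "P", "M")
  expect_equal(s1, s2)
  # unit change of P: same relative perturbation, same score
  f3 <- function(p) c(M = (p[["P"]] / 1000)^2 + p[["P"]] / 1000)
  s3 <- local_sensitivity(f3, c(P = 2000), "P", "M")
  expect_equal(s1, s3)
})

test_that("zero or failed baselines are reported, not raised", {
  z <- function(p) c(M = 0)
  s <- local_sensitivity(z, c(P = 1), "P", "M")
  expect_true(is.na(s))
  expect_equal(attr(s, "reason"), "zero_baseline_output")
  bad <- function(p) stop("boom")
  s2 <- local_sensitivity(bad, c(P = 1), "P", "M")
  expect_true(is.na(s2))
})

test_that("ratio model ranks its two parameters first with opposite signs", {
  f <- function(p) c(M = p[["Vtot"]] / p[["Vu_ven"]])
  tab <- sensitivity_table(f, baseline_parameters(),
                           c("Vtot", "Vu_ven", "Pn"), "M")
  rk <- tab$ranking
  expect_setequal(rk$parameter[rk$rank <= 2], c("Vtot", "Vu_ven"))
  expect_gt(tab$scores["Vtot", "M"], 0)
  expect_lt(tab$scores["Vu_ven", "M"], 0)
  # power-law oracle: |S| -> 1 for both
  expect_equal(unname(tab$scores["Vtot", "M"]), 1, tolerance = 0.02)
  expect_equal(unname(tab$scores["Vu_ven", "M"]), -1, tolerance = 0.02)
  expect_equal(unname(tab$scores["Pn", "M"]), 0)
})

test_that("sensitivity report round-trips through CSV", {
  f <- function(p) c(A = p[["Vtot"]]^2, B = 1 / p[["Pn"]])
  tab <- sensitivity_table(f, baseline_parameters(), c("Vtot", "Pn"),
                           c("A", "B"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensitivity_csv(tab, path)
  back <- read_sensitivity_csv(path)
  expect_equal(back$score[back$parameter == "Vtot" & back$output == "A"],
               tab$scores["Vtot", "A"])
  expect_equal(nrow(back), 4)
})

test_that("additive model splits total indices evenly", {
  fn <- function(p) c(y = unclass(p)[["Vtot"]] + unclass(p)[["Pn"]])
  gt <- global_total_indices(fn, space = fx_space_2d(), n = 4096, seed = 5)
  expect_equal(unname(gt$total[, "y"]), c(0.5, 0.5), tolerance = 0.05)
  expect_equal(sum(gt$total[, "y"]), 1, tolerance = 1e-6)
})

test_that("a single active input takes all the variance", {
  fn <- function(p) c(y = unclass(p)[["Vtot"]])
  gt <- global_total_indices(fn, space = fx_space_2d(), n = 1024, seed = 2)
  expect_equal(unname(gt$total["x1", "y"]), 1, tolerance = 0.02)
  expect_equal(unname(gt$total["x2", "y"]), 0, tolerance = 0.02)
})

test_that("Jansen estimator agrees with brute-force double-loop variance", {
  # interaction model y = x1 + 2*x2 + 3*x1*x2 on U(0,1)^2
  f2 <- function(x1, x2) x1 + 2 * x2 + 3 * x1 * x2
  fn <- function(p) c(y = f2(unclass(p)[["Vtot"]], unclass(p)[["Pn"]]))
  gt <- global_total_indices(fn, space = fx_space_2d(), n = 4096, seed = 9)
  # brute force: ST_i = E_x~i[Var_xi(f)] / Var(f) on a fine grid
  g <- seq(0.0005, 0.9995, length.out = 1000)
  G <- expand.grid(x1 = g, x2 = g)
  y <- f2(G$x1, G$x2)
  vtot <- stats::var(y)
  vx1 <- mean(tapply(y, rep(seq_along(g), each = length(g)), stats::var))
  vx2 <- mean(tapply(y, rep(seq_along(g), times = length(g)), stats::var))
  st <- c(vx1, vx2) / vtot
  st_norm <- st / sum(st)
  expect_equal(unname(gt$total[, "y"]), unname(st_norm), tolerance = 0.03)
})

test_that("given-data estimator recovers the surrogate's driving inputs", {
  gd <- global_total_indices(fx_vp1024(), outputs = c("PaCO2", "HR"))
  expect_equal(colSums(gd$total), c(PaCO2 = 1, HR = 1), tolerance = 1e-6)
  expect_true(all(gd$total >= -1e-9))
  # PaCO2 is driven by the CO2 dissociation parameters only
  expect_gt(gd$total["Csat_CO2", "PaCO2"] + gd$total["hCO2", "PaCO2"], 0.9)
  # HR is driven mostly by volumes and the cardiac-cycle dimension
  top_hr <- sum(gd$total[c("Vtot", "Vu_ven", "T0_GTv"), "HR"])
  expect_gt(top_hr, 0.8)
})

test_that("a constant output is flagged, not fabricated", {
  fn <- function(p) c(y = 1)
  gt <- global_total_indices(fn, space = fx_space_2d(), n = 512, seed = 1)
  expect_true("y" %in% gt$flagged)
})
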