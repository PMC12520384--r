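# shared, lazily built fixtures (one build per test run)

.fx_cache <- new.env(parent = emptyenv())

fx_memo <- function(key, expr) {
  if (!exists(key, envir = .fx_cache)) {
    assign(key, force(expr), envir = .fx_cache)
  }
  get(key, envir = .fx_cache)
}

# baseline fast-mode trace of the reference simulator
fx_baseline_trace <- function() {
  fx_memo("trace", simulate_subject(baseline_parameters(), sim_config("fast")))
}

# filtered + classified fixture population, n = 1024 (study-scale)
fx_vp1024 <- function() {
  fx_memo("vp1024", {
    vp <- make_fixture_population(1024, "vp1", seed = 1)
    classify_cvrd(apply_filters(vp))
  })
}

# its 80/20 split
fx_split <- function() {
  fx_memo("split", split_population(fx_vp1024(), 0.8, seed = 2))
}

# a tuned GP per target on the fixture training set (built on demand)
fx_model <- function(target) {
  fx_memo(paste0("gpr_", target), {
    tr <- make_dataset(fx_split()$train, target, "train")
    fit_gpr(tr, gpr_config(seed = 3))
  })
}

# 2-D unit-square custom space for estimator oracles
fx_space_2d <- function() {
  parameter_space(
    "custom",
    dims = data.frame(dimension = c("x1", "x2"), lower = c(0, 0),
                      upper = c(1, 1)),
    targets = list(x1 = data.frame(param = "Vtot", lower = 0, upper = 1),
                   x2 = data.frame(param = "Pn", lower = 0, upper = 1)))
}
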