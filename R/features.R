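# Per-cardiac-cycle extraction of the 12 clinically relevant indexes from a
# simulated trace. Cycle boundaries come from resets of the cardiac phase
# variable u (a sample where u decreases starts a new cycle; u = 0 marks the
# beginning of systole). Indexes are computed per cycle and then averaged
# arithmetically across all complete cycles in the save window; incomplete
# boundary cycles are discarded. Extrema are taken over sampled points
# without sub-sample interpolation, so the sampling period bounds the
# extremum error.

#' Detect complete cardiac cycles
#'
#' @param trace A `cr_trace` (or data.frame with `time` and `u` columns).
#' @return Object of class `cr_cycles`: data.frame with half-open intervals
#'   `start`, `end` (seconds), one row per complete cycle.
#' @export
detect_cycles <- function(trace) {
  stopifnot(is.data.frame(trace), all(c("time", "u") %in% names(trace)))
  u <- trace$u
  if (any(u < 0 | u >= 1)) stop("u must lie in [0, 1)")
  resets <- which(diff(u) < 0) + 1L
  if (length(resets) < 2L) {
    stop("fewer than one complete cardiac cycle in the trace")
  }
  cyc <- data.frame(start = trace$time[resets[-length(resets)]],
                    end = trace$time[resets[-1L]])
  class(cyc) <- c("cr_cycles", "data.frame")
  cyc
}

.cycle_slices <- function(trace, cycles) {
  lapply(seq_len(nrow(cycles)), function(i) {
    sel <- trace$time >= cycles$start[i] & trace$time < cycles$end[i]
    trace[sel, , drop = FALSE]
  })
}

#' Extract cycle-averaged clinical indexes from a trace
#'
#' CDBP, MAP and CSBP are the minimum, mean and maximum of the arterial
#' pressure waveform over each cycle; CPP their per-cycle difference. CVP,
#' CO, SaO2, PaO2 and PaCO2 are per-cycle means of the thoracic-vein
#' pressure, aortic-valve flow and arterial gas signals. SV is the product
#' of per-cycle CO and heart period; LVEDV/LVESV are the per-cycle extremes
#' of left-ventricular volume and EF = (LVEDV - LVESV) / LVEDV. All
#' per-cycle values are averaged over the complete cycles of the window;
#' HR = 60 / mean heart period.
#'
#' @param trace A `cr_trace`.
#' @param cycles Optional [detect_cycles()] result (computed if missing).
#' @return Named list of class `cr_indexset` with entries HR, CSBP, CDBP,
#'   CPP, MAP, CVP, SV, CO, EF, SaO2, PaO2, PaCO2, LVEDV, LVESV, n_cycles.
#' @export
extract_indexes <- function(trace, cycles = NULL) {
  if (is.null(cycles)) cycles <- detect_cycles(trace)
  slices <- .cycle_slices(trace, cycles)
  keep <- vapply(slices, nrow, integer(1)) >= 2L
  if (any(!keep)) {
    warning(sum(!keep), " degenerate cycle(s) of < 2 samples dropped")
    slices <- slices[keep]
    cycles <- cycles[keep, , drop = FALSE]
  }
  if (!length(slices)) stop("no usable cardiac cycles")
  per <- lapply(seq_along(slices), function(i) {
    s <- slices[[i]]
    Tcyc <- cycles$end[i] - cycles$start[i]
    csbp <- max(s$Psa); cdbp <- min(s$Psa)
    co <- mean(s$qAV)
    lvedv <- max(s$VLV); lvesv <- min(s$VLV)
    c(Tcyc = Tcyc, CSBP = csbp, CDBP = cdbp, CPP = csbp - cdbp,
      MAP = mean(s$Psa), CVP = mean(s$Ptv), CO = co, SV = co * Tcyc,
      EF = 100 * (lvedv - lvesv) / lvedv,
      SaO2 = mean(s$SaO2), PaO2 = mean(s$PaO2), PaCO2 = mean(s$PaCO2),
      LVEDV = lvedv, LVESV = lvesv)
  })
  m <- colMeans(do.call(rbind, per))
  idx <- list(HR = 60 / m[["Tcyc"]], CSBP = m[["CSBP"]], CDBP = m[["CDBP"]],
              CPP = m[["CPP"]], MAP = m[["MAP"]], CVP = m[["CVP"]],
              SV = m[["SV"]], CO = m[["CO"]], EF = m[["EF"]],
              SaO2 = m[["SaO2"]], PaO2 = m[["PaO2"]], PaCO2 = m[["PaCO2"]],
              LVEDV = m[["LVEDV"]], LVESV = m[["LVESV"]],
              n_cycles = length(slices))
  class(idx) <- "cr_indexset"
  idx
}

#' Names of the 12 clinically relevant indexes
#' @return Character vector in canonical order.
#' @export
cr_index_names <- function() {
  c("HR", "CSBP", "CDBP", "CPP", "MAP", "CVP", "SV", "CO", "EF",
    "SaO2", "PaO2", "PaCO2")
}

#' @export
print.cr_indexset <- function(x, ...) {
  v <- unlist(x[cr_index_names()])
  cat("<cr_indexset> averaged over", x$n_cycles, "cycles\n")
  print(round(v, 2))
  invisible(x)
}

#' @export
as.data.frame.cr_indexset <- function(x, ...) {
  as.data.frame(x[c(cr_index_names(), "LVEDV", "LVESV", "n_cycles")])
}
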