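# Model parameters: the 14 range-specified physiological parameters plus the
# remaining constants of the reduced closed-loop model, all carried in one
# named numeric vector of class "cr_params".

#' Parameter metadata table
#'
#' Units and one-line descriptions for every model parameter. The first 14
#' rows are the physiologically range-specified parameters used to build the
#' virtual-population presets; the rest are the constants of the reduced
#' closed-loop model with their documented defaults.
#'
#' @return A data.frame with columns `name`, `unit`, `description`.
#' @export
cr_param_table <- function() {
  tab <- rbind(
    c("Vtot",      "mL",          "total blood volume"),
    c("Vu_ven",    "mL",          "systemic venous unstressed volume"),
    c("T0",        "s",           "basal (denervated) cardiac cycle length"),
    c("GTv",       "s per spikes/s", "gain of vagal stimulus on heart period"),
    c("Pn",        "mmHg",        "carotid baroreflex activation level (set-point)"),
    c("Emax_LV0",  "mmHg/mL",     "basal maximum active elastance, left ventricle"),
    c("kE_LV",     "1/mL",        "passive elastance exponent, left ventricle"),
    c("kE_RV",     "1/mL",        "passive elastance exponent, right ventricle"),
    c("FiO2",      "%",           "inspired O2 fraction"),
    c("hgb",       "g/mL",        "blood hemoglobin content"),
    c("Csat_CO2",  "mL/mL",       "maximum concentration of hemoglobin-bound CO2"),
    c("hO2",       "-",           "O2 dissociation curve exponent"),
    c("hCO2",      "-",           "CO2 dissociation curve exponent"),
    c("kCO2",      "-",           "CO2 dissociation curve constant"),
    c("Emax_RV0",  "mmHg/mL",     "basal maximum active elastance, right ventricle"),
    c("k_sym",     "-",           "basal sympathetic scaling of maximum elastances"),
    c("P0_LV",     "mmHg",        "passive elastance scale, left ventricle"),
    c("P0_RV",     "mmHg",        "passive elastance scale, right ventricle"),
    c("Vu_LV",     "mL",          "left ventricular unstressed volume"),
    c("Vu_RV",     "mL",          "right ventricular unstressed volume"),
    c("C_sa",      "mL/mmHg",     "systemic arterial compliance"),
    c("Vu_sa",     "mL",          "systemic arterial unstressed volume"),
    c("C_sv",      "mL/mmHg",     "systemic venous compliance"),
    c("C_pa",      "mL/mmHg",     "pulmonary arterial compliance"),
    c("Vu_pa",     "mL",          "pulmonary arterial unstressed volume"),
    c("C_pv",      "mL/mmHg",     "pulmonary venous compliance"),
    c("Vu_pv",     "mL",          "pulmonary venous unstressed volume"),
    c("C_la",      "mL/mmHg",     "left atrial compliance"),
    c("Vu_la",     "mL",          "left atrial unstressed volume"),
    c("C_ra",      "mL/mmHg",     "right atrial compliance"),
    c("Vu_ra",     "mL",          "right atrial unstressed volume"),
    c("R_sys",     "mmHg.s/mL",   "systemic peripheral resistance"),
    c("R_vr",      "mmHg.s/mL",   "venous return resistance"),
    c("R_pul",     "mmHg.s/mL",   "pulmonary peripheral resistance"),
    c("R_pvein",   "mmHg.s/mL",   "pulmonary venous resistance"),
    c("R_mv",      "mmHg.s/mL",   "mitral valve forward resistance"),
    c("R_av",      "mmHg.s/mL",   "aortic valve forward resistance"),
    c("R_tc",      "mmHg.s/mL",   "tricuspid valve forward resistance"),
    c("R_pvalve",  "mmHg.s/mL",   "pulmonary valve forward resistance"),
    c("R_rev",     "mmHg.s/mL",   "valve reverse (leak) resistance"),
    c("Tsys0",     "s",           "systole duration intercept"),
    c("ksys",      "s^2",         "systole duration rate coefficient"),
    c("f_min",     "spikes/s",    "minimum carotid afferent firing rate"),
    c("f_max",     "spikes/s",    "maximum carotid afferent firing rate"),
    c("ka",        "mmHg",        "afferent sigmoid width"),
    c("fev0",      "spikes/s",    "minimum efferent vagal firing rate"),
    c("fev_inf",   "spikes/s",    "maximum efferent vagal firing rate"),
    c("fcs0",      "spikes/s",    "efferent sigmoid midpoint firing rate"),
    c("kev",       "spikes/s",    "efferent sigmoid width"),
    c("tau_T",     "s",           "heart-period effector time constant"),
    c("tau_p",     "s",           "afferent pressure low-pass time constant"),
    c("resp_T_mod","s",           "respiratory modulation amplitude of heart period"),
    c("VA_vol",    "mL",          "alveolar gas volume"),
    c("Vdot_A0",   "mL/s",        "basal alveolar ventilation"),
    c("G_vent",    "1/mmHg",      "ventilatory chemoreflex gain on PaCO2"),
    c("T_resp",    "s",           "respiratory period"),
    c("vent_amp",  "-",           "within-breath ventilation modulation amplitude"),
    c("sh",        "-",           "pulmonary shunt fraction"),
    c("alpha_O2",  "mL/mL/mmHg",  "dissolved O2 solubility"),
    c("Hufner",    "mL/g",        "O2 binding capacity of hemoglobin"),
    c("beta_O2",   "1/mmHg",      "O2 dissociation curve pressure coefficient"),
    c("K_O2",      "-",           "O2 dissociation curve constant"),
    c("beta_CO2",  "1/mmHg",      "CO2 dissociation curve pressure coefficient"),
    c("M_O2",      "mL/s",        "whole-body O2 consumption rate"),
    c("M_CO2",     "mL/s",        "whole-body CO2 production rate"),
    c("Vtis_O2",   "mL",          "effective tissue O2 storage volume"),
    c("Vtis_CO2",  "mL",          "effective tissue CO2 storage volume"),
    c("Patm",      "mmHg",        "atmospheric pressure"),
    c("P_H2O",     "mmHg",        "water vapor pressure at body temperature")
  )
  data.frame(name = tab[, 1], unit = tab[, 2], description = tab[, 3],
             stringsAsFactors = FALSE)
}

#' Names of the 14 range-specified physiological parameters
#' @return Character vector.
#' @export
cr_named_parameters <- function() {
  c("Vtot", "Vu_ven", "T0", "GTv", "Pn", "Emax_LV0", "kE_LV", "kE_RV",
    "FiO2", "hgb", "Csat_CO2", "hO2", "hCO2", "kCO2")
}

#' Baseline parameter set
#'
#' The complete baseline parameter set of the reduced closed-loop model.
#' The 14 range-specified parameters take reference-literature values where
#' one exists inside their sampling range (dissociation-curve constants,
#' ventricular passive elastances, inspired O2 fraction) and the midpoint of
#' their range otherwise. The remaining constants are calibrated once so the
#' baseline simulation lies inside the admissible physiological envelope of
#' every extracted index.
#'
#' @return A named numeric vector of class `cr_params`.
#' @examples
#' p <- baseline_parameters()
#' p[["T0"]]
#' @export
baseline_parameters <- function() {
  p <- c(
    Vtot = 5268.7, Vu_ven = 3102.25, T0 = 0.50, GTv = 0.09, Pn = 92.0,
    Emax_LV0 = 2.39, kE_LV = 0.014, kE_RV = 0.011, FiO2 = 21.0, hgb = 0.17,
    Csat_CO2 = 1.95, hO2 = 0.3836, hCO2 = 1.819, kCO2 = 194.4,
    Emax_RV0 = 1.75, k_sym = 1.6, P0_LV = 1.5, P0_RV = 1.5,
    Vu_LV = 16.8, Vu_RV = 16.8,
    C_sa = 1.5, Vu_sa = 600, C_sv = 200,
    C_pa = 4.0, Vu_pa = 50, C_pv = 16, Vu_pv = 120,
    C_la = 10, Vu_la = 25, C_ra = 10, Vu_ra = 25,
    R_sys = 1.1, R_vr = 0.006, R_pul = 0.08, R_pvein = 0.006,
    R_mv = 0.0025, R_av = 0.003, R_tc = 0.0025, R_pvalve = 0.003,
    R_rev = 25,
    Tsys0 = 0.5, ksys = 0.075,
    f_min = 2.52, f_max = 47.78, ka = 11.758,
    fev0 = 3.2, fev_inf = 6.3, fcs0 = 25.15, kev = 7.06,
    tau_T = 1.5, tau_p = 2.0, resp_T_mod = 0.02,
    VA_vol = 3000, Vdot_A0 = 76.8, G_vent = 0.04, T_resp = 4.0,
    vent_amp = 0.45, sh = 0.017,
    alpha_O2 = 3e-5, Hufner = 1.34, beta_O2 = 0.008275, K_O2 = 14990,
    beta_CO2 = 0.03198, M_O2 = 4.2, M_CO2 = 3.5,
    Vtis_O2 = 6000, Vtis_CO2 = 15000,
    Patm = 760, P_H2O = 47
  )
  class(p) <- "cr_params"
  p
}

#' Construct a parameter set from overrides of the baseline
#'
#' @param ... Named scalar overrides, e.g. `parameter_set(Vtot = 5000)`.
#' @param base Parameter set to start from (default [baseline_parameters()]).
#' @return A `cr_params` named numeric vector.
#' @export
parameter_set <- function(..., base = baseline_parameters()) {
  ov <- c(...)
  p <- unclass(base)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == "")) {
      stop("all overrides must be named")
    }
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    p[names(ov)] <- ov
  }
  validate_params(structure(p, class = "cr_params"))
}

#' @keywords internal
validate_params <- function(p) {
  stopifnot(inherits(p, "cr_params") || is.numeric(p))
  missing <- setdiff(cr_named_parameters(), names(p))
  if (length(missing)) {
    stop("parameter set is missing: ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(unclass(p)))) stop("non-finite parameter value")
  # zero is physically meaningful only for gains/modulations
  zero_ok <- c("G_vent", "resp_T_mod", "vent_amp", "sh", "GTv")
  chk <- unclass(p)[setdiff(names(p), zero_ok)]
  if (any(chk <= 0)) {
    stop("non-positive value for: ",
         paste(names(chk)[chk <= 0], collapse = ", "))
  }
  structure(unclass(p), class = "cr_params")
}

#' @export
print.cr_params <- function(x, ...) {
  cat("<cr_params> ", length(x), " parameters\n", sep = "")
  named <- cr_named_parameters()
  print(round(unclass(x)[named], 4))
  cat("... plus", length(x) - length(named), "model constants\n")
  invisible(x)
}
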