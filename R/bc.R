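#' CGS unit helpers
#'
#' The package works in CGS units (cm, g, s, dyn, Poise); pressures are
#' reported in mmHg using 1 mmHg = 1333.22 dyn/cm^2.
#' @name units
NULL

#' @rdname units
#' @export
MMHG_TO_DYN <- 1333.22

#' @rdname units
#' @param p_dyn pressure in dyn/cm^2.
#' @export
dyn_to_mmhg <- function(p_dyn) p_dyn / MMHG_TO_DYN

#' @rdname units
#' @param p_mmhg pressure in mmHg.
#' @export
mmhg_to_dyn <- function(p_mmhg) p_mmhg * MMHG_TO_DYN

#' Blood-analog fluid properties
#'
#' The mock loop uses a 40/60 glycerol/water mixture with density
#' 1.06 g/cm^3 and dynamic viscosity 0.035 Poise; these are the defaults.
#'
#' @param density g/cm^3.
#' @param viscosity dynamic viscosity (Poise = dyn.s/cm^2).
#' @return A `fluid_properties` object.
#' @export
fluid_properties <- function(density = 1.06, viscosity = 0.035) {
  if (density <= 0 || viscosity <= 0)
    stop("fluid properties must be strictly positive")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Boundary-condition set for one operating point
#'
#' Converts a cardiac output and caval flow split into inlet volumetric
#' flows (cm^3/s) and attaches outlet resistances, mirroring the bench
#' operating points: IVC flow = `ivc_fraction * CO`, SVC the remainder,
#' resistances on the RPA and LPA outlets.
#'
#' @param CO cardiac output (L/min), > 0.
#' @param ivc_fraction fraction of CO entering through the IVC (default 0.6,
#'   the 60/40 IVC/SVC split).
#' @param R_rpa,R_lpa outlet resistances (dyn.s/cm^5); defaults are the
#'   values calibrated on the blank housing at CO = 11 L/min.
#' @param fluid a [fluid_properties] object.
#' @param inlet_profile `"parabolic"` (default) or `"plug"`.
#' @param distal_pressure pressure offset added downstream of the
#'   resistances (dyn/cm^2, default 0).
#' @return A `bc_set` with `inlet_flows` (named, cm^3/s), `outlet_resistances`
#'   (named, dyn.s/cm^5), `inlet_profile`, `distal_pressure`, `fluid`.
#' @export
make_bc_set <- function(CO, ivc_fraction = 0.6,
                        R_rpa = 204.51, R_lpa = 222.49,
                        fluid = fluid_properties(),
                        inlet_profile = c("parabolic", "plug"),
                        distal_pressure = 0) {
  if (!is.finite(CO) || CO <= 0)
    stop("make_bc_set: cardiac output must be positive")
  if (ivc_fraction <= 0 || ivc_fraction >= 1)
    stop("make_bc_set: ivc_fraction must lie strictly between 0 and 1")
  if (R_rpa < 0 || R_lpa < 0)
    stop("make_bc_set: resistances must be non-negative")
  inlet_profile <- match.arg(inlet_profile)
  q_total <- CO * 1000 / 60   # L/min -> cm^3/s
  structure(list(
    CO = CO,
    inlet_flows = c(inlet_IVC = ivc_fraction * q_total,
                    inlet_SVC = (1 - ivc_fraction) * q_total),
    inlet_profile = inlet_profile,
    outlet_resistances = c(outlet_RPA = R_rpa, outlet_LPA = R_lpa),
    distal_pressure = distal_pressure,
    fluid = fluid), class = "bc_set")
}

#' Inlet Reynolds number
#'
#' Re = 4 rho Q / (pi D mu) for a circular tube of diameter D carrying
#' volumetric flow Q.
#'
#' @param bc a [make_bc_set] object.
#' @param diameter tube diameter (cm).
#' @param inlet inlet name (e.g. `"inlet_IVC"`).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(bc, diameter = 1.91, inlet = "inlet_IVC") {
  if (diameter <= 0) stop("reynolds_number: diameter must be positive")
  if (!inlet %in% names(bc$inlet_flows))
    stop(sprintf("reynolds_number: unknown inlet '%s'", inlet))
  Q <- bc$inlet_flows[[inlet]]
  4 * bc$fluid$density * Q / (pi * diameter * bc$fluid$viscosity)
}

#' Target pulmonary artery pressure of the mock loop
#'
#' The loop's pulmonary impedance networks make the outflow pressures vary
#' as 6.0 + 0.74 * CO (RPA) and 6.0 + 0.77 * CO (LPA), in mmHg with CO in
#' L/min.
#'
#' @param CO cardiac output (L/min), >= 0.
#' @param side `"RPA"` or `"LPA"`.
#' @return Pressure in mmHg.
#' @export
mcl_target_pa_pressure <- function(CO, side = c("RPA", "LPA")) {
  side <- match.arg(side)
  if (CO < 0) stop("mcl_target_pa_pressure: CO must be non-negative")
  6.0 + if (side == "RPA") 0.74 * CO else 0.77 * CO
}

#' Synthetic mock-loop pressure-loss measurements
#'
#' Emulates paired bench measurements for the agreement analysis: measured =
#' model + bias + Gaussian(0, noise_sd), reproducibly for a given seed.
#'
#' @param model_pressure_losses numeric vector of simulated losses (mmHg).
#' @param bias systematic offset (mmHg).
#' @param noise_sd Gaussian noise SD (mmHg), >= 0.
#' @param seed integer RNG seed.
#' @param CO optional vector of cardiac outputs per case (L/min).
#' @param model optional vector of model ids per case.
#' @return A data.frame of class `mcl_dataset` with columns `case_id`,
#'   `CO_L_min`, `model`, `dP_model_mmHg`, `dP_mmHg` (measured), `source`.
#' @export
synth_mcl_measurements <- function(model_pressure_losses, bias = 0,
                                   noise_sd = 0, seed = 1L,
                                   CO = NULL, model = NULL) {
  if (noise_sd < 0) stop("synth_mcl_measurements: noise_sd must be >= 0")
  n <- length(model_pressure_losses)
  noise <- withr::with_seed(as.integer(seed), stats::rnorm(n, 0, noise_sd))
  if (noise_sd == 0) noise <- rep(0, n)
  out <- data.frame(
    case_id = seq_len(n),
    CO_L_min = if (is.null(CO)) NA_real_ else CO,
    model = if (is.null(model)) "synthetic" else as.character(model),
    dP_model_mmHg = as.numeric(model_pressure_losses),
    dP_mmHg = as.numeric(model_pressure_losses) + bias + noise,
    source = "synthetic_mcl",
    stringsAsFactors = FALSE)
  class(out) <- c("mcl_dataset", class(out))
  out
}
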