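# Force inference through the overdamped Langevin picture: the viscous
# drag gamma * xdot balances the applied force, so the ensemble-averaged
# velocity is <xdot> = F / gamma and the measured drift velocity is
# proportional to the mean force on the locus.  The drag itself is
# estimated from the effective diffusion constant via the Einstein
# relation gamma = k_B T / D — an order-of-magnitude assumption that the
# position fluctuations are not much larger than thermal.

BOLTZMANN_J_PER_K <- 1.380649e-23
MIN_PER_S <- 1 / 60

#' Physical context for unit conversion
#'
#' @param temperature absolute temperature in K (default 303 K, i.e. the
#'   30 C growth temperature of slow-growing cultures).
#' @param cell_length_um representative cell length (um) used to convert
#'   relative positions to physical distance.
#' @param delta_t sampling interval (min).
#' @return a `physical_context` with the thermal energy `kBT` (J) derived.
#' @export
physical_context <- function(temperature = 303, cell_length_um = 2.5,
                             delta_t = 1) {
  stopifnot(temperature > 0, cell_length_um > 0, delta_t > 0)
  structure(list(temperature = temperature,
                 kBT = BOLTZMANN_J_PER_K * temperature,
                 cell_length_um = cell_length_um,
                 delta_t = delta_t),
            class = "physical_context")
}

#' Estimate the viscous drag from the effective diffusion constant
#'
#' Einstein relation: gamma = k_B T / D.
#'
#' @param D_m2_s effective diffusion constant in m^2/s, > 0.
#' @param context a [physical_context()].
#' @return drag coefficient gamma in kg/s.
#' @export
estimate_drag <- function(D_m2_s, context = physical_context()) {
  if (!is.numeric(D_m2_s) || any(D_m2_s <= 0)) {
    stop("diffusion constant must be positive")
  }
  context$kBT / D_m2_s
}

#' Convert a drift profile into a force profile
#'
#' Converts the binned drift velocity and the interval's effective
#' diffusion constant from relative units to SI via the cell length
#' (v_phys = v * L, D_phys = D_eff * L^2), estimates the drag by the
#' Einstein relation, and reports F(x) = gamma * v_phys(x) per bin together
#' with the peak magnitude.  The annotation compares the peak to a 1 pN
#' reference — molecular-motor stall forces are of order several pN, so a
#' much smaller peak indicates a bias far weaker than canonical motors.
#'
#' @param profile a `drift_profile` (relative units/min).
#' @param D_eff effective diffusion constant of the same interval,
#'   (relative units)^2/min.
#' @param context a [physical_context()] supplying temperature and cell
#'   length.
#' @return a `force_profile`: list with per-bin table (`x`, `F_N`, `n`,
#'   `populated`), `gamma_kg_s`, `D_m2_s`, `peak_F_N`, `annotation`.
#' @export
force_profile <- function(profile, D_eff, context = physical_context()) {
  if (is.null(context$cell_length_um) || !is.finite(context$cell_length_um)) {
    stop("physical conversion requires cell length")
  }
  if (!is.numeric(D_eff) || D_eff <= 0) stop("D_eff must be positive")
  L_m <- context$cell_length_um * 1e-6
  v_m_s <- profile$v * L_m * MIN_PER_S          # rel/min -> m/s
  D_m2_s <- D_eff * L_m^2 * MIN_PER_S           # rel^2/min -> m^2/s
  gamma <- estimate_drag(D_m2_s, context)
  F_N <- gamma * v_m_s
  peak <- max(abs(F_N[profile$populated]), na.rm = TRUE)
  annotation <- sprintf(
    paste0("Assumes fluctuations are close to thermal (Einstein relation); ",
           "peak |F| = %.3g N = %.3g pN relative to a 1 pN motor-scale ",
           "reference (%s)."),
    peak, peak * 1e12,
    if (peak < 1e-12) "substantially smaller" else "comparable or larger")
  structure(list(bins = data.frame(x = profile$x, F_N = F_N, n = profile$n,
                                   populated = profile$populated),
                 gamma_kg_s = gamma, D_m2_s = D_m2_s, peak_F_N = peak,
                 annotation = annotation, context = context),
            class = "force_profile")
}

#' @export
print.force_profile <- function(x, ...) {
  cat(sprintf("<force_profile> gamma = %.3g kg/s, peak |F| = %.3g pN\n",
              x$gamma_kg_s, x$peak_F_N * 1e12))
  cat(" ", x$annotation, "\n")
  invisible(x)
}
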