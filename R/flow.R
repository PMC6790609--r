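#' Construct fluid properties
#'
#' Defaults are the perfusion media used throughout: water-like dynamic
#' viscosity 1e-3 Pa s and density 1000 kg/m^3.
#'
#' @param dynamic_viscosity Pa s.
#' @param density kg/m^3.
#' @return A validated [FluidProps-class].
#' @export
fluidProps <- function(dynamic_viscosity = 1e-3, density = 1000) {
  new("FluidProps", dynamic_viscosity = dynamic_viscosity,
      density = density)
}

#' Construct porous-medium properties
#'
#' Defaults describe the collagen hydrogel filling the chondral pores:
#' permeability 1e-12 m^2 and porosity 0.90. `solid_penalization_k` is
#' the vanishing permeability assigned to PLA voxels so one Brinkman
#' equation covers lumen, collagen, and solid; at the default 1e-18 m^2
#' the velocity leaking into struts is negligible compared to the inlet
#' velocity.
#'
#' @param permeability collagen permeability (m^2).
#' @param porosity collagen porosity.
#' @param solid_penalization_k solid penalization permeability (m^2).
#' @return A validated [PorousProps-class].
#' @export
porousProps <- function(permeability = 1e-12, porosity = 0.90,
                        solid_penalization_k = 1e-18) {
  new("PorousProps", permeability = permeability, porosity = porosity,
      solid_penalization_k = solid_penalization_k)
}

#' Construct flow boundary conditions
#'
#' Defaults perfuse each chamber at 0.02 ml/min against 0 Pa outlets with
#' no-slip walls. The chamber total is split equally over that chamber's
#' inlet ports.
#'
#' @param inlet_flow_rate named numeric (names `top`, `bottom`), total
#'   volumetric inflow per chamber in m^3/s. The default corresponds to
#'   0.02 ml/min per chamber.
#' @param outlet_pressure outlet reference pressure (Pa).
#' @param slip_axes logical length 3; free-slip side walls per axis
#'   (verification fixtures only).
#' @return A validated [FlowBC-class].
#' @examples
#' flowBC()                                  # 0.02 ml/min per chamber
#' flowBC(inlet_flow_rate = mlPerMin(0.04))  # doubled
#' @export
flowBC <- function(inlet_flow_rate = mlPerMin(c(top = 0.02, bottom = 0.02)),
                   outlet_pressure = 0,
                   slip_axes = c(FALSE, FALSE, FALSE)) {
  new("FlowBC", inlet_flow_rate = inlet_flow_rate,
      outlet_pressure = outlet_pressure, slip_axes = slip_axes)
}

#' Convert ml/min to m^3/s
#' @param x flow rate(s) in ml/min.
#' @return Flow rate(s) in m^3/s (names preserved).
#' @examples mlPerMin(0.02)
#' @export
mlPerMin <- function(x) x * 1e-6 / 60

#' Mean inlet velocity through a circular port
#'
#' `flow_rate / (pi (d/2)^2)`: the mean velocity a prescribed volumetric
#' flow produces in a circular bore. With the default operating point --
#' 0.02 ml/min through 1.02 mm tubing -- this is 0.41 mm/s.
#'
#' @param flow_rate volumetric flow (m^3/s).
#' @param port_diameter bore diameter (m).
#' @return Mean velocity (m/s).
#' @examples
#' inletVelocity(mlPerMin(0.02), 1.02e-3) * 1e3  # mm/s
#' @export
inletVelocity <- function(flow_rate, port_diameter) {
  stopifnot(flow_rate > 0, port_diameter > 0)
  flow_rate / (pi * (port_diameter / 2)^2)
}

#' Reynolds number of the perfusion flow
#'
#' `Re = rho v L / mu`. The creeping-flow (Stokes) approximation used by
#' [solveFlow()] assumes `Re << 1`; a warning is raised above 1, and
#' above 100 the steady laminar assumption itself becomes questionable.
#'
#' @param props a [FluidProps-class].
#' @param velocity characteristic velocity (m/s).
#' @param length_scale characteristic length (m).
#' @return The Reynolds number.
#' @examples
#' reynoldsNumber(fluidProps(), 0.41e-3, 1.02e-3)
#' @export
reynoldsNumber <- function(props, velocity, length_scale) {
  stopifnot(velocity >= 0, length_scale > 0)
  re <- props@density * velocity * length_scale / props@dynamic_viscosity
  if (re > 100) {
    warning(sprintf("Re = %.3g: laminar assumption questionable", re))
  } else if (re > 1) {
    warning(sprintf("Re = %.3g: Stokes (creeping flow) approximation degrades", re))
  }
  re
}

#' Mass conservation check for a solved flow field
#'
#' Flux bookkeeping over the port set: relative imbalance
#' `|Q_in - Q_out| / Q_in` globally and per chamber, from the solved
#' face velocities. With a sealed separator each chamber must conserve
#' mass individually; any through-scaffold exchange shows up as equal
#' and opposite per-chamber imbalances.
#'
#' @param field a [FlowField-class] from [solveFlow()].
#' @param grid the [LabeledGrid-class] it was solved on (unused beyond
#'   interface symmetry; port bookkeeping travels with the field).
#' @param bc the [FlowBC-class] used.
#' @return List with `global`, `per_chamber` (named numeric), and the
#'   per-port flux `table`.
#' @export
checkMassConservation <- function(field, grid, bc) {
  pf <- field@diagnostics$port_flux
  if (is.null(pf) || !nrow(pf)) stop("field carries no port flux table")
  tot_in <- sum(pf$flux[pf$role == "inlet"])   # into the domain, >= 0
  tot_out <- sum(pf$flux[pf$role == "outlet"])
  scale <- max(abs(tot_in), .Machine$double.eps)
  global <- abs(tot_in - tot_out) / scale
  chambers <- unique(pf$chamber)
  per <- vapply(chambers, function(ch) {
    qin <- sum(pf$flux[pf$chamber == ch & pf$role == "inlet"])
    qout <- sum(pf$flux[pf$chamber == ch & pf$role == "outlet"])
    abs(qin - qout) / max(abs(qin), scale * 1e-6, .Machine$double.eps)
  }, numeric(1))
  names(per) <- chambers
  list(global = global, per_chamber = per, table = pf)
}

setMethod("show", "FlowField", function(object) {
  d <- dim(object@p)
  dg <- object@diagnostics
  cat(sprintf(
    "FlowField: %d x %d x %d cells @ %.0f um | converged=%s, iters=%d, continuity residual %.2e\n",
    d[1], d[2], d[3], object@spacing * 1e6,
    isTRUE(dg$converged), dg$iterations %||% NA_integer_,
    dg$continuity_residual %||% NA_real_
  ))
})
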