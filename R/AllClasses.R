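#' @import methods
#' @importFrom stats rnorm runif setNames sd aggregate dist quantile
#' @importFrom utils head tail write.csv
NULL

# Integer label codes for LabeledGrid voxels. WALL is 0 so that a zeroed
# array is a sealed box.
.LABELS <- c(WALL = 0L, LUMEN = 1L, SOLID = 2L, POROUS = 3L)

# Layer tags, ordered bottom-up along the chamber axis (z).
.LAYERS <- c(
  NONE = 0L, BOTTOM_CHAMBER = 1L, OSSEOUS = 2L, SEPARATOR = 3L,
  CHONDRAL = 4L, TOP_CHAMBER = 5L
)

#' Voxel label and layer code tables
#'
#' Integer codes used in the `label` and `layer` arrays of a
#' [LabeledGrid-class] object. Labels classify each voxel as chamber wall,
#' free medium, PLA strut, or collagen-filled pore space; layers tag the
#' axial band (bottom plenum, osseous, separator, chondral, top plenum).
#'
#' @return Named integer vector mapping tag names to codes.
#' @examples
#' gridLabels()
#' gridLayers()
#' @export
gridLabels <- function() .LABELS

#' @rdname gridLabels
#' @export
gridLayers <- function() .LAYERS

#' Parametric description of the bilayered lattice scaffold
#'
#' Cylindrical PLA lattice with a fine chondral mesh on top, a coarse
#' osseous mesh on the bottom, and two close-packed separator layers in
#' between; chondral pores may be filled with collagen. All lengths are in
#' metres (SI). Construct with [scaffoldSpec()].
#'
#' @slot cylinder_diameter,cylinder_height scaffold envelope (m).
#' @slot chondral_strut_d,chondral_spacing fine-mesh strut diameter and
#'   in-layer gap between struts (m).
#' @slot osseous_strut_d,osseous_spacing coarse-mesh strut diameter and
#'   in-layer gap (m).
#' @slot osseous_spacing_range admissible range for `osseous_spacing` (m).
#' @slot separator_strut_d separator strut diameter (m).
#' @slot separator_layers number of close-packed separator layers.
#' @slot separator_gap in-layer gap between close-packed separator
#'   struts (m); a small positive gap keeps the two chambers in
#'   communication through the separator.
#' @slot chondral_height,osseous_height axial extent of each section (m);
#'   the separator occupies `separator_layers * separator_strut_d`.
#' @slot layer_height nominal print layer height (m), retained for
#'   reporting.
#' @slot rotation_deg in-plane rotation of the whole lattice (degrees).
#' @slot collagen_in_chondral_pores logical; fill chondral pore space with
#'   collagen (modeled as porous medium).
#' @export
setClass("ScaffoldSpec", representation(
  cylinder_diameter = "numeric", cylinder_height = "numeric",
  chondral_strut_d = "numeric", chondral_spacing = "numeric",
  osseous_strut_d = "numeric", osseous_spacing = "numeric",
  osseous_spacing_range = "numeric",
  separator_strut_d = "numeric", separator_layers = "integer",
  separator_gap = "numeric",
  chondral_height = "numeric", osseous_height = "numeric",
  layer_height = "numeric", rotation_deg = "numeric",
  collagen_in_chondral_pores = "logical"
))

setValidity("ScaffoldSpec", function(object) {
  msg <- character()
  lens <- c(
    object@cylinder_diameter, object@cylinder_height,
    object@chondral_strut_d, object@osseous_strut_d,
    object@separator_strut_d, object@chondral_height,
    object@osseous_height, object@layer_height
  )
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    msg <- c(msg, "all lengths must be finite and > 0")
  }
  if (object@chondral_spacing < 0 || object@osseous_spacing < 0 ||
      object@separator_gap < 0) {
    msg <- c(msg, "spacings/gaps must be >= 0")
  }
  if (length(object@osseous_spacing_range) != 2L ||
      diff(object@osseous_spacing_range) < 0) {
    msg <- c(msg, "osseous_spacing_range must be an increasing length pair")
  }
  if (object@osseous_spacing < object@osseous_spacing_range[1] - 1e-12 ||
      object@osseous_spacing > object@osseous_spacing_range[2] + 1e-12) {
    msg <- c(msg, "osseous_spacing outside osseous_spacing_range")
  }
  if (object@rotation_deg < 0 || object@rotation_deg >= 90) {
    msg <- c(msg, "rotation_deg must lie in [0, 90)")
  }
  sep_h <- object@separator_layers * object@separator_strut_d
  total <- object@chondral_height + object@osseous_height + sep_h
  if (total > object@cylinder_height + 1e-9) {
    msg <- c(msg, sprintf(
      "section heights (%.3g m) exceed cylinder height (%.3g m)",
      total, object@cylinder_height
    ))
  }
  if (length(msg)) msg else TRUE
})

#' Dual-chamber bioreactor chamber description
#'
#' Cylindrical chamber enclosing the scaffold, with plenum space above and
#' below and inlet/outlet ports on the side wall of each chamber. The
#' scaffold perimeter may be sealed to the chamber wall at separator
#' mid-height so that the only communication between chambers runs through
#' the scaffold. Construct with [chamberSpec()].
#'
#' @slot inner_diameter chamber inner diameter (m).
#' @slot plenum_top,plenum_bottom free medium height above/below the
#'   scaffold (m).
#' @slot port_diameter port bore (m); default matches 1.02 mm pump tubing.
#' @slot midplane_seal logical; seal the scaffold-wall annulus at
#'   separator height.
#' @slot ports data.frame of ports (one row each) with columns
#'   `role` ("inlet"/"outlet"), `chamber` ("top"/"bottom"), `px,py,pz`
#'   centre (m), `nx,ny,nz` outward unit normal, `diameter` (m),
#'   `profile` ("parabolic"/"uniform"), `conc` inlet concentration
#'   (normalized; NA for outlets). Empty means "derive default ports at
#'   voxelization time".
#' @export
setClass("ChamberSpec", representation(
  inner_diameter = "numeric", plenum_top = "numeric",
  plenum_bottom = "numeric", port_diameter = "numeric",
  midplane_seal = "logical", ports = "data.frame"
))

setValidity("ChamberSpec", function(object) {
  msg <- character()
  if (object@inner_diameter <= 0) msg <- c(msg, "inner_diameter must be > 0")
  if (object@plenum_top <= 0 || object@plenum_bottom <= 0) {
    msg <- c(msg, "plenum heights must be > 0")
  }
  if (object@port_diameter <= 0) msg <- c(msg, "port_diameter must be > 0")
  p <- object@ports
  if (nrow(p)) {
    need <- c("role", "chamber", "px", "py", "pz", "nx", "ny", "nz",
              "diameter", "profile", "conc")
    if (!all(need %in% names(p))) {
      msg <- c(msg, "ports data.frame missing required columns")
    } else {
      for (ch in c("top", "bottom")) {
        sel <- p$chamber == ch
        if (any(sel)) {
          if (!any(p$role[sel] == "inlet") || !any(p$role[sel] == "outlet")) {
            msg <- c(msg, sprintf(
              "chamber '%s' needs at least one inlet and one outlet", ch
            ))
          }
        }
      }
      if (nrow(p) > 1) {
        d <- as.matrix(dist(p[, c("px", "py", "pz")]))
        diag(d) <- Inf
        rr <- outer(p$diameter / 2, p$diameter / 2, "+")
        if (any(d < rr - 1e-12)) msg <- c(msg, "ports overlap")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Set of capped-cylinder struts forming the lattice
#'
#' Each strut is a horizontal cylinder segment clipped to the scaffold
#' envelope, tagged by the lattice section it belongs to. Manufacturing
#' deviations (diameter scaling, vertical flattening, surface roughness)
#' are stored per strut so that the voxelizer can render them. Built by
#' [buildLattice()]; perturbed by [applyPrintArtifacts()].
#'
#' @slot struts data.frame with one row per strut: `x0,y0,z0,x1,y1,z1`
#'   axis endpoints (m), `radius` (m), `layer` tag ("chondral",
#'   "separator", "osseous"), `zscale` vertical semi-axis scaling
#'   (1 = circular cross-section), `rough_amp` roughness amplitude (m)
#'   and `rough_f1,rough_p1,rough_f2,rough_p2` sinusoid frequency/phase
#'   pairs describing the along-axis radius modulation.
#' @slot spec the [ScaffoldSpec-class] the lattice was built from.
#' @export
setClass("StrutSet", representation(struts = "data.frame",
                                    spec = "ScaffoldSpec"))

setValidity("StrutSet", function(object) {
  s <- object@struts
  need <- c("x0", "y0", "z0", "x1", "y1", "z1", "radius", "layer",
            "zscale", "rough_amp", "rough_f1", "rough_p1", "rough_f2",
            "rough_p2")
  if (!all(need %in% names(s))) return("struts data.frame missing columns")
  if (nrow(s)) {
    if (any(s$radius <= 0)) return("every strut radius must be > 0")
    if (!all(s$layer %in% c("chondral", "separator", "osseous"))) {
      return("strut layer tags must cover {chondral, separator, osseous}")
    }
    if (any(s$zscale <= 0 | s$zscale > 1)) {
      return("zscale must lie in (0, 1]")
    }
  }
  TRUE
})

#' Labeled voxel grid of the chamber + scaffold domain
#'
#' The single geometry currency of the solvers: a uniform, isotropic,
#' cell-centred voxel grid labeling every cell as chamber wall, free
#' medium (lumen), PLA strut (solid), or collagen (porous), with an
#' axial layer tag. The z axis is the scaffold axis, pointing from the
#' osseous (bottom) towards the chondral (top) section.
#'
#' @slot spacing isotropic voxel edge length (m).
#' @slot origin coordinates of the grid corner (m); cell centres sit at
#'   `origin + (i - 0.5) * spacing`.
#' @slot label integer array, see [gridLabels()].
#' @slot layer integer array, see [gridLayers()].
#' @slot ports data.frame of ports (same schema as in
#'   [ChamberSpec-class]); consumed by the flow and transport solvers.
#' @slot meta list of geometry metadata (layer z-bands, axis centre,
#'   scaffold/chamber radii, specs used).
#' @export
setClass("LabeledGrid", representation(
  spacing = "numeric", origin = "numeric", label = "array",
  layer = "array", ports = "data.frame", meta = "list"
))

setValidity("LabeledGrid", function(object) {
  msg <- character()
  if (length(object@spacing) != 1L || object@spacing <= 0) {
    msg <- c(msg, "spacing must be a single positive length")
  }
  if (length(object@origin) != 3L) msg <- c(msg, "origin must be length 3")
  if (!identical(dim(object@label), dim(object@layer))) {
    msg <- c(msg, "label and layer arrays must have identical shape")
  }
  if (length(dim(object@label)) != 3L) {
    msg <- c(msg, "label must be a 3-D array")
  }
  if (!all(object@label %in% .LABELS)) {
    msg <- c(msg, "unknown label codes present")
  }
  if (!all(object@layer %in% .LAYERS)) {
    msg <- c(msg, "unknown layer codes present")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic grayscale micro-CT-like volume
#'
#' Float intensity volume on the same cell-centred grid convention as
#' [LabeledGrid-class]. Produced by [renderGrayscale()]; collagen is
#' radiolucent and rendered as background.
#'
#' @slot intensity 3-D numeric array of voxel intensities.
#' @slot spacing voxel edge length (m).
#' @slot origin grid corner (m).
#' @export
setClass("GrayVolume", representation(
  intensity = "array", spacing = "numeric", origin = "numeric"
))

setValidity("GrayVolume", function(object) {
  if (length(dim(object@intensity)) != 3L) return("intensity must be 3-D")
  if (any(!is.finite(object@intensity))) return("intensities must be finite")
  if (object@spacing <= 0) return("spacing must be > 0")
  TRUE
})

#' Manufacturing-deviation parameters for the synthetic print pathway
#'
#' Emulates the deviation classes of fused-deposition printing relative to
#' CAD: strut diameter error (part accuracy/shrinkage), vertical sag of
#' deposited strands (ellipticity), and surface roughness.
#' Construct with [artifactParams()].
#'
#' @slot diameter_scale_mean,diameter_scale_sd mean and sd of the
#'   multiplicative per-strut diameter error (1 = faithful print).
#' @slot sag_fraction vertical flattening of strut cross-sections in
#'   `[0, 1)`; 0 keeps them circular.
#' @slot roughness_amplitude amplitude of the along-strut surface
#'   perturbation (m).
#' @slot seed integer RNG seed making the pathway deterministic.
#' @export
setClass("ArtifactParams", representation(
  diameter_scale_mean = "numeric", diameter_scale_sd = "numeric",
  sag_fraction = "numeric", roughness_amplitude = "numeric",
  seed = "integer"
))

setValidity("ArtifactParams", function(object) {
  msg <- character()
  if (object@diameter_scale_mean <= 0) {
    msg <- c(msg, "diameter_scale_mean must be > 0")
  }
  if (object@diameter_scale_sd < 0) {
    msg <- c(msg, "diameter_scale_sd must be >= 0")
  }
  if (object@sag_fraction < 0 || object@sag_fraction >= 1) {
    msg <- c(msg, "sag_fraction must lie in [0, 1)")
  }
  if (object@roughness_amplitude < 0) {
    msg <- c(msg, "roughness_amplitude must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Perfusion medium properties
#' @slot dynamic_viscosity Pa s.
#' @slot density kg/m^3.
#' @export
setClass("FluidProps", representation(
  dynamic_viscosity = "numeric", density = "numeric"
))
setValidity("FluidProps", function(object) {
  if (object@dynamic_viscosity <= 0 || object@density <= 0) {
    return("viscosity and density must be > 0")
  }
  TRUE
})

#' Porous-medium (collagen) properties and solid penalization
#'
#' @slot permeability collagen permeability (m^2).
#' @slot porosity collagen porosity (fraction of fluid volume).
#' @slot solid_penalization_k vanishing permeability assigned to PLA
#'   voxels so that a single Brinkman equation covers the whole domain
#'   (m^2); must be many orders below `permeability`.
#' @export
setClass("PorousProps", representation(
  permeability = "numeric", porosity = "numeric",
  solid_penalization_k = "numeric"
))
setValidity("PorousProps", function(object) {
  msg <- character()
  if (object@permeability <= 0) msg <- c(msg, "permeability must be > 0")
  if (object@porosity <= 0 || object@porosity > 1) {
    msg <- c(msg, "porosity must lie in (0, 1]")
  }
  if (object@solid_penalization_k <= 0 ||
      object@solid_penalization_k > object@permeability * 1e-3) {
    msg <- c(msg, "solid_penalization_k must be > 0 and << permeability")
  }
  if (length(msg)) msg else TRUE
})

#' Flow boundary conditions
#'
#' @slot inlet_flow_rate named numeric, total volumetric inflow per
#'   chamber (m^3/s), split equally over that chamber's inlet ports.
#' @slot outlet_pressure reference pressure at the outlets (Pa).
#' @slot slip_axes logical length-3; TRUE turns the domain-box wall
#'   tangential condition of that axis into free slip (used for
#'   quasi-2-D verification fixtures; physical walls are no-slip).
#' @export
setClass("FlowBC", representation(
  inlet_flow_rate = "numeric", outlet_pressure = "numeric",
  slip_axes = "logical"
))
setValidity("FlowBC", function(object) {
  if (any(object@inlet_flow_rate < 0)) {
    return("inlet flow rates must be >= 0")
  }
  if (length(object@slip_axes) != 3L) return("slip_axes must be length 3")
  TRUE
})

#' Steady velocity/pressure field on the staggered grid
#'
#' Face-normal velocities on a MAC arrangement: `ux` has dimension
#' `(nx+1, ny, nz)` with `ux[i,,]` the x-face between cells `i-1` and `i`
#' (faces on walls or outside the fluid carry 0), similarly `uy`, `uz`;
#' `p` is the cell-centred pressure. Produced by [solveFlow()].
#'
#' @slot ux,uy,uz face-normal velocity arrays (m/s).
#' @slot p cell-centred pressure (Pa); NA in WALL cells.
#' @slot diagnostics list: residual history, convergence flag, per-port
#'   flux table, solver settings.
#' @slot spacing,origin grid convention carried over.
#' @export
setClass("FlowField", representation(
  ux = "array", uy = "array", uz = "array", p = "array",
  diagnostics = "list", spacing = "numeric", origin = "numeric"
))

#' Normalized media concentration field
#'
#' Cell-centred steady tracer concentration; 1 corresponds to the 1 mM
#' chondrogenic marker at the top inlets, 0 to osteogenic medium at the
#' bottom inlets. Produced by [solveTransport()].
#'
#' @slot conc 3-D numeric array; NA in WALL and SOLID cells.
#' @slot diagnostics list: residuals, flux balance, solver settings.
#' @slot spacing,origin grid convention carried over.
#' @export
setClass("ConcentrationField", representation(
  conc = "array", diagnostics = "list", spacing = "numeric",
  origin = "numeric"
))

setValidity("ConcentrationField", function(object) {
  v <- object@conc[!is.na(object@conc)]
  if (length(v) && (any(v < -1e-6) || any(v > 1 + 1e-6))) {
    return("concentrations must lie in [0, 1]")
  }
  TRUE
})

#' Fluid-induced shear stress on strut surfaces
#'
#' Shear stress magnitude defined on SOLID voxels that border fluid
#' (lumen or collagen); NA elsewhere. Produced by [wallShearStress()].
#'
#' @slot tau 3-D numeric array of shear stress magnitude (Pa); NA off the
#'   strut surface.
#' @slot spacing,origin grid convention carried over.
#' @export
setClass("WSSField", representation(
  tau = "array", spacing = "numeric", origin = "numeric"
))
setValidity("WSSField", function(object) {
  v <- object@tau[!is.na(object@tau)]
  if (length(v) && any(v < 0)) return("shear stress must be >= 0")
  TRUE
})

#' Per-layer microenvironment report
#'
#' The per-layer summary the pipeline produces: mean/max velocity
#' magnitude, mean/max fluid-induced shear stress, mean concentration for
#' the chondral and osseous scaffold sections, plus per-chamber outlet
#' mixing fractions and optional extras (chamber velocity maxima,
#' fraction of strut surface below 1 mPa). Built by [microenvReport()];
#' two reports are compared with [compareReports()].
#'
#' @slot table data.frame with one row per scaffold layer and columns
#'   `layer`, `mean_v_um_s`, `max_v_um_s`, `mean_fss_mpa`, `max_fss_mpa`,
#'   `mean_conc`.
#' @slot mixing named numeric: flux-weighted outlet mixing fraction for
#'   `top` and `bottom` chambers.
#' @slot extras list of auxiliary scalars.
#' @export
setClass("MicroenvReport", representation(
  table = "data.frame", mixing = "numeric", extras = "list"
))
setValidity("MicroenvReport", function(object) {
  t <- object@table
  need <- c("layer", "mean_v_um_s", "max_v_um_s", "mean_fss_mpa",
            "max_fss_mpa", "mean_conc")
  if (!all(need %in% names(t))) return("report table missing columns")
  if (nrow(t)) {
    if (any(t$max_v_um_s < t$mean_v_um_s - 1e-9, na.rm = TRUE) ||
        any(t$max_fss_mpa < t$mean_fss_mpa - 1e-9, na.rm = TRUE)) {
      return("max statistics must be >= mean statistics")
    }
    cc <- t$mean_conc[!is.na(t$mean_conc)]
    if (length(cc) && (any(cc < -1e-9) || any(cc > 1 + 1e-9))) {
      return("mean concentrations must lie in [0, 1]")
    }
  }
  if (length(object@mixing)) {
    m <- object@mixing[!is.na(object@mixing)]
    if (any(m < -1e-9) || any(m > 1 + 1e-9)) {
      return("mixing fractions must lie in [0, 1]")
    }
  }
  TRUE
})

#' Literature-derived effective-culture thresholds
#'
#' Threshold set against which a [MicroenvReport-class] is classified:
#' chondrogenesis tolerates only very low shear and moderate flow rate,
#' osteogenesis responds to a broad band of shear magnitudes, and high
#' local velocity risks detaching bridging cells. Each threshold carries
#' a citation string so verdicts are self-documenting. Construct with
#' [regimeThresholds()].
#'
#' @slot chondro_max_mean_fss mPa; chondral mean FSS must stay below.
#' @slot chondro_max_flow_rate ml/min; chondral perfusion rate cap.
#' @slot detachment_velocity um/s; local velocity above which bridging
#'   cells detach.
#' @slot osteo_fss_band mPa interval of effective osteogenic mean FSS.
#' @slot citations named character vector of sources.
#' @export
setClass("RegimeThresholds", representation(
  chondro_max_mean_fss = "numeric", chondro_max_flow_rate = "numeric",
  detachment_velocity = "numeric", osteo_fss_band = "numeric",
  citations = "character"
))
setValidity("RegimeThresholds", function(object) {
  msg <- character()
  if (object@chondro_max_mean_fss <= 0 ||
      object@chondro_max_flow_rate <= 0 ||
      object@detachment_velocity <= 0) {
    msg <- c(msg, "thresholds must be > 0")
  }
  if (length(object@osteo_fss_band) != 2L ||
      diff(object@osteo_fss_band) <= 0 || any(object@osteo_fss_band <= 0)) {
    msg <- c(msg, "osteo_fss_band must be a positive non-empty interval")
  }
  if (length(msg)) msg else TRUE
})

#' Regime classification verdict
#'
#' Pure function of a report and a threshold set: per-layer flags for
#' chondrogenic compatibility, osteogenic compatibility, and detachment
#' risk, with the triggering values retained. Produced by
#' [classifyRegime()].
#'
#' @slot flags data.frame with columns `layer`,
#'   `chondrogenic_compatible`, `osteogenic_compatible`,
#'   `detachment_risk`.
#' @slot details list of the values and thresholds that produced each
#'   flag.
#' @export
setClass("RegimeVerdict", representation(
  flags = "data.frame", details = "list"
))
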