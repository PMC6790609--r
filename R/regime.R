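#' Construct effective-culture thresholds
#'
#' Literature-derived operating windows for perfused 3-D osteochondral
#' culture: chondrogenesis requires very low shear (mean FSS below
#' 0.1 mPa) and at most 0.2 ml/min perfusion; reported effective
#' osteogenic mean FSS spans 0.05-100 mPa depending on scaffold and
#' cells; local velocities above 235 um/s detach bridging cells. Each
#' threshold carries its citation so verdicts are self-documenting; the
#' osteogenic band is deliberately configurable because the literature
#' disagrees on the effective magnitude.
#'
#' @param chondro_max_mean_fss mPa.
#' @param chondro_max_flow_rate ml/min.
#' @param detachment_velocity um/s.
#' @param osteo_fss_band mPa interval.
#' @param citations named character vector.
#' @return A validated [RegimeThresholds-class].
#' @examples
#' regimeThresholds()
#' @export
regimeThresholds <- function(chondro_max_mean_fss = 0.1,
                             chondro_max_flow_rate = 0.2,
                             detachment_velocity = 235,
                             osteo_fss_band = c(0.05, 100),
                             citations = c(
    chondro_max_mean_fss = "FSS up to ~0.1 mPa maintains cartilage phenotype; 100 mPa reduces chondrogenesis",
    chondro_max_flow_rate = "enhanced chondrogenesis reported for perfusion up to 0.2 ml/min",
    detachment_velocity = "flow velocity over 235 um/s linked to detachment of bridging cells",
    osteo_fss_band = "reported effective osteogenic mean FSS spans 0.05-100 mPa"
                             )) {
  new("RegimeThresholds",
    chondro_max_mean_fss = chondro_max_mean_fss,
    chondro_max_flow_rate = chondro_max_flow_rate,
    detachment_velocity = detachment_velocity,
    osteo_fss_band = osteo_fss_band,
    citations = citations
  )
}

#' Classify a microenvironment report against culture regimes
#'
#' Pure threshold classification of a [MicroenvReport-class]:
#' the chondral layer is chondrogenic-compatible iff its mean FSS is
#' strictly below the chondrogenic cap and the flow rate does not
#' exceed the chondrogenic flow limit; the osseous layer is
#' osteogenic-compatible iff its mean FSS falls inside the osteogenic
#' band; a layer carries detachment risk iff its maximum velocity
#' strictly exceeds the detachment velocity (boundary values do not
#' trigger the flag).
#'
#' @param report a [MicroenvReport-class].
#' @param flow_rate perfusion rate per chamber (ml/min).
#' @param thresholds a [RegimeThresholds-class].
#' @return A [RegimeVerdict-class].
#' @examples
#' # the default operating point: ~0.03 / ~0.28 mPa mean FSS at
#' # 0.02 ml/min sits inside the effective osteochondral region
#' tab <- data.frame(
#'   layer = c("chondral", "osseous"),
#'   mean_v_um_s = c(5, 30), max_v_um_s = c(150, 200),
#'   mean_fss_mpa = c(0.03, 0.28), max_fss_mpa = c(5, 8),
#'   mean_conc = c(0.95, 0.2)
#' )
#' rep <- new("MicroenvReport", table = tab,
#'            mixing = c(top = 0.05, bottom = 0.2), extras = list())
#' classifyRegime(rep, flow_rate = 0.02)
#' @export
classifyRegime <- function(report, flow_rate,
                           thresholds = regimeThresholds()) {
  t <- report@table
  need <- c("mean_fss_mpa", "max_v_um_s")
  missing <- need[vapply(need, function(m) any(is.na(t[[m]])), logical(1))]
  if (length(missing)) {
    stop(sprintf("report entries missing: %s",
                 paste(missing, collapse = ", ")))
  }
  flags <- data.frame(
    layer = t$layer,
    chondrogenic_compatible =
      t$mean_fss_mpa < thresholds@chondro_max_mean_fss &
      flow_rate <= thresholds@chondro_max_flow_rate,
    osteogenic_compatible =
      t$mean_fss_mpa >= thresholds@osteo_fss_band[1] &
      t$mean_fss_mpa <= thresholds@osteo_fss_band[2],
    detachment_risk = t$max_v_um_s > thresholds@detachment_velocity
  )
  new("RegimeVerdict",
    flags = flags,
    details = list(
      flow_rate_ml_min = flow_rate,
      mean_fss_mpa = setNames(t$mean_fss_mpa, t$layer),
      max_v_um_s = setNames(t$max_v_um_s, t$layer),
      thresholds = thresholds
    )
  )
}

#' Access the verdict flags
#' @param x a [RegimeVerdict-class].
#' @return data.frame of per-layer flags.
#' @export
verdictFlags <- function(x) x@flags

setMethod("show", "RegimeVerdict", function(object) {
  cat("RegimeVerdict (flow",
      object@details$flow_rate_ml_min, "ml/min)\n")
  print(object@flags, row.names = FALSE)
})

setMethod("show", "RegimeThresholds", function(object) {
  cat(sprintf(
    "RegimeThresholds: chondro FSS < %.3g mPa & flow <= %.3g ml/min; osteo FSS in [%.3g, %.3g] mPa; detachment > %.3g um/s\n",
    object@chondro_max_mean_fss, object@chondro_max_flow_rate,
    object@osteo_fss_band[1], object@osteo_fss_band[2],
    object@detachment_velocity
  ))
})

#' Literature operating points for perfused 3-D culture
#'
#' Static citation table of the operating points quoted in the text
#' sources behind [regimeThresholds()]: cell type, scaffold material,
#' outcome, and the FSS or flow-rate coordinate as printed. Only
#' numbers stated in prose are encoded.
#'
#' @return data.frame with `tissue`, `cells`, `material`, `outcome`,
#'   `fss_mpa`, `flow_ml_min`.
#' @export
regimeLiterature <- function() {
  data.frame(
    tissue = c("bone", "bone", "bone", "bone", "bone", "bone",
               "cartilage", "cartilage", "cartilage"),
    cells = c("MC3T3-E1", "MC3T3-E1", "MC3T3-E1", "hMSC", "MSC", "MSC",
              "chondrocytes", "chondrocytes", "chondrocytes"),
    material = c("decellularized trabecular bone",
                 "decellularized trabecular bone",
                 "decellularized trabecular bone",
                 "polyethylene terephthalate", "beta-TCP",
                 "decellularized trabecular bone",
                 "3-D porous scaffold", "3-D porous scaffold",
                 "3-D porous scaffold"),
    outcome = c("high viability/proliferation",
                "high osteogenic expression", "significant cell death",
                "increased osteogenic expression",
                "higher proliferation (lower FSS)",
                "improved osteogenesis (max FSS)",
                "phenotype maintained", "reduced chondrogenesis",
                "enhanced chondrogenesis up to this flow"),
    fss_mpa = c(0.05, 1, 5, 0.1, 5, 10, 0.1, 100, NA),
    flow_ml_min = c(NA, NA, NA, NA, NA, NA, NA, NA, 0.2)
  )
}
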