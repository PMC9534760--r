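#' Published thermal-limit and climate summaries for Rana parvipalmata
#'
#' Per-population summaries for 11 populations of the Galician common frog
#' along an elevational gradient (36-1835 m): sample sizes, means and
#' standard errors of CTmax and CTmin assayed at a 20 degrees C
#' pre-acclimation, macroclimate (TMAX, TMIN, SR) and pond microclimate
#' (tmax, tmin, sr, dr) over each population's larval period, and the
#' published warming/cooling tolerance columns (WT, wt, CT, ct).
#'
#' @return data.frame, one row per population.
#' @export
thermalLimitsTable <- function() {
  read.csv(system.file("extdata", "rana_parvipalmata_thermal_limits.csv",
                       package = "thermocline"), stringsAsFactors = FALSE)
}

#' Published acclimation-treatment CTmax means for five populations
#'
#' Group sizes, means and standard errors of CTmax after acclimation to 6,
#' 13, 20 or 27 degrees C in five Rana parvipalmata populations spanning
#' the elevational gradient. Input for [plasticityRange()] and [arr()].
#'
#' @return data.frame with columns `population`, `trait_name`,
#'   `acclimation_c`, `n`, `mean`, `se`.
#' @export
acclimationMeansTable <- function() {
  read.csv(system.file("extdata", "rana_parvipalmata_acclimation_means.csv",
                       package = "thermocline"), stringsAsFactors = FALSE)
}
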