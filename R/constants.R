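#' @useDynLib migcon, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dbeta dnorm plogis qlogis rbeta rbinom rmultinom rnorm
#'   runif density sd quantile median bw.SJ bw.nrd0 setNames rgamma
#' @importFrom utils read.csv write.csv
#' @keywords internal
"_PACKAGE"

# The model's fixed dimensions: 8 marking groups, 4 wintering areas, 3
# breeding populations, 2 isotope regions (Southern Africa vs the pooled
# Western/Central/Eastern region, "WCE"), 5 parasite lineages.

#' Marking-group, wintering-area and population labels
#'
#' The model distinguishes eight marking groups: birds ringed in Sweden and
#' Finland (never split seasonally) and, for the central and southern
#' European ringing regions, separate spring-migration, breeding and
#' autumn-migration groups.  Three of the eight groups have a known breeding
#' origin and are called populations: `SWE` (Northern), `Central_breeding`
#' and `Southern_breeding`.  The four sub-Saharan wintering areas are
#' Western, Central, Eastern and Southern Africa.
#'
#' @return Character vectors of labels, in the fixed index order used by all
#'   matrices in the package.
#' @export
group_labels <- function() {
  c("SWE", "FIN",
    "Central_spring", "Central_breeding", "Central_autumn",
    "Southern_spring", "Southern_breeding", "Southern_autumn")
}

#' @rdname group_labels
#' @export
area_labels <- function() c("Western", "Central", "Eastern", "Southern")

#' @rdname group_labels
#' @export
population_labels <- function() c("Northern", "Central", "Southern")

#' Rows of the connectivity matrix that correspond to breeding populations
#'
#' The isotope and parasite likelihoods only see the three groups of known
#' breeding origin; this maps population index (Northern, Central, Southern)
#' to the corresponding row of the 8x4 connectivity matrix.
#' @return Named integer vector of length 3.
#' @export
population_rows <- function() {
  stats::setNames(c(1L, 4L, 7L), population_labels())
}

#' @rdname group_labels
#' @export
lineage_labels <- function() c("SYBOR21", "GRW02", "GRW09", "LINOLI1", "PSEGRI1")

n_groups <- function() 8L
n_areas <- function() 4L
n_pops <- function() 3L
n_lineages <- function() 5L

#' Spatial and seasonal configuration
#'
#' Defaults encode the study design: the Sahara cutoff at 15 degrees N, the
#' Southern-Africa boundary at 15.4 degrees S, rectangular stand-ins for the
#' verbal longitudinal boundaries (Western/Central at 15 degrees E, the Rift
#' Valley at 30 degrees E), the 52 degrees N split between the central and
#' southern European marking regions, and the November--February wintering
#' window.  Boundaries are half-open with the southern/western side
#' inclusive.
#'
#' @param ... Named overrides for any default entry.
#' @return A list of class `mc_config`.
#' @examples
#' cfg <- mc_config(rift_lon = 32)
#' cfg$rift_lon
#' @export
mc_config <- function(...) {
  cfg <- list(
    sahara_lat = 15.0,       # north of this: outside the wintering domain
    southern_lat = -15.4,    # at/south of this: Southern Africa
    west_central_lon = 15.0, # at/west of this: Western Africa
    rift_lon = 30.0,         # at/west of this (and east of the above): Central
    lat_split = 52.0,        # >= 52 N: central European region, else southern
    winter_months = c(11L, 12L, 1L, 2L),
    spring_months = 3:5,
    breeding_months = 6:7,
    autumn_months = 8:10,
    chick_autumn_rule = TRUE # chicks ringed Aug-Oct join the autumn group
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  structure(cfg, class = "mc_config")
}

#' Prior hyperparameters
#'
#' All values the model treats as fixed prior constants: the informative
#' normal prior on the Southern-Africa mean d13C (mean 0.97, sd 0.07 on the
#' standardized scale, derived from independent wintering-ground feather
#' data), the negative-half-normal sd for the d13C offset theta of the
#' pooled WCE region, the standard-normal priors on the d15N means, the
#' Beta(10,4) / Beta(2,4) priors on the correlation auxiliaries rho0 (with
#' rho = 2(rho0 - 0.5)), the positive-half-normal sd 5 prior on the
#' prevalence ratio a, and a weakly informative half-normal sd on the
#' isotope standard deviations (the latter is a package choice; the source
#' model left it unstated).
#'
#' @param ... Named overrides.
#' @return A list of class `mc_priors`.
#' @export
mc_priors <- function(...) {
  pr <- list(
    mu_SC_mean = 0.97, mu_SC_sd = 0.07,
    theta_sd = 1,
    mu_N_sd = 1,
    rho0_S_shape1 = 10, rho0_S_shape2 = 4,
    rho0_WCE_shape1 = 2, rho0_WCE_shape2 = 4,
    sigma_sd = 2,
    a_sd = 5
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(pr))
    if (length(bad)) stop("unknown prior entries: ", paste(bad, collapse = ", "))
    pr[names(ov)] <- ov
  }
  structure(pr, class = "mc_priors")
}

#' Read a JSON configuration file
#'
#' Accepts a JSON object whose top-level keys are any subset of the
#' [mc_config()] and [mc_priors()] entries; unknown keys are rejected.
#'
#' @param path Path to a JSON file.
#' @return A list with elements `config` and `priors`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_keys <- intersect(names(raw), names(mc_config()))
  pri_keys <- intersect(names(raw), names(mc_priors()))
  bad <- setdiff(names(raw), c(cfg_keys, pri_keys))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  list(config = do.call(mc_config, raw[cfg_keys]),
       priors = do.call(mc_priors, raw[pri_keys]))
}
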