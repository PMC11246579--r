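#' Default run parameters
#'
#' The canonical parameter set used when a YAML configuration does not
#' override a value: zone calling at a mean of 1 read per sample, 100 bp
#' merge distance and 100 bp minimum length; duplicate removal,
#' proper-pair/primary-only record filters and a MAPQ 30 floor; the
#' filtering-cascade defaults of [filter_config()]; and 10 genotyped
#' individuals per population for the diversity statistics.
#'
#' @return Named list of defaults (`NULL` = filter disabled).
#' @export
config_defaults <- function() {
  list(min_mean_cov = 1, min_dist = 100L, min_length = 100L,
       drop_duplicates = TRUE, require_proper_pair = TRUE,
       drop_secondary_supplementary = TRUE, min_mapq = 30L,
       min_dp = 5L, min_gq = 15L, min_qual = 30,
       max_f_missing = NULL, max_sample_missing = NULL,
       biallelic_only = TRUE, min_fis = 0.8,
       require_minor_homozygote = TRUE,
       min_per_pop = 10L, scan_quantile = 0.95, seed = 1L)
}

config_aliases <- c(
  BED_MIN_MEAN_COV = "min_mean_cov",
  BED_MIN_DIST = "min_dist",
  BED_MIN_LENGTH = "min_length",
  REMOVE_DUP_MARKDUPLICATES = "drop_duplicates",
  REQUIRE_PROPER_PAIR = "require_proper_pair",
  DROP_SECONDARY_SUPPLEMENTARY = "drop_secondary_supplementary",
  MIN_MAPQ = "min_mapq",
  MIN_DP = "min_dp",
  MIN_GQ = "min_gq",
  MIN_QUAL = "min_qual",
  MAX_F_MISSING = "max_f_missing",
  MAX_SAMPLE_MISSING = "max_sample_missing",
  BIALLELIC_ONLY = "biallelic_only",
  MIN_FIS = "min_fis",
  REQUIRE_MINOR_HOMOZYGOTE = "require_minor_homozygote",
  MIN_PER_POP = "min_per_pop",
  SCAN_QUANTILE = "scan_quantile",
  SEED = "seed")

#' Load a YAML run configuration
#'
#' Reads a YAML parameter file, resolves upper-case capture-workflow-style
#' parameter names (e.g. `BED_MIN_MEAN_COV`, `REMOVE_DUP_MARKDUPLICATES`,
#' `MIN_MAPQ`) to their internal equivalents, rejects unknown keys by
#' name, and fills unset parameters with the package defaults.
#'
#' @param path YAML file path; an empty or absent-key file yields all
#'   defaults.
#' @return Named list of resolved parameters.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- config_defaults()
  out <- defaults
  for (key in names(raw)) {
    internal <- if (key %in% names(config_aliases)) config_aliases[[key]]
                else key
    if (!internal %in% names(defaults))
      stop("unknown configuration key: ", key)
    value <- raw[[key]]
    template <- defaults[[internal]]
    if (!is.null(template) && !is.null(value)) {
      if (is.logical(template) && !is.logical(value))
        stop("parameter ", key, " must be true/false")
      if (is.numeric(template) && !is.numeric(value))
        stop("parameter ", key, " must be numeric")
    }
    out[internal] <- list(value)
  }
  out
}
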