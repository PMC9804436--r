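#' Species registry for US east coast odontocetes
#'
#' Maps species identifiers to names, climatic category (warm-water,
#' cool-water, Arctic/sub-Arctic, or cosmopolitan, following MacLeod's
#' thermal-niche framework), and whether the trailing (equatorward) edge of
#' the species' range falls inside the study region. Among the species well
#' represented in the 1996-2020 US east coast stranding record, only the
#' harbor porpoise, long-finned pilot whale and Atlantic white-sided dolphin
#' have trailing-edge distributions there; no well-represented species has a
#' leading edge in the region.
#'
#' @return tibble with columns `species_id`, `common_name`, `scientific_name`,
#'   `climatic_category`, `trailing_edge`.
#' @export
species_registry <- function() {
  tibble::tribble(
    ~species_id,        ~common_name,                    ~scientific_name,             ~climatic_category, ~trailing_edge,
    "harbor_porpoise",  "Harbor porpoise",               "Phocoena phocoena",          "cool",             TRUE,
    "awsd",             "Atlantic white-sided dolphin",  "Lagenorhynchus acutus",      "cool",             TRUE,
    "lfpw",             "Long-finned pilot whale",       "Globicephala melas",         "cool",             TRUE,
    "bottlenose",       "Common bottlenose dolphin",     "Tursiops truncatus",         "warm",             FALSE,
    "common_dolphin",   "Common dolphin",                "Delphinus delphis",          "warm",             FALSE,
    "striped_dolphin",  "Striped dolphin",               "Stenella coeruleoalba",      "warm",             FALSE,
    "rissos_dolphin",   "Risso's dolphin",               "Grampus griseus",            "warm",             FALSE,
    "pygmy_sperm",      "Pygmy sperm whale",             "Kogia breviceps",            "warm",             FALSE,
    "dwarf_sperm",      "Dwarf sperm whale",             "Kogia sima",                 "warm",             FALSE,
    "sperm_whale",      "Sperm whale",                   "Physeter macrocephalus",     "cosmopolitan",     FALSE,
    "killer_whale",     "Killer whale",                  "Orcinus orca",               "cosmopolitan",     FALSE,
    "beluga",           "Beluga",                        "Delphinapterus leucas",      "arctic",           FALSE,
    "narwhal",          "Narwhal",                       "Monodon monoceros",          "arctic",           FALSE
  )
}

#' Climatic categories recognised by the registry
#' @export
climatic_categories <- function() c("warm", "cool", "arctic", "cosmopolitan")

#' Reference data profiles for the nine well-represented species
#'
#' Observed characteristics of the nine odontocete species averaging at least
#' five stranding events per year in the 1996-2020 US east coast record:
#' mean annual number of stranding events, event-level standard deviation of
#' poleward distance (km), and (where a shift was modelled) the fitted
#' poleward-shift slope with its 95% bootstrap confidence interval
#' (km/year). Trailing-edge species carry a second row for the trailing-edge
#' (annual 5th percentile) statistic. These profiles parameterise the power
#' simulations.
#'
#' @return tibble with columns `species_id`, `statistic` ("mean" or "q05"),
#'   `mean_annual_n`, `sd_km`, `slope`, `ci_low`, `ci_high`.
#' @export
species_profiles <- function() {
  tibble::tribble(
    ~species_id,       ~statistic, ~mean_annual_n, ~sd_km, ~slope, ~ci_low, ~ci_high,
    "awsd",            "mean",     24,             217,    5.2,    2.4,     8.9,
    "awsd",            "q05",      24,             217,    26.6,   12.4,    33.6,
    "lfpw",            "mean",     8,              290,    13.1,   6.0,     21.9,
    "lfpw",            "q05",      8,              290,    40.6,   16.0,    54.1,
    "harbor_porpoise", "mean",     86,             428,    14.0,   11.5,    17.0,
    "harbor_porpoise", "q05",      86,             428,    11.2,   7.4,     18.7,
    "common_dolphin",  "mean",     66,             307,    8.7,    5.1,     12.8,
    "striped_dolphin", "mean",     7,              516,    NA,     NA,      NA,
    "rissos_dolphin",  "mean",     7,              648,    NA,     NA,      NA,
    "bottlenose",      "mean",     331,            569,    9.3,    6.4,     9.6,
    "pygmy_sperm",     "mean",     24,             733,    NA,     NA,      NA,
    "dwarf_sperm",     "mean",     6,              586,    27.8,   9.5,     39.7
  )
}

#' Species eligible for shift analysis
#'
#' A species enters the distributional-shift analysis when it averages at
#' least `min_per_year` stranding events per year over the study period.
#'
#' @param mean_annual_counts named numeric vector (or two-column data frame
#'   `species_id`, `mean_annual_n`) of mean annual stranding counts.
#' @param min_per_year inclusion threshold; default 5 events/year.
#' @return character vector of eligible `species_id`s.
#' @export
eligible_species <- function(mean_annual_counts, min_per_year = 5) {
  if (is.data.frame(mean_annual_counts)) {
    counts <- stats::setNames(mean_annual_counts$mean_annual_n,
                              mean_annual_counts$species_id)
  } else {
    counts <- mean_annual_counts
  }
  stopifnot(!is.null(names(counts)))
  names(counts)[!is.na(counts) & counts >= min_per_year]
}
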