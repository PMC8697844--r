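#' Configuration for the synthetic focal-follow generator
#'
#' Defines the community demography, observation scale, and ground-truth
#' effects used by [generate_community()] and [simulate_observations()].
#' Defaults emulate a community of 38 adults (22 females, 16 males) aged
#' 12--57 years followed over 7 annual networks, with skewed positive
#' dyadic grooming rates and males more gregarious than females.
#'
#' Age effects act on the log of the expected dyadic grooming rate and can
#' be given as a single number (linear slope in scaled age), a length-2
#' vector (linear and quadratic coefficients in scaled age), or a function
#' of age in years. Scaled age maps `age_range` onto \[-1, 1\].
#' Actor-side ("out") effects move grooming given by an individual of that
#' sex; receiver-side ("in") effects move grooming received, and are the
#' lever for attractivity/embeddedness: an uplift on older males raises
#' their in-strength and, because their partners concentrate on them, their
#' eigenvector centrality.
#'
#' @param n_females,n_males number of adult females and males.
#' @param n_years number of consecutive annual networks.
#' @param age_range numeric length-2, minimum and maximum adult age (years).
#' @param sociality_sd SD of per-individual grooming-propensity intercepts
#'   on the log scale (actor side). Zero gives identical individuals.
#' @param attractivity_sd SD of per-individual intercepts on the receiver
#'   side (log scale).
#' @param age_effect_out_female,age_effect_out_male actor-side age effects
#'   per sex (see Details).
#' @param age_effect_in_female,age_effect_in_male receiver-side age effects
#'   per sex.
#' @param cross_sex_age_effect_male log-scale slope in the male member's
#'   scaled age applied only to mixed-sex dyads; negative values make older
#'   males interact less with females, which raises their same-sex
#'   cliquishness in the mixed network without touching same-sex networks.
#' @param baseline_log_rate log grooming minutes per minute of co-party
#'   time for an average same-sex female dyad. The default corresponds to
#'   grooming roughly 0.8% of shared party time.
#' @param sex_pair_effects named log-scale additive offsets for dyad sex
#'   classes `FF`, `FM`, `MF`, `MM` (actor sex first). Defaults order
#'   MM > MF = FM > FF, males being the more gregarious sex.
#' @param mean_co_party_minutes mean dyadic co-party minutes per year.
#' @param co_party_sdlog lognormal log-SD of dyadic co-party minutes.
#' @param prob_zero_exposure probability that a dyad shares no party time
#'   in a year (structural zero; fission--fusion avoidance).
#' @param edge_prob baseline probability that a contacted ordered dyad
#'   grooms at all in a year; the realized probability is shifted on the
#'   logit scale by the same predictors as the rate, so gregarious
#'   individuals also have more partners. Set to 1 for complete networks.
#' @param grooming_dispersion Gamma dispersion of grooming minutes around
#'   their conditional mean (1 = exponential-like, strongly right-skewed).
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_community()], [simulate_observations()],
#'   [simulate_dataset()]
#' @examples
#' cfg <- sim_config(n_females = 6, n_males = 4, n_years = 3, seed = 42)
#' cfg$n_females + cfg$n_males
#' @export
sim_config <- function(n_females = 22,
                       n_males = 16,
                       n_years = 7,
                       age_range = c(12, 57),
                       sociality_sd = 0.45,
                       attractivity_sd = 0.35,
                       age_effect_out_female = c(0, 0),
                       age_effect_out_male = c(0, 0),
                       age_effect_in_female = c(0, 0),
                       age_effect_in_male = c(0, 0),
                       cross_sex_age_effect_male = 0,
                       baseline_log_rate = log(0.008),
                       sex_pair_effects = c(FF = 0, FM = 0.3, MF = 0.3, MM = 0.8),
                       mean_co_party_minutes = 6000,
                       co_party_sdlog = 0.6,
                       prob_zero_exposure = 0.05,
                       edge_prob = 0.45,
                       grooming_dispersion = 1,
                       seed = 1L) {
  cfg <- list(
    n_females = n_females, n_males = n_males, n_years = n_years,
    age_range = age_range,
    sociality_sd = sociality_sd, attractivity_sd = attractivity_sd,
    age_effect_out_female = age_effect_out_female,
    age_effect_out_male = age_effect_out_male,
    age_effect_in_female = age_effect_in_female,
    age_effect_in_male = age_effect_in_male,
    cross_sex_age_effect_male = cross_sex_age_effect_male,
    baseline_log_rate = baseline_log_rate,
    sex_pair_effects = sex_pair_effects,
    mean_co_party_minutes = mean_co_party_minutes,
    co_party_sdlog = co_party_sdlog,
    prob_zero_exposure = prob_zero_exposure,
    edge_prob = edge_prob,
    grooming_dispersion = grooming_dispersion,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  cfg_stop <- function(field, why) {
    stop(sprintf("invalid sim_config: field '%s' %s", field, why), call. = FALSE)
  }
  count_ok <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
    x >= 0 && x == round(x)
  if (!count_ok(cfg$n_females)) cfg_stop("n_females", "must be a nonnegative integer")
  if (!count_ok(cfg$n_males)) cfg_stop("n_males", "must be a nonnegative integer")
  if (cfg$n_females + cfg$n_males < 3)
    cfg_stop("n_females", "+ n_males must be at least 3")
  if (!count_ok(cfg$n_years) || cfg$n_years < 1)
    cfg_stop("n_years", "must be a positive integer")
  if (!is.numeric(cfg$age_range) || length(cfg$age_range) != 2 ||
      any(is.na(cfg$age_range)) || cfg$age_range[1] >= cfg$age_range[2])
    cfg_stop("age_range", "must be c(min, max) with min < max")
  if (cfg$age_range[2] - cfg$age_range[1] + 1 < cfg$n_years)
    cfg_stop("age_range", "must span at least n_years of aging")
  nonneg <- function(field) {
    x <- cfg[[field]]
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0) cfg_stop(field, "must be >= 0")
  }
  pos <- function(field) {
    x <- cfg[[field]]
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x <= 0) cfg_stop(field, "must be > 0")
  }
  nonneg("sociality_sd"); nonneg("attractivity_sd")
  pos("mean_co_party_minutes"); pos("co_party_sdlog"); pos("grooming_dispersion")
  if (cfg$prob_zero_exposure < 0 || cfg$prob_zero_exposure > 1)
    cfg_stop("prob_zero_exposure", "must lie in [0, 1]")
  if (cfg$edge_prob <= 0 || cfg$edge_prob > 1)
    cfg_stop("edge_prob", "must lie in (0, 1]")
  want <- c("FF", "FM", "MF", "MM")
  if (!all(want %in% names(cfg$sex_pair_effects)))
    cfg_stop("sex_pair_effects", "must name all of FF, FM, MF, MM")
  for (field in c("age_effect_out_female", "age_effect_out_male",
                  "age_effect_in_female", "age_effect_in_male")) {
    x <- cfg[[field]]
    if (!(is.function(x) || (is.numeric(x) && length(x) %in% 1:2 && !any(is.na(x)))))
      cfg_stop(field, "must be a slope, c(linear, quadratic), or a function(age)")
  }
  if (!is.numeric(cfg$cross_sex_age_effect_male) ||
      length(cfg$cross_sex_age_effect_male) != 1)
    cfg_stop("cross_sex_age_effect_male", "must be a single number")
  if (length(cfg$seed) != 1 || is.na(cfg$seed))
    cfg_stop("seed", "must be a single integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d F + %d M over %d years, ages %g-%g, seed %d\n",
    x$n_females, x$n_males, x$n_years, x$age_range[1], x$age_range[2], x$seed))
  invisible(x)
}

# Evaluate an age-effect knob at given ages (log scale).
# Numeric coefficients apply to scaled age in [-1, 1].
eval_age_effect <- function(effect, age, age_range) {
  if (is.function(effect)) return(effect(age))
  z <- (age - mean(age_range)) / (diff(age_range) / 2)
  if (length(effect) == 1) effect * z else effect[1] * z + effect[2] * z^2
}
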