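#' Generate a synthetic community roster with ground-truth effects
#'
#' Draws a community of adult females and males followed over consecutive
#' annual observation windows, together with the latent quantities that the
#' grooming generator and downstream recovery experiments need: stable
#' per-individual sociality (actor-side) and attractivity (receiver-side)
#' log-scale intercepts, per-sex age-effect functions, and the rank and
#' sexual-swelling trajectories.
#'
#' Demography follows a mixed-longitudinal design: every individual is
#' present in all years and ages by exactly one year between consecutive
#' annual windows. Dominance rank is a within-sex, within-year percentile in
#' (0, 1]: male latent quality peaks in mid-adulthood (rank rises then falls
#' over the lifespan), female latent quality increases with age (queue-like
#' ascent), both with a stable individual component plus yearly noise.
#' The female proportion of days with maximal sexual swelling declines with
#' age in expectation; males have zero.
#'
#' @param config a [sim_config()].
#' @return A list with elements `roster` (data.frame: `id`, `year`, `sex`,
#'   `age`, `rank`, `time_swollen`) and `effects` (class `true_effects`:
#'   centered `sociality` and `attractivity` intercepts, age-effect
#'   functions evaluated on `age_grid`, and the trajectory functions).
#' @examples
#' com <- generate_community(sim_config(n_females = 5, n_males = 4,
#'                                      n_years = 2, seed = 7))
#' head(com$roster)
#' @export
generate_community <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_f <- config$n_females
  n_m <- config$n_males
  n <- n_f + n_m
  ids <- c(if (n_f > 0) sprintf("F%02d", seq_len(n_f)),
           if (n_m > 0) sprintf("M%02d", seq_len(n_m)))
  sexes <- c(rep("F", n_f), rep("M", n_m))
  amin <- config$age_range[1]
  amax <- config$age_range[2]
  # age in the first year; capped so no one exceeds amax while aging
  start_age <- amin + floor(stats::runif(n) * (amax - amin - config$n_years + 2))

  draw_centered <- function(sd) {
    if (sd == 0) return(stats::setNames(rep(0, n), ids))
    x <- stats::rnorm(n, 0, sd)
    stats::setNames(x - mean(x), ids)
  }
  sociality <- draw_centered(config$sociality_sd)
  attractivity <- draw_centered(config$attractivity_sd)
  rank_quality <- stats::setNames(stats::rnorm(n, 0, 0.5), ids)

  # latent rank trajectories (arbitrary monotone-transform scale)
  rank_peak_age <- amin + 0.35 * (amax - amin)  # males peak in mid-adulthood
  male_rank_shape <- function(age) -((age - rank_peak_age) / (0.35 * (amax - amin)))^2
  female_rank_shape <- function(age) 2 * (age - amin) / (amax - amin)
  swelling_shape <- function(age) 0.45 * stats::plogis((rank_peak_age + 5 - age) / 8)

  roster <- expand.grid(id = ids, year = seq_len(config$n_years),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  roster <- roster[order(roster$year, roster$id), , drop = FALSE]
  rownames(roster) <- NULL
  idx <- match(roster$id, ids)
  roster$sex <- sexes[idx]
  roster$age <- start_age[idx] + roster$year - 1

  latent <- ifelse(roster$sex == "M",
                   male_rank_shape(roster$age), female_rank_shape(roster$age)) +
    rank_quality[idx] + stats::rnorm(nrow(roster), 0, 0.15)
  roster$rank <- stats::ave(latent, roster$sex, roster$year,
                            FUN = function(x) rank(x) / length(x))
  roster$time_swollen <- ifelse(
    roster$sex == "F",
    pmin(1, pmax(0, swelling_shape(roster$age) +
                   stats::rnorm(nrow(roster), 0, 0.05))),
    0)

  age_grid <- seq(amin, amax, length.out = 46)
  effects <- structure(list(
    sociality = sociality,
    attractivity = attractivity,
    age_grid = age_grid,
    age_effects = list(
      out_female = eval_age_effect(config$age_effect_out_female, age_grid, config$age_range),
      out_male = eval_age_effect(config$age_effect_out_male, age_grid, config$age_range),
      in_female = eval_age_effect(config$age_effect_in_female, age_grid, config$age_range),
      in_male = eval_age_effect(config$age_effect_in_male, age_grid, config$age_range)
    ),
    rank_trajectory = list(F = female_rank_shape, M = male_rank_shape),
    swelling_trajectory = swelling_shape
  ), class = "true_effects")

  list(roster = roster, effects = effects)
}

#' Simulate annual dyadic grooming observations
#'
#' Emits one row per ordered dyad per year with the co-party exposure time
#' shared by the dyad and the minutes the actor groomed the receiver.
#' Co-party minutes are lognormal around `mean_co_party_minutes` (identical
#' for the two directions of a dyad), with a configurable probability of
#' structural zeros. Conditional on contact, an ordered dyad grooms at all
#' with a probability shifted on the logit scale by the same log-linear
#' predictor as the rate; grooming minutes are then Gamma with log-mean
#'
#' `baseline + sociality(actor) + attractivity(receiver) +
#'  age_out(sex_actor)(age_actor) + age_in(sex_receiver)(age_receiver) +
#'  sex_pair + cross_sex_male_term`,
#'
#' multiplied by the exposure, and never exceed the exposure.
#'
#' @param roster individual-year attribute records from
#'   [generate_community()].
#' @param effects the matching `true_effects` object.
#' @param config the [sim_config()] used to generate the roster.
#' @return data.frame with columns `year`, `actor_id`, `receiver_id`,
#'   `groom_min`, `co_party_min`.
#' @examples
#' cfg <- sim_config(n_females = 4, n_males = 3, n_years = 1, seed = 3)
#' com <- generate_community(cfg)
#' obs <- simulate_observations(com$roster, com$effects, cfg)
#' stopifnot(all(obs$groom_min <= obs$co_party_min))
#' @export
simulate_observations <- function(roster, effects, config) {
  validate_sim_config(config)
  if (!is.data.frame(roster) || nrow(roster) == 0)
    stop("roster must be a nonempty data.frame", call. = FALSE)
  set.seed(config$seed + 1L)

  out <- vector("list", config$n_years)
  for (y in sort(unique(roster$year))) {
    ry <- roster[roster$year == y, , drop = FALSE]
    n <- nrow(ry)
    if (n < 2) next
    pair <- expand.grid(a = seq_len(n), b = seq_len(n), KEEP.OUT.ATTRS = FALSE)
    pair <- pair[pair$a != pair$b, , drop = FALSE]
    # symmetric exposure: draw once per unordered dyad
    lo <- pmin(pair$a, pair$b); hi <- pmax(pair$a, pair$b)
    key <- (lo - 1) * n + hi
    ukey <- sort(unique(key))
    meanlog <- log(config$mean_co_party_minutes) - config$co_party_sdlog^2 / 2
    uexpo <- stats::rlnorm(length(ukey), meanlog, config$co_party_sdlog) *
      (stats::runif(length(ukey)) >= config$prob_zero_exposure)
    expo <- uexpo[match(key, ukey)]

    sex_a <- ry$sex[pair$a]; sex_b <- ry$sex[pair$b]
    age_a <- ry$age[pair$a]; age_b <- ry$age[pair$b]
    ae <- function(effect, age) eval_age_effect(effect, age, config$age_range)
    mu <- config$baseline_log_rate +
      effects$sociality[ry$id[pair$a]] +
      effects$attractivity[ry$id[pair$b]] +
      ifelse(sex_a == "F", ae(config$age_effect_out_female, age_a),
             ae(config$age_effect_out_male, age_a)) +
      ifelse(sex_b == "F", ae(config$age_effect_in_female, age_b),
             ae(config$age_effect_in_male, age_b)) +
      config$sex_pair_effects[paste0(sex_a, sex_b)]
    if (config$cross_sex_age_effect_male != 0) {
      mixed <- sex_a != sex_b
      male_age <- ifelse(sex_a == "M", age_a, age_b)
      z <- (male_age - mean(config$age_range)) / (diff(config$age_range) / 2)
      mu <- mu + ifelse(mixed, config$cross_sex_age_effect_male * z, 0)
    }

    p_edge <- stats::plogis(stats::qlogis(config$edge_prob) +
                              (mu - config$baseline_log_rate))
    if (config$edge_prob == 1) p_edge[] <- 1
    present <- stats::runif(nrow(pair)) < p_edge
    shape <- 1 / config$grooming_dispersion
    groom <- stats::rgamma(nrow(pair), shape = shape,
                           scale = exp(mu) * expo * config$grooming_dispersion)
    groom <- ifelse(present & expo > 0, pmin(groom, expo), 0)

    out[[y]] <- data.frame(
      year = y,
      actor_id = ry$id[pair$a],
      receiver_id = ry$id[pair$b],
      groom_min = as.numeric(groom),
      co_party_min = as.numeric(expo),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-call synthetic dataset
#'
#' Convenience wrapper running [generate_community()] then
#' [simulate_observations()].
#'
#' @param config a [sim_config()].
#' @return list with `roster`, `effects`, `observations`.
#' @export
simulate_dataset <- function(config) {
  com <- generate_community(config)
  obs <- simulate_observations(com$roster, com$effects, config)
  list(roster = com$roster, effects = com$effects, observations = obs)
}

#' Simulate a longitudinal response with a known intraclass correlation
#'
#' Direct generator for repeatability calibration: a balanced
#' individual-by-year table whose response is the sum of a stable
#' individual effect (variance `icc`) and yearly noise (variance
#' `1 - icc`), with age, sex and rank attributes that carry no signal.
#' With `icc = 0` this is a pure-noise table, the null generator used for
#' permutation-test size checks.
#'
#' @param n_id number of individuals (female:male ratio about 11:8, as in
#'   the default community).
#' @param n_years annual records per individual.
#' @param icc intraclass correlation in \[0, 1\]; total variance is 1.
#' @param age_effect optional linear slope of the response in scaled age
#'   (\[-1, 1\] over the age span), for power experiments.
#' @param seed integer seed.
#' @return data.frame with `id`, `year`, `sex`, `age`, `rank`,
#'   `time_swollen`, `composition` and response `y`.
#' @export
simulate_repeatability_data <- function(n_id = 38, n_years = 7, icc = 0.5,
                                        age_effect = 0, seed = 1L) {
  stopifnot(n_id >= 2, n_years >= 1, icc >= 0, icc <= 1)
  set.seed(as.integer(seed))
  n_f <- round(n_id * 22 / 38)
  ids <- c(sprintf("F%02d", seq_len(n_f)), sprintf("M%02d", seq_len(n_id - n_f)))
  sexes <- rep(c("F", "M"), c(n_f, n_id - n_f))
  start_age <- sample(12:50, n_id, replace = TRUE)
  b <- stats::rnorm(n_id, 0, sqrt(icc))
  d <- expand.grid(id = ids, year = seq_len(n_years),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(d$id, ids)
  d$sex <- sexes[i]
  d$age <- start_age[i] + d$year - 1
  d$rank <- stats::runif(nrow(d))
  d$time_swollen <- ifelse(d$sex == "F", stats::runif(nrow(d), 0, 0.5), 0)
  d$composition <- "mixed"
  z <- (d$age - mean(range(d$age))) / (diff(range(d$age)) / 2)
  d$y <- b[i] + age_effect * z + stats::rnorm(nrow(d), 0, sqrt(1 - icc))
  d
}

#' Write a synthetic dataset to disk
#'
#' Writes the observation table and roster as CSV and the ground-truth
#' effects (intercepts and age-effect grids) as JSON.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    observations = file.path(dir, "observations.csv"),
    roster = file.path(dir, "roster.csv"),
    effects = file.path(dir, "true_effects.json")
  )
  utils::write.csv(dataset$observations, paths["observations"], row.names = FALSE)
  utils::write.csv(dataset$roster, paths["roster"], row.names = FALSE)
  eff <- dataset$effects
  jsonlite::write_json(
    list(sociality = as.list(eff$sociality),
         attractivity = as.list(eff$attractivity),
         age_grid = eff$age_grid,
         age_effects = eff$age_effects),
    paths["effects"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
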