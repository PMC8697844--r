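test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(n_females = 1, n_males = 1), "n_females")
  expect_error(sim_config(n_years = 0), "n_years")
  expect_error(sim_config(mean_co_party_minutes = 0), "mean_co_party_minutes")
  expect_error(sim_config(grooming_dispersion = -1), "grooming_dispersion")
  expect_error(sim_config(age_range = c(30, 20)), "age_range")
  expect_error(sim_config(edge_prob = 0), "edge_prob")
  expect_error(sim_config(prob_zero_exposure = 1.5), "prob_zero_exposure")
})

test_that("the community roster matches the study demography", {
  cfg <- sim_config(n_females = 22, n_males = 16, n_years = 7, seed = 4)
  com <- generate_community(cfg)
  r <- com$roster
  expect_equal(length(unique(r$id)), 38)
  expect_equal(sum(table(unique(r[, c("id", "sex")])$sex) ==
                     c(F = 22, M = 16)), 2)
  expect_equal(nrow(r), 38 * 7)
  expect_true(all(r$age >= 12 & r$age <= 57))
  # ages increase by exactly 1 between consecutive years
  for (id in unique(r$id)) {
    ri <- r[r$id == id, ]
    ri <- ri[order(ri$year), ]
    expect_equal(diff(ri$age), rep(1, 6))
  }
  expect_true(all(r$time_swollen[r$sex == "M"] == 0))
  expect_true(all(r$time_swollen >= 0 & r$time_swollen <= 1))
})

test_that("rank and swelling trajectories have the configured shapes", {
  # average over seeds: female rank rises with age, male rank peaks at
  # mid-adulthood (concave: negative correlation with squared distance
  # from the peak), swelling declines with female age
  cors_f <- cors_m <- cors_ts <- numeric(10)
  for (s in 1:10) {
    r <- generate_community(sim_config(seed = 100 + s))$roster
    f <- r[r$sex == "F", ]
    m <- r[r$sex == "M", ]
    peak <- 12 + 0.35 * (57 - 12)
    cors_f[s] <- cor(f$age, f$rank)
    cors_m[s] <- cor((m$age - peak)^2, m$rank)
    cors_ts[s] <- cor(f$age, f$time_swollen)
  }
  expect_gt(mean(cors_f), 0.3)
  expect_lt(mean(cors_m), -0.3)
  expect_lt(mean(cors_ts), -0.3)
})

test_that("individual intercepts are centered with the requested spread", {
  com0 <- generate_community(sim_config(sociality_sd = 0, seed = 2))
  expect_true(all(com0$effects$sociality == 0))
  sds <- vapply(1:10, function(s) {
    e <- generate_community(sim_config(n_females = 30, n_males = 20,
                                       sociality_sd = 0.5, seed = s))$effects
    expect_equal(mean(e$sociality), 0)
    sd(e$sociality)
  }, 0)
  expect_lt(abs(mean(sds) - 0.5), 0.15)
})

test_that("the generator is deterministic in the seed and sensitive to it", {
  cfg <- sim_config(n_females = 8, n_males = 6, n_years = 2, seed = 31)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$roster, d2$roster)
  expect_identical(d1$observations, d2$observations)
  cfg2 <- sim_config(n_females = 8, n_males = 6, n_years = 2, seed = 32)
  d3 <- simulate_dataset(cfg2)
  expect_false(identical(d1$effects$sociality, d3$effects$sociality))
})

test_that("grooming never exceeds co-party exposure, across seeds", {
  for (s in 1:5) {
    ds <- simulate_dataset(sim_config(n_females = 10, n_males = 8,
                                      n_years = 2, seed = 400 + s))
    expect_true(all(ds$observations$groom_min <= ds$observations$co_party_min))
    expect_true(all(ds$observations$co_party_min >= 0))
  }
})

test_that("zero exposure forces zero grooming", {
  cfg <- sim_config(n_females = 6, n_males = 5, n_years = 1,
                    prob_zero_exposure = 1, seed = 8)
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$observations$co_party_min == 0))
  expect_true(all(ds$observations$groom_min == 0))
})

test_that("with all effects zero the mean dyadic rate matches exp(baseline)", {
  # analytic expectation of the log-linear generator, checked by
  # simulation over >= 10^4 dyad-years with dense contact
  cfg <- sim_config(n_females = 25, n_males = 25, n_years = 5,
                    sociality_sd = 0, attractivity_sd = 0,
                    sex_pair_effects = c(FF = 0, FM = 0, MF = 0, MM = 0),
                    edge_prob = 1, prob_zero_exposure = 0,
                    baseline_log_rate = log(0.004), seed = 77)
  ds <- simulate_dataset(cfg)
  o <- ds$observations
  expect_gte(nrow(o), 1e4)
  rate <- o$groom_min / o$co_party_min
  # truncation at the exposure bound only ever lowers the mean; with a
  # baseline rate of 0.4% it is negligible relative to MC error
  mc_se <- sd(rate) / sqrt(nrow(o))
  expect_lt(abs(mean(rate) - 0.004), 3 * mc_se + 1e-5)
})

test_that("a negative female age effect lowers grooming given by older females", {
  signs <- vapply(1:20, function(s) {
    cfg <- sim_config(age_effect_out_female = -0.8, seed = 500 + s)
    ds <- simulate_dataset(cfg)
    given <- aggregate(groom_min ~ actor_id + year, ds$observations, sum)
    given <- merge(given, ds$roster,
                   by.x = c("actor_id", "year"), by.y = c("id", "year"))
    f <- given[given$sex == "F", ]
    cor(f$age, f$groom_min / 1)
  }, 0)
  expect_true(mean(signs < 0) >= 0.9)
  expect_lt(mean(signs), 0)
})

test_that("repeatability generator hits the requested intraclass correlation", {
  d <- simulate_repeatability_data(n_id = 50, n_years = 8, icc = 0.6, seed = 3)
  v <- tapply(d$y, d$id, mean)
  expect_equal(nrow(d), 400)
  # crude moment check: between-individual variance of means ~ icc + (1-icc)/n_years
  expect_lt(abs(var(v) - (0.6 + 0.4 / 8)), 0.25)
  d0 <- simulate_repeatability_data(icc = 0, seed = 4)
  expect_lt(abs(var(tapply(d0$y, d0$id, mean)) - 1 / 7), 0.15)
})

test_that("datasets round-trip through CSV and validators", {
  ds <- simulate_dataset(sim_config(n_females = 5, n_males = 4, n_years = 2,
                                    seed = 12))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  obs <- read_observations(paths["observations"])
  roster <- read_roster(paths["roster"])
  expect_equal(nrow(obs), nrow(ds$observations))
  expect_equal(roster$id, ds$roster$id)
  eff <- jsonlite::read_json(paths["effects"])
  expect_equal(length(eff$sociality), 9)
})
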