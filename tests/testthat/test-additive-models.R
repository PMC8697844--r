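test_that("family choice follows positivity and skewness diagnostics", {
  set.seed(1)
  sym <- c(0, rnorm(99))
  expect_equal(quietly(choose_family(sym)), "gaussian")
  # lognormal(sigma = 1) has skewness ~ 6.18, far above the threshold
  for (s in 1:3) {
    set.seed(s)
    ln <- rlnorm(1000, 0, 1)
    m2 <- mean((ln - mean(ln))^2); m3 <- mean((ln - mean(ln))^3)
    expect_gt(m3 / m2^1.5, 1)
    expect_equal(quietly(choose_family(ln)), "gamma_log")
  }
  expect_warning(fam <- choose_family(rep(2, 20)), "zero variance")
  expect_equal(fam, "gaussian")
  expect_error(choose_family(1:5), "at least 10")
})

test_that("model_sets emits the full three-set cross in deterministic order", {
  specs <- quietly(model_sets())
  expect_length(specs, 49)
  set2 <- Filter(function(s) s$set == 2, specs)
  expect_length(set2, 7)
  expect_true(all(vapply(set2, function(s) s$subset, "") == "females_only"))
  expect_true(all(vapply(set2, function(s) s$composition, "") == "mixed"))
  expect_true(all(vapply(set2, function(s) s$include_swollen, TRUE)))
  set3_mixed <- Filter(function(s) s$set == 3 && s$composition == "mixed", specs)
  expect_length(set3_mixed, 7)
  f <- deparse1(spec_formula(set3_mixed[[1]]))
  expect_match(f, "sex \\+ s\\(age, by = sex")
  expect_match(f, "s\\(id, bs = \"re\"\\)")
  expect_no_match(f, "rank")
  # deterministic ordering across calls
  lab <- function(s) paste(s$set, s$composition, s$response)
  expect_identical(vapply(specs, lab, ""), vapply(quietly(model_sets()), lab, ""))
  expect_error(model_spec("y", subset = "males_only", include_swollen = TRUE),
               "females-only")
})

test_that("a linear age truth is recovered as a monotone near-linear smooth", {
  ups <- edfs <- NULL
  for (s in 1:5) {
    d <- simulate_repeatability_data(n_id = 30, n_years = 5, icc = 0.2,
                                     age_effect = 1.5, seed = 600 + s)
    spec <- model_spec("y", "mixed", "both_sexes")
    fit <- quietly(fit_model(d, spec))
    for (sex in c("F", "M")) {
      g <- age_smooth_grid(fit, sex)
      ups <- c(ups, all(diff(g$value) > 0))
      edfs <- c(edfs, fit$s_table$edf[fit$s_table$term == age_term(fit, sex)])
    }
  }
  expect_true(mean(ups) >= 0.9)
  expect_lt(mean(edfs), 2)
})

test_that("deviance explained never decreases when a term is added", {
  d <- simulate_repeatability_data(n_id = 25, n_years = 5, icc = 0.3,
                                   seed = 42)
  spec_small <- model_spec("y", "mixed", "both_sexes", family = "gaussian")
  spec_big <- model_spec("y", "mixed", "both_sexes", include_rank = TRUE,
                         family = "gaussian")
  f_small <- quietly(fit_model(d, spec_small))
  f_big <- quietly(fit_model(d, spec_big))
  expect_gte(f_big$dev_expl, f_small$dev_expl - 1e-6)
  expect_true(f_small$dev_expl >= 0 && f_small$dev_expl <= 1)
  expect_true(all(f_big$s_table$statistic >= 0))
})

test_that("with the penalty sent to infinity the age smooth collapses to a line", {
  d <- simulate_repeatability_data(n_id = 25, n_years = 4, icc = 0,
                                   age_effect = 2, seed = 7)
  spec <- model_spec("y", "mixed", "males_only", k = 10, family = "gaussian")
  form <- spec_formula(spec, include_id = FALSE)
  dm <- d[d$sex == "M", ]
  dm$id <- factor(dm$id)
  fit <- mgcv::gam(form, data = dm, sp = 1e9)
  lin <- lm(y ~ age, data = dm)
  expect_lt(sqrt(mean((fitted(fit) - fitted(lin))^2)), 1e-3)
})

test_that("gaussian fits with fixed smoothing equal the penalized least-squares solution", {
  set.seed(5)
  d <- data.frame(age = runif(50, 12, 57))
  d$y <- sin(d$age / 10) + rnorm(50, 0, 0.3)
  lambda <- 2.5
  fit <- mgcv::gam(y ~ s(age, k = 8), data = d, sp = lambda)
  sm <- mgcv::smoothCon(mgcv::s(age, k = 8), data = d, absorb.cons = TRUE,
                        scale.penalty = TRUE)[[1]]
  X <- cbind(1, sm$X)
  S <- matrix(0, ncol(X), ncol(X))
  S[-1, -1] <- sm$S[[1]]
  beta <- solve(crossprod(X) + lambda * S, crossprod(X, d$y))
  expect_lt(max(abs(as.numeric(X %*% beta) - unname(fitted(fit)))), 1e-6)
})

test_that("ide recovers simulated repeatability and vanishes under the null", {
  vr <- ide05 <- ide0 <- numeric(5)
  for (s in 1:5) {
    d5 <- simulate_repeatability_data(icc = 0.5, seed = 700 + s)
    r5 <- quietly(ide(d5, model_spec("y", "mixed", "both_sexes",
                                     family = "gaussian")))
    vr[s] <- r5$variance_ratio
    ide05[s] <- r5$ide
    d0 <- simulate_repeatability_data(icc = 0, seed = 800 + s)
    r0 <- quietly(ide(d0, model_spec("y", "mixed", "both_sexes",
                                     family = "gaussian")))
    ide0[s] <- r0$ide
  }
  expect_lt(abs(mean(vr) - 0.5), 0.15)
  expect_gt(mean(ide05), 0.1)
  expect_lt(abs(mean(ide0)), 0.05)
})

test_that("ide is invariant to relabeling individuals", {
  d <- simulate_repeatability_data(n_id = 20, n_years = 5, icc = 0.4, seed = 9)
  spec <- model_spec("y", "mixed", "both_sexes", family = "gaussian")
  r1 <- quietly(ide(d, spec))
  ids <- unique(d$id)
  relabel <- setNames(sample(sprintf("X%02d", seq_along(ids))), ids)
  d2 <- d
  d2$id <- unname(relabel[d$id])
  r2 <- quietly(ide(d2, spec))
  expect_equal(r1$ide, r2$ide, tolerance = 1e-8)
  expect_equal(r1$variance_ratio, r2$variance_ratio, tolerance = 1e-6)
})

test_that("degenerate designs are flagged or rejected", {
  d1 <- simulate_repeatability_data(n_id = 30, n_years = 1, icc = 0.5, seed = 2)
  r <- quietly(ide(d1, model_spec("y", "mixed", "both_sexes",
                                  family = "gaussian")))
  expect_true(r$flagged)
  expect_match(r$note, "single observation")
  d <- simulate_repeatability_data(seed = 3)  # y has negative values
  expect_error(
    quietly(fit_model(d, model_spec("y", "mixed", "both_sexes",
                                    family = "gamma_log"))),
    "strictly positive")
})
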