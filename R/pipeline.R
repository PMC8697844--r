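#' Pipeline configuration
#'
#' Describes one end-to-end run: either a synthetic-data configuration or
#' paths to observation/roster CSVs (exactly one of the two), the network
#' compositions and responses to analyze, and the permutation settings.
#'
#' @param simulate a [sim_config()], or `NULL` when reading from files.
#' @param observations,roster CSV paths, or `NULL` when simulating.
#' @param compositions network compositions to run.
#' @param responses integration measures to model.
#' @param n_perm permutations per test.
#' @param threshold significance percentile.
#' @param seed integer seed governing permutation draws.
#' @param out_dir output directory for artifacts, or `NULL` to skip
#'   writing.
#' @param engine fitting engine for permutation sweeps (`"bam"` default).
#' @param k basis dimension for univariate smooths.
#' @param min_exposure dyadic exposure threshold for rate inclusion.
#' @param do_mediation run the set-3 models and classify mediation.
#' @param do_repeatability compute ide and its permutation percentile.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, observations = NULL, roster = NULL,
                            compositions = c("mixed", "male_only", "female_only"),
                            responses = METRIC_NAMES,
                            n_perm = 1000, threshold = 95, seed = 1L,
                            out_dir = NULL, engine = "bam", k = 5,
                            min_exposure = 0,
                            do_mediation = TRUE, do_repeatability = TRUE) {
  has_sim <- !is.null(simulate)
  has_files <- !is.null(observations) || !is.null(roster)
  if (has_sim == has_files)
    stop("exactly one of 'simulate' or ('observations' + 'roster') must be given",
         call. = FALSE)
  if (has_files && (is.null(observations) || is.null(roster)))
    stop("both 'observations' and 'roster' paths are required", call. = FALSE)
  if (has_sim && !inherits(simulate, "sim_config"))
    stop("'simulate' must be a sim_config", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  stopifnot(all(compositions %in% c("mixed", "male_only", "female_only")),
            all(responses %in% METRIC_NAMES))
  structure(list(simulate = simulate, observations = observations,
                 roster = roster, compositions = compositions,
                 responses = responses, n_perm = n_perm,
                 threshold = threshold, seed = as.integer(seed),
                 out_dir = out_dir, engine = engine, k = k,
                 min_exposure = min_exposure,
                 do_mediation = do_mediation,
                 do_repeatability = do_repeatability),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulate:` mapping is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate)) raw$simulate <- do.call(sim_config, raw$simulate)
  do.call(pipeline_config, raw)
}

#' Read and validate an observation table
#'
#' @param path CSV with columns `year`, `actor_id`, `receiver_id`,
#'   `groom_min`, `co_party_min`.
#' @return the validated data.frame.
#' @export
read_observations <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(actor_id = "character",
                                        receiver_id = "character"))
  need <- c("year", "actor_id", "receiver_id", "groom_min", "co_party_min")
  missing <- setdiff(need, names(obs))
  if (length(missing) > 0)
    stop(sprintf("observation file lacks column(s): %s (expected header: %s)",
                 paste(missing, collapse = ", "), paste(need, collapse = ", ")),
         call. = FALSE)
  dup <- duplicated(obs[, c("year", "actor_id", "receiver_id")])
  if (any(dup))
    stop(sprintf("duplicate (year, actor, receiver) rows at line(s): %s",
                 paste(which(dup) + 1, collapse = ", ")), call. = FALSE)
  bad <- which(obs$groom_min > obs$co_party_min)
  if (length(bad) > 0)
    stop(sprintf("grooming exceeds co-party minutes at line(s): %s",
                 paste(bad + 1, collapse = ", ")), call. = FALSE)
  neg <- which(obs$groom_min < 0 | obs$co_party_min < 0)
  if (length(neg) > 0)
    stop(sprintf("negative minutes at line(s): %s",
                 paste(neg + 1, collapse = ", ")), call. = FALSE)
  obs
}

#' Read and validate a roster table
#'
#' @param path CSV with columns `id`, `year`, `sex`, `age`, `rank`,
#'   `time_swollen`.
#' @return the validated data.frame.
#' @export
read_roster <- function(path) {
  # sex must be forced to character: a column of all "F" would otherwise
  # be parsed as logical FALSE
  roster <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(id = "character",
                                           sex = "character"))
  need <- c("id", "year", "sex", "age", "rank", "time_swollen")
  missing <- setdiff(need, names(roster))
  if (length(missing) > 0)
    stop(sprintf("roster file lacks column(s): %s (expected header: %s)",
                 paste(missing, collapse = ", "), paste(need, collapse = ", ")),
         call. = FALSE)
  dup <- duplicated(roster[, c("id", "year")])
  if (any(dup))
    stop(sprintf("duplicate (id, year) rows at line(s): %s",
                 paste(which(dup) + 1, collapse = ", ")), call. = FALSE)
  badsex <- which(!roster$sex %in% c("F", "M"))
  if (length(badsex) > 0)
    stop(sprintf("sex must be 'F' or 'M'; offending line(s): %s",
                 paste(badsex + 1, collapse = ", ")), call. = FALSE)
  badts <- which(roster$time_swollen < 0 | roster$time_swollen > 1)
  if (length(badts) > 0)
    stop(sprintf("time_swollen outside [0, 1] at line(s): %s",
                 paste(badts + 1, collapse = ", ")), call. = FALSE)
  roster
}

#' Classify the shape of a fitted age smooth
#'
#' Maps a fitted age trajectory to a direction-of-change token:
#' `increase`, `decrease`, `peak_then_decline` (interior maximum with the
#' terminal value more than `tol_frac` of the fitted range below the
#' peak), `rise_then_plateau` (interior rise, terminal within `tol_frac`
#' of the peak), or `none`. A non-significant term is always `none`,
#' whatever its shape.
#'
#' @param fit a `gamm_fit` with the model kept.
#' @param sex sex whose smooth to classify in by-sex models.
#' @param significant significance of the age term (from the permutation
#'   test).
#' @param tol_frac fraction of the fitted range used for the
#'   peak-vs-plateau call.
#' @return a token string.
#' @export
direction_of_change <- function(fit, sex = NULL, significant = TRUE,
                                tol_frac = 0.1) {
  if (!significant) return("none")
  g <- age_smooth_grid(fit, sex)
  v <- g$value
  rng <- diff(range(v))
  if (rng <= .Machine$double.eps^0.5) return("none")
  tol <- 1e-3 * rng
  d <- diff(v)
  if (all(d >= -tol)) return("increase")
  if (all(d <= tol)) return("decrease")
  peak <- which.max(v)
  n <- length(v)
  if (peak > 1 && peak < n && v[peak] - v[1] > tol) {
    drop_after <- v[peak] - v[n]
    if (drop_after > tol_frac * rng) return("peak_then_decline")
    return("rise_then_plateau")
  }
  "none"
}

cell_subsets <- function(composition) {
  switch(composition,
         mixed = list(list(subset = "both_sexes", sexes = c("F", "M"))),
         male_only = list(list(subset = "males_only", sexes = "M")),
         female_only = list(list(subset = "females_only", sexes = "F")))
}

#' Run the full social-aging analysis
#'
#' End-to-end orchestration: simulate (or read) observations, build the
#' annual network sequence, compute the integration metrics, fit the
#' model sets, run node-permutation tests for age effects and
#' repeatability, classify mediation by rank (and, for females in the
#' mixed-sex network, by time swollen), and assemble the summary table.
#' One permutation sweep per fitted model collects the null statistics of
#' every term (and of `ide`) simultaneously.
#'
#' The summary reports, per (response x sex x composition) cell, the age
#' effect of the covariate-controlled model (its permutation percentile
#' and direction-of-change token), the deviance explained by individual
#' identity with its percentile, and the mediation label.
#'
#' @param config a [pipeline_config()].
#' @return list with `summary` (data.frame), `metrics`, `results` (per-cell
#'   permutation details), `data` (roster/observations), invisibly written
#'   to `out_dir` when configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (!is.null(config$simulate)) {
    dataset <- simulate_dataset(config$simulate)
    obs <- dataset$observations
    roster <- dataset$roster
  } else {
    obs <- read_observations(config$observations)
    roster <- read_roster(config$roster)
    dataset <- list(observations = obs, roster = roster)
  }
  message(sprintf("run_pipeline: %d observation rows, %d roster rows",
                  nrow(obs), nrow(roster)))
  metrics <- compute_metrics(obs, roster, config$compositions,
                             config$min_exposure)
  message(sprintf("run_pipeline: metrics table with %d rows", nrow(metrics)))

  sweep_seed <- config$seed
  next_seed <- function() {
    sweep_seed <<- sweep_seed + 1L
    sweep_seed
  }
  rows <- list()
  results <- list()
  for (comp in config$compositions) {
    for (cell in cell_subsets(comp)) {
      for (response in config$responses) {
        res <- analyze_cell(metrics, response, comp, cell, config, next_seed)
        results[[paste(response, comp, sep = ".")]] <- res
        rows <- c(rows, res$summary_rows)
      }
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    perms <- unlist(lapply(results, function(r) r$perm_results),
                    recursive = FALSE)
    write_perm_results(perms, file.path(config$out_dir, "permutation_results.json"))
    log <- c(sprintf("seed: %d", config$seed),
             sprintf("n_perm: %d", config$n_perm),
             sprintf("threshold: %g", config$threshold),
             sprintf("engine: %s", config$engine),
             sprintf("observation rows: %d", nrow(obs)),
             sprintf("metrics rows: %d", nrow(metrics)),
             sprintf("summary cells: %d", nrow(summary)),
             sprintf("elapsed: %.1f s", as.numeric(Sys.time() - t0, units = "secs")))
    writeLines(log, file.path(config$out_dir, "run_log.txt"))
  }
  list(summary = summary, metrics = metrics, results = results, data = dataset)
}

# Analysis of one (response x composition): fits the controlled (set 1)
# and general (set 3) models, one permutation sweep each, then one summary
# row per sex in the cell.
analyze_cell <- function(metrics, response, comp, cell, config, next_seed) {
  spec1 <- model_spec(response, comp, cell$subset, include_rank = TRUE,
                      k = config$k, set = 1)
  d <- model_frame_for_spec(metrics, spec1)
  spec1 <- resolve_spec_family(spec1, d)
  fit1 <- fit_model(d, spec1, engine = "gam", keep_model = TRUE)

  sexes <- cell$sexes
  age_terms <- vapply(sexes, function(s) age_term(fit1, s), "")
  rank_terms <- vapply(sexes, function(s) {
    if (cell$subset == "both_sexes") sprintf("s(rank):sex%s", s) else "s(rank)"
  }, "")
  want1 <- unique(c(age_terms, rank_terms))

  stat_fun1 <- function(dd) {
    f <- fit_model(dd, spec1, engine = config$engine, keep_model = FALSE)
    if (!f$converged) stop("non-convergent fit")
    st <- stats::setNames(
      vapply(want1, function(tm) term_statistic(f, tm), 0), want1)
    if (config$do_repeatability) {
      r <- ide(dd, spec1, engine = config$engine)
      if (is.na(r$ide)) stop("non-convergent fit")
      st <- c(st, ide = r$ide)
    }
    st
  }
  sw1 <- permute_sweep(d, spec1, stat_fun1, config$n_perm, next_seed(),
                       config$engine)

  perm_of <- function(sw, stat, spec, sex = NULL) {
    new_perm_result(stat, unname(sw$observed[stat]),
                    as.numeric(sw$null[, stat]), config$n_perm,
                    config$threshold, NA_integer_, sw$n_failed,
                    spec_keys(spec, sex))
  }

  sw3 <- NULL; spec3 <- NULL
  if (config$do_mediation) {
    spec3 <- model_spec(response, comp, cell$subset, k = config$k,
                        family = spec1$family, set = 3)
    stat_fun3 <- function(dd) {
      f <- fit_model(dd, spec3, engine = config$engine, keep_model = FALSE)
      if (!f$converged) stop("non-convergent fit")
      stats::setNames(
        vapply(age_terms, function(tm) term_statistic(f, tm), 0), age_terms)
    }
    sw3 <- permute_sweep(d, spec3, stat_fun3, config$n_perm, next_seed(),
                         config$engine)
  }

  # swelling-controlled model for females in the mixed-sex network
  sw2 <- NULL; spec2 <- NULL
  if (config$do_mediation && comp == "mixed" && "F" %in% sexes) {
    spec2 <- model_spec(response, comp, "females_only", include_rank = TRUE,
                        include_swollen = TRUE, k = config$k,
                        k_ti = min(config$k, 4), family = spec1$family, set = 2)
    d2 <- model_frame_for_spec(metrics, spec2)
    want2 <- c("s(age)", "s(time_swollen)")
    stat_fun2 <- function(dd) {
      f <- fit_model(dd, spec2, engine = config$engine, keep_model = FALSE)
      if (!f$converged) stop("non-convergent fit")
      stats::setNames(
        vapply(want2, function(tm) term_statistic(f, tm), 0), want2)
    }
    sw2 <- tryCatch(
      permute_sweep(d2, spec2, stat_fun2, config$n_perm, next_seed(),
                    config$engine),
      error = function(e) {
        warning(sprintf("swelling-controlled model failed for %s: %s",
                        response, conditionMessage(e)))
        NULL
      })
  }

  perm_results <- list()
  summary_rows <- list()
  for (i in seq_along(sexes)) {
    s <- sexes[i]
    p_age1 <- perm_of(sw1, age_terms[i], spec1, s)
    p_rank <- perm_of(sw1, rank_terms[i], spec1, s)
    p_ide <- if (config$do_repeatability) perm_of(sw1, "ide", spec1, s) else NULL
    direction <- direction_of_change(fit1, if (cell$subset == "both_sexes") s,
                                     significant = p_age1$significant)
    mediation <- NA_character_
    if (config$do_mediation && !is.null(sw3)) {
      p_age3 <- perm_of(sw3, age_terms[i], spec3, s)
      verdict <- classify_mediation(p_age3, p_age1, p_rank, "rank")
      mediation <- verdict$label
      if (s == "F" && !is.null(sw2)) {
        p_age2 <- perm_of(sw2, "s(age)", spec2, s)
        p_swell <- perm_of(sw2, "s(time_swollen)", spec2, s)
        verdict2 <- classify_mediation(p_age3, p_age2, p_swell, "swelling")
        # an age effect must survive both controls to count as independent
        if (mediation == "age_effect_independent" &&
            verdict2$label != "age_effect_independent")
          mediation <- verdict2$label
      }
      perm_results <- c(perm_results, list(p_age3))
    }
    ide_obs <- if (!is.null(p_ide)) p_ide$observed_stat else NA_real_
    summary_rows[[i]] <- data.frame(
      response = response, sex = s, composition = comp,
      direction = direction,
      age_percentile = p_age1$percentile,
      age_significant = p_age1$significant,
      ide = ide_obs,
      ide_percentile = if (!is.null(p_ide)) p_ide$percentile else NA_real_,
      ide_significant = if (!is.null(p_ide)) p_ide$significant else NA,
      mediation = mediation,
      stringsAsFactors = FALSE
    )
    perm_results <- c(perm_results, list(p_age1, p_rank),
                      if (!is.null(p_ide)) list(p_ide))
  }
  list(summary_rows = summary_rows, perm_results = perm_results,
       fit = fit1)
}
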