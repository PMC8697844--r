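#' Node-randomized permutation of a metrics table
#'
#' Implements the node-permutation null model for network regressions:
#' within each group (by default year x composition, optionally further
#' stratified by sex), the intact blocks of node attributes (`id`, `sex`,
#' `age`, `rank`, `time_swollen`) are re-assigned to the network positions'
#' metric values by a uniform random permutation. Metric values never move,
#' so network structure is held fixed and only the attribute-to-position
#' mapping is broken. Every column's multiset per group is preserved
#' exactly. Groups with fewer than two rows are left unpermuted with a
#' warning.
#'
#' Sex stratification keeps each sex's attribute blocks on positions of
#' the same sex, so the null preserves sex-specific marginals and targets
#' age/identity structure rather than sex composition; it is the default
#' whenever the model contains sex or by-sex terms.
#'
#' @param data metrics table.
#' @param stratify_by_sex shuffle within sex strata.
#' @param group_cols grouping columns (intersected with the table's
#'   columns).
#' @return the permuted table.
#' @export
node_permute <- function(data, stratify_by_sex = FALSE,
                         group_cols = c("year", "composition")) {
  attr_cols <- intersect(c("id", "sex", "age", "rank", "time_swollen"),
                         names(data))
  gcols <- intersect(c(group_cols, if (stratify_by_sex) "sex"), names(data))
  key <- if (length(gcols)) {
    interaction(data[, gcols, drop = FALSE], drop = TRUE)
  } else factor(rep(1, nrow(data)))
  out <- data
  small <- 0L
  for (g in levels(key)) {
    idx <- which(key == g)
    if (length(idx) < 2) { small <- small + 1L; next }
    out[idx, attr_cols] <- data[idx[sample.int(length(idx))], attr_cols]
  }
  if (small > 0)
    warning(sprintf("%d group(s) with fewer than 2 rows left unpermuted", small))
  out
}

new_perm_result <- function(term, observed, null_stats, n_perm, threshold,
                            seed, n_failed, keys) {
  percentile <- 100 * sum(null_stats < observed) / length(null_stats)
  structure(list(
    term = term,
    observed_stat = observed,
    null_stats = null_stats,
    percentile = percentile,
    significant = percentile >= threshold,
    threshold = threshold,
    n_perm = length(null_stats),
    n_failed = n_failed,
    seed = seed,
    response = keys$response, sex = keys$sex, composition = keys$composition
  ), class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("perm_result: %s | observed %.3f, percentile %.1f over %d permutations -> %s\n",
              x$term, x$observed_stat, x$percentile, x$n_perm,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

# Core permutation sweep shared by permutation_test / repeatability_test /
# run_pipeline: refits the model on node-permuted tables and collects, per
# successful refit, the named statistics produced by `stat_fun(fit_data)`.
# Returns list(observed = named numeric, null = matrix n_perm x stats).
permute_sweep <- function(data, spec, stat_fun, n_perm, seed = NULL,
                          engine = "bam", max_tries = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(max_tries)) max_tries <- 2L * n_perm
  stratify <- spec$subset == "both_sexes"
  observed <- stat_fun(data)
  null <- matrix(NA_real_, nrow = n_perm, ncol = length(observed),
                 dimnames = list(NULL, names(observed)))
  got <- 0L; tries <- 0L
  while (got < n_perm && tries < max_tries) {
    tries <- tries + 1L
    perm <- node_permute(data, stratify_by_sex = stratify)
    st <- tryCatch(stat_fun(perm), error = function(e) NULL)
    if (is.null(st) || any(!is.finite(st))) next
    got <- got + 1L
    null[got, ] <- st
  }
  n_failed <- tries - got
  if (got < n_perm) {
    warning(sprintf("only %d of %d permutation refits succeeded", got, n_perm))
    null <- null[seq_len(got), , drop = FALSE]
  } else if (n_failed > 0.1 * n_perm) {
    warning(sprintf("%d of %d permutation refits failed to converge",
                    n_failed, tries))
  }
  list(observed = observed, null = null, n_failed = n_failed)
}

spec_keys <- function(spec, sex = NULL) {
  list(response = spec$response,
       sex = if (!is.null(sex)) sex else switch(spec$subset,
                                                females_only = "F",
                                                males_only = "M",
                                                both_sexes = NA_character_),
       composition = spec$composition)
}

#' Node-permutation significance test for one smooth term
#'
#' Fits the model on the observed metrics table, then on `n_perm`
#' independently node-permuted tables, and locates the observed term
#' statistic within the null distribution. The reported percentile is the
#' percentage of null statistics that the observed statistic is strictly
#' greater than (ties count against significance); the term is significant
#' when the percentile reaches `threshold`. Non-convergent permutation
#' refits are dropped and logged; `n_perm` counts successes.
#'
#' @param data metrics table.
#' @param spec a [model_spec()].
#' @param term term label (see [age_term()]); defaults to the age smooth
#'   (of `sex` in by-sex models).
#' @param sex sex whose age smooth to test in by-sex models.
#' @param n_perm number of permutations.
#' @param threshold significance percentile (default 95).
#' @param seed integer seed for reproducibility.
#' @param engine fitting engine for observed and null fits (same for
#'   both).
#' @return object of class `perm_result`.
#' @export
permutation_test <- function(data, spec, term = NULL, sex = NULL,
                             n_perm = 1000, threshold = 95, seed = NULL,
                             engine = "bam") {
  d <- model_frame_for_spec(data, spec)
  spec <- resolve_spec_family(spec, d)
  term_resolved <- NULL
  stat_fun <- function(dd) {
    fit <- fit_model(dd, spec, engine = engine, keep_model = FALSE)
    if (!fit$converged) stop("non-convergent fit")
    if (is.null(term_resolved))
      term_resolved <<- if (is.null(term)) age_term(fit, sex) else term
    stats::setNames(term_statistic(fit, term_resolved), term_resolved)
  }
  sw <- permute_sweep(d, spec, stat_fun, n_perm, seed, engine)
  new_perm_result(term_resolved, unname(sw$observed), as.numeric(sw$null),
                  n_perm, threshold, seed, sw$n_failed, spec_keys(spec, sex))
}

resolve_spec_family <- function(spec, d) {
  if (is.null(spec$family))
    spec$family <- resolve_family(spec, d[[spec$response]])
  spec
}

#' Node-permutation test of repeatability
#'
#' As [permutation_test()], with the statistic being the deviance explained
#' by individual identity (`ide`, see [ide()]): the observed `ide` is
#' compared against `ide` values from models refit on node-permuted data,
#' in which the linkage between an individual's identity and its network
#' positions across years is broken.
#'
#' @inheritParams permutation_test
#' @return object of class `perm_result` with `term = "ide"`.
#' @export
repeatability_test <- function(data, spec, n_perm = 1000, threshold = 95,
                               seed = NULL, engine = "bam") {
  d <- model_frame_for_spec(data, spec)
  spec <- resolve_spec_family(spec, d)
  stat_fun <- function(dd) {
    r <- ide(dd, spec, engine = engine)
    if (is.na(r$ide)) stop("non-convergent fit")
    c(ide = r$ide)
  }
  sw <- permute_sweep(d, spec, stat_fun, n_perm, seed, engine)
  new_perm_result("ide", unname(sw$observed), as.numeric(sw$null),
                  n_perm, threshold, seed, sw$n_failed, spec_keys(spec))
}

#' Classify whether a covariate mediates an age effect
#'
#' Compares the significance of the age effect in the general model
#' (age only, set 3) with the controlled model (age plus the covariate,
#' set 1 or 2) and the covariate's own significance:
#' age significant in both -> the age effect is covariate-independent;
#' age significant only in the general model while the covariate is itself
#' significant -> the covariate mediates the apparent age effect;
#' age not significant in the general model -> no age effect; any other
#' pattern -> no age effect, with a note.
#'
#' @param general `perm_result` for the age term in the set-3 model.
#' @param controlled_age `perm_result` for the age term in the
#'   covariate-controlled model.
#' @param covariate `perm_result` for the covariate's own term in the
#'   controlled model.
#' @param covariate_name `"rank"` or `"swelling"`.
#' @return object of class `mediation_verdict` with a `label` among
#'   `age_effect_independent`, `mediated_by_rank`, `mediated_by_swelling`,
#'   `no_age_effect`.
#' @export
classify_mediation <- function(general, controlled_age, covariate,
                               covariate_name = c("rank", "swelling")) {
  covariate_name <- match.arg(covariate_name)
  keys <- function(x) list(x$response, x$sex, x$composition)
  if (!identical(keys(general), keys(controlled_age)) ||
      !identical(general$response, covariate$response))
    stop("mediation inputs refer to different response/sex/composition cells",
         call. = FALSE)
  note <- ""
  label <- if (general$significant && controlled_age$significant) {
    "age_effect_independent"
  } else if (general$significant && covariate$significant) {
    paste0("mediated_by_", covariate_name)
  } else if (!general$significant) {
    "no_age_effect"
  } else {
    note <- "age effect lost under control but covariate itself not significant"
    "no_age_effect"
  }
  structure(list(response = general$response, sex = general$sex,
                 composition = general$composition, label = label,
                 note = note),
            class = "mediation_verdict")
}

#' @export
print.mediation_verdict <- function(x, ...) {
  cat(sprintf("mediation: %s / %s / %s -> %s%s\n", x$response, x$sex,
              x$composition, x$label,
              if (nzchar(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

#' Serialize permutation results to JSON
#'
#' @param results a `perm_result` or list of them.
#' @param path output file.
#' @param include_null include the full null distributions.
#' @return invisibly, `path`.
#' @export
write_perm_results <- function(results, path, include_null = FALSE) {
  if (inherits(results, "perm_result")) results <- list(results)
  payload <- lapply(results, function(r) {
    out <- unclass(r)
    if (!include_null) out$null_stats <- NULL
    out
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
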