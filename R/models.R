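#' Choose the response family from model diagnostics
#'
#' Strictly positive, strongly right-skewed responses get a Gamma error
#' distribution with a log link; anything else (including responses with
#' zeros, for which a Gamma likelihood is inadmissible) gets Gaussian.
#' Skewness is the usual moment estimator `m3 / m2^(3/2)`.
#'
#' @param values response sample (missing values dropped).
#' @param skew_threshold skewness above which Gamma-log is preferred.
#' @return `"gamma_log"` or `"gaussian"`.
#' @export
choose_family <- function(values, skew_threshold = 1) {
  v <- values[!is.na(values)]
  if (length(v) < 10)
    stop("choose_family needs at least 10 nonmissing values", call. = FALSE)
  if (stats::sd(v) == 0) {
    warning("response has zero variance; defaulting to gaussian")
    return("gaussian")
  }
  m <- mean(v)
  skew <- mean((v - m)^3) / mean((v - m)^2)^1.5
  fam <- if (all(v > 0) && skew > skew_threshold) "gamma_log" else "gaussian"
  message(sprintf("choose_family: skewness %.2f, all positive: %s -> %s",
                  skew, all(v > 0), fam))
  fam
}

#' Declare one additive mixed model
#'
#' A declarative description of a penalized-spline additive mixed model of
#' one integration measure. All models carry individual identity as a
#' ridge-penalized random intercept, `s(id, bs = "re")`. Models over both
#' sexes use sex-specific smooths (`by = sex`) plus a linear sex term;
#' single-sex models use plain smooths. The swelling terms (marginal smooth
#' plus a tensor-product interaction with age, `ti(age, time_swollen)`) are
#' admissible only in females-only models.
#'
#' @param response metric name (a column of the metrics table).
#' @param composition network composition the metric came from.
#' @param subset `"both_sexes"`, `"females_only"` or `"males_only"`.
#' @param include_rank include the dominance-rank smooth.
#' @param include_swollen include the time-swollen smooth and its `ti`
#'   interaction with age (females only).
#' @param k basis dimension of univariate smooths.
#' @param k_ti per-margin basis dimension of the tensor interaction.
#' @param family `"gaussian"`, `"gamma_log"`, or `NULL` to choose from the
#'   data via [choose_family()].
#' @param set optional model-set label (1, 2 or 3).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(response,
                       composition = "mixed",
                       subset = c("both_sexes", "females_only", "males_only"),
                       include_rank = FALSE,
                       include_swollen = FALSE,
                       k = 5, k_ti = 5,
                       family = NULL,
                       set = NA_integer_) {
  subset <- match.arg(subset)
  if (include_swollen && subset != "females_only")
    stop("time-swollen terms are admissible only in females-only models",
         call. = FALSE)
  if (!is.null(family) && !family %in% c("gaussian", "gamma_log"))
    stop("family must be NULL, 'gaussian' or 'gamma_log'", call. = FALSE)
  structure(list(response = response, composition = composition,
                 subset = subset, include_rank = include_rank,
                 include_swollen = include_swollen, k = k, k_ti = k_ti,
                 family = family, set = set),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec [set %s]: %s ~ %s | %s, %s\n", x$set, x$response,
              deparse1(spec_formula(x)[[3]]), x$composition, x$subset))
  invisible(x)
}

#' Model formula of a spec
#'
#' @param spec a [model_spec()].
#' @param include_id keep the individual random intercept (dropped by
#'   [ide()] for the reduced fit).
#' @return a formula.
#' @export
spec_formula <- function(spec, include_id = TRUE) {
  k <- spec$k
  terms <- if (spec$subset == "both_sexes") {
    c("sex",
      sprintf("s(age, by = sex, k = %d)", k),
      if (spec$include_rank) sprintf("s(rank, by = sex, k = %d)", k))
  } else {
    c(sprintf("s(age, k = %d)", k),
      if (spec$include_rank) sprintf("s(rank, k = %d)", k),
      if (spec$include_swollen)
        c(sprintf("s(time_swollen, k = %d)", k),
          sprintf("ti(age, time_swollen, k = c(%d, %d))", spec$k_ti, spec$k_ti)))
  }
  if (include_id) terms <- c(terms, "s(id, bs = 're')")
  stats::as.formula(paste(spec$response, "~", paste(terms, collapse = " + ")),
                    env = globalenv())
}

#' The three model sets of the social-aging analysis
#'
#' Emits the full cross of responses, compositions and model sets:
#' set 1 (rank-independent age effects) over mixed- and same-sex networks,
#' set 2 (time-swollen-independent age effects; females in the mixed-sex
#' network only), and set 3 (general age effects) over mixed- and same-sex
#' networks. Ordering is deterministic: set, then composition, then
#' response.
#'
#' @param responses metric names to model.
#' @param k,k_ti basis dimensions.
#' @return list of [model_spec()] objects.
#' @export
model_sets <- function(responses = METRIC_NAMES, k = 5, k_ti = 5) {
  specs <- list()
  add <- function(...) specs[[length(specs) + 1]] <<- model_spec(..., k = k, k_ti = k_ti)
  for (r in responses) add(r, "mixed", "both_sexes", include_rank = TRUE, set = 1)
  for (r in responses) add(r, "male_only", "males_only", include_rank = TRUE, set = 1)
  for (r in responses) add(r, "female_only", "females_only", include_rank = TRUE, set = 1)
  for (r in responses) add(r, "mixed", "females_only", include_rank = TRUE,
                           include_swollen = TRUE, set = 2)
  for (r in responses) add(r, "mixed", "both_sexes", set = 3)
  for (r in responses) add(r, "male_only", "males_only", set = 3)
  for (r in responses) add(r, "female_only", "females_only", set = 3)
  message(sprintf("model_sets: %d specs over %d responses", length(specs),
                  length(responses)))
  specs
}

spec_variables <- function(spec) {
  c(spec$response, "age", "id",
    if (spec$subset == "both_sexes") "sex",
    if (spec$include_rank) "rank",
    if (spec$include_swollen) "time_swollen")
}

# Subset and type the metrics table for one spec; drops rows with missing
# response or predictors (count reported by fit_model).
model_frame_for_spec <- function(data, spec) {
  d <- data
  if (!is.null(d$composition) && spec$composition %in% d$composition)
    d <- d[d$composition == spec$composition, , drop = FALSE]
  if (spec$subset == "females_only") d <- d[d$sex == "F", , drop = FALSE]
  if (spec$subset == "males_only") d <- d[d$sex == "M", , drop = FALSE]
  vars <- spec_variables(spec)
  missing_vars <- setdiff(vars, names(d))
  if (length(missing_vars) > 0)
    stop(sprintf("metrics table lacks column(s): %s",
                 paste(missing_vars, collapse = ", ")), call. = FALSE)
  keep <- stats::complete.cases(d[, vars, drop = FALSE])
  d <- d[keep, , drop = FALSE]
  d$id <- droplevels(factor(d$id))
  if ("sex" %in% names(d)) d$sex <- factor(d$sex, levels = c("F", "M"))
  attr(d, "n_dropped") <- sum(!keep)
  d
}

resolve_family <- function(spec, y) {
  fam <- spec$family
  if (is.null(fam))
    fam <- suppressMessages(choose_family(y))
  if (fam == "gamma_log" && any(y <= 0, na.rm = TRUE))
    stop("gamma_log family requires a strictly positive response", call. = FALSE)
  fam
}

#' Fit one additive mixed model
#'
#' Fits the penalized-spline additive mixed model described by `spec` with
#' smoothing parameters estimated by restricted maximum likelihood, and
#' extracts the statistics the permutation framework consumes: the
#' Wood-type approximate F statistic and effective degrees of freedom of
#' every smooth term, and the proportion of deviance explained.
#'
#' @param data metrics table (or any table with the spec's variables).
#' @param spec a [model_spec()].
#' @param engine `"gam"` (exact REML; default) or `"bam"` (fast fREML with
#'   discretized covariates, used for permutation sweeps).
#' @param keep_model keep the fitted mgcv object (needed for
#'   [age_smooth_grid()] and variance components).
#' @return object of class `gamm_fit`: `spec`, `family`, `s_table`
#'   (data.frame: term, edf, ref_df, statistic), `dev_expl`, `n_obs`,
#'   `n_dropped`, `converged`, and the mgcv `model` if kept.
#' @export
fit_model <- function(data, spec, engine = c("gam", "bam"), keep_model = TRUE) {
  engine <- match.arg(engine)
  d <- model_frame_for_spec(data, spec)
  if (nrow(d) == 0) stop("no usable rows for this model spec", call. = FALSE)
  fam_name <- resolve_family(spec, d[[spec$response]])
  if (stats::sd(d[[spec$response]]) == 0) {
    warning("response has zero variance; returning a degenerate fit")
    return(degenerate_fit(spec, fam_name, engine, nrow(d), attr(d, "n_dropped")))
  }
  fam <- if (fam_name == "gamma_log") stats::Gamma(link = "log") else stats::gaussian()
  form <- spec_formula(spec)
  fit <- if (engine == "bam") {
    mgcv::bam(form, data = d, family = fam, method = "fREML", discrete = TRUE)
  } else {
    mgcv::gam(form, data = d, family = fam, method = "REML")
  }
  res <- summarize_gamm(fit, spec, fam_name, engine,
                        n_dropped = attr(d, "n_dropped"))
  if (keep_model) res$model <- fit
  res
}

# Smooth-term labels as mgcv's summary names them.
spec_term_labels <- function(spec) {
  if (spec$subset == "both_sexes") {
    c("s(age):sexF", "s(age):sexM",
      if (spec$include_rank) c("s(rank):sexF", "s(rank):sexM"),
      "s(id)")
  } else {
    c("s(age)",
      if (spec$include_rank) "s(rank)",
      if (spec$include_swollen) c("s(time_swollen)", "ti(age,time_swollen)"),
      "s(id)")
  }
}

# Zero-variance responses carry no information about any term; every
# statistic is 0 and no deviance is explained.
degenerate_fit <- function(spec, fam_name, engine, n_obs, n_dropped) {
  terms <- spec_term_labels(spec)
  structure(list(
    spec = spec, family = fam_name, engine = engine,
    s_table = data.frame(term = terms, edf = 0, ref_df = 0, statistic = 0,
                         stringsAsFactors = FALSE),
    dev_expl = 0, n_obs = as.integer(n_obs),
    n_dropped = as.integer(n_dropped),
    converged = TRUE, scale = 0, sp = NULL
  ), class = "gamm_fit")
}

summarize_gamm <- function(fit, spec, fam_name, engine, n_dropped = 0) {
  sm <- summary(fit)
  st <- sm$s.table
  stat_col <- intersect(c("F", "Chi.sq"), colnames(st))[1]
  stat <- unname(st[, stat_col])
  stat[!is.finite(stat)] <- 0  # degenerate (zero-variance) responses
  s_table <- data.frame(
    term = rownames(st),
    edf = unname(st[, "edf"]),
    ref_df = unname(st[, "Ref.df"]),
    statistic = stat,
    stringsAsFactors = FALSE
  )
  structure(list(
    spec = spec, family = fam_name, engine = engine,
    s_table = s_table,
    dev_expl = as.numeric(sm$dev.expl),
    n_obs = as.integer(sm$n),
    n_dropped = as.integer(n_dropped),
    converged = isTRUE(fit$converged),
    scale = fit$sig2,
    sp = fit$sp
  ), class = "gamm_fit")
}

#' @export
print.gamm_fit <- function(x, ...) {
  cat(sprintf("gamm_fit (%s, %s): %s, n = %d, deviance explained = %.3f%s\n",
              x$engine, x$family, x$spec$response, x$n_obs, x$dev_expl,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$s_table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Name of the age smooth for one sex
#'
#' @param fit a `gamm_fit`.
#' @param sex `"F"` or `"M"`; ignored for single-sex models.
#' @return the term label, e.g. `"s(age)"` or `"s(age):sexM"`.
#' @export
age_term <- function(fit, sex = NULL) {
  terms <- fit$s_table$term
  if ("s(age)" %in% terms) return("s(age)")
  if (is.null(sex))
    stop("by-sex model: a sex must be named to select the age term", call. = FALSE)
  tm <- sprintf("s(age):sex%s", sex)
  if (!tm %in% terms) stop(sprintf("no term '%s' in fit", tm), call. = FALSE)
  tm
}

#' Extract one term's statistic from a fit
#'
#' @param fit a `gamm_fit`.
#' @param term term label as in `fit$s_table$term`.
#' @return the approximate F (or chi-square) statistic.
#' @export
term_statistic <- function(fit, term) {
  i <- match(term, fit$s_table$term)
  if (is.na(i)) stop(sprintf("no term '%s' in fit", term), call. = FALSE)
  fit$s_table$statistic[i]
}

#' Fitted age smooth on a grid
#'
#' Evaluates the (link-scale, centered) age smooth of a fitted model on an
#' even grid over the observed age range, for sign and shape
#' classification and for plotting.
#'
#' @param fit a `gamm_fit` with the model kept.
#' @param sex sex whose smooth to evaluate in by-sex models.
#' @param length.out grid size.
#' @return data.frame `age`, `value`.
#' @export
age_smooth_grid <- function(fit, sex = NULL, length.out = 50) {
  if (is.null(fit$model))
    stop("fit was created with keep_model = FALSE", call. = FALSE)
  term <- age_term(fit, sex)
  mf <- fit$model$model
  ages <- if (!is.null(sex) && "sex" %in% names(mf)) {
    mf$age[mf$sex == sex]
  } else mf$age
  grid <- seq(min(ages), max(ages), length.out = length.out)
  nd <- data.frame(age = grid)
  if ("sex" %in% names(mf))
    nd$sex <- factor(if (is.null(sex)) levels(mf$sex)[1] else sex,
                     levels = levels(mf$sex))
  if ("rank" %in% names(mf)) nd$rank <- stats::median(mf$rank)
  if ("time_swollen" %in% names(mf)) nd$time_swollen <- stats::median(mf$time_swollen)
  nd$id <- factor(levels(mf$id)[1], levels = levels(mf$id))
  tm <- stats::predict(fit$model, newdata = nd, type = "terms")
  col <- match(term, colnames(tm))
  if (is.na(col)) stop(sprintf("term '%s' not found in prediction", term), call. = FALSE)
  data.frame(age = grid, value = as.numeric(tm[, col]))
}

#' Repeatability: deviance explained by individual identity
#'
#' Quantifies stable inter-individual differences as the drop in deviance
#' explained when the individual random intercept is removed from the
#' model, both fits run on identical rows (the headline `ide`), together
#' with the variance-components ratio `sigma2_id / (sigma2_id +
#' sigma2_resid)` from the full fit. For Gamma-log models the residual
#' variance is taken on the link scale (`trigamma(1/dispersion)`, the
#' variance of the log of a Gamma variate).
#'
#' The result is flagged when either fit fails to converge (then `ide` is
#' `NA`) or when individuals are observed only once, in which case the
#' identity and residual components are confounded and `ide` is
#' near-unidentifiable.
#'
#' @param data metrics table.
#' @param spec a [model_spec()]; must include the ID random intercept
#'   (all specs built by this package do).
#' @param engine fitting engine, as in [fit_model()].
#' @return object of class `repeatability`: `ide`, `variance_ratio`,
#'   `dev_expl_full`, `dev_expl_noid`, `flagged`, `note`.
#' @export
ide <- function(data, spec, engine = c("gam", "bam")) {
  engine <- match.arg(engine)
  d <- model_frame_for_spec(data, spec)
  if (nrow(d) == 0) stop("no usable rows for this model spec", call. = FALSE)
  fam_name <- resolve_family(spec, d[[spec$response]])
  spec_res <- spec
  spec_res$family <- fam_name
  fam <- if (fam_name == "gamma_log") stats::Gamma(link = "log") else stats::gaussian()
  fit_one <- function(include_id) {
    form <- spec_formula(spec_res, include_id = include_id)
    if (engine == "bam") {
      mgcv::bam(form, data = d, family = fam, method = "fREML", discrete = TRUE)
    } else {
      mgcv::gam(form, data = d, family = fam, method = "REML")
    }
  }
  full <- fit_one(TRUE)
  noid <- fit_one(FALSE)
  dev_full <- as.numeric(summary(full)$dev.expl)
  dev_noid <- as.numeric(summary(noid)$dev.expl)
  conv <- isTRUE(full$converged) && isTRUE(noid$converged)
  singleton <- max(table(d$id)) == 1
  vr <- tryCatch({
    invisible(utils::capture.output(vc <- mgcv::gam.vcomp(full, rescale = TRUE)))
    if (is.matrix(vc)) {
      sd_id <- vc[grep("s\\(id\\)", rownames(vc))[1], "std.dev"]
    } else {
      sd_id <- vc[grep("s\\(id\\)", names(vc))[1]]
    }
    v_id <- sd_id^2
    v_res <- if (fam_name == "gamma_log") trigamma(1 / full$sig2) else full$sig2
    as.numeric(v_id / (v_id + v_res))
  }, error = function(e) NA_real_)
  note <- if (!conv) "non-convergent fit; ide unavailable"
          else if (singleton) "single observation per individual; ide near-unidentifiable"
          else ""
  structure(list(
    ide = if (conv) dev_full - dev_noid else NA_real_,
    variance_ratio = vr,
    dev_expl_full = dev_full,
    dev_expl_noid = dev_noid,
    family = fam_name,
    flagged = !conv || singleton,
    note = note
  ), class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("repeatability: ide = %.3f, variance ratio = %.3f%s\n",
              x$ide, x$variance_ratio,
              if (x$flagged) paste0(" [flagged: ", x$note, "]") else ""))
  invisible(x)
}
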