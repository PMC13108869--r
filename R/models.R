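# Binomial mixed-effects feeding classifier: random-intercept logistic
# GLMM (feeding = 1, non-feeding travel = 0), AIC-based candidate-set
# comparison, and population-level prediction.

#' Specify a feeding classifier model
#'
#' @param fixed character vector of fixed-effect column names (empty for
#'   the null, intercept-only model).
#' @param random_intercept grouping column for the random intercept
#'   (default `deployment_id`).
#' @param name optional model label.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(fixed = character(0),
                       random_intercept = "deployment_id",
                       name = NULL) {
  if (is.null(name))
    name <- if (length(fixed) == 0) "null" else paste(fixed, collapse = "+")
  structure(list(fixed = fixed, random_intercept = random_intercept,
                 name = name), class = "model_spec")
}

#' Candidate model set for the feeding classifier
#'
#' The four fitted candidates compared against the null
#' (intercept + random intercept) model: bottom speed alone; bottom fluke
#' rate alone; speed + peak jerk + pitch + roll + linear time of day; and
#' the full model with the speed change and the circular time-of-day
#' encoding.
#'
#' @return named list of [model_spec()] objects (including the null).
#' @export
candidate_model_specs <- function() {
  list(
    null = model_spec(name = "null"),
    m1 = model_spec("bottom_mean_speed", name = "m1_speed"),
    m2 = model_spec("bottom_fluke_rate", name = "m2_fluke_rate"),
    m3 = model_spec(c("bottom_mean_speed", "bottom_peak_jerk",
                      "bottom_mean_pitch", "bottom_mean_roll", "tod_hour"),
                    name = "m3_linear_tod"),
    m4 = model_spec(c("bottom_mean_speed", "bottom_peak_jerk",
                      "bottom_speed_change", "bottom_mean_roll",
                      "bottom_mean_pitch", "tod"),
                    name = "m4_circular_tod"))
}

# Feeding = 1, Travel (non-feeding) = 0; PotentialForaging and NoVideo rows
# are excluded from fitting.
feeding_response <- function(features) {
  if (!is.null(features$feeding)) {
    keep <- !is.na(features$feeding)
    features <- features[keep, , drop = FALSE]
    features$feeding <- as.integer(features$feeding)
    return(features)
  }
  if (is.null(features$label))
    stop("features need a `label` or `feeding` column", call. = FALSE)
  keep <- features$label %in% c("Feeding", "Travel")
  features <- features[keep, , drop = FALSE]
  features$feeding <- as.integer(features$label == "Feeding")
  features
}

#' Fit the binomial mixed-effects feeding classifier
#'
#' Maximum-likelihood (Laplace) fit of a logistic GLMM with the spec's
#' fixed effects and a random intercept per deployment. The response is
#' feeding (1) vs non-feeding travel (0); rows labelled
#' `PotentialForaging` or `NoVideo` are excluded, as are rows with any
#' missing fixed effect. Coefficients are reported on the input scale.
#'
#' @param features feature table from [dive_features()] (or any data.frame
#'   with a `label`/`feeding` column, the fixed-effect columns and the
#'   grouping column).
#' @param spec a [model_spec()].
#' @return object of class `feeding_fit`: `coefficients` (matrix with
#'   estimate, SE, z, p), `log_likelihood`, `aic`, `n_obs`, `n_groups`,
#'   `ranef_sd`, `converged`, `separation` flag, `spec`, `model`.
#' @export
fit_feeding_glmm <- function(features, spec = model_spec()) {
  d <- feeding_response(features)
  cols <- c("feeding", spec$fixed, spec$random_intercept)
  miss <- setdiff(cols, names(d))
  if (length(miss) > 0)
    stop("features missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- d[stats::complete.cases(d[, cols, drop = FALSE]), , drop = FALSE]
  if (length(unique(d$feeding)) < 2)
    stop("response is all ", unique(d$feeding),
         ": cannot fit a classifier (complete separation)", call. = FALSE)
  if (length(unique(d[[spec$random_intercept]])) < 2)
    stop("need at least 2 groups for the random intercept", call. = FALSE)

  rhs <- paste(c(if (length(spec$fixed) > 0) spec$fixed else "1",
                 sprintf("(1 | %s)", spec$random_intercept)),
               collapse = " + ")
  form <- stats::as.formula(paste("feeding ~", rhs))

  warns <- character(0)
  run_glmer <- function(nAGQ) withCallingHandlers(
    lme4::glmer(form, data = d, family = stats::binomial("logit"),
                nAGQ = nAGQ,
                control = lme4::glmerControl(
                  optimizer = "bobyqa",
                  check.conv.singular = lme4::.makeCC(action = "ignore",
                                                      tol = 1e-4),
                  optCtrl = list(maxfun = 5e4))),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  # Laplace first; fall back to the PIRLS-only fit when near-separable
  # data break the PWRSS iterations
  fit <- tryCatch(run_glmer(1L), error = function(e) {
    warns <<- c(warns, conditionMessage(e))
    run_glmer(0L)
  })

  cf <- withCallingHandlers(stats::coef(summary(fit)),
                            warning = function(w) {
                              warns <<- c(warns, conditionMessage(w))
                              invokeRestart("muffleWarning")
                            })
  eta <- stats::predict(fit, type = "link")
  separation <- max(abs(cf[, "Estimate"])) > 50 || max(abs(eta)) > 30
  if (separation)
    warning("possible complete separation: coefficients are unstable",
            call. = FALSE)
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  structure(list(
    coefficients = cf,
    log_likelihood = ll,
    aic = 2 * k - 2 * ll,
    df = k,
    n_obs = nrow(d),
    n_groups = length(unique(d[[spec$random_intercept]])),
    ranef_sd = sqrt(unlist(lme4::VarCorr(fit))[[1]]),
    converged = length(fit@optinfo$conv$lme4$messages) == 0,
    separation = separation,
    warnings = warns,
    spec = spec,
    model = fit), class = "feeding_fit")
}

#' @export
print.feeding_fit <- function(x, ...) {
  cat(sprintf("Feeding GLMM '%s': n = %d dives, %d deployments\n",
              x$spec$name, x$n_obs, x$n_groups))
  cat(sprintf("  logLik %.1f, AIC %.1f, random-intercept SD %.2f\n",
              x$log_likelihood, x$aic, x$ranef_sd))
  stats::printCoefmat(x$coefficients, digits = 4)
  invisible(x)
}

#' Compare candidate feeding models by AIC
#'
#' Fits every spec on the common observation set (rows with any missing
#' value in the union of all fixed effects are dropped before any fit, so
#' AICs are comparable) and tabulates AIC, log-likelihood and the AIC drop
#' relative to the null (intercept + random intercept) model
#' (`dAIC = AIC_null - AIC_model`; larger is better). The winner is the
#' minimum-AIC model.
#'
#' @param features feature table.
#' @param specs list of [model_spec()]s; a null model is prepended if none
#'   of the specs is intercept-only.
#' @return data.frame of class `model_comparison` with attributes
#'   `winner` (spec name) and `fits` (named list of `feeding_fit`s).
#' @export
compare_models <- function(features, specs = candidate_model_specs()) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  if (!any(vapply(specs, function(s) length(s$fixed) == 0, logical(1))))
    specs <- c(list(null = model_spec(name = "null")), specs)
  names(specs) <- vapply(specs, `[[`, character(1), "name")

  d <- feeding_response(features)
  all_fixed <- unique(unlist(lapply(specs, `[[`, "fixed")))
  group <- unique(vapply(specs, `[[`, character(1), "random_intercept"))
  cols <- c("feeding", all_fixed, group)
  d <- d[stats::complete.cases(d[, cols, drop = FALSE]), , drop = FALSE]

  fits <- lapply(specs, function(s) fit_feeding_glmm(d, s))
  ns <- vapply(fits, `[[`, numeric(1), "n_obs")
  if (length(unique(ns)) != 1)
    stop("internal error: observation counts differ across fits",
         call. = FALSE)
  null_aic <- fits[["null"]]$aic
  tab <- data.frame(
    model = names(fits),
    fixed = vapply(specs, function(s)
      if (length(s$fixed) == 0) "-" else paste(s$fixed, collapse = " + "),
      character(1)),
    AIC = vapply(fits, `[[`, numeric(1), "aic"),
    logLik = vapply(fits, `[[`, numeric(1), "log_likelihood"))
  tab$dAIC <- null_aic - tab$AIC
  rownames(tab) <- NULL
  attr(tab, "winner") <- tab$model[which.min(tab$AIC)]
  attr(tab, "fits") <- fits
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' Predict feeding probability
#'
#' Inverse-logit of the linear predictor. Rows from deployments present in
#' the fit use their estimated random intercept; new deployments (or
#' `population = TRUE`) use the population-level (zero) random effect.
#' Rows with a missing fixed effect yield `NA`.
#'
#' @param fit a `feeding_fit`.
#' @param features new data with the fixed-effect columns.
#' @param population force population-level prediction.
#' @return numeric vector of probabilities.
#' @export
predict_feeding <- function(fit, features, population = FALSE) {
  stopifnot(inherits(fit, "feeding_fit"))
  needed <- fit$spec$fixed
  ok <- if (length(needed) > 0)
    stats::complete.cases(features[, needed, drop = FALSE])
  else rep(TRUE, nrow(features))
  out <- rep(NA_real_, nrow(features))
  if (!any(ok)) return(out)
  nd <- features[ok, , drop = FALSE]
  grp <- fit$spec$random_intercept
  use_pop <- population || is.null(nd[[grp]])
  if (!use_pop) {
    # unseen deployments get a zero random effect via allow.new.levels
    out[ok] <- stats::predict(fit$model, newdata = nd, type = "response",
                              re.form = NULL, allow.new.levels = TRUE)
  } else {
    nd[[grp]] <- "..new.."
    out[ok] <- stats::predict(fit$model, newdata = nd, type = "response",
                              re.form = NA)
  }
  out
}
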