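# Internal OLS wrapper around lm(): fits y ~ X with intercept and extracts
# the pieces the equation-development workflow reports (estimates, 95% CIs
# from the t distribution, two-sided p-values, R^2, adjusted R^2).
fit_ols <- function(data, response, predictors, conf_level = 0.95) {
  n <- nrow(data)
  if (n < length(predictors) + 2L) {
    stop(sprintf("need at least %d observations to fit %d predictor(s)",
                 length(predictors) + 2L, length(predictors)), call. = FALSE)
  }
  fml <- stats::reformulate(
    if (length(predictors) > 0) sprintf("`%s`", predictors) else "1",
    response = sprintf("`%s`", response))
  fit <- stats::lm(fml, data = data)
  if (anyNA(stats::coef(fit))) {
    stop("design matrix is rank deficient; resolve aliasing first",
         call. = FALSE)
  }
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  ct <- sm$coefficients
  terms_clean <- gsub("`", "", rownames(ct))
  coef_table <- data.frame(
    term = terms_clean,
    estimate = ct[, "Estimate"],
    ci_lower = ci[, 1],
    ci_upper = ci[, 2],
    p_value = ct[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    response = response,
    predictors = predictors,
    coefficients = coef_table,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    n = n,
    residual_sd = sm$sigma,
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit))),
    class = "ree_fit")
}

#' @export
print.ree_fit <- function(x, ...) {
  cat(sprintf("<OLS fit> %s ~ %s  (n = %d, R2 = %.4f, adj R2 = %.4f)\n",
              x$response,
              if (length(x$predictors) > 0) paste(x$predictors, collapse = " + ")
              else "1",
              x$n, x$r_squared, x$adj_r_squared))
  print(x$coefficients, digits = 6)
  invisible(x)
}

#' Univariate linear regression of measured REE on one predictor
#'
#' Ordinary least squares with intercept; 95% confidence intervals from the
#' t distribution with n - 2 degrees of freedom; two-sided p-value on the
#' slope. This is the screening regression run once per candidate predictor
#' before stepwise model building.
#'
#' @param x predictor values (nonzero variance, n >= 3).
#' @param y response values (measured REE, kcal/d).
#' @param name predictor name used in reports.
#' @return a `ree_fit` object.
#' @export
univariate_fit <- function(x, y, name = deparse(substitute(x))) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop(sprintf("predictor '%s' has zero variance", name), call. = FALSE)
  }
  data <- stats::setNames(data.frame(x, y), c(name, "y"))
  fit_ols(data, "y", name)
}

slope_p_value <- function(fit) {
  fit$coefficients$p_value[fit$coefficients$term != "(Intercept)"][1]
}

#' Screen predictors by univariate significance
#'
#' Keeps, in input order, the predictors whose univariate slope p-value is
#' at most `alpha` (the threshold is inclusive: p exactly equal to alpha
#' passes).
#'
#' @param fits list of univariate `ree_fit` objects.
#' @param alpha significance threshold, default 0.05.
#' @return character vector of retained predictor names.
#' @export
screen_predictors <- function(fits, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  keep <- vapply(fits, function(f) slope_p_value(f) <= alpha, logical(1))
  vapply(fits[keep], function(f) f$predictors[1], character(1))
}

# Drop exactly collinear predictors before stepwise fitting. The design
# matrix rank is inspected via QR; while it is deficient, the aliased
# predictor with the weakest univariate R^2 is removed (deterministic, and
# the choice any stepwise run on such data implicitly makes).
resolve_aliasing <- function(data, response, predictors) {
  dropped <- character(0)
  repeat {
    X <- cbind(1, as.matrix(data[, predictors, drop = FALSE]))
    qr_x <- qr(X)
    if (qr_x$rank == ncol(X)) break
    aliased_cols <- qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(X))]
    aliased <- predictors[aliased_cols - 1L]  # column 1 is the intercept
    r2 <- vapply(predictors, function(p)
      stats::cor(data[[p]], data[[response]])^2, numeric(1))
    # among the aliased group plus everything they alias with, drop the
    # weakest univariately; restricting to the reported aliased columns is
    # enough because removing one restores rank one step at a time
    victim <- aliased[which.min(r2[aliased])]
    dropped <- c(dropped, victim)
    predictors <- setdiff(predictors, victim)
    if (length(predictors) == 0L) break
  }
  list(predictors = predictors, dropped = dropped)
}

#' Backward stepwise regression
#'
#' Fits the full model on the screened predictors, then repeatedly removes
#' the predictor with the largest p-value exceeding `removal_alpha` and
#' refits, until every remaining coefficient satisfies p <=
#' `removal_alpha` or the model is empty (then reported as intercept-only).
#' Exact linear dependencies among the candidates (e.g. weight = fat mass +
#' fat-free mass from a bioimpedance decomposition) are resolved before
#' elimination starts by dropping, within an aliased group, the predictor
#' with the weakest univariate R^2; such drops are recorded separately from
#' the elimination trace.
#'
#' @param data data frame containing the response and candidate predictor
#'   columns.
#' @param response response column name.
#' @param predictors character vector of screened candidate predictors.
#' @param removal_alpha retention threshold, default 0.05.
#' @return object of class `"ree_stepwise"`: list with `screened` (the
#'   candidates after aliasing resolution), `dropped_for_collinearity`,
#'   `trace` (data frame `step`, `removed`, `p_at_removal`), and `fit`
#'   (the final `ree_fit`).
#' @export
backward_stepwise <- function(data, response, predictors,
                              removal_alpha = 0.05) {
  if (length(predictors) == 0L) {
    stop("backward selection needs at least one screened predictor",
         call. = FALSE)
  }
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols) > 0L) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  alias <- resolve_aliasing(data, response, predictors)
  current <- alias$predictors
  trace <- data.frame(step = integer(0), removed = character(0),
                      p_at_removal = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fit <- fit_ols(data, response, current)
    if (length(current) == 0L) break
    slopes <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    worst <- which.max(slopes$p_value)
    if (slopes$p_value[worst] <= removal_alpha) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step, removed = slopes$term[worst],
      p_at_removal = slopes$p_value[worst], stringsAsFactors = FALSE))
    current <- setdiff(current, slopes$term[worst])
  }
  structure(list(screened = alias$predictors,
                 dropped_for_collinearity = alias$dropped,
                 trace = trace, fit = fit),
            class = "ree_stepwise")
}

#' @export
print.ree_stepwise <- function(x, ...) {
  cat(sprintf("<backward stepwise> %d screened, %d aliased drop(s), %d elimination step(s)\n",
              length(x$screened), length(x$dropped_for_collinearity),
              nrow(x$trace)))
  if (nrow(x$trace) > 0) print(x$trace)
  print(x$fit)
  invisible(x)
}

#' Package a fitted model as a prediction equation
#'
#' Turns a `ree_fit` whose predictors are subject fields (`weight`,
#' `height`, `age`, `sex`, `fat_mass`, `fat_free_mass`) into an equation
#' specification usable by [predict_ree()], in kcal/d. Numeric `sex` in a
#' fit is assumed coded female = 0, male = 1. Predicting on the training
#' cohort reproduces the fitted values exactly.
#'
#' @param fit a `ree_fit` with response in kcal/d.
#' @param equation_id identifier for the new equation.
#' @param label human-readable label.
#' @param age_range stated applicable age range in years.
#' @return a `ree_equation_spec`.
#' @export
package_equation <- function(fit, equation_id = "fitted_equation",
                             label = "User-fitted equation",
                             age_range = c(6, 18)) {
  allowed <- c(weight = "weight", height = "height_cm", age = "age",
               sex = "sex", fat_mass = "fat_mass",
               fat_free_mass = "fat_free_mass")
  bad <- setdiff(fit$predictors, names(allowed))
  if (length(bad) > 0L) {
    stop("predictor(s) not subject fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  coef <- c(intercept = unname(est["(Intercept)"]))
  for (p in fit$predictors) coef[allowed[[p]]] <- est[[p]]
  ree_equation_spec(
    equation_id, label, "kcal_per_day",
    sex_code = c(male = 1, female = 0),
    stated_age_range = age_range,
    variants = list(ree_variant("all", age_range[1], age_range[2], coef)))
}
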