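#' Principal-component score of a covariate item block
#'
#' Collapses a block of related items (e.g. the deterrence or legitimacy
#' items) to the first principal component of the standardised items,
#' standardises the scores to mean 0 / variance 1, and orients the sign so
#' that higher scores mean more of the named construct (the mean item
#' loading is made positive).
#'
#' @param items numeric matrix or data frame, respondents in rows, k >= 2
#'   items in columns; complete cases only.
#' @param block_name optional label attached to the result.
#' @return Numeric vector of standardised scores with attributes
#'   `"loadings"` (first-component loadings), `"prop_var"` (share of
#'   variance explained), and `"block"`.
#' @export
pca_block_score <- function(items, block_name = NULL) {
  m <- as.matrix(items)
  if (ncol(m) < 2L) stop("a component block needs at least 2 items")
  if (anyNA(m)) stop("pca_block_score requires complete cases")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance item(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  load1 <- pc$rotation[, 1]
  scores <- pc$x[, 1]
  if (mean(load1) < 0) {       # sign aligned with the mean item loading
    load1 <- -load1
    scores <- -scores
  }
  scores <- as.numeric(scale(scores))
  attr(scores, "loadings") <- load1
  attr(scores, "prop_var") <- unname(pc$sdev[1]^2 / sum(pc$sdev^2))
  attr(scores, "block") <- block_name
  scores
}

#' Specify an association model
#'
#' A declarative model specification covering the four families used in the
#' analyses: multinomial logit for group membership, negative binomial for
#' the emotion score, Poisson for non-compliance counts, and linear for the
#' re-engagement change score.
#'
#' @param family one of `"multinomial_logit"`, `"negative_binomial"`,
#'   `"poisson"`, `"linear"`.
#' @param outcome name of the outcome column.
#' @param predictors character vector of predictor terms (interactions in
#'   formula syntax, e.g. `"age_band:gender"`).
#' @param reference_outcome for multinomial models, the outcome category
#'   treated as reference.
#' @param reference_levels named list giving the reference level of
#'   categorical predictors (e.g. `list(age_band = "16-24", city =
#'   "Birmingham")`).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("multinomial_logit", "negative_binomial",
                                  "poisson", "linear"),
                       outcome, predictors,
                       reference_outcome = NULL,
                       reference_levels = list()) {
  family <- match.arg(family)
  structure(list(family = family, outcome = outcome, predictors = predictors,
                 reference_outcome = reference_outcome,
                 reference_levels = reference_levels),
            class = "model_spec")
}

#' Fit an association model
#'
#' Fits the model described by a [model_spec()] with listwise deletion of
#' incomplete rows. Multinomial and negative-binomial estimates are returned
#' exponentiated (relative-risk / rate ratios) with standard errors on the
#' log scale, matching how such models are conventionally reported; Poisson
#' and linear estimates are raw coefficients.
#'
#' @param spec a [model_spec()].
#' @param data data frame holding outcome and predictors.
#' @param weights optional numeric case weights (unweighted by default).
#' @return An object of class `model_result`: a data frame with columns
#'   `outcome_level` (multinomial only, else `NA`), `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `conf_low`, `conf_high`, plus
#'   attributes `family`, `n`, `aic`, `loglik`, `theta`/`theta_se`
#'   (negative binomial), and `fit` (the underlying fitted object).
#' @export
fit_model <- function(spec, data, weights = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- unique(c(spec$outcome, all.vars(stats::reformulate(spec$predictors))))
  absent <- setdiff(vars, names(data))
  if (length(absent)) stop("columns missing from data: ", paste(absent, collapse = ", "))
  df <- data[, vars, drop = FALSE]
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  w <- if (is.null(weights)) NULL else weights[keep]

  for (v in intersect(names(spec$reference_levels), names(df))) {
    df[[v]] <- stats::relevel(factor(df[[v]]), ref = spec$reference_levels[[v]])
  }
  if (spec$family == "multinomial_logit") {
    ref <- spec$reference_outcome
    if (is.null(ref)) stop("multinomial models need a reference_outcome")
    y <- factor(as.character(df[[spec$outcome]]))
    if (!ref %in% levels(y)) stop("reference_outcome '", ref, "' not an outcome level")
    df[[spec$outcome]] <- stats::relevel(y, ref = ref)
  }
  n_par <- length(spec$predictors) + 1L
  if (nrow(df) < n_par + 5L)
    stop("too few complete cases (", nrow(df), ") for ", n_par, " parameters")

  form <- stats::reformulate(spec$predictors, response = spec$outcome)
  fit <- switch(spec$family,
    multinomial_logit = {
      cl <- list(form, data = df, trace = FALSE, maxit = 1000,
                 reltol = 1e-14, abstol = 1e-12)
      if (!is.null(w)) cl$weights <- w
      do.call(nnet::multinom, cl)
    },
    negative_binomial = {
      if (is.null(w)) MASS::glm.nb(form, data = df, control = stats::glm.control(maxit = 100))
      else MASS::glm.nb(form, data = df, weights = w,
                        control = stats::glm.control(maxit = 100))
    },
    poisson = stats::glm(form, data = df, family = stats::poisson(), weights = w),
    linear = stats::lm(form, data = df, weights = w)
  )
  res <- tidy_fit(fit, spec)
  check_convergence(fit, spec)
  attr(res, "spec") <- spec
  attr(res, "n") <- nrow(df)
  attr(res, "fit") <- fit
  class(res) <- c("model_result", "data.frame")
  res
}

# Flatten any of the four fit types to the common reporting layout.
tidy_fit <- function(fit, spec) {
  z975 <- stats::qnorm(0.975)
  if (spec$family == "multinomial_logit") {
    s <- summary(fit)
    co <- s$coefficients
    se <- s$standard.errors
    if (is.null(dim(co))) {  # two outcome levels: nnet returns vectors
      co <- matrix(co, nrow = 1, dimnames = list(fit$lev[2], names(co)))
      se <- matrix(se, nrow = 1, dimnames = list(fit$lev[2], colnames(co)))
    }
    rows <- expand.grid(term = colnames(co), outcome_level = rownames(co),
                        stringsAsFactors = FALSE)
    b <- mapply(function(tm, lv) co[lv, tm], rows$term, rows$outcome_level)
    s2 <- mapply(function(tm, lv) se[lv, tm], rows$term, rows$outcome_level)
    z <- b / s2
    out <- data.frame(outcome_level = rows$outcome_level, term = rows$term,
                      estimate = exp(b), std_error = s2, statistic = z,
                      p_value = 2 * stats::pnorm(-abs(z)),
                      conf_low = exp(b - z975 * s2),
                      conf_high = exp(b + z975 * s2))
    attr(out, "aic") <- stats::AIC(fit)
    attr(out, "loglik") <- -fit$value
    attr(out, "family") <- spec$family
    return(out)
  }
  co <- summary(fit)$coefficients
  b <- co[, 1]; s2 <- co[, 2]; z <- co[, 3]; p <- co[, 4]
  expo <- spec$family == "negative_binomial"
  out <- data.frame(outcome_level = NA_character_, term = rownames(co),
                    estimate = if (expo) exp(b) else b,
                    std_error = s2, statistic = z, p_value = p,
                    conf_low = if (expo) exp(b - z975 * s2) else b - z975 * s2,
                    conf_high = if (expo) exp(b + z975 * s2) else b + z975 * s2)
  rownames(out) <- NULL
  attr(out, "aic") <- stats::AIC(fit)
  attr(out, "loglik") <- as.numeric(stats::logLik(fit))
  attr(out, "family") <- spec$family
  if (spec$family == "negative_binomial") {
    attr(out, "theta") <- fit$theta
    attr(out, "theta_se") <- fit$SE.theta
  }
  out
}

# Non-convergence and aliasing are analysis errors, never silent.
check_convergence <- function(fit, spec) {
  if (spec$family == "multinomial_logit" && !is.null(fit$convergence) &&
      fit$convergence != 0)
    stop("multinomial model did not converge")
  if (spec$family %in% c("negative_binomial", "poisson") &&
      isFALSE(fit$converged))
    stop(spec$family, " model did not converge")
  al <- tryCatch(stats::alias(fit)$Complete, error = function(e) NULL)
  if (!is.null(al) && nrow(al))
    stop("rank-deficient design; aliased terms: ",
         paste(rownames(al), collapse = ", "))
  invisible(fit)
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s, n=%d, AIC=%.1f\n",
              attr(x, "family"), attr(x, "n"), attr(x, "aic")))
  print.data.frame(cbind(as.data.frame(x)[, c("outcome_level", "term")],
                         round(as.data.frame(x)[, -(1:2)], 4)), ...)
  invisible(x)
}

#' Significance stars at the conventional thresholds
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05 (strict
#' inequalities), empty otherwise.
#'
#' @param p numeric vector of p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Combine model results into a formatted report table
#'
#' @param results named list of `model_result` objects (possibly empty).
#' @param digits rounding applied to the numeric columns.
#' @return A data frame stacking all results with a `model` column, rounded
#'   estimates, and a `stars` significance column.
#' @export
model_report <- function(results, digits = 3) {
  if (!length(results))
    return(data.frame(model = character(0), outcome_level = character(0),
                      term = character(0), estimate = numeric(0),
                      std_error = numeric(0), p_value = numeric(0),
                      conf_low = numeric(0), conf_high = numeric(0),
                      stars = character(0)))
  nm <- names(results)
  if (is.null(nm)) nm <- paste0("model_", seq_along(results))
  do.call(rbind, lapply(seq_along(results), function(i) {
    r <- as.data.frame(results[[i]])
    data.frame(model = nm[i],
               outcome_level = r$outcome_level, term = r$term,
               estimate = round(r$estimate, digits),
               std_error = round(r$std_error, digits),
               p_value = round(r$p_value, digits + 1),
               conf_low = round(r$conf_low, digits),
               conf_high = round(r$conf_high, digits),
               stars = significance_stars(r$p_value))
  }))
}
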