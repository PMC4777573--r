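#' Mixed-model contract
#'
#' Thin, typed layer over lme4: binomial (logit) and Poisson (log) GLMMs
#' via the Laplace approximation and Gaussian LMMs via REML, restricted
#' to random intercepts with optional factor-within-factor nesting —
#' exactly the model class the analyses here need. The wrapper fixes the
#' output contract (coefficient table with Wald z and p for GLMMs, t for
#' LMMs; random-effect SDs; log-likelihood; convergence flag) and the
#' prediction conventions (fixed part only by default).
#'
#' @name mixed-models
NULL

#' Specify a mixed model
#'
#' @param family `"binomial"`, `"poisson"` or `"gaussian"`.
#' @param response response variable name; for binomial models give
#'   `trials` as well, so the response is `cbind(response, trials - response)`.
#' @param fixed character vector of fixed-effect terms (main effects and
#'   `a:b` interactions), e.g. `c("water", "site", "water:site")`.
#' @param random character vector of random-intercept groupings; write
#'   nesting as `"outer/inner"` (lme4 style) meaning intercepts for
#'   `outer` and for `inner` within `outer`, or give simple factor names.
#' @param trials variable holding binomial trial counts.
#' @return a `model_spec` list.
#' @export
model_spec <- function(family = c("binomial", "poisson", "gaussian"),
                       response, fixed, random, trials = NULL) {
  family <- match.arg(family)
  if (family == "binomial" && is.null(trials))
    stop_data("binomial models need `trials`")
  structure(list(family = family, response = response, fixed = fixed,
                 random = random, trials = trials), class = "model_spec")
}

spec_formula <- function(spec) {
  lhs <- if (spec$family == "binomial")
    sprintf("cbind(%s, %s - %s)", spec$response, spec$trials, spec$response)
  else spec$response
  ran <- vapply(spec$random, function(g) {
    if (grepl("/", g, fixed = TRUE)) {
      parts <- strsplit(g, "/", fixed = TRUE)[[1]]
      # outer/inner: intercepts for outer and inner-within-outer
      sprintf("(1 | %s) + (1 | %s:%s)", parts[1], parts[1], parts[2])
    } else sprintf("(1 | %s)", g)
  }, "")
  stats::as.formula(paste(lhs, "~", paste(c(spec$fixed, ran), collapse = " + ")),
                    env = globalenv())
}

check_spec_data <- function(spec, data) {
  vars <- unique(c(spec$response, spec$trials,
                   unlist(strsplit(spec$fixed, ":", fixed = TRUE)),
                   unlist(strsplit(spec$random, "/", fixed = TRUE))))
  miss <- setdiff(setdiff(vars, c("1", "0")), names(data))
  if (length(miss))
    stop_data("data lacks variable(s): ", paste(miss, collapse = ", "))
}

build_fit <- function(model, spec, converged) {
  sm <- summary(model)
  ct <- as.data.frame(sm$coefficients)
  is_gauss <- spec$family == "gaussian"
  out <- data.frame(term = rownames(ct),
                    estimate = ct[, 1], se = ct[, 2],
                    stringsAsFactors = FALSE)
  if (is_gauss) {
    out$t <- ct[, 3]
    out$p <- NA_real_  # no p-values for LMM fixed effects by convention
  } else {
    out$z <- ct[, 3]
    out$p <- ct[, 4]
  }
  rownames(out) <- NULL
  vc <- lme4::VarCorr(model)
  ranef_sd <- vapply(vc, function(m) attr(m, "stddev")[[1]], 0)
  structure(list(coefficients = out,
                 ranef_sd = ranef_sd,
                 sigma = if (is_gauss) stats::sigma(model) else NA_real_,
                 logLik = as.numeric(stats::logLik(model)),
                 converged = converged,
                 family = spec$family,
                 spec = spec,
                 model = model),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("%s mixed model (%s), logLik = %.2f, converged: %s\n",
              tools::toTitleCase(x$family),
              if (x$family == "gaussian") "REML" else "Laplace ML",
              x$logLik, x$converged))
  print(x$coefficients, digits = 4)
  cat("Random-effect SDs:\n")
  print(round(x$ranef_sd, 3))
  invisible(x)
}

#' Fit a binomial or Poisson GLMM (Laplace approximation)
#'
#' @param spec a [model_spec()] with family `"binomial"` or `"poisson"`.
#' @param data data frame of records.
#' @return a `mixed_fit`: coefficient table (estimate, SE, Wald z, p),
#'   random-effect SDs, log-likelihood, convergence flag and the
#'   underlying model object.
#' @export
fit_glmm <- function(spec, data) {
  if (spec$family == "gaussian") stop_data("use fit_lmm() for gaussian models")
  check_spec_data(spec, data)
  data <- as.data.frame(data)
  if (spec$family == "binomial") {
    y <- data[[spec$response]]; n <- data[[spec$trials]]
    if (all(y == 0) || all(y == n))
      warning("degenerate binomial response (all failures or all successes); ",
              "possible separation", call. = FALSE)
  }
  fam <- if (spec$family == "binomial") stats::binomial() else stats::poisson()
  model <- tryCatch(suppressMessages(lme4::glmer(
    spec_formula(spec), data = data, family = fam,
    control = lme4::glmerControl(check.conv.singular = "ignore"))),
    error = function(e) e)
  if (inherits(model, "error")) {
    warning("GLMM could not be fitted (", conditionMessage(model),
            "); returning an unconverged shell", call. = FALSE)
    return(structure(list(coefficients = data.frame(term = character(0),
                                                    estimate = numeric(0),
                                                    se = numeric(0),
                                                    z = numeric(0),
                                                    p = numeric(0)),
                          ranef_sd = numeric(0), sigma = NA_real_,
                          logLik = NA_real_, converged = FALSE,
                          family = spec$family, spec = spec, model = NULL),
                     class = "mixed_fit"))
  }
  conv <- length(model@optinfo$conv$lme4$messages) == 0 &&
    model@optinfo$conv$opt == 0
  fit <- build_fit(model, spec, conv)
  if (!conv)
    warning("GLMM did not cleanly converge; inspect fit$model", call. = FALSE)
  big <- abs(fit$coefficients$estimate) > 15
  if (spec$family == "binomial" && any(big))
    warning("very large logit coefficient(s) (",
            paste(fit$coefficients$term[big], collapse = ", "),
            "); likely separation", call. = FALSE)
  fit
}

#' Fit a Gaussian linear mixed model by REML
#'
#' @inheritParams fit_glmm
#' @return a `mixed_fit`; fixed-effect table reports t ratios and no
#'   p-values. The residual SD is in `$sigma`.
#' @export
fit_lmm <- function(spec, data) {
  if (spec$family != "gaussian") stop_data("fit_lmm() is for gaussian models")
  check_spec_data(spec, data)
  model <- suppressMessages(lme4::lmer(
    spec_formula(spec), data = as.data.frame(data), REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  conv <- length(model@optinfo$conv$lme4$messages) == 0 &&
    model@optinfo$conv$opt == 0
  fit <- build_fit(model, spec, conv)
  if (!conv) warning("LMM did not cleanly converge", call. = FALSE)
  fit
}

#' Predict expected responses from a mixed fit
#'
#' @param fit a `mixed_fit`.
#' @param newdata data frame covering the fixed covariates.
#' @param include_random include the fitted random intercepts (requires
#'   known group levels); default `FALSE` uses the fixed part only, the
#'   convention for out-of-sample cages and map surfaces.
#' @return numeric vector of expected responses (inverse-link scale).
#' @export
predict_response <- function(fit, newdata, include_random = FALSE) {
  stats::predict(fit$model, newdata = as.data.frame(newdata),
                 re.form = if (include_random) NULL else NA,
                 type = "response", allow.new.levels = FALSE)
}

# Fixed-part linear predictor and its delta-method SE on the link scale.
fixed_predictor <- function(fit, newdata) {
  X <- stats::model.matrix(lme4::nobars(stats::formula(fit$model, fixed.only = TRUE)[-2]),
                           as.data.frame(newdata))
  beta <- lme4::fixef(fit$model)
  X <- X[, names(beta), drop = FALSE]
  eta <- drop(X %*% beta)
  se <- sqrt(rowSums((X %*% as.matrix(stats::vcov(fit$model))) * X))
  list(eta = eta, se = se)
}
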