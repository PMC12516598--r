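#' Fit the pairwise-distance linear mixed model
#'
#' Fits `Y = b0 + sum_m b_m x_m + r_0k + e` on the within-group pair table,
#' with an optional random song-group intercept `r_0k ~ N(0, tau^2)` and
#' residual `e ~ N(0, sigma^2)`. Rows with missing values in any used column
#' are dropped (the count is recorded), so pairs with unknown recording
#' sites only leave models that use `I` or `D`. Mixed fits go through
#' `lmerTest::lmer` (REML by default); with `random_intercept = FALSE` the
#' model is ordinary least squares via `lm`.
#'
#' @param table Pair table from [build_pair_table()] (optionally
#'   standardized with [standardize_columns()]).
#' @param fixed_terms Subset of `c("I","D","T","C","S")` (may be empty).
#' @param random_intercept Include the song-group random intercept.
#' @param method `"REML"` or `"ML"`.
#' @return An object of class `"melody_lmm"`: the underlying fit (`fit`),
#'   `fixed_terms`, `random_intercept`, `method`, `n_used`, `n_dropped`,
#'   `converged`, and the variance components `tau2`, `sigma2`.
#' @export
fit_lmm <- function(table, fixed_terms = c("I", "D", "T", "C", "S"),
                    random_intercept = TRUE,
                    method = c("REML", "ML")) {
  method <- match.arg(method)
  fixed_terms <- as.character(fixed_terms)
  bad <- setdiff(fixed_terms, c("I", "D", "T", "C", "S"))
  if (length(bad) > 0L) {
    abort(paste("unknown fixed terms:", paste(bad, collapse = ", ")),
          class = "melodiverge_input_error")
  }
  used <- c("Y", fixed_terms, if (random_intercept) "group")
  cc <- complete.cases(table[used])
  dat <- table[cc, , drop = FALSE]
  n_dropped <- sum(!cc)
  if (random_intercept && length(unique(dat$group)) < 2L) {
    abort("random intercept needs at least 2 song groups",
          class = "melodiverge_input_error")
  }
  if (nrow(dat) < length(fixed_terms) + 3L) {
    abort("too few complete-case rows for the requested model",
          class = "melodiverge_input_error")
  }
  rhs <- if (length(fixed_terms) > 0L) paste(fixed_terms, collapse = " + ") else "1"
  if (random_intercept) {
    fml <- as.formula(paste("Y ~", rhs, "+ (1 | group)"))
    fit <- lmerTest::lmer(fml, data = dat, REML = method == "REML")
    converged <- is.null(fit@optinfo$conv$lme4$code) &&
      length(fit@optinfo$conv$lme4$messages) == 0L
    vc <- as.data.frame(lme4::VarCorr(fit))
    tau2 <- vc$vcov[vc$grp == "group"]
    sigma2 <- vc$vcov[vc$grp == "Residual"]
  } else {
    fml <- as.formula(paste("Y ~", rhs))
    fit <- lm(fml, data = dat)
    converged <- TRUE
    tau2 <- 0
    sigma2 <- summary(fit)$sigma^2
  }
  structure(list(fit = fit, fixed_terms = fixed_terms,
                 random_intercept = random_intercept, method = method,
                 n_used = nrow(dat), n_dropped = n_dropped,
                 converged = converged, tau2 = tau2, sigma2 = sigma2,
                 data = dat),
            class = "melody_lmm")
}

#' @export
print.melody_lmm <- function(x, ...) {
  cat(sprintf("Pairwise-distance LMM (%s): Y ~ %s%s\n", x$method,
              if (length(x$fixed_terms)) paste(x$fixed_terms, collapse = " + ") else "1",
              if (x$random_intercept) " + (1 | group)" else ""))
  cat(sprintf("n = %d pairs used (%d dropped), tau^2 = %.5f, sigma^2 = %.5f\n",
              x$n_used, x$n_dropped, x$tau2, x$sigma2))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.melody_lmm <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  out <- tibble::tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"]
  )
  if (x$random_intercept) {
    out$df <- cf[, "df"]
    out$statistic <- cf[, "t value"]
    out$p.value <- cf[, "Pr(>|t|)"]
  } else {
    out$df <- df.residual(x$fit)
    out$statistic <- cf[, "t value"]
    out$p.value <- cf[, "Pr(>|t|)"]
  }
  out
}

#' @export
glance.melody_lmm <- function(x, ...) {
  tibble::tibble(
    n_used = x$n_used, n_dropped = x$n_dropped,
    tau2 = x$tau2, sigma2 = x$sigma2,
    logLik = as.numeric(logLik(x$fit)),
    method = x$method, converged = x$converged
  )
}

#' @export
autoplot.melody_lmm <- function(object, ...) {
  tidy(object) |>
    dplyr::filter(.data$term != "(Intercept)") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::labs(x = "estimate (+/- 1.96 SE)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Likelihood ratio test for the song-group random intercept
#'
#' Compares the REML criterion of the mixed model with that of the
#' corresponding fixed-effects-only model; the statistic
#' `2 (logLik_with - logLik_without)` (clamped at 0) is referred to
#' chi-square(1). The chi-square(1) reference is conservative at the
#' boundary tau^2 = 0; `boundary_mixture = TRUE` halves the p-value (the
#' 0.5 chi0 + 0.5 chi1 mixture).
#'
#' @inheritParams fit_lmm
#' @param boundary_mixture Use the halved-mixture reference distribution.
#' @return A list with `chi2`, `df`, `p`, and the two fits.
#' @export
lrt_random_effect <- function(table, fixed_terms = c("I", "D", "T", "C", "S"),
                              method = "REML", boundary_mixture = FALSE) {
  with_re <- fit_lmm(table, fixed_terms, random_intercept = TRUE,
                     method = method)
  # refit the OLS model on exactly the rows the mixed fit used
  without <- fit_lmm(with_re$data, fixed_terms, random_intercept = FALSE)
  ll1 <- as.numeric(logLik(with_re$fit))
  ll0 <- as.numeric(logLik(without$fit, REML = method == "REML"))
  chi2 <- max(0, 2 * (ll1 - ll0))
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  if (boundary_mixture) p <- p / 2
  list(chi2 = chi2, df = 1, p = p, with_re = with_re, without = without)
}

#' Satterthwaite F test for one fixed term
#'
#' For mixed fits the denominator degrees of freedom come from
#' Satterthwaite's approximation (delta method on the variance-parameter
#' covariance, as provided by `lmerTest`); for OLS fits the classical F test
#' with the residual degrees of freedom is returned, which is the limit of
#' the approximation when there is no random effect.
#'
#' @param fit A `"melody_lmm"` object.
#' @param term One of the fit's fixed terms.
#' @return A list with `F`, `ndf`, `ddf`, `p`.
#' @export
satterthwaite_ftest <- function(fit, term) {
  stopifnot(inherits(fit, "melody_lmm"))
  if (!term %in% fit$fixed_terms) {
    abort(sprintf("term '%s' is not in the model", term),
          class = "melodiverge_input_error")
  }
  if (fit$random_intercept) {
    a <- tryCatch(anova(fit$fit, ddf = "Satterthwaite"),
                  error = function(e) NULL)
    if (is.null(a) || !term %in% rownames(a) || !is.finite(a[term, "DenDF"])) {
      # fall back to an ML likelihood-ratio test
      message("Satterthwaite approximation unavailable for '", term,
              "'; falling back to an ML likelihood ratio test")
      full <- fit_lmm(fit$data, fit$fixed_terms, TRUE, method = "ML")
      red <- fit_lmm(fit$data, setdiff(fit$fixed_terms, term), TRUE,
                     method = "ML")
      chi2 <- max(0, 2 * (as.numeric(logLik(full$fit)) -
                            as.numeric(logLik(red$fit))))
      return(list(F = chi2, ndf = 1, ddf = NA_real_,
                  p = pchisq(chi2, 1, lower.tail = FALSE), test = "LRT-ML"))
    }
    list(F = a[term, "F value"], ndf = a[term, "NumDF"],
         ddf = a[term, "DenDF"], p = a[term, "Pr(>F)"],
         test = "F-Satterthwaite")
  } else {
    # marginal F via the t statistic of the coefficient; an aliased
    # (perfectly collinear) term explains nothing beyond the others and
    # tests as p = 1, so elimination discards it first
    cf <- summary(fit$fit)$coefficients
    ddf <- df.residual(fit$fit)
    if (!term %in% rownames(cf)) {
      return(list(F = 0, ndf = 1, ddf = ddf, p = 1, test = "F-OLS (aliased)"))
    }
    tval <- cf[term, "t value"]
    list(F = tval^2, ndf = 1, ddf = ddf,
         p = 2 * pt(-abs(tval), ddf), test = "F-OLS")
  }
}

# all fixed-term tests of a fit in one pass (one anova call for mixed fits)
satterthwaite_table <- function(fit) {
  if (length(fit$fixed_terms) == 0L) return(list())
  if (fit$random_intercept) {
    a <- tryCatch(anova(fit$fit, ddf = "Satterthwaite"), error = function(e) NULL)
    if (!is.null(a) && all(fit$fixed_terms %in% rownames(a)) &&
        all(is.finite(a[fit$fixed_terms, "DenDF"]))) {
      return(lapply(fit$fixed_terms, function(tm) {
        list(F = a[tm, "F value"], ndf = a[tm, "NumDF"], ddf = a[tm, "DenDF"],
             p = a[tm, "Pr(>F)"], test = "F-Satterthwaite")
      }))
    }
  }
  lapply(fit$fixed_terms, function(tm) satterthwaite_ftest(fit, tm))
}

#' Backward elimination of random and fixed effects
#'
#' Stage 1 drops the song-group random intercept if its likelihood ratio
#' test p-value is at or above `alpha_random`. Stage 2 repeatedly removes
#' the fixed term with the largest Satterthwaite F p-value at or above
#' `alpha_fixed`, refitting until every remaining term is significant. With
#' `restrict_ID = TRUE` the island indicator and the geographic distance are
#' never allowed in the same start model: the procedure is run once per
#' configuration (I only, D only, neither) and all three results are
#' returned.
#'
#' @inheritParams fit_lmm
#' @param alpha_random Significance level for the random-effect LRT.
#' @param alpha_fixed Significance level for the fixed-effect F tests.
#' @param restrict_ID Restrict to at most one of `I` and `D`.
#' @return An object of class `"melody_elimination"`: `fit` (the selected
#'   model), `trace` (a tibble recording every decision), `random_kept`.
#'   With `restrict_ID = TRUE`, a named list of three such objects
#'   (`"I"`, `"D"`, `"neither"`).
#' @export
backward_eliminate <- function(table, fixed_terms = c("I", "D", "T", "C", "S"),
                               alpha_random = 0.1, alpha_fixed = 0.05,
                               restrict_ID = FALSE) {
  if (restrict_ID) {
    pools <- list(I = setdiff(fixed_terms, "D"),
                  D = setdiff(fixed_terms, "I"),
                  neither = setdiff(fixed_terms, c("I", "D")))
    return(purrr::map(pools, backward_eliminate, table = table,
                      alpha_random = alpha_random, alpha_fixed = alpha_fixed,
                      restrict_ID = FALSE))
  }
  trace <- list()
  step_i <- 0L
  # stage 1: random effect
  lrt <- lrt_random_effect(table, fixed_terms)
  random_kept <- lrt$p < alpha_random
  step_i <- step_i + 1L
  trace[[step_i]] <- tibble::tibble(
    step = step_i, term = "(1 | group)",
    action = if (random_kept) "retained" else "removed",
    test = "LRT", statistic = lrt$chi2, df1 = 1, df2 = NA_real_,
    p = lrt$p, alpha = alpha_random)
  # stage 2: fixed effects
  terms <- fixed_terms
  fit <- fit_lmm(table, terms, random_intercept = random_kept)
  while (length(terms) > 0L) {
    tests <- satterthwaite_table(fit)
    ps <- vapply(tests, `[[`, numeric(1), "p")
    worst <- which.max(ps)
    if (ps[worst] >= alpha_fixed) {
      step_i <- step_i + 1L
      trace[[step_i]] <- tibble::tibble(
        step = step_i, term = terms[worst], action = "removed",
        test = tests[[worst]]$test, statistic = tests[[worst]]$F,
        df1 = tests[[worst]]$ndf, df2 = tests[[worst]]$ddf,
        p = ps[worst], alpha = alpha_fixed)
      terms <- terms[-worst]
      fit <- fit_lmm(table, terms, random_intercept = random_kept)
    } else {
      for (k in order(ps)) {
        step_i <- step_i + 1L
        trace[[step_i]] <- tibble::tibble(
          step = step_i, term = terms[k], action = "retained",
          test = tests[[k]]$test, statistic = tests[[k]]$F,
          df1 = tests[[k]]$ndf, df2 = tests[[k]]$ddf,
          p = ps[k], alpha = alpha_fixed)
      }
      break
    }
  }
  structure(list(fit = fit, trace = dplyr::bind_rows(trace),
                 random_kept = random_kept),
            class = "melody_elimination")
}

#' @export
print.melody_elimination <- function(x, ...) {
  cat("Backward elimination\n")
  print(x$trace)
  cat("\nSelected model:\n")
  print(x$fit)
  invisible(x)
}

#' @export
tidy.melody_elimination <- function(x, ...) x$trace

#' @export
glance.melody_elimination <- function(x, ...) {
  tibble::tibble(
    random_kept = x$random_kept,
    retained_terms = paste(x$fit$fixed_terms, collapse = "+"),
    n_used = x$fit$n_used
  )
}

#' Variance inflation factors for the fixed-effect design
#'
#' Computed from the OLS fit of the pair table's complete cases; values
#' above `threshold` raise a collinearity warning (never an automatic
#' removal).
#'
#' @inheritParams fit_lmm
#' @param threshold Warning threshold (conventionally 5).
#' @return A tibble with `term` and `vif`.
#' @export
vif_fixed <- function(table, fixed_terms = c("I", "D", "T", "C", "S"),
                      threshold = 5) {
  if (length(fixed_terms) < 2L) {
    abort("VIF needs at least 2 terms", class = "melodiverge_input_error")
  }
  cc <- complete.cases(table[c("Y", fixed_terms)])
  dat <- table[cc, ]
  vifs <- vapply(fixed_terms, function(tm) {
    r2 <- summary(lm(as.formula(paste(tm, "~",
      paste(setdiff(fixed_terms, tm), collapse = " + "))), data = dat))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  out <- tibble::tibble(term = fixed_terms, vif = unname(vifs))
  if (any(out$vif > threshold)) {
    warn(paste("possible multicollinearity; VIF >", threshold, "for:",
               paste(out$term[out$vif > threshold], collapse = ", ")),
         class = "melodiverge_collinearity_warning")
  }
  out
}
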