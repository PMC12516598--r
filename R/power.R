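#' Simulation-based power analysis for one fixed term
#'
#' Simulates the response from the fitted model (optionally with the fixed
#' effects overridden, e.g. a focal coefficient set to 0 to check the size
#' of the test), refits the same model to each simulated response, and tests
#' the focal term at level `alpha` (Satterthwaite F for mixed fits, the
#' classical F for OLS fits). Power is the fraction of significant refits;
#' refits that fail to converge are counted separately, never as
#' significant.
#'
#' @param fit A `"melody_lmm"` object (the design and variance components to
#'   simulate from).
#' @param focal_term The fixed term whose test is evaluated.
#' @param n_sim Number of simulated datasets.
#' @param alpha Test level.
#' @param seed Optional integer seed for reproducibility.
#' @param beta Optional named replacement for (a subset of) the fixed-effect
#'   coefficients used in simulation, e.g. `c(C = 0)`.
#' @return An object of class `"melody_power"`: `power`, a binomial 95%
#'   confidence interval (`ci_low`, `ci_high`), `n_significant`, `n_sim`,
#'   `n_failed`, `alpha`, `focal_term`.
#' @export
power_simulation <- function(fit, focal_term, n_sim = 1000, alpha = 0.05,
                             seed = NULL, beta = NULL) {
  stopifnot(inherits(fit, "melody_lmm"))
  if (!focal_term %in% fit$fixed_terms) {
    abort(sprintf("focal term '%s' is not in the model", focal_term),
          class = "melodiverge_input_error")
  }
  if (!is.null(seed)) set.seed(seed)

  b <- if (fit$random_intercept) lme4::fixef(fit$fit) else coef(fit$fit)
  if (!is.null(beta)) {
    unknown <- setdiff(names(beta), names(b))
    if (length(unknown) > 0L) {
      abort(paste("unknown coefficient(s):", paste(unknown, collapse = ", ")),
            class = "melodiverge_input_error")
    }
    b[names(beta)] <- beta
  }

  if (fit$random_intercept) {
    sims <- simulate(fit$fit, nsim = n_sim,
                     newparams = list(beta = b,
                                      theta = lme4::getME(fit$fit, "theta"),
                                      sigma = stats::sigma(fit$fit)))
  } else {
    X <- stats::model.matrix(fit$fit)
    mu <- as.numeric(X %*% b)
    s <- summary(fit$fit)$sigma
    sims <- as.data.frame(replicate(n_sim, mu + rnorm(length(mu), sd = s)))
  }

  n_sig <- 0L; n_failed <- 0L
  for (k in seq_len(n_sim)) {
    refit <- tryCatch({
      if (fit$random_intercept) {
        m <- lme4::refit(fit$fit, newresp = sims[[k]])
        lmerTest::as_lmerModLmerTest(m)
      } else {
        dat <- fit$data
        dat$Y <- sims[[k]]
        lm(stats::formula(fit$fit), data = dat)
      }
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(refit)) { n_failed <- n_failed + 1L; next }
    p <- tryCatch({
      if (fit$random_intercept) {
        a <- anova(refit, ddf = "Satterthwaite")
        a[focal_term, "Pr(>F)"]
      } else {
        cf <- summary(refit)$coefficients
        2 * pt(-abs(cf[focal_term, "t value"]), df.residual(refit))
      }
    }, error = function(e) NA_real_)
    if (is.na(p)) { n_failed <- n_failed + 1L; next }
    if (p < alpha) n_sig <- n_sig + 1L
  }
  n_ok <- n_sim - n_failed
  ci <- if (n_ok > 0) as.numeric(stats::binom.test(n_sig, n_ok)$conf.int) else c(NA, NA)
  structure(list(power = if (n_ok > 0) n_sig / n_ok else NA_real_,
                 ci_low = ci[1], ci_high = ci[2],
                 n_significant = n_sig, n_sim = n_sim, n_failed = n_failed,
                 alpha = alpha, focal_term = focal_term),
            class = "melody_power")
}

#' @export
print.melody_power <- function(x, ...) {
  cat(sprintf("Power for '%s' at alpha = %g: %.2f%% (95%% CI %.2f%%-%.2f%%)\n",
              x$focal_term, x$alpha, 100 * x$power,
              100 * x$ci_low, 100 * x$ci_high))
  cat(sprintf("%d of %d simulations significant, %d failed refits\n",
              x$n_significant, x$n_sim, x$n_failed))
  invisible(x)
}

#' @export
tidy.melody_power <- function(x, ...) {
  tibble::tibble(focal_term = x$focal_term, power = x$power,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 n_significant = x$n_significant, n_sim = x$n_sim,
                 n_failed = x$n_failed, alpha = x$alpha)
}
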