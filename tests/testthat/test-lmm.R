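test_that("haversine distances match closed-form great-circle values", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  expect_equal(haversine_km(0, 0, 0, 1), 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(haversine_km(0, 0, 0, 180), 6371 * pi, tolerance = 1e-6)
  expect_equal(haversine_km(10, 20, 30, 40), haversine_km(30, 40, 10, 20))
  expect_error(haversine_km(91, 0, 0, 0), class = "melodiverge_input_error")
  expect_error(haversine_km(0, 181, 0, 0), class = "melodiverge_input_error")
})

test_that("the pair table holds one row per within-group pair with the transmission covariates", {
  corpus <- toy_corpus()
  D <- distance_matrix(corpus, alignment_preset(2))
  pt <- build_pair_table(corpus, dmat = D)
  expect_equal(nrow(pt), 2 * choose(3, 2))
  expect_true(all(pt$group %in% c("A1", "B1")))
  expect_equal(pt$Y, D[cbind(pt$song_i, pt$song_j)])

  r12 <- pt[pt$song_i == "A1.1" & pt$song_j == "A1.2", ]
  expect_equal(r12$T, 48)                      # |1968 - 2016|
  expect_equal(r12$I, 0)                       # same island
  expect_equal(r12$D, haversine_km(28.33, 129.43, 28.32, 129.98))
  expect_equal(r12$C, 0)
  expect_equal(r12$S, 1)                       # SJF vs field

  # unknown recording site nulls I and D but nothing else
  r13 <- pt[pt$song_j == "A1.3", ]
  expect_true(all(is.na(r13$I)) && all(is.na(r13$D)))
  expect_false(anyNA(r13$T) || anyNA(r13$C) || anyNA(r13$S))

  expect_error(build_pair_table(corpus, dmat = D[-1, -1]), "A1.1",
               class = "melodiverge_input_error")
  # computed directly from sequences when no matrix is given
  pt2 <- build_pair_table(corpus, params = alignment_preset(2))
  expect_equal(pt2, pt)
})

test_that("pair-table size is sum over groups of C(n_k, 2)", {
  gen <- generate_corpus(simulation_config(n_groups = 15, seed = 51))
  sizes <- table(gen$corpus$group_id)
  pt <- build_pair_table(gen$corpus, params = alignment_preset(1))
  expect_equal(nrow(pt), sum(choose(sizes, 2)))
})

test_that("standardization z-scores complete cases and is invertible", {
  set.seed(52)
  tab <- simulate_pair_table(10, 8, p_na_site = 0.1)
  z <- standardize_columns(tab, c("Y", "I", "D", "T", "C", "S"))
  sc <- attr(z, "scaling")
  expect_equal(mean(z$Y), 0, tolerance = 1e-12)
  expect_equal(sd(z$D, na.rm = TRUE), 1, tolerance = 1e-12)
  # already-standard column is unchanged
  tab2 <- tab; tab2$Y <- as.numeric(scale(tab$Y))
  z2 <- standardize_columns(tab2, "Y")
  expect_equal(z2$Y, tab2$Y, tolerance = 1e-12)
  # constant column errors by name
  tab3 <- tab; tab3$C <- 1
  expect_error(standardize_columns(tab3, c("Y", "C")), "'C'",
               class = "melodiverge_input_error")
  # binary columns can be exempted
  zb <- standardize_columns(tab, c("Y", "I"), keep_binary = TRUE)
  expect_equal(zb$I, tab$I)

  # back-transformation: standardized coefficients reproduce raw ones
  fit_raw <- fit_lmm(tab, random_intercept = FALSE)
  fit_std <- fit_lmm(z, random_intercept = FALSE)
  sy <- sc$sd[sc$column == "Y"]
  for (term in c("I", "D", "T", "C", "S")) {
    sx <- sc$sd[sc$column == term]
    expect_equal(tidy(fit_std)$estimate[tidy(fit_std)$term == term] * sy / sx,
                 tidy(fit_raw)$estimate[tidy(fit_raw)$term == term],
                 tolerance = 1e-8)
  }
})

test_that("noise-free linear data is interpolated exactly", {
  set.seed(53)
  tab <- simulate_pair_table(8, 6, beta = c(`(Intercept)` = 0.2, I = 0.05,
                                            D = 1e-4, T = 1e-3, C = 0.15, S = 0.02),
                             tau = 0, sigma = 0)
  fit <- fit_lmm(tab, random_intercept = FALSE)
  est <- tidy(fit)
  expect_equal(unname(est$estimate[est$term == "I"]), 0.05, tolerance = 1e-8)
  expect_equal(unname(est$estimate[est$term == "C"]), 0.15, tolerance = 1e-8)
  expect_equal(unname(est$estimate[est$term == "(Intercept)"]), 0.2, tolerance = 1e-8)
})

test_that("without a random intercept the fit is ordinary least squares", {
  set.seed(54)
  tab <- simulate_pair_table(1, 40, tau = 0)
  fit <- fit_lmm(tab, random_intercept = FALSE)
  X <- cbind(1, as.matrix(tab[c("I", "D", "T", "C", "S")]))
  beta_hat <- solve(crossprod(X), crossprod(X, tab$Y))   # normal equations
  expect_equal(unname(tidy(fit)$estimate), unname(drop(beta_hat)),
               tolerance = 1e-8)
  expect_equal(fit$tau2, 0)
})

test_that("complete-case dropping only affects models using I or D", {
  set.seed(55)
  tab <- simulate_pair_table(12, 8, p_na_site = 0.2)
  full <- fit_lmm(tab)
  expect_equal(full$n_used + full$n_dropped, nrow(tab))
  expect_equal(full$n_dropped, sum(is.na(tab$I)))
  no_geo <- fit_lmm(tab, fixed_terms = c("T", "C", "S"))
  expect_equal(no_geo$n_used, nrow(tab))
  expect_equal(no_geo$n_dropped, 0)
})

test_that("the random-effect likelihood ratio test behaves at and away from the null", {
  set.seed(56)
  # strong grouping: decisively detected
  tab <- simulate_pair_table(25, 8, tau = 0.25, sigma = 0.05)
  lrt <- lrt_random_effect(tab)
  expect_gte(lrt$chi2, 0)
  expect_lt(lrt$p, 0.001)
  # boundary mixture halves the p-value
  lrt_m <- lrt_random_effect(tab, boundary_mixture = TRUE)
  expect_equal(lrt_m$p, lrt$p / 2)
  # no grouping: mostly not rejected (conservative chi2(1) reference)
  rejections <- sum(vapply(1:20, function(i) {
    t0 <- simulate_pair_table(20, 6, tau = 0, sigma = 0.05)
    lrt_random_effect(t0)$p < 0.1
  }, logical(1)))
  expect_lte(rejections, 4)
})

test_that("Satterthwaite denominator df reduces to the OLS residual df without grouping", {
  set.seed(57)
  tab <- simulate_pair_table(1, 60, tau = 0)
  fit <- fit_lmm(tab, random_intercept = FALSE)
  ft <- satterthwaite_ftest(fit, "C")
  expect_equal(ft$ddf, 60 - 6)
  expect_equal(unname(ft$F), unname((tidy(fit)$statistic[tidy(fit)$term == "C"])^2),
               tolerance = 1e-10)
  # and for a mixed fit with near-zero group variance it comes close
  tab2 <- simulate_pair_table(30, 10, tau = 0.002, sigma = 0.05)
  fit2 <- fit_lmm(tab2)
  ft2 <- satterthwaite_ftest(fit2, "C")
  expect_gt(ft2$ddf, 200)   # approaches n - p = 294
  expect_error(satterthwaite_ftest(fit2, "Z"), class = "melodiverge_input_error")
})

test_that("backward elimination keeps real effects and records every decision", {
  set.seed(58)
  tab <- simulate_pair_table(30, 10, beta = c(`(Intercept)` = 0.15, I = 0.05,
                                              D = 0, T = 0, C = 0.15, S = 0),
                             tau = 0.05, sigma = 0.05)
  sel <- backward_eliminate(tab)
  expect_true(all(c("I", "C") %in% sel$fit$fixed_terms))
  expect_true(sel$random_kept)
  tr <- sel$trace
  expect_equal(tr$term[1], "(1 | group)")
  expect_equal(tr$test[1], "LRT")
  expect_equal(tr$alpha[1], 0.1)                 # random-effect level
  expect_true(all(tr$alpha[-1] == 0.05))         # fixed-effect level
  removed <- tr$term[tr$action == "removed"]
  retained <- tr$term[tr$action == "retained"]
  expect_setequal(c(removed, setdiff(retained, "(1 | group)")),
                  c("I", "D", "T", "C", "S"))
})

test_that("restricted selection never lets island and distance coexist", {
  set.seed(59)
  tab <- simulate_pair_table(20, 8)
  sel <- backward_eliminate(tab, restrict_ID = TRUE)
  expect_named(sel, c("I", "D", "neither"))
  expect_false("D" %in% sel$I$fit$fixed_terms)
  expect_false("I" %in% sel$D$fit$fixed_terms)
  expect_true(all(!c("I", "D") %in% sel$neither$fit$fixed_terms))
})

test_that("a perfectly collinear term is aliased out, not a crash", {
  set.seed(66)
  tab <- simulate_pair_table(6, 5, tau = 0, sigma = 0.05)
  tab$D <- 133.52 * tab$I    # distance determined by the island indicator
  fit <- fit_lmm(tab, random_intercept = FALSE)
  ft <- satterthwaite_ftest(fit, "D")
  expect_equal(ft$p, 1)
  expect_match(ft$test, "aliased")
  sel <- backward_eliminate(tab)
  expect_false("D" %in% sel$fit$fixed_terms)
  expect_equal(sel$trace$term[sel$trace$action == "removed" &
                                sel$trace$test != "LRT"][1], "D")
})

test_that("variance inflation factors flag collinear designs", {
  set.seed(60)
  tab <- simulate_pair_table(20, 8)
  v <- vif_fixed(tab)
  expect_equal(nrow(v), 5)
  expect_true(all(v$vif >= 1))
  # force near-collinearity: D a noisy copy of I
  tab$D <- tab$I * 100 + rnorm(nrow(tab), 0, 1)
  expect_warning(vif_fixed(tab), class = "melodiverge_collinearity_warning")
})

test_that("a coefficient five times its standard error is detected almost surely", {
  set.seed(61)
  tab <- simulate_pair_table(25, 8, tau = 0.03, sigma = 0.05)
  fit <- fit_lmm(tab)
  se_C <- unname(tidy(fit)$std.error[tidy(fit)$term == "C"])
  pw <- power_simulation(fit, "C", n_sim = 60, seed = 62,
                         beta = c(C = 5 * se_C))
  expect_gte(pw$power, 0.95)
  expect_equal(pw$n_failed, 0)
})

test_that("power is non-decreasing in the number of pairs", {
  set.seed(63)
  powers <- vapply(c(4, 10, 25), function(ppg) {
    tab <- simulate_pair_table(12, ppg, tau = 0, sigma = 0.08)
    fit <- fit_lmm(tab, random_intercept = FALSE)
    power_simulation(fit, "C", n_sim = 150, seed = 64,
                     beta = c(C = 0.03))$power
  }, numeric(1))
  expect_true(all(diff(powers) >= 0))
})
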