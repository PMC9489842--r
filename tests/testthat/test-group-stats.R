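# Mixed-effects group comparison with a random intercept per cell line.

test_that("covariate centering is exact and does not move the diagnosis effect", {
  tab <- simulate_variable_table(n_lines = 10, nets_per_line = 4,
                                 beta_dx = 0.5, seed = 2)
  cen <- center_covariates(tab)
  expect_equal(mean(cen$n_neurons_c), 0, tolerance = 1e-12)
  expect_equal(mean(cen$n_neurons_sq_c), 0, tolerance = 1e-12)

  # all-equal neuron counts center to zero
  tab2 <- tab
  tab2$n_neurons <- 100
  expect_equal(center_covariates(tab2)$n_neurons_c, rep(0, nrow(tab2)))

  # centering leaves beta_diagnosis unchanged (shifted covariates only)
  shifted <- tab
  shifted$n_neurons <- shifted$n_neurons + 1000
  f1 <- fit_mixed_model(tab)
  f2 <- fit_mixed_model(shifted)
  expect_equal(f1$beta_diagnosis, f2$beta_diagnosis, tolerance = 1e-6)
})

test_that("planted diagnosis effect is recovered", {
  tab <- simulate_variable_table(n_lines = 5, nets_per_line = 20,
                                 beta_dx = -1, sd_line = 0.3, seed = 8)
  fit <- fit_mixed_model(tab, include_covariates = TRUE)
  expect_lt(abs(fit$beta_diagnosis - (-1)), 0.9) # single-replicate bound
  expect_true(fit$p_diagnosis >= 0 && fit$p_diagnosis <= 1)
})

test_that("relabeling the groups flips the diagnosis coefficient exactly", {
  tab <- simulate_variable_table(n_lines = 8, nets_per_line = 5,
                                 beta_dx = 0.7, seed = 3)
  flipped <- tab
  flipped$diagnosis <- 1 - flipped$diagnosis
  f1 <- fit_mixed_model(tab, include_covariates = FALSE)
  f2 <- fit_mixed_model(flipped, include_covariates = FALSE)
  expect_equal(f1$beta_diagnosis, -f2$beta_diagnosis, tolerance = 1e-6)

  # adding a constant to y shifts only the intercept
  shifted <- tab
  shifted$y <- shifted$y + 5
  f3 <- fit_mixed_model(shifted, include_covariates = FALSE)
  expect_equal(f1$beta_diagnosis, f3$beta_diagnosis, tolerance = 1e-6)
})

test_that("zero planted cell-line variance degenerates to OLS", {
  tab <- simulate_variable_table(n_lines = 12, nets_per_line = 30,
                                 beta_dx = 0.4, sd_line = 0, seed = 5)
  fit <- suppressWarnings(fit_mixed_model(tab, include_covariates = FALSE))
  # the intercept variance collapses toward the boundary and the fixed
  # effect coincides with ordinary least squares
  expect_lt(fit$random_intercept_variance, fit$residual_variance / 4)
  ols <- coef(lm(y ~ diagnosis, data = tab))[["diagnosis"]]
  expect_equal(fit$beta_diagnosis, ols, tolerance = 1e-6)
})

test_that("SZ/HC labels are accepted and validated", {
  tab <- simulate_variable_table(n_lines = 6, nets_per_line = 4, seed = 9)
  lab <- tab
  lab$diagnosis <- ifelse(tab$diagnosis == 1, "SZ", "HC")
  expect_equal(fit_mixed_model(lab)$beta_diagnosis,
               fit_mixed_model(tab)$beta_diagnosis, tolerance = 1e-9)
  bad <- tab
  bad$diagnosis[1] <- 2
  expect_error(variable_table(bad), class = "fcdyn_invalid_input")
  expect_error(fit_mixed_model(tab[1:5, ]), class = "fcdyn_invalid_input")
})

test_that("deviance selection prefers the right covariate set", {
  # response independent of n_neurons: unadjusted wins in most replicates
  picks <- sapply(1:10, function(s) {
    tab <- simulate_variable_table(n_lines = 10, nets_per_line = 5,
                                   beta_dx = 0, seed = 100 + s)
    deviance_select(tab)$selected
  })
  expect_gte(mean(picks == "unadjusted"), 0.9)

  # strongly quadratic response: adjusted wins
  tab <- simulate_variable_table(n_lines = 10, nets_per_line = 5, seed = 17)
  nn_c <- tab$n_neurons - mean(tab$n_neurons)
  tab$y <- tab$y + 1e-3 * nn_c^2
  sel <- deviance_select(tab)
  expect_identical(sel$selected, "adjusted")

  # nesting: adjusted ML deviance never exceeds unadjusted
  for (s in 31:34) {
    tab <- simulate_variable_table(n_lines = 8, nets_per_line = 5, seed = s)
    sel <- deviance_select(tab)
    expect_lte(sel$fit_adjusted$deviance, sel$fit_unadjusted$deviance + 1e-6)
  }
})

test_that("one network per cell line still returns a (degenerate) fit", {
  tab <- simulate_variable_table(n_lines = 14, nets_per_line = 1, seed = 21)
  fit <- suppressWarnings(fit_mixed_model(tab, include_covariates = FALSE))
  expect_true(is.finite(fit$beta_diagnosis))
  expect_true(is.finite(fit$p_diagnosis))
})

test_that("compare_groups reports one tested row per variable", {
  tab <- simulate_variable_table(n_lines = 8, nets_per_line = 5,
                                 beta_dx = -0.8, seed = 12)
  vars <- tab
  vars$n_visited_ms <- vars$y + 10
  vars$traveled_distance <- vars$y * 2 + 20
  out <- compare_groups(vars, responses = c("n_visited_ms", "traveled_distance"))
  expect_identical(out$variable, c("n_visited_ms", "traveled_distance"))
  expect_true(all(is.finite(out$z)))
  out_b <- compare_groups(vars, responses = c("n_visited_ms", "traveled_distance"),
                          bonferroni = TRUE)
  expect_true(all(out_b$p >= out$p - 1e-15))
})
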