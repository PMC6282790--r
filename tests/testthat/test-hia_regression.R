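# Logit transform, OLS diagnostics, PRESS, backward elimination, prediction
# and validation.

test_that("base-10 logit and its inverse behave as stated", {
  expect_equal(logit_hia(50), 0)
  expect_equal(logit_hia(82), log10(82 / 18), tolerance = 1e-12)
  expect_equal(round(logit_hia(82), 4), 0.6585)
  expect_error(logit_hia(100), "0 or 100")
  expect_error(logit_hia(0), "0 or 100")
  expect_equal(inverse_logit_hia(0), 50)
  expect_equal(inverse_logit_hia(3), 100 * 1000 / 1001, tolerance = 1e-12)
})

test_that("logit/inverse-logit round-trip to 1e-10 and logit is increasing", {
  p <- seq(0.5, 99.5, by = 0.5)
  expect_equal(inverse_logit_hia(logit_hia(p)), p, tolerance = 1e-10)
  expect_true(all(diff(logit_hia(p)) > 0))
})

test_that("exact linear logit data gives an exact fit", {
  tab <- exact_logit_table(n = 12, beta = c(1, 2))
  fit <- fit_mlr(tab, predictors = "x")
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-8)
  expect_equal(fit$r_squared, 100, tolerance = 1e-8)
  expect_equal(fit$s, 0, tolerance = 1e-7)
  expect_equal(unname(fit$vif), 1)  # single predictor
})

test_that("fit_mlr matches the normal-equations oracle on random data", {
  for (seed in 1:10) {
    d <- random_regression_data(n = 30, p = 3, seed = seed)
    hia <- 100 * 10^(d$y / 10) / (1 + 10^(d$y / 10))  # squash into (0,100)
    tab <- cbind(data.frame(name = seq_along(hia), hia_percent = hia,
                            role = "train"), as.data.frame(d$X))
    fit <- fit_mlr(tab, predictors = colnames(d$X))
    oracle <- ols_normal_equations(d$X, logit_hia(hia))
    expect_equal(unname(coef(fit)), oracle, tolerance = 1e-8)
  }
})

test_that("hat-matrix PRESS equals explicit leave-one-out PRESS", {
  for (seed in 1:50) {
    n <- sample(8:20, 1)
    d <- random_regression_data(n = n, p = sample(1:3, 1), seed = seed)
    lmf <- lm(d$y ~ d$X)
    h <- hatvalues(lmf); e <- residuals(lmf)
    press_hat <- sum((e / (1 - h))^2)
    press_loo <- press_loo_explicit(d$X, d$y)
    expect_equal(press_hat, press_loo, tolerance = 1e-8)
  }
})

test_that("predictive R^2 never exceeds R^2 and is 100% for exact fits", {
  for (seed in 1:20) {
    d <- random_regression_data(n = 25, p = 2, seed = seed + 100)
    hia <- 100 * 10^(d$y / 10) / (1 + 10^(d$y / 10))
    tab <- cbind(data.frame(name = seq_along(hia), hia_percent = hia,
                            role = "train"), as.data.frame(d$X))
    fit <- fit_mlr(tab, predictors = colnames(d$X))
    expect_lte(fit$r_squared_pred, fit$r_squared)
  }
  exact <- fit_mlr(exact_logit_table(n = 15), predictors = "x")
  expect_equal(exact$r_squared_pred, 100, tolerance = 1e-6)
})

test_that("VIF matches the car package on the reference fit", {
  skip_if_not_installed("car")
  fit <- fit_mlr(paper_compounds())
  expect_equal(unname(fit$vif), unname(car::vif(fit$lm_fit)),
               tolerance = 1e-10)
})

test_that("singular designs are rejected with the collinear predictor named", {
  tab <- exact_logit_table(n = 10)
  tab$x2 <- tab$x
  set.seed(1)
  tab$hia_percent <- pmin(99, pmax(1, tab$hia_percent + rnorm(10)))
  expect_error(fit_mlr(tab, predictors = c("x", "x2")), "singular|collinear")
})

test_that("compounds at the %HIA boundary are excluded from training", {
  tab <- exact_logit_table(n = 12)
  set.seed(2)
  tab$hia_percent <- pmin(99, pmax(1, tab$hia_percent + rnorm(12)))
  tab$hia_percent[1] <- 100
  expect_message(fit <- fit_mlr(tab, predictors = "x"), tab$name[1])
  expect_equal(fit$n_train, 11)
  expect_false(tab$name[1] %in% fit$training_names)
})

test_that("backward elimination drops a pure-noise predictor, keeps the true one", {
  set.seed(11)
  n <- 100
  x1 <- runif(n, 0, 3)
  x2 <- rnorm(n)                      # pure noise
  L <- 2 - 1.2 * x1 + rnorm(n, 0, 0.2)  # strong effect, high power
  tab <- data.frame(name = seq_len(n), x1 = x1, x2 = x2,
                    hia_percent = 100 * 10^L / (1 + 10^L), role = "train")
  fit <- backward_eliminate(tab, c("x1", "x2"))
  expect_identical(fit$predictor_names, "x1")
  expect_identical(fit$elimination_log$predictor, "x2")
  expect_identical(fit$elimination_log$reason, "p_value")
})

test_that("an exact copy of a predictor is removed in the VIF phase", {
  set.seed(12)
  n <- 40
  x1 <- runif(n, 0, 3)
  L <- 2 - 1.2 * x1 + rnorm(n, 0, 0.2)
  tab <- data.frame(name = seq_len(n), x1 = x1, x2 = x1,
                    hia_percent = 100 * 10^L / (1 + 10^L), role = "train")
  fit <- backward_eliminate(tab, c("x1", "x2"))
  expect_length(fit$predictor_names, 1)
  expect_identical(fit$elimination_log$reason[1], "vif")
})

test_that("eliminating every candidate falls back to intercept-only with warning", {
  set.seed(13)
  n <- 40
  L <- rnorm(n, 0.5, 0.3)  # no predictor signal at all
  tab <- data.frame(name = seq_len(n), x1 = rnorm(n),
                    hia_percent = 100 * 10^L / (1 + 10^L), role = "train")
  expect_warning(fit <- backward_eliminate(tab, "x1"), "intercept-only")
  expect_length(fit$predictor_names, 0)
})

test_that("coefficient recovery improves with sample size", {
  beta <- c(4.103, -0.939, -0.02218)
  bias <- vapply(c(15, 50, 200), function(n) {
    ests <- vapply(1:60, function(r) {
      tab <- simulate_compound_table(compound_sim_spec(
        n_compounds = n, noise_sd = 0.247, seed = 1000 + r))
      coef(fit_mlr(tab))["log_pmw"]
    }, numeric(1))
    abs(mean(ests) - beta[2])
  }, numeric(1))
  expect_lt(bias[3], 0.03)          # near-unbiased at n = 200
  expect_lt(bias[3], bias[1] + 0.02)  # no growth with n
})

test_that("recovered coefficients sit inside their own 95% CIs at nominal rate", {
  beta <- c(4.1, -0.94, -0.022)
  hits <- vapply(1:100, function(r) {
    tab <- simulate_compound_table(compound_sim_spec(
      n_compounds = 200, beta = beta, noise_sd = 0.25, seed = 2000 + r))
    fit <- fit_mlr(tab)
    ci <- fit$confidence_intervals
    all(beta >= ci[, 1] & beta <= ci[, 2])
  }, logical(1))
  # joint coverage of three 95% intervals; must clear 90% comfortably
  expect_gte(mean(hits), 0.80)
  expect_gte(mean(vapply(1:100, function(r) {
    tab <- simulate_compound_table(compound_sim_spec(
      n_compounds = 200, beta = beta, noise_sd = 0.25, seed = 2000 + r))
    ci <- fit_mlr(tab)$confidence_intervals
    beta[2] >= ci["log_pmw", 1] && beta[2] <= ci["log_pmw", 2]
  }, logical(1))), 0.90)
})

test_that("predictions decrease in each predictor when both coefficients are negative", {
  fit <- fit_mlr(paper_compounds())
  lp <- seq(0.9, 3, length.out = 15)
  p1 <- predict_hia(fit, data.frame(log_pmw = lp, psa = 60))$hia_predicted
  expect_true(all(diff(p1) < 0))
  ps <- seq(37, 89, length.out = 15)
  p2 <- predict_hia(fit, data.frame(log_pmw = 2, psa = ps))$hia_predicted
  expect_true(all(diff(p2) < 0))
})

test_that("validation reporting covers the degenerate cases", {
  fit <- fit_mlr(paper_compounds())
  one <- data.frame(name = "solo", log_pmw = 2.0, psa = 50,
                    hia_percent = 80, role = "validation")
  rep1 <- validate_model(fit, one)
  expect_equal(rep1$min_difference, rep1$max_difference)
  # a compound constructed to sit exactly on the model surface
  L <- sum(coef(fit) * c(1, 2.0, 50))
  exact <- data.frame(name = "onmodel", log_pmw = 2.0, psa = 50,
                      hia_percent = inverse_logit_hia(L), role = "validation")
  expect_equal(validate_model(fit, exact)$max_difference, 0, tolerance = 1e-10)
  expect_error(validate_model(fit, one[0, ]), "no validation")
})

test_that("model export/import round-trips predictions", {
  fit <- fit_mlr(paper_compounds())
  f <- withr::local_tempfile(fileext = ".json")
  write_hia_model(fit, f)
  back <- read_hia_model(f)
  expect_equal(coef(back), coef(fit), tolerance = 1e-12)
  expect_equal(back$n_train, fit$n_train)
  newd <- data.frame(log_pmw = c(1.0, 2.5), psa = c(45, 80))
  expect_equal(predict_hia(back, newd), predict_hia(fit, newd),
               tolerance = 1e-12)
})

test_that("the reproduction report assembles computed vs published values", {
  rep <- reproduce_paper()
  expect_s3_class(rep, "hia_reproduction")
  expect_equal(nrow(rep$predictions), 18)
  expect_equal(rep$fit$n_train, 15)
  expect_true(all(c("computed", "published", "difference") %in%
                    names(rep$statistics)))
  expect_true(any(grepl("F distribution", rep$notes)))  # p-value discrepancy note
  f <- withr::local_tempdir()
  files <- write_reproduction_report(rep, file.path(f, "rep"))
  expect_true(all(file.exists(files)))
  stats_back <- read.csv(files[2])
  expect_equal(nrow(stats_back), nrow(rep$statistics))
})
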