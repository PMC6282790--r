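# Retention analysis: peak picking, dead time, retention factors and the
# reciprocal-retention binding fit.

test_that("apex detection finds symmetric peaks to within one sample spacing", {
  tr <- gaussian_trace(4.0, sd = 0.1, by = 0.01)
  ch <- chromatogram(tr$time, tr$signal)
  expect_equal(detect_apex(ch), 4.0, tolerance = 0.011)

  # multi-peak mode returns both apices sorted by time
  tr2 <- gaussian_trace(c(1.2, 4.0), heights = c(0.5, 1), sd = 0.08)
  ch2 <- chromatogram(tr2$time, tr2$signal)
  apices <- detect_apex(ch2, multi = TRUE)
  expect_length(apices, 2)
  expect_equal(apices, c(1.2, 4.0), tolerance = 0.011)

  expect_error(detect_apex(chromatogram(1:100, rep(0, 100))), "no peak")
})

test_that("apex detection validates the smoothing window", {
  tr <- gaussian_trace(4.0)
  ch <- chromatogram(tr$time, tr$signal)
  expect_error(detect_apex(ch, smoothing_window = 4), "odd")
  expect_error(detect_apex(ch, smoothing_window = 0), "shorter than")
  expect_error(detect_apex(ch, smoothing_window = length(tr$time)),
               "shorter than")
})

test_that("dead time is the replicate mean, warning below 10 replicates", {
  est <- estimate_dead_time(rep(1.50, 10))
  expect_equal(est$t0, 1.50)
  expect_equal(est$sd, 0)
  expect_equal(est$n, 10)

  expect_warning(est2 <- estimate_dead_time(c(1.4, 1.6)), "at least 10")
  expect_equal(est2$t0, 1.5)
  expect_error(estimate_dead_time(c(1.5, -0.1)), "positive")
  expect_error(estimate_dead_time(numeric()), "no solvent-front")
})

test_that("retention factor is (rt - t0)/t0 and rejects pre-front elution", {
  expect_equal(retention_factor(6.0, 3.0), 1.0)
  expect_equal(retention_factor(3.0, 3.0), 0.0)
  expect_equal(retention_factor(4.2, 1.4), 2.0)
  expect_error(retention_factor(1.0, 1.4), "solvent front")
  # invariant under common rescaling of the time unit
  for (seed in 1:10) {
    set.seed(seed)
    t0 <- runif(1, 0.5, 3); rt <- t0 * runif(1, 1, 10); s <- runif(1, 0.1, 60)
    expect_equal(retention_factor(rt, t0), retention_factor(rt * s, t0 * s),
                 tolerance = 1e-12)
  }
})

test_that("noise-free binding series recovers K_AM and log Pmw exactly", {
  cm <- c(0.0004, 0.002, 0.005, 0.009, 0.0124)
  bs <- binding_series("demo", cm, 10 / (1 + 40 * cm))
  fit <- fit_binding_model(bs)
  expect_equal(fit$slope, 4.0, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-9)
  expect_equal(fit$k_am, 40, tolerance = 1e-7)
  expect_equal(fit$log_pmw, log10(40), tolerance = 1e-7)
  expect_identical(fit$binding_class, "binding")
  expect_identical(fit$convention, "slope_over_intercept")
})

test_that("the literal intercept/slope convention is available and recorded", {
  cm <- c(0.0004, 0.002, 0.005, 0.009, 0.0124)
  bs <- binding_series("demo", cm, 10 / (1 + 40 * cm))
  fit <- fit_binding_model(bs, convention = "intercept_over_slope")
  expect_equal(fit$k_am, 0.1 / 4.0, tolerance = 1e-7)
  expect_identical(fit$convention, "intercept_over_slope")
})

test_that("constant retention yields class none with NA log Pmw", {
  cm <- c(0.001, 0.004, 0.008, 0.012)
  bs <- binding_series("flat", cm, rep(5.0, 4))
  fit <- fit_binding_model(bs)
  expect_identical(fit$binding_class, "none")
  expect_true(is.na(fit$log_pmw))
  expect_match(fit$reason, "no concentration dependence")
})

test_that("antibinding series is classified from its negative 1/k' slope", {
  cm <- c(0.001, 0.004, 0.008, 0.012)
  bs <- binding_series("anti", cm, 5 * (1 + 30 * cm))
  fit <- fit_binding_model(bs)
  expect_lt(fit$slope, 0)
  expect_identical(fit$binding_class, "antibinding")
  expect_true(is.na(fit$log_pmw))
})

test_that("replicate k' values are averaged before the reciprocal", {
  # 1/mean(k') differs from mean(1/k'); the series must use the former
  cm <- rep(c(0.002, 0.006, 0.010), each = 2)
  kp <- c(4, 6, 3, 5, 2, 4)
  bs <- binding_series("rep", cm, kp)
  expect_equal(bs$inv_k_prime, 1 / c(5, 4, 3))
  expect_false(isTRUE(all.equal(bs$inv_k_prime,
                                tapply(1 / kp, cm, mean), check.names = FALSE)))
})

test_that("binding fit recovers K_AM across the parameter range (noise-free)", {
  cm <- micellar_concentration(seq(5, 17, length.out = 5) / 1000, 0.0046)
  set.seed(7)
  for (i in 1:25) {
    k0 <- runif(1, 0.5, 50); kam <- runif(1, 5, 500)
    bs <- binding_series("x", cm, k0 / (1 + kam * cm))
    fit <- fit_binding_model(bs)
    expect_equal(fit$k_am, kam, tolerance = 1e-6)
  }
})

test_that("binding fit rejects degenerate series", {
  expect_error(fit_binding_model(binding_series("d", c(0.001, 0.005),
                                                c(2, 1))),
               "at least 3")
  expect_error(binding_series("d", c(0.001, 0.005, 0.01), c(2, -1, 1)),
               "> 0")
})

test_that("logpmw_table fits per drug and isolates failures", {
  cm <- c(0.0004, 0.002, 0.005, 0.009, 0.0124)
  series <- list(
    binding_series("low", cm, 10 / (1 + 10 * cm)),
    binding_series("high", cm, 10 / (1 + 100 * cm)),
    binding_series("flat", cm, rep(5, length(cm))))
  tab <- logpmw_table(series)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$log_pmw[tab$drug == "low"], 1.0, tolerance = 1e-7)
  expect_equal(tab$log_pmw[tab$drug == "high"], 2.0, tolerance = 1e-7)
  expect_true(is.na(tab$log_pmw[tab$drug == "flat"]))
  expect_match(tab$reason[tab$drug == "flat"], "no concentration dependence")

  empty <- logpmw_table(list())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("drug", "log_pmw", "reason") %in% names(empty)))
})

test_that("chromatogram CSV dialect round-trips with metadata", {
  tr <- gaussian_trace(3.0)
  ch <- chromatogram(tr$time, tr$signal, drug = "ketoprofen",
                     total_surfactant_M = 0.012)
  f <- withr::local_tempfile(fileext = ".csv")
  write_chromatogram(ch, f)
  back <- read_chromatogram(f)
  expect_equal(back$time, ch$time)
  expect_equal(back$signal, ch$signal, tolerance = 1e-12)
  expect_identical(back$drug, "ketoprofen")
  expect_equal(back$total_surfactant_M, 0.012)
})

test_that("retention table reader validates and converts concentrations", {
  f <- withr::local_tempfile(fileext = ".csv")
  tab <- data.frame(drug = "d", total_conc_M = rep(c(0.008, 0.012, 0.017), 2),
                    replicate = rep(1:2, each = 3),
                    retention_time_min = 2 + rep(c(0.9, 0.7, 0.5), 2))
  write_retention_table(tab, f, header_comments = "seed=1")
  back <- read_retention_table(f)
  expect_equal(nrow(back), 6)
  series <- retention_table_to_series(back, t0_min = 2, cmc_M = 0.0046)
  expect_equal(series$d$cm, c(0.008, 0.012, 0.017) - 0.0046)
  expect_error(retention_table_to_series(back[, -2], t0_min = 2),
               "cm|total_conc_M")
  writeLines("", f)
  expect_error(read_retention_table(f), "empty|malformed")
})
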