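# Fitting GAM/NGAM by minimax relative error over growth observations.

test_that("predict_mu composes maintenance, medium, and FBA", {
  m <- mini_atp_toy(y = 4, gam = 30, ngam = 5, uptake = 10)
  med <- mini_media(10)[[1]]

  # no maintenance: the pure stoichiometric maximum is unbounded growth in
  # this toy only through the ATP drain, so gam = 0 is degenerate; use a
  # small gam instead to check the relaxation ordering
  expect_gt(predict_mu(m, 1, 0, med), predict_mu(m, 30, 5, med))

  expect_equal(predict_mu(m, 30, 5, med), (4 * 10 - 5) / 30,
               tolerance = 1e-8)
  expect_equal(predict_mu(m, 12, 1, mini_media(7)[[1]]), (4 * 7 - 1) / 12,
               tolerance = 1e-8)

  # NGAM above capacity: growth 0 with a warning, not an error
  expect_warning(mu <- predict_mu(m, 30, 1000, med), "treating growth as 0")
  expect_equal(mu, 0)
})

test_that("noiseless observations from known parameters are recovered", {
  m <- mini_atp_toy(y = 4)
  media <- mini_media(c(5, 10, 15))
  obs <- synth_calibration(m, gam = 30, ngam = 5, media = media)
  expect_length(obs, 3)
  fit <- calibrate_maintenance(m, obs)
  expect_equal(fit$gam, 30, tolerance = 1e-3)
  expect_equal(fit$ngam, 5, tolerance = 1e-3)
  expect_lt(fit$max_relative_error, 1e-3)
})

test_that("observations matching the initial point return it with zero error", {
  m <- mini_atp_toy(y = 4)
  media <- mini_media(c(5, 12))
  obs <- synth_calibration(m, gam = 100, ngam = 6, media = media)
  fit <- calibrate_maintenance(m, obs, initial = c(100, 6))
  expect_equal(fit$gam, 100, tolerance = 1e-2)
  expect_equal(fit$ngam, 6, tolerance = 1e-2)
  expect_lt(fit$max_relative_error, 1e-6)
})

test_that("the reported errors recompute from the stored predictions", {
  m <- mini_atp_toy(y = 4)
  obs <- synth_calibration(m, gam = 25, ngam = 4, media = mini_media(c(6, 12)))
  fit <- calibrate_maintenance(m, obs)
  rel <- abs(fit$predicted_mu - fit$observed_mu) / fit$observed_mu
  expect_equal(fit$max_relative_error, max(rel), tolerance = 1e-12)
  expect_equal(fit$mean_percent_error, mean(rel) * 100, tolerance = 1e-12)
})

test_that("error report does the arithmetic it claims", {
  fake <- structure(list(
    gam = 10, ngam = 1,
    predicted_mu = c(a = 0.44, b = 0.2, c = 0.3),
    observed_mu = c(a = 0.4, b = 0.2, c = 0.3),
    max_relative_error = 0.1, mean_percent_error = 10 / 3,
    trace = c(evaluations = 0), restarts = NULL), class = "calibration_result")
  rep <- error_report(fake)
  expect_equal(attr(rep, "max_relative_error"), 0.1, tolerance = 1e-12)
  expect_equal(attr(rep, "mean_percent_error"), 10 / 3, tolerance = 1e-12)
  expect_equal(rep$relative_error, c(0.1, 0, 0), tolerance = 1e-12)

  m <- mini_atp_toy(y = 4)
  obs <- synth_calibration(m, gam = 30, ngam = 5, media = mini_media(c(5, 15)))
  rep2 <- error_report(calibrate_maintenance(m, obs))
  expect_true(all(rep2$relative_error < 1e-3))
})

test_that("a grid of initial guesses converges to a single basin", {
  m <- mini_atp_toy(y = 4)
  obs <- synth_calibration(m, gam = 30, ngam = 5,
                           media = mini_media(c(5, 10, 15)))
  fit <- calibrate_maintenance(m, obs, grid_restarts = 3,
                               grid_range = c(1, 45))
  expect_equal(fit$gam, 30, tolerance = 1e-3)
  expect_equal(fit$ngam, 5, tolerance = 1e-3)
  # every start, including ones beyond the ATP capacity of the weakest
  # medium, lands in the same basin
  expect_true(all(fit$restarts$error < 1e-4))
  expect_true(all(abs(fit$restarts$gam - 30) < 0.1))
  expect_true(all(abs(fit$restarts$ngam - 5) < 0.1))
})

test_that("degenerate designs are flagged", {
  m <- mini_atp_toy(y = 4)
  expect_warning(synth_calibration(m, 30, 5, media = mini_media(10)),
                 "single medium")
  dead <- suppressWarnings(
    synth_calibration(m, 30, 500, media = mini_media(c(5, 10))))
  expect_length(dead, 0)   # NGAM above capacity: every medium excluded
  obs <- synth_calibration(m, gam = 30, ngam = 5, media = mini_media(c(5, 10)))
  expect_error(calibrate_maintenance(m, obs[1]), "length")
})
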