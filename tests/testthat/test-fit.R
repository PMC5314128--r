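test_that("the closed-form toy recovers exposed IRR 3 exactly", {
  fx <- toy_fixture("irr3_pair")
  fit <- sccs_fit(fx$intervals, adjust_age = FALSE, adjust_season = FALSE)
  expect_equal(unname(exp(coef(fit)["exposed"])), 3, tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("coefficients match an exhaustive grid-search oracle", {
  # two exposure parameters, four patients, uneven person-time
  ints <- mk_ints(
    pid = c(1, 1, 1, 2, 2, 2, 3, 3, 4, 4),
    cat = c("baseline", "pre_exposure", "exposed",
            "baseline", "pre_exposure", "exposed",
            "baseline", "exposed", "baseline", "pre_exposure"),
    len = c(300, 60, 90, 500, 90, 30, 200, 150, 400, 45),
    ev  = c(0, 1, 0, 0, 0, 1, 1, 0, 0, 1)
  )
  fit <- sccs_fit(ints, adjust_age = FALSE, adjust_season = FALSE)
  oracle <- grid_fit(ints, c("pre_exposure", "exposed"))
  expect_equal(unname(coef(fit)[names(oracle)]), unname(oracle), tolerance = 1e-4)

  # single parameter, three patients
  ints1 <- mk_ints(
    pid = c(1, 1, 2, 2, 3, 3),
    cat = rep(c("baseline", "exposed"), 3),
    len = c(365, 70, 200, 35, 600, 140),
    ev  = c(0, 1, 1, 0, 0, 1)
  )
  fit1 <- sccs_fit(ints1, adjust_age = FALSE, adjust_season = FALSE)
  oracle1 <- grid_fit(ints1, "exposed")
  expect_equal(unname(coef(fit1)["exposed"]), unname(oracle1), tolerance = 1e-4)
})

test_that("the likelihood and derivatives match brute force and finite differences", {
  ints <- mk_ints(
    pid = c(1, 1, 1, 2, 2),
    cat = c("baseline", "pre_exposure", "exposed", "baseline", "exposed"),
    len = c(120, 30, 60, 250, 40),
    ev  = c(0, 1, 0, 0, 1)
  )
  beta <- c(pre_exposure = 0.7, exposed = -0.3)
  got <- sccs_loglik(ints, beta, adjust_age = FALSE, adjust_season = FALSE)
  expect_equal(got$ll, brute_loglik(ints, as.list(beta)), tolerance = 1e-12)
  h <- 1e-6
  for (k in 1:2) {
    bp <- beta; bp[k] <- bp[k] + h
    bm <- beta; bm[k] <- bm[k] - h
    num <- (brute_loglik(ints, as.list(bp)) - brute_loglik(ints, as.list(bm))) / (2 * h)
    expect_equal(unname(got$grad[k]), num, tolerance = 1e-5)
    gp <- sccs_loglik(ints, bp, adjust_age = FALSE, adjust_season = FALSE)$grad
    gm <- sccs_loglik(ints, bm, adjust_age = FALSE, adjust_season = FALSE)$grad
    expect_equal(unname(got$hess[, k]), unname((gp - gm) / (2 * h)), tolerance = 1e-5)
  }
})

test_that("the fit agrees with the conditional Cox oracle on a simulated cohort", {
  skip_if_not_installed("survival")
  co <- sim_cohort_cached()
  sc <- scenario_config("pre90")
  ev <- classify_codes(co$events, default_code_map())
  epi <- build_episodes(co$prescriptions)
  w <- build_windows(co$patients, key_dates(co$prescriptions, ev), sc)
  cases <- select_incident_events(ev, w, sc, default_code_map())
  ints <- sccs_intervals(co$patients, w, epi, cases, sc)
  fit <- suppressWarnings(sccs_fit(ints))
  d <- ints
  d$category <- factor(d$category, levels = c("baseline", "pre_exposure", "exposed"))
  d$age_band <- factor(d$age_band)
  d$season <- factor(d$season)
  cf <- survival::coxph(
    survival::Surv(rep(1, nrow(d)), events) ~ category + age_band + season +
      survival::strata(patient_id) + offset(log(length_days)),
    data = d, method = "exact")
  expect_equal(unname(coef(fit)[c("pre_exposure", "exposed")]),
               unname(coef(cf)[c("categorypre_exposure", "categoryexposed")]),
               tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(vcov(fit)))[c("pre_exposure", "exposed")]),
               unname(sqrt(diag(vcov(cf)))[c("categorypre_exposure", "categoryexposed")]),
               tolerance = 1e-6)
})

test_that("refining the interval partition leaves the fit unchanged", {
  fx <- toy_fixture("irr3_pair")
  fit <- sccs_fit(fx$intervals, adjust_age = FALSE, adjust_season = FALSE)
  fine <- refine_intervals(fx$intervals)
  fit2 <- sccs_fit(fine, adjust_age = FALSE, adjust_season = FALSE)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-10)
  # the likelihood changes only by a beta-independent constant under
  # refinement, so likelihood *differences* are invariant
  b1 <- c(exposed = 0.4); b2 <- c(exposed = -1.1)
  d_fine <- sccs_loglik(fine, b1, FALSE, FALSE)$ll - sccs_loglik(fine, b2, FALSE, FALSE)$ll
  d_coarse <- sccs_loglik(fx$intervals, b1, FALSE, FALSE)$ll -
    sccs_loglik(fx$intervals, b2, FALSE, FALSE)$ll
  expect_equal(d_fine, d_coarse, tolerance = 1e-12)
})

test_that("rescaling all interval lengths shifts the likelihood but not the IRRs", {
  fx <- toy_fixture("irr3_pair")
  scaled <- fx$intervals
  scaled$length_days <- scaled$length_days * 7L
  fit <- sccs_fit(fx$intervals, adjust_age = FALSE, adjust_season = FALSE)
  fit7 <- sccs_fit(scaled, adjust_age = FALSE, adjust_season = FALSE)
  expect_equal(coef(fit7), coef(fit), tolerance = 1e-8)
  expect_equal(vcov(fit7), vcov(fit), tolerance = 1e-8)
})

test_that("uninformative patients are dropped and counted, never fitted", {
  ints <- dplyr::bind_rows(
    toy_fixture("irr3_pair")$intervals,
    mk_ints(pid = "Z", cat = "baseline", len = 400, ev = 1),        # one pattern
    mk_ints(pid = c("Y", "Y"), cat = c("baseline", "exposed"),
            len = c(100, 50), ev = c(0, 0))                          # no event
  )
  fit <- sccs_fit(ints, adjust_age = FALSE, adjust_season = FALSE)
  expect_equal(fit$n_cases_used, 2L)
  expect_equal(fit$n_dropped_noninformative, 1L)
  expect_equal(fit$n_dropped_no_event, 1L)
  expect_equal(unname(exp(coef(fit)["exposed"])), 3, tolerance = 1e-8)
})

test_that("a dataset with no information raises an estimation error", {
  expect_error(sccs_fit(toy_fixture("no_information")$intervals),
               class = "sccs_estimation_error")
})

test_that("complete separation is flagged with a warning, not hidden", {
  ints <- mk_ints(
    pid = c(1, 1, 2, 2),
    cat = rep(c("baseline", "exposed"), 2),
    len = c(300, 100, 300, 100),
    ev  = c(0, 1, 0, 1)  # every event exposed
  )
  expect_warning(fit <- sccs_fit(ints, adjust_age = FALSE, adjust_season = FALSE),
                 "separation")
  expect_true("exposed" %in% fit$separation)
})

test_that("Wald summaries and contrasts follow from the covariance", {
  co <- sim_cohort_cached()
  fit <- pipeline_fit(co)
  wd <- sccs_wald(fit, "exposed")
  b <- coef(fit)[["exposed"]]; se <- sqrt(vcov(fit)["exposed", "exposed"])
  expect_equal(wd$irr, exp(b))
  expect_equal(wd$ci_low, exp(b - qnorm(0.975) * se))
  expect_equal(wd$p_value, 2 * pnorm(-abs(b / se)))
  expect_error(sccs_wald(fit, "nonexistent"), class = "sccs_lookup_error")

  # contrast equals the exposed coefficient after re-basing on pre-exposure
  ctr <- sccs_contrast(fit, "exposed", "pre_exposure")
  ev <- classify_codes(co$events, default_code_map())
  sc <- scenario_config("pre90")
  epi <- build_episodes(co$prescriptions)
  w <- build_windows(co$patients, key_dates(co$prescriptions, ev), sc)
  cases <- select_incident_events(ev, w, sc, default_code_map())
  ints <- sccs_intervals(co$patients, w, epi, cases, sc)
  swapped <- ints
  swapped$category[ints$category == "baseline"] <- "pre_exposure"
  swapped$category[ints$category == "pre_exposure"] <- "baseline"
  refit <- suppressWarnings(sccs_fit(swapped))
  expect_equal(log(ctr$irr), unname(coef(refit)["exposed"]), tolerance = 1e-6)
  expect_equal(ctr$ci_low, exp(unname(coef(refit)["exposed"]) -
                               qnorm(0.975) * sqrt(vcov(refit)["exposed", "exposed"])),
               tolerance = 1e-6)
})

test_that("tidy and glance expose broom-shaped summaries", {
  fit <- sccs_fit(toy_fixture("irr3_pair")$intervals,
                  adjust_age = FALSE, adjust_season = FALSE)
  td <- generics::tidy(fit, exponentiate = TRUE)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value", "conf.low", "conf.high"))
  expect_equal(td$estimate[td$term == "exposed"], 3, tolerance = 1e-8)
  gl <- generics::glance(fit)
  expect_equal(gl$n_cases_used, 2L)
  expect_true(gl$converged)
})
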