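test_that("triad fits match the normal-equations oracle", {
  set.seed(101)
  for (i in 1:5) {
    n <- 12
    x <- rnorm(n); m <- rnorm(n); y <- rnorm(n)
    z <- rep(c(0, 1), each = 6)
    fit <- fit_triad(mediation_triad(x, m, y, z))
    expect_true(fit$ok)

    o1 <- ols_oracle(cbind(1, x, z), y)
    o2 <- ols_oracle(cbind(1, x, z), m)
    o3 <- ols_oracle(cbind(1, m, x, z), y)
    expect_equal(fit$beta1, o1$beta[2], tolerance = 1e-10)
    expect_equal(fit$beta2, o2$beta[2], tolerance = 1e-10)
    expect_equal(fit$beta3, o3$beta[2], tolerance = 1e-10)
    expect_equal(fit$beta4, o3$beta[3], tolerance = 1e-10)
    expect_equal(fit$beta1_se, unname(o1$se[2]), tolerance = 1e-10)
    expect_equal(fit$beta1_p, unname(o1$p[2]), tolerance = 1e-10)
    expect_equal(fit$beta3_p, unname(o3$p[2]), tolerance = 1e-10)

    # OLS nested-model identity: total = direct + indirect
    expect_equal(fit$beta1, fit$beta4 + fit$beta2 * fit$beta3, tolerance = 1e-10)
  }
})

test_that("a (near-)deterministic chain yields the textbook coefficients and gates", {
  # the exactly collinear chain M = X is rank deficient in the outcome
  # model and is flagged, per the error contract
  x0 <- rnorm(12)
  exact <- fit_triad(mediation_triad(x0, x0, x0, rep(c(0, 1), each = 6)))
  expect_false(exact$ok)

  # in the near-deterministic limit the chain gives b1 = b2 = b3 = 1, b4 = 0
  set.seed(102)
  n <- 20
  x <- rnorm(n)
  m <- x + rnorm(n, sd = 1e-6)
  y <- m
  z <- rep(c(0, 1), 10)
  fit <- suppressWarnings(fit_triad(mediation_triad(x, m, y, z)))
  expect_equal(fit$beta1, 1, tolerance = 1e-5)
  expect_equal(fit$beta2, 1, tolerance = 1e-5)
  expect_equal(fit$beta3, 1, tolerance = 1e-5)
  expect_equal(fit$beta4, 0, tolerance = 1e-4)

  gate <- assumption_gate(fit)
  expect_true(attr(gate, "all_pass"))

  eff <- estimate_effects(fit, n_sims = 500, seed = 1)
  expect_equal(eff$acme, 1, tolerance = 1e-4)
  expect_equal(eff$ade, 0, tolerance = 1e-4)
  expect_equal(eff$total, 1, tolerance = 1e-4)
  expect_equal(eff$prop_mediated, 1, tolerance = 1e-4)
})

test_that("collinear exposure and treatment is flagged, not fatal", {
  z <- rep(c(0, 1), each = 6)
  fit <- fit_triad(mediation_triad(x = z, m = rnorm(12), y = rnorm(12), z = z))
  expect_false(fit$ok)
  expect_match(fit$reason, "rank-deficient")
  expect_error(assumption_gate(fit), "skipped")
  expect_error(estimate_effects(fit), "skipped")
})

test_that("the no-mediation boundary fails gate 4 strictly", {
  # y depends on x only: beta4 equals beta1, |beta4| < |beta1| is false
  set.seed(103)
  n <- 40
  x <- rnorm(n); z <- rep(c(0, 1), n / 2)
  y <- 2 * x + rnorm(n, sd = 0.1)
  m <- rnorm(n)  # unrelated mediator
  fit <- fit_triad(mediation_triad(x, m, y, z))
  gate <- assumption_gate(fit)
  # with an unrelated mediator the decomposition forces |beta4| ~ |beta1|;
  # all four passing simultaneously should not happen
  expect_false(gate[["xm"]] && gate[["my"]] && gate[["weakened"]])
})

test_that("ACME + ADE = total on arbitrary fitted triads (OLS identity)", {
  set.seed(104)
  worst <- 0
  for (i in 1:200) {
    n <- 12
    b <- rnorm(4, sd = 2)
    x <- rnorm(n); z <- rep(c(0, 1), each = 6)
    m <- b[1] * x + rnorm(n)
    y <- b[2] * m + b[3] * x + b[4] * z + rnorm(n)
    fit <- fit_triad(mediation_triad(x, m, y, z))
    worst <- max(worst, abs(fit$beta2 * fit$beta3 + fit$beta4 - fit$beta1))
  }
  expect_lt(worst, 1e-10)
})

test_that("effect estimation is reproducible and validates n_sims", {
  set.seed(105)
  x <- rnorm(12); z <- rep(c(0, 1), each = 6)
  m <- 0.8 * x + rnorm(12); y <- 0.8 * m + rnorm(12)
  fit <- fit_triad(mediation_triad(x, m, y, z))
  e1 <- estimate_effects(fit, n_sims = 1000, seed = 42)
  e2 <- estimate_effects(fit, n_sims = 1000, seed = 42)
  expect_identical(e1$acme_ci, e2$acme_ci)
  expect_identical(e1$acme_p, e2$acme_p)
  expect_gte(e1$acme_p, 2 / 1000)
  expect_true(e1$acme_ci[1] <= e1$acme && e1$acme <= e1$acme_ci[2])
  expect_true(e1$total_ci[1] <= e1$total && e1$total <= e1$total_ci[2])
  expect_error(estimate_effects(fit, n_sims = 50), "n_sims")
})

test_that("quasi-Bayesian ACME recovers the simulated product of coefficients", {
  # x ~ N(0,1), m = 0.6 x + e, y = 0.7 m + e', true ACME = 0.42
  set.seed(106)
  reps <- 100
  n <- 200
  est <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(n); z <- sample(rep(c(0, 1), n / 2))
    m <- 0.6 * x + rnorm(n, sd = 0.5)
    y <- 0.7 * m + rnorm(n, sd = 0.5)
    fit <- fit_triad(mediation_triad(x, m, y, z))
    est[i] <- fit$beta2 * fit$beta3
  }
  expect_lt(abs(mean(est) - 0.42), 0.03)
})

test_that("screen_triples handles empty candidates and orders output deterministically", {
  cfg <- synthetic_config(n_per_group = 4, n_genera = 12, n_fecal_mets = 20,
                          n_serum_mets = 10, n_diff_genera = 2, n_diff_fecal = 2,
                          n_diff_serum = 2, n_diff_hormones = 2, seed = 5)
  st <- generate_study(cfg)
  mets <- feature_table(rbind(st$fecal$values, st$serum$values),
                        st$fecal$group, "intensity")

  empty <- suppressMessages(screen_triples(
    st$hormones, st$genera, mets,
    candidates = list(hormones = character(), genera = character(),
                      metabolites = character()),
    seed = 1
  ))
  expect_equal(nrow(empty), 0)

  cands <- list(hormones = c("CRH", "ACTH"), genera = c("genus_001", "genus_002"),
                metabolites = c("fecal_met_0001", "serum_met_0001"))
  res <- screen_triples(st$hormones, st$genera, mets, cands, n_sims = 200, seed = 9)
  expect_equal(nrow(res), 2 * 2 * 2 * 2)
  ord <- order(res$direction, res$x_id, res$m_id, res$y_id)
  expect_equal(ord, seq_len(nrow(res)))
  # per-triad seeds derive from labels: rerun matches exactly
  res2 <- screen_triples(st$hormones, st$genera, mets, cands, n_sims = 200, seed = 9)
  expect_identical(res, res2)
})
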