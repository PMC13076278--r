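make_lpm_data <- function(seed = 301, n_regions = 20, n_years = 12) {
  set.seed(seed)
  cfg <- synth_config(n_regions = n_regions, n_years = n_years, seed = seed)
  g <- generate_panel(cfg)
  st <- g$truth$latent_states
  attr(st, "threshold_spec") <- list(thresholds = c(NA, NA),
                                     scheme = "fixture", n_states = 3)
  list(states = st, covs = generate_covariates(cfg, g$truth),
       groups = two_group_map(sprintf("R%02d", seq_len(n_regions))))
}

test_that("mobility indicators and at-risk accounting are exact", {
  st <- state_panel(matrix(c(1, 2, 3), 1))
  oc <- build_outcomes(st)
  expect_equal(oc$upward, c(1L, 1L))
  expect_equal(oc$downward, c(0L, 0L))

  d <- make_lpm_data()
  oc <- build_outcomes(d$states)
  # top-state origins are not at risk of moving up; the two sets partition
  expect_equal(sum(oc$at_risk_up) + sum(oc$state == 3), nrow(oc))
  expect_equal(sum(oc$at_risk_down) + sum(oc$state == 1), nrow(oc))
  expect_true(all(oc$upward[oc$state == 3] == 0))
})

test_that("upward and downward models use different at-risk samples", {
  d <- make_lpm_data()
  oc <- build_outcomes(d$states)
  up <- fit_lpm(oc, d$covs, "upward", region_groups = d$groups)
  dn <- fit_lpm(oc, d$covs, "downward", region_groups = d$groups)
  expect_equal(up$n_obs, sum(oc$at_risk_up))
  expect_equal(dn$n_obs, sum(oc$at_risk_down))
  expect_false(up$n_obs == dn$n_obs)  # top and bottom occupancy differ
})

test_that("a constant outcome gives zero slopes and zero R-squared", {
  d <- make_lpm_data()
  oc <- build_outcomes(d$states)
  oc$upward <- 0L
  m <- fit_lpm(oc, d$covs, "upward", region_groups = d$groups)
  expect_true(all(abs(m$coefficients$estimate) < 1e-10))
  expect_equal(m$r_squared, 0)
})

test_that("CR1 covariance matches the sandwich cross-check", {
  skip_if_not_installed("sandwich")
  d <- make_lpm_data()
  oc <- build_outcomes(d$states)
  m <- fit_lpm(oc, d$covs, "upward", region_groups = d$groups)
  cl <- merge(oc[oc$at_risk_up, ], d$covs,
              by = c("region_id", "year"))$region_id
  V_ref <- sandwich::vcovCL(m$fit, cluster = cl, type = "HC1",
                            cadjust = TRUE)
  expect_equal(unname(m$vcov), unname(V_ref), tolerance = 1e-8)
})

test_that("singleton clusters reduce CR1 to the HC1 heteroskedastic form", {
  skip_if_not_installed("sandwich")
  set.seed(305)
  n <- 80
  oc <- data.frame(region_id = sprintf("U%03d", 1:n), year = 2001,
                   state = 1L, state_next = 1L,
                   upward = rbinom(n, 1, 0.3), downward = 0L,
                   at_risk_up = TRUE, at_risk_down = FALSE)
  covs <- data.frame(region_id = oc$region_id, year = 2001,
                     doctor_nurse_ratio = rnorm(n), staff_per_10k = rnorm(n),
                     beds_per_staff = rnorm(n), ln_gdp_pc = rnorm(n))
  groups <- two_group_map(oc$region_id)
  m <- fit_lpm(oc, covs, "upward", region_groups = groups)
  V_hc1 <- sandwich::vcovHC(m$fit, type = "HC1")
  expect_equal(unname(m$vcov), unname(V_hc1), tolerance = 1e-8)
})

test_that("row duplication keeps slopes; clustered SEs resist the fake n", {
  d <- make_lpm_data()
  oc <- build_outcomes(d$states)
  m1 <- fit_lpm(oc, d$covs, "upward", region_groups = d$groups)
  oc2 <- rbind(oc, oc)
  m2 <- fit_lpm(oc2, d$covs, "upward", region_groups = d$groups)
  expect_equal(m2$coefficients$estimate, m1$coefficients$estimate,
               tolerance = 1e-8)
  # naive OLS SEs shrink by ~sqrt(2); cluster-robust SEs barely move
  naive1 <- summary(m1$fit)$coefficients["beds_per_staff", "Std. Error"]
  naive2 <- summary(m2$fit)$coefficients["beds_per_staff", "Std. Error"]
  cl1 <- m1$coefficients$se[m1$coefficients$term == "beds_per_staff"]
  cl2 <- m2$coefficients$se[m2$coefficients$term == "beds_per_staff"]
  expect_lt(naive2, 0.75 * naive1)
  expect_gt(cl2, 0.85 * cl1)
})

test_that("slopes are invariant to the fixed-effect reference level", {
  d <- make_lpm_data()
  oc <- build_outcomes(d$states)
  m1 <- fit_lpm(oc, d$covs, "upward", region_groups = d$groups)
  g2 <- d$groups
  g2$group <- factor(g2$group, levels = c("B", "A"))
  m2 <- fit_lpm(oc, d$covs, "upward", region_groups = g2)
  expect_equal(m2$coefficients$estimate, m1$coefficients$estimate,
               tolerance = 1e-9)
  expect_equal(fitted(m2$fit), fitted(m1$fit), tolerance = 1e-9)
})

test_that("collinear covariates and single clusters are rejected", {
  d <- make_lpm_data()
  oc <- build_outcomes(d$states)
  covs <- d$covs
  covs$dup <- covs$beds_per_staff
  expect_error(fit_lpm(oc, covs, "upward",
                       covariate_names = c("beds_per_staff", "dup"),
                       region_groups = d$groups),
               "collinear")
  one <- oc[oc$region_id == "R01", ]
  expect_error(fit_lpm(one, covs, "upward", region_groups = d$groups),
               "clusters")
})

test_that("province fixed effects are available as an alternative", {
  d <- make_lpm_data()
  oc <- build_outcomes(d$states)
  m <- fit_lpm(oc, d$covs, "upward", fe_region = "province")
  expect_true(is.finite(m$r_squared))
  expect_true(all(m$coefficients$se > 0))
})
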