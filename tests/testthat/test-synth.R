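test_that("config validation enforces the latent-process invariants", {
  expect_error(synth_config(true_transition = matrix(c(0.5, 0.4, 0.6, 0.5),
                                                     2, 2, byrow = TRUE),
                            state_inefficiency_levels = c(0.8, 1)),
               "sum to 1")
  expect_error(synth_config(state_inefficiency_levels = c(0.78, 0.9, 0.99)),
               "exactly 1")
  expect_error(synth_config(n_regions = 0), "n_regions")
  expect_silent(synth_config())
})

test_that("a single frontier unit is its own frontier", {
  cfg <- synth_config(n_regions = 1, n_years = 1, noise_sd = 0,
                      true_transition = matrix(1),
                      state_inefficiency_levels = 1, seed = 2)
  g <- generate_panel(cfg)
  expect_equal(g$truth$true_efficiency$efficiency, 1)
  eff <- dea_score_panel(g$panel)
  expect_equal(eff$pte, 1)
  expect_equal(eff$te, 1)
})

test_that("an identity kernel freezes every region's state sequence", {
  cfg <- synth_config(n_regions = 8, n_years = 20, true_transition = diag(3),
                      seed = 21)
  st <- generate_panel(cfg)$truth$latent_states
  per_region <- tapply(st$state, st$region_id, function(s) length(unique(s)))
  expect_true(all(per_region == 1))
})

test_that("identical configs give byte-identical panels, different seeds differ", {
  cfg <- synth_config(n_regions = 6, n_years = 4, seed = 33)
  g1 <- generate_panel(cfg)
  g2 <- generate_panel(cfg)
  expect_identical(g1, g2)
  g3 <- generate_panel(synth_config(n_regions = 6, n_years = 4, seed = 34))
  expect_false(identical(g1$panel, g3$panel))
})

test_that("generated quantities are strictly positive and the panel complete", {
  cfg <- synth_config(n_regions = 9, n_years = 7, seed = 8)
  g <- generate_panel(cfg)
  num <- g$panel[, !(names(g$panel) %in% c("region_id", "year"))]
  expect_true(all(num > 0))
  expect_equal(nrow(g$panel), 63)
  expect_equal(anyDuplicated(g$panel[c("region_id", "year")]), 0L)
})

test_that("latent transition frequencies track the configured kernel", {
  cfg <- synth_config(seed = 7)   # default 31 x 20, published kernel
  st <- generate_panel(cfg)$truth$latent_states
  est <- estimate_transitions(st, n_states = 3)
  expect_gte(est$n_transitions, 31 * 19)
  expect_true(all(abs(est$probabilities - cfg$true_transition) <= 0.08))
})

test_that("long single-region chains reach the analytic stationary shares", {
  cfg <- synth_config(n_regions = 1, n_years = 20000, noise_sd = 0, seed = 13)
  st <- generate_panel(cfg)$truth$latent_states
  freq <- tabulate(st$state, 3) / nrow(st)
  pi_true <- stationary_distribution(cfg$true_transition)$pi
  expect_true(all(abs(freq - pi_true) <= 0.03))
})

test_that("lattice adjacency has the right edge structure", {
  w22 <- generate_adjacency(4, dims = c(2, 2))
  expect_equal(nrow(w22$edges), 4)
  w_line <- generate_adjacency(7, dims = c(1, 7))
  expect_equal(nrow(w_line$edges), 6)

  w <- generate_adjacency(31, dims = c(4, 8))
  deg <- table(c(w$edges$from, w$edges$to))
  expect_equal(length(deg), 31)               # no islands
  expect_true(all(deg >= 2 & deg <= 4))       # rook degrees on a lattice
  expect_equal(length(w$islands), 0)
})

test_that("kernel tilting moves mass between the diagonal and adjacent cells", {
  p <- c(0.1, 0.8, 0.1)
  expect_equal(effdyn:::tilt_row(p, 2, 3, 0.05, 0.02),
               c(0.12, 0.73, 0.15))
  expect_equal(sum(effdyn:::tilt_row(p, 2, 3, 0.5, 0.5)), 1)
  # clipping: an oversized shift empties the diagonal but stays a valid row
  tilted <- effdyn:::tilt_row(p, 2, 3, 0.9, 0.9)
  expect_true(all(tilted >= 0) && abs(sum(tilted) - 1) < 1e-12)
  # bottom state has no downward cell to receive mass
  expect_equal(effdyn:::tilt_row(c(0.9, 0.1, 0), 1, 3, 0, 0.5),
               c(0.9, 0.1, 0))
})

test_that("null covariate effects leave transitions unrelated to covariates", {
  cfg <- synth_config(seed = 55)
  g <- generate_panel(cfg)
  covs <- generate_covariates(cfg, g$truth)
  expect_setequal(names(covs), c("region_id", "year", "doctor_nurse_ratio",
                                 "staff_per_10k", "beds_per_staff",
                                 "ln_gdp_pc"))
  oc <- build_outcomes(g$truth$latent_states)
  m <- fit_lpm(oc, covs, "upward",
               region_groups = two_group_map(unique(covs$region_id)))
  co <- m$coefficients[m$coefficients$term == "beds_per_staff", ]
  expect_lt(abs(co$estimate), 2 * co$se)
})

test_that("configured covariate effects are recoverable from the panel", {
  cfg <- synth_config(seed = 56,
                      covariate_effects = list(
                        upward = c(beds_per_staff = 1.0)))
  g <- generate_panel(cfg)
  covs <- generate_covariates(cfg, g$truth)
  expect_identical(covs, g$truth$covariates)   # stashed, not redrawn
  oc <- build_outcomes(g$truth$latent_states)
  m <- fit_lpm(oc, covs, "upward",
               region_groups = two_group_map(unique(covs$region_id)))
  co <- m$coefficients[m$coefficients$term == "beds_per_staff", ]
  expect_gt(co$estimate, 0)
  expect_lt(abs(co$estimate - 1.0), 2 * co$se)
})
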