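test_that("weights are symmetric, deduplicated, and track islands", {
  w <- spatial_weights(data.frame(from = c("A", "B", "B", "C"),
                                  to = c("B", "A", "C", "C")),
                       regions = c("A", "B", "C", "D"))
  expect_equal(nrow(w$edges), 2)              # A-B once, B-C once, C-C dropped
  expect_equal(w$islands, "D")
  expect_error(spatial_weights(data.frame(from = "A", to = "Z"),
                               regions = "A"), "outside the region set")
})

test_that("spatial lag is the unweighted mean of neighbour states", {
  # star: center X with neighbours N1..N3
  w <- spatial_weights(data.frame(from = "X", to = c("N1", "N2", "N3")))
  st <- state_panel(matrix(c(2, 1, 1, 1), 4, 1))
  st$region_id <- c("X", "N1", "N2", "N3")
  lag <- spatial_lag(st, w)
  expect_equal(lag$lag_value[lag$region_id == "X"], 1)       # unanimous

  st$state <- c(2L, 1L, 2L, 3L)
  expect_equal(spatial_lag(st, w)$lag_value[1], 2)           # mean(1,2,3)

  # islands get NA lags and a logged count
  w2 <- spatial_weights(data.frame(from = "X", to = "N1"),
                        regions = c("X", "N1", "LONE"))
  st2 <- state_panel(matrix(c(1, 2, 3), 3, 1))
  st2$region_id <- c("X", "N1", "LONE")
  expect_message(lag2 <- spatial_lag(st2, w2), "island")
  expect_true(is.na(lag2$lag_value[lag2$region_id == "LONE"]))

  # a region with states but absent from the weights is an error
  st3 <- st2; st3$region_id <- c("X", "N1", "GHOST")
  expect_error(spatial_lag(st3, w2), "GHOST")
})

test_that("same-region scheme lags over group members excluding self", {
  groups <- data.frame(region_id = c("A", "B", "C", "D"),
                       group = c("g1", "g1", "g2", "g2"))
  w <- same_region_weights(groups)
  st <- state_panel(matrix(c(1, 3, 2, 2), 4, 1))
  st$region_id <- c("A", "B", "C", "D")
  lag <- spatial_lag(st, w)
  expect_equal(lag$lag_value, c(3, 1, 2, 2))   # each sees only its groupmate
})

test_that("context assignment cuts pooled lags by terciles", {
  set.seed(71)
  lags <- data.frame(region_id = "A", year = 1:600,
                     lag_value = runif(600, 1, 3))
  ctx <- assign_contexts(lags)
  shares <- tabulate(ctx$context, 3) / 600
  expect_true(all(abs(shares - 1 / 3) < 0.05))

  same <- data.frame(region_id = "A", year = 1:5, lag_value = rep(2, 5))
  expect_warning(ctx2 <- assign_contexts(same), "degenerate")
  expect_equal(length(unique(ctx2$context)), 1)
})

test_that("conditioning on a constant context reproduces the pooled matrix", {
  set.seed(72)
  st <- state_panel(matrix(sample(1:3, 50, TRUE), 5, 10))
  ctx <- data.frame(region_id = st$region_id, year = st$year,
                    lag_value = 2, context = 1L)
  cond <- conditional_transitions(st, ctx)
  pooled <- estimate_transitions(st)
  expect_equal(cond$by_context$context_1$counts, pooled$counts)
  expect_equal(cond$pooled$counts, pooled$counts)
})

test_that("per-context counts sum exactly to the pooled counts", {
  set.seed(73)
  cfg <- synth_config(n_regions = 16, n_years = 10, spatial_coupling = 0.3,
                      seed = 73)
  st <- generate_panel(cfg)$truth$latent_states
  attr(st, "threshold_spec") <- list(thresholds = c(NA, NA),
                                     scheme = "fixture", n_states = 3)
  w <- generate_adjacency(cfg)
  ctx <- assign_contexts(spatial_lag(st, w))
  cond <- conditional_transitions(st, ctx)
  expect_identical(Reduce(`+`, lapply(cond$by_context, `[[`, "counts")),
                   cond$pooled$counts)
  expect_equal(cond$n_dropped, 0)
})

test_that("transitions with undefined origin contexts are dropped, logged", {
  st <- state_panel(matrix(c(1, 2, 2, 3), 2, 2))
  ctx <- data.frame(region_id = st$region_id, year = st$year,
                    lag_value = c(1, 1, NA, NA),
                    context = c(1L, 1L, NA, NA))
  expect_message(cond <- conditional_transitions(st, ctx), "dropped")
  expect_equal(cond$pooled$n_transitions, 1L)
})

test_that("context contrast isolates constructed cell differences", {
  mk <- function(p12) {
    counts <- matrix(20L, 3, 3)
    P <- matrix(c(0.9 - p12, p12, 0, 0.1, 0.8, 0.1, 0, 0.2, 0.8),
                3, 3, byrow = TRUE)
    structure(list(counts = counts, probabilities = P, n_transitions = 180L,
                   undefined_rows = integer(0), n_states = 3L),
              class = "transition_estimate")
  }
  cond <- structure(list(by_context = list(context_1 = mk(0.05),
                                           context_2 = mk(0.15)),
                         pooled = mk(0.10), n_dropped = 0),
                    class = "conditional_transitions")
  cc <- context_contrast(cond)
  key <- cc$key_cells
  expect_equal(key$spread[key$cell == "p12"], 0.10, tolerance = 1e-12)
  expect_equal(key$spread[key$cell == "p23"], 0, tolerance = 1e-12)
  expect_equal(key$spread[key$cell == "p33"], 0, tolerance = 1e-12)

  # identical matrices: all contrasts zero
  cond0 <- structure(list(by_context = list(context_1 = mk(0.1),
                                            context_2 = mk(0.1)),
                          pooled = mk(0.1), n_dropped = 0),
                     class = "conditional_transitions")
  expect_true(all(context_contrast(cond0)$key_cells$spread == 0))
})
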