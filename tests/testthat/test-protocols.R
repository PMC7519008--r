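# small schedules keep the protocol tests fast; the physics-scale checks
# live in test-acceptance.R
fast_schedule <- chain_schedule(2000, 3000, seed = 1)

test_that("sweeps are reproducible bit-for-bit from the master seed", {
  a <- temperature_sweep(c(0.5, 5), J = 1, h = 0, n_nodes = 100, m = 3,
                         n_realizations = 2, schedule = fast_schedule,
                         master_seed = 11)
  b <- temperature_sweep(c(0.5, 5), J = 1, h = 0, n_nodes = 100, m = 3,
                         n_realizations = 2, schedule = fast_schedule,
                         master_seed = 11)
  expect_identical(a$M_per_realization, b$M_per_realization)
  expect_equal(a$M_mean, colMeans(a$M_per_realization))
  expect_true(all(a$M_mean >= 0 & a$M_mean <= 1))
  c <- temperature_sweep(c(0.5, 5), J = 1, h = 0, n_nodes = 100, m = 3,
                         n_realizations = 2, schedule = fast_schedule,
                         master_seed = 12)
  expect_false(identical(a$M_per_realization, c$M_per_realization))
  expect_error(temperature_sweep(c(5, 0.5), n_nodes = 50, m = 2), "ascending")
})

test_that("a one-point field sweep reduces to a run_chain ensemble", {
  sw <- field_sweep(2, J = 1, T = 0.5, n_nodes = 80, m = 3,
                    n_realizations = 3, schedule = fast_schedule,
                    master_seed = 5)
  direct <- vapply(1:3, function(r) {
    net <- ba_network(80, 3, seed = derive_seed(5, r, 0L))
    sch <- fast_schedule
    sch$seed <- derive_seed(5, r, 1L)
    run_chain(net, model_params(1, 2, 0.5), sch)$mean_M
  }, numeric(1))
  expect_equal(as.vector(sw$M_per_realization), direct)
})

test_that("critical-field estimation interpolates the first upward 0.5 crossing", {
  sw <- as_sweep_result("field", c(-1, 0, 1, 2), c(0, 0, 1, 1))
  expect_equal(estimate_critical_field(sw), 0.5)
  # exact grid hit is returned as-is (tie toward the lower h)
  sw2 <- as_sweep_result("field", c(0, 1, 2), c(0, 0.5, 1))
  expect_equal(estimate_critical_field(sw2), 1)
  sw3 <- as_sweep_result("field", c(0, 1, 2), c(0.99, 0.99, 1))
  expect_error(estimate_critical_field(sw3), "no transition")
  sw4 <- as_sweep_result("temperature", c(1, 2), c(0.2, 0.8))
  expect_error(estimate_critical_field(sw4), "field sweep")
})

test_that("hysteresis branches retrace the field grid and close at high T", {
  net <- ba_network(150, 3, seed = 2)
  loop <- hysteresis_loop(net, J = 1, T = 100, h_start = 5, h_end = -5,
                          n_points = 11, schedule = fast_schedule, seed = 3)
  expect_identical(loop$h_backward, rev(loop$h_forward))
  expect_gte(loop$loop_area, 0)
  # no memory far above the ordering temperature
  expect_lt(loop$loop_area, 0.1 * 10)
})

test_that("hysteresis memory fades as temperature grows", {
  net <- ba_network(150, 3, seed = 4)
  areas <- vapply(c(0.1, 100), function(T)
    hysteresis_loop(net, J = 1, T = T, h_start = 6, h_end = -6,
                    n_points = 25, schedule = fast_schedule,
                    seed = 5)$loop_area, numeric(1))
  expect_gt(areas[1], areas[2])
  expect_gt(areas[1], 1) # cold loop encloses a macroscopic area
})

test_that("Monte Carlo temperature curves track the mean-field solution", {
  # ferromagnetic: agreement across the full temperature range
  T_grid <- exp(seq(log(0.2), log(100), length.out = 8))
  sw <- temperature_sweep(T_grid, J = 1, h = 0, n_nodes = 500, m = 5,
                          n_realizations = 3,
                          schedule = chain_schedule(10000, 20000),
                          master_seed = 21)
  deg <- ba_network(500, 5, seed = derive_seed(21, 1, 0L))$degree
  mf <- vapply(T_grid, function(T)
    mf_fixed_point(deg, 1, 0, T, start_M = 1)$M, numeric(1))
  expect_true(all(abs(sw$M_mean - mf) < 0.1))
  # antiferromagnetic: the annealed approximation is reliable at T >= 1
  # (at lower T it misses the entropy of the degenerate independent-set
  # ground states and underestimates M)
  T_af <- c(1, 3, 10, 100)
  sw_af <- temperature_sweep(T_af, J = -1, h = 0, n_nodes = 500, m = 5,
                             n_realizations = 3,
                             schedule = chain_schedule(10000, 20000),
                             master_seed = 22)
  deg_af <- ba_network(500, 5, seed = derive_seed(22, 1, 0L))$degree
  mf_af <- vapply(T_af, function(T)
    mf_fixed_point(deg_af, -1, 0, T, start_M = 0)$M, numeric(1))
  expect_true(all(abs(sw_af$M_mean - mf_af) < 0.1))
})

test_that("the critical-field scan pairs MC estimates with the analytic line", {
  sc <- critical_field_scan("J", c(0.5, 1), m = 3, n_nodes = 200, T = 0.1,
                            n_realizations = 2,
                            schedule = chain_schedule(5000, 10000),
                            master_seed = 9)
  expect_identical(sc$h_c_analytic, c(0.5 * 3, 1 * 3))
  expect_true(all(is.finite(sc$h_c_mc)))
  expect_true(all(sc$h_c_mc <= sc$h_c_analytic + 1))
  expect_error(critical_field_scan("J", c(2, 1)), "ascending")
})

test_that("sweep and loop results export to tidy CSV", {
  sw <- field_sweep(c(-1, 1), J = 1, T = 1, n_nodes = 60, m = 2,
                    n_realizations = 2, schedule = fast_schedule,
                    master_seed = 2)
  s_path <- withr::local_tempfile(fileext = ".csv")
  p_path <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(sw, s_path, p_path)
  s_df <- read.csv(s_path)
  expect_identical(names(s_df), c("field", "M_mean", "M_stderr"))
  expect_equal(nrow(s_df), 2)
  p_df <- read.csv(p_path)
  expect_equal(nrow(p_df), 4)

  net <- ba_network(60, 2, seed = 1)
  loop <- hysteresis_loop(net, 1, 1, 2, -2, n_points = 5,
                          schedule = fast_schedule, seed = 1)
  l_path <- withr::local_tempfile(fileext = ".csv")
  write_hysteresis_csv(loop, l_path)
  l_df <- read.csv(l_path)
  expect_identical(names(l_df), c("branch", "h", "M"))
  expect_equal(nrow(l_df), 10)
})
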