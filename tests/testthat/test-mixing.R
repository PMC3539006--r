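pair_unequal <- end_members(d15N_M = -4, d15N_P = -16, N_M = 1, N_P = 4)

test_that("nitrogen fractions weight biomass by nitrogen content", {
  expect_equal(nitrogen_fractions(1, pair_unequal)$f_M_N, 1)
  expect_equal(nitrogen_fractions(0, pair_unequal)$f_M_N, 0)
  eq <- end_members(-4, -16, 2, 2)
  expect_equal(nitrogen_fractions(0.5, eq)$f_M_N, 0.5)
  fr <- nitrogen_fractions(0.9, pair_unequal)
  expect_equal(fr$f_M_N, 0.9 / 1.3)  # 0.6923...
  expect_equal(fr$f_P_N, 1 - 0.9 / 1.3)
  expect_error(nitrogen_fractions(1.2, pair_unequal), "\\[0, 1\\]")
  expect_error(nitrogen_fractions(-0.1, pair_unequal), "\\[0, 1\\]")
})

test_that("forward model hits end points and the equal-concentration linear limit", {
  expect_equal(forward_d15N(1, pair_unequal), -4)
  expect_equal(forward_d15N(0, pair_unequal), -16)
  eq <- end_members(-4, -16, 3, 3)
  f <- seq(0, 1, by = 0.1)
  expect_equal(forward_d15N(f, eq), f * -4 + (1 - f) * -16)
  expect_equal(forward_d15N(0.9, pair_unequal), -100 / 13)  # -7.6923...
})

test_that("forward model is bounded and strictly monotone between distinct end-members", {
  f <- seq(0, 1, by = 0.01)
  d <- forward_d15N(f, pair_unequal)
  expect_true(all(d >= -16 & d <= -4))
  expect_true(all(diff(d) > 0))  # d15N_M > d15N_P => increasing in f_M_B
  flipped <- end_members(-16, -4, 1, 4)
  expect_true(all(diff(forward_d15N(f, flipped)) < 0))
})

test_that("closed-form inversion is the algebraic inverse of the forward model", {
  expect_equal(closed_form_f_M_B(-100 / 13, pair_unequal), 0.9)
  expect_equal(closed_form_f_M_B(-16, pair_unequal), 0)
  expect_equal(closed_form_f_M_B(-4, pair_unequal), 1)
  # beyond the mycobiont end-member: unclamped value exceeds 1
  expect_gt(closed_form_f_M_B(-3, pair_unequal), 1)
  expect_lt(closed_form_f_M_B(-17, pair_unequal), 0)
  expect_error(closed_form_f_M_B(-5, end_members(-4, -4, 1, 4)),
               "unidentifiable")
})

test_that("iterative inversion converges and round-trips the forward model", {
  s <- invert_f_M_B(-100 / 13, pair_unequal)
  expect_equal(s$status, "converged")
  expect_lt(abs(s$f_M_B - 0.9), 1e-8)
  expect_lt(abs(s$residual), 1e-10)
  expect_equal(s$f_M_B + s$f_P_B, 1)
  expect_equal(s$f_M_N + s$f_P_N, 1)

  s_end <- invert_f_M_B(-4, pair_unequal)
  expect_equal(s_end$f_M_B, 1)
  expect_equal(s_end$status, "converged")

  for (f_true in seq(0, 1, by = 0.01)) {
    s <- invert_f_M_B(forward_d15N(f_true, pair_unequal), pair_unequal)
    expect_lt(abs(s$f_M_B - f_true), 1e-8)
  }
})

test_that("observations outside the end-member interval clamp with explicit status", {
  s_hi <- invert_f_M_B(-3, pair_unequal)  # beyond mycobiont
  expect_equal(s_hi$status, "clamped_high")
  expect_equal(s_hi$f_M_B, 1)
  expect_equal(s_hi$residual, -3 - (-4))
  s_lo <- invert_f_M_B(-17.5, pair_unequal)  # beyond photobiont
  expect_equal(s_lo$status, "clamped_low")
  expect_equal(s_lo$f_M_B, 0)
  expect_lt(s_lo$residual, 0)
  expect_error(invert_f_M_B(-5, end_members(-4, -4, 1, 4)), "unidentifiable")
})

test_that("iterative and closed-form paths agree over random valid systems", {
  set.seed(42)
  for (i in 1:1000) {
    pair <- random_end_members()
    obs <- forward_d15N(stats::runif(1), pair)
    f_it <- invert_f_M_B(obs, pair)$f_M_B
    f_cf <- min(max(closed_form_f_M_B(obs, pair), 0), 1)
    expect_lt(abs(f_it - f_cf), 1e-8)
  }
})

test_that("model outputs are invariant to the nitrogen-content scale", {
  set.seed(7)
  for (c_scale in c(1e-6, 0.37, 1, 1e6)) {
    pair <- end_members(-4.2, -15.7, 0.818, 3.488)
    scaled <- end_members(-4.2, -15.7, 0.818 * c_scale, 3.488 * c_scale)
    f <- seq(0, 1, by = 0.05)
    expect_lt(max(abs(forward_d15N(f, pair) - forward_d15N(f, scaled))), 1e-12)
    obs <- -9.7
    expect_lt(abs(invert_f_M_B(obs, pair)$f_M_B -
                    invert_f_M_B(obs, scaled)$f_M_B), 1e-12)
    expect_lt(abs(closed_form_f_M_B(obs, pair) -
                    closed_form_f_M_B(obs, scaled)), 1e-12)
  }
})

test_that("mixing lines span the end-members on an even grid", {
  ml2 <- mixing_line(pair_unequal, n_points = 2)
  expect_equal(ml2$f_M_B, c(0, 1))
  expect_equal(ml2$d15N_L, c(-16, -4))
  ml <- mixing_line(pair_unequal, n_points = 101)
  expect_equal(ml$d15N_L[1], -16)
  expect_equal(ml$d15N_L[101], -4)
  expect_true(all(diff(ml$d15N_L) > 0))
  # equal concentrations: straight line, zero second differences
  straight <- mixing_line(end_members(-4, -16, 2, 2), n_points = 11)
  expect_equal(max(abs(diff(diff(straight$d15N_L)))), 0, tolerance = 1e-12)
  # curvature example: f = 0.5 with N_P = 4 N_M pulls toward the photobiont
  curve <- mixing_line(end_members(0, -10, 1, 4), n_points = 3)
  expect_equal(curve$d15N_L[2], -8)
  expect_error(mixing_line(pair_unequal, n_points = 1), "at least 2")
})

test_that("population partitioning recovers noise-free fractions and summarises by substrate", {
  cfg <- generator_config(n_populations = 8, measurement_noise_sd = 0, seed = 3)
  sim <- generate_triplets(cfg)
  res <- partition_populations(sim$triplets)
  joined <- merge(res$solutions, sim$truth, by = "population_id")
  expect_lt(max(abs(joined$f_M_B - joined$true_f_M_B)), 1e-8)
  expect_equal(sort(res$summary$substrate_class), c("minerogenic", "organic"))
  expect_equal(sum(res$summary$n), 8)
  expect_true(all(res$summary$n_clamped == 0))
  expect_equal(res$solutions$f_M_B + res$solutions$f_P_B, rep(1, 8))
  expect_equal(res$solutions$f_M_N + res$solutions$f_P_N, rep(1, 8))
})

test_that("identical triplets give zero spread and unidentifiable ones are reported", {
  trip <- group_triplets(make_population_records(3))
  trip$d15N_L <- -9
  trip$d15N_P <- -16
  trip$d15N_M <- -5
  res <- partition_populations(trip)
  expect_equal(res$summary$sd_f_M_B[res$summary$substrate_class == "organic"], 0)

  trip$d15N_M[1] <- trip$d15N_P[1]
  res2 <- partition_populations(trip)
  expect_equal(res2$unidentifiable$population_id, trip$population_id[1])
  expect_equal(nrow(res2$solutions), 2)
})

test_that("partition and mixing-line CSV exports round-trip", {
  sim <- generate_triplets(generator_config(n_populations = 4, seed = 5))
  res <- partition_populations(sim$triplets)
  dir <- withr::local_tempdir()
  write_partition(res, file.path(dir, "part.csv"))
  expect_true(file.exists(file.path(dir, "part_summary.csv")))
  sols <- readr::read_csv(file.path(dir, "part.csv"), show_col_types = FALSE)
  expect_equal(nrow(sols), 4)
  write_mixing_lines(sim$triplets, file.path(dir, "lines.csv"), n_points = 11)
  lines <- readr::read_csv(file.path(dir, "lines.csv"), show_col_types = FALSE)
  expect_equal(nrow(lines), 44)
  ends <- lines[lines$f_M_B == 1, ]
  expect_equal(ends$d15N_L, sim$triplets$d15N_M[match(ends$population_id,
                                                      sim$triplets$population_id)])
})
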