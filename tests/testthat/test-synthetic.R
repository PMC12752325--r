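test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(n_participants = 0), "n_participants")
  expect_error(sim_config(fps = -1), "fps")
  expect_error(sim_config(trunk_coupling = 1.5), "trunk_coupling")
  expect_error(sim_config(fma_ue_range = c(10, 80)), "fma_ue_range")
  expect_error(sim_config(frame_size = c(1920, 0)), "frame_size")
})

test_that("the default protocol arithmetic is 200/1000/5000 movements", {
  pc <- protocol_counts(sim_config())
  expect_equal(pc$movements_per_block, 200L)
  expect_equal(pc$movements_per_session, 1000L)
  expect_equal(pc$movements_total, 5000L)
})

test_that("identical config and seed reproduce the cohort bit for bit", {
  cfg <- sim_config(n_participants = 2, days = 2, blocks_per_day = 2,
                    movements_per_block = 6, seed = 61)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$truth$blocks, b$truth$blocks)
  for (i in seq_along(a$series)) {
    expect_identical(a$series[[i]]$data, b$series[[i]]$data)
  }
  c2 <- simulate_cohort(sim_config(n_participants = 2, days = 2,
                                   blocks_per_day = 2,
                                   movements_per_block = 6, seed = 62))
  expect_false(identical(a$series[[1]]$data, c2$series[[1]]$data))
})

test_that("disabling all variability gives constant proximal tracks and zero BVE", {
  cfg <- sim_config(n_participants = 1, days = 1, blocks_per_day = 1,
                    movements_per_block = 10, jitter_sd = 0,
                    trunk_coupling = 0, shoulder_coupling = 0,
                    participant_sd = 0, seed = 63)
  sim <- simulate_cohort(cfg)
  s <- sim$series[[1]]
  tr <- trunk_track(s)
  sh <- shoulder_track(s, sim$participants$paretic_side[1])
  expect_equal(diff(range(tr$x)), 0)
  expect_equal(diff(range(tr$y)), 0)
  expect_equal(bve(tr), 0)
  expect_equal(bve(sh), 0)
  expect_equal(sim$truth$blocks$true_bve_trunk, 0)
  expect_equal(sim$truth$blocks$true_bve_shoulder, 0)
})

test_that("noise-free pipeline outcomes equal the generator ground truth", {
  cfg <- sim_config(n_participants = 2, days = 2, blocks_per_day = 1,
                    movements_per_block = 8, jitter_sd = 0, seed = 64)
  sim <- simulate_cohort(cfg)
  summ <- summarize_cohort(sim$series, sim$participants)
  joined <- dplyr::inner_join(summ, sim$truth$blocks,
                              by = c("participant_id", "day", "block"))
  expect_equal(joined$bve_palm, joined$true_bve_palm, tolerance = 1e-9)
  expect_equal(joined$bve_shoulder, joined$true_bve_shoulder,
               tolerance = 1e-9)
  expect_equal(joined$bve_trunk, joined$true_bve_trunk, tolerance = 1e-9)
  expect_equal(joined$mean_speed_palm, joined$true_mean_speed_palm,
               tolerance = 1e-9)
  expect_equal(joined$n_frames.x, joined$n_frames.y)
})

test_that("frame accounting: dwell frames add movements x dwell per block", {
  base <- sim_config(n_participants = 1, days = 1, blocks_per_day = 1,
                     movements_per_block = 12, seed = 65)
  with_dwell <- sim_config(n_participants = 1, days = 1, blocks_per_day = 1,
                           movements_per_block = 12, dwell_frames = 3,
                           seed = 65)
  n0 <- simulate_cohort(base)$truth$blocks$n_frames
  n3 <- simulate_cohort(with_dwell)$truth$blocks$n_frames
  expect_equal(n3, n0 + 12L * 3L)
})

test_that("the analytic mean-speed oracle matches its closed form and the pipeline", {
  # single reach of amplitude A and duration T: path A, speed A*f/(ceil(T*f)-1)
  cfg1 <- sim_config(n_participants = 1, days = 1, blocks_per_day = 1,
                     movements_per_block = 1,
                     reach_amplitude = c(80, 0), reach_duration = c(1, 0),
                     jitter_sd = 0, day_speed_gain = 1, seed = 66)
  sim1 <- simulate_cohort(cfg1)
  exp1 <- expected_mean_speed(sim1$truth, "S01", 1)
  f <- cfg1$fps
  expect_equal(unname(exp1), 80 * f / (ceiling(1 * f) - 1))

  # pipeline agreement within 1% on a full noise-free block
  cfg <- sim_config(n_participants = 1, days = 2, blocks_per_day = 1,
                    movements_per_block = 50, jitter_sd = 0,
                    day_speed_gain = 1, seed = 67)
  sim <- simulate_cohort(cfg)
  for (i in seq_along(sim$series)) {
    s <- sim$series[[i]]
    measured <- mean_speed(palm_track(s))
    oracle <- expected_mean_speed(sim$truth, s$participant_id, s$day, s$block)
    expect_equal(unname(measured), unname(oracle), tolerance = 0.01)
  }

  # day_speed_gain = 1 keeps the expectation's distribution identical across
  # days (amplitudes/durations are fresh draws, so compare via path stats)
  tb <- sim$truth$blocks
  expect_equal(tb$path_length[tb$day == 1] / tb$n_frames[tb$day == 1],
               tb$path_length[tb$day == 2] / tb$n_frames[tb$day == 2],
               tolerance = 0.15)

  with_noise <- simulate_cohort(sim_config(n_participants = 1, days = 1,
                                           blocks_per_day = 1,
                                           movements_per_block = 2,
                                           jitter_sd = 1, seed = 68))
  expect_error(expected_mean_speed(with_noise$truth, "S01", 1),
               "jitter")
})

test_that("stationary palm BVE converges to the sqrt(2) * jitter_sd floor", {
  sigma <- 3
  cfg <- sim_config(n_participants = 1, days = 1, blocks_per_day = 1,
                    movements_per_block = 700,
                    reach_amplitude = c(0, 0), reach_duration = c(1, 0),
                    jitter_sd = sigma, trunk_coupling = 0,
                    shoulder_coupling = 0, participant_sd = 0, seed = 69)
  sim <- simulate_cohort(cfg)
  s <- sim$series[[1]]
  expect_gte(n_frames(s), 20000L)
  expect_equal(bve(palm_track(s)), sqrt(2) * sigma, tolerance = 0.02)
  # single-landmark effector has the same floor
  expect_equal(bve(shoulder_track(s, sim$participants$paretic_side[1])),
               sqrt(2) * sigma, tolerance = 0.02)
  # trunk averages four independently jittered landmarks: floor halves
  expect_equal(bve(trunk_track(s)), sqrt(2) * sigma / 2, tolerance = 0.02)
})

test_that("measured trunk BVE increases strictly with trunk coupling", {
  vals <- c(0.05, 0.15, 0.3, 0.5)
  bves <- vapply(vals, function(tc) {
    cfg <- sim_config(n_participants = 1, days = 1, blocks_per_day = 1,
                      movements_per_block = 40, trunk_coupling = tc,
                      participant_sd = 0, fma_ue_range = c(50, 50),
                      seed = 70)
    sim <- simulate_cohort(cfg)
    bve(trunk_track(sim$series[[1]]))
  }, numeric(1))
  expect_true(all(diff(bves) > 0))
})

test_that("measured palm speed increases strictly with day speed gain", {
  gains <- c(1, 1.05, 1.15, 1.3)
  speeds <- vapply(gains, function(g) {
    cfg <- sim_config(n_participants = 1, days = 3, blocks_per_day = 1,
                      movements_per_block = 40, day_speed_gain = g,
                      jitter_sd = 0, seed = 71)
    sim <- simulate_cohort(cfg)
    day3 <- Filter(function(s) s$day == 3, sim$series)[[1]]
    mean_speed(palm_track(day3))
  }, numeric(1))
  expect_true(all(diff(speeds) > 0))
})

test_that("trunk coupling correlates negatively with FMA-UE across a cohort", {
  cfg <- sim_config(n_participants = 60, days = 1, blocks_per_day = 1,
                    movements_per_block = 1, seed = 72)
  sim <- simulate_cohort(cfg)
  tp <- sim$truth$participants
  expect_lt(cor(tp$fma_ue, tp$trunk_coupling), 0)
  expect_lt(cor(tp$fma_ue, tp$shoulder_coupling), 0)
})

test_that("per-reach speed ground truth follows the minimum-jerk closed forms", {
  cfg <- sim_config(n_participants = 1, days = 1, blocks_per_day = 1,
                    movements_per_block = 1, reach_amplitude = c(100, 0),
                    reach_duration = c(1, 0), jitter_sd = 0,
                    day_speed_gain = 1, seed = 73)
  tb <- simulate_cohort(cfg)$truth$blocks
  expect_equal(tb$mean_reach_mean_speed, 100)        # A / T
  expect_equal(tb$mean_reach_peak_speed, 187.5)      # 1.875 * A / T
})

test_that("min_jerk is a monotone 0-to-1 position fraction", {
  tau <- seq(0, 1, by = 0.01)
  s <- min_jerk(tau)
  expect_equal(s[1], 0)
  expect_equal(s[length(s)], 1)
  expect_true(all(diff(s) >= 0))
  expect_error(min_jerk(c(0.5, 1.2)))
})
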