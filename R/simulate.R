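#' Minimum-jerk position fraction
#'
#' The canonical smooth point-to-point reach profile: at normalized time
#' `tau = t/T` in \[0, 1\] the fraction of the movement completed is
#' `10*tau^3 - 15*tau^4 + 6*tau^5`.
#'
#' @param tau Numeric vector in \[0, 1\].
#' @return Numeric vector of position fractions in \[0, 1\].
#' @export
min_jerk <- function(tau) {
  stopifnot(all(tau >= 0 & tau <= 1))
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Simulation configuration
#'
#' Parameters of the synthetic reaching-session generator. Defaults mirror a
#' multi-session gamified reaching protocol: 5 days, 5 blocks per day, 200
#' target-directed paretic-arm movements per block (so 1000 per session and
#' 5000 across the protocol), sampled at 30 Hz in a 1920x1080 pixel frame.
#'
#' @param n_participants Number of simulated participants (default 7).
#' @param days Number of practice sessions (default 5).
#' @param blocks_per_day Blocks per session (default 5).
#' @param movements_per_block Reaches per block (default 200).
#' @param fps Sampling rate in Hz (default 30).
#' @param frame_size `c(width, height)` in pixels (default 1920x1080).
#' @param reach_amplitude `c(mean, sd)` of reach amplitude in pixels.
#' @param reach_duration `c(mean, sd)` of reach duration in seconds.
#' @param jitter_sd SD (pixels) of isotropic Gaussian landmark measurement
#'   noise. Noise is applied per rigid landmark group: the three hand
#'   landmarks share one draw per frame (pose errors on adjacent keypoints
#'   are strongly correlated), while elbow, each shoulder and each hip get
#'   independent draws.
#' @param trunk_coupling Fraction in \[0, 1\] of the reach displacement
#'   contributed by trunk lean (compensation strength).
#' @param shoulder_coupling Fraction in \[0, 1\] of additional paretic
#'   shoulder excursion beyond the trunk motion.
#' @param day_speed_gain Multiplicative per-day change in reach speed
#'   (durations are divided by `day_speed_gain^(day-1)`).
#' @param participant_sd Relative between-participant SD of the coupling
#'   fractions (multiplicative Gaussian variation).
#' @param fma_ue_range Integer interval within \[0, 66\] from which FMA-UE
#'   scores are drawn; couplings correlate negatively with FMA-UE (more
#'   impaired participants compensate more).
#' @param dwell_frames Stationary frames inserted after each reach
#'   (default 0).
#' @param seed Integer RNG seed; identical configurations (including seed)
#'   produce identical output.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_participants = 7L, days = 5L, blocks_per_day = 5L,
                       movements_per_block = 200L, fps = 30,
                       frame_size = c(1920L, 1080L),
                       reach_amplitude = c(mean = 120, sd = 25),
                       reach_duration = c(mean = 0.8, sd = 0.15),
                       jitter_sd = 2,
                       trunk_coupling = 0.15, shoulder_coupling = 0.25,
                       day_speed_gain = 1.05, participant_sd = 0.3,
                       fma_ue_range = c(40L, 66L),
                       dwell_frames = 0L, seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              days = as.integer(days),
              blocks_per_day = as.integer(blocks_per_day),
              movements_per_block = as.integer(movements_per_block),
              fps = as.numeric(fps),
              frame_size = as.numeric(frame_size),
              reach_amplitude = as.numeric(reach_amplitude),
              reach_duration = as.numeric(reach_duration),
              jitter_sd = as.numeric(jitter_sd),
              trunk_coupling = as.numeric(trunk_coupling),
              shoulder_coupling = as.numeric(shoulder_coupling),
              day_speed_gain = as.numeric(day_speed_gain),
              participant_sd = as.numeric(participant_sd),
              fma_ue_range = as.integer(fma_ue_range),
              dwell_frames = as.integer(dwell_frames),
              seed = as.integer(seed))
  chk <- function(ok, field) {
    if (!ok) stop("invalid simulation config field: ", field, call. = FALSE)
  }
  chk(cfg$n_participants >= 1L, "n_participants")
  chk(cfg$days >= 1L, "days")
  chk(cfg$blocks_per_day >= 1L, "blocks_per_day")
  chk(cfg$movements_per_block >= 1L, "movements_per_block")
  chk(is.finite(cfg$fps) && cfg$fps > 0, "fps")
  chk(length(cfg$frame_size) == 2L && all(cfg$frame_size > 0), "frame_size")
  chk(length(cfg$reach_amplitude) == 2L && all(cfg$reach_amplitude >= 0),
      "reach_amplitude")
  chk(length(cfg$reach_duration) == 2L && cfg$reach_duration[1] > 0 &&
        cfg$reach_duration[2] >= 0, "reach_duration")
  chk(cfg$jitter_sd >= 0, "jitter_sd")
  chk(cfg$trunk_coupling >= 0 && cfg$trunk_coupling <= 1, "trunk_coupling")
  chk(cfg$shoulder_coupling >= 0 && cfg$shoulder_coupling <= 1,
      "shoulder_coupling")
  chk(cfg$day_speed_gain > 0, "day_speed_gain")
  chk(cfg$participant_sd >= 0, "participant_sd")
  chk(length(cfg$fma_ue_range) == 2L && cfg$fma_ue_range[1] >= 0 &&
        cfg$fma_ue_range[2] <= 66 &&
        cfg$fma_ue_range[1] <= cfg$fma_ue_range[2], "fma_ue_range")
  chk(cfg$dwell_frames >= 0L, "dwell_frames")
  chk(!is.na(cfg$seed), "seed")
  structure(cfg, class = "sim_config")
}

#' Protocol movement counts
#'
#' Movement arithmetic implied by a simulation configuration: movements per
#' block, per session (blocks x movements), and across the full protocol
#' (days x sessions). With the defaults this is 200 / 1000 / 5000.
#'
#' @param config A [sim_config()].
#' @return A one-row tibble: `movements_per_block`, `movements_per_session`,
#'   `movements_total`.
#' @export
protocol_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  per_session <- config$movements_per_block * config$blocks_per_day
  tibble::tibble(movements_per_block = config$movements_per_block,
                 movements_per_session = per_session,
                 movements_total = per_session * config$days)
}

# fixed body offsets (pixels): hand offsets sum to zero so the palm centroid
# of pinky/index/wrist equals the simulated palm path exactly when jitter = 0;
# torso offsets average to zero about the trunk centre.
hand_offsets <- list(pinky = c(-8, 6), index = c(9, 4), wrist = c(-1, -10))
torso_offsets <- list(shoulder_left = c(-90, -130),
                      shoulder_right = c(90, -130),
                      hip_left = c(-70, 130), hip_right = c(70, 130))

# palm path of one block: alternating out-and-back minimum-jerk reaches from
# a home position to random targets. Returns the path, per-movement analytic
# amplitudes/durations and the frame count.
sim_block_path <- function(config, home, speed_factor) {
  M <- config$movements_per_block
  n_out <- ceiling(M / 2)
  A_out <- pmax(stats::rnorm(n_out, config$reach_amplitude[1],
                             config$reach_amplitude[2]), 0)
  theta <- stats::runif(n_out, -pi, pi)
  targets <- cbind(home[1] + A_out * cos(theta), home[2] + A_out * sin(theta))
  # movement m endpoints: odd m reaches out to target (m+1)/2, even m returns
  ends <- matrix(0, M, 2)
  amps <- numeric(M)
  for (m in seq_len(M)) {
    if (m %% 2L == 1L) {
      k <- (m + 1L) %/% 2L
      ends[m, ] <- targets[k, ]
      amps[m] <- A_out[k]
    } else {
      ends[m, ] <- home
      amps[m] <- A_out[m %/% 2L]
    }
  }
  dur <- pmax(stats::rnorm(M, config$reach_duration[1],
                           config$reach_duration[2]),
              2 / config$fps) / speed_factor
  n_m <- pmax(ceiling(dur * config$fps), 1L)
  starts <- rbind(matrix(home, 1, 2), ends[-M, , drop = FALSE])
  seg <- rep(seq_len(M), n_m)
  tau <- sequence(n_m) / rep(n_m, n_m)
  s <- min_jerk(tau)
  px <- starts[seg, 1] + (ends[seg, 1] - starts[seg, 1]) * s
  py <- starts[seg, 2] + (ends[seg, 2] - starts[seg, 2]) * s
  if (config$dwell_frames > 0L) {
    # insert dwell_frames stationary frames after each movement
    move_end <- cumsum(n_m)
    idx <- unlist(lapply(seq_len(M), function(m) {
      c(seq.int(move_end[m] - n_m[m] + 1L, move_end[m]),
        rep(move_end[m], config$dwell_frames))
    }))
    px <- px[idx]; py <- py[idx]
  }
  list(path = cbind(px, py), amps = amps, dur = dur,
       n_frames = length(px),
       n_frames_moving = sum(n_m))
}

#' Simulate a multi-session reaching cohort
#'
#' Generates landmark time series for a cohort performing a block-structured
#' reaching protocol, together with participant metadata and an analytic
#' ground-truth record. Each movement takes the palm from its current
#' position to a random target along a minimum-jerk profile ([min_jerk()]),
#' alternating out-and-back about a home position. The trunk centroid
#' translates toward the target by `trunk_coupling` times the reach
#' displacement (its own minimum-jerk profile), and the paretic shoulder
#' adds a further `shoulder_coupling` fraction on top of the trunk motion.
#' The eight landmarks sit at fixed body offsets from these effectors and
#' are perturbed by isotropic Gaussian jitter (`jitter_sd`); `day_speed_gain`
#' scales reach speed across days; coupling fractions vary across
#' participants and correlate negatively with their FMA-UE score.
#'
#' The ground truth records, per block, the noise-free BVE of the palm,
#' paretic-shoulder and trunk effector paths, the exact noise-free mean palm
#' speed, the analytic straight-line path length, and the jitter-only BVE
#' floor for a stationary effector (`sqrt(2) * jitter_sd` for palm and
#' shoulder, `sqrt(2)/2 * jitter_sd` for the trunk, whose four landmarks
#' jitter independently).
#'
#' @param config A [sim_config()].
#' @return A list with elements `series` (list of [landmark_series()]),
#'   `participants` (metadata tibble as from [read_participants()]), and
#'   `truth` (list with `participants`, `blocks` tibbles and the `config`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  ids <- sprintf("S%02d", seq_len(n))
  fma <- if (config$fma_ue_range[1] == config$fma_ue_range[2])
    rep(config$fma_ue_range[1], n) else
    sample(seq(config$fma_ue_range[1], config$fma_ue_range[2]), n,
           replace = TRUE)
  span <- diff(config$fma_ue_range)
  impairment <- if (span == 0) rep(0.5, n) else
    (config$fma_ue_range[2] - fma) / span
  trunk_c <- clamp01(config$trunk_coupling * (0.5 + impairment) *
                       pmax(1 + config$participant_sd * stats::rnorm(n), 0))
  shoulder_c <- clamp01(config$shoulder_coupling * (0.5 + impairment) *
                          pmax(1 + config$participant_sd * stats::rnorm(n), 0))
  participants <- validate_participants(tibble::tibble(
    participant_id = ids,
    age = sample(62:85, n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE),
    time_since_stroke_months = sample(3:260, n, replace = TRUE),
    hemisphere = sample(c("L", "R"), n, replace = TRUE),
    fma_ue = fma))

  width <- config$frame_size[1]; height <- config$frame_size[2]
  trunk0 <- c(0.30 * width, 0.55 * height)
  home <- trunk0 + c(0.115 * width, -0.11 * height)

  series <- list()
  blocks <- list()
  k <- 0L
  for (p in seq_len(n)) {
    paretic <- participants$paretic_side[p]
    par_sh <- if (paretic == "L") "shoulder_left" else "shoulder_right"
    for (d in seq_len(config$days)) {
      speed_factor <- config$day_speed_gain^(d - 1)
      for (b in seq_len(config$blocks_per_day)) {
        bp <- sim_block_path(config, home, speed_factor)
        nf <- bp$n_frames
        rel <- cbind(bp$path[, 1] - home[1], bp$path[, 2] - home[2])
        trunk_disp <- trunk_c[p] * rel
        shoulder_extra <- shoulder_c[p] * rel

        clean <- list()
        for (lm in names(hand_offsets)) {
          clean[[lm]] <- cbind(bp$path[, 1] + hand_offsets[[lm]][1],
                               bp$path[, 2] + hand_offsets[[lm]][2])
        }
        for (lm in names(torso_offsets)) {
          pos <- cbind(trunk0[1] + torso_offsets[[lm]][1] + trunk_disp[, 1],
                       trunk0[2] + torso_offsets[[lm]][2] + trunk_disp[, 2])
          if (lm == par_sh) {
            pos <- pos + shoulder_extra
          }
          clean[[lm]] <- pos
        }
        clean$elbow <- (clean[[par_sh]] + bp$path) / 2

        # ground truth from the noise-free effector paths
        pbve <- function(m) {
          sqrt(mean((m[, 1] - mean(m[, 1]))^2 + (m[, 2] - mean(m[, 2]))^2))
        }
        trunk_true <- Reduce(`+`, clean[names(torso_offsets)]) / 4
        steps <- sqrt(diff(bp$path[, 1])^2 + diff(bp$path[, 2])^2)
        blocks[[length(blocks) + 1L]] <- tibble::tibble(
          participant_id = ids[p], day = d, block = b,
          n_frames = nf,
          path_length = sum(bp$amps),
          true_bve_palm = pbve(bp$path),
          true_bve_shoulder = pbve(clean[[par_sh]]),
          true_bve_trunk = pbve(trunk_true),
          true_mean_speed_palm = if (nf >= 2)
            sum(steps) * config$fps / (nf - 1) else 0,
          mean_reach_peak_speed = mean(1.875 * bp$amps / bp$dur),
          mean_reach_mean_speed = mean(bp$amps / bp$dur))

        # measurement noise: rigid hand group shares a draw, others independent
        if (config$jitter_sd > 0) {
          jit <- function() matrix(stats::rnorm(2 * nf, 0, config$jitter_sd),
                                   nf, 2)
          hand_j <- jit()
          for (lm in names(hand_offsets)) clean[[lm]] <- clean[[lm]] + hand_j
          for (lm in c("elbow", names(torso_offsets))) {
            clean[[lm]] <- clean[[lm]] + jit()
          }
        }

        cols <- list(frame = seq_len(nf))
        for (lm in landmark_names()) {
          cols[[paste0(lm, "_x")]] <- clean[[lm]][, 1]
          cols[[paste0(lm, "_y")]] <- clean[[lm]][, 2]
          cols[[paste0(lm, "_v")]] <- rep(1, nf)
        }
        k <- k + 1L
        series[[k]] <- landmark_series(ids[p], d, b, config$fps,
                                       tibble::as_tibble(cols))
      }
    }
  }
  truth <- list(
    participants = tibble::tibble(participant_id = ids, fma_ue = fma,
                                  trunk_coupling = trunk_c,
                                  shoulder_coupling = shoulder_c,
                                  paretic_side = participants$paretic_side),
    blocks = dplyr::bind_rows(blocks),
    config = config)
  list(series = series, participants = participants, truth = truth)
}

#' Analytic mean palm speed of a noise-free simulated block
#'
#' Closed-form oracle for the generator: for jitter-free reaches the palm's
#' path length is the sum of the straight-line reach amplitudes (the
#' minimum-jerk profile is monotone along a straight segment), so the mean
#' framewise speed is `path_length * fps / (n_frames - 1)`.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result whose
#'   configuration had `jitter_sd = 0`.
#' @param participant_id,day Which block(s) to evaluate.
#' @param block Optional block number; all blocks of the day if `NULL`.
#' @return Named numeric vector of expected mean speeds (pixels/second), one
#'   per block.
#' @export
expected_mean_speed <- function(truth, participant_id, day, block = NULL) {
  if (truth$config$jitter_sd != 0) {
    stop("expected_mean_speed is only defined for jitter-free simulations ",
         "(jitter_sd = 0)", call. = FALSE)
  }
  rows <- truth$blocks[truth$blocks$participant_id == participant_id &
                         truth$blocks$day == day, ]
  if (!is.null(block)) rows <- rows[rows$block %in% block, ]
  if (nrow(rows) == 0L) {
    stop("no simulated block matches the requested participant/day/block",
         call. = FALSE)
  }
  stats::setNames(
    rows$path_length * truth$config$fps / (rows$n_frames - 1),
    paste0("block", rows$block))
}

#' Simulate an analysis table with known model parameters
#'
#' Generates a long analysis table in the format of [build_model_table()]
#' directly from a known linear mixed-effects data-generating process, for
#' validating [fit_lme()] (parameter recovery, confidence-interval coverage,
#' variance-component estimation). The outcome is
#' `X beta + b_participant + b_participant_day + noise` with independent
#' Gaussian random intercepts.
#'
#' @param n_participants Number of participants.
#' @param beta Named vector of true fixed effects; names must be
#'   `intercept`, `day`, `block`, `bve_trunk`, `bve_shoulder`, `fma_ue`,
#'   `day_block`, `trunk_shoulder` (treatment coding, second level = 1).
#' @param tau_participant,tau_day Variances of the participant and
#'   day-within-participant random intercepts.
#' @param sigma Residual SD.
#' @param days,blocks Grid levels (defaults `c(1, 5)`).
#' @param seed RNG seed.
#' @return A tibble with columns `participant_id`, `day`, `block` (factors),
#'   `bve_palm`, `mean_speed_palm` (both set to the simulated outcome),
#'   `bve_trunk`, `bve_shoulder`, `fma_ue`, plus attribute `truth` echoing
#'   the generating parameters.
#' @export
simulate_model_table <- function(n_participants = 50L,
                                 beta = c(intercept = 50, day = -6,
                                          block = 1, bve_trunk = 1.5,
                                          bve_shoulder = 3.5, fma_ue = 2,
                                          day_block = -1.5,
                                          trunk_shoulder = -0.1),
                                 tau_participant = 25, tau_day = 4,
                                 sigma = 5,
                                 days = c(1L, 5L), blocks = c(1L, 5L),
                                 seed = 1L) {
  needed <- c("intercept", "day", "block", "bve_trunk", "bve_shoulder",
              "fma_ue", "day_block", "trunk_shoulder")
  stopifnot(setequal(names(beta), needed))
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n_participants))
  fma <- sample(30:66, n_participants, replace = TRUE)
  b_p <- stats::rnorm(n_participants, 0, sqrt(tau_participant))
  grid <- expand.grid(participant_id = ids, day = days, block = blocks,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$participant_id, grid$day, grid$block), ]
  b_pd <- stats::rnorm(n_participants * length(days), 0, sqrt(tau_day))
  names(b_pd) <- apply(expand.grid(ids, days), 1, paste, collapse = ".")
  out <- tibble::tibble(
    participant_id = grid$participant_id,
    day = factor(paste("Day", grid$day), levels = paste("Day", days)),
    block = factor(paste("Block", grid$block),
                   levels = paste("Block", blocks)),
    bve_trunk = abs(stats::rnorm(nrow(grid), 10, 4)),
    bve_shoulder = abs(stats::rnorm(nrow(grid), 22, 8)),
    fma_ue = fma[match(grid$participant_id, ids)])
  day_i <- as.integer(out$day == levels(out$day)[2])
  block_i <- as.integer(out$block == levels(out$block)[2])
  mu <- beta[["intercept"]] + beta[["day"]] * day_i +
    beta[["block"]] * block_i +
    beta[["bve_trunk"]] * out$bve_trunk +
    beta[["bve_shoulder"]] * out$bve_shoulder +
    beta[["fma_ue"]] * out$fma_ue +
    beta[["day_block"]] * day_i * block_i +
    beta[["trunk_shoulder"]] * out$bve_trunk * out$bve_shoulder
  y <- mu + b_p[match(out$participant_id, ids)] +
    b_pd[paste(out$participant_id, grid$day, sep = ".")] +
    stats::rnorm(nrow(out), 0, sigma)
  out$bve_palm <- y
  out$mean_speed_palm <- y
  attr(out, "truth") <- list(beta = beta, tau_participant = tau_participant,
                             tau_day = tau_day, sigma = sigma)
  out
}
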