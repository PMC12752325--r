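test_that("a minimal well-formed file reads into one series", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- expand.grid(frame = 1:2, landmark = landmark_names(),
                      stringsAsFactors = FALSE)
  df <- data.frame(participant_id = "P1", day = 1L, block = 1L,
                   frame = rows$frame, fps = 30,
                   landmark = rows$landmark,
                   x = seq_len(nrow(rows)), y = seq_len(nrow(rows)) + 0.5,
                   visibility = 1)
  write.csv(df, path, row.names = FALSE)
  out <- read_landmark_csv(path)
  expect_length(out, 1L)
  expect_s3_class(out[[1]], "landmark_series")
  expect_equal(n_frames(out[[1]]), 2L)
  expect_equal(out[[1]]$fps, 30)
})

test_that("malformed landmark CSVs raise named validation errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  base <- data.frame(participant_id = "P1", day = 1L, block = 1L,
                     frame = 1L, fps = 30, landmark = "pinky",
                     x = 1, y = 2, visibility = 1)

  bad <- base
  bad$landmark <- "nose"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_landmark_csv(path), "nose")

  write.csv(base[setdiff(names(base), "visibility")], path,
            row.names = FALSE)
  expect_error(read_landmark_csv(path), "visibility")

  rows <- expand.grid(frame = 1:2, landmark = landmark_names(),
                      stringsAsFactors = FALSE)
  varying <- data.frame(participant_id = "P1", day = 1L, block = 1L,
                        frame = rows$frame, fps = ifelse(rows$frame == 1, 30, 60),
                        landmark = rows$landmark, x = 1, y = 2,
                        visibility = 1)
  write.csv(varying, path, row.names = FALSE)
  expect_error(read_landmark_csv(path), "fps is not constant")

  expect_error(read_landmark_csv(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("write/read round trip is the identity on a simulated session", {
  cfg <- sim_config(n_participants = 2, days = 2, blocks_per_day = 1,
                    movements_per_block = 5, seed = 11)
  sim <- simulate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmark_csv(sim$series, path)

  # row count: frames x 8 landmarks per series
  n_rows <- length(readLines(path)) - 1L
  expect_equal(n_rows, sum(vapply(sim$series, n_frames, integer(1))) * 8L)

  back <- read_landmark_csv(path)
  expect_length(back, length(sim$series))
  key <- function(s) paste(s$participant_id, s$day, s$block)
  back <- back[match(vapply(sim$series, key, character(1)),
                     vapply(back, key, character(1)))]
  for (i in seq_along(sim$series)) {
    expect_equal(back[[i]]$fps, sim$series[[i]]$fps)
    expect_equal(as.data.frame(back[[i]]$data),
                 as.data.frame(sim$series[[i]]$data), tolerance = 1e-12)
  }
})

test_that("an empty collection writes a header-only file", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmark_csv(list(), path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_match(lines, "^participant_id,day,block,frame,fps,landmark,x,y,visibility$")
  expect_length(read_landmark_csv(path), 0L)
})

test_that("adapt_pose33 resolves the paretic side and scales to pixels", {
  frame33 <- function(i) {
    list(frame = i,
         landmarks = data.frame(x = seq(0, 0.32, by = 0.01),
                                y = seq(0.5, 0.82, by = 0.01),
                                visibility = 1))
  }
  raw <- lapply(1:3, frame33)
  info_l <- make_info("P1", paretic = "L")
  info_r <- make_info("P1", paretic = "R")
  s_l <- adapt_pose33(raw, info_l, fps = 30, width = 100, height = 200)
  s_r <- adapt_pose33(raw, info_r, fps = 30, width = 100, height = 200)
  # left pinky is source index 17, right is 18 (0-based): x = 0.17 vs 0.18
  expect_equal(s_l$data$pinky_x, rep(0.17 * 100, 3))
  expect_equal(s_r$data$pinky_x, rep(0.18 * 100, 3))
  # shoulders are side-fixed regardless of paretic side
  expect_equal(s_l$data$shoulder_left_x, s_r$data$shoulder_left_x)
  # normalized (x, y) scales by (width, height)
  expect_equal(s_l$data$wrist_y, rep((0.5 + 0.15) * 200, 3))

  expect_error(adapt_pose33(raw, info_l, 30, width = 0, height = 200),
               "positive")
})

test_that("adapt_pose33 reproduces an injected shoulder signal", {
  set.seed(4)
  n <- 40
  sx <- 0.3 + cumsum(rnorm(n, 0, 0.002))
  sy <- 0.4 + cumsum(rnorm(n, 0, 0.002))
  raw <- lapply(seq_len(n), function(i) {
    lms <- data.frame(x = rep(0.5, 33), y = rep(0.5, 33), visibility = 1)
    lms$x[12] <- sx[i]  # 0-based index 11 = left shoulder
    lms$y[12] <- sy[i]
    list(frame = i, landmarks = lms)
  })
  s <- adapt_pose33(raw, make_info("P1", paretic = "L"), fps = 30,
                    width = 1920, height = 1080)
  tr <- shoulder_track(s, "L")
  expect_equal(tr$x, sx * 1920, tolerance = 1e-12)
  expect_equal(tr$y, sy * 1080, tolerance = 1e-12)
})

test_that("adapt_pose33 flags frames with missing keypoints as invisible", {
  lms_full <- data.frame(x = rep(0.5, 33), y = rep(0.5, 33), visibility = 1)
  lms_short <- lms_full[1:10, ]  # wrists, pinkies etc. absent
  raw <- list(list(frame = 1, landmarks = lms_full),
              list(frame = 2, landmarks = lms_short))
  s <- adapt_pose33(raw, make_info("P1"), fps = 30, width = 100, height = 100)
  expect_equal(s$data$pinky_v, c(1, 0))
  pre <- preprocess(s, visibility_threshold = 0.5, max_gap = 0)
  expect_equal(pre$data$frame, 1L)
})

test_that("JSON-lines pose records read back frame by frame", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  rec <- function(i) jsonlite::toJSON(
    list(frame = i,
         landmarks = data.frame(x = rep(0.1 * i, 33), y = rep(0.2, 33),
                                visibility = rep(1, 33))),
    auto_unbox = TRUE, digits = NA)
  writeLines(vapply(1:3, function(i) as.character(rec(i)), character(1)),
             path)
  raw <- read_pose33_jsonl(path)
  expect_length(raw, 3L)
  expect_equal(raw[[2]]$frame, 2)
  expect_equal(raw[[3]]$landmarks$x[1], 0.3)
})

test_that("preprocess is a no-op on fully visible series and threshold 0", {
  s <- make_series(list(pinky = cbind(1:10, 1:10)), fps = 30)
  expect_identical(preprocess(s)$data, s$data)
  low <- make_series(list(pinky = cbind(1:10, 1:10)),
                     visibility = list(pinky = rep(0.1, 10)))
  expect_identical(preprocess(low, visibility_threshold = 0)$data, low$data)
})

test_that("preprocess interpolates short gaps at the midpoint", {
  vis <- rep(1, 5); vis[3] <- 0.2
  s <- make_series(list(wrist = cbind(c(0, 10, 999, 30, 40),
                                      c(0, 2, -50, 6, 8))),
                   visibility = list(wrist = vis))
  out <- preprocess(s, visibility_threshold = 0.5, max_gap = 1)
  expect_equal(out$data$wrist_x[3], 20)  # midpoint of 10 and 30
  expect_equal(out$data$wrist_y[3], 4)
  expect_equal(out$n_interpolated, 1L)
  expect_equal(out$n_dropped, 0L)
})

test_that("preprocess drops long gaps and never invents frames", {
  vis <- rep(1, 8); vis[3:5] <- 0
  s <- make_series(list(elbow = cbind(1:8, 1:8)),
                   visibility = list(elbow = vis))
  out <- preprocess(s, visibility_threshold = 0.5, max_gap = 2)
  expect_equal(out$data$frame, c(1L, 2L, 6L, 7L, 8L))
  expect_equal(out$n_dropped, 3L)
  expect_true(all(out$data$frame %in% s$data$frame))
  all_bad <- make_series(list(elbow = cbind(1:4, 1:4)),
                         visibility = list(elbow = rep(0, 4)))
  expect_error(preprocess(all_bad, 0.5, 0), "all .* frames dropped")
})

test_that("randomized masking conserves frames: kept + dropped = input", {
  set.seed(21)
  n <- 400
  vis <- list()
  for (lm in landmark_names()) {
    v <- rep(1, n)
    v[runif(n) < 0.05] <- 0.1
    vis[[lm]] <- v
  }
  s <- make_series(list(pinky = cbind(cumsum(rnorm(n)), cumsum(rnorm(n)))),
                   n = n, visibility = vis)
  out <- preprocess(s, visibility_threshold = 0.5, max_gap = 3)
  expect_equal(nrow(out$data) + out$n_dropped, n)
  vmat <- as.matrix(out$data[paste0(landmark_names(), "_v")])
  expect_true(all(vmat >= 0.5))
  xy <- as.matrix(out$data[grep("_(x|y)$", names(out$data))])
  expect_false(anyNA(xy))
})

test_that("participant metadata derives the paretic side and validates FMA-UE", {
  info <- example_participants()
  expect_equal(nrow(info), 7L)
  expect_true(all(info$paretic_side != info$hemisphere))
  expect_true(all(info$fma_ue >= 0 & info$fma_ue <= 66))

  path <- withr::local_tempfile(fileext = ".csv")
  bad <- utils::read.csv(system.file("extdata", "participants.csv",
                                     package = "reachkin"))
  bad$fma_ue[1] <- 70
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_participants(path), "fma_ue")
})
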