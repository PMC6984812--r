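test_that("looming annuli expand linearly and a new one starts every 125 ms", {
  tr <- visual_annulus_trajectories(looming_visual_spec())
  expect_length(tr, 4L)
  expect_equal(vapply(tr, `[[`, numeric(1), "onset_ms"), c(0, 125, 250, 375))
  for (a in tr) {
    expect_equal(a$radius(0), 0.25)
    expect_equal(a$t_max_s, (3.88 - 0.25) / 15.52, tolerance = 1e-12)
    # annulus removed once it reaches the maximum radius
    expect_true(is.na(a$radius(a$t_max_s + 0.01)))
    expect_equal(a$radius(0.1), 0.25 + 15.52 * 0.1)
  }
  expect_error(looming_visual_spec(speed_deg_per_s = -1), "positive")
  expect_error(looming_visual_spec(start_radius_deg = 4), "smaller")
})

test_that("looming sound ramps frequency by two thirds and amplitude exponentially", {
  spec <- looming_sound_spec(base_amplitude = 2)
  tones <- auditory_looming_trajectories(spec)
  expect_length(tones, 14L)
  f440 <- tones[[which(spec$base_frequencies_hz == 440)]]
  expect_equal(f440$frequency(0.5), 440 * 5 / 3, tolerance = 1e-12)
  expect_equal(f440$amplitude(0), 2 - 1)
  expect_equal(f440$amplitude(0.5), 2 * exp(0.34) - 1, tolerance = 1e-12)
  expect_error(looming_sound_spec(base_frequencies_hz = c(200, 100)),
               "increasing")
})

test_that("run design has 18 pseudorandomized blocks per run with SOA-exact stimuli", {
  d <- build_run_design(rng_seed = 3)
  expect_equal(nrow(d$blocks), 4 * 18)
  expect_equal(d$stimuli_per_block, 50L)
  per_run <- table(d$blocks$run, d$blocks$condition)
  expect_true(all(per_run == 3))
  # 12 blocks per condition per participant over 4 runs
  expect_true(all(table(d$blocks$condition) == 12))
  # day mapping: runs 1-2 on day 1, runs 3-4 on day 2
  expect_equal(unique(d$blocks$day[d$blocks$run <= 2]), 1)
  expect_equal(unique(d$blocks$day[d$blocks$run >= 3]), 2)
  ons <- stimulus_onsets(d)
  one_block <- ons[ons$run == 1 & ons$block == 1, ]
  expect_equal(nrow(one_block), 50L)
  expect_equal(unique(round(diff(one_block$onset), 10)), 0.66)
  # fixations interleave: consecutive block onsets 49 s apart
  expect_equal(unique(diff(d$blocks$onset[d$blocks$run == 1])), 49)
  expect_equal(d$run_duration_s, 18 * 49 + 20)
})

test_that("identical seeds give identical timelines; different seeds differ", {
  a <- build_run_design(rng_seed = 10)
  b <- build_run_design(rng_seed = 10)
  c <- build_run_design(rng_seed = 11)
  expect_identical(a$blocks, b$blocks)
  expect_false(identical(a$blocks$condition, c$blocks$condition))
  s1 <- schedule_targets(a, rng_seed = 4)
  s2 <- schedule_targets(a, rng_seed = 4)
  expect_identical(s1, s2)
})

test_that("target schedule gives 16 per modality per condition with a 2:1 block split", {
  d <- build_run_design(rng_seed = 1)
  for (seed in c(1, 22, 333)) {
    s <- schedule_targets(d, rng_seed = seed)
    counts <- table(s$condition, s$modality)
    expect_true(all(counts == 16))
    # 8 single + 4 double blocks per condition and modality
    per_block <- stats::aggregate(
      onset ~ run + block + condition + modality, data = s, FUN = length)
    split <- table(per_block$condition, per_block$onset)
    expect_true(all(split[, "1"] == 2 * 8))   # 8 blocks x 2 modalities
    expect_true(all(split[, "2"] == 2 * 4))
    # onsets in the final half of their block, separated by >= 1 s
    blk <- merge(as.data.frame(s), as.data.frame(d$blocks),
                 by = c("run", "block", "condition", "day"))
    expect_true(all(blk$onset.x >= blk$onset.y + blk$duration / 2))
    expect_true(all(blk$onset.x < blk$onset.y + blk$duration))
    seps <- stats::aggregate(onset ~ run + block, data = s,
                             FUN = function(o) if (length(o) > 1) min(diff(sort(o))) else Inf)
    expect_true(all(seps$onset >= 1))
  }
})

test_that("an empty design yields an empty target schedule", {
  d0 <- build_run_design(design_params(n_runs = 0))
  s0 <- schedule_targets(d0)
  expect_s3_class(s0, "target_schedule")
  expect_equal(nrow(s0), 0L)
})

test_that("response windows extend 2.5 s or until the next target", {
  mk <- function(onsets, modality = "A", cond = "A_AttA") {
    s <- tibble::tibble(run = 1L, day = 1L, block = 1L, condition = cond,
                        modality = modality, onset = onsets)
    class(s) <- c("target_schedule", class(s))
    s
  }
  # single target, press inside the window
  sc <- score_responses(mk(10), 11.0)
  expect_equal(sum(sc$n_responded), 1L)
  expect_equal(attr(sc, "extra_responses"), 0L)
  # press after the window closes: an extra-response
  sc <- score_responses(mk(10), 13.0)
  expect_equal(sum(sc$n_responded), 0L)
  expect_equal(attr(sc, "extra_responses"), 1L)
  # the next target truncates the first window
  sc <- score_responses(mk(c(10, 11)), 11.2)
  expect_equal(sum(sc$n_responded), 1L)
  expect_equal(attr(sc, "extra_responses"), 0L)
  # a press before any target is an extra-response, not an error
  sc <- score_responses(mk(10), c(2.0, 10.5))
  expect_equal(attr(sc, "extra_responses"), 1L)
})

test_that("every press is a hit of exactly one target or an extra-response", {
  d <- build_run_design(rng_seed = 2)
  s <- schedule_targets(d, rng_seed = 2)
  withr::with_seed(42, {
    presses <- data.frame(run = sample(1:4, 300, replace = TRUE),
                          time = runif(300, 0, d$run_duration_s))
  })
  sc <- score_responses(s, presses)
  expect_true(all(sc$pct_responded >= 0 & sc$pct_responded <= 100))
  expect_equal(sum(sc$n_targets), nrow(s))
  # hits + extras account for all presses (multiple presses can hit one
  # target, so count assigned presses directly)
  win_hits <- nrow(presses) - attr(sc, "extra_responses")
  expect_gte(win_hits, sum(sc$n_responded))
  expect_equal(attr(sc, "n_presses"), nrow(presses))
})

test_that("timeline exports as a BIDS-style events table", {
  d <- build_run_design(rng_seed = 1)
  s <- schedule_targets(d, rng_seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  ev <- write_events_tsv(d, s, run = 1, path = path)
  back <- utils::read.delim(path)
  expect_equal(names(back), c("onset", "duration", "trial_type"))
  expect_equal(nrow(back), nrow(ev))
  expect_equal(sum(grepl("^block_", back$trial_type)), 18L)
})
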