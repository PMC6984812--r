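#' Timing and counting parameters of the block design
#'
#' Defaults reproduce the experiment's constants: 33 s stimulation blocks of
#' 50 looming stimuli at a fixed 660 ms onset asynchrony, preceded by 16 s
#' fixation with a 3 s attention cue, 3 blocks per condition per run, 4 runs
#' split over 2 days, and a final 20 s fixation.
#'
#' @param block_s stimulation block duration, seconds.
#' @param fixation_s fixation period before each block, seconds.
#' @param cue_lead_s attention-cue lead time before block onset, seconds.
#' @param final_fixation_s fixation after the last block, seconds.
#' @param soa_s stimulus onset asynchrony within a block, seconds.
#' @param blocks_per_condition_per_run repetitions of each condition per run.
#' @param n_runs number of runs.
#' @param runs_per_day runs acquired per scanning day.
#' @return a named list of validated parameters.
#' @export
design_params <- function(block_s = 33, fixation_s = 16, cue_lead_s = 3,
                          final_fixation_s = 20, soa_s = 0.66,
                          blocks_per_condition_per_run = 3, n_runs = 4,
                          runs_per_day = 2) {
  stopifnot_positive(block_s = block_s, fixation_s = fixation_s,
                     soa_s = soa_s, runs_per_day = runs_per_day)
  if (cue_lead_s < 0 || final_fixation_s < 0) {
    stop("cue_lead_s and final_fixation_s must be non-negative", call. = FALSE)
  }
  if (cue_lead_s > fixation_s) {
    stop("cue must fall inside the preceding fixation period", call. = FALSE)
  }
  if (blocks_per_condition_per_run < 0 || n_runs < 0) {
    stop("block and run counts must be non-negative", call. = FALSE)
  }
  list(block_s = block_s, fixation_s = fixation_s, cue_lead_s = cue_lead_s,
       final_fixation_s = final_fixation_s, soa_s = soa_s,
       blocks_per_condition_per_run = blocks_per_condition_per_run,
       n_runs = n_runs, runs_per_day = runs_per_day)
}

#' Build the block timeline of a whole experiment
#'
#' Block order within each run is a seeded pseudorandom permutation
#' constrained to `blocks_per_condition_per_run` occurrences of each of the 6
#' conditions.  Runs 1..`runs_per_day` map to day 1, the next to day 2, and so
#' on.  Stimulus onsets within a block are exactly SOA-spaced, with
#' `floor(block_s / soa_s)` stimuli per block.
#'
#' @param params a [design_params()] list.
#' @param rng_seed integer seed; identical seeds give identical timelines.
#' @return an object of class `run_design`: `params`, `stimuli_per_block`,
#'   `run_duration_s`, and `blocks`, a tibble with one row per block (run,
#'   day, block index within run, condition, onset, duration).
#' @export
build_run_design <- function(params = design_params(), rng_seed = 1L) {
  stimuli_per_block <- floor(params$block_s / params$soa_s + 1e-9)
  labels <- rep(CONDITIONS, params$blocks_per_condition_per_run)
  n_blocks <- length(labels)
  blocks <- with_rng_seed(rng_seed, {
    out <- vector("list", params$n_runs)
    for (run in seq_len(params$n_runs)) {
      order <- if (n_blocks > 0) sample(labels) else character(0)
      onsets <- params$fixation_s +
        (seq_len(n_blocks) - 1) * (params$fixation_s + params$block_s)
      run_col <- rep(run, n_blocks)
      day_col <- rep(ceiling(run / params$runs_per_day), n_blocks)
      out[[run]] <- tibble::tibble(
        run = run_col,
        day = day_col,
        block = seq_len(n_blocks),
        condition = order,
        onset = onsets,
        duration = rep(params$block_s, n_blocks))
    }
    do.call(rbind, out)
  })
  if (is.null(blocks)) {
    blocks <- tibble::tibble(run = integer(), day = integer(),
                             block = integer(), condition = character(),
                             onset = double(), duration = double())
  }
  run_duration <- if (n_blocks > 0) {
    n_blocks * (params$fixation_s + params$block_s) + params$final_fixation_s
  } else 0
  structure(list(params = params, blocks = blocks,
                 stimuli_per_block = stimuli_per_block,
                 run_duration_s = run_duration),
            class = "run_design")
}

#' @export
print.run_design <- function(x, ...) {
  cat(sprintf("<run_design> %d run(s) x %d blocks, %d stimuli/block, %.0f s/run\n",
              x$params$n_runs, nrow(x$blocks) / max(1, x$params$n_runs),
              x$stimuli_per_block, x$run_duration_s))
  invisible(x)
}

#' Stimulus onsets of every block in a design
#'
#' @param design a [build_run_design()] object.
#' @return a tibble (run, block, condition, stimulus index, onset in seconds).
#' @export
stimulus_onsets <- function(design) {
  stopifnot(inherits(design, "run_design"))
  b <- design$blocks
  k <- design$stimuli_per_block
  if (nrow(b) == 0 || k == 0) {
    return(tibble::tibble(run = integer(), block = integer(),
                          condition = character(), stimulus = integer(),
                          onset = double()))
  }
  tibble::tibble(
    run = rep(b$run, each = k),
    block = rep(b$block, each = k),
    condition = rep(b$condition, each = k),
    stimulus = rep(seq_len(k), nrow(b)),
    onset = rep(b$onset, each = k) +
      rep((seq_len(k) - 1) * design$params$soa_s, nrow(b)))
}

#' Schedule the auditory and visual targets of an experiment
#'
#' Per condition, two thirds of its blocks receive exactly one target of each
#' modality and the remaining third exactly two of each (16 per modality per
#' condition for the default 12 blocks).  Target onsets are drawn uniformly
#' from the final half of the block (targets cluster at the end of blocks),
#' with at least `min_sep_s` between any two targets of the same block.
#'
#' @param design a [build_run_design()] object.
#' @param rng_seed integer seed.
#' @param min_sep_s minimum separation between targets within a block.
#' @return a tibble of class `target_schedule` (run, day, block, condition,
#'   modality, onset).
#' @export
schedule_targets <- function(design, rng_seed = 1L, min_sep_s = 1) {
  stopifnot(inherits(design, "run_design"))
  blocks <- design$blocks
  if (nrow(blocks) == 0) {
    out <- tibble::tibble(run = integer(), day = integer(), block = integer(),
                          condition = character(), modality = character(),
                          onset = double())
    class(out) <- c("target_schedule", class(out))
    return(out)
  }
  dur <- design$params$block_s
  ## up to 4 targets must fit the final half of the block with min_sep gaps
  if (dur / 2 < 3 * min_sep_s) {
    stop("block too short to place targets with the requested separation",
         call. = FALSE)
  }
  with_rng_seed(rng_seed, {
    rows <- list()
    for (cond in unique(blocks$condition)) {
      idx <- which(blocks$condition == cond)
      nb <- length(idx)
      n_double <- round(nb / 3)
      dbl <- if (n_double > 0) sample(idx, n_double) else integer(0)
      for (i in idx) {
        per_mod <- if (i %in% dbl) 2L else 1L
        k <- 2L * per_mod
        repeat {
          ons <- sort(runif(k, blocks$onset[i] + dur / 2,
                            blocks$onset[i] + dur - 1e-6))
          if (k == 1L || min(diff(ons)) >= min_sep_s) break
        }
        mods <- sample(rep(c("A", "V"), per_mod))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          run = blocks$run[i], day = blocks$day[i], block = blocks$block[i],
          condition = cond, modality = mods, onset = ons)
      }
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$run, out$onset), ]
    class(out) <- c("target_schedule", class(out))
    out
  })
}

#' Score button presses against the target schedule
#'
#' The response window of a target extends from its onset for `window_s`
#' seconds or until the next target (of either modality) in the same run,
#' whichever comes first.  Every press falls in at most one window; presses
#' outside all windows are extra-responses.  A target counts as responded if
#' at least one press falls in its window.
#'
#' @param schedule a [schedule_targets()] tibble.
#' @param presses a data frame of button presses (columns `run`, `time`), or a
#'   numeric vector of times for a single-run log.
#' @param window_s maximal response window, seconds.
#' @return an object of class `behavioral_score`: a tibble with one row per
#'   (target modality x attended modality x block modality) cell giving
#'   `n_targets`, `n_responded` and `pct_responded`, with attributes
#'   `extra_responses` (count) and `n_presses`.
#' @export
score_responses <- function(schedule, presses, window_s = 2.5) {
  if (is.numeric(presses)) presses <- data.frame(run = 1L, time = presses)
  stopifnot(all(c("run", "time") %in% names(presses)))
  sch <- as.data.frame(schedule)
  sch$responded <- FALSE
  assigned <- rep(FALSE, nrow(presses))
  for (run in unique(sch$run)) {
    tidx <- which(sch$run == run)
    tidx <- tidx[order(sch$onset[tidx])]
    ons <- sch$onset[tidx]
    ends <- pmin(ons + window_s, c(ons[-1], Inf))
    pidx <- which(presses$run == run)
    for (j in seq_along(tidx)) {
      inwin <- pidx[presses$time[pidx] >= ons[j] & presses$time[pidx] < ends[j]]
      if (length(inwin) > 0) {
        sch$responded[tidx[j]] <- TRUE
        assigned[inwin] <- TRUE
      }
    }
  }
  sch$target_modality <- sch$modality
  sch$attended <- condition_attention(sch$condition)
  sch$block_modality <- condition_modality(sch$condition)
  cells <- expand.grid(target_modality = c("A", "V"),
                       attended = c("AttA", "AttV"),
                       block_modality = c("A", "V", "AV"),
                       stringsAsFactors = FALSE)
  score <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- sch$target_modality == cells$target_modality[i] &
      sch$attended == cells$attended[i] &
      sch$block_modality == cells$block_modality[i]
    n <- sum(sel)
    r <- sum(sch$responded[sel])
    tibble::tibble(target_modality = cells$target_modality[i],
                   attended = cells$attended[i],
                   block_modality = cells$block_modality[i],
                   n_targets = n, n_responded = r,
                   pct_responded = if (n > 0) 100 * r / n else NA_real_)
  }))
  structure(score, class = c("behavioral_score", class(score)),
            extra_responses = sum(!assigned), n_presses = nrow(presses))
}

#' Export a run's timeline as a BIDS-style events table
#'
#' @param design a [build_run_design()] object.
#' @param schedule optional [schedule_targets()] tibble; targets are added as
#'   zero-duration events.
#' @param run run number to export.
#' @param path output path for the tab-separated file.
#' @return the events data frame, invisibly.
#' @export
write_events_tsv <- function(design, schedule = NULL, run = 1L, path) {
  b <- design$blocks[design$blocks$run == run, ]
  ev <- data.frame(onset = b$onset, duration = b$duration,
                   trial_type = paste0("block_", b$condition))
  cue <- data.frame(onset = b$onset - design$params$cue_lead_s,
                    duration = design$params$cue_lead_s,
                    trial_type = paste0("cue_",
                                        condition_attention(b$condition)))
  ev <- rbind(ev, cue)
  if (!is.null(schedule)) {
    s <- schedule[schedule$run == run, ]
    ev <- rbind(ev, data.frame(onset = s$onset, duration = 0,
                               trial_type = paste0("target_", s$modality)))
  }
  ev <- ev[order(ev$onset), ]
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ev)
}
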