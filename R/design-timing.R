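#' Timing configuration for the rapid event-related design
#'
#' Defaults reproduce the experiment's stated timing: 2.5 s clips separated
#' by jittered fixation intervals averaging 2.5 s with a 2 s floor, 5 s
#' lead-in and 15 s tail fixation per run, and 1000 candidate onset
#' sequences scored for estimation efficiency.
#'
#' @param stim_duration_s stimulus duration (seconds).
#' @param mean_isi_s mean interstimulus interval (seconds).
#' @param min_isi_s minimum interstimulus interval (seconds).
#' @param lead_in_s fixation prepended to each run (seconds).
#' @param tail_s fixation appended to each run (seconds).
#' @param n_candidates candidate onset sequences per design selection.
#' @param isi_truncation_factor ISIs are capped at
#'   `isi_truncation_factor * mean_isi_s` before rescaling.
#' @return a `timing_config` list.
#' @export
timing_config <- function(stim_duration_s = 2.5, mean_isi_s = 2.5,
                          min_isi_s = 2.0, lead_in_s = 5, tail_s = 15,
                          n_candidates = 1000L, isi_truncation_factor = 3) {
  if (min_isi_s > mean_isi_s) stop_arg("min_isi_s must not exceed mean_isi_s")
  if (n_candidates < 1) stop_arg("n_candidates must be >= 1")
  structure(list(stim_duration_s = stim_duration_s, mean_isi_s = mean_isi_s,
                 min_isi_s = min_isi_s, lead_in_s = lead_in_s, tail_s = tail_s,
                 n_candidates = as.integer(n_candidates),
                 isi_truncation_factor = isi_truncation_factor),
            class = "timing_config")
}

#' Sample jittered interstimulus intervals
#'
#' Draws ISIs as `min_isi_s` plus truncated-exponential jitter, then rescales
#' the jitter so that the ISIs sum to exactly `n_trials * mean_isi_s` (the
#' total is what fixes the printed run duration), and finally quantizes to a
#' 0.1 s grid by largest-remainder apportionment so the exact sum and the
#' minimum are both preserved.
#'
#' @param n_trials number of intervals to draw.
#' @param cfg a [timing_config()].
#' @param rng_seed integer seed.
#' @return numeric vector of ISIs (seconds, 0.1 s resolution), summing to
#'   `n_trials * mean_isi_s` within 1e-9 with every ISI `>= min_isi_s`.
#' @export
sample_jittered_isis <- function(n_trials, cfg = timing_config(), rng_seed = 1L) {
  if (n_trials < 1) stop_arg("n_trials must be >= 1")
  mean_ex <- cfg$mean_isi_s - cfg$min_isi_s
  if (mean_ex == 0) return(rep(cfg$min_isi_s, n_trials))
  cap <- cfg$isi_truncation_factor * cfg$mean_isi_s - cfg$min_isi_s
  with_seed(rng_seed, {
    ex <- pmin(rexp(n_trials, rate = 1 / mean_ex), cap)
    # iterative rescale: clipping at the cap perturbs the sum, so repeat
    for (it in 1:50) {
      total <- sum(ex)
      if (abs(total - n_trials * mean_ex) < 1e-12) break
      ex <- pmin(ex * (n_trials * mean_ex) / total, cap)
    }
    ex <- ex * (n_trials * mean_ex) / sum(ex)  # final exact rescale
    isi <- cfg$min_isi_s + ex
    quantize_preserving_sum(isi, grid = 0.1, minimum = cfg$min_isi_s)
  })
}

# Round values to a grid while preserving the (grid-aligned) sum and a
# minimum: floor everything, then hand out the remaining grid steps to the
# largest fractional remainders.
quantize_preserving_sum <- function(x, grid = 0.1, minimum = 0) {
  units <- x / grid
  total_units <- round(sum(units))
  lo <- floor(units + 1e-9)
  deficit <- total_units - sum(lo)
  frac <- units - lo
  if (deficit > 0) {
    bump <- order(frac, decreasing = TRUE)[seq_len(deficit)]
    lo[bump] <- lo[bump] + 1
  } else if (deficit < 0) {
    min_units <- ceiling(minimum / grid - 1e-9)
    drop <- order(frac)[lo[order(frac)] > min_units][seq_len(-deficit)]
    lo[drop] <- lo[drop] - 1
  }
  lo * grid
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style canonical shape: a gamma density peaking at 6 s minus a
#' 16 s-peaking undershoot scaled by 1/6, normalized to unit peak.
#'
#' @param t time points (seconds).
#' @export
hrf_double_gamma <- function(t) {
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Estimation efficiency of an event-related design
#'
#' Builds the design matrix at 0.1 s resolution by convolving per-condition
#' boxcars with the canonical double-gamma response, samples it at `tr_s`,
#' and scores `1 / trace(C (X'X)^-1 C')` for the contrast rows `C` (by
#' default one identity contrast per condition). Higher is better. A singular
#' design scores 0 with a warning.
#'
#' @param onsets numeric vector of event onsets (seconds, strictly
#'   increasing).
#' @param durations event durations (seconds; scalar or per event).
#' @param conditions integer/character condition label per event.
#' @param contrasts contrast matrix with one column per condition; default
#'   identity.
#' @param tr_s sampling interval of the scanner (seconds).
#' @param total_s scan duration; defaults to covering the last event plus
#'   30 s.
#' @return efficiency score (dimensionless, >= 0).
#' @export
design_efficiency <- function(onsets, durations, conditions,
                              contrasts = NULL, tr_s = 1, total_s = NULL) {
  if (any(diff(onsets) <= 0)) stop_arg("onsets must be strictly increasing")
  n_ev <- length(onsets)
  durations <- rep_len(durations, n_ev)
  conditions <- as.character(conditions)
  cond_levels <- unique(conditions)
  dt <- 0.1
  if (is.null(total_s)) total_s <- max(onsets + durations) + 30
  n_fine <- ceiling(total_s / dt)
  hrf <- hrf_double_gamma(seq(0, 32, by = dt))
  X_fine <- matrix(0, n_fine, length(cond_levels))
  for (ci in seq_along(cond_levels)) {
    box <- numeric(n_fine)
    ev <- which(conditions == cond_levels[ci])
    for (e in ev) {
      i0 <- floor(onsets[e] / dt + 1e-9) + 1
      i1 <- min(n_fine, floor((onsets[e] + durations[e]) / dt + 1e-9))
      box[i0:i1] <- 1
    }
    conv <- convolve(box, rev(hrf), type = "open")[seq_len(n_fine)]
    X_fine[, ci] <- conv
  }
  keep <- seq(1, n_fine, by = round(tr_s / dt))
  X <- cbind(1, X_fine[keep, , drop = FALSE])
  if (is.null(contrasts)) contrasts <- diag(length(cond_levels))
  C <- cbind(0, contrasts)  # never contrast the intercept
  xtx <- crossprod(X)
  inv <- tryCatch(solve(xtx), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv)) || rcond(xtx) < 1e-12) {
    warning("singular design matrix; efficiency reported as 0", call. = FALSE)
    return(0)
  }
  1 / sum(diag(C %*% inv %*% t(C)))
}

#' Select the most efficient candidate design
#'
#' Generates `n_candidates` candidate designs from a seeded generator
#' function and returns the one maximizing [design_efficiency()]; ties break
#' toward the lowest candidate index.
#'
#' @param generator `function(candidate_index)` returning a list with at
#'   least `onsets`, `durations` and `conditions` (any further elements are
#'   passed through).
#' @param n_candidates number of candidates to score.
#' @param contrasts optional contrast matrix forwarded to
#'   [design_efficiency()].
#' @param rng_seed integer seed governing the generator's randomness.
#' @return the winning candidate list, with `efficiency` and
#'   `candidate_index` fields added, and attribute `efficiencies` holding all
#'   scores.
#' @export
select_best_design <- function(generator, n_candidates, contrasts = NULL,
                               rng_seed = 1L) {
  if (n_candidates < 1) stop_arg("n_candidates must be >= 1")
  with_seed(rng_seed, {
    best <- NULL
    effs <- numeric(n_candidates)
    for (k in seq_len(n_candidates)) {
      cand <- generator(k)
      effs[k] <- suppressWarnings(
        design_efficiency(cand$onsets, cand$durations, cand$conditions,
                          contrasts = contrasts))
      if (is.null(best) || effs[k] > best$efficiency) {
        best <- cand
        best$efficiency <- effs[k]
        best$candidate_index <- k
      }
    }
    if (best$efficiency == 0) stop_arg("all candidate designs are singular")
    attr(best, "efficiencies") <- effs
    best
  })
}

#' Partition a session design into runs with preparatory context trials
#'
#' Splits a timed session into `n_runs` runs. Each run is prepended with a
#' lead-in fixation and three context trials that replicate the categories of
#' the previous run's final three trials -- drawn from a separate preparatory
#' exemplar pool so no exemplar repeats within a run -- and is closed with a
#' tail fixation. The first run takes its context from the session's final
#' three trials. At default timing each run lasts
#' `5 + 3*(2.5+2.5) + 100*2.5 + 250 + 15 = 535` seconds.
#'
#' @param design a `design_sequence` (one session).
#' @param n_runs number of runs; must divide the trial count.
#' @param prep_pool data frame with columns `category`, `stimulus_id`: one
#'   spare exemplar per category for context trials.
#' @param cfg a [timing_config()].
#' @param rng_seed integer seed for the ISI draw.
#' @return list of runs; each run is a data frame with columns `phase`
#'   (`"context"`/`"trial"`), trial fields, `onset_s`, `duration_s`, `isi_s`,
#'   plus attributes `duration_s` (total run length) and `run`.
#' @export
partition_runs <- function(design, n_runs, prep_pool, cfg = timing_config(),
                           rng_seed = 1L) {
  n_trials <- nrow(design)
  if (n_trials %% n_runs != 0) stop_arg("n_runs must divide the trial count")
  run_len <- n_trials %/% n_runs
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    rows <- design[((r - 1) * run_len + 1):(r * run_len), , drop = FALSE]
    prev <- if (r == 1) n_runs else r - 1
    ctx_src <- design[(prev * run_len - 2):(prev * run_len), , drop = FALSE]
    ctx <- ctx_src
    for (k in seq_len(nrow(ctx))) {
      if (!is.na(ctx$category[k])) {
        hit <- prep_pool$stimulus_id[prep_pool$category == ctx$category[k]]
        if (!length(hit)) {
          stop_arg("preparatory pool lacks an exemplar for category '",
                   ctx$category[k], "'")
        }
        ctx$exemplar_id[k] <- hit[1]
      }
    }
    isis <- sample_jittered_isis(run_len, cfg, rng_seed = rng_seed + r)
    ctx_isi <- rep(cfg$mean_isi_s, 3)
    all_isi <- c(ctx_isi, isis)
    starts <- cfg$lead_in_s +
      cumsum(c(0, (cfg$stim_duration_s + all_isi)[-(3 + run_len)]))
    total <- cfg$lead_in_s + sum(cfg$stim_duration_s + all_isi) + cfg$tail_s
    out <- rbind(
      data.frame(phase = "context", ctx, onset_s = starts[1:3],
                 duration_s = cfg$stim_duration_s, isi_s = ctx_isi,
                 stringsAsFactors = FALSE),
      data.frame(phase = "trial", rows, onset_s = starts[-(1:3)],
                 duration_s = cfg$stim_duration_s, isi_s = isis,
                 stringsAsFactors = FALSE)
    )
    rownames(out) <- NULL
    attr(out, "duration_s") <- total
    attr(out, "run") <- r
    runs[[r]] <- out
  }
  runs
}
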