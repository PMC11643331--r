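#' Preprocess a gaze trajectory
#'
#' Censored (invalid) spans are linearly interpolated from flanking valid
#' samples, the x and y traces are median filtered with a rolling window of
#' `window_ms` (nearest odd sample count at the native rate; edges use
#' shrinking windows), and the result is decimated to `duration_s *
#' out_rate_hz` samples by per-frame-bin averaging (60 samples at defaults:
#' one per frame at 24 Hz over 2.5 s).
#'
#' @param traj a `gaze_trajectory` (list with `samples` data frame: `t_ms`,
#'   `x_px`, `y_px`, `valid`).
#' @param window_ms median filter window (milliseconds).
#' @param out_rate_hz output sampling rate (Hz).
#' @param duration_s stimulus duration (seconds).
#' @return the trajectory with `samples` replaced by the decimated frame
#'   series (`t_ms`, `x_px`, `y_px`) and `excluded = FALSE`; if the input has
#'   no valid samples at all, the trial is returned with `excluded = TRUE`
#'   and no samples (eyes closed for the whole presentation).
#' @export
preprocess_gaze <- function(traj, window_ms = 84, out_rate_hz = 24,
                            duration_s = 2.5) {
  s <- traj$samples
  n <- nrow(s)
  if (!any(s$valid)) {
    traj$samples <- NULL
    traj$excluded <- TRUE
    return(traj)
  }
  rate_hz <- 1000 * (n - 1) / (s$t_ms[n] - s$t_ms[1])
  k <- round(window_ms / 1000 * rate_hz)
  if (k %% 2 == 0) k <- k + 1   # runmed needs an odd window
  k <- max(3L, min(k, if (n %% 2 == 0) n - 1 else n))
  clean <- function(v) {
    if (!all(s$valid)) {
      v <- approx(s$t_ms[s$valid], v[s$valid], xout = s$t_ms, rule = 2)$y
    }
    as.numeric(runmed(v, k, endrule = "median"))
  }
  x <- clean(s$x_px); y <- clean(s$y_px)
  n_out <- round(duration_s * out_rate_hz)
  bin <- pmin(floor((s$t_ms / 1000) / (duration_s / n_out)) + 1, n_out)
  traj$samples <- data.frame(
    t_ms = (seq_len(n_out) - 0.5) * 1000 * duration_s / n_out,
    x_px = as.numeric(tapply(x, bin, mean)),
    y_px = as.numeric(tapply(y, bin, mean))
  )
  traj$excluded <- FALSE
  traj
}

#' Spatiotemporal distance between two gaze trajectories
#'
#' The Euclidean distance between the two gaze locations at each sample,
#' summed over the presentation.
#'
#' @param a,b preprocessed trajectories with equal sample counts.
#' @return nonnegative scalar (pixel-sum).
#' @export
gaze_trial_distance <- function(a, b) {
  sa <- a$samples; sb <- b$samples
  if (is.null(sa) || is.null(sb) || nrow(sa) != nrow(sb)) {
    stop_arg("trajectories must be preprocessed and of equal length")
  }
  sum(sqrt((sa$x_px - sb$x_px)^2 + (sa$y_px - sb$y_px)^2))
}

#' Build a gaze RDM with inter-block reliability filtering
#'
#' Preprocesses all trajectories, builds one RDM per participant per block
#' (pairwise trajectory distances across stimuli), computes each
#' participant's mean pairwise inter-block Pearson correlation of vectorized
#' RDMs, drops participants below `min_interblock_r`, and averages the
#' surviving RDMs over blocks and then participants.
#'
#' @param trajectories list of `gaze_trajectory` records covering
#'   participants x blocks x stimuli.
#' @param min_interblock_r reliability threshold (Pearson r); `-1` retains
#'   everyone.
#' @param stimulus_ids optional stimulus order for the RDM.
#' @param preprocess set `FALSE` if trajectories are already preprocessed.
#' @param ... passed to [preprocess_gaze()].
#' @return an `rdm` with meta `source = "gaze"`; attribute `"reliability"`
#'   holds a data frame (`participant`, `n_blocks`, `interblock_r`,
#'   `retained`) and attribute `"excluded_trials"` the count of fully
#'   censored trials.
#' @export
build_gaze_rdm <- function(trajectories, min_interblock_r = 0.1,
                           stimulus_ids = NULL, preprocess = TRUE, ...) {
  if (preprocess) trajectories <- lapply(trajectories, preprocess_gaze, ...)
  excluded <- vapply(trajectories, function(tr) isTRUE(tr$excluded), TRUE)
  trajectories <- trajectories[!excluded]
  if (!length(trajectories)) stop_arg("all gaze trials were fully censored")
  if (is.null(stimulus_ids)) {
    stimulus_ids <- unique(vapply(trajectories, `[[`, "", "stimulus_id"))
  }
  m <- length(stimulus_ids)
  key <- paste(vapply(trajectories, `[[`, "", "participant"),
               vapply(trajectories, function(tr) tr$block, 1))
  participants <- unique(vapply(trajectories, `[[`, "", "participant"))
  block_rdm <- function(trs) {
    hit <- match(stimulus_ids, vapply(trs, `[[`, "", "stimulus_id"))
    if (anyNA(hit)) return(NULL)   # block missing stimuli: skip
    mat <- matrix(0, m, m)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        mat[i, j] <- gaze_trial_distance(trs[[hit[i]]], trs[[hit[j]]])
      }
    }
    mat + t(mat)
  }
  rel <- list(); kept <- list()
  for (p in participants) {
    blocks <- unique(vapply(trajectories[startsWith(key, paste0(p, " "))],
                            function(tr) tr$block, 1))
    rdms <- list()
    for (b in blocks) {
      trs <- trajectories[key == paste(p, b)]
      rb <- block_rdm(trs)
      if (!is.null(rb)) rdms[[length(rdms) + 1]] <- rb
    }
    if (length(rdms) < 2) {
      rel[[p]] <- data.frame(participant = p, n_blocks = length(rdms),
                             interblock_r = NA_real_, retained = FALSE)
      next
    }
    vmat <- vapply(rdms, function(M) M[upper.tri(M)],
                   numeric(m * (m - 1) / 2))
    cm <- cor(vmat)
    ib <- mean(cm[upper.tri(cm)])
    keep <- ib >= min_interblock_r
    rel[[p]] <- data.frame(participant = p, n_blocks = length(rdms),
                           interblock_r = ib, retained = keep)
    if (keep) kept[[p]] <- Reduce(`+`, rdms) / length(rdms)
  }
  rel <- do.call(rbind, rel)
  rownames(rel) <- NULL
  if (!length(kept)) stop_arg("no participant passed the gaze reliability filter")
  avg <- Reduce(`+`, kept) / length(kept)
  out <- rdm(avg, stimulus_ids = stimulus_ids,
             meta = list(source = "gaze", min_interblock_r = min_interblock_r))
  attr(out, "reliability") <- rel
  attr(out, "excluded_trials") <- sum(excluded)
  out
}
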