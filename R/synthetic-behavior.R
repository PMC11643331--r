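#' Simulate multiple-arrangement trials
#'
#' Emulates the arrangement task's logs: for each planned subset, the
#' corresponding sub-RDM is laid out in two dimensions by classical metric
#' scaling, randomly rotated/reflected, scaled into the circular arena, and
#' jittered with isotropic Gaussian placement noise.
#'
#' @param behavior_rdm target behavioral geometry (an [rdm()]).
#' @param subset_plan a [plan_arrangement_subsets()] plan (or list of
#'   stimulus-id vectors).
#' @param placement_noise_sd placement jitter SD in screen pixels.
#' @param arena_radius arena radius in screen pixels.
#' @param task task label recorded on each trial.
#' @param participant participant label.
#' @param rng_seed integer seed.
#' @return list of `arrangement_trial` records: `task`, `participant`,
#'   `trial_index`, `subset` (stimulus ids), `coords` (matrix of x/y screen
#'   px with stimulus ids as rownames).
#' @export
simulate_arrangements <- function(behavior_rdm, subset_plan,
                                  placement_noise_sd = 10, arena_radius = 400,
                                  task = "task", participant = "p01",
                                  rng_seed = 1L) {
  subsets <- if (inherits(subset_plan, "subset_plan")) subset_plan$subsets
             else subset_plan
  ids_all <- rdm_ids(behavior_rdm)
  with_seed(rng_seed, {
    lapply(seq_along(subsets), function(ti) {
      ids <- subsets[[ti]]
      if (!all(ids %in% ids_all)) stop_arg("subset stimuli missing from RDM")
      sub <- rdm_align(behavior_rdm, ids)
      # tiny subsets can have degenerate (rank < 2) metric-scaling solutions;
      # cmdscale warns and returns fewer columns, which we zero-pad
      xy <- suppressWarnings(cmdscale(unclass(sub), k = min(2, length(ids) - 1)))
      while (ncol(xy) < 2) xy <- cbind(xy, 0)
      theta <- runif(1, 0, 2 * pi)
      rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
      if (runif(1) < 0.5) rot[, 2] <- -rot[, 2]  # random reflection
      xy <- xy %*% rot
      span <- max(sqrt(rowSums(xy^2)))
      if (span > 0) xy <- xy * (0.9 * arena_radius / span)
      xy <- xy + placement_noise_sd * matrix(rnorm(length(xy)), ncol = 2)
      rownames(xy) <- ids
      colnames(xy) <- c("x_px", "y_px")
      structure(list(task = task, participant = participant, trial_index = ti,
                     subset = ids, coords = xy),
                class = "arrangement_trial")
    })
  })
}

#' Simulate gaze trajectories
#'
#' Each stimulus gets a smooth prototype gaze path (a low-pass-filtered
#' random walk around screen center); each participant and block receives a
#' noisy copy with randomly placed blink gaps flagged invalid.
#'
#' @param stimulus_set a [make_stimulus_set()] data frame.
#' @param n_participants number of eye-tracking participants.
#' @param n_blocks blocks per participant (each stimulus once per block).
#' @param duration_s stimulus duration (seconds).
#' @param rate_hz sampling rate; `duration_s * rate_hz` must be integral.
#' @param blink_prob probability that a trial contains a blink gap;
#'   `blink_prob = 1` censors every trial completely.
#' @param noise_sd_px per-sample gaze noise SD (pixels) around the prototype.
#' @param screen_px screen size (pixels, square).
#' @param rng_seed integer seed.
#' @return list of `gaze_trajectory` records: `participant`, `block`,
#'   `stimulus_id`, and `samples` data frame (`t_ms`, `x_px`, `y_px`,
#'   `valid`).
#' @export
simulate_gaze <- function(stimulus_set, n_participants = 17L, n_blocks = 4L,
                          duration_s = 2.5, rate_hz = 1000, blink_prob = 0.2,
                          noise_sd_px = 15, screen_px = 1024, rng_seed = 1L) {
  n_samp <- duration_s * rate_hz
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    stop_arg("duration_s * rate_hz must be an integer sample count")
  }
  n_samp <- as.integer(round(n_samp))
  smooth_walk <- function() {
    raw <- cumsum(rnorm(n_samp, sd = 2))
    k <- min(201L, if (n_samp %% 2 == 0) n_samp - 1 else n_samp)
    sm <- stats::filter(raw, rep(1 / k, k), sides = 2)
    sm[is.na(sm)] <- raw[is.na(sm)]
    screen_px / 2 + as.numeric(sm)
  }
  t_ms <- (seq_len(n_samp) - 1) * 1000 / rate_hz
  with_seed(rng_seed, {
    protos <- lapply(stimulus_set$stimulus_id, function(id) {
      cbind(x = smooth_walk(), y = smooth_walk())
    })
    names(protos) <- stimulus_set$stimulus_id
    out <- list()
    for (p in seq_len(n_participants)) {
      pid <- sprintf("p%02d", p)
      for (b in seq_len(n_blocks)) {
        for (id in stimulus_set$stimulus_id) {
          xy <- protos[[id]] + noise_sd_px * matrix(rnorm(2 * n_samp), ncol = 2)
          valid <- rep(TRUE, n_samp)
          if (blink_prob >= 1) {
            valid[] <- FALSE
          } else if (runif(1) < blink_prob) {
            len <- min(n_samp, max(20L, stats::rgeom(1, 1 / 150) + 20L))
            at <- sample.int(n_samp - len + 1L, 1)
            valid[at:(at + len - 1L)] <- FALSE
          }
          out[[length(out) + 1]] <- structure(
            list(participant = pid, block = b, stimulus_id = id,
                 samples = data.frame(t_ms = t_ms, x_px = xy[, 1],
                                      y_px = xy[, 2], valid = valid)),
            class = "gaze_trajectory")
        }
      }
    }
    out
  })
}

#' Simulate stimulus annotations and a word-embedding table
#'
#' Builds synthetic verb and nonverb vocabularies with category-clustered
#' embedding vectors, then assigns each stimulus a verb token list (2-5
#' tokens) and a nonverb token list (3-6 tokens) drawn from its category's
#' vocabulary, emulating the label counts observed for manually annotated
#' clips.
#'
#' @param stimulus_set a [make_stimulus_set()] data frame.
#' @param embedding_dim embedding dimensionality.
#' @param tokens_per_category vocabulary size per category and class.
#' @param cluster_sd within-category token scatter relative to unit-norm
#'   category centroids.
#' @param verb_range,nonverb_range inclusive token-count ranges per stimulus.
#' @param rng_seed integer seed.
#' @return list with `annotations` (data frame `stimulus_id`, `token`,
#'   `class`) and `embeddings` (token x dim matrix).
#' @export
simulate_annotations <- function(stimulus_set, embedding_dim = 300L,
                                 tokens_per_category = 8L, cluster_sd = 0.4,
                                 verb_range = c(2L, 5L),
                                 nonverb_range = c(3L, 6L), rng_seed = 1L) {
  if (tokens_per_category < max(verb_range[2], nonverb_range[2])) {
    stop_arg("tokens_per_category must cover the requested token ranges")
  }
  cats <- unique(stimulus_set$category)
  with_seed(rng_seed, {
    vocab <- list(); vecs <- list()
    for (cls in c("verb", "nonverb")) {
      for (cat in cats) {
        centroid <- rnorm(embedding_dim)
        centroid <- centroid / sqrt(sum(centroid^2))
        for (k in seq_len(tokens_per_category)) {
          tok <- sprintf("%s_%s_%02d", substr(cls, 1, 1), cat, k)
          vocab[[length(vocab) + 1]] <- data.frame(
            token = tok, class = cls, category = cat, stringsAsFactors = FALSE)
          vecs[[tok]] <- centroid +
            cluster_sd * rnorm(embedding_dim) / sqrt(embedding_dim)
        }
      }
    }
    vocab <- do.call(rbind, vocab)
    ann <- list()
    for (i in seq_len(nrow(stimulus_set))) {
      id <- stimulus_set$stimulus_id[i]
      cat <- stimulus_set$category[i]
      for (cls in c("verb", "nonverb")) {
        rng <- if (cls == "verb") verb_range else nonverb_range
        n_tok <- sample(rng[1]:rng[2], 1)
        toks <- sample(vocab$token[vocab$class == cls & vocab$category == cat],
                       n_tok)
        ann[[length(ann) + 1]] <- data.frame(stimulus_id = id, token = toks,
                                             class = cls,
                                             stringsAsFactors = FALSE)
      }
    }
    emb <- do.call(rbind, vecs[vocab$token])
    rownames(emb) <- vocab$token
    list(annotations = do.call(rbind, ann), embeddings = emb)
  })
}

#' Grid searchlight neighborhoods
#'
#' A desk-scale stand-in for surface-based searchlights: measurement units
#' are laid out on a `width x height` grid and each unit's neighborhood is
#' the set of units within Euclidean `radius` of it.
#'
#' @param width,height grid dimensions (units).
#' @param radius neighborhood radius in grid spacings.
#' @return named list: for each center unit index, an integer vector of
#'   member unit indices. Grid coordinates attached as attribute `"coords"`.
#' @export
make_grid_neighborhoods <- function(width, height, radius) {
  if (radius < 0) stop_arg("radius must be >= 0")
  coords <- expand.grid(x = seq_len(width), y = seq_len(height))
  n <- nrow(coords)
  d2 <- as.matrix(dist(coords))^2
  out <- lapply(seq_len(n),
                function(i) unname(which(d2[i, ] <= radius^2 + 1e-12)))
  names(out) <- paste0("u", seq_len(n))
  attr(out, "coords") <- as.matrix(coords)
  out
}
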