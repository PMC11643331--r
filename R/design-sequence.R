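#' Build a circular type 1 index 1 serially balanced sequence
#'
#' Constructs a trial-type sequence of length `n_types^2` in which every
#' ordered pair of type codes -- self pairs included -- occurs exactly once
#' among the circular adjacencies. Such sequences exactly counterbalance
#' first-order carryover: each trial type precedes and follows every other
#' type (and itself) exactly once.
#'
#' For even `n_types` the sequence additionally decomposes into `n_types`
#' consecutive blocks, each a permutation of the code alphabet, so that a run
#' built from consecutive blocks features every trial type equally often.
#' The one exception is `n_types = 4`, for which exhaustive search proves
#' that no block-structured circular sequence exists; the unblocked sequence
#' is returned with a warning. Odd alphabets cannot support the block
#' structure (self pairs cannot all sit at junctions) and use the plain
#' Eulerian-circuit solution.
#'
#' The search is a randomized backtracking walk over the complete digraph
#' with self-loops (a de Bruijn cycle of order 2), implemented in C++ with
#' Warnsdorff candidate ordering.
#'
#' @param n_types number of trial-type codes (alphabet size), >= 1.
#' @param rng_seed integer seed; the construction is reproducible given the
#'   seed.
#' @param blocked logical or `NULL`; `NULL` (default) requests block
#'   structure for even alphabets where it exists.
#' @return integer vector of type codes `0 .. n_types-1`, length `n_types^2`,
#'   to be read circularly.
#' @examples
#' s <- build_serially_balanced_sequence(6, rng_seed = 1)
#' table(paste(s, c(s[-1], s[1])))  # every ordered pair exactly once
#' @export
build_serially_balanced_sequence <- function(n_types, rng_seed = 1L,
                                             blocked = NULL) {
  if (n_types < 1) stop_arg("n_types must be >= 1")
  n_types <- as.integer(n_types)
  if (n_types == 1L) return(0L)
  want_block <- if (is.null(blocked)) (n_types %% 2L == 0L) else isTRUE(blocked)
  with_seed(rng_seed, {
    if (want_block) {
      ex <- logical(1)
      s <- sbs_search_cpp(n_types, TRUE, 5e6, 60L, ex)
      if (length(s)) return(s)
      if (ex) {
        warning("no block-structured serially balanced sequence exists for ",
                "n_types = ", n_types, "; returning the unblocked solution",
                call. = FALSE)
      } else {
        warning("block-structured search did not converge for n_types = ",
                n_types, "; returning the unblocked solution", call. = FALSE)
      }
    }
    ex <- logical(1)
    s <- sbs_search_cpp(n_types, FALSE, 5e6, 60L, ex)
    if (!length(s)) stop_arg("serially balanced sequence construction failed ",
                             "for n_types = ", n_types)
    s
  })
}

#' Verify serial balance of a type sequence
#'
#' Checks that every ordered pair of codes occurs exactly once among circular
#' adjacencies, and (optionally) that consecutive blocks of `n` trials are
#' permutations of the alphabet.
#'
#' @param s integer sequence of codes `0..n-1`, length `n^2`.
#' @param blocked also require the block structure.
#' @return `TRUE`/`FALSE`.
#' @export
is_serially_balanced <- function(s, blocked = FALSE) {
  n <- round(sqrt(length(s)))
  if (n * n != length(s)) return(FALSE)
  if (n == 1) return(s == 0)
  adj <- s * n + c(s[-1], s[1])
  if (length(unique(adj)) != n * n) return(FALSE)
  if (blocked) {
    blocks <- split(s, rep(seq_len(n), each = n))
    if (!all(vapply(blocks, function(b) length(unique(b)) == n, TRUE))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Assign action categories and exemplars to a balanced type sequence
#'
#' Maps the abstract type codes of a serially balanced sequence onto the
#' experiment's trial roles: one code per action category plus one null
#' (fixation) code and one probe code. The code-to-category mapping is a
#' random seeded bijection. Within each run partition, every occurrence of a
#' category draws its exemplar by sampling without replacement from the
#' category's exemplar set, so each exemplar occurs exactly once per run.
#'
#' @param type_sequence integer codes from
#'   [build_serially_balanced_sequence()]; the alphabet size must equal
#'   `n_categories + 2`.
#' @param stimulus_set a stimulus set from [make_stimulus_set()].
#' @param run_length trials per run; must divide the sequence length, and
#'   each category must occur exactly `n_exemplars` times per run.
#' @param rng_seed integer seed.
#' @return a `design_sequence` data frame: one row per trial with columns
#'   `trial`, `type_code`, `role` (category id, `"null"` or `"probe"`),
#'   `category`, `exemplar_id`, `run`.
#' @export
assign_categories_and_exemplars <- function(type_sequence, stimulus_set,
                                            run_length = NULL, rng_seed = 1L) {
  categories <- unique(stimulus_set$category)
  n_cat <- length(categories)
  n_types <- n_cat + 2L
  if (length(type_sequence) %% n_types != 0 ||
      !setequal(unique(type_sequence), 0:(n_types - 1L))) {
    stop_arg("type_sequence alphabet must have n_categories + 2 codes")
  }
  n_trials <- length(type_sequence)
  if (is.null(run_length)) run_length <- n_trials
  if (n_trials %% run_length != 0) {
    stop_arg("run_length must divide the sequence length")
  }
  n_runs <- n_trials %/% run_length
  run <- rep(seq_len(n_runs), each = run_length)
  with_seed(rng_seed, {
    roles <- sample(c(categories, "null", "probe"))  # random code -> role bijection
    role <- roles[type_sequence + 1L]
    exemplar_id <- rep(NA_character_, n_trials)
    ex_by_cat <- split(stimulus_set$stimulus_id, stimulus_set$category)
    for (r in seq_len(n_runs)) {
      in_run <- which(run == r)
      for (cat in categories) {
        idx <- in_run[role[in_run] == cat]
        exemplars <- ex_by_cat[[cat]]
        if (length(idx) %% length(exemplars) != 0) {
          stop_arg("category '", cat, "' occurs ", length(idx),
                   " times in run ", r, " but has ", length(exemplars),
                   " exemplars; choose run_length so the counts match")
        }
        # one shuffled pass per exemplar-set repetition (exactly one pass --
        # each exemplar once per run -- in the default configuration)
        passes <- length(idx) %/% length(exemplars)
        draw <- unlist(lapply(seq_len(passes),
                              function(p) sample(exemplars)))
        exemplar_id[idx] <- draw
      }
    }
    out <- data.frame(
      trial = seq_len(n_trials),
      type_code = type_sequence,
      role = role,
      category = ifelse(role %in% c("null", "probe"), NA_character_, role),
      exemplar_id = exemplar_id,
      run = run,
      stringsAsFactors = FALSE
    )
    class(out) <- c("design_sequence", "data.frame")
    out
  })
}

#' Repair probe trials that follow null or probe trials
#'
#' A semantic probe asks about the preceding clip, so a probe immediately
#' preceded by a fixation (null) trial or another probe has nothing to probe.
#' Every such trailing probe is converted to a null trial. The scan runs once
#' in session order, left to right: a probe whose predecessor was itself just
#' converted to null is still repaired.
#'
#' @param design a `design_sequence` from [assign_categories_and_exemplars()].
#' @return the repaired `design_sequence`.
#' @export
fix_probe_collisions <- function(design) {
  role <- design$role
  if (!all(c("null", "probe") %in% role)) {
    stop_arg("design must contain null and probe trials")
  }
  for (i in seq_along(role)[-1]) {
    if (role[i] == "probe" && role[i - 1] %in% c("null", "probe")) {
      role[i] <- "null"
    }
  }
  design$role <- role
  design$category[role == "null"] <- NA_character_
  design$exemplar_id[role == "null"] <- NA_character_
  design
}
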