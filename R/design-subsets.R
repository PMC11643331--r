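#' Plan stimulus subsets for the multiple arrangements task
#'
#' Participants first arrange the full stimulus set, then a series of smaller
#' subsets; distances from all arrangements are later averaged into one RDM.
#' Subsets are planned by repeatedly permuting the stimulus list and slicing
#' it into `subset_size` groups, scoring each candidate plan by the number of
#' distinct stimulus pairs that co-occur in at least one subset, and keeping
#' the best of `n_candidates` plans (ties toward the lowest candidate index).
#' The returned plan is prepended with the full-set arrangement, which
#' guarantees at least one measurement of every pair.
#'
#' @param stimulus_ids character vector of stimulus ids (or an integer count).
#' @param n_subsets number of partial subsets per plan.
#' @param subset_size stimuli per partial subset.
#' @param n_candidates candidate plans to score.
#' @param rng_seed integer seed.
#' @return a `subset_plan` list: `subsets` (list of id vectors; first element
#'   is the full set), `unique_pair_count` (pairs covered by the partial
#'   subsets), `candidate_index`.
#' @export
plan_arrangement_subsets <- function(stimulus_ids, n_subsets = 12L,
                                     subset_size = 30L, n_candidates = 1000L,
                                     rng_seed = 1L) {
  if (length(stimulus_ids) == 1 && is.numeric(stimulus_ids)) {
    stimulus_ids <- paste0("s", seq_len(stimulus_ids))
  }
  n <- length(stimulus_ids)
  if (subset_size > n) stop_arg("subset_size must not exceed the number of stimuli")
  per_perm <- n %/% subset_size
  n_perms <- ceiling(n_subsets / per_perm)
  with_seed(rng_seed, {
    best <- NULL
    for (k in seq_len(n_candidates)) {
      subsets <- list()
      for (p in seq_len(n_perms)) {
        perm <- sample(n)
        for (s in seq_len(per_perm)) {
          if (length(subsets) < n_subsets) {
            subsets[[length(subsets) + 1]] <-
              perm[((s - 1) * subset_size + 1):(s * subset_size)]
          }
        }
      }
      score <- count_unique_pairs(subsets, n)
      if (is.null(best) || score > best$unique_pair_count) {
        best <- list(subsets = subsets, unique_pair_count = score,
                     candidate_index = k)
      }
    }
    best$subsets <- c(list(seq_len(n)), best$subsets)
    best$subsets <- lapply(best$subsets, function(ix) stimulus_ids[ix])
    class(best) <- "subset_plan"
    best
  })
}

# number of distinct unordered pairs co-occurring in >= 1 subset
count_unique_pairs <- function(subsets, n) {
  seen <- logical(n * n)
  for (sub in subsets) {
    pairs <- utils::combn(sort(sub), 2)
    seen[(pairs[1, ] - 1) * n + pairs[2, ]] <- TRUE
  }
  sum(seen)
}

#' @export
print.subset_plan <- function(x, ...) {
  sizes <- lengths(x$subsets)
  cat(sprintf("arrangement subset plan: %d sets (sizes %s)\n", length(sizes),
              paste(unique(sizes), collapse = "/")))
  cat(sprintf("  unique pairs covered by partial subsets: %d\n",
              x$unique_pair_count))
  invisible(x)
}

#' Write a subset plan as delimited text
#'
#' One row per (subset index, stimulus id).
#' @param plan a `subset_plan`.
#' @param path output file.
#' @export
write_subset_plan <- function(plan, path) {
  df <- do.call(rbind, lapply(seq_along(plan$subsets), function(i) {
    data.frame(subset_index = i, stimulus_id = plan$subsets[[i]],
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
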