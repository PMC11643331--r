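#' Fisher z-transform of correlations
#'
#' Correlations are transformed with `atanh` before averaging or resampling
#' and back-transformed with `tanh` for reporting.
#'
#' @param r correlation(s), `|r| < 1`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop_arg("|r| must be < 1 for the Fisher transform")
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher-z value(s).
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Inference configuration
#'
#' Defaults mirror the study's settings: 10,000 permutations/bootstrap
#' iterations, FDR control at q = .001, one-sided (greater) alternatives.
#'
#' @param n_permutations permutation count.
#' @param n_bootstrap bootstrap iteration count.
#' @param fdr_q false discovery rate level.
#' @param seed integer seed.
#' @export
inference_config <- function(n_permutations = 10000L, n_bootstrap = 10000L,
                             fdr_q = 0.001, seed = 1L) {
  if (n_permutations < 1 || n_bootstrap < 1) stop_arg("counts must be >= 1")
  if (fdr_q <= 0 || fdr_q >= 1) stop_arg("fdr_q must be in (0, 1)")
  structure(list(n_permutations = as.integer(n_permutations),
                 n_bootstrap = as.integer(n_bootstrap),
                 fdr_q = fdr_q, seed = as.integer(seed)),
            class = "inference_config")
}

# add-one permutation p-value, >= on ties (conservative)
perm_p <- function(null_stats, observed) {
  (1 + sum(null_stats >= observed)) / (1 + length(null_stats))
}

#' Sign-flip permutation test for group-level correlations
#'
#' The observed statistic is the mean of the Fisher-transformed subject
#' correlations. Under the null each subject's sign is flipped independently
#' with probability 1/2 before z-averaging; the one-sided p-value is the
#' add-one-corrected proportion of permuted means at or above the observed
#' mean.
#'
#' @param subject_correlations per-subject correlations (`|r| < 1`, n >= 2).
#' @param cfg an [inference_config()].
#' @param exhaustive enumerate all `2^n` sign patterns instead of sampling
#'   (small n only).
#' @return list: `observed` (mean Fisher z), `observed_r` (back-transformed),
#'   `p_value`, `method`, `n_permutations`, `seed`.
#' @export
signflip_permutation_test <- function(subject_correlations,
                                      cfg = inference_config(),
                                      exhaustive = FALSE) {
  n <- length(subject_correlations)
  if (n < 2) stop_arg("need >= 2 subjects")
  z <- fisher_z(subject_correlations)
  observed <- mean(z)
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_stats <- as.numeric(signs %*% z) / n
  } else {
    null_stats <- with_seed(cfg$seed, {
      flips <- matrix(sample(c(-1, 1), n * cfg$n_permutations, replace = TRUE),
                      nrow = cfg$n_permutations)
      as.numeric(flips %*% z) / n
    })
  }
  list(observed = observed, observed_r = fisher_z_inverse(observed),
       p_value = perm_p(null_stats, observed),
       method = if (exhaustive) "signflip_exhaustive" else "signflip",
       n_permutations = length(null_stats), seed = cfg$seed)
}

#' Re-centered bootstrap test for group-level R-squared
#'
#' R-squared values are positively biased, so a permutation of signs is not
#' available; instead subject-level values are resampled with replacement,
#' the bootstrap distribution of the mean is re-centered by subtracting the
#' observed mean, and the one-sided p-value is the add-one-corrected
#' proportion of re-centered means at or above the observed mean.
#'
#' @param subject_r2s per-subject R-squared values in `[0, 1]`, n >= 2.
#' @param cfg an [inference_config()].
#' @param exhaustive enumerate all `n^n` ordered resamples (tiny n only).
#' @return list: `observed` (mean), `p_value`, `method`, `n_bootstrap`,
#'   `seed`.
#' @export
recentered_bootstrap_test <- function(subject_r2s, cfg = inference_config(),
                                      exhaustive = FALSE) {
  n <- length(subject_r2s)
  if (n < 2) stop_arg("need >= 2 subjects")
  if (any(subject_r2s < 0 - 1e-12 | subject_r2s > 1 + 1e-12)) {
    stop_arg("R-squared values must lie in [0, 1]")
  }
  observed <- mean(subject_r2s)
  boots <- if (exhaustive) {
    idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    rowMeans(matrix(subject_r2s[idx], nrow(idx), n))
  } else {
    with_seed(cfg$seed, {
      idx <- matrix(sample.int(n, n * cfg$n_bootstrap, replace = TRUE),
                    nrow = cfg$n_bootstrap)
      rowMeans(matrix(subject_r2s[idx], cfg$n_bootstrap, n))
    })
  }
  list(observed = observed,
       p_value = perm_p(boots - observed, observed),
       method = if (exhaustive) "recentered_bootstrap_exhaustive"
                else "recentered_bootstrap",
       n_bootstrap = length(boots), seed = cfg$seed)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure: with ordered p-values `p_(1) <= ... <= p_(m)`, find the
#' largest `k` with `p_(k) <= k q / m` and reject the hypotheses with the `k`
#' smallest p-values.
#'
#' @param p_values p-values in (0, 1].
#' @param q FDR level.
#' @return list: `rejected` (logical mask in input order), `threshold` (the
#'   effective p cutoff; 0 if nothing is rejected), `q`.
#' @export
bh_fdr <- function(p_values, q) {
  if (any(p_values <= 0 | p_values > 1)) stop_arg("p-values must be in (0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  below <- which(ps <= seq_len(m) * q / m)
  if (!length(below)) {
    return(list(rejected = rep(FALSE, m), threshold = 0, q = q))
  }
  k <- max(below)
  rejected <- rep(FALSE, m)
  rejected[ord[seq_len(k)]] <- TRUE
  list(rejected = rejected, threshold = ps[k], q = q)
}

#' Condition-label permutation null for RDM comparisons
#'
#' Builds a null distribution by applying random stimulus permutations
#' jointly to the rows and columns of the model RDM and recomputing the
#' comparison statistic, leaving the neural RDM fixed.
#'
#' @param neural,model `rdm`s over the same stimuli.
#' @param cfg an [inference_config()].
#' @param statistic `function(neural, permuted_model) -> scalar`; default
#'   [spearman_rsa()].
#' @param exhaustive enumerate all `m!` permutations (tiny m only).
#' @return list: `observed`, `p_value`, `null` (numeric vector), `method`,
#'   `seed`.
#' @export
condition_label_permutation_null <- function(neural, model,
                                             cfg = inference_config(),
                                             statistic = spearman_rsa,
                                             exhaustive = FALSE) {
  check_same_stimuli(neural, model)
  m <- nrow(model)
  observed <- statistic(neural, model)
  ids <- rdm_ids(model)
  fast_spearman <- identical(statistic, spearman_rsa)
  if (fast_spearman) {
    # rank the neural vector once; per permutation only the permuted model
    # vector needs ranking
    vn <- rank_standardize(rdm_vectorize(neural))
    mmat <- unclass(model)
    L <- length(vn)
    perm_stat <- function(perm) {
      pm <- mmat[perm, perm]
      tp <- t(pm)
      vm <- rank_standardize(tp[lower.tri(tp)])
      sum(vn * vm) / (L - 1)
    }
  } else {
    perm_stat <- function(perm) {
      pm <- rdm(unclass(model)[perm, perm], stimulus_ids = ids)
      statistic(neural, pm)
    }
  }
  null_stats <- if (exhaustive) {
    perms <- all_permutations(m)
    vapply(perms, perm_stat, numeric(1))
  } else {
    with_seed(cfg$seed,
              vapply(seq_len(cfg$n_permutations),
                     function(k) perm_stat(sample(m)), numeric(1)))
  }
  list(observed = observed, p_value = perm_p(null_stats, observed),
       null = null_stats,
       method = if (exhaustive) "condition_permutation_exhaustive"
                else "condition_permutation",
       seed = cfg$seed)
}

all_permutations <- function(m) {
  if (m > 7) stop_arg("exhaustive permutation only supported for m <= 7")
  if (m == 1) return(list(1L))
  sub <- all_permutations(m - 1)
  out <- vector("list", m * length(sub))
  k <- 0
  for (p in sub) {
    for (pos in seq_len(m)) {
      k <- k + 1
      out[[k]] <- append(p, m, after = pos - 1)
    }
  }
  out
}

#' Bootstrap confidence intervals over subjects (and stimuli)
#'
#' Percentile 95% intervals for a group statistic. In `"subjects"` mode,
#' subject indices are resampled with replacement and the statistic is
#' recomputed. In `"subjects_and_stimuli"` mode, stimulus indices are also
#' resampled with replacement and each resampled subject RDM is rebuilt from
#' the sampled rows/columns; cells pairing a stimulus with its own duplicate
#' (zero-distance artifacts) are set to `NA` and excluded by the statistic.
#'
#' @param per_subject_inputs list of per-subject inputs: scalars for
#'   `"subjects"` mode, `rdm`s for `"subjects_and_stimuli"`.
#' @param statistic `function(list_of_inputs)` or
#'   `function(list_of_inputs, stimulus_index)` returning a scalar. In
#'   stimulus mode the resampled stimulus index vector is passed as second
#'   argument (when accepted) so model RDMs inside the closure can be
#'   resampled identically; duplicate-pair cells arrive as `NA` and must be
#'   excluded (the vectorized comparisons in this package do).
#' @param resample resampling scheme.
#' @param cfg an [inference_config()].
#' @param probs interval probabilities.
#' @return list: `observed`, `ci_low`, `ci_high`, `n_discarded`, `method`,
#'   `seed`.
#' @export
bootstrap_ci <- function(per_subject_inputs, statistic,
                         resample = c("subjects", "subjects_and_stimuli"),
                         cfg = inference_config(), probs = c(0.025, 0.975)) {
  resample <- match.arg(resample)
  n <- length(per_subject_inputs)
  if (n < 2) stop_arg("need >= 2 subjects")
  takes_stim <- length(formals(statistic)) >= 2
  eval_stat <- function(inputs, stim) {
    if (takes_stim) statistic(inputs, stim) else statistic(inputs)
  }
  m <- if (resample == "subjects_and_stimuli") {
    nrow(per_subject_inputs[[1]])
  } else NA_integer_
  observed <- eval_stat(per_subject_inputs,
                        if (is.na(m)) NULL else seq_len(m))
  draws <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_bootstrap), function(k) {
      subj <- sample.int(n, n, replace = TRUE)
      inputs <- per_subject_inputs[subj]
      stim <- NULL
      if (resample == "subjects_and_stimuli") {
        stim <- sample.int(m, m, replace = TRUE)
        dup <- outer(stim, stim, "==") & !diag(TRUE, m)
        inputs <- lapply(inputs, function(r) {
          mat <- unclass(r)[stim, stim]
          mat[dup] <- NA
          structure(mat, class = class(r),
                    dimnames = list(paste0("b", seq_len(m)),
                                    paste0("b", seq_len(m))))
        })
      }
      tryCatch(eval_stat(inputs, stim), error = function(e) NA_real_)
    }, numeric(1))
  })
  bad <- sum(is.na(draws))
  if (bad > 0.1 * cfg$n_bootstrap) {
    stop_arg("statistic undefined on ", bad, " of ", cfg$n_bootstrap,
             " bootstrap draws (> 10%)")
  }
  qs <- quantile(draws, probs = probs, na.rm = TRUE, names = FALSE)
  list(observed = observed, ci_low = qs[1], ci_high = qs[2],
       n_discarded = bad, method = paste0("bootstrap_", resample),
       seed = cfg$seed)
}
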