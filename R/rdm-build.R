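#' Z-score unit response profiles across conditions
#'
#' Standardizes each unit (column) of a condition-by-unit pattern table to
#' mean 0 and population SD 1 across conditions. Constant columns become
#' all-zero with a warning.
#'
#' @param patterns conditions x units numeric matrix.
#' @return matrix of the same shape.
#' @export
zscore_profiles <- function(patterns) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 2) stop_arg("need >= 2 conditions to z-score profiles")
  mu <- colMeans(patterns)
  sdv <- sqrt(colMeans(patterns^2) - mu^2)
  flat <- sdv < 1e-12
  if (any(flat)) {
    warning(sum(flat), " constant unit profile(s) set to zero", call. = FALSE)
    sdv[flat] <- 1
  }
  out <- sweep(sweep(patterns, 2, mu), 2, sdv, "/")
  out[, flat] <- 0
  out
}

#' Split-session neural RDM
#'
#' Correlates every condition's response pattern in session 1 with every
#' condition's pattern in session 2 (Pearson, across units) and converts the
#' cross-session correlation matrix to dissimilarities:
#' `d_ij = 1 - (c_ij + c_ji) / 2` for `i != j`. Because the two sessions
#' carry independent measurement noise, the expected diagonal is no longer
#' zero; `1 - c_ii` is stored on the diagonal but excluded from the
#' vectorized form used in all comparisons.
#'
#' @param patterns_session1,patterns_session2 condition x unit matrices with
#'   identical stimulus order (rownames) and unit count.
#' @return an `rdm` with meta `source = "split_data"`.
#' @export
split_data_rdm <- function(patterns_session1, patterns_session2) {
  p1 <- as.matrix(patterns_session1); p2 <- as.matrix(patterns_session2)
  if (!identical(dim(p1), dim(p2))) {
    stop_arg("sessions must have identical condition and unit counts")
  }
  if (!is.null(rownames(p1)) && !is.null(rownames(p2)) &&
      !identical(rownames(p1), rownames(p2))) {
    stop_arg("sessions must share the same stimulus order")
  }
  if (ncol(p1) < 2) stop_arg("need >= 2 units")
  ids <- rownames(p1)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(p1)))
  flat1 <- apply(p1, 1, sd) < 1e-12
  flat2 <- apply(p2, 1, sd) < 1e-12
  if (any(flat1 | flat2)) {
    stop_arg("zero-variance response pattern for stimulus: ",
             paste(ids[flat1 | flat2], collapse = ", "))
  }
  cc <- cor(t(p1), t(p2))
  d <- 1 - (cc + t(cc)) / 2
  rdm(d, stimulus_ids = ids, meta = list(source = "split_data"))
}

#' Pairwise screen distances of one arrangement trial
#'
#' @param trial an `arrangement_trial` (see [simulate_arrangements()] or
#'   [read_arrangement_log()]).
#' @return data frame `stim_i`, `stim_j`, `distance` (screen px), one row per
#'   unordered pair in the trial's subset.
#' @export
arrangement_distances <- function(trial) {
  xy <- trial$coords
  if (nrow(xy) < 2) stop_arg("an arrangement trial needs >= 2 stimuli")
  idx <- rdm_pair_index(nrow(xy))
  data.frame(
    stim_i = rownames(xy)[idx[, 1]],
    stim_j = rownames(xy)[idx[, 2]],
    distance = sqrt(rowSums((xy[idx[, 1], , drop = FALSE] -
                             xy[idx[, 2], , drop = FALSE])^2)),
    stringsAsFactors = FALSE
  )
}

#' Aggregate arrangement trials into an RDM
#'
#' Averages the sparse pairwise screen distances over all trials measuring
#' each pair (raw pixels, no per-trial rescaling unless requested). With
#' multiple participants, pass trials per participant and average the
#' resulting RDMs with [average_rdms()].
#'
#' @param trials list of `arrangement_trial`s.
#' @param stimulus_ids the full stimulus id set (fixes the RDM order).
#' @param normalize if `TRUE`, divide each trial's distances by their RMS
#'   before averaging (off by default).
#' @return an `rdm` with meta `source = "arrangement"`.
#' @export
aggregate_arrangements <- function(trials, stimulus_ids, normalize = FALSE) {
  m <- length(stimulus_ids)
  sums <- matrix(0, m, m, dimnames = list(stimulus_ids, stimulus_ids))
  counts <- matrix(0L, m, m, dimnames = list(stimulus_ids, stimulus_ids))
  for (tr in trials) {
    dd <- arrangement_distances(tr)
    if (normalize) dd$distance <- dd$distance / sqrt(mean(dd$distance^2))
    i <- match(dd$stim_i, stimulus_ids); j <- match(dd$stim_j, stimulus_ids)
    if (anyNA(i) || anyNA(j)) stop_arg("trial contains unknown stimuli")
    for (k in seq_len(nrow(dd))) {
      sums[i[k], j[k]] <- sums[i[k], j[k]] + dd$distance[k]
      counts[i[k], j[k]] <- counts[i[k], j[k]] + 1L
    }
  }
  sums <- sums + t(sums); counts <- counts + t(counts)
  off <- upper.tri(counts)
  if (any(counts[off] == 0)) {
    idx <- which(counts == 0 & off, arr.ind = TRUE)
    miss <- paste(stimulus_ids[idx[, 1]], stimulus_ids[idx[, 2]], sep = "/")
    stop_arg("pairs never measured: ",
             paste(head(miss, 10), collapse = ", "),
             if (length(miss) > 10) sprintf(" (and %d more)", length(miss) - 10))
  }
  mat <- matrix(0, m, m)
  mat[counts > 0] <- sums[counts > 0] / counts[counts > 0]
  diag(mat) <- 0
  rdm(mat, stimulus_ids = stimulus_ids, meta = list(source = "arrangement"))
}

#' Element-wise average of RDMs
#'
#' @param rdms list of `rdm`s over the same stimuli (same order).
#' @param meta metadata for the result.
#' @export
average_rdms <- function(rdms, meta = list(source = "average")) {
  ids <- rdm_ids(rdms[[1]])
  for (r in rdms) {
    if (!identical(rdm_ids(r), ids)) stop_arg("RDMs must share stimulus order")
  }
  rdm(Reduce(`+`, lapply(rdms, unclass)) / length(rdms),
      stimulus_ids = ids, meta = meta)
}

#' Feature-table RDM
#'
#' Pairwise dissimilarities between condition rows of a feature matrix
#' (e.g., motion-energy features) under a chosen metric. The default is
#' correlation distance (`1 - Pearson r`).
#'
#' @param feature_table conditions x features matrix (rownames = stimulus
#'   ids).
#' @param metric `"correlation"`, `"euclidean"`, or `"cosine"`.
#' @return an `rdm`.
#' @export
feature_rdm <- function(feature_table,
                        metric = c("correlation", "euclidean", "cosine")) {
  metric <- match.arg(metric)
  X <- as.matrix(feature_table)
  if (ncol(X) < 2) stop_arg("need >= 2 features")
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(X)))
  mat <- switch(metric,
    correlation = {
      if (any(apply(X, 1, sd) < 1e-12)) {
        stop_arg("zero-variance feature row under the correlation metric")
      }
      1 - cor(t(X))
    },
    euclidean = as.matrix(dist(X)),
    cosine = {
      nrm <- sqrt(rowSums(X^2))
      if (any(nrm < 1e-12)) stop_arg("zero-norm row under the cosine metric")
      1 - tcrossprod(X / nrm)
    })
  diag(mat) <- 0
  rdm(mat, stimulus_ids = ids, meta = list(source = "feature", metric = metric))
}
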