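#' Spearman RSA between two RDMs
#'
#' Spearman rank correlation between the vectorized upper triangles of a
#' neural and a model RDM (average ranks for ties).
#'
#' @param neural,model `rdm`s over the same stimuli in the same order.
#' @return rank correlation rho.
#' @export
spearman_rsa <- function(neural, model) {
  check_same_stimuli(neural, model)
  v1 <- rdm_vectorize(neural); v2 <- rdm_vectorize(model)
  ok <- is.finite(v1) & is.finite(v2)
  if (sd(v1[ok]) < 1e-12 || sd(v2[ok]) < 1e-12) {
    stop_arg("constant RDM vector: Spearman correlation undefined")
  }
  cor(v1[ok], v2[ok], method = "spearman")
}

check_same_stimuli <- function(a, b) {
  if (!identical(rdm_ids(a), rdm_ids(b))) {
    stop_arg("RDMs must share the same stimuli in the same order")
  }
}

#' Intersubject noise ceiling of representational geometry
#'
#' Leave-one-out intersubject correlation: each subject's RDM is Spearman-
#' correlated with the element-wise mean RDM of the remaining subjects. The
#' group value averages the per-subject correlations on the Fisher-z scale
#' and back-transforms.
#'
#' @param subject_rdms list of `rdm`s, one per subject (>= 2), same stimulus
#'   order.
#' @return list with `per_subject` (named rho vector) and `group` (Fisher-z
#'   mean, back-transformed).
#' @export
isc_noise_ceiling <- function(subject_rdms) {
  n <- length(subject_rdms)
  if (n < 2) stop_arg("need >= 2 subjects for a noise ceiling")
  for (r in subject_rdms) check_same_stimuli(subject_rdms[[1]], r)
  mats <- lapply(subject_rdms, unclass)
  total <- Reduce(`+`, mats)
  rho <- vapply(seq_len(n), function(s) {
    loo <- rdm((total - mats[[s]]) / (n - 1),
               stimulus_ids = rdm_ids(subject_rdms[[1]]))
    spearman_rsa(subject_rdms[[s]], loo)
  }, numeric(1))
  names(rho) <- names(subject_rdms)
  # clamp the boundary (identical RDMs give rho = 1, infinite Fisher z)
  z <- atanh(pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15))
  list(per_subject = rho, group = tanh(mean(z)))
}

rank_standardize <- function(x) {
  r <- rank(x)               # average ranks for ties
  (r - mean(r)) / sd(r)
}

#' Joint rank-regression fit of model RDMs to a neural RDM
#'
#' All model RDM vectors are rank-transformed (average ranks) and
#' standardized; by default the neural RDM vector is transformed the same way
#' so that the single-model case reduces exactly to Spearman rho squared.
#' Ordinary least squares with an intercept; `R^2 = 1 - SSE/SST`.
#'
#' @param neural an `rdm`.
#' @param models named list of model `rdm`s.
#' @param rank_response rank-standardize the neural vector too (default
#'   `TRUE`; set `FALSE` for raw-response regression).
#' @param allow_aliased tolerate perfectly collinear predictors by dropping
#'   aliased columns from the fit (used by [variance_partition()], where a
#'   redundant model must simply contribute no unique variance); the default
#'   errors, naming the dependent models.
#' @return a `joint_fit` list: `r_squared`, `coefficients` (standardized,
#'   named by model; `NA` for aliased columns), `models`, `rank_response`.
#' @export
joint_regression_r2 <- function(neural, models, rank_response = TRUE,
                                allow_aliased = FALSE) {
  if (!length(models)) stop_arg("need >= 1 model")
  if (is.null(names(models)) || any(names(models) == "")) {
    stop_arg("models must be named")
  }
  for (mdl in models) check_same_stimuli(neural, mdl)
  X <- vapply(models, function(mdl) rank_standardize(rdm_vectorize(mdl)),
              numeric(length(rdm_vectorize(neural))))
  X <- as.matrix(X)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1 && !allow_aliased) {
    dep <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1]
    stop_arg("collinear model RDMs: ", paste(dep, collapse = ", "))
  }
  y <- rdm_vectorize(neural)
  y <- if (rank_response) rank_standardize(y) else y
  fit <- lm.fit(cbind(`(intercept)` = 1, X), y)
  sse <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  structure(list(r_squared = 1 - sse / sst,
                 coefficients = fit$coefficients[-1],
                 models = names(models),
                 rank_response = rank_response),
            class = "joint_fit")
}

#' Variance partitioning over model groups
#'
#' Hierarchical regression: the full model uses every model RDM; for each
#' named group a nested model excludes that group's members; the group's
#' unique contribution is `unique R^2 = full R^2 - nested R^2`.
#'
#' @param neural an `rdm`.
#' @param models named list of model `rdm`s.
#' @param groups named list of character vectors, each a proper nonempty
#'   subset of `names(models)`.
#' @param rank_response passed to [joint_regression_r2()].
#' @return a `variance_partition` list: `full_r2`, `nested_r2` (named by
#'   group), `unique_r2` (named by group).
#' @export
variance_partition <- function(neural, models, groups,
                               rank_response = TRUE) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop_arg("groups must be named")
  }
  for (g in names(groups)) {
    mem <- groups[[g]]
    if (!length(mem) || !all(mem %in% names(models))) {
      stop_arg("group '", g, "' must be a nonempty subset of the models")
    }
    if (setequal(mem, names(models))) {
      stop_arg("group '", g, "' equals the full model set; nested model ",
               "would be empty")
    }
  }
  full <- joint_regression_r2(neural, models, rank_response,
                              allow_aliased = TRUE)
  nested <- vapply(groups, function(mem) {
    joint_regression_r2(neural, models[setdiff(names(models), mem)],
                        rank_response, allow_aliased = TRUE)$r_squared
  }, numeric(1))
  structure(list(full_r2 = full$r_squared, nested_r2 = nested,
                 unique_r2 = full$r_squared - nested,
                 coefficients = full$coefficients),
            class = "variance_partition")
}

#' Searchlight-style neighborhood mapping
#'
#' Applies a split-data RSA analysis independently within each neighborhood
#' of measurement units: the two sessions' patterns are restricted to the
#' neighborhood's member units, a split-session RDM is built, and the
#' supplied analysis reduces it to a scalar.
#'
#' @param patterns_s1,patterns_s2 condition x unit matrices (two sessions).
#' @param neighborhoods named list mapping center ids to member unit indices
#'   (e.g., [make_grid_neighborhoods()]).
#' @param analysis `function(rdm) -> scalar`, e.g.
#'   `function(r) spearman_rsa(r, model)`.
#' @return data frame (`center`, `n_members`, `value`); neighborhoods with
#'   fewer than 2 members get `NA`.
#' @export
neighborhood_map <- function(patterns_s1, patterns_s2, neighborhoods,
                             analysis) {
  stopifnot(is.function(analysis))
  centers <- names(neighborhoods)
  if (is.null(centers)) centers <- as.character(seq_along(neighborhoods))
  vals <- vapply(seq_along(neighborhoods), function(k) {
    members <- neighborhoods[[k]]
    if (length(members) < 2) return(NA_real_)
    r <- split_data_rdm(patterns_s1[, members, drop = FALSE],
                        patterns_s2[, members, drop = FALSE])
    analysis(r)
  }, numeric(1))
  data.frame(center = centers, n_members = lengths(neighborhoods),
             value = vals, stringsAsFactors = FALSE)
}
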