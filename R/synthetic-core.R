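#' Construct the stimulus set
#'
#' Builds the labeled stimulus inventory: `n_categories` action categories
#' with `n_exemplars` clip exemplars each (default 18 x 5 = 90 stimuli), with
#' a social/nonsocial flag per category.
#'
#' @param n_categories number of action categories.
#' @param n_exemplars exemplars per category.
#' @param social_fraction fraction of categories flagged social.
#' @return a `stimulus_set` data frame with columns `stimulus_id`,
#'   `category`, `exemplar_index`, `is_social`.
#' @examples
#' nrow(make_stimulus_set())  # 90
#' @export
make_stimulus_set <- function(n_categories = 18L, n_exemplars = 5L,
                              social_fraction = 0.5) {
  if (n_categories < 1 || n_exemplars < 1) {
    stop_arg("n_categories and n_exemplars must be >= 1")
  }
  cats <- sprintf("category%02d", seq_len(n_categories))
  n_social <- round(social_fraction * n_categories)
  out <- data.frame(
    stimulus_id = sprintf("%s_ex%d", rep(cats, each = n_exemplars),
                          rep(seq_len(n_exemplars), n_categories)),
    category = rep(cats, each = n_exemplars),
    exemplar_index = rep(seq_len(n_exemplars), n_categories),
    is_social = rep(seq_len(n_categories) <= n_social, each = n_exemplars),
    stringsAsFactors = FALSE
  )
  class(out) <- c("stimulus_set", "data.frame")
  out
}

# Alternately center rows and z-score columns (population SD) of a feature
# matrix until both hold to ~1e-10.  Balanced features make the downstream
# unit z-scoring of simulated patterns a pure rescaling, so the correlation
# geometry of the latent features survives measurement intact.
balance_features <- function(Z, iters = 80L) {
  for (i in seq_len(iters)) {
    Z <- Z - rowMeans(Z)
    mu <- colMeans(Z)
    sdv <- sqrt(colMeans(Z^2) - mu^2)
    if (any(sdv < 1e-12)) stop_arg("degenerate feature column while balancing")
    Z <- sweep(sweep(Z, 2, mu), 2, sdv, "/")
    if (max(abs(rowMeans(Z))) < 1e-10) break
  }
  Z
}

# Category-structured latent feature matrix: per-feature category effects
# plus exemplar-level noise, balanced.
category_features <- function(stimulus_set, n_features, exemplar_sd = 1.5) {
  cats <- factor(stimulus_set$category)
  m <- nrow(stimulus_set)
  Z <- matrix(rnorm(nlevels(cats) * n_features), nlevels(cats),
              n_features)[as.integer(cats), , drop = FALSE] +
    exemplar_sd * matrix(rnorm(m * n_features), m, n_features)
  rownames(Z) <- stimulus_set$stimulus_id
  balance_features(Z)
}

feature_correlation_rdm <- function(Z, source = "latent") {
  rdm(1 - cor(t(Z)), stimulus_ids = rownames(Z),
      meta = list(source = source, metric = "correlation"))
}

#' Generate named latent model geometries
#'
#' Each model is a correlation-distance RDM over a latent feature matrix
#' (category-structured Gaussian features plus exemplar noise). The pairwise
#' Spearman correlation between model RDM vectors is controlled by mixing a
#' shared latent component into every model's features; the mixing proportion
#' is calibrated numerically against the realized matrices so the mean
#' pairwise model correlation lands within about 0.1 of
#' `inter_model_correlation`.
#'
#' @param stimulus_set a [make_stimulus_set()] data frame.
#' @param model_names character vector of model names.
#' @param inter_model_correlation target pairwise Spearman correlation
#'   between model RDM vectors, in `[0, 1)`.
#' @param n_features latent features per model.
#' @param exemplar_sd within-category feature noise SD.
#' @param rng_seed integer seed.
#' @return named list of `rdm` objects; each carries its latent feature
#'   matrix as attribute `"features"` (the generator's ground truth).
#' @export
make_model_geometries <- function(stimulus_set,
                                  model_names = c("sociality", "transitivity",
                                                  "object", "nuisance"),
                                  inter_model_correlation = 0,
                                  n_features = 25L, exemplar_sd = 1.5,
                                  rng_seed = 1L) {
  if (inter_model_correlation < 0 || inter_model_correlation >= 1) {
    stop_arg("inter_model_correlation must be in [0, 1)")
  }
  with_seed(rng_seed, {
    own <- lapply(model_names, function(nm) {
      category_features(stimulus_set, n_features, exemplar_sd)
    })
    names(own) <- model_names
    if (inter_model_correlation == 0 || length(model_names) < 2) {
      feats <- own
    } else {
      shared <- category_features(stimulus_set, n_features, exemplar_sd)
      mix <- function(a) {
        lapply(own, function(Zm) {
          balance_features(sqrt(a) * shared + sqrt(1 - a) * Zm)
        })
      }
      mean_corr <- function(a) {
        vs <- lapply(mix(a), function(Z) rdm_vectorize(feature_correlation_rdm(Z)))
        cm <- cor(do.call(cbind, vs), method = "spearman")
        mean(cm[upper.tri(cm)])
      }
      # realized-matrix calibration: monotone in the mixing proportion
      f <- function(a) mean_corr(a) - inter_model_correlation
      a_star <- if (f(0) >= 0) 0 else uniroot(f, c(0, 0.999), tol = 1e-4)$root
      feats <- mix(a_star)
    }
    out <- lapply(model_names, function(nm) {
      r <- feature_correlation_rdm(feats[[nm]], source = nm)
      attr(r, "features") <- feats[[nm]]
      r
    })
    names(out) <- model_names
    out
  })
}

#' Category-block model RDM
#'
#' The idealized categorical geometry: dissimilarity `within` for stimulus
#' pairs sharing a category and `between` otherwise.
#'
#' @param stimulus_set a [make_stimulus_set()] data frame.
#' @param within,between dissimilarity values (within < between).
#' @export
category_block_rdm <- function(stimulus_set, within = 0, between = 1) {
  same <- outer(stimulus_set$category, stimulus_set$category, "==")
  mat <- ifelse(same, within, between)
  diag(mat) <- 0
  rdm(mat, stimulus_ids = stimulus_set$stimulus_id,
      meta = list(source = "category_block"))
}

#' Ground truth for the pattern simulator
#'
#' Bundles the latent model geometries, their mixture weights, and the
#' simulated measurement parameters.
#'
#' @param model_rdms named list of model RDMs carrying `"features"`
#'   attributes (from [make_model_geometries()]).
#' @param weights nonnegative mixture weight per model (recycled if scalar).
#' @param n_subjects,n_sessions,n_units measurement dimensions.
#' @param noise_sd per-unit Gaussian noise SD, in units of the (unit-variance)
#'   latent feature scale.
#' @param seed integer seed for the shared unit map and noise streams.
#' @return a `ground_truth` list.
#' @export
ground_truth <- function(model_rdms, weights = 1, n_subjects = 20L,
                         n_sessions = 2L, n_units = 500L, noise_sd = 0.6,
                         seed = 1L) {
  weights <- rep_len(weights, length(model_rdms))
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop_arg("mixture weights must be finite and nonnegative")
  }
  if (is.null(names(model_rdms))) stop_arg("model_rdms must be named")
  ids <- rdm_ids(model_rdms[[1]])
  for (r in model_rdms) {
    if (!identical(rdm_ids(r), ids)) {
      stop_arg("all model RDMs must share the same stimulus order")
    }
  }
  structure(list(model_rdms = model_rdms, weights = weights,
                 n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 n_units = as.integer(n_units),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ground_truth")
}

# Equalize the per-unit response variances of the linear map A (latent x
# units, orthonormal rows) under the feature covariance Sc by Givens
# rotations of unit pairs.  Rotations preserve A A' (hence the condition
# geometry) while moving variance between the two units; pairing the current
# extremes drives the spread to ~1e-10 in O(n_units) steps.
equalize_unit_variances <- function(A, Sc, tol = 1e-10, max_steps = 50000L) {
  SA <- Sc %*% A
  v <- colSums(A * SA)
  tgt <- mean(v)
  for (step in seq_len(max_steps)) {
    j1 <- which.min(v); j2 <- which.max(v)
    if (v[j2] - v[j1] < tol) break
    a1 <- A[, j1]; a2 <- A[, j2]
    v1 <- v[j1]; v2 <- v[j2]
    x12 <- sum(a1 * SA[, j2])
    fv <- function(th) cos(th)^2 * v1 + sin(th)^2 * v2 + sin(2 * th) * x12 - tgt
    th <- uniroot(fv, c(0, pi / 2), tol = 1e-14)$root
    c1 <- cos(th) * a1 + sin(th) * a2
    c2 <- -sin(th) * a1 + cos(th) * a2
    A[, j1] <- c1; A[, j2] <- c2
    SA[, j1] <- Sc %*% c1; SA[, j2] <- Sc %*% c2
    v[j1] <- sum(c1 * SA[, j1]); v[j2] <- sum(c2 * SA[, j2])
  }
  A
}

#' Simulate condition-by-unit response patterns
#'
#' Generates per-subject, per-session response pattern tables whose
#' split-session correlation geometry reflects a known weighted mixture of
#' the latent model geometries. The weighted, concatenated latent features
#' are mapped to `n_units` measurement channels through a single shared
#' linear map with orthonormal rows (topographic idiosyncrasy is assumed
#' removed by functional alignment); the map's per-unit response variances
#' are exactly equalized so that unit-wise z-scoring does not distort the
#' condition geometry. Independent Gaussian noise is added per subject,
#' session, and unit, and every unit profile is z-scored across conditions.
#'
#' With `noise_sd = 0` and a single model at weight 1, the split-data RDM of
#' the simulated patterns rank-correlates with the generating model RDM at
#' Spearman rho > 0.999.
#'
#' @param truth a [ground_truth()] object.
#' @return nested list `patterns[[subject]][[session]]`: condition x unit
#'   matrices (stimulus ids as rownames), unit profiles z-scored across
#'   conditions. The composite latent RDM is attached as attribute
#'   `"composite_rdm"`.
#' @export
simulate_subject_patterns <- function(truth) {
  feats <- lapply(truth$model_rdms, attr, "features")
  if (any(vapply(feats, is.null, TRUE))) {
    stop_arg("model RDMs must carry latent features (use make_model_geometries)")
  }
  w <- truth$weights / sum(truth$weights)
  Zmix <- do.call(cbind, Map(function(Z, wi) sqrt(wi) * Z, feats, w))
  q <- ncol(Zmix)
  if (q > truth$n_units) stop_arg("latent dimension exceeds n_units")
  m <- nrow(Zmix)
  with_seed(truth$seed, {
    A <- t(qr.Q(qr(matrix(rnorm(truth$n_units * q), truth$n_units, q))))
    A <- equalize_unit_variances(A, crossprod(Zmix) / m)
    P0 <- Zmix %*% A
    patterns <- lapply(seq_len(truth$n_subjects), function(s) {
      lapply(seq_len(truth$n_sessions), function(ss) {
        P <- P0 + truth$noise_sd * matrix(rnorm(m * truth$n_units), m,
                                          truth$n_units)
        rownames(P) <- rownames(Zmix)
        zscore_profiles(P)
      })
    })
  })
  attr(patterns, "composite_rdm") <- feature_correlation_rdm(Zmix, "composite")
  patterns
}
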