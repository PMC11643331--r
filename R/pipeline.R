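#' Pipeline configuration
#'
#' One configuration object drives the full synthetic pipeline: the stimulus
#' set shape, the latent model geometries and their mixture weights in the
#' simulated neural data, the measured-model roster, model groupings for
#' variance partitioning, measurement dimensions, and inference settings.
#'
#' Defaults state the emulated experiment: 18 categories x 5 exemplars,
#' 20 subjects, 2 sessions, 500 units, nine measured models (five
#' arrangement tasks, verb/nonverb semantics, gaze, motion energy), with the
#' action-task geometries (transitivity, sociality) dominating the neural
#' mixture.
#'
#' @param n_categories,n_exemplars stimulus set shape.
#' @param n_subjects,n_sessions,n_units neural measurement dimensions.
#' @param noise_sd pattern noise SD (latent feature scale).
#' @param weights named nonnegative mixture weights over the latent
#'   arrangement geometries.
#' @param groups named model groups for variance partitioning.
#' @param n_latent_features latent features per model geometry.
#' @param arrangement_noise_px placement jitter for simulated arrangements.
#' @param n_gaze_participants,n_gaze_blocks gaze simulation size.
#' @param gaze_rate_hz gaze sampling rate (Hz).
#' @param inference an [inference_config()].
#' @param timing a [timing_config()].
#' @param seed global seed; all stage seeds derive from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_categories = 18L, n_exemplars = 5L,
                            n_subjects = 20L, n_sessions = 2L,
                            n_units = 500L, noise_sd = 0.6,
                            weights = c(transitivity = 0.35, sociality = 0.30,
                                        person = 0.15, object = 0.12,
                                        scene = 0.08),
                            groups = list(
                              action = c("sociality", "transitivity"),
                              visual = c("person", "object", "scene"),
                              semantic = c("verb", "nonverb")),
                            n_latent_features = 25L,
                            arrangement_noise_px = 10,
                            n_gaze_participants = 17L, n_gaze_blocks = 4L,
                            gaze_rate_hz = 1000,
                            inference = inference_config(),
                            timing = timing_config(),
                            seed = 1L) {
  if (any(weights < 0) || is.null(names(weights))) {
    stop_arg("weights must be named and nonnegative")
  }
  structure(list(n_categories = as.integer(n_categories),
                 n_exemplars = as.integer(n_exemplars),
                 n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 n_units = as.integer(n_units), noise_sd = noise_sd,
                 weights = weights, groups = groups,
                 n_latent_features = as.integer(n_latent_features),
                 arrangement_noise_px = arrangement_noise_px,
                 n_gaze_participants = as.integer(n_gaze_participants),
                 n_gaze_blocks = as.integer(n_gaze_blocks),
                 gaze_rate_hz = gaze_rate_hz,
                 inference = inference, timing = timing,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Simulate every pipeline input from known ground truth
#'
#' Builds the full synthetic bundle: stimulus set, latent model geometries,
#' neural patterns mixing the latent geometries at the configured weights,
#' arrangement logs for each latent task, gaze logs, annotations plus
#' embedding table, a motion-energy-like feature table, and the ground-truth
#' record.
#'
#' @param cfg a [pipeline_config()].
#' @return a `synthetic_bundle` list.
#' @export
make_synthetic_bundle <- function(cfg = pipeline_config()) {
  stim <- make_stimulus_set(cfg$n_categories, cfg$n_exemplars)
  latents <- make_model_geometries(stim, model_names = names(cfg$weights),
                                   n_features = cfg$n_latent_features,
                                   rng_seed = cfg$seed)
  truth <- ground_truth(latents, weights = cfg$weights,
                        n_subjects = cfg$n_subjects,
                        n_sessions = cfg$n_sessions,
                        n_units = cfg$n_units, noise_sd = cfg$noise_sd,
                        seed = cfg$seed + 1L)
  patterns <- simulate_subject_patterns(truth)
  plan <- plan_arrangement_subsets(stim$stimulus_id,
                                   n_subsets = min(12L, nrow(stim) %/% 5L),
                                   subset_size = max(3L, nrow(stim) %/% 3L),
                                   n_candidates = 50L,
                                   rng_seed = cfg$seed + 2L)
  arrangements <- lapply(seq_along(latents), function(k) {
    simulate_arrangements(latents[[k]], plan,
                          placement_noise_sd = cfg$arrangement_noise_px,
                          task = names(latents)[k],
                          rng_seed = cfg$seed + 10L + k)
  })
  names(arrangements) <- names(latents)
  gaze <- simulate_gaze(stim, n_participants = cfg$n_gaze_participants,
                        n_blocks = cfg$n_gaze_blocks,
                        rate_hz = cfg$gaze_rate_hz,
                        rng_seed = cfg$seed + 20L)
  sem <- simulate_annotations(stim, rng_seed = cfg$seed + 21L)
  moten <- with_seed(cfg$seed + 22L, {
    base <- attr(latents[[length(latents)]], "features")
    feats <- base + 0.8 * matrix(rnorm(length(base)), nrow(base))
    rownames(feats) <- stim$stimulus_id
    feats
  })
  structure(list(config = cfg, stimulus_set = stim, latent_models = latents,
                 truth = truth, patterns = patterns, subset_plan = plan,
                 arrangements = arrangements, gaze = gaze,
                 annotations = sem$annotations, embeddings = sem$embeddings,
                 motion_energy = moten),
            class = "synthetic_bundle")
}

# measured model RDMs from the bundle's raw simulated logs
build_model_rdms <- function(bundle) {
  stim_ids <- bundle$stimulus_set$stimulus_id
  models <- lapply(bundle$arrangements, aggregate_arrangements,
                   stimulus_ids = stim_ids)
  models$verb <- semantic_rdm(bundle$annotations, bundle$embeddings, "verb",
                              stimulus_ids = stim_ids)
  models$nonverb <- semantic_rdm(bundle$annotations, bundle$embeddings,
                                 "nonverb", stimulus_ids = stim_ids)
  models$gaze <- build_gaze_rdm(bundle$gaze, stimulus_ids = stim_ids)
  models$motion_energy <- feature_rdm(bundle$motion_energy, "correlation")
  models
}

#' Run the full synthetic analysis pipeline
#'
#' simulate -> build RDMs -> RSA -> joint fit -> variance partitioning ->
#' inference. All stage seeds derive from `cfg$seed`; rerunning with the same
#' configuration reproduces every table bit for bit.
#'
#' @param cfg a [pipeline_config()].
#' @param bundle optionally, a pre-built [make_synthetic_bundle()] result
#'   (it must carry the same config).
#' @return a `pipeline_result` list of tidy tables: `rsa` (subject x model
#'   rho), `rsa_summary` (group-mean r, sign-flip p, FDR mask), `ceiling`
#'   (noise-ceiling r per subject and group), `joint` (per-subject R^2 and
#'   coefficients), `joint_summary`, `partition` (per-subject unique R^2 per
#'   group), `partition_summary`, plus `model_rdms`, `neural_rdms`, and a
#'   `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), bundle = NULL) {
  if (is.null(bundle)) bundle <- make_synthetic_bundle(cfg)
  models <- build_model_rdms(bundle)
  neural <- lapply(bundle$patterns, function(sess) {
    split_data_rdm(sess[[1]], sess[[length(sess)]])
  })
  names(neural) <- sprintf("sub%02d", seq_along(neural))

  rsa_tab <- do.call(rbind, lapply(names(neural), function(s) {
    data.frame(subject = s, model = names(models),
               rho = vapply(models, function(mdl)
                 spearman_rsa(neural[[s]], mdl), numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  ceiling <- isc_noise_ceiling(neural)

  infc <- cfg$inference
  rsa_summary <- do.call(rbind, lapply(names(models), function(mdl) {
    rs <- rsa_tab$rho[rsa_tab$model == mdl]
    test <- signflip_permutation_test(rs, infc)
    data.frame(model = mdl, mean_r = test$observed_r, p = test$p_value,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rsa_summary$p_fdr_rejected <- bh_fdr(rsa_summary$p, infc$fdr_q)$rejected

  fits <- lapply(neural, joint_regression_r2, models = models)
  joint_tab <- do.call(rbind, lapply(names(fits), function(s) {
    data.frame(subject = s, t(c(r_squared = fits[[s]]$r_squared,
                                fits[[s]]$coefficients)),
               stringsAsFactors = FALSE, row.names = NULL, check.names = FALSE)
  }))
  r2s <- vapply(fits, `[[`, numeric(1), "r_squared")
  boot <- recentered_bootstrap_test(pmin(pmax(r2s, 0), 1), infc)
  joint_summary <- data.frame(
    mean_r2 = mean(r2s), p = boot$p_value,
    ceiling_r = ceiling$group,
    ceiling_share = ceiling_normalized_share(mean(r2s), ceiling$group),
    row.names = NULL)

  parts <- lapply(neural, variance_partition, models = models,
                  groups = cfg$groups)
  partition_tab <- do.call(rbind, lapply(names(parts), function(s) {
    vp <- parts[[s]]
    data.frame(subject = s, group = names(vp$unique_r2),
               full_r2 = vp$full_r2,
               nested_r2 = as.numeric(vp$nested_r2),
               unique_r2 = as.numeric(vp$unique_r2),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  partition_summary <- do.call(rbind, lapply(names(cfg$groups), function(g) {
    u <- partition_tab$unique_r2[partition_tab$group == g]
    boot_g <- recentered_bootstrap_test(pmin(pmax(u, 0), 1), infc)
    data.frame(group = g, mean_unique_r2 = mean(u), p = boot_g$p_value,
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  structure(list(
    rsa = rsa_tab, rsa_summary = rsa_summary,
    ceiling = data.frame(subject = names(ceiling$per_subject),
                         rho = as.numeric(ceiling$per_subject),
                         row.names = NULL),
    ceiling_group = ceiling$group,
    joint = joint_tab, joint_summary = joint_summary,
    partition = partition_tab, partition_summary = partition_summary,
    model_rdms = models, neural_rdms = neural, bundle = bundle,
    manifest = list(seed = cfg$seed,
                    package_version = as.character(
                      utils::packageVersion("actionrsa")),
                    n_subjects = cfg$n_subjects, n_units = cfg$n_units,
                    noise_sd = cfg$noise_sd, weights = as.list(cfg$weights),
                    n_permutations = infc$n_permutations,
                    n_bootstrap = infc$n_bootstrap, fdr_q = infc$fdr_q)),
    class = "pipeline_result")
}

#' Share of the meaningful (noise-ceiling-bounded) variance explained
#'
#' The noise ceiling is an intersubject correlation `r`; squaring it bounds
#' the variance any model could explain. The ceiling-normalized share of a
#' joint fit is `R^2 / r_ceiling^2`.
#'
#' @param r2 joint-model R-squared.
#' @param ceiling_r noise-ceiling correlation.
#' @return the share (proportion; multiply by 100 for percent).
#' @examples
#' ceiling_normalized_share(0.22, 0.75)  # ~0.39
#' @export
ceiling_normalized_share <- function(r2, ceiling_r) {
  if (ceiling_r <= 0) stop_arg("ceiling_r must be positive")
  r2 / ceiling_r^2
}

#' Human-readable summary of a pipeline result
#'
#' @param result a `pipeline_result`.
#' @return markdown text (character scalar), also printed.
#' @export
report_summary <- function(result) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")
  lines <- c(
    "# Representational geometry summary",
    "",
    sprintf("Subjects: %d; models: %d; seed: %d",
            length(result$neural_rdms), length(result$model_rdms),
            result$manifest$seed),
    "",
    "## Model correlations (group mean r, sign-flip p)",
    sprintf("- %s: r = %s (p = %s%s)", result$rsa_summary$model,
            fmt(result$rsa_summary$mean_r), fmt(result$rsa_summary$p, 4),
            ifelse(result$rsa_summary$p_fdr_rejected, ", FDR+", "")),
    "",
    sprintf("Noise ceiling (leave-one-out intersubject r): %s",
            fmt(result$ceiling_group)),
    sprintf("Joint model R^2: %s (bootstrap p = %s)",
            fmt(result$joint_summary$mean_r2),
            fmt(result$joint_summary$p, 4)),
    sprintf("Ceiling-normalized share: %s%% of the meaningful variance",
            fmt(100 * result$joint_summary$ceiling_share, 1)),
    "",
    "## Unique variance by model group",
    sprintf("- %s: unique R^2 = %s (p = %s)",
            result$partition_summary$group,
            fmt(result$partition_summary$mean_unique_r2),
            fmt(result$partition_summary$p, 4)))
  txt <- paste(lines, collapse = "\n")
  cat(txt, "\n")
  invisible(txt)
}

#' @export
print.pipeline_result <- function(x, ...) {
  report_summary(x)
  invisible(x)
}
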