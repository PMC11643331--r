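# exhaustive adjacency oracle: table of ordered circular pairs
count_circular_pairs <- function(s) {
  table(paste(s, c(s[-1], s[1]), sep = "->"))
}

test_that("serially balanced sequences cover every ordered pair exactly once (n = 1..12)", {
  for (n in 1:12) {
    suppress <- if (n == 4) suppressWarnings else identity
    s <- suppress(build_serially_balanced_sequence(n, rng_seed = 100 + n))
    expect_length(s, n^2)
    expect_setequal(unique(s), 0:(n - 1))
    counts <- count_circular_pairs(s)
    expect_length(counts, n^2)
    expect_true(all(counts == 1))
  }
})

test_that("even alphabets yield block structure (each block a permutation), except the provably infeasible n = 4", {
  for (n in c(2, 6, 8, 10, 12)) {
    s <- build_serially_balanced_sequence(n, rng_seed = n)
    blocks <- split(s, rep(seq_len(n), each = n))
    expect_true(all(vapply(blocks, function(b) length(unique(b)) == n, TRUE)))
  }
  # n = 4: the complete search space contains no block-structured circular
  # solution; the generator says so and falls back to the unblocked sequence
  expect_warning(s4 <- build_serially_balanced_sequence(4, rng_seed = 1),
                 "no block-structured")
  expect_true(is_serially_balanced(s4))
  expect_false(is_serially_balanced(s4, blocked = TRUE))
})

test_that("n = 20 sequence has 400 trials and is reproducible; n = 1 degenerates to (0,0) self pair", {
  s <- build_serially_balanced_sequence(20, rng_seed = 7)
  expect_length(s, 400)
  expect_true(is_serially_balanced(s, blocked = TRUE))
  expect_identical(s, build_serially_balanced_sequence(20, rng_seed = 7))
  expect_identical(build_serially_balanced_sequence(1), 0L)
})

test_that("category/exemplar assignment uses each exemplar once per run", {
  # 4 categories x 2 exemplars on a 6-code balanced sequence, runs of 12:
  # each code occurs twice per run, matching the exemplar count
  stim <- make_stimulus_set(4L, 2L)
  s <- build_serially_balanced_sequence(6, rng_seed = 2)
  des <- assign_categories_and_exemplars(s, stim, run_length = 12,
                                         rng_seed = 3)
  expect_s3_class(des, "design_sequence")
  for (r in unique(des$run)) {
    for (cat in unique(stim$category)) {
      got <- sort(des$exemplar_id[des$run == r & des$role == cat])
      expect_identical(got, sort(stim$stimulus_id[stim$category == cat]))
    }
  }
  # degenerate world: one category, one exemplar, single run
  stim1 <- make_stimulus_set(1L, 1L)
  s3 <- build_serially_balanced_sequence(3, rng_seed = 4)
  des1 <- assign_categories_and_exemplars(s3, stim1, rng_seed = 5)
  expect_true(all(des1$exemplar_id[!is.na(des1$category)] ==
                    stim1$stimulus_id))
  expect_true(sum(des1$role == "category01") > 0)
  # mismatched run length errors, naming the category
  expect_error(assign_categories_and_exemplars(s, stim, run_length = 6),
               "category")
})

test_that("probe trials following null/probe trials are converted to nulls, left to right", {
  stim <- make_stimulus_set(2L, 1L)
  mk <- function(roles) {
    structure(data.frame(trial = seq_along(roles), type_code = 0L,
                         role = roles,
                         category = ifelse(roles %in% c("null", "probe"),
                                           NA, roles),
                         exemplar_id = NA_character_, run = 1L,
                         stringsAsFactors = FALSE),
              class = c("design_sequence", "data.frame"))
  }
  fixed <- fix_probe_collisions(mk(c("category01", "null", "probe",
                                     "category02", "probe")))
  expect_identical(fixed$role, c("category01", "null", "null", "category02",
                                 "probe"))
  # chained repair: probe after probe-after-null is also repaired
  chained <- fix_probe_collisions(mk(c("category01", "null", "probe",
                                       "probe", "category02")))
  expect_identical(chained$role[3:4], c("null", "null"))
  # no-collision sequence passes through unchanged
  clean <- mk(c("category01", "probe", "category02", "null", "category01"))
  expect_identical(fix_probe_collisions(clean)$role, clean$role)
})

test_that("no repaired design retains a probe preceded by null/probe (scan oracle over full designs)", {
  stim <- make_stimulus_set()
  for (seed in 1:3) {
    s <- build_serially_balanced_sequence(20, rng_seed = seed)
    des <- assign_categories_and_exemplars(s, stim, run_length = 100,
                                           rng_seed = seed)
    fixed <- fix_probe_collisions(des)
    role <- fixed$role
    bad <- which(role[-1] == "probe" & role[-length(role)] %in%
                   c("null", "probe"))
    expect_length(bad, 0)
  }
})

test_that("jittered ISIs hit the exact total, respect the floor, and sit on the 0.1 s grid", {
  for (seed in 1:20) {
    isis <- sample_jittered_isis(100, rng_seed = seed)
    expect_equal(sum(isis), 250, tolerance = 1e-9)
    expect_true(all(isis >= 2 - 1e-12))
    expect_equal(isis, round(isis, 1), tolerance = 1e-12)
  }
  # zero-variance limit: mean == min
  cfg0 <- timing_config(mean_isi_s = 2, min_isi_s = 2)
  expect_identical(sample_jittered_isis(10, cfg0), rep(2, 10))
  expect_error(timing_config(mean_isi_s = 1.5, min_isi_s = 2), "min_isi")
})

test_that("design efficiency matches an independent trace-formula oracle and flags singular designs", {
  gen <- toy_design_generator(n_events = 20, n_cond = 4)
  cand <- with_seed_test(11, gen(1))
  eff <- design_efficiency(cand$onsets, cand$durations, cand$conditions)
  expect_gt(eff, 0)
  expect_identical(eff,
                   design_efficiency(cand$onsets, cand$durations,
                                     cand$conditions))
  # independent oracle: rebuild X by direct convolution sums, then the trace
  dt <- 0.1
  total_s <- max(cand$onsets + 2.5) + 30
  n_fine <- ceiling(total_s / dt)
  tgrid <- (seq_len(n_fine) - 1) * dt
  hrf <- hrf_double_gamma(seq(0, 32, by = dt))
  X <- matrix(0, length(seq(1, n_fine, by = 10)), 4)
  for (ci in 1:4) {
    resp <- numeric(n_fine)
    for (e in which(cand$conditions == ci)) {
      idx_on <- (floor(cand$onsets[e] / dt + 1e-9) + 1):
        min(n_fine, floor((cand$onsets[e] + 2.5) / dt + 1e-9))
      for (i in idx_on) {
        span <- i:min(n_fine, i + length(hrf) - 1)
        resp[span] <- resp[span] + hrf[seq_along(span)]
      }
    }
    X[, ci] <- resp[seq(1, n_fine, by = 10)]
  }
  Xd <- cbind(1, X)
  C <- cbind(0, diag(4))
  oracle <- 1 / sum(diag(C %*% solve(crossprod(Xd)) %*% t(C)))
  expect_equal(eff, oracle, tolerance = 1e-10)
})

test_that("overlapping duplicate condition columns give zero efficiency", {
  on <- seq(0, 95, by = 5)
  conds <- rep(c("a", "b"), length.out = length(on))
  # condition b events duplicated exactly onto condition a onsets
  expect_warning(
    eff <- design_efficiency(sort(c(on, on + 1e-6)), 2.5,
                             c(rep("a", length(on)), rep("b", length(on)))[
                               order(c(on, on + 1e-6))]),
    "singular")
  expect_identical(eff, 0)
})

test_that("select_best_design returns the argmax with lowest-index ties, reproducibly", {
  gen <- toy_design_generator()
  sel <- select_best_design(gen, n_candidates = 10, rng_seed = 5)
  effs <- attr(sel, "efficiencies")
  expect_length(effs, 10)
  expect_identical(sel$candidate_index, which.max(effs))
  expect_identical(sel$efficiency, max(effs))
  sel2 <- select_best_design(gen, n_candidates = 10, rng_seed = 5)
  expect_identical(sel$onsets, sel2$onsets)
  one <- select_best_design(gen, n_candidates = 1, rng_seed = 6)
  expect_identical(one$candidate_index, 1L)
})

test_that("runs are partitioned with correct context trials and a 535 s default duration", {
  stim <- make_stimulus_set()
  s <- build_serially_balanced_sequence(20, rng_seed = 8)
  des <- assign_categories_and_exemplars(s, stim, run_length = 100,
                                         rng_seed = 8)
  prep <- data.frame(category = unique(stim$category),
                     stimulus_id = paste0(unique(stim$category), "_prep"),
                     stringsAsFactors = FALSE)
  runs <- partition_runs(des, 4, prep, rng_seed = 9)
  expect_length(runs, 4)
  for (r in runs) expect_equal(attr(r, "duration_s"), 535, tolerance = 1e-9)
  # context categories replicate the previous run's final three trials
  for (k in 2:4) {
    ctx <- runs[[k]][runs[[k]]$phase == "context", ]
    prev_tail <- tail(runs[[k - 1]][runs[[k - 1]]$phase == "trial", ], 3)
    expect_identical(ctx$role, prev_tail$role)
    # context exemplars come from the preparatory pool, not the main set
    real <- !is.na(ctx$category)
    expect_true(all(grepl("_prep$", ctx$exemplar_id[real])))
  }
  # first run wraps around to the session's final three trials
  ctx1 <- runs[[1]][runs[[1]]$phase == "context", ]
  sess_tail <- tail(runs[[4]][runs[[4]]$phase == "trial", ], 3)
  expect_identical(ctx1$role, sess_tail$role)
  # missing category in the pool errors (drop one the context actually needs)
  needed <- stats::na.omit(unlist(lapply(runs, function(r) {
    r$category[r$phase == "context"]
  })))[1]
  expect_error(partition_runs(des, 4, prep[prep$category != needed, ],
                              rng_seed = 9),
               "preparatory pool")
})

test_that("arrangement subset plans cover pairs as scored by a brute-force oracle", {
  plan <- plan_arrangement_subsets(paste0("v", 1:6), n_subsets = 2,
                                   subset_size = 3, n_candidates = 20,
                                   rng_seed = 3)
  expect_length(plan$subsets, 3)
  expect_length(plan$subsets[[1]], 6)    # full set first
  expect_true(all(lengths(plan$subsets[-1]) == 3))
  # oracle recount of the winning plan's score
  pairs <- unique(unlist(lapply(plan$subsets[-1], function(s) {
    apply(combn(sort(s), 2), 2, paste, collapse = "|")
  })))
  expect_identical(plan$unique_pair_count, length(pairs))
  # full-coverage limit
  full <- plan_arrangement_subsets(paste0("v", 1:6), n_subsets = 2,
                                   subset_size = 6, n_candidates = 3,
                                   rng_seed = 4)
  expect_equal(full$unique_pair_count, choose(6, 2))
  # reproducible
  plan2 <- plan_arrangement_subsets(paste0("v", 1:6), n_subsets = 2,
                                    subset_size = 3, n_candidates = 20,
                                    rng_seed = 3)
  expect_identical(plan$subsets, plan2$subsets)
})

test_that("default-shaped plan has 13 subsets: the full set plus 12 of 30", {
  plan <- plan_arrangement_subsets(paste0("v", 1:90), n_candidates = 5,
                                   rng_seed = 1)
  expect_length(plan$subsets, 13)
  expect_identical(lengths(plan$subsets), c(90L, rep(30L, 12)))
  expect_true(all(vapply(plan$subsets, anyDuplicated, 1L) == 0L))
})
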