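test_that("rdm objects validate, vectorize in row-major pair order, and round-trip", {
  mat <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  r <- rdm(mat, stimulus_ids = c("a", "b", "c"))
  expect_identical(rdm_vectorize(r), c(1, 2, 3))  # (1,2), (1,3), (2,3)
  expect_identical(rdm_pair_index(3)[, "j"], c(2L, 3L, 3L))
  # row-major order differs from column-major beyond m = 3
  idx4 <- rdm_pair_index(4)
  expect_identical(idx4[, "i"], c(1L, 1L, 1L, 2L, 2L, 3L))
  v <- rdm_vectorize(random_rdm(7, seed = 1))
  expect_identical(rdm_vectorize(rdm_devectorize(v)), v)
  expect_length(rdm_vectorize(random_rdm(90, seed = 2)), 4005L)
  expect_error(rdm(matrix(1:6, 2, 3)), "square")
  bad <- mat; bad[1, 2] <- 9
  expect_error(rdm(bad), "asymmetric")
  expect_error(rdm(matrix(c(0, NA, NA, 0), 2)), "finite")
})

test_that("rdm text formats round-trip in both layouts", {
  r <- random_rdm(6, seed = 3)
  sq <- tempfile(fileext = ".csv"); lg <- tempfile(fileext = ".tsv")
  write_rdm(r, sq, "square"); write_rdm(r, lg, "long")
  expect_equal(unclass(read_rdm(sq)), unclass(r), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rdm_vectorize(read_rdm(lg)), rdm_vectorize(r),
               tolerance = 1e-12)
  expect_identical(rdm_ids(read_rdm(lg, "long")), rdm_ids(r))
  unlink(c(sq, lg))
})

test_that("zscore_profiles standardizes every unit, is idempotent, and flags constants", {
  expect_equal(zscore_profiles(cbind(u = c(1, 2, 3)))[, 1],
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  X <- with_seed_test(4, matrix(rnorm(90 * 50), 90))
  Z <- zscore_profiles(X)
  # recompute oracle, column by column
  for (j in c(1, 25, 50)) {
    mu <- mean(X[, j]); sdv <- sqrt(mean((X[, j] - mu)^2))
    expect_equal(Z[, j], (X[, j] - mu) / sdv, tolerance = 1e-12)
  }
  expect_equal(colMeans(Z), rep(0, 50), tolerance = 1e-9)
  expect_equal(colMeans(Z^2), rep(1, 50), tolerance = 1e-9)
  expect_equal(zscore_profiles(Z), Z, tolerance = 1e-9)
  expect_warning(Zc <- zscore_profiles(cbind(a = c(1, 2, 3), b = c(5, 5, 5))),
                 "constant")
  expect_identical(Zc[, "b"], c(0, 0, 0))
})

test_that("split-data RDMs match a naive double-loop correlation oracle", {
  p1 <- with_seed_test(5, matrix(rnorm(10 * 30), 10,
                                 dimnames = list(paste0("s", 1:10), NULL)))
  p2 <- with_seed_test(6, matrix(rnorm(10 * 30), 10,
                                 dimnames = list(paste0("s", 1:10), NULL)))
  r <- split_data_rdm(p1, p2)
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) {
    for (j in 1:10) {
      oracle[i, j] <- 1 - (cor(p1[i, ], p2[j, ]) + cor(p1[j, ], p2[i, ])) / 2
    }
  }
  expect_equal(unclass(r), oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("split-data RDM limiting cases: identity, orthogonality, anti-correlation", {
  base <- rbind(s1 = c(1, 0, 1, 0, 1, 0), s2 = c(1, 1, 0, 0, 1, 1))
  # identical sessions, orthogonal centered patterns
  expect_equal(unclass(split_data_rdm(base, base))["s1", "s2"], 1,
               tolerance = 1e-9)
  expect_equal(unclass(split_data_rdm(base, base))["s1", "s1"], 0,
               tolerance = 1e-12)
  # anti-correlated cross-session pattern drives d toward 2
  flip <- base; flip["s2", ] <- 1 - base["s2", ]
  expect_equal(unclass(split_data_rdm(base, flip))["s2", "s2"], 2,
               tolerance = 1e-9)
})

test_that("split-data RDM is invariant to shared unit permutations and rejects flat patterns", {
  p1 <- with_seed_test(7, matrix(rnorm(8 * 20), 8,
                                 dimnames = list(paste0("s", 1:8), NULL)))
  p2 <- with_seed_test(8, matrix(rnorm(8 * 20), 8,
                                 dimnames = list(paste0("s", 1:8), NULL)))
  perm <- with_seed_test(9, sample(20))
  expect_equal(unclass(split_data_rdm(p1[, perm], p2[, perm])),
               unclass(split_data_rdm(p1, p2)), tolerance = 1e-12)
  p1flat <- p1; p1flat["s3", ] <- 2
  expect_error(split_data_rdm(p1flat, p2), "s3")
})

test_that("arrangement distances enumerate pairs with Euclidean geometry", {
  tr <- structure(list(task = "t", participant = "p", trial_index = 1,
                       subset = c("a", "b"),
                       coords = matrix(c(0, 3, 0, 4), 2,
                                       dimnames = list(c("a", "b"),
                                                       c("x_px", "y_px")))),
                  class = "arrangement_trial")
  expect_equal(arrangement_distances(tr)$distance, 5)
  tr$coords[2, ] <- tr$coords[1, ]
  expect_equal(arrangement_distances(tr)$distance, 0)
  big <- structure(list(task = "t", participant = "p", trial_index = 1,
                        subset = paste0("s", 1:30),
                        coords = with_seed_test(10, {
                          xy <- matrix(runif(60), 30)
                          rownames(xy) <- paste0("s", 1:30); xy
                        })),
                   class = "arrangement_trial")
  expect_equal(nrow(arrangement_distances(big)), 435L)
})

test_that("aggregation averages per pair, matches a per-pair accumulation oracle, and reports gaps", {
  ids <- paste0("s", 1:9)
  target <- random_rdm(9, seed = 11, ids = ids)
  plan <- plan_arrangement_subsets(ids, n_subsets = 4, subset_size = 3,
                                   n_candidates = 10, rng_seed = 12)
  trials <- simulate_arrangements(target, plan, placement_noise_sd = 5,
                                  rng_seed = 13)
  got <- aggregate_arrangements(trials, ids)
  # oracle: accumulate pair sums/counts straight from the trial coordinates
  sums <- counts <- matrix(0, 9, 9, dimnames = list(ids, ids))
  for (tr in trials) {
    xy <- tr$coords
    for (i in seq_len(nrow(xy) - 1)) {
      for (j in (i + 1):nrow(xy)) {
        a <- rownames(xy)[i]; b <- rownames(xy)[j]
        d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
        sums[a, b] <- sums[a, b] + d; sums[b, a] <- sums[b, a] + d
        counts[a, b] <- counts[a, b] + 1; counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  expect_equal(unclass(got)[counts > 0], (sums / pmax(counts, 1))[counts > 0],
               tolerance = 1e-9)
  # single full-set trial reproduces its own distance matrix
  one <- trials[1]
  d1 <- aggregate_arrangements(one, ids)
  dd <- arrangement_distances(one[[1]])
  expect_equal(unclass(d1)[cbind(dd$stim_i, dd$stim_j)], dd$distance,
               tolerance = 1e-9)
  # two measurements of a pair average arithmetically
  mk_tr <- function(d) {
    structure(list(task = "t", participant = "p", trial_index = 1,
                   subset = c("a", "b"),
                   coords = matrix(c(0, d, 0, 0), 2,
                                   dimnames = list(c("a", "b"),
                                                   c("x_px", "y_px")))),
              class = "arrangement_trial")
  }
  two <- aggregate_arrangements(list(mk_tr(100), mk_tr(200)), c("a", "b"))
  expect_equal(unclass(two)["a", "b"], 150)
  # unmeasured pairs are named
  expect_error(aggregate_arrangements(list(mk_tr(1)), c("a", "b", "c")),
               "never measured")
})

test_that("aggregation is invariant to rigid motions of any trial", {
  ids <- paste0("s", 1:7)
  target <- random_rdm(7, seed = 14, ids = ids)
  trials <- simulate_arrangements(target, list(ids, ids[1:4]),
                                  placement_noise_sd = 3, rng_seed = 15)
  moved <- trials
  th <- 0.83
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved[[1]]$coords <- sweep(moved[[1]]$coords %*% rot, 2, c(-40, 12))
  moved[[2]]$coords <- moved[[2]]$coords[, 2:1]  # reflection
  colnames(moved[[2]]$coords) <- c("x_px", "y_px")
  expect_equal(unclass(aggregate_arrangements(moved, ids)),
               unclass(aggregate_arrangements(trials, ids)),
               tolerance = 1e-9)
})

test_that("feature RDMs match per-pair metric oracles", {
  X <- with_seed_test(16, matrix(rnorm(6 * 5), 6,
                                 dimnames = list(paste0("s", 1:6), NULL)))
  for (metric in c("correlation", "euclidean", "cosine")) {
    r <- feature_rdm(X, metric)
    oracle <- matrix(0, 6, 6)
    for (i in 1:6) {
      for (j in 1:6) {
        oracle[i, j] <- switch(metric,
          correlation = 1 - cor(X[i, ], X[j, ]),
          euclidean = sqrt(sum((X[i, ] - X[j, ])^2)),
          cosine = 1 - sum(X[i, ] * X[j, ]) /
            sqrt(sum(X[i, ]^2) * sum(X[j, ]^2)))
      }
    }
    diag(oracle) <- 0
    expect_equal(unclass(r), oracle, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # identical rows are zero-distance under every metric
  X2 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  for (metric in c("correlation", "euclidean", "cosine")) {
    expect_equal(unclass(feature_rdm(X2, metric))["a", "b"], 0,
                 tolerance = 1e-12)
  }
  expect_equal(unclass(feature_rdm(rbind(a = c(0, 0), b = c(3, 4)),
                                   "euclidean"))["a", "b"], 5)
  expect_error(feature_rdm(rbind(a = c(1, 1, 1), b = c(1, 2, 3)),
                           "correlation"), "zero-variance")
})
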