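# Shared fixture builders. Everything is generated in code under fixed seeds.

# random symmetric zero-diagonal RDM on m stimuli
random_rdm <- function(m, seed, ids = paste0("s", seq_len(m))) {
  with_seed_test(seed, {
    v <- runif(m * (m - 1) / 2)
    rdm_devectorize(v, stimulus_ids = ids)
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# independent oracle: Spearman as Pearson on average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# independent oracle: R^2 of OLS on rank-standardized vectors via lm()
oracle_rank_r2 <- function(y, X) {
  rs <- function(v) { r <- rank(v); (r - mean(r)) / sd(r) }
  yr <- rs(y)
  Xr <- apply(as.matrix(X), 2, rs)
  summary(lm(yr ~ Xr))$r.squared
}

# tiny timed candidate generator for design-selection tests
toy_design_generator <- function(n_events = 12, n_cond = 3) {
  function(k) {
    isis <- 2 + runif(n_events, 0, 2)
    onsets <- cumsum(c(2, (2.5 + isis)[-n_events]))
    list(onsets = onsets, durations = 2.5,
         conditions = rep_len(seq_len(n_cond), n_events))
  }
}

# small world shared by several files
small_stimulus_set <- function() make_stimulus_set(6L, 3L)
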