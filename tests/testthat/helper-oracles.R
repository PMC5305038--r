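# Independent brute-force oracles used across the suite. These deliberately
# follow the *definitions*, not the package's vectorised implementations.

# O(n^2) cluster partitioner: walk the licks, close a cluster whenever the
# next gap reaches the criterion; recompute every ILI from scratch.
brute_force_clusters <- function(times, criterion) {
  if (length(times) == 0) return(list())
  clusters <- list()
  current <- times[1]
  for (t in times[-1]) {
    if (t - current[length(current)] >= criterion) {
      clusters[[length(clusters) + 1]] <- current
      current <- t
    } else current <- c(current, t)
  }
  clusters[[length(clusters) + 1]] <- current
  clusters
}

# Full permutation oracle for the two-sided Mann-Whitney p-value:
# enumerate every split of the pooled sample, recompute U_A by direct
# pair counting (wins + half-ties), use the symmetric tail definition.
permutation_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n2 <- length(b)
  count_ua <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  mu <- n1 * n2 / 2
  obs <- abs(count_ua(a, b) - mu)
  sets <- combn(n1 + n2, n1)
  stat <- apply(sets, 2, function(ix)
    abs(count_ua(pooled[ix], pooled[-ix]) - mu))
  mean(stat >= obs - 1e-9)
}

# Random clustered-looking lick stream (not via the package generator).
random_stream <- function(n, gap_choices = c(0.05, 0.1, 0.15, 0.6, 2)) {
  if (n == 0) return(numeric(0))
  cumsum(c(0.5, sample(gap_choices, n - 1, replace = TRUE)))
}

make_session <- function(times, consumption = 1, ...) {
  lickstat:::new_lick_session("S1", "control", "none", 1L, times,
                              consumption, integer(0), NA_integer_)
}

# Small, fast cohort configuration used where the full study-size default
# would waste test budget; group effect structure is the caller's choice.
small_cohort <- function(master_seed, n_control = 8, n_mcao = 8,
                         sessions = 2,
                         control = group_params(clusters_per_session_mean = 6,
                                                cluster_size_mean = 10),
                         mcao = control) {
  cohort_config(n_control = n_control, n_mcao = n_mcao,
                sessions_per_subject = sessions,
                control_params = control, mcao_params = mcao,
                master_seed = master_seed)
}
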