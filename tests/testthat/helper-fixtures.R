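# Shared fixtures. Everything is generated in code; the expensive
# integration objects (default simulation + periodicity scan + mixture fit)
# are computed once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

toy_dataset <- function(scale = "linear") {
  values <- matrix(c(1, 2, 3, 4, 5,
                     2, 4, 6, 8, 10,
                     5, 5, 5, 5, 5), nrow = 3, byrow = TRUE,
                   dimnames = list(c("pA", "pB", "pC"),
                                   c("s1", "s2", "s3", "s4", "s5")))
  meta <- data.frame(sample_id = c("s1", "s2", "s3", "s4", "s5"),
                     cycle = c("natural", "natural", "natural",
                               "induced", "induced"),
                     day = c(24, 30, 40, 5, 8))
  expression_dataset(values, meta, scale = scale)
}

# merged time grid of the default synthetic design
default_times <- function() {
  sim <- sim_config(n_cluster1 = 1, n_cluster2 = 1, n_noise = 0,
                    n_feedback = 0)
  ds <- merge_cycles(simulate_dataset(sim)$dataset)
  ds$samples$merged_day
}

integration_fixture <- function() {
  if (!is.null(.fixture_cache$integration)) return(.fixture_cache$integration)
  sim <- simulate_dataset(sim_config(seed = 4))
  ds <- merge_cycles(sim$dataset)
  scan <- suppressMessages(periodic_scan(ds, n_perm = 300L, n_max = 300L,
                                         seed = 11))
  mix <- fit_mixture(ds)
  .fixture_cache$integration <- list(sim = sim, ds = ds, scan = scan,
                                     mix = mix)
  .fixture_cache$integration
}

# brute-force hypergeometric upper tail by enumeration (independent oracle)
enum_hyper_tail <- function(N, m, n_draw, k) {
  ks <- k:min(m, n_draw)
  sum(choose(m, ks) * choose(N - m, n_draw - ks)) / choose(N, n_draw)
}
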