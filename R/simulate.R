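#' Configuration for the synthetic hair-cycle generator
#'
#' Defines the statistical structure the analysis assumes: a two-population
#' mixture (a static background and a transiently expanding population, both
#' with static intracellular expression), two out-of-phase clusters of
#' periodic probes with asymmetric sizes, non-periodic background probes,
#' multiplicative log-normal noise, and "feedback" probes whose background-
#' population expression bumps upward 14-16 days after cycle initiation.
#' The time design is the merged two-cycle grid: a natural-cycle day grid
#' plus the induced days 3, 5, 8, 12, 17 pooled through [hair_time_map()].
#' The default natural grid is a synthetic default, not the grid of any
#' particular public dataset.
#'
#' @param n_cluster1,n_cluster2 probes high in the expanding (1) resp.
#'   background (2) population. The 120/200 default keeps the published
#'   cluster-size asymmetry (smaller cluster peaks in anagen).
#' @param n_noise non-periodic probes with equal expression in both
#'   populations.
#' @param n_feedback cluster-2-like probes carrying the intracellular bump.
#' @param period_days nominal expression period (days).
#' @param cluster1_peak_day postnatal day of maximal cluster-1 expression;
#'   tied to the expansion peak. Cluster 2 peaks half a period later.
#' @param phase_jitter_sd per-probe jitter (days) applied as a time shift of
#'   the expansion trajectory; 0 gives an exact shared-fraction mixture.
#' @param noise_sd_log2 SD of multiplicative log-normal noise, log2 units.
#' @param level_log2_mean,level_log2_sd log2 expression level distribution.
#' @param fold_separation fold difference between the high and low
#'   population for cluster probes.
#' @param expansion list: `onset_day`, `peak_day`, `collapse_day` (merged
#'   postnatal days), `peak_fraction` in (0, 1].
#' @param bump list describing the feedback signature: the background-
#'   population expression of feedback probes rises by `amplitude_fold` in a
#'   sigmoid step centered `center_day` days after cycle initiation (near
#'   catagen onset), with a transition half-width of `width_days`, and stays
#'   elevated for the remainder of the cycle. This violates the
#'   static-intracellular-expression assumption by construction, which is
#'   what makes these probes screenable.
#' @param feedback_intra_sd optional SD (log2) of additional broadband
#'   intracellular fluctuation of feedback probes' background expression
#'   (0 = none).
#' @param natural_days,induced_days per-cycle sampling grids.
#' @param time_map a [hair_time_map()] covering `induced_days`.
#' @param initiation_day postnatal day taken as cycle initiation for the
#'   natural cycle (end of morphogenesis); induced samples count days from
#'   depilation.
#' @param seed master seed; all probe-level draws derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cluster1 = 120, n_cluster2 = 200, n_noise = 150,
                       n_feedback = 12,
                       period_days = 31, cluster1_peak_day = 33,
                       phase_jitter_sd = 0.5, noise_sd_log2 = 0.15,
                       level_log2_mean = 8, level_log2_sd = 1,
                       fold_separation = 12,
                       expansion = list(onset_day = 23, peak_day = 31,
                                        collapse_day = 42,
                                        peak_fraction = 0.85),
                       bump = list(center_day = 15, width_days = 1.5,
                                   amplitude_fold = 3),
                       feedback_intra_sd = 0,
                       natural_days = c(23, 25, 27, 29, 31, 33, 35, 37, 39,
                                        41, 44, 47, 50, 53),
                       induced_days = c(3, 5, 8, 12, 17),
                       time_map = hair_time_map(),
                       initiation_day = 23,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_cluster1, cfg$n_cluster2, cfg$n_noise, cfg$n_feedback)
  if (any(counts < 0)) stop_hw("probe counts must be >= 0",
                               class = "hairwave_config_error")
  if (sum(counts) == 0) stop_hw("zero total probes",
                                class = "hairwave_config_error")
  if (cfg$period_days <= 0) stop_hw("period_days must be > 0",
                                    class = "hairwave_config_error")
  ex <- cfg$expansion
  if (!(ex$peak_fraction > 0 && ex$peak_fraction <= 1))
    stop_hw("peak_fraction must be in (0, 1]", class = "hairwave_config_error")
  if (!(ex$collapse_day > ex$peak_day && ex$peak_day > ex$onset_day))
    stop_hw("need onset_day < peak_day < collapse_day",
            class = "hairwave_config_error")
  structure(cfg, class = "sim_config")
}

#' Relative size of the expanding population over the cycle
#'
#' Piecewise-smooth trajectory: zero through late morphogenesis, a logistic
#' rise from exactly 0 at `onset_day` to `peak_fraction` at `peak_day`
#' (anagen growth), a plateau at `peak_fraction` while the follicle matrix
#' stays fully expanded through anagen, and a short Gaussian-flank fall
#' back to exactly 0 at `collapse_day` (the sharp and complete catagen
#' depletion), then zero afterwards (telogen). The fall occupies the last
#' `min(3, (collapse - peak)/2)` days before `collapse_day`. Smoothness
#' avoids introducing spectral artifacts into the simulated expression.
#'
#' @param days numeric vector of merged postnatal days.
#' @param params list with `onset_day`, `peak_day`, `collapse_day`,
#'   `peak_fraction` (see [sim_config()]).
#' @return Fractions in `[0, peak_fraction]`; days outside the cycle span
#'   clamp to 0.
#' @export
expansion_trajectory <- function(days, params = sim_config()$expansion) {
  on <- params$onset_day; pk <- params$peak_day; cl <- params$collapse_day
  pf <- params$peak_fraction
  fall_w <- min(3, (cl - pk) / 2)
  fall_t <- cl - fall_w
  f <- numeric(length(days))
  rise <- days > on & days <= pk
  if (any(rise)) {
    u <- (days[rise] - on) / (pk - on)
    k <- 8  # logistic steepness; endpoints renormalized to hit 0 and pf
    s <- stats::plogis(k * (u - 0.5))
    s0 <- stats::plogis(-k / 2); s1 <- stats::plogis(k / 2)
    f[rise] <- pf * (s - s0) / (s1 - s0)
  }
  f[days > pk & days <= fall_t] <- pf
  fall <- days > fall_t & days < cl
  if (any(fall)) {
    v <- (days[fall] - fall_t) / fall_w
    a <- 9  # ~3-sigma flank; renormalized to hit pf at fall start, 0 at collapse
    f[fall] <- pf * (exp(-a * v^2) - exp(-a)) / (1 - exp(-a))
  }
  f
}

# Sample table of the merged two-cycle design.
sim_sample_table <- function(cfg) {
  map <- cfg$time_map
  nat <- data.frame(sample_id = sprintf("N_d%02d", cfg$natural_days),
                    cycle = "natural", day = cfg$natural_days)
  ind <- data.frame(sample_id = sprintf("I_d%02d", cfg$induced_days),
                    cycle = "induced", day = cfg$induced_days)
  list(samples = rbind(nat, ind), map = map)
}

#' Simulate a hair-cycle expression dataset with known ground truth
#'
#' Builds a linear-scale dataset by the two-population mixing rule
#' `x_ij = f_i * y1_j + (1 - f_i) * y2_j` (expanding fraction `f_i`, static
#' intracellular expressions `y1`, `y2`), then applies multiplicative
#' log-normal noise. Cluster-1 probes are high in the expanding population,
#' cluster-2 probes are high in the background (so the two observed profiles
#' are reciprocal and out of phase), noise probes are equal in both, and
#' feedback probes are cluster-2-like with a multiplicative bump in their
#' background-population expression centered `bump$center_day` days after
#' initiation. Per-probe phase jitter is a small time shift of the expansion
#' trajectory. The same seed gives bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `hair_sim` with `dataset` (merged, linear-scale
#'   [expression_dataset()]), `truth` (data frame of per-probe labels and
#'   population expressions), per-sample `fractions`, `fractions_raw` and
#'   the config. Because the mixture model identifies the fraction
#'   trajectory only up to an affine rescaling, `fractions` and the truth
#'   expressions are reported in the identifiable gauge (fractions
#'   normalized to peak 1, `y_expanding` re-mixed to match); the raw
#'   trajectory is kept in `fractions_raw`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  st <- sim_sample_table(cfg)
  labels <- rep(c("cluster1", "cluster2", "noise", "feedback"),
                c(cfg$n_cluster1, cfg$n_cluster2, cfg$n_noise,
                  cfg$n_feedback))
  n_probes <- length(labels)
  probe_ids <- sprintf("%s_%04d", sub("cluster", "c", labels),
                       seq_len(n_probes))

  # skeleton dataset to obtain merged days / sample order
  ds0 <- expression_dataset(matrix(0, 1, nrow(st$samples),
                                   dimnames = list("tmp", st$samples$sample_id)),
                            st$samples, scale = "linear")
  ds0 <- merge_cycles(ds0, st$map)
  samp <- ds0$samples
  n_samp <- nrow(samp)
  t_init <- ifelse(samp$cycle == "natural",
                   samp$merged_day - cfg$initiation_day, samp$day)

  f <- expansion_trajectory(samp$merged_day, cfg$expansion)

  x <- matrix(NA_real_, n_probes, n_samp,
              dimnames = list(probe_ids, samp$sample_id))
  truth <- data.frame(probe_id = probe_ids, label = labels,
                      y_expanding = NA_real_, y_background = NA_real_,
                      jitter_days = 0, peak_day = NA_real_,
                      stringsAsFactors = FALSE)
  half_period <- cfg$period_days / 2

  with_seed(cfg$seed, {
    base_l2 <- stats::rnorm(n_probes, cfg$level_log2_mean, cfg$level_log2_sd)
    # signaling candidates sit at modest abundance (ligands, not structural
    # genes); also keeps their intracellular excursions from dominating the
    # linear least-squares fraction update
    base_l2[labels == "feedback"] <- base_l2[labels == "feedback"] - 2
    jit <- stats::rnorm(n_probes, 0, cfg$phase_jitter_sd)
    sqf <- sqrt(cfg$fold_separation)
    for (j in seq_len(n_probes)) {
      hi <- 2^base_l2[j] * sqf
      lo <- hi / cfg$fold_separation
      lab <- labels[j]
      y1 <- switch(lab, cluster1 = hi, cluster2 = lo, noise = 2^base_l2[j],
                   feedback = lo)
      y2 <- switch(lab, cluster1 = lo, cluster2 = hi, noise = 2^base_l2[j],
                   feedback = hi)
      dj <- if (lab %in% c("cluster1", "cluster2", "feedback")) jit[j] else 0
      fj <- expansion_trajectory(samp$merged_day - dj, cfg$expansion)
      y2_t <- rep(y2, n_samp)
      if (lab == "feedback") {
        b <- cfg$bump
        # sustained sigmoid up-shift: intracellular expression rises near
        # catagen onset and stays elevated through the cycle's end
        step <- stats::plogis((t_init - b$center_day) / (b$width_days / 2))
        y2_t <- y2 * (1 + (b$amplitude_fold - 1) * step) *
          2^stats::rnorm(n_samp, 0, cfg$feedback_intra_sd)
      }
      x[j, ] <- fj * y1 + (1 - fj) * y2_t
      truth$y_expanding[j] <- y1
      truth$y_background[j] <- y2
      truth$jitter_days[j] <- dj
      truth$peak_day[j] <- switch(lab,
        cluster1 = cfg$cluster1_peak_day + dj,
        cluster2 = cfg$cluster1_peak_day + dj + half_period,
        feedback = cfg$cluster1_peak_day + dj + half_period,
        noise = NA_real_)
    }
    if (cfg$noise_sd_log2 > 0)
      x <- x * 2^matrix(stats::rnorm(length(x), 0, cfg$noise_sd_log2),
                        nrow(x), ncol(x))
  })

  ds <- expression_dataset(x, samp, scale = "linear")
  # report ground truth in the identifiable gauge: the two-population model
  # determines f only up to an affine rescaling, so fractions are normalized
  # to peak 1 and the population expressions re-mixed accordingly
  # (f*y1 + (1-f)*y2 is exactly invariant under this reparameterization)
  pf <- cfg$expansion$peak_fraction
  y1_raw <- truth$y_expanding
  truth$y_expanding <- pf * y1_raw + (1 - pf) * truth$y_background
  structure(list(dataset = ds, truth = truth, fractions = f / pf,
                 fractions_raw = f, config = cfg),
            class = "hair_sim")
}

#' @export
print.hair_sim <- function(x, ...) {
  cat(sprintf("<hair_sim> %d probes (%s) x %d samples, seed %d\n",
              nrow(x$dataset$values),
              paste(sprintf("%s=%d", names(table(x$truth$label)),
                            table(x$truth$label)), collapse = " "),
              ncol(x$dataset$values), x$config$seed))
  invisible(x)
}

#' Simulate a labeled sinusoid-plus-noise benchmark dataset
#'
#' Companion generator for calibrating the periodicity pipeline: a set of
#' log2-scale probes carrying a pure sinusoid of known period (with random
#' phase per probe) over the merged two-cycle grid, plus pure-noise probes.
#' Labels are returned so realized false-discovery proportions can be
#' computed against known truth.
#'
#' @param n_periodic,n_noise probe counts.
#' @param period_days sinusoid period.
#' @param amplitude sinusoid amplitude (log2 units).
#' @param noise_sd Gaussian noise SD (log2 units).
#' @param baseline_log2 mean level.
#' @param cfg a [sim_config()] supplying the time grid.
#' @param seed RNG seed.
#' @return list with `dataset` (merged log2 [expression_dataset()]) and
#'   `labels` (`"periodic"`/`"noise"` per probe).
#' @export
simulate_sinusoid_dataset <- function(n_periodic = 200, n_noise = 800,
                                      period_days = 31, amplitude = 2,
                                      noise_sd = 1, baseline_log2 = 8,
                                      cfg = sim_config(), seed = 1L) {
  st <- sim_sample_table(cfg)
  ds0 <- expression_dataset(matrix(0, 1, nrow(st$samples),
                                   dimnames = list("tmp", st$samples$sample_id)),
                            st$samples, scale = "linear")
  ds0 <- merge_cycles(ds0, st$map)
  samp <- ds0$samples
  n <- n_periodic + n_noise
  labels <- rep(c("periodic", "noise"), c(n_periodic, n_noise))
  ids <- sprintf("%s_%04d", substr(labels, 1, 3), seq_len(n))
  x <- with_seed(seed, {
    ph <- stats::runif(n, 0, 2 * pi)
    m <- matrix(stats::rnorm(n * nrow(samp), 0, noise_sd), n, nrow(samp))
    per <- labels == "periodic"
    m[per, ] <- m[per, ] + amplitude *
      cos(outer(ph[per], 2 * pi * samp$merged_day / period_days,
                function(p, w) w - p))
    m + baseline_log2
  })
  dimnames(x) <- list(ids, samp$sample_id)
  list(dataset = expression_dataset(x, samp, scale = "log2"),
       labels = labels)
}

#' Time-shuffled negative-control dataset
#'
#' Permutes each probe's values across time points independently, separately
#' within the natural and the induced cycle (values never migrate between
#' cycles), destroying any relation between expression and hair-cycle time
#' while preserving each probe's per-cycle value distribution. This is the
#' negative control used for the two-population model.
#'
#' @param ds an [expression_dataset()].
#' @param seed RNG seed; the shuffle is reproducible.
#' @return The permuted dataset.
#' @export
simulate_null_dataset <- function(ds, seed = 1L) {
  stopifnot(inherits(ds, "expr_dataset"))
  groups <- split(seq_len(ncol(ds$values)), ds$samples$cycle)
  with_seed(seed, {
    for (idx in groups) {
      if (length(idx) < 2) next
      for (j in seq_len(nrow(ds$values)))
        ds$values[j, idx] <- ds$values[j, sample(idx)]
    }
  })
  ds
}
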