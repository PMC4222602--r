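test_that("fraction solve has the documented closed form and clipping", {
  set.seed(1)
  y1 <- runif(20, 1, 10); y2 <- runif(20, 1, 10)
  expect_equal(solve_fractions(y1, y1, y2), 1)
  expect_equal(solve_fractions(y2, y1, y2), 0)
  expect_equal(solve_fractions(y2 + 2 * (y1 - y2), y1, y2), 1)  # clipped
  expect_equal(solve_fractions(0.3 * y1 + 0.7 * y2, y1, y2), 0.3,
               tolerance = 1e-12)
  expect_error(solve_fractions(y1, y2, y2),
               class = "hairwave_unidentifiable_error")
})

test_that("noiseless mixtures are recovered to numerical precision", {
  cfg <- sim_config(n_cluster1 = 20, n_cluster2 = 30, n_noise = 10,
                    n_feedback = 0, noise_sd_log2 = 0, phase_jitter_sd = 0,
                    seed = 6)
  sim <- simulate_dataset(cfg)
  ds <- merge_cycles(sim$dataset)
  fit <- fit_mixture(ds, tol = 1e-10)
  ftruth <- sim$fractions[match(fit$fractions$sample_id,
                                sim$dataset$samples$sample_id)]
  expect_lt(max(abs(fit$fractions$f - ftruth)), 1e-6)
  m <- match(fit$genes$probe_id, sim$truth$probe_id)
  expect_lt(max(abs(fit$genes$y_expanding - sim$truth$y_expanding[m]) /
                  sim$truth$y_expanding[m]), 1e-6)
  expect_lt(max(abs(fit$genes$y_background - sim$truth$y_background[m]) /
                  sim$truth$y_background[m]), 1e-6)
  expect_equal(min(fit$genes$cod[sim$truth$label[m] != "noise"]), 1,
               tolerance = 1e-9)
})

test_that("log2-scale input is refused", {
  ds <- convert_scale(integration_fixture()$ds, "log2")
  expect_error(fit_mixture(ds), class = "hairwave_scale_error")
})

test_that("the alternating objective never increases", {
  fx <- integration_fixture()
  expect_true(all(diff(fx$mix$objective) <= 1e-8 * fx$mix$objective[1]))
  expect_true(fx$mix$converged)
})

test_that("per-gene inference matches an explicit normal-equations oracle", {
  f <- c(0.1, 0.4, 0.7, 0.95)
  x <- c(3.2, 5.5, 8.1, 10.2)
  st <- population_expression_stats(matrix(x, 1, 4,
                                           dimnames = list("g1", NULL)), f)
  # brute-force oracle: build the normal equations by hand
  D <- cbind(f, 1 - f)
  G <- t(D) %*% D
  beta <- solve(G) %*% t(D) %*% x
  res <- x - D %*% beta
  s2 <- sum(res^2) / (4 - 2)
  covb <- s2 * solve(G)
  se_d <- sqrt(covb[1, 1] + covb[2, 2] - 2 * covb[1, 2])
  expect_equal(st$y_expanding, beta[1], tolerance = 1e-10)
  expect_equal(st$y_background, beta[2], tolerance = 1e-10)
  expect_equal(st$se1, sqrt(covb[1, 1]), tolerance = 1e-10)
  expect_equal(st$se2, sqrt(covb[2, 2]), tolerance = 1e-10)
  expect_equal(st$t, (beta[1] - beta[2]) / se_d, tolerance = 1e-10)
  expect_equal(st$p, 2 * pt(abs(st$t), df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("degenerate genes get t = 0, separated genes huge t", {
  f <- seq(0.05, 0.95, length.out = 8)
  same <- rep(4, 8)                      # y1 = y2, no noise
  apart <- 10 * f + 1 * (1 - f)          # strong separation
  st <- population_expression_stats(rbind(g_same = same, g_apart = apart), f)
  expect_equal(st$t[1], 0)
  expect_gt(abs(st$t[2]), 1e6)
  expect_error(population_expression_stats(rbind(same, apart), rep(0.5, 8)),
               class = "hairwave_unidentifiable_error")
})

test_that("scale equivariance: rescaling expression rescales y and fixes f", {
  fx <- integration_fixture()
  ds2 <- fx$ds
  ds2$values <- ds2$values * 3.7
  fit2 <- fit_mixture(ds2)
  expect_equal(fit2$fractions$f, fx$mix$fractions$f, tolerance = 1e-6)
  expect_equal(fit2$genes$y_expanding, 3.7 * fx$mix$genes$y_expanding,
               tolerance = 1e-6)
  expect_equal(fit2$genes$t, fx$mix$genes$t, tolerance = 1e-6)
})

test_that("estimated fractions rise through anagen and collapse in catagen", {
  fx <- integration_fixture()
  fr <- fx$mix$fractions
  anagen <- fr$merged_day >= 31 & fr$merged_day <= 38
  telogen <- fr$merged_day >= 44
  expect_gt(min(fr$f[anagen]), 0.75)
  expect_lt(max(fr$f[telogen]), 0.1)
  # both cycles show the same collapse on the merged axis
  for (cyc in c("natural", "induced")) {
    s <- fr[fr$cycle == cyc, ]
    expect_gt(max(s$f), 0.7)
  }
})

test_that("COD separates mixture-driven, bursting and flat genes", {
  fx <- integration_fixture()
  g <- fx$mix$genes
  lab <- fx$sim$truth$label[match(g$probe_id, fx$sim$truth$probe_id)]
  med <- tapply(g$cod, lab, median)
  expect_gt(med[["cluster1"]], 0.85)
  expect_gt(med[["cluster2"]], 0.85)
  expect_lt(med[["feedback"]], med[["cluster2"]] - 0.2)
  expect_lt(abs(med[["noise"]]), 0.2)
})

test_that("population assignment covers nearly all LFO probes and matches the
          phase split", {
  fx <- integration_fixture()
  tab <- fx$scan$table
  lfo_ids <- tab$probe_id[tab$is_lfo]
  assign <- assign_populations(fx$mix, lfo_ids, fdr = 0.10)
  expect_gte(attr(assign, "assigned_fraction"), 0.95)
  # concordance with the phase-based split
  ens <- oscillator_ensemble(fx$scan)
  cl <- cluster_by_phase(ens$shift_days, ens$period, ens$t_ref)
  pop <- assign[match(ens$probe_ids, fx$mix$genes$probe_id)]
  keep <- pop != "none"
  phase_split <- cl$labels[keep]
  pop_split <- ifelse(pop[keep] == "expanding", 1L, 2L)
  expect_gte(max(mean(phase_split == pop_split),
                 mean(phase_split == 3L - pop_split)), 0.95)
})

test_that("the permutation negative control destroys time structure", {
  fx <- integration_fixture()
  nc <- negative_control(fx$ds, seed = 5)
  expect_true(isTRUE(nc$negative_control))
  template <- expansion_trajectory(nc$fractions$merged_day,
                                   fx$sim$config$expansion)
  # the real fit tracks the expansion trajectory; the control does not
  expect_gt(cor(fx$mix$fractions$f, template), 0.9)
  expect_lt(abs(cor(nc$fractions$f, template)), 0.5)
  # LFO probes lose their COD advantage on permuted data
  lab <- fx$sim$truth$label[match(nc$genes$probe_id, fx$sim$truth$probe_id)]
  lfo_like <- lab %in% c("cluster1", "cluster2")
  d <- median(nc$genes$cod[lfo_like], na.rm = TRUE) -
    median(nc$genes$cod[!lfo_like], na.rm = TRUE)
  expect_lt(abs(d), 0.1)
})

test_that("feedback screening recovers the implanted signature", {
  fx <- integration_fixture()
  truth <- fx$sim$truth
  truefb <- truth$probe_id[truth$label == "feedback"]
  # operation-level test: cluster membership supplied from ground truth
  c2 <- c(truth$probe_id[truth$label == "cluster2"], truefb)
  fb <- feedback_candidates(fx$ds, fx$mix, c2)
  expect_gte(mean(truefb %in% fb$probe_id), 0.9)
  # false positives among the static background cluster stay below 5%
  fp <- setdiff(fb$probe_id, truefb)
  expect_lte(length(fp) / length(c2), 0.05)
  expect_true(all(fb$min_window_ratio > 1))
  # a well-described static cluster-2 probe is excluded
  g <- fx$mix$genes
  static_best <- g$probe_id[which.max(replace(g$cod, !(g$probe_id %in% c2), -Inf))]
  expect_false(static_best %in% fb$probe_id)
  # an empty initiation window is an error
  expect_error(feedback_candidates(fx$ds, fx$mix, c2, window = c(98, 99)),
               class = "hairwave_window_error")
})

test_that("mixture methods expose fractions, fits and predictions", {
  fx <- integration_fixture()
  co <- coef(fx$mix)
  expect_named(co, fx$mix$fractions$sample_id)
  fit_m <- fitted(fx$mix)
  expect_identical(dim(fit_m), dim(fx$ds$values))
  r <- residuals(fx$mix, fx$ds)
  expect_equal(fit_m + r, fx$ds$values[rownames(fit_m), ],
               tolerance = 1e-12, ignore_attr = TRUE)
  pr <- predict(fx$mix, newfractions = c(0, 1))
  expect_equal(pr[, 1], setNames(fx$mix$genes$y_background,
                                 fx$mix$genes$probe_id))
  expect_equal(pr[, 2], setNames(fx$mix$genes$y_expanding,
                                 fx$mix$genes$probe_id))
})
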