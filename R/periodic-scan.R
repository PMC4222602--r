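#' Scan every probe for periodic expression
#'
#' The periodic-identification pipeline on a merged dataset: per probe, a
#' robust Fourier-series fit on the non-uniform merged time grid
#' ([fit_fourier_robust()]), the power spectrum and Fisher's g-statistic,
#' a permutation p-value with generalized-Pareto tail refinement
#' ([permutation_pvalue()]), Benjamini-Hochberg q-values across all probes,
#' and the principal periodic component (frequency, amplitude, phase and
#' phase shift in days to the next maximum). Probes at or below the FDR
#' threshold are flagged periodic; periodic probes whose principal period is
#' the longest period of the grid are flagged low-frequency oscillators
#' (LFOs), the group whose period matches the hair cycle.
#'
#' Periodicity is assessed on the log2 scale; a linear-scale dataset is
#' converted internally (and this is the only implicit conversion in the
#' package, flagged by a message).
#'
#' @param ds a merged [expression_dataset()].
#' @param grid a [build_frequency_grid()]; defaults to the grid of the
#'   merged days.
#' @param n_perm,n_max,use_gpd permutation controls, see
#'   [permutation_pvalue()].
#' @param fdr FDR threshold for the periodic call (default 0.10).
#' @param seed master seed; each probe gets a derived stream so results do
#'   not depend on probe order or parallel chunking.
#' @return Object of class `periodic_scan`: `table` (one row per probe:
#'   `probe_id`, `g`, `p`, `q`, `ppc_period`, `ppc_amplitude`, `ppc_phase`,
#'   `phase_shift_days`, `r2`, `mad`, `used_gpd`, `is_periodic`, `is_lfo`),
#'   `fits` (list of `fourier_fit`), `grid`, `t_ref`, and the call
#'   parameters.
#' @export
periodic_scan <- function(ds, grid = NULL, n_perm = 1000L, n_max = 10000L,
                          use_gpd = TRUE, fdr = 0.10, seed = 1L) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (anyNA(ds$samples$merged_day))
    stop_hw("dataset not merged: run merge_cycles() first",
            class = "hairwave_validation_error")
  if (ds$scale == "linear") {
    message("periodic_scan: converting linear-scale values to log2")
    ds <- convert_scale(ds, "log2", offset = .Machine$double.eps)
  }
  times <- ds$samples$merged_day
  if (is.null(grid)) grid <- build_frequency_grid(times)
  t_ref <- min(times)
  n_probes <- nrow(ds$values)
  ids <- rownames(ds$values)

  fits <- vector("list", n_probes)
  names(fits) <- ids
  tab <- data.frame(probe_id = ids, g = NA_real_, p = NA_real_,
                    q = NA_real_, ppc_period = NA_real_,
                    ppc_amplitude = NA_real_, ppc_phase = NA_real_,
                    phase_shift_days = NA_real_, r2 = NA_real_,
                    mad = NA_real_, used_gpd = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(n_probes)) {
    y <- ds$values[j, ]
    fit <- fit_fourier_robust(y, times, grid)
    fits[[j]] <- fit
    S <- power_spectrum(fit)
    if (sum(S) <= 0) next  # flat signal: left NA, never called periodic
    tab$g[j] <- g_statistic(S)
    pv <- permutation_pvalue(y, times, grid, n_perm = n_perm, n_max = n_max,
                             use_gpd = use_gpd,
                             seed = derive_seed(seed, j))
    tab$p[j] <- pv$p
    tab$used_gpd[j] <- pv$used_gpd
    ppc <- principal_component(fit)
    tab$ppc_period[j] <- ppc$period
    tab$ppc_amplitude[j] <- ppc$amplitude
    tab$ppc_phase[j] <- ppc$phase
    tab$phase_shift_days[j] <- phase_shift_days(ppc, t_ref)
    tab$r2[j] <- fit$r2
    tab$mad[j] <- fit$mad
  }
  ok <- !is.na(tab$p)
  tab$q[ok] <- bh_fdr(tab$p[ok])
  tab$is_periodic <- !is.na(tab$q) & tab$q <= fdr
  longest <- max(grid$periods)
  tab$is_lfo <- tab$is_periodic &
    abs(tab$ppc_period - longest) < 1e-9 * longest
  structure(list(table = tab, fits = fits, grid = grid, t_ref = t_ref,
                 fdr = fdr, n_perm = n_perm, seed = seed,
                 times = times, samples = ds$samples),
            class = "periodic_scan")
}

#' @export
print.periodic_scan <- function(x, ...) {
  tab <- x$table
  cat(sprintf("<periodic_scan> %d probes, FDR %.2g: %d periodic, %d LFO (period %.3g d)\n",
              nrow(tab), x$fdr, sum(tab$is_periodic), sum(tab$is_lfo),
              max(x$grid$periods)))
  invisible(x)
}

#' @export
summary.periodic_scan <- function(object, ...) {
  tab <- object$table
  by_period <- table(factor(signif(tab$ppc_period[tab$is_periodic], 4)))
  out <- list(n_probes = nrow(tab), n_periodic = sum(tab$is_periodic),
              n_lfo = sum(tab$is_lfo), fdr = object$fdr,
              periodic_by_period = by_period,
              median_r2 = stats::median(tab$r2, na.rm = TRUE),
              gpd_fraction = mean(tab$used_gpd))
  class(out) <- "summary.periodic_scan"
  out
}

#' @export
print.summary.periodic_scan <- function(x, ...) {
  cat(sprintf("Periodicity scan of %d probes (BH FDR %.2g)\n", x$n_probes,
              x$fdr))
  cat(sprintf("  periodic: %d   LFO: %d   median r2: %.3f   GPD-refined: %.1f%%\n",
              x$n_periodic, x$n_lfo, x$median_r2, 100 * x$gpd_fraction))
  if (length(x$periodic_by_period)) {
    cat("  periodic calls by principal period (d):\n")
    print(x$periodic_by_period)
  }
  invisible(x)
}

#' @export
fitted.periodic_scan <- function(object, ...) {
  t(vapply(object$fits, function(f) f$fitted,
           numeric(length(object$times))))
}

#' @export
residuals.periodic_scan <- function(object, ...) {
  t(vapply(object$fits, function(f) f$residuals,
           numeric(length(object$times))))
}

#' Heat-map style plot of periodic probes
#'
#' Draws 0-1 normalized expression of the probes called periodic, sorted by
#' principal frequency then phase shift, against merged day.
#'
#' @param x a [periodic_scan()].
#' @param values optional probe x sample matrix to display (defaults to the
#'   fitted values).
#' @param ... ignored.
#' @export
plot.periodic_scan <- function(x, values = NULL, ...) {
  tab <- x$table[x$table$is_periodic, ]
  if (!nrow(tab)) {
    warning("no periodic probes to plot"); return(invisible(x))
  }
  if (is.null(values)) values <- fitted(x)[tab$probe_id, , drop = FALSE]
  o <- order(-tab$ppc_period, tab$phase_shift_days)
  m <- t(apply(values[o, , drop = FALSE], 1, normalize_for_viz))
  graphics::image(x = x$times, y = seq_len(nrow(m)), z = t(m),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "merged postnatal day", ylab = "probe (sorted)",
                  main = "periodic expression (0-1 normalized)")
  invisible(x)
}
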