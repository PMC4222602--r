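#' Run the full hair-cycle analysis end-to-end
#'
#' Orchestrates every stage with one configuration: simulate (or load) a
#' dataset, merge the two cycles, scan for periodic probes, build the phase
#' ensemble and split it into the two clusters, fit the coupled oscillator
#' model (both coupling configurations, with the stability verdict and an
#' optional bifurcation scan), deconvolve the expression matrix into the
#' expanding and background populations, screen feedback candidates, and
#' test enrichment of the population assignments within the phase clusters.
#' Every stage is a pure function of its inputs and the seeds, so two runs
#' with the same config produce identical reports.
#'
#' @param config either a list or a path to a `key=value` text file.
#'   Recognized keys (defaults in parentheses): `seed` (1), `matrix_path` /
#'   `metadata_path` / `scale` to load data, or `simulate = TRUE` (default)
#'   to generate a [sim_config()] dataset (simulation fields can be set via
#'   `sim.<name>` keys); `n_perm` (500), `n_max` (2000), `fdr` (0.10),
#'   `bifurcation` (FALSE), `p_grid_step` (0.05).
#' @param out_dir optional directory; when given, stage outputs are written
#'   as TSVs plus a JSON run report.
#' @return list of class `hairwave_report`: per-stage results and a
#'   `summary` with the headline counts (periodic, LFO, cluster sizes,
#'   assigned probes, feedback candidates, model parameters and verdict).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  seed <- as.integer(cfg$seed %||% 1L)
  stages <- list()
  status <- character(0)
  note <- function(stage, ok) status[[stage]] <<- ok

  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      note(name, paste("error:", conditionMessage(res)))
      stop_hw("stage '", name, "' failed: ", conditionMessage(res),
              class = "hairwave_pipeline_error")
    }
    note(name, "ok")
    res
  }

  # --- data -----------------------------------------------------------
  if (!is.null(cfg$matrix_path)) {
    ds <- run_stage("load", read_expression(cfg$matrix_path,
                                            cfg$metadata_path,
                                            scale = cfg$scale %||% "log2"))
    truth <- NULL
    sim <- NULL
  } else {
    sim_args <- cfg[startsWith(names(cfg), "sim.")]
    names(sim_args) <- sub("^sim\\.", "", names(sim_args))
    sim_args$seed <- derive_seed(seed, 101L)
    sim <- run_stage("simulate", do.call(sim_config, sim_args))
    sim <- run_stage("simulate", simulate_dataset(sim))
    ds <- sim$dataset
    truth <- sim$truth
  }
  ds <- run_stage("merge", merge_cycles(ds))
  stages$dataset <- ds

  # --- periodicity ----------------------------------------------------
  scan <- run_stage("periodicity",
                    periodic_scan(ds, n_perm = as.integer(cfg$n_perm %||% 500L),
                                  n_max = as.integer(cfg$n_max %||% 2000L),
                                  fdr = as.numeric(cfg$fdr %||% 0.10),
                                  seed = derive_seed(seed, 202L)))
  stages$scan <- scan

  # --- oscillator ensemble and clusters -------------------------------
  ens <- run_stage("oscillator", {
    if (sum(scan$table$is_lfo) < 4)
      stop_hw("fewer than 4 LFO probes", class = "hairwave_validation_error")
    oscillator_ensemble(scan)
  })
  clusters <- run_stage("clusters",
                        cluster_by_phase(ens$shift_days, ens$period,
                                         t_ref = ens$t_ref))
  stages$ensemble <- ens
  stages$clusters <- clusters

  # --- coupled model --------------------------------------------------
  model <- run_stage("coupled_model", {
    zc <- vapply(1:2, function(k) {
      mean(Mod(order_parameter(ens$phase[clusters$labels == k, ,
                                         drop = FALSE])))
    }, numeric(1))
    fit_coupled_model(r_cluster1 = zc[1], r_cluster2 = zc[2],
                      n_cluster1 = sum(clusters$labels == 1),
                      n_cluster2 = sum(clusters$labels == 2),
                      omega0 = 2 * pi / ens$period)
  })
  stages$model <- model
  if (isTRUE(cfg$bifurcation) && model$verdict != "none") {
    stages$bifurcation <- run_stage("bifurcation", {
      co <- coef(model)
      bifurcation_diagram(list(K_plus = co[["K_plus"]],
                               K_minus = co[["K_minus"]],
                               gamma = co[["gamma"]]),
                          omega0 = model$omega0,
                          p_grid = seq(0.05, 0.95,
                                       by = as.numeric(cfg$p_grid_step %||%
                                                         0.05)))
    })
  }

  # --- mixture --------------------------------------------------------
  mix <- run_stage("deconvolve",
                   fit_mixture(convert_scale(ds, "linear")))
  lfo_ids <- scan$table$probe_id[scan$table$is_lfo]
  assign <- run_stage("assign", assign_populations(mix, lfo_ids,
                                                   fdr = as.numeric(cfg$fdr %||% 0.10)))
  stages$mixture <- mix
  stages$assignments <- assign

  cluster2_ids <- ens$probe_ids[clusters$labels == 2]
  fb <- run_stage("feedback",
                  feedback_candidates(convert_scale(ds, "linear"), mix,
                                      cluster2_probes = cluster2_ids))
  stages$feedback <- fb

  # --- enrichment: population assignment vs phase clusters ------------
  enr <- run_stage("enrich", {
    bg <- scan$table$probe_id
    target <- mix$genes$probe_id[assign == "expanding"]
    sig <- ens$probe_ids[clusters$labels == 1]
    hypergeom_enrichment(target, sig, bg)
  })
  stages$enrichment <- enr

  co <- coef(model)
  report <- list(
    seed = seed,
    status = status,
    counts = list(n_probes = nrow(scan$table),
                  n_periodic = sum(scan$table$is_periodic),
                  n_lfo = sum(scan$table$is_lfo),
                  cluster_sizes = as.integer(table(clusters$labels)),
                  n_assigned = sum(assign != "none"),
                  n_feedback_candidates = nrow(fb)),
    model = c(as.list(co %||% list()),
              list(verdict = model$verdict,
                   separation_deg = clusters$separation_degrees)),
    enrichment_p = enr$p_value,
    config = cfg)
  out <- structure(c(list(summary = report), stages),
                   class = "hairwave_report")
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' @export
print.hairwave_report <- function(x, ...) {
  s <- x$summary
  cat("<hairwave_report>\n")
  cat(sprintf("  probes: %d | periodic: %d | LFO: %d | clusters: %s\n",
              s$counts$n_probes, s$counts$n_periodic, s$counts$n_lfo,
              paste(s$counts$cluster_sizes, collapse = "/")))
  cat(sprintf("  model verdict: %s | cluster separation %.1f deg\n",
              s$model$verdict, s$model$separation_deg))
  cat(sprintf("  assigned: %d | feedback candidates: %d | cluster/population enrichment p = %.3g\n",
              s$counts$n_assigned, s$counts$n_feedback_candidates,
              s$enrichment_p))
  invisible(x)
}

# Parse a key=value config file (comments with '#', blank lines ignored).
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad))
    stop_hw("malformed config line(s): ", paste(lines[bad], collapse = "; "),
            class = "hairwave_config_error")
  vals <- lapply(kv, function(x) {
    v <- trimws(x[2])
    if (v %in% c("TRUE", "FALSE")) as.logical(v)
    else if (grepl("^-?[0-9.eE+]+$", v) && !is.na(suppressWarnings(as.numeric(v))))
      as.numeric(v)
    else v
  })
  stats::setNames(vals, vapply(kv, function(x) trimws(x[1]), character(1)))
}

# Write stage TSVs and the JSON run summary.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(report$scan$table, "periodic_calls.tsv")
  w(data.frame(probe_id = report$ensemble$probe_ids,
               cluster = report$clusters$labels), "phase_clusters.tsv")
  w(report$mixture$fractions, "fractions.tsv")
  genes <- report$mixture$genes
  genes$assignment <- report$assignments
  w(genes, "population_genes.tsv")
  w(report$feedback, "feedback_candidates.tsv")
  jsonlite::write_json(report$summary,
                       file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
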