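#' Read and validate a pipeline run configuration
#'
#' The YAML layout mirrors the analysis stages: a `simulate` block (any
#' [sim_config()] field plus `n_traces`, `duration`, `n_bursts`), a `bursts`
#' block (`T_us`, `M`, `N`, `alex_2cde_max`, `n_components`), an `idealize`
#' block (`K`, `n_restarts`, `tol`), a `kinetics` block (`topology`) and a
#' top-level `seed`. Every numeric field is validated before any stage runs.
#'
#' @param path YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

as_run_config <- function(raw) {
  cfg <- list(
    seed = as.integer(raw$seed %||% 1L),
    stages = raw$stages %||% c("simulate", "idealize", "kinetics"),
    simulate = raw$simulate %||% list(),
    bursts = raw$bursts %||% list(),
    idealize = raw$idealize %||% list(),
    kinetics = raw$kinetics %||% list())
  sim_args <- cfg$simulate
  sim_args$n_traces <- NULL; sim_args$duration <- NULL; sim_args$n_bursts <- NULL
  cfg$sim_config <- do.call(sim_config, sim_args)      # validates
  if (!is.null(cfg$idealize$K) && !cfg$idealize$K %in% 1:3)
    stopf("invalid config: idealize K must be 1, 2 or 3, got %s", cfg$idealize$K)
  if (length(cfg$bursts))
    burst_params(cfg$bursts$T_us %||% 500, cfg$bursts$M %||% 30,
                 cfg$bursts$N %||% 120)                # validates
  if (!is.null(cfg$kinetics$topology) &&
      !cfg$kinetics$topology %in% c("two-state", "linear-three-state"))
    stopf("invalid config: unknown topology %s", cfg$kinetics$topology)
  structure(cfg, class = "run_config")
}

#' Run the simulate -> analyse pipeline end to end
#'
#' Executes the configured stages (`simulate`, `bursts`, `idealize`,
#' `kinetics`), writes every artifact (traces, paths, dwell tables, burst
#' tables, results JSON) into `out_dir` together with a manifest recording
#' the configuration, its md5 hash, the seed and the package version.
#' Rerunning with the same configuration and seed reproduces all stochastic
#' stages bit-identically.
#'
#' @param config A `run_config` (from [read_run_config()]) or the path to a
#'   YAML file.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage progress on stderr.
#' @return A results list (invisibly): fitted dwell times, rates, population
#'   fits, as configured.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) if (!quiet) message(sprintf(...))
  scfg <- config$sim_config
  results <- list(seed = config$seed)
  t0 <- proc.time()[["elapsed"]]

  traces <- NULL; stream <- NULL
  if ("simulate" %in% config$stages) {
    log_stage("[simulate] seed %d", config$seed)
    n_traces <- config$simulate$n_traces %||% 0
    duration <- config$simulate$duration %||% 30
    n_bursts <- config$simulate$n_bursts %||% 0
    if (n_traces > 0) {
      traces <- simulate_traces(scfg, n_traces, duration, rng_seed = config$seed)
      write_traces_csv(traces, file.path(out_dir, "traces.csv"))
      paths <- lapply(traces, function(tr) attr(tr, "truth")$path)
      names(paths) <- vapply(traces, function(tr) attr(tr, "trace_id"), "")
      write_paths_csv(paths, file.path(out_dir, "truth_paths.csv"))
    }
    if (n_bursts > 0) {
      stream <- simulate_photon_stream(scfg, n_bursts, rng_seed = config$seed + 1L)
      write_photon_tsv(stream, file.path(out_dir, "photons.tsv"))
    }
  }

  if ("bursts" %in% config$stages && !is.null(stream)) {
    bp <- burst_params(config$bursts$T_us %||% 500, config$bursts$M %||% 30,
                       config$bursts$N %||% 120)
    log_stage("[bursts] T=%d M=%d N=%d", bp$T_us, bp$M, bp$N)
    bursts <- search_bursts(stream, bp)
    bg <- estimate_background(stream, bp)
    bursts <- correct_counts(bursts, correction_factors(
      leakage = scfg$leakage, direct_exc = scfg$direct_exc,
      background_rates = bg))
    bursts <- compute_es(bursts)
    bursts <- two_cde_scores(bursts, stream)
    kept <- filter_bursts(bursts, alex_2cde_max = config$bursts$alex_2cde_max %||% 12)
    write_bursts_csv(kept, file.path(out_dir, "bursts.csv"))
    if (sum(is.finite(kept$E)) >= 50) {
      pf <- fit_populations(kept$E, config$bursts$n_components %||% 1)
      results$population_fit <- list(components = pf$components,
                                     bent_fraction = bent_fraction(pf),
                                     n_bursts = pf$n)
    }
    results$n_bursts_found <- nrow(bursts)
    results$n_bursts_kept <- nrow(kept)
  }

  if ("idealize" %in% config$stages && !is.null(traces)) {
    K <- config$idealize$K %||% scfg$n_states
    log_stage("[idealize] K=%d on %d traces", K, length(traces))
    corrected <- lapply(traces, correct_trace)
    fit <- fit_hmm(corrected, K,
                   n_restarts = config$idealize$n_restarts %||% 10,
                   tol = config$idealize$tol %||% 1e-6,
                   seed = config$seed)
    paths <- lapply(corrected, function(tr) viterbi_path(fit, tr))
    dwells <- extract_dwells(paths, frame_period = scfg$frame_period)
    write_dwells_csv(dwells, file.path(out_dir, "dwells.csv"))
    idl <- do.call(rbind, lapply(seq_along(paths), function(i)
      data.frame(trace_id = attr(paths[[i]], "trace_id") %||% sprintf("trace%04d", i),
                 frame = seq_along(paths[[i]]), state = as.integer(paths[[i]]))))
    write.table(idl, file.path(out_dir, "idealized.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    results$hmm <- list(mu = fit$mu, sigma = fit$sigma, loglik = fit$loglik,
                        converged = fit$converged)

    if ("kinetics" %in% config$stages) {
      topo <- config$kinetics$topology %||% scfg$topology
      log_stage("[kinetics] topology %s", topo)
      taus <- ses <- rep(NA_real_, K)
      for (s in seq_len(K)) {
        f <- tryCatch(fit_exponential(dwells, state = s), error = function(e) NULL)
        if (!is.null(f)) { taus[s] <- f$tau; ses[s] <- f$se }
      }
      results$dwell_tau_s <- taus
      results$dwell_tau_se_s <- ses
      if (!anyNA(taus)) {
        tf <- transition_frequencies(paths, n_states = K,
                                     frame_period = scfg$frame_period)
        rm_ <- tryCatch(derive_rates(taus, tf, topology = topo),
                        error = function(e) NULL)
        if (!is.null(rm_)) {
          results$rates_per_s <- rm_$k
          results$rates_rounded <- rm_$k_rounded
        }
        results$transition_counts <- tf$counts
      }
    }
  }

  manifest <- list(
    package = "tatabend",
    version = as.character(packageVersion("tatabend")),
    seed = config$seed,
    stages = config$stages,
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2),
    config = config[c("seed", "stages", "simulate", "bursts", "idealize",
                      "kinetics")])
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(manifest$config, cfg_file)
  manifest$config_md5 <- unname(tools::md5sum(cfg_file))
  write_results_json(manifest, file.path(out_dir, "manifest.json"))
  write_results_json(results, file.path(out_dir, "results.json"))
  invisible(results)
}
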