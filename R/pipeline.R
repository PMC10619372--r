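#' Save / load a cohort container
#'
#' Cohorts are serialized as RDS with a format tag and validated on load
#' (sampling rate present, equal ROI counts across subjects, finite data).
#' Round-trips are bit-identical.
#'
#' @param cohort A `docm_cohort`.
#' @param path File path.
#' @return `save_cohort` returns `path` invisibly; `load_cohort` returns the
#'   validated `docm_cohort`.
#' @export
save_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "docm_cohort"))
  saveRDS(cohort, path)
  invisible(path)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cohort <- readRDS(path)
  if (!inherits(cohort, "docm_cohort")) {
    stop("schema error: not a docm_cohort container", call. = FALSE)
  }
  if (is.null(cohort$rate)) stop("schema error: missing sampling rate", call. = FALSE)
  ncols <- unlist(lapply(cohort$subjects, function(s) {
    vapply(s$sessions, ncol, 0L)
  }))
  if (length(unique(ncols)) != 1) {
    stop("schema error: mixed ROI counts across subjects/sessions", call. = FALSE)
  }
  bad <- any(vapply(cohort$subjects, function(s) {
    any(vapply(s$sessions, function(x) any(!is.finite(x)), TRUE))
  }, TRUE))
  if (bad) stop("schema error: non-finite values in recordings", call. = FALSE)
  cohort
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis with validation and a
#' provenance hash; flags passed to [run_pipeline()] are recorded in the
#' artifacts it writes.
#'
#' @param n_subjects,n_rois,duration,rate,n_driven,noise_level Generator
#'   settings (see [gen_cohort()]).
#' @param window A [window_spec()].
#' @param cfg A [surrogate_config()].
#' @param state_grid dHMM candidate state counts.
#' @param plateau_patience Step-wise selection patience.
#' @param seed Master seed.
#' @return A validated `pipeline_config` object (with `hash`).
#' @export
pipeline_config <- function(n_subjects = 10, n_rois = 20, duration = 60,
                            rate = 600, n_driven = 6, noise_level = 0.35,
                            window = window_spec(), cfg = surrogate_config(),
                            state_grid = 2:3, plateau_patience = 5, seed = 1) {
  stopifnot(inherits(window, "window_spec"), inherits(cfg, "surrogate_config"))
  if (n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
  if (duration < window$width) stop("recording shorter than the window", call. = FALSE)
  if (window$step > window$width) {
    warning("step larger than width: windows leave gaps", call. = FALSE)
  }
  out <- list(n_subjects = n_subjects, n_rois = n_rois, duration = duration,
              rate = rate, n_driven = n_driven, noise_level = noise_level,
              window = window, cfg = cfg, state_grid = state_grid,
              plateau_patience = plateau_patience, seed = seed)
  out$hash <- rlang::hash(out)
  structure(out, class = "pipeline_config")
}

#' Run the end-to-end pipeline
#'
#' Generates (or loads) a two-session cohort, runs the DoCM pipeline on both
#' sessions, trains per-edge dHMMs on session 1, performs step-wise
#' identification against session 2, derives flexibility indices, and scores
#' the spectral / static-connectome / dynamic-strength / random-subset
#' baselines. Artifacts (CSV/JSON/RDS) are written under `out_dir`, each with
#' the config hash and seed in a provenance block.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param cohort Optional pre-built `docm_cohort`; generated from `config`
#'   when NULL.
#' @param stages Character subset of
#'   `c("docm", "flexibility", "fingerprint", "baselines")`.
#' @param verbose Print stage progress.
#' @return A list with the main artifacts (`selection`, `similarity`,
#'   `flexibility`, `baselines`, paths).
#' @export
run_pipeline <- function(config, out_dir = tempfile("docm-run-"),
                         cohort = NULL,
                         stages = c("docm", "flexibility", "fingerprint",
                                    "baselines"),
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  prov <- list(config_hash = config$hash, seed = config$seed,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  if (is.null(cohort)) {
    say("generating cohort (%d subjects, %d ROIs, %g s)",
        config$n_subjects, config$n_rois, config$duration)
    cohort <- gen_cohort(config$n_subjects, config$n_rois, config$duration,
                         config$rate, config$n_driven,
                         noise_level = config$noise_level, seed = config$seed)
  }
  result <- list(out_dir = out_dir, provenance = prov)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s (partial outputs in %s)",
                   name, conditionMessage(e), out_dir), call. = FALSE)
    })
  }

  if ("docm" %in% stages) {
    say("DoCM pipeline on both sessions")
    result$seqs1 <- run_stage("docm", cohort_docm_sequences(
      cohort, 1, config$window, config$cfg, verbose = verbose))
    result$seqs2 <- run_stage("docm", cohort_docm_sequences(
      cohort, 2, config$window, config$cfg, verbose = verbose))
  }
  if ("flexibility" %in% stages) {
    say("flexibility indices")
    result$flexibility <- run_stage("flexibility", {
      lapply(result$seqs1, function(m) {
        T_ <- nrow(m)
        mean(colMeans(m[-1, , drop = FALSE] != m[-T_, , drop = FALSE]))
      })
    })
    fi_tab <- tibble(subject = seq_along(result$flexibility),
                     fi_global = unlist(result$flexibility))
    utils::write.csv(cbind(fi_tab, config_hash = config$hash),
                     file.path(out_dir, "flexibility.csv"), row.names = FALSE)
  }
  if ("fingerprint" %in% stages) {
    say("per-edge dHMM training and step-wise identification")
    result$models <- run_stage("fingerprint", fit_edge_models(
      result$seqs1, config$state_grid, seed = config$seed))
    result$cube <- run_stage("fingerprint",
                             edge_loglik_cube(result$models, result$seqs2))
    ranked <- rank_edges(result$cube)
    result$selection <- stepwise_select(ranked, result$cube,
                                        config$plateau_patience)
    result$similarity <- similarity_matrix(result$cube, result$selection$edges)
    utils::write.csv(cbind(as.data.frame(unclass(result$similarity)),
                           config_hash = config$hash),
                     file.path(out_dir, "similarity.csv"), row.names = FALSE)
    utils::write.csv(result$selection$curve,
                     file.path(out_dir, "accuracy_curve.csv"), row.names = FALSE)
  }
  if ("baselines" %in% stages) {
    say("baseline identification methods")
    result$baselines <- run_stage("baselines", {
      bands <- canonical_bands()
      alpha1 <- bands$alpha1
      p1 <- t(vapply(cohort$subjects, function(s) {
        psd_profile(s$sessions[[1]], cohort$rate)
      }, numeric(length(psd_profile(cohort$subjects[[1]]$sessions[[1]],
                                    cohort$rate)))))
      p2 <- t(vapply(cohort$subjects, function(s) {
        psd_profile(s$sessions[[2]], cohort$rate)
      }, numeric(ncol(p1))))
      sf1 <- t(vapply(cohort$subjects, function(s) {
        static_fc_profile(s$sessions[[1]], cohort$rate, alpha1)
      }, numeric(cohort$n_rois * (cohort$n_rois - 1) / 2)))
      sf2 <- t(vapply(cohort$subjects, function(s) {
        static_fc_profile(s$sessions[[2]], cohort$rate, alpha1)
      }, numeric(ncol(sf1))))
      rand <- random_subset_control(result$cube,
                                    k = max(1, length(result$selection$edges)),
                                    n_draws = 200, seed = config$seed)
      tibble(
        method = c("docm_dhmm", "psd", "static_fc", "random_subset"),
        accuracy = c(result$selection$accuracy,
                     correlation_match(p1, p2)$accuracy,
                     correlation_match(sf1, sf2)$accuracy,
                     rand$mean)
      )
    })
    utils::write.csv(result$baselines, file.path(out_dir, "baselines.csv"),
                     row.names = FALSE)
  }
  saveRDS(prov, file.path(out_dir, "provenance.rds"))
  say("done: artifacts in %s", out_dir)
  invisible(result)
}
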