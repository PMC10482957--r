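#' Configuration for an end-to-end pipeline run
#'
#' Bundles the stage parameters of every module with a single global seed.
#' Per-stage seeds are derived deterministically from the global seed by
#' fixed small offsets (session +1, spikes +2, photometry +3, collision +4,
#' unit features +5), so no stage reads ambient entropy.
#'
#' @param seed Global integer seed. Default 1.
#' @param n_trials Session length in trials. Default 300.
#' @param task A [task_config()].
#' @param policy A [policy_params()]; default [default_policy()].
#' @param neuron A [neuron_spec()] for the simulated unit; the default
#'   couples the movement response positively to reward rate.
#' @param photometry A [photometry_spec()].
#' @param collision A [collision_spec()].
#' @param n_units Size of the synthetic unit-feature population. Default 300.
#' @param n_past Lags in the choice regression. Default 8.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_trials = 300L,
                       task = task_config(),
                       policy = default_policy(),
                       neuron = neuron_spec(coupling = c(movement = 1)),
                       photometry = photometry_spec(),
                       collision = collision_spec(),
                       n_units = 300L, n_past = 8L) {
  cfg <- structure(list(seed = as.integer(seed), n_trials = as.integer(n_trials),
                        task = task, policy = policy, neuron = neuron,
                        photometry = photometry, collision = collision,
                        n_units = as.integer(n_units), n_past = as.integer(n_past)),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Checks every stage's invariants and rejects unknown fields, naming the
#' offending field in the error.
#'
#' @param config A `run_config` (or a bare list shaped like one).
#' @return The config, invisibly; errors otherwise.
#' @export
validate_run_config <- function(config) {
  known <- c("seed", "n_trials", "task", "policy", "neuron", "photometry",
             "collision", "n_units", "n_past")
  extra <- setdiff(names(config), known)
  if (length(extra)) {
    stop("unknown run_config field(s): ", paste(extra, collapse = ", "))
  }
  missing <- setdiff(known, names(config))
  if (length(missing)) {
    stop("missing run_config field(s): ", paste(missing, collapse = ", "))
  }
  validate_task_config(config$task)
  if (config$n_trials < 1L) stop("run_config field 'n_trials' must be >= 1")
  if (config$n_units < 3L) stop("run_config field 'n_units' must be >= 3")
  if (config$n_past < 1L) stop("run_config field 'n_past' must be >= 1")
  invisible(config)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
}

#' Run the full simulation and analysis pipeline
#'
#' Executes simulate -> synthesise (spikes, photometry, collision ensemble)
#' -> behavioral analysis -> photometry analysis -> collision identification
#' -> unit classification -> peri-event statistics, writing every artifact to
#' `out_dir` and finishing with a manifest (file names, MD5 hashes, seed)
#' that makes a run reproducible: the same config and seed give identical
#' hashes. Any stage failure aborts with the stage name.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory; created if needed.
#' @return The manifest, invisibly (data frame of file names and MD5 hashes).
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  validate_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  paths <- character(0)
  emit <- function(p) paths <<- c(paths, p)

  session <- stage("simulate", {
    s <- run_session(config$task, config$policy, config$n_trials,
                     seed = config$seed + 1L)
    write_session_log(s, file.path(out_dir, "session.csv"))
    emit(c("session.csv", "session.json"))
    s
  })

  spikes <- stage("synth-spikes", {
    sp <- gen_spike_train(config$neuron, session, seed = config$seed + 2L)
    utils::write.csv(data.frame(unit = 1L, time = sprintf("%.6f", sp)),
                     file.path(out_dir, "spikes.csv"), row.names = FALSE,
                     quote = FALSE)
    emit("spikes.csv")
    sp
  })

  trace <- stage("synth-photometry",
                 gen_photometry(config$photometry, session,
                                seed = config$seed + 3L))

  ensemble <- stage("synth-collision",
                    gen_collision_ensemble(config$collision, 50L, 50L,
                                           seed = config$seed + 4L))

  stage("analyze-behavior", {
    fit <- fit_choice_regression(session, config$n_past)
    utils::write.csv(
      data.frame(lag = seq_len(fit$n_past),
                 beta_reward = fit$beta_reward,
                 beta_noreward = fit$beta_noreward,
                 se_reward = fit$se_reward, se_noreward = fit$se_noreward,
                 p_reward = fit$p_reward, p_noreward = fit$p_noreward),
      file.path(out_dir, "choice_fit.csv"), row.names = FALSE)
    write_json_file(list(beta0 = fit$beta0, se0 = fit$se0,
                         n_trials_used = fit$n_trials_used,
                         log_lik = fit$log_lik, separation = fit$separation),
                    file.path(out_dir, "choice_fit.json"))
    utils::write.csv(switch_probability_by_reward_rate(session),
                     file.path(out_dir, "switch_probability.csv"),
                     row.names = FALSE)
    emit(c("choice_fit.csv", "choice_fit.json", "switch_probability.csv"))
  })

  stage("analyze-photometry", {
    nsig <- process_photometry(trace)
    tr <- session$trials
    wins <- event_windows()
    aligned <- align_to_events(nsig, tr$movement_onset_time, window = c(1, 1))
    mv <- window_values(aligned, wins$movement)
    utils::write.csv(
      data.frame(index = tr$index[attr(aligned, "events") %in%
                                    tr$movement_onset_time],
                 movement_z = mv),
      file.path(out_dir, "photometry_windows.csv"), row.names = FALSE)
    emit("photometry_windows.csv")
  })

  stage("identify", {
    res <- collision_test(ensemble)
    write_json_file(list(window_start_ms = res$window[1],
                         window_end_ms = res$window[2],
                         cutoff = res$cutoff, p_control = res$p_control,
                         p_test = res$p_test, chi2_p = res$chi2_p,
                         latency_ms = res$latency_ms,
                         jitter_ms = res$jitter_ms, passed = res$passed,
                         flags = res$flags),
                    file.path(out_dir, "collision_result.json"))
    emit("collision_result.json")
  })

  stage("classify", {
    feats <- gen_unit_features(config$n_units, seed = config$seed + 5L)
    km <- striatal_kmeans(feats, seed = config$seed)
    feats$label <- km$labels
    utils::write.csv(feats, file.path(out_dir, "unit_labels.csv"),
                     row.names = FALSE)
    write_json_file(list(silhouette = km$silhouette,
                         accuracy = mean(feats$label == feats$true_class)),
                    file.path(out_dir, "classification.json"))
    emit(c("unit_labels.csv", "classification.json"))
  })

  stage("peth", {
    tr <- session$trials
    ws <- unit_window_stats(spikes, session)
    trt <- task_related_test(ws)
    rr <- compute_reward_rate(tr$rewarded)
    corr <- reward_rate_correlation(ws$z$movement, rr)
    peth <- build_peth(spikes, tr$movement_onset_time, span = c(-1, 1),
                       event = "movement")
    utils::write.csv(data.frame(time = peth$bin_centers, rate = peth$rate),
                     file.path(out_dir, "peth_movement.csv"),
                     row.names = FALSE)
    write_json_file(list(task_related = trt$task_related,
                         window_p = as.list(stats::setNames(trt$table$p,
                                                            trt$table$window)),
                         movement_reward_rate_r = corr$r,
                         movement_reward_rate_p = corr$p),
                    file.path(out_dir, "peth_summary.json"))
    emit(c("peth_movement.csv", "peth_summary.json"))
  })

  manifest <- data.frame(
    file = paths,
    md5 = unname(tools::md5sum(file.path(out_dir, paths))),
    stringsAsFactors = FALSE
  )
  write_json_file(list(seed = config$seed,
                       files = manifest),
                  file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
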