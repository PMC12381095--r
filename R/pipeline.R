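# Config-driven orchestration: schedule -> simulate -> ERP stats ->
# decoding -> behaviour stats -> machine-readable report.

#' Pipeline configuration
#'
#' Bundles the sub-configurations of a full synthetic-study run. All
#' randomness derives from `seed`; stages draw deterministic sub-streams, so
#' two runs with the same configuration are identical.
#'
#' @param experiment `1` or `2`.
#' @param n_objects Objects in the design (defaults: 180 for Experiment 1,
#'   300 for Experiment 2).
#' @param params A [generator_params()] object (defaults to the experiment's
#'   defaults with `seed` injected).
#' @param cluster A [cluster_config()] object.
#' @param decoder A [decoder_config()] object.
#' @param stages Character subset of `c("erp", "decoding", "behavior")`;
#'   scheduling and simulation always run as needed.
#' @param decoding_phases Phases to decode within (default `"encoding"`).
#' @param erp_contrasts List of `c(cond_a, cond_b)` pairs (default: all
#'   pairs of the experiment's conditions).
#' @param seed Master seed (mandatory).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment = 1,
                            n_objects = NULL,
                            params = NULL,
                            cluster = cluster_config(),
                            decoder = decoder_config(),
                            stages = c("erp", "decoding", "behavior"),
                            decoding_phases = "encoding",
                            erp_contrasts = NULL,
                            seed = 1L) {
  experiment <- check_experiment(experiment)
  if (is.null(n_objects)) n_objects <- if (experiment == 1L) 180L else 300L
  if (is.null(params)) {
    params <- generator_params(experiment = experiment, seed = seed)
  }
  stages <- match.arg(stages, c("erp", "decoding", "behavior"),
                      several.ok = TRUE)
  conds <- experiment_conditions(experiment)
  if (is.null(erp_contrasts)) {
    cmb <- utils::combn(conds, 2)
    erp_contrasts <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  }
  structure(list(experiment = experiment, n_objects = as.integer(n_objects),
                 params = params, cluster = cluster, decoder = decoder,
                 stages = stages, decoding_phases = decoding_phases,
                 erp_contrasts = erp_contrasts, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the `params`,
#' `cluster` and `decoder` keys hold named lists passed to
#' [generator_params()], [cluster_config()] and [decoder_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- raw$seed
  if (is.null(seed)) stop("config must set `seed`", call. = FALSE)
  experiment <- raw$experiment %||% 1
  params <- do.call(generator_params,
                    c(list(experiment = experiment, seed = seed),
                      raw$params %||% list()))
  cl_args <- raw$cluster %||% list()
  if (is.null(cl_args$seed)) cl_args$seed <- seed
  dc_args <- raw$decoder %||% list()
  if (is.null(dc_args$seed)) dc_args$seed <- seed
  pipeline_config(
    experiment = experiment,
    n_objects = raw$n_objects,
    params = params,
    cluster = do.call(cluster_config, cl_args),
    decoder = do.call(decoder_config, dc_args),
    stages = raw$stages %||% c("erp", "decoding", "behavior"),
    decoding_phases = raw$decoding_phases %||% "encoding",
    seed = seed
  )
}

stage_time <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- force(expr)
  list(value = value, elapsed = proc.time()[["elapsed"]] - t0)
}

#' Run the full synthetic-study pipeline
#'
#' Builds the design (condition assignment and the three phase schedules),
#' simulates the requested data, and runs the enabled analysis stages in
#' dependency order: ERP cluster-permutation contrasts on the retrieval
#' phase, within-phase location decoding with the swap-with-chance cluster
#' test, and the behavioural statistics battery. Any stage failure aborts
#' with an error naming the stage.
#'
#' @param config A [pipeline_config()] object.
#' @return A `run_report` list: per-stage results, wall-clock seconds per
#'   stage, the configuration echo, and the package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(config = config,
                 version = as.character(utils::packageVersion("retrocue")),
                 stages = list(), timing = list())
  run_stage <- function(name, expr) {
    res <- tryCatch(stage_time(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report$stages[[name]] <<- res$value
    report$timing[[name]] <<- res$elapsed
    res$value
  }

  sched <- run_stage("schedule", {
    objects <- assign_conditions(config$n_objects, config$experiment,
                                 seed = derive_seed(config$seed, "objects"))
    wm <- build_wm_schedule(objects, config$experiment,
                            seed = derive_seed(config$seed, "wm"))
    list(
      objects = objects,
      encoding = build_encoding_schedule(objects,
                                         seed = derive_seed(config$seed, "enc")),
      wm = wm,
      retrieval = build_retrieval_schedule(objects,
                                           seed = derive_seed(config$seed, "ret")),
      probing = count_probe_instances(wm)
    )
  })

  if ("behavior" %in% config$stages) {
    run_stage("behavior", {
      behav <- simulate_behavior(sched$retrieval, config$params,
                                 probing_counts = sched$probing)
      list(table = behav,
           accuracy = behavior_battery(behav, "accuracy"),
           rt = behavior_battery(behav, "rt"))
    })
  }

  if ("erp" %in% config$stages) {
    run_stage("erp", {
      epochs <- simulate_study("retrieval", sched$retrieval, config$params)
      erp <- condition_erp(epochs)
      contrasts <- lapply(config$erp_contrasts, function(pr) {
        cluster_permutation_test(erp, pr[1], pr[2], config$cluster)
      })
      names(contrasts) <- vapply(config$erp_contrasts,
                                 function(pr) paste(pr[1], "vs", pr[2]),
                                 character(1))
      list(erp = erp, contrasts = contrasts)
    })
  }

  if ("decoding" %in% config$stages) {
    run_stage("decoding", {
      out <- lapply(config$decoding_phases, function(ph) {
        schedule <- sched[[ph]]
        epochs <- simulate_study(ph, schedule, config$params)
        tc <- decode_within_phase(epochs, config$decoder)
        cl_cfg <- config$cluster
        cl_cfg$sidedness <- "one"
        list(timecourse = tc, cluster = decoding_cluster_test(tc, cl_cfg))
      })
      names(out) <- config$decoding_phases
      out
    })
  }

  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> retrocue ", x$version, ", experiment ",
      x$config$experiment, "\n", sep = "")
  for (nm in names(x$stages)) {
    cat(sprintf("  %-10s %6.2f s\n", nm, x$timing[[nm]]))
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits a JSON master report (summary statistics, cluster bounds in ms,
#' decoding chance level, configuration echo, timings) plus CSV/TSV tables
#' for the schedules, behaviour table and decoding timecourses.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of files written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name) {
    files <<- c(files, file.path(dir, name))
    file.path(dir, name)
  }

  sched <- report$stages$schedule
  write_schedule(sched$encoding, emit("schedule_encoding.tsv"))
  write_schedule(sched$wm, emit("schedule_wm.tsv"))
  write_schedule(sched$retrieval, emit("schedule_retrieval.tsv"))

  master <- list(
    version = report$version,
    experiment = report$config$experiment,
    seed = report$config$seed,
    timing = report$timing,
    schedule = list(
      n_encoding = nrow(sched$encoding),
      n_wm = nrow(sched$wm),
      n_retrieval = nrow(sched$retrieval),
      frac_no_response = mean(sched$wm$correct_response == "no")
    )
  )

  if (!is.null(report$stages$behavior)) {
    b <- report$stages$behavior
    readr::write_csv(b$table, emit("behavior.csv"))
    readr::write_csv(b$accuracy$pairwise, emit("behavior_accuracy_pairwise.csv"))
    readr::write_csv(b$rt$pairwise, emit("behavior_rt_pairwise.csv"))
    master$behavior <- list(
      accuracy = list(
        F = b$accuracy$anova$F, p_corrected = b$accuracy$anova$p_corrected,
        partial_eta_sq = b$accuracy$anova$partial_eta_sq,
        epsilon_gg = b$accuracy$anova$epsilon_gg,
        friedman_chi2 = b$accuracy$friedman$chi2,
        kendall_w = b$accuracy$friedman$kendall_w,
        condition_means = as.list(colMeans(b$accuracy$matrix))
      ),
      rt = list(
        F = b$rt$anova$F, p_corrected = b$rt$anova$p_corrected,
        condition_means = as.list(colMeans(b$rt$matrix))
      )
    )
  }

  if (!is.null(report$stages$erp)) {
    e <- report$stages$erp
    master$erp <- lapply(e$contrasts, function(cl) {
      sig <- cl$clusters[cl$clusters$significant, , drop = FALSE]
      list(size_threshold = cl$size_threshold,
           n_clusters = nrow(cl$clusters),
           significant_clusters_ms = if (nrow(sig)) {
             lapply(seq_len(nrow(sig)), function(i) {
               c(sig$start_ms[i], sig$end_ms[i])
             })
           } else {
             list()
           })
    })
    for (nm in names(e$contrasts)) {
      write_cluster_result(
        e$contrasts[[nm]],
        emit(paste0("erp_", gsub(" ", "_", nm), ".json")))
    }
  }

  if (!is.null(report$stages$decoding)) {
    master$decoding <- lapply(report$stages$decoding, function(d) {
      sig <- d$cluster$clusters[d$cluster$clusters$significant, , drop = FALSE]
      list(chance = d$timecourse$chance_level,
           peak_accuracy = max(colMeans(d$timecourse$accuracy)),
           significant_clusters_ms = if (nrow(sig)) {
             lapply(seq_len(nrow(sig)), function(i) {
               c(sig$start_ms[i], sig$end_ms[i])
             })
           } else {
             list()
           })
    })
    for (nm in names(report$stages$decoding)) {
      write_decoding_timecourse(
        report$stages$decoding[[nm]]$timecourse,
        emit(paste0("decoding_", nm, ".csv")))
    }
  }

  jsonlite::write_json(master, emit("report.json"), auto_unbox = TRUE,
                       digits = NA)
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    stop("report validation failed; missing outputs: ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  }
  invisible(files)
}
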