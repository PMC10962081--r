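# End-to-end orchestration: simulate -> cluster -> exclusivity -> profiles
# -> association from one configuration, with per-stage sub-seeding, a log,
# and a manifest of outputs.

#' Assemble a pipeline run configuration
#'
#' @param stages Character subset of
#'   `c("simulate", "cluster", "exclusivity", "profile", "assoc")`.
#'   `"exclusivity"` requires `"cluster"`; with `"simulate"` absent, input
#'   paths must be supplied.
#' @param out_dir Output directory (created if missing).
#' @param seed Global integer seed; every stage derives its own seed from
#'   it (see [stage_seed()]).
#' @param fibre_config A [fibre_sim_config()] used by the simulate stage
#'   (its own `seed` field is overridden by the derived stage seed).
#' @param profile_config A [profile_sim_config()], likewise.
#' @param locs_path,profiles_path Input files used when `"simulate"` is
#'   not requested.
#' @param marks Two mark labels clustered and tested for exclusivity.
#' @param clustering A [clustering_params()].
#' @param overlap_radius Overlap radius in nm.
#' @param mcf_bins Mark connection bin edges in nm.
#' @param n_permutations Random-labelling replicates for the envelope.
#' @param tolerance_factors Peak-detection tolerances to run.
#' @param max_lag Cross-correlation maximum lag in nm.
#' @param knn_k Neighbour ranks for the association stage.
#' @param reference_mark Reference label for the association stage.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(stages = c("simulate", "cluster", "exclusivity"),
                       out_dir = tempfile("loopstate_run_"),
                       seed = 1L,
                       fibre_config = fibre_sim_config(),
                       profile_config = profile_sim_config(),
                       locs_path = NULL, profiles_path = NULL,
                       marks = fibre_config$class_labels,
                       clustering = clustering_params(),
                       overlap_radius = 50,
                       mcf_bins = seq(0, 500, by = 20),
                       n_permutations = 199,
                       tolerance_factors = c(0.17, 1.0),
                       max_lag = 1000,
                       knn_k = c(5, 9, 21),
                       reference_mark = "RPolPser2") {
  known <- c("simulate", "cluster", "exclusivity", "profile", "assoc")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if ("exclusivity" %in% stages && !"cluster" %in% stages)
    stop("stage 'exclusivity' requires stage 'cluster'")
  if (!"simulate" %in% stages) {
    if (any(c("cluster", "exclusivity", "assoc") %in% stages) &&
        is.null(locs_path))
      stop("locs_path is required when 'simulate' is not run")
    if ("profile" %in% stages && is.null(profiles_path))
      stop("profiles_path is required when 'simulate' is not run")
  }
  structure(list(stages = stages, out_dir = out_dir, seed = as.integer(seed),
                 fibre_config = fibre_config,
                 profile_config = profile_config,
                 locs_path = locs_path, profiles_path = profiles_path,
                 marks = marks, clustering = clustering,
                 overlap_radius = overlap_radius, mcf_bins = mcf_bins,
                 n_permutations = n_permutations,
                 tolerance_factors = tolerance_factors, max_lag = max_lag,
                 knn_k = knn_k, reference_mark = reference_mark),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()];
#' `fibre_config`, `profile_config` and `clustering` are nested mappings
#' with the field names of their constructors.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$fibre_config))
    args$fibre_config <- do.call(fibre_sim_config, y$fibre_config)
  if (!is.null(y$profile_config))
    args$profile_config <- do.call(profile_sim_config, y$profile_config)
  if (!is.null(y$clustering))
    args$clustering <- do.call(clustering_params, y$clustering)
  do.call(run_config, args)
}

#' Derive a stage seed from the global seed
#'
#' Stable string hash of the stage name folded with the global seed, kept
#' below 2^31 so it is a valid R seed. Adding new stages never perturbs
#' the seeds of existing ones.
#'
#' @param global_seed Integer.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(global_seed, stage) {
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 1000000007
  as.integer((as.numeric(global_seed) %% 1000003 * 1009 + h) %% 2147483629)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order, writing every stage
#' output under `config$out_dir` together with a timestamped log and a
#' JSON manifest. A stage failure is logged and halts its dependents, but
#' independent branches still run; the manifest records per-stage status
#' and is written even on partial failure.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (list with `seed`, `config`, `stages`,
#'   `log`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    writeLines(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                       sprintf(...)), log_con)
  }
  manifest <- list(seed = config$seed,
                   config = unclass_deep(config),
                   stages = list(), log = log_path)
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, deps, fn) {
    if (!name %in% config$stages) return()
    for (d in deps) {
      st <- manifest$stages[[d]]
      if (is.null(st) || st$status != "ok") {
        logmsg("stage %s skipped: dependency %s not satisfied", name, d)
        manifest$stages[[name]] <<- list(status = "skipped", outputs = list())
        return()
      }
    }
    logmsg("stage %s: start (seed %d)", name, stage_seed(config$seed, name))
    res <- tryCatch({
      outs <- fn(stage_seed(config$seed, name))
      list(status = "ok", outputs = outs)
    }, error = function(e) {
      logmsg("stage %s FAILED: %s", name, conditionMessage(e))
      list(status = "failed", error = conditionMessage(e), outputs = list())
    })
    logmsg("stage %s: %s", name, res$status)
    manifest$stages[[name]] <<- res
  }

  run_stage("simulate", character(0), function(seed) {
    outs <- list()
    fc <- config$fibre_config
    fc$seed <- seed
    sim <- simulate_fibre(fc)
    state$table <- sim$table
    state$fibre_truth <- sim$truth
    outs$locs <- file.path(config$out_dir, "locs.csv")
    write_localisations(sim$table, outs$locs)
    outs$fibre_truth <- file.path(config$out_dir, "fibre_truth.json")
    jsonlite::write_json(truth_summary(sim$truth), outs$fibre_truth,
                         auto_unbox = TRUE, digits = NA)
    pc <- config$profile_config
    pc$seed <- stage_seed(seed, "profiles")
    psim <- simulate_paired_profiles(pc)
    state$profiles <- psim$profiles
    state$profile_truth <- psim$truth
    outs$profiles <- file.path(config$out_dir, "profiles.csv")
    write_profiles(psim$profiles, outs$profiles)
    outs
  })

  if (!"simulate" %in% config$stages) {
    if (!is.null(config$locs_path))
      state$table <- read_localisations(config$locs_path)
    if (!is.null(config$profiles_path))
      state$profiles <- read_profiles(config$profiles_path)
  }

  run_stage("cluster",
            if ("simulate" %in% config$stages) "simulate" else character(0),
            function(seed) {
    outs <- list()
    state$clusters <- list()
    for (mk in config$marks) {
      cs <- mean_shift_cluster(state$table, mk, config$clustering)
      state$clusters[[mk]] <- cs
      p <- file.path(config$out_dir, sprintf("clusters_%s.txt", mk))
      write_results(cs, p)
      outs[[mk]] <- p
    }
    outs
  })

  run_stage("exclusivity", "cluster", function(seed) {
    outs <- list()
    for (i in 1:2) {
      mk <- config$marks[i]
      other <- config$marks[3 - i]
      ov <- overlap_fraction(state$clusters[[mk]], state$table,
                             other_mark = other,
                             radius = config$overlap_radius)
      p <- file.path(config$out_dir, sprintf("overlap_%s_clustered.txt", mk))
      write_results(ov, p)
      outs[[paste0("overlap_", mk)]] <- p
    }
    mcf <- mark_connection(state$table, config$marks[1], config$marks[2],
                           bin_edges = config$mcf_bins,
                           n_permutations = config$n_permutations,
                           seed = seed)
    p <- file.path(config$out_dir, "mark_connection.txt")
    write_results(mcf, p)
    outs$mcf <- p
    outs$verdict <- exclusivity_verdict(mcf)$summary
    outs
  })

  run_stage("profile",
            if ("simulate" %in% config$stages) "simulate" else character(0),
            function(seed) {
    outs <- list()
    for (tol in config$tolerance_factors) {
      ps <- lapply(state$profiles, find_peaks, channel = "a",
                   tolerance_factor = tol)
      ps <- ps[vapply(ps, function(p) length(p$positions) >= 2, logical(1))]
      if (length(ps)) {
        st <- spacing_stats(ps)
        p <- file.path(config$out_dir,
                       sprintf("spacings_tol%s.txt", format(tol)))
        write_results(st, p)
        outs[[sprintf("spacings_tol%s", format(tol))]] <- p
      }
    }
    xc <- lapply(state$profiles, cross_correlate, max_lag = config$max_lag)
    state$xcorr <- xc
    for (x in xc)
      write_results(x, file.path(config$out_dir,
                                 sprintf("xcorr_%s.txt", x$roi_id)))
    n_sig <- sum(vapply(xc, `[[`, logical(1), "significant"))
    logmsg("profile stage: %d/%d ROIs significant; non-significant discarded",
           n_sig, length(xc))
    outs$xcorr_dir <- config$out_dir
    outs
  })

  run_stage("assoc",
            if ("simulate" %in% config$stages) "simulate" else character(0),
            function(seed) {
    outs <- list()
    ref <- state$table[state$table$mark == config$reference_mark, ,
                       drop = FALSE]
    if (nrow(ref) == 0L)
      stop("no localisations of reference mark '", config$reference_mark, "'")
    for (mk in config$marks) {
      for (k in config$knn_k) {
        kn <- knn_distances(state$table, state$table, k, mark = mk,
                            reference_mark = config$reference_mark)
        p <- file.path(config$out_dir, sprintf("knn_%s_k%d.txt", mk, k))
        write_results(kn, p)
        outs[[sprintf("%s_k%d", mk, k)]] <- p
      }
    }
    outs
  })

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  manifest$path <- manifest_path
  invisible(manifest)
}

truth_summary <- function(truth) {
  list(true_fwhm = truth$true_fwhm,
       true_shift = truth$true_shift,
       true_overlap_fraction = truth$true_overlap_fraction,
       n_clusters = if (!is.null(truth$cluster_centres))
         nrow(truth$cluster_centres) else 0L,
       mean_spacing = mean(truth$true_spacings))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
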