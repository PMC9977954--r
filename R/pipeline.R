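#' @title Pipeline driver and report assembly
#' @name pipeline
#' @description
#' `run_pipeline()` ties the stages together behind one configuration object:
#' `validate` (blot table to significant-pair table), `score` (model plus
#' restraints to a satisfaction report), `rank` (several models), `sample`
#' (rigid-body Metropolis Monte Carlo), `orient` (ensemble to per-frame
#' orientation tables) and `simulate` (synthetic fixtures with ground truth).
#' Every run writes a provenance log (package and R versions, seed, full
#' configuration echo); identical configuration, inputs and seed give
#' byte-identical outputs. Output files are never overwritten unless
#' `overwrite = TRUE`. A thin command-line wrapper around this function ships
#' in the package's `exec` directory.
NULL

#' Pipeline configuration
#'
#' @param subcommand One of `validate`, `score`, `rank`, `sample`, `orient`,
#'   `simulate`.
#' @param inputs Named list of input paths (see [run_pipeline()]).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed used by stochastic subcommands.
#' @param overwrite Allow overwriting existing outputs (default `FALSE`).
#' @param alpha_t,alpha_welch,min_n Significance-filter settings.
#' @param lo,hi Restraint walls, Angstroms.
#' @param cutoffs Satisfaction cutoffs, Angstroms.
#' @param sampler Optional [sampler_config()] for `sample`.
#' @param receptor_chains,arrestin_chains Chain ids for `orient`.
#' @return List of class `xl_config`.
#' @export
pipeline_config <- function(subcommand, inputs = list(), out_dir = ".",
                            seed = 1L, overwrite = FALSE,
                            alpha_t = 0.02, alpha_welch = 0.05, min_n = 3,
                            lo = 4.0, hi = 10.2, cutoffs = c(10.2, 15.0),
                            sampler = NULL,
                            receptor_chains = "R", arrestin_chains = "A") {
  if (alpha_t <= 0 || alpha_welch <= 0 || lo <= 0 || hi <= lo)
    stop("thresholds must be positive and walls ordered", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "xl_config"
  cfg
}

out_path <- function(config, name) {
  p <- file.path(config$out_dir, name)
  if (file.exists(p) && !isTRUE(config$overwrite))
    stop("output ", p, " exists; set overwrite = TRUE to replace it",
         call. = FALSE)
  p
}

write_provenance <- function(config, files) {
  log <- c(
    paste0("xltrap version: ",
           as.character(utils::packageVersion("xltrap"))),
    paste0("R version: ", R.version.string),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("subcommand: ", config$subcommand),
    paste0("seed: ", config$seed),
    paste0("inputs: ", paste(names(config$inputs), unlist(config$inputs),
                             sep = "=", collapse = "; ")),
    paste0("settings: alpha_t=", config$alpha_t,
           " alpha_welch=", config$alpha_welch, " min_n=", config$min_n,
           " walls=", config$lo, "/", config$hi,
           " cutoffs=", paste(config$cutoffs, collapse = "/")),
    paste0("outputs: ", paste(files, collapse = "; "))
  )
  writeLines(log, file.path(config$out_dir, paste0(config$subcommand,
                                                   "_run.log")))
}

require_inputs <- function(config, names) {
  for (nm in names) {
    p <- config$inputs[[nm]]
    if (is.null(p) || !file.exists(p))
      stop("missing input '", nm, "' for subcommand ", config$subcommand,
           call. = FALSE)
  }
}

#' Run one pipeline stage
#'
#' Input slots by subcommand: `validate` needs `blot`; `score` needs `model`
#' and `restraints`; `rank` needs `models` (vector of paths) and
#' `restraints`; `sample` needs `receptor`, `mobile`, `restraints`; `orient`
#' needs `ensemble`; `simulate` needs nothing.
#'
#' @param config An [pipeline_config()].
#' @return Invisibly, a character vector of output paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "xl_config"))
    stop("config must come from pipeline_config()", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- switch(
    config$subcommand,
    validate = {
      require_inputs(config, "blot")
      pairs <- validate_pairs(read_blot_table(config$inputs$blot),
                              alpha_t = config$alpha_t,
                              alpha_welch = config$alpha_welch,
                              min_n = config$min_n)
      f <- out_path(config, "validated_pairs.tsv")
      write_pairs(pairs, f)
      f
    },
    score = {
      require_inputs(config, c("model", "restraints"))
      model <- read_structure(config$inputs$model)
      restraints <- read_restraints(config$inputs$restraints,
                                    lo = config$lo, hi = config$hi)
      rep <- score_model(model, restraints, cutoffs = config$cutoffs)
      f <- out_path(config, "restraint_report.tsv")
      write_report(rep, f)
      f
    },
    rank = {
      require_inputs(config, "restraints")
      paths <- config$inputs$models
      if (is.null(paths) || !all(file.exists(paths)))
        stop("missing input 'models' for subcommand rank", call. = FALSE)
      restraints <- read_restraints(config$inputs$restraints,
                                    lo = config$lo, hi = config$hi)
      ranking <- rank_models(lapply(paths, read_structure), restraints,
                             cutoffs = config$cutoffs)
      ranking$path <- paths[ranking$model]
      f <- out_path(config, "model_ranking.tsv")
      utils::write.table(ranking, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      f
    },
    sample = {
      require_inputs(config, c("receptor", "mobile", "restraints"))
      receptor <- read_structure(config$inputs$receptor)
      mobile <- read_structure(config$inputs$mobile)
      restraints <- read_restraints(config$inputs$restraints,
                                    lo = config$lo, hi = config$hi)
      sc <- if (is.null(config$sampler))
        sampler_config(steps = 10000L, seed = config$seed) else config$sampler
      res <- mmc_optimize(receptor, mobile, restraints, sc)
      fs <- character()
      for (k in seq_along(res$trials)) {
        f <- out_path(config, sprintf("best_pose_trial%02d.pdb", k))
        write_pdb(apply_pose(mobile, res$trials[[k]]$best_pose), f)
        fs <- c(fs, f)
      }
      tr <- do.call(rbind, lapply(seq_along(res$trials), function(k)
        cbind(trial = k, res$trials[[k]]$trace)))
      names(tr)[names(tr) == "energy"] <- "energy_weighted_A2"
      f <- out_path(config, "energy_trace.tsv")
      utils::write.table(tr, f, sep = "\t", quote = FALSE, row.names = FALSE)
      c(fs, f)
    },
    orient = {
      require_inputs(config, "ensemble")
      ens <- read_ensemble(config$inputs$ensemble)
      rec_nose <- config$inputs$receptor_nose
      arr_nose <- config$inputs$arrestin_nose
      if (is.null(rec_nose) || is.null(arr_nose))
        stop("orient needs receptor_nose and arrestin_nose definitions",
             call. = FALSE)
      ori <- ensemble_orientation(ens, config$receptor_chains,
                                  config$arrestin_chains, rec_nose, arr_nose)
      f <- out_path(config, "orientation.tsv")
      utils::write.table(ori, f, sep = "\t", quote = FALSE, row.names = FALSE)
      f
    },
    simulate = {
      toy <- make_toy_complex(seed = config$seed)
      sim <- simulate_blot_table(
        stats::setNames(toy$restraints$yield,
                        paste0("pair", seq_len(nrow(toy$restraints)))),
        seed = config$seed)
      traj <- simulate_trajectory(toy$receptor, toy$mobile,
                                  seed = config$seed)
      fs <- c(receptor = out_path(config, "receptor.pdb"),
              mobile = out_path(config, "mobile.pdb"),
              restraints = out_path(config, "restraints.tsv"),
              blot = out_path(config, "blot.tsv"),
              blot_truth = out_path(config, "blot_truth.tsv"),
              trajectory = out_path(config, "trajectory.pdb"),
              planted = out_path(config, "planted_angles.tsv"))
      write_pdb(toy$receptor, fs["receptor"])
      write_pdb(toy$mobile, fs["mobile"])
      write_restraints(toy$restraints, fs["restraints"])
      utils::write.table(sim$table, fs["blot"], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(sim$truth, fs["blot_truth"], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_ensemble(traj$ensemble, fs["trajectory"])
      utils::write.table(traj$planted, fs["planted"], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      unname(fs)
    },
    stop("unknown subcommand: ", config$subcommand, call. = FALSE)
  )
  write_provenance(config, files)
  invisible(files)
}
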