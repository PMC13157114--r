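#' Run configuration for the end-to-end pipeline
#'
#' A flat, serializable set of scalars that drives simulation and every
#' analysis stage. Defaults equal the experiment's stated values (512 Hz,
#' 12/15 Hz tags, -200..3000 ms epochs, 150 uV rejection, 0.02 uS SCR
#' threshold, five-valid-trial inclusion). Being flat, the config
#' round-trips exactly through its YAML serialization.
#'
#' @param n_per_group participants per group.
#' @param n_trials_atb ATB trials per emotion combination.
#' @param n_trials_viewing viewing trials per expression.
#' @param seed master seed.
#' @param noise_sd_uv EEG background noise SD.
#' @param hemifield_bias stress-group left-hemifield gain.
#' @param stages character vector of stages to run, a subset of
#'   `c("ratings", "ssvep", "erp", "erd", "scr", "hr", "saliva")`.
#' @param out_dir output directory for report tables (`NULL` = do not
#'   write).
#' @return list of class `run_config`.
#' @export
run_config <- function(n_per_group = 4, n_trials_atb = 12,
                       n_trials_viewing = 6, seed = 1L, noise_sd_uv = 2,
                       hemifield_bias = 0.35,
                       stages = c("ratings", "ssvep", "erp", "erd", "scr",
                                  "hr", "saliva"),
                       out_dir = NULL) {
  cfg <- list(n_per_group = n_per_group, n_trials_atb = n_trials_atb,
              n_trials_viewing = n_trials_viewing, seed = as.integer(seed),
              noise_sd_uv = noise_sd_uv, hemifield_bias = hemifield_bias,
              stages = stages, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration
#'
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns the restored `run_config`;
#'   `write_run_config` returns `path` invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$stages)) cfg$stages <- as.character(cfg$stages)
  class(cfg) <- "run_config"
  cfg
}

#' @keywords internal
sim_config_from_run <- function(cfg) {
  sim_config(n_participants_per_group = cfg$n_per_group,
             n_trials_atb = cfg$n_trials_atb,
             n_trials_viewing = cfg$n_trials_viewing,
             noise = list(exponent = 1, sd_uv = cfg$noise_sd_uv),
             hemifield_bias = cfg$hemifield_bias,
             seed = cfg$seed)
}

#' Run the full simulate-and-analyze pipeline
#'
#' For every simulated participant: preprocesses both EEG tasks (band-pass,
#' notch, epoching, average reference, baseline, 150 uV rejection), scores
#' attentional bias (global window), ERP components, frontal alpha ERD (on
#' epochs padded 500 ms before the baseline window so the wavelet baseline
#' is edge-free), skin conductance, heart rate, saliva AUCs, and ratings;
#' then fits the group-level models and assembles report tables.
#'
#' @param cfg a [run_config()].
#' @return list of class `pipeline_report`: per-stage tidy tables
#'   (`ratings_summary`, `abs_scores`, `erp_components`, `erd_values`,
#'   `scr_cells`, `hr_means`, `saliva_auc`), model results (`anovas`,
#'   `group_tests`), and a `log` of parameters and seeds. Tables are also
#'   written as TSVs when `cfg$out_dir` is set.
#' @export
run_pipeline <- function(cfg) {
  sim <- sim_config_from_run(cfg)
  stages <- cfg$stages
  acc <- list(ratings = list(), abs = list(), erp = list(), erd = list(),
              scr = list(), hr = list(), auc = list())
  for (group in c("stress", "control")) {
    for (p in seq_len(cfg$n_per_group)) {
      pid <- paste0(substr(group, 1, 1), p)
      session <- generate_session(sim, group, p)

      if ("ssvep" %in% stages) {
        ep <- preprocess_recording(session$atb$recording,
                                   session$atb$conditions)
        tab <- abs_table(ep, pid, group,
                         windows = list("100-3000" = c(100, 3000)))
        acc$abs[[length(acc$abs) + 1]] <- tab
      }
      need_viewing <- any(c("erp", "erd") %in% stages)
      if (need_viewing) {
        ep_v <- preprocess_recording(session$viewing$recording,
                                     session$viewing$conditions)
        if ("erp" %in% stages) {
          acc$erp[[length(acc$erp) + 1]] <- component_table(ep_v, pid, group)
        }
        if ("erd" %in% stages) {
          ep_pad <- preprocess_recording(session$viewing$recording,
                                         session$viewing$conditions,
                                         tmin_ms = -700)
          erd <- alpha_erd(ep_pad, participant = pid, group = group)
          acc$erd[[length(acc$erd) + 1]] <- data.frame(
            participant = pid, group = group, erd_value = erd$erd_value)
        }
      }
      if ("scr" %in% stages) {
        onsets <- (session$atb$conditions$onset_sample - 1) / sim$sample_rate
        scores <- score_scr_trials(preprocess_scr(session$scr$atb), onsets,
                                   session$atb$conditions$trial_id)
        cond <- data.frame(trial_id = session$atb$conditions$trial_id,
                           condition = session$atb$conditions$combination)
        cells <- participant_scr_cells(scores, cond)
        cells$cells$participant <- pid
        cells$cells$group <- group
        cells$cells$included <- cells$included
        acc$scr[[length(acc$scr) + 1]] <- cells$cells
      }
      if ("hr" %in% stages) {
        onsets_ms <- (session$atb$conditions$onset_sample - 1) /
          sim$sample_rate * 1000
        hr <- do.call(rbind, lapply(seq_along(onsets_ms), function(i) {
          h <- hr_windows(session$rr$atb, onsets_ms[i])
          h$combination <- session$atb$conditions$combination[i]
          h
        }))
        hr_cells <- stats::aggregate(mean_hr_bpm ~ window + combination,
                                     hr, mean, na.action = stats::na.omit)
        hr_cells$participant <- pid
        hr_cells$group <- group
        acc$hr[[length(acc$hr) + 1]] <- hr_cells
      }
      if ("saliva" %in% stages) {
        for (an in c("cortisol", "saa")) {
          ser <- session$saliva[session$saliva$analyte == an, ]
          acc$auc[[length(acc$auc) + 1]] <- data.frame(
            participant = pid, group = group, analyte = an,
            aucg = aucg(ser), auci = auci(ser))
        }
      }
      if ("ratings" %in% stages) {
        r <- session$ratings
        r$participant <- pid
        r$group <- group
        acc$ratings[[length(acc$ratings) + 1]] <- r
      }
    }
  }

  report <- list(anovas = list(), group_tests = list())

  if ("ratings" %in% stages) {
    ratings <- do.call(rbind, acc$ratings)
    per_cell <- stats::aggregate(cbind(arousal, valence) ~
                                   participant + group + expression,
                                 ratings, mean)
    report$ratings_summary <- do.call(rbind, lapply(
      split(per_cell, list(per_cell$group, per_cell$expression)),
      function(d) data.frame(group = d$group[1], expression = d$expression[1],
                             arousal_mean = mean(d$arousal),
                             arousal_sd = stats::sd(d$arousal),
                             valence_mean = mean(d$valence),
                             valence_sd = stats::sd(d$valence))))
    rownames(report$ratings_summary) <- NULL
    if (cfg$n_per_group >= 2) {
      report$anovas$arousal <- mixed_rmanova(per_cell, "arousal",
                                             "participant", "group",
                                             "expression")
      report$anovas$valence <- mixed_rmanova(per_cell, "valence",
                                             "participant", "group",
                                             "expression")
    }
  }
  if ("ssvep" %in% stages) {
    report$abs_scores <- do.call(rbind, acc$abs)
    if (cfg$n_per_group >= 2) {
      report$anovas$abs <- mixed_rmanova(report$abs_scores, "abs",
                                         "participant", "group",
                                         c("combination", "hemifield"))
    }
  }
  if ("erp" %in% stages) {
    report$erp_components <- do.call(rbind, acc$erp)
    if (cfg$n_per_group >= 2) {
      for (comp in c("P1", "N170", "EPN", "P1N170_pp")) {
        d <- report$erp_components[report$erp_components$component == comp, ]
        report$anovas[[comp]] <- mixed_rmanova(d, "amplitude", "participant",
                                               "group",
                                               c("expression", "hemisphere"))
      }
      d <- report$erp_components[report$erp_components$component == "LPP", ]
      report$anovas$LPP <- mixed_rmanova(d, "amplitude", "participant",
                                         "group", "expression")
    }
  }
  if ("erd" %in% stages) {
    report$erd_values <- do.call(rbind, acc$erd)
    if (cfg$n_per_group >= 2) {
      g <- split(report$erd_values$erd_value, report$erd_values$group)
      report$group_tests$erd <- ttest_ind(g$stress, g$control)
    }
  }
  if ("scr" %in% stages) {
    report$scr_cells <- do.call(rbind, acc$scr)
  }
  if ("hr" %in% stages) {
    report$hr_means <- do.call(rbind, acc$hr)
  }
  if ("saliva" %in% stages) {
    report$saliva_auc <- do.call(rbind, acc$auc)
    if (cfg$n_per_group >= 2) {
      for (an in c("cortisol", "saa")) {
        d <- report$saliva_auc[report$saliva_auc$analyte == an, ]
        g <- split(d$aucg, d$group)
        report$group_tests[[paste0(an, "_aucg")]] <- ttest_ind(g$stress,
                                                               g$control)
      }
    }
  }

  report$log <- list(
    package_version = as.character(utils::packageVersion("stressvep")),
    r_version = R.version.string,
    seed = cfg$seed, config = unclass(cfg),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  class(report) <- "pipeline_report"

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Write a pipeline report's tables to TSV files
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the written paths.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  tables <- Filter(is.data.frame, report)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p)
  }
  for (nm in names(report$anovas)) {
    p <- file.path(dir, paste0("anova_", nm, ".tsv"))
    utils::write.table(report$anovas[[nm]]$table, p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  writeLines(yaml::as.yaml(report$log), file.path(dir, "run_log.yaml"))
  invisible(c(paths, file.path(dir, "run_log.yaml")))
}

#' Write a simulated session to plain-text files
#'
#' Serializes a [generate_session()] result into a directory of TSVs: the
#' event/condition tables for both tasks (`atb_events.tsv`,
#' `viewing_events.tsv`), skin conductance traces (`scr_<task>.tsv`:
#' `time_s`, `value_us`), RR series (`rr_<task>.tsv`: `beat_time_ms`,
#' `rr_ms`), the saliva series and per-trial ratings, and optionally the
#' continuous EEG as a wide TSV (`eeg_<task>.tsv`, one column per channel;
#' large).
#'
#' @param session a `stress_session`.
#' @param dir output directory.
#' @param include_eeg write the continuous EEG matrices too.
#' @return invisibly, the written paths.
#' @export
write_session <- function(session, dir, include_eeg = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(d, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(d, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  paths <- c(
    w(session$atb$conditions, "atb_events"),
    w(session$viewing$conditions, "viewing_events"),
    w(session$scr$atb, "scr_atb"), w(session$scr$viewing, "scr_viewing"),
    w(session$rr$atb, "rr_atb"), w(session$rr$viewing, "rr_viewing"),
    w(session$saliva, "saliva"), w(session$ratings, "ratings")
  )
  if (include_eeg) {
    for (task in c("atb", "viewing")) {
      rec <- session[[task]]$recording
      paths <- c(paths, w(as.data.frame(t(rec$data)),
                          paste0("eeg_", task)))
    }
  }
  invisible(paths)
}

#' Power of hemifield-bias recovery at study scale
#'
#' Simulates `n_experiments` full-size experiments at the amplitude level
#' ([simulate_bias_experiment()]), fits the group x combination x hemifield
#' split-plot ANOVA to each, and returns the fraction in which the
#' group x hemifield interaction is significant.
#'
#' @param config a [sim_config()]; its `hemifield_bias` and
#'   `n_participants_per_group` set the effect and sample size.
#' @param n_experiments number of simulated experiments.
#' @param seed base seed; experiment e uses `seed + e`.
#' @param alpha significance level.
#' @return detection rate in `[0, 1]`.
#' @export
recovery_power_bias <- function(config, n_experiments = 100,
                                seed = config$seed, alpha = 0.05) {
  hits <- 0
  for (e in seq_len(n_experiments)) {
    tab <- simulate_bias_experiment(config, seed = seed + e)
    fit <- mixed_rmanova(tab, "abs", "participant", "group",
                         c("combination", "hemifield"))
    p <- fit$table$p[fit$table$effect == "group:hemifield"]
    hits <- hits + (p < alpha)
  }
  hits / n_experiments
}

#' Power of ERP group-attenuation recovery at study scale
#'
#' Simulates `n_experiments` component tables ([simulate_erp_experiment()]),
#' fits the group x expression x hemisphere ANOVA to the chosen component,
#' and returns the fraction in which the group main effect is significant.
#'
#' @inheritParams recovery_power_bias
#' @param component which component to test (default "P1").
#' @return detection rate in `[0, 1]`.
#' @export
recovery_power_erp <- function(config, n_experiments = 100,
                               seed = config$seed, component = "P1",
                               alpha = 0.05) {
  hits <- 0
  for (e in seq_len(n_experiments)) {
    tab <- simulate_erp_experiment(config, seed = seed + e)
    d <- tab[tab$component == component, ]
    fit <- mixed_rmanova(d, "amplitude", "participant", "group",
                         c("expression", "hemisphere"))
    p <- fit$table$p[fit$table$effect == "group"]
    hits <- hits + (p < alpha)
  }
  hits / n_experiments
}

#' Read deposited behavioral/physiological tables
#'
#' Reads long-format tabular exports (TSV or CSV, autodetected by
#' extension) of the repeated measures the deposited study data provide:
#' each file must carry `participant`, `group`, one within-factor column,
#' and `value`. Expected files: `vas.tsv` (within column `timepoint`),
#' `cortisol.tsv` and `saa.tsv` (`timepoint`), `arousal.tsv` and
#' `valence.tsv` (`expression`).
#'
#' @param dir directory of the exports.
#' @return named list of data.frames (absent files are dropped).
#' @export
read_deposited_tables <- function(dir) {
  specs <- list(vas = "timepoint", cortisol = "timepoint", saa = "timepoint",
                arousal = "expression", valence = "expression")
  out <- list()
  for (nm in names(specs)) {
    path <- NULL
    for (ext in c(".tsv", ".csv")) {
      cand <- file.path(dir, paste0(nm, ext))
      if (file.exists(cand)) path <- cand
    }
    if (is.null(path)) next
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    d <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
    need <- c("participant", "group", specs[[nm]], "value")
    if (!all(need %in% names(d))) {
      stop(path, " lacks columns: ", paste(setdiff(need, names(d)),
                                           collapse = ", "))
    }
    out[[nm]] <- d
  }
  out
}

#' Group x repeated-factor ANOVAs on deposited tables
#'
#' Fits the split-plot group x timepoint (VAS, cortisol, alpha-amylase) and
#' group x expression (arousal, valence) models, with Greenhouse-Geisser
#' correction, to tables read by [read_deposited_tables()].
#'
#' @param tables list of data.frames, or a directory path.
#' @return named list of [mixed_rmanova()] results.
#' @export
reproduce_deposited_anovas <- function(tables) {
  if (is.character(tables)) tables <- read_deposited_tables(tables)
  within_of <- c(vas = "timepoint", cortisol = "timepoint",
                 saa = "timepoint", arousal = "expression",
                 valence = "expression")
  out <- list()
  for (nm in names(tables)) {
    out[[nm]] <- mixed_rmanova(tables[[nm]], "value", "participant",
                               "group", within_of[[nm]])
  }
  out
}
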