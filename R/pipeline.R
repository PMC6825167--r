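#' Pipeline configuration
#'
#' Assembles (and validates) the full set of analysis settings with the
#' study defaults. Any subset can be overridden via arguments or a YAML file
#' ([read_pipeline_config()]); unspecified fields keep their defaults.
#'
#' Named seeds for the stochastic stages (simulation, permutation null,
#' Bayesian integration) are derived from the single master `seed` by fixed
#' offsets, so runs are reproducible piecewise.
#'
#' @param seed Master seed.
#' @param sim A [sim_params()] object, or a list of overrides for its
#'   defaults.
#' @param input_dir Optional directory of serialized epoch arrays (pairs of
#'   `*.f64` + `*.f64.json`, see [write_epochs()]); when given, simulation
#'   is skipped.
#' @param csd A [csd_params()] object or list of overrides; `no_csd = TRUE`
#'   bypasses the surface Laplacian to analyse average-referenced scalp data.
#' @param no_csd Bypass flag for the CSD stage.
#' @param wavelet List with `f_min`, `f_max`, `f_step`, `m`, `trunc_sd`.
#' @param taper_baseline_ms Time-domain baseline window (subtraction).
#' @param rise_fall_samples Cosine-square taper flank length.
#' @param norm_baseline_ms Percent-change baseline window.
#' @param baseline_mode `"power"` or `"amplitude"` divisor domain.
#' @param band_hz Alpha band for summaries.
#' @param roi ROI channels.
#' @param tf_channels Channels at which wavelet power is computed after the
#'   spatial transform; defaults to the ROI (all the downstream summaries
#'   need). Set to `NULL` to keep full-scalp time-frequency maps.
#' @param window_ms A priori analysis window.
#' @param alpha Family-wise level for the permutation test.
#' @param n_perm Number of permutations.
#' @param include_identity Include the observed labeling in the null.
#' @param iterations Bayesian Monte-Carlo iterations.
#' @param n_blocks Blocks for the stability analysis.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = list(),
                            input_dir = NULL,
                            csd = list(),
                            no_csd = FALSE,
                            wavelet = list(),
                            taper_baseline_ms = c(-600, -500),
                            rise_fall_samples = 20L,
                            norm_baseline_ms = c(-400, -200),
                            baseline_mode = "power",
                            band_hz = c(8.1, 11.9),
                            roi = roi_channels(),
                            tf_channels = roi_channels(),
                            window_ms = c(500, 1200),
                            alpha = 0.05,
                            n_perm = 1000L,
                            include_identity = FALSE,
                            iterations = 100000L,
                            n_blocks = 4L) {
  if (!inherits(sim, "sim_params")) sim <- do.call(sim_params, sim)
  if (!inherits(csd, "csd_params")) csd <- do.call(csd_params, csd)
  wdefaults <- list(f_min = 3.8, f_max = 30.4, f_step = 0.38, m = 12,
                    trunc_sd = 3.5)
  wavelet <- utils::modifyList(wdefaults, wavelet)
  seed <- as.integer(seed)
  cfg <- list(seed = seed,
              sim_seed = derive_seed(seed, 101L),
              perm_seed = derive_seed(seed, 202L),
              bayes_seed = derive_seed(seed, 303L),
              sim = sim, input_dir = input_dir,
              csd = csd, no_csd = isTRUE(no_csd),
              wavelet = wavelet,
              taper_baseline_ms = taper_baseline_ms,
              rise_fall_samples = rise_fall_samples,
              norm_baseline_ms = norm_baseline_ms,
              baseline_mode = baseline_mode,
              band_hz = band_hz, roi = roi, tf_channels = tf_channels,
              window_ms = window_ms,
              alpha = alpha, n_perm = as.integer(n_perm),
              include_identity = isTRUE(include_identity),
              iterations = as.integer(iterations),
              n_blocks = as.integer(n_blocks))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Every field of [pipeline_config()] can appear in the file; missing fields
#' take the defaults. `sim` and `csd` are nested maps of the corresponding
#' constructor arguments.
#'
#' @param path YAML file.
#' @param ... Overrides applied after the file (e.g. from command-line
#'   flags); these win over file values.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) {
    stop("Config file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path) %||% list()
  if (!is.null(raw$sim$suppression_depth)) {
    raw$sim$suppression_depth <- unlist(raw$sim$suppression_depth)
  }
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("Unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

config_digest <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config_as_list(cfg), tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$sim <- unclass(out$sim)
  out$csd <- unclass(out$csd)
  out
}

#' Analyse one subject's epochs
#'
#' Runs the single-subject stages: time-domain baseline/taper, optional
#' surface Laplacian, per-condition (and per-block) Morlet power, percent
#' -change normalization, and the alpha summaries.
#'
#' @param epochs An [epoch_array()].
#' @param cfg A [pipeline_config()].
#' @param basis Optional precomputed [csd_basis()] (built from the montage
#'   implied by the epochs when omitted and CSD is enabled).
#' @param montage Montage matching the epochs (needed to build the basis).
#' @return List with `effect_rows`, `timecourse_rows` (tibbles) and
#'   `block_timecourses` (cs x block list of band/ROI series).
#' @export
analyze_subject <- function(epochs, cfg, basis = NULL, montage = NULL) {
  ep <- taper_and_baseline(epochs, cfg$taper_baseline_ms,
                           cfg$rise_fall_samples)
  if (!cfg$no_csd) {
    if (is.null(basis)) {
      stopifnot(!is.null(montage))
      basis <- csd_basis(montage, cfg$csd)
    }
    ep <- csd_transform(ep, basis)
  }
  if (!is.null(cfg$tf_channels)) {
    ep <- subset_epochs(ep, channels = union(cfg$tf_channels, cfg$roi))
  }
  bank <- wavelet_bank(seq(cfg$wavelet$f_min, cfg$wavelet$f_max,
                           by = cfg$wavelet$f_step),
                       m = cfg$wavelet$m, srate = ep$srate,
                       trunc_sd = cfg$wavelet$trunc_sd)

  # per-condition, per-block raw power; condition averages pooled from
  # blocks (power averaging is linear in trials)
  block_power <- list()
  cond_tf <- list()
  for (cs in cs_types()) {
    idx <- which(ep$trial_labels == cs)
    if (length(idx) < cfg$n_blocks) {
      stop("Subject ", ep$subject_id, ": fewer than ", cfg$n_blocks,
           " trials for ", cs, call. = FALSE)
    }
    bl <- block_partition(length(idx), cfg$n_blocks)
    per_block <- lapply(seq_len(cfg$n_blocks), function(b) {
      morlet_power(subset_epochs(ep, trials = idx[bl == b]), bank)
    })
    block_power[[cs]] <- per_block
    cond_tf[[cs]] <- baseline_normalize(pool_power(per_block),
                                        cfg$norm_baseline_ms,
                                        mode = cfg$baseline_mode)
  }

  effect_rows <- alpha_summary(cond_tf, cfg$band_hz, cfg$roi, cfg$window_ms,
                               subject_id = ep$subject_id)
  timecourse_rows <- timecourse_summary(cond_tf, cfg$band_hz, cfg$roi,
                                        subject_id = ep$subject_id)

  block_tc <- purrr::map(block_power, function(per_block) {
    purrr::map(per_block, function(tf) {
      ntf <- baseline_normalize(tf, cfg$norm_baseline_ms,
                                mode = cfg$baseline_mode)
      fb <- band_bins(ntf$freqs, cfg$band_hz)
      chsel <- match(cfg$roi, ntf$channels)
      apply(ntf$power[fb, , chsel, drop = FALSE], 2, mean)
    })
  })

  list(effect_rows = effect_rows, timecourse_rows = timecourse_rows,
       block_timecourses = block_tc, times = ep$times)
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load) -> baseline/taper -> surface Laplacian ->
#' wavelet power -> percent-change normalization -> alpha summaries -> 2x2
#' frequentist and Bayesian inference -> per-sample tmax permutation test ->
#' block-stability ANOVA. With `out_dir` set, writes the effect table and
#' permutation series as CSV, all inferential results as JSON, a
#' human-readable text report, and a log with one timestamped entry per
#' stage; every output embeds the config hash and seeds. On failure the
#' partially written outputs are removed and the error names the stage.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return An object of class `"alpha_pipeline"` (list): `effect_table`,
#'   `timecourses`, `anova`, `bayes`, `dist_check`, `sem`, `perm`,
#'   `block_window_ms`, `block_table`, `block`, `config`, `config_hash`,
#'   `log`, `reference` (`"csd"` or `"average-reference"`).
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log <- character(0)
  note <- function(...) {
    entry <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ",
                    paste0(...))
    log <<- c(log, entry)
  }
  stage <- "setup"
  written <- character(0)
  result <- tryCatch({
    stage <- "montage"
    montage <- build_montage(64)
    note("montage: ", nrow(montage), " channels")

    stage <- "data"
    if (!is.null(cfg$input_dir)) {
      if (!dir.exists(cfg$input_dir)) {
        stop("Input directory not found: ", cfg$input_dir, call. = FALSE)
      }
      files <- list.files(cfg$input_dir, pattern = "\\.f64$",
                          full.names = TRUE)
      if (length(files) == 0) {
        stop("No epoch files (*.f64) in ", cfg$input_dir, call. = FALSE)
      }
      cohort <- lapply(files, read_epochs)
      names(cohort) <- vapply(cohort, `[[`, "", "subject_id")
      note("loaded ", length(cohort), " subjects from ", cfg$input_dir)
    } else {
      cohort <- simulate_cohort(cfg$sim, montage, seed = cfg$sim_seed)
      note("simulated ", length(cohort), " subjects (seed ", cfg$sim_seed,
           ")")
    }

    stage <- "csd"
    basis <- if (cfg$no_csd) NULL else csd_basis(montage, cfg$csd)
    reference <- if (cfg$no_csd) "average-reference" else "csd"
    note("spatial transform: ", reference)

    stage <- "single-subject analysis"
    per_subject <- lapply(cohort, function(ep) {
      sub_montage <- subset_montage(montage, ep$channels)
      analyze_subject(ep, cfg, basis = basis, montage = sub_montage)
    })
    effect_table <- dplyr::bind_rows(
      purrr::map(per_subject, "effect_rows"))
    timecourses <- dplyr::bind_rows(
      purrr::map(per_subject, "timecourse_rows"))
    note("effect table: ", nrow(effect_table), " rows (",
         length(per_subject), " subjects x 4 cells)")

    stage <- "2x2 inference"
    anova <- rm_anova_2x2(effect_table)
    dist_check <- distribution_check(effect_table)
    sem <- within_subject_sem(effect_table)
    note("ANOVA: Contingency F(", anova$df1[1], ",", anova$df2[1], ") = ",
         signif(anova$statistic[1], 4))

    stage <- "bayes"
    bayes <- bayes_model_comparison(effect_table,
                                    iterations = cfg$iterations,
                                    seed = cfg$bayes_seed)
    note("Bayes: best BF10 = ", signif(max(bayes$models$bf10), 4))

    stage <- "permutation"
    diffs <- contingency_diffs(timecourses)
    perm <- permutation_test(diffs, attr(diffs, "times"),
                             n_perm = cfg$n_perm, alpha = cfg$alpha,
                             seed = cfg$perm_seed,
                             include_identity = cfg$include_identity)
    note("permutation: ", nrow(diffs), " subjects x ", ncol(diffs),
         " samples, ", cfg$n_perm, " permutations, ",
         nrow(perm$windows), " significant window(s)")

    stage <- "block analysis"
    if (nrow(perm$windows) > 0) {
      w <- perm$windows[which.max(perm$windows$n_samples), ]
      block_window <- c(w$start_ms, w$end_ms)
      window_source <- "permutation"
    } else {
      block_window <- cfg$window_ms
      window_source <- "a priori (no significant permutation window)"
    }
    times <- per_subject[[1]]$times
    wsel <- times >= block_window[1] & times <= block_window[2]
    block_table <- purrr::imap_dfr(per_subject, function(ps, sid) {
      purrr::map_dfr(c("CS+", "CS-"), function(cgrp) {
        members <- paste0(cgrp, c("E", "N"))
        purrr::map_dfr(seq_len(cfg$n_blocks), function(b) {
          val <- mean(c(ps$block_timecourses[[members[1]]][[b]][wsel],
                        ps$block_timecourses[[members[2]]][[b]][wsel]))
          tibble::tibble(subject_id = sid, contingency = cgrp, block = b,
                         alpha_pct = val)
        })
      })
    })
    block <- block_anova(block_table, cfg$n_blocks)
    note("block ANOVA on ", block_window[1], "-", block_window[2],
         " ms window (", window_source, ")")

    res <- structure(
      list(effect_table = effect_table, timecourses = timecourses,
           anova = anova, bayes = bayes, dist_check = dist_check, sem = sem,
           perm = perm, block_window_ms = block_window,
           block_window_source = window_source,
           block_table = block_table, block = block,
           config = cfg, config_hash = config_digest(cfg), log = log,
           reference = reference),
      class = "alpha_pipeline")

    if (!is.null(out_dir)) {
      stage <- "write outputs"
      written <- write_pipeline_outputs(res, out_dir)
      res$log <- log
    }
    res
  }, error = function(e) {
    if (length(written) > 0) unlink(written)
    stop("Pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- res$config
  meta <- list(config_hash = res$config_hash, seed = cfg$seed,
               sim_seed = cfg$sim_seed, perm_seed = cfg$perm_seed,
               bayes_seed = cfg$bayes_seed, reference = res$reference)
  paths <- character(0)
  wr <- function(name) {
    p <- file.path(out_dir, name)
    paths <<- c(paths, p)
    p
  }

  et <- dplyr::bind_cols(res$effect_table,
                         tibble::tibble(config_hash = res$config_hash,
                                        reference = res$reference))
  utils::write.csv(et, wr("effect_table.csv"), row.names = FALSE)

  perm_csv <- tibble::tibble(time_ms = res$perm$times,
                             t = res$perm$t_series,
                             sig = res$perm$sig_mask)
  utils::write.csv(perm_csv, wr("permutation_series.csv"), row.names = FALSE)

  jsonlite::write_json(
    c(meta, list(anova = res$anova,
                 distribution_check = res$dist_check,
                 within_subject_sem = res$sem)),
    wr("anova.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(
    c(meta, list(models = res$bayes$models, inclusion = res$bayes$incl,
                 iterations = res$bayes$iterations)),
    wr("bayes.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(
    c(meta, list(t_crit_low = res$perm$t_crit_low,
                 t_crit_high = res$perm$t_crit_high,
                 alpha = res$perm$alpha, n_perm = res$perm$n_perm,
                 windows = res$perm$windows)),
    wr("permutation.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(
    c(meta, list(window_ms = res$block_window_ms,
                 window_source = res$block_window_source,
                 anova = res$block$anova, t_tests = res$block$t_tests)),
    wr("block.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(config_as_list(cfg), wr("config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  writeLines(pipeline_report(res), wr("report.txt"))
  writeLines(res$log, wr("log.txt"))
  paths
}

#' Plain-text report in the field's reporting style
#'
#' @param res An `"alpha_pipeline"` result.
#' @return Character vector of report lines.
#' @export
pipeline_report <- function(res) {
  a <- res$anova
  fmt_f <- function(i) {
    sprintf("%s: F(%d, %d) = %.2f, p = %.3g, eta_p^2 = %.3f",
            a$effect[i], a$df1[i], a$df2[i], a$statistic[i], a$p_value[i],
            a$eta_p_sq[i])
  }
  bf <- res$bayes$models
  incl <- res$bayes$incl
  lines <- c(
    "Occipital alpha suppression analysis report",
    paste0("reference: ", res$reference,
           if (res$reference == "average-reference")
             " (surface Laplacian bypassed)" else ""),
    paste0("config hash: ", res$config_hash,
           "; master seed: ", res$config$seed),
    paste0("subjects: ", length(unique(res$effect_table$subject_id))),
    "",
    "2x2 within-subject ANOVA (Contingency x Extinction):",
    vapply(seq_len(nrow(a)), fmt_f, ""),
    "",
    "Bayesian model comparison vs. null (subject-only) model:",
    sprintf("  %s: BF10 = %s (MC error of log BF: %.3g)",
            bf$model, format_bf(bf$bf10), bf$mc_error),
    "Inclusion Bayes factors (matched models):",
    sprintf("  %s: BF_Incl = %s", incl$effect, incl$label),
    "",
    sprintf("Permutation test (%d permutations): t_crit %.2f / %.2f",
            res$perm$n_perm, res$perm$t_crit_low, res$perm$t_crit_high),
    if (nrow(res$perm$windows) > 0) {
      sprintf("  significant window: %g to %g ms",
              res$perm$windows$start_ms, res$perm$windows$end_ms)
    } else "  no significant windows",
    "",
    sprintf("Block analysis window: %g to %g ms (%s)",
            res$block_window_ms[1], res$block_window_ms[2],
            res$block_window_source),
    sprintf("  %s: F(%.2f, %.2f) = %.2f, GG eps = %.3f, p(GG) = %.3g",
            res$block$anova$effect,
            res$block$anova$df1 * res$block$anova$gg_epsilon,
            res$block$anova$df2 * res$block$anova$gg_epsilon,
            res$block$anova$statistic, res$block$anova$gg_epsilon,
            res$block$anova$p_gg),
    sprintf("  block %d: t(%d) = %.2f, p = %.3g (uncorrected)",
            res$block$t_tests$block, res$block$t_tests$df,
            res$block$t_tests$statistic, res$block$t_tests$p_value)
  )
  unlist(lines)
}

#' @export
print.alpha_pipeline <- function(x, ...) {
  cat(pipeline_report(x), sep = "\n")
  invisible(x)
}
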