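# Config-driven orchestration of the full comparison experiment on a
# synthetic cohort: generate -> segment (ROI recipes and template-guided
# clustering, four bundles) -> shape measures -> paired comparison ->
# report files. Every stage is reproducible from (config, master seed).

#' Default run configuration
#'
#' The configuration mirrors the study design: a 25-subject phantom cohort
#' with all artefact populations enabled, the four default bundle recipes,
#' and the template-guided clustering policy.
#'
#' @param n_subjects Cohort size (default 25).
#' @param master_seed Master seed (default 42); per-subject seeds are
#'   derived as `master_seed + subject_id`.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(n_subjects = 25, master_seed = 42) {
  structure(list(
    version = 1L,
    phantom = list(
      n_subjects = as.integer(n_subjects),
      master_seed = as.integer(master_seed),
      grid_dims = c(180L, 216L, 180L),
      bundles = list(n_streamlines = 500L, radius = 2.5, step = 1,
                     jitter_amp = 1, end_trim = 3),
      artefacts = list(parietal_ending = 100L, u_fiber = 100L,
                       dorsal_loop = 100L, projection_vertical = 100L,
                       commissural = 100L, background = 1000L),
      artefact_radius = 2,
      deformation = list(max_rotation_deg = 4, max_scale_dev = 0.04)
    ),
    recipes = list(ifof_extended = TRUE, insula_exclusion = TRUE),
    clustering = list(n_points = 20L, tau_select = 15, tau_final = 8,
                      k_schedule = c(50L, 100L, 200L, 400L)),
    output = list(dir = NULL, write_bundles = FALSE),
    verbosity = 1L
  ), class = "run_config")
}

#' Read and validate a run configuration
#'
#' YAML keys override the defaults of [default_run_config()]; unknown keys
#' are rejected (silent config drift is the main reproducibility hazard).
#'
#' @param path Path to a YAML config file, or a named list.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) abort(sprintf("config not found: %s", path))
    yaml::read_yaml(path)
  } else if (is.list(path)) {
    path
  } else {
    abort("`path` must be a file path or a list")
  }
  cfg <- merge_config(unclass(default_run_config()), user, "config")
  if (!identical(as.integer(cfg$version), 1L)) {
    abort("unsupported config version (expected 1)")
  }
  if (cfg$phantom$n_subjects < 2L) abort("config: cohort size must be >= 2")
  if (is.null(cfg$phantom$master_seed)) abort("config: master_seed must be set")
  structure(cfg, class = "run_config")
}

merge_config <- function(base, user, where) {
  if (!length(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s) under %s: %s", where,
                  paste(unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], as.list(user[[k]]),
                                paste(where, k, sep = "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

config_cohort <- function(cfg) {
  ph <- cfg$phantom
  bundles <- default_bundle_specs(
    n_streamlines = ph$bundles$n_streamlines, radius = ph$bundles$radius,
    step = ph$bundles$step, jitter_amp = ph$bundles$jitter_amp,
    end_trim = ph$bundles$end_trim)
  artefacts <- default_artefact_specs(
    counts = unlist(ph$artefacts), radius = ph$artefact_radius,
    step = ph$bundles$step, jitter_amp = ph$bundles$jitter_amp,
    end_trim = ph$bundles$end_trim)
  grid <- ref_grid(ph$grid_dims)
  generate_cohort(n_subjects = ph$n_subjects, master_seed = ph$master_seed,
                  bundles = bundles, artefacts = artefacts, grid = grid,
                  max_rotation_deg = ph$deformation$max_rotation_deg,
                  max_scale_dev = ph$deformation$max_scale_dev)
}

segment_subject <- function(tract, spec, cfg) {
  recipes <- default_recipes(tract$grid, deformation = spec$deformation,
                             ifof_extended = cfg$recipes$ifof_extended,
                             insula_exclusion = cfg$recipes$insula_exclusion)
  roi_ids <- apply_recipes(tract, recipes)
  templates <- phantom_templates(tract)
  dcfg <- distance_config(cfg$clustering$n_points)
  policy <- list(tau_select = cfg$clustering$tau_select,
                 tau_final = cfg$clustering$tau_final,
                 k_schedule = cfg$clustering$k_schedule)
  cl_ids <- lapply(seq_along(templates), function(j) {
    auto_segment_by_template(tract, templates[[j]], policy, dcfg,
                             seed = spec$seed + 31L * j)
  })
  names(cl_ids) <- names(templates)
  list(roi = roi_ids, streamline = cl_ids)
}

subject_measures <- function(tract, segs, subject_id) {
  rows <- list()
  for (method in names(segs)) {
    for (bundle in names(segs[[method]])) {
      ids <- segs[[method]][[bundle]]
      if (!length(ids)) {
        abort(sprintf("empty %s segmentation of %s for subject %d",
                      method, bundle, subject_id))
      }
      rows[[length(rows) + 1L]] <- bundle_shape_measures(
        tract, ids, subject_id = subject_id, bundle = bundle, method = method)
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full comparison experiment
#'
#' Generates the phantom cohort, segments all four bundles per subject with
#' both engines, computes shape measures, and runs the cohort comparison.
#' When `out_dir` is set, writes `shape_measures.csv`, `table1.csv`
#' (descriptives), `table2.csv` (t / p / Cohen's d), `report.json`,
#' `manifest.json`, a `run.log`, and optionally per-subject bundle TRK
#' files.
#'
#' @param cfg A `run_config` (from [default_run_config()] or
#'   [read_run_config()]).
#' @param out_dir Output directory (created if needed); `NULL` for no file
#'   output.
#' @param quiet Suppress per-subject progress messages.
#' @return A list with `comparison` (a [compare_cohort()] result),
#'   `measures` (the long shape-measure tibble), and `manifest`.
#' @export
run_experiment <- function(cfg = default_run_config(), out_dir = NULL,
                           quiet = cfg$verbosity < 1) {
  if (!inherits(cfg, "run_config")) cfg <- read_run_config(cfg)
  out_dir <- out_dir %||% cfg$output$dir
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    if (!quiet) message(msg)
  }
  say("generating cohort: %d subjects, master seed %d",
      cfg$phantom$n_subjects, cfg$phantom$master_seed)
  cohort <- config_cohort(cfg)
  measures <- vector("list", length(cohort))
  outputs <- character()
  for (i in seq_along(cohort)) {
    subj <- cohort[[i]]
    stage <- "segment"
    res <- tryCatch({
      segs <- segment_subject(subj$tract, subj$spec, cfg)
      stage <- "shape"
      subject_measures(subj$tract, segs, subj$spec$subject_id)
    }, error = function(e) {
      abort(sprintf("stage '%s' failed for subject %d: %s",
                    stage, subj$spec$subject_id, conditionMessage(e)))
    })
    measures[[i]] <- res
    say("subject %d/%d: ROI %s | streamline %s", i, length(cohort),
        paste(vapply(segs$roi, length, integer(1)), collapse = "/"),
        paste(vapply(segs$streamline, length, integer(1)), collapse = "/"))
    if (!is.null(out_dir) && isTRUE(cfg$output$write_bundles)) {
      sdir <- file.path(out_dir, sprintf("subject_%02d", i))
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      for (method in names(segs)) {
        for (bundle in names(segs[[method]])) {
          f <- file.path(sdir, sprintf("%s_%s.trk", bundle, method))
          write_tractogram(subset_tractogram(subj$tract, segs[[method]][[bundle]]), f)
          outputs <- c(outputs, f)
        }
      }
    }
  }
  measures <- dplyr::bind_rows(measures)
  comparison <- compare_cohort(measures)
  say("comparison: max p = %.3g, min |d| = %.2f",
      max(comparison$tests$p_value), min(abs(comparison$tests$cohen_d)))
  manifest <- list(
    config_hash = rlang::hash(unclass(cfg)),
    master_seed = cfg$phantom$master_seed,
    n_subjects = cfg$phantom$n_subjects,
    subject_seeds = vapply(cohort, function(s) s$spec$seed, integer(1)),
    outputs = outputs,
    status = "ok"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(measures, file.path(out_dir, "shape_measures.csv"),
              row.names = FALSE)
    write.csv(comparison$descriptives, file.path(out_dir, "table1.csv"),
              row.names = FALSE)
    write.csv(comparison$tests, file.path(out_dir, "table2.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(descriptives = comparison$descriptives, tests = comparison$tests,
           alpha = comparison$alpha, metric = comparison$metric),
      file.path(out_dir, "report.json"), dataframe = "rows", digits = NA,
      auto_unbox = TRUE)
    manifest$outputs <- c(manifest$outputs,
                          file.path(out_dir, c("shape_measures.csv",
                                               "table1.csv", "table2.csv",
                                               "report.json")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  list(comparison = comparison, measures = measures, manifest = manifest)
}

cli_usage <- function() {
  paste(
    "usage: bundlescope <subcommand> [options]",
    "",
    "subcommands:",
    "  generate        generate a phantom cohort (TRK + labels + grid NIfTI)",
    "  segment-roi     ROI-recipe segmentation of one tractogram",
    "  segment-cluster template-guided clustering segmentation",
    "  shape           shape measures of a bundle TRK",
    "  compare         cohort comparison from a shape-measures CSV",
    "  run-all         full experiment (generate -> segment -> shape -> compare)",
    "",
    "common options: --config <yaml>  --seed <int>  --out <path>",
    sep = "\n")
}

cli_opts <- function(args) {
  out <- list(positional = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i == length(args) || grepl("^--", args[i + 1L])) {
        out[[key]] <- TRUE
        i <- i + 1L
      } else {
        out[[key]] <- args[i + 1L]
        i <- i + 2L
      }
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

cli_load_config <- function(opts) {
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else default_run_config()
  if (!is.null(opts$seed)) cfg$phantom$master_seed <- as.integer(opts$seed)
  cfg
}

#' Command-line dispatcher
#'
#' Thin entry point over the package functions; see `inst/cli/bundlescope`
#' for the executable wrapper. Each subcommand is runnable standalone on
#' files produced by earlier stages.
#'
#' @param args Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_dispatch <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) {
      message(cli_usage())
      return(invisible(1L))
    }
    sub <- args[1]
    opts <- cli_opts(args[-1])
    switch(
      sub,
      "generate" = cli_generate(opts),
      "segment-roi" = cli_segment_roi(opts),
      "segment-cluster" = cli_segment_cluster(opts),
      "shape" = cli_shape(opts),
      "compare" = cli_compare(opts),
      "run-all" = cli_run_all(opts),
      {
        message("unknown subcommand: ", sub, "\n\n", cli_usage())
        1L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}

cli_need <- function(opts, key) {
  v <- opts[[key]]
  if (is.null(v) || isTRUE(v)) abort(sprintf("missing required option --%s", key))
  v
}

cli_generate <- function(opts) {
  cfg <- cli_load_config(opts)
  out <- cli_need(opts, "out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cohort <- config_cohort(cfg)
  grid <- cohort[[1]]$tract$grid
  write_mask(binary_mask(grid, array(FALSE, grid$dims)),
             file.path(out, "grid.nii.gz"))
  for (i in seq_along(cohort)) {
    base <- file.path(out, sprintf("subject_%02d", i))
    write_tractogram(cohort[[i]]$tract, paste0(base, ".trk"))
    sp <- cohort[[i]]$spec
    # the subject's deformation travels with the tractogram so standalone
    # stages place ROIs on this subject's anatomy, as run-all does
    yaml::write_yaml(list(
      subject_id = sp$subject_id, seed = sp$seed,
      deformation = list(rotation_deg = sp$deformation$rotation_deg,
                         axis = sp$deformation$axis,
                         scale = sp$deformation$scale,
                         center = sp$deformation$center)),
      paste0(base, ".meta.yaml"))
    templates <- phantom_templates(cohort[[i]]$tract)
    for (b in names(templates)) {
      write_tractogram(tractogram(list(templates[[b]]), grid),
                       paste0(base, "_template_", b, ".trk"))
    }
  }
  message(sprintf("wrote %d subjects under %s", length(cohort), out))
  0L
}

read_subject_meta <- function(tract_path) {
  meta_path <- paste0(sub("\\.(trk|tck)$", "", tract_path), ".meta.yaml")
  if (!file.exists(meta_path)) return(NULL)
  m <- yaml::read_yaml(meta_path)
  d <- m$deformation
  list(subject_id = m$subject_id, seed = m$seed,
       deformation = deformation(d$rotation_deg, unlist(d$axis),
                                 unlist(d$scale), unlist(d$center)))
}

cli_segment_roi <- function(opts) {
  cfg <- cli_load_config(opts)
  tract_path <- cli_need(opts, "tract")
  tract <- read_tractogram(tract_path)
  meta <- read_subject_meta(tract_path)
  recipes <- default_recipes(tract$grid, deformation = meta$deformation,
                             ifof_extended = cfg$recipes$ifof_extended,
                             insula_exclusion = cfg$recipes$insula_exclusion)
  if (!is.null(opts$recipe) && !isTRUE(opts$recipe)) {
    if (!opts$recipe %in% names(recipes)) {
      abort(sprintf("unknown recipe '%s'", opts$recipe))
    }
    recipes <- recipes[opts$recipe]
  }
  ids <- apply_recipes(tract, recipes)
  out <- cli_need(opts, "out")
  sel <- dplyr::bind_rows(lapply(names(ids), function(nm) {
    tibble(bundle = nm, id = ids[[nm]])
  }))
  write.csv(sel, out, row.names = FALSE)
  message(sprintf("wrote %d selections to %s", nrow(sel), out))
  0L
}

cli_segment_cluster <- function(opts) {
  cfg <- cli_load_config(opts)
  tract <- read_tractogram(cli_need(opts, "tract"))
  template <- read_tractogram(cli_need(opts, "template"))
  policy <- list(
    tau_select = as.numeric(opts[["tau-select"]] %||% cfg$clustering$tau_select),
    tau_final = as.numeric(opts[["tau-final"]] %||% cfg$clustering$tau_final),
    k_schedule = if (!is.null(opts[["k-schedule"]])) {
      as.integer(strsplit(opts[["k-schedule"]], ",")[[1]])
    } else {
      cfg$clustering$k_schedule
    })
  ids <- auto_segment_by_template(
    tract, template$streamlines, policy,
    distance_config(cfg$clustering$n_points),
    seed = as.integer(opts$seed %||% cfg$phantom$master_seed))
  out <- cli_need(opts, "out")
  write.csv(tibble(id = ids), out, row.names = FALSE)
  message(sprintf("selected %d streamlines -> %s", length(ids), out))
  0L
}

cli_shape <- function(opts) {
  tract <- read_tractogram(cli_need(opts, "bundle"))
  m <- bundle_shape_measures(tract, seq_len(n_streamlines(tract)))
  out <- opts$out
  if (!is.null(out) && !isTRUE(out)) {
    if (grepl("\\.json$", out)) {
      jsonlite::write_json(as.list(m), out, auto_unbox = TRUE, digits = NA)
    } else {
      write.csv(m, out, row.names = FALSE)
    }
    message("wrote ", out)
  } else {
    print(m)
  }
  0L
}

cli_compare <- function(opts) {
  measures <- read.csv(cli_need(opts, "measures"), stringsAsFactors = FALSE)
  out <- cli_need(opts, "out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  comparison <- compare_cohort(measures)
  write.csv(comparison$descriptives, file.path(out, "table1.csv"),
            row.names = FALSE)
  write.csv(comparison$tests, file.path(out, "table2.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(descriptives = comparison$descriptives, tests = comparison$tests,
         alpha = comparison$alpha, metric = comparison$metric),
    file.path(out, "report.json"), dataframe = "rows", digits = NA,
    auto_unbox = TRUE)
  message("wrote comparison tables under ", out)
  0L
}

cli_run_all <- function(opts) {
  cfg <- cli_load_config(opts)
  out <- cli_need(opts, "out")
  run_experiment(cfg, out_dir = out)
  message("experiment complete; outputs under ", out)
  0L
}
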