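#' Run configuration for the end-to-end pipeline
#'
#' @param out output directory; created if missing.
#' @param seed master random seed; seeds the synthetic cohort and the
#'   train/test split.
#' @param stages subset of `c("simulate", "ingest", "score", "evaluate",
#'   "maps")`, or `"all"`.
#' @param n_per_class synthetic subjects per class.
#' @param train_fraction training fraction of the evaluation split.
#' @param write_plots whether the simulate stage writes per-subject PNG
#'   plots (required by a subsequent ingest stage).
#' @param synthetic optional list of overrides passed to
#'   [synthetic_config()].
#' @return object of class `run_config`.
#' @export
run_config <- function(out, seed = 1L, stages = "all", n_per_class = 50,
                       train_fraction = 0.7, write_plots = TRUE,
                       synthetic = list()) {
  all_stages <- c("simulate", "ingest", "score", "evaluate", "maps")
  if (identical(stages, "all")) stages <- all_stages
  if (!all(stages %in% all_stages))
    stop("unknown stage(s): ",
         paste(setdiff(stages, all_stages), collapse = ", "))
  structure(list(out = out, seed = as.integer(seed), stages = stages,
                 n_per_class = n_per_class,
                 train_fraction = train_fraction,
                 write_plots = isTRUE(write_plots), synthetic = synthetic),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with the [run_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

#' Execute the processing pipeline
#'
#' Runs the requested stages in order -- simulate (synthetic cohort with
#' ground truth), ingest (measure every plot image), score (FIS + HADS),
#' evaluate (classifiers, ROC/AUC, DeLong, Youden, Spearman) and maps
#' (class-wise average position maps) -- and writes a manifest
#' (`manifest.json`: config, seed, package version, every artifact path,
#' status) alongside the outputs. Reruns with an identical config reproduce
#' integer artifacts byte-identically.
#'
#' Subject identifiers in all outputs are serial numbers, never external
#' IDs.
#'
#' @param config a [run_config()] or path to a YAML file of one.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = config$stages,
                   version = as.character(utils::packageVersion("fixstab")),
                   n_per_class = config$n_per_class,
                   files = character(0), status = "running")
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  note <- function(...) {
    f <- file.path(config$out, c(...))
    manifest$files <<- c(manifest$files, f)
    f
  }
  on.exit({ manifest$status <- "failed"; write_manifest() })

  scfg <- do.call(synthetic_config,
                  utils::modifyList(list(n_per_class = config$n_per_class,
                                         seed = config$seed),
                                    config$synthetic))
  cohort <- NULL

  if ("simulate" %in% config$stages) {
    cohort <- sample_cohort(scfg)
    meta <- cohort_table(cohort)
    utils::write.csv(meta, note("metadata.csv"), row.names = FALSE)
    gt <- do.call(rbind, lapply(cohort, function(g)
      cbind(subject_id = g$subject_id, g$squares)))
    utils::write.csv(gt, note("ground_truth_squares.csv"), row.names = FALSE)
    ap <- do.call(rbind, lapply(cohort, function(g)
      data.frame(subject_id = g$subject_id, sa = g$params$sa,
                 sp = g$params$sp, acd = g$params$acd)))
    utils::write.csv(ap, note("analytic_parameters.csv"), row.names = FALSE)
    yaml::write_yaml(list(seed = scfg$seed, n_per_class = scfg$n_per_class,
                          mark_side_px = scfg$mark_side_px,
                          margin_px = scfg$margin_px,
                          px_per_mm = scfg$grid$px_per_mm,
                          dispersion_px = as.numeric(scfg$dispersion_px)),
                     note("config.yaml"))
    if (config$write_plots) {
      pdir <- file.path(config$out, "plots")
      dir.create(pdir, showWarnings = FALSE)
      sidecar <- data.frame(
        image = sprintf("subj_%04d.png", meta$subject_id),
        subject_id = meta$subject_id, eye = meta$eye,
        center_x = scfg$grid$center_px[1], center_y = scfg$grid$center_px[2],
        px_per_mm = scfg$grid$px_per_mm)
      utils::write.csv(sidecar, note("plots/sidecar.csv"), row.names = FALSE)
      for (g in cohort) {
        render_plot(g, path = note(file.path(
          "plots", sprintf("subj_%04d.png", g$subject_id))))
      }
    }
  }

  params <- NULL
  if ("ingest" %in% config$stages) {
    pdir <- file.path(config$out, "plots")
    if (!dir.exists(pdir)) stop("no plots directory to ingest: ", pdir)
    params <- ingest_directory(pdir, file.path(pdir, "sidecar.csv"))
    utils::write.csv(params, note("measured_parameters.csv"),
                     row.names = FALSE)
  }

  if ("score" %in% config$stages) {
    meta <- utils::read.csv(file.path(config$out, "metadata.csv"))
    if (is.null(params)) {
      src <- file.path(config$out, "measured_parameters.csv")
      params <- if (file.exists(src)) utils::read.csv(src) else
        utils::read.csv(file.path(config$out, "analytic_parameters.csv"))
    }
    scored <- score_subjects(merge(
      params, meta[setdiff(names(meta), c("sa", "sp", "acd"))],
      by = "subject_id"))
    utils::write.csv(scored, note("scores.csv"), row.names = FALSE)
  }

  if ("evaluate" %in% config$stages) {
    scored <- utils::read.csv(file.path(config$out, "scores.csv"))
    scored$hads_class <- factor(scored$hads_class,
                                levels = anxiety_levels())
    rep <- evaluate_all(scored, split_spec(config$train_fraction,
                                           config$seed))
    utils::write.csv(rep$delong, note("delong.csv"), row.names = FALSE)
    ovo_tbl <- do.call(rbind, lapply(names(rep$ovo), function(f)
      cbind(feature = toupper(f), rep$ovo[[f]]$pairs)))
    utils::write.csv(ovo_tbl, note("one_vs_one_auc.csv"), row.names = FALSE)
    sp <- spearman_matrix(scored[c("sa", "sp", "acd", "fis_raw",
                                   "hads_sub_score", "vas",
                                   "n_breaks", "breaks_duration_s")])
    utils::write.csv(sp$r, note("spearman_r.csv"))
    utils::write.csv(sp$r_filtered, note("spearman_r_filtered.csv"))
    jsonlite::write_json(
      list(macro_auc = as.list(rep$macro_auc),
           cutoffs = lapply(rep$cutoffs, function(co)
             co[c("threshold", "youden_j", "sensitivity", "specificity")]),
           spearman_fis_hads = unname(sp$r["fis_raw", "hads_sub_score"])),
      note("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if ("maps" %in% config$stages) {
    if (is.null(cohort)) cohort <- sample_cohort(scfg)
    offs <- list()
    for (cls in anxiety_levels()) for (side in c("right", "left")) {
      sel <- Filter(function(g)
        as.character(g$class) == cls && g$eye == side, cohort)
      if (!length(sel)) next
      m <- average_class_map(lapply(sel, rasterize_squares),
                             class_label = cls, eye_side = side)
      write_map_png(m, note(sprintf("map_%s_%s.png", cls, side)))
      offs[[length(offs) + 1]] <- data.frame(
        class = cls, eye = side, n = m$n_subjects,
        support_px = map_support_area(m),
        centroid_dx = m$centroid_offset["x"],
        centroid_dy = m$centroid_offset["y"])
    }
    utils::write.csv(do.call(rbind, offs), note("map_centroids.csv"),
                     row.names = FALSE)
  }

  on.exit()
  manifest$status <- "ok"
  write_manifest()
  invisible(manifest)
}

#' Measure every plot image in a directory
#'
#' Reads a sidecar CSV (columns `image`, `subject_id`, `center_x`,
#' `center_y`, `px_per_mm`, optionally `eye`) and runs the measurement
#' chain on each referenced image.
#'
#' @param dir directory of PNG/TIFF plot images.
#' @param sidecar path to the sidecar CSV.
#' @param color_spec a [mark_color_spec()].
#' @return data.frame: `subject_id`, `sa`, `sp`, `acd`, `n_clusters`,
#'   `empty`.
#' @export
ingest_directory <- function(dir, sidecar, color_spec = mark_color_spec()) {
  sc <- utils::read.csv(sidecar)
  need <- c("image", "subject_id", "center_x", "center_y", "px_per_mm")
  if (!all(need %in% names(sc)))
    stop("sidecar must contain columns: ", paste(need, collapse = ", "))
  rows <- lapply(seq_len(nrow(sc)), function(i) {
    grid <- tracking_grid(c(sc$center_x[i], sc$center_y[i]),
                          sc$px_per_mm[i])
    mask <- suppressWarnings(detect_marks(
      file.path(dir, sc$image[i]), grid,
      color_spec, source_id = as.character(sc$subject_id[i])))
    cs <- extract_clusters(mask)
    p <- compute_parameters(cs)
    data.frame(subject_id = sc$subject_id[i], sa = p$sa, sp = p$sp,
               acd = p$acd, n_clusters = nrow(cs$clusters),
               empty = p$empty)
  })
  do.call(rbind, rows)
}
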