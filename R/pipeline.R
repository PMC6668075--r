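#' Build a pipeline configuration
#'
#' Assembles (and defaults) the configuration consumed by [run_pipeline()].
#' Inputs are either TIFF slice-stack paths (with a voxel size) or phantom
#' specifications (`list(preset =, seed =)`), one entry per grain.
#'
#' @param inputs list of grain inputs: each a `list(path =, voxel_size_mm =,
#'   id =, stage =)` or `list(preset =, seed =, id =, stage =)`.
#' @param out_dir output directory (created if missing).
#' @param segmentation a [segmentation_params()] bundle.
#' @param se_radius structuring-element radius for tissue separation; `NULL`
#'   uses the shell-thickness heuristic.
#' @param downsample 1 or 2 (tissue-opening acceleration).
#' @param target_dims,n_slices alignment grid and estimation window.
#' @param crease list of [crease_depth()] options (`chord_lengths`,
#'   `threshold`, `depth_mode`) plus `k` (normalized profile length).
#' @param write_volumes write mask/label stacks (TIFF) per grain; the CSV and
#'   JSON outputs are always written.
#' @param seed base seed recorded in the report.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs, out_dir,
                            segmentation = segmentation_params(),
                            se_radius = NULL, downsample = 2L,
                            target_dims = NULL, n_slices = 200L,
                            crease = list(chord_lengths = c(10L, 20L, 30L),
                                          threshold = 0.2,
                                          depth_mode = "chord", k = 100L),
                            write_volumes = TRUE, seed = 1L) {
  structure(list(inputs = inputs, out_dir = out_dir,
                 segmentation = segmentation, se_radius = se_radius,
                 downsample = downsample, target_dims = target_dims,
                 n_slices = n_slices, crease = crease,
                 write_volumes = isTRUE(write_volumes), seed = seed),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param cfg a [pipeline_config()].
#' @return Character vector of problems, each naming the offending field;
#'   empty when the configuration is runnable.
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  add <- function(p) problems <<- c(problems, p)
  if (!is.list(cfg$inputs) || length(cfg$inputs) == 0) {
    add("inputs: need at least one grain input")
  } else {
    for (i in seq_along(cfg$inputs)) {
      inp <- cfg$inputs[[i]]
      if (!is.null(inp$path)) {
        if (!file.exists(inp$path)) {
          add(sprintf("inputs[%d]$path: does not exist (%s)", i, inp$path))
        }
        vs <- inp$voxel_size_mm
        if (is.null(vs) || !is.numeric(vs) || vs <= 0 || !is.finite(vs)) {
          add(sprintf("inputs[%d]$voxel_size_mm: must be a positive number", i))
        }
      } else if (!is.null(inp$preset)) {
        if (!inp$preset %in% c("early", "mid", "late")) {
          add(sprintf("inputs[%d]$preset: unknown preset '%s'", i, inp$preset))
        }
      } else {
        add(sprintf("inputs[%d]: needs either $path or $preset", i))
      }
    }
  }
  if (is.null(cfg$out_dir) || !is.character(cfg$out_dir) || !nzchar(cfg$out_dir)) {
    add("out_dir: must be a non-empty path")
  }
  if (!cfg$downsample %in% c(1L, 2L)) add("downsample: must be 1 or 2")
  if (!is.null(cfg$se_radius) && (!is.numeric(cfg$se_radius) || cfg$se_radius < 1)) {
    add("se_radius: must be >= 1 or NULL")
  }
  if (!is.null(cfg$target_dims) &&
      (length(cfg$target_dims) != 3 || any(cfg$target_dims < 8))) {
    add("target_dims: must be three values >= 8")
  }
  problems
}

#' Run the full grain-analysis pipeline
#'
#' For each configured grain: segmentation, tissue partition, void detection,
#' alignment, morphometry and crease profiling, with per-grain isolation (a
#' failure in one grain never aborts the batch) and per-stage status codes.
#' Outputs per grain: mask/label/void/aligned stacks (optional), `pose.json`,
#' a crease CSV; plus batch-level `morphometry.csv`, `summary.csv`,
#' `mean_profile.csv` and a machine-readable `report.json` echoing every
#' parameter.
#'
#' @param cfg a [pipeline_config()]; configuration problems fail fast.
#' @return Invisibly, the run report (also written as JSON).
#' @export
run_pipeline <- function(cfg) {
  problems <- validate_config(cfg)
  gt_assert(length(problems) == 0, "argument",
            paste("invalid configuration:", paste(problems, collapse = "; ")))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)

  grains <- list()
  morpho <- list()
  profiles <- list()

  for (i in seq_along(cfg$inputs)) {
    inp <- cfg$inputs[[i]]
    id <- if (!is.null(inp$id)) inp$id else sprintf("grain-%02d", i)
    stage <- if (!is.null(inp$stage)) inp$stage else NA_real_
    gdir <- file.path(cfg$out_dir, id)
    if (!dir.exists(gdir)) dir.create(gdir, recursive = TRUE)
    entry <- list(id = id, stage = stage, stages = list())
    mark <- function(stage_name, status, detail = NULL) {
      entry$stages[[stage_name]] <<- list(status = status, detail = detail)
    }

    res <- tryCatch({
      # ---- input
      if (!is.null(inp$path)) {
        v <- read_volume(inp$path, inp$voxel_size_mm, id = id, stage = stage)
      } else {
        pseed <- if (!is.null(inp$seed)) inp$seed else cfg$seed
        ph <- generate_phantom(phantom_preset(inp$preset, seed = pseed))
        v <- ph$volume
      }
      mark("input", "ok", sprintf("dims %s", paste(v$dims, collapse = "x")))

      # ---- grain segmentation
      g <- segment_grain(v, cfg$segmentation)
      seg_log <- attr(g, "log")
      mark("segmentation", "ok",
           sprintf("threshold %.1f, %d voxels", seg_log$threshold, sum(g$data)))

      # ---- voids
      voids <- detect_voids(g)
      mark("voids", "ok", sprintf("%d voxels", sum(voids$data)))

      # ---- tissue partition (documented failure regime: thick shell /
      # missing voids; the opening either empties or leaks into the shell)
      labels <- NULL
      tis <- tryCatch(
        segment_tissues(g, se_radius = cfg$se_radius, downsample = cfg$downsample),
        graintomo_se_too_large = function(e) e,
        graintomo_argument = function(e) e)
      if (inherits(tis, "condition")) {
        mark("tissues", "warning", conditionMessage(tis))
      } else {
        labels <- tis
        frac_inner <- sum(labels$data == 2L) / sum(labels$data > 0L)
        support <- tissue_boundary_support(labels, voids)
        if (frac_inner < 0.10) {
          mark("tissues", "warning",
               sprintf("inner compartment only %.1f%% of grain (thick shell?)",
                       100 * frac_inner))
        } else if (is.na(support) || support < 0.7) {
          mark("tissues", "warning",
               sprintf(paste0("only %.0f%% of the outer/inner boundary is",
                              " supported by voids (thick shell / missing",
                              " voids?)"), 100 * support))
        } else mark("tissues", "ok", sprintf("se radius %g", labels$se_radius_used))
      }

      # ---- alignment
      td <- cfg$target_dims
      if (is.null(td)) td <- dim(g$data) + c(0L, 0L, 16L)
      aligned <- align_grain(g, n_slices = cfg$n_slices, target_dims = td)
      mark("alignment", "ok",
           sprintf("theta_z %.2f, theta_y %.2f, flip %s",
                   aligned$pose$theta_z, aligned$pose$theta_y,
                   aligned$pose$flip_y))

      # ---- morphometry
      if (!is.null(labels)) {
        row <- grain_morphometry(aligned, labels, voids, id = id, stage = stage,
                                 n_slices = cfg$n_slices)
      } else {
        wt <- width_thickness(aligned, cfg$n_slices)
        row <- data.frame(id = id, stage = stage,
                          length_mm = grain_length(aligned),
                          width_mm = unname(wt["width"]),
                          thickness_mm = unname(wt["thickness"]),
                          vol_grain_mm3 = sum(g$data) * g$voxel_size^3,
                          vol_inner_mm3 = NA_real_, vol_outer_mm3 = NA_real_,
                          vol_void_mm3 = sum(voids$data) * g$voxel_size^3,
                          voxel_size_mm = g$voxel_size)
      }
      morpho[[id]] <- row
      mark("morphometry", "ok")

      # ---- crease profile (documented failure regime: touching lobes)
      prof <- tryCatch(
        crease_profile(aligned, k = cfg$crease$k,
                       chord_lengths = cfg$crease$chord_lengths,
                       threshold = cfg$crease$threshold,
                       depth_mode = cfg$crease$depth_mode, id = id),
        graintomo_profile_failed = function(e) e)
      if (inherits(prof, "condition")) {
        mark("crease", "failed", conditionMessage(prof))
      } else {
        frac_invalid <- 1 - mean(prof$measurements$valid)
        if (frac_invalid > 0.25) {
          mark("crease", "warning",
               sprintf("%.0f%% of slices invalid (deep narrow crease?)",
                       100 * frac_invalid))
        } else mark("crease", "ok")
        profiles[[id]] <- prof
        write.csv(prof$measurements, file.path(gdir, "crease.csv"),
                  row.names = FALSE)
      }

      # ---- outputs
      jsonlite::write_json(aligned$pose, file.path(gdir, "pose.json"),
                           auto_unbox = TRUE, digits = NA)
      if (cfg$write_volumes) {
        write_volume(g, file.path(gdir, "grain_mask"))
        if (!is.null(labels)) write_volume(labels, file.path(gdir, "labels"))
        write_volume(voids, file.path(gdir, "voids"))
        write_volume(aligned$mask, file.path(gdir, "aligned"))
      }
      entry
    }, error = function(e) {
      entry$stages[["error"]] <- list(status = "failed",
                                      detail = conditionMessage(e))
      entry
    })
    grains[[id]] <- res
  }

  morpho_df <- do.call(rbind, morpho)
  if (!is.null(morpho_df)) {
    write.csv(morpho_df, file.path(cfg$out_dir, "morphometry.csv"),
              row.names = FALSE)
    if (nrow(morpho_df) >= 1 && any(!is.na(morpho_df$stage))) {
      write.csv(summarize_replicates(morpho_df),
                file.path(cfg$out_dir, "summary.csv"), row.names = FALSE)
    }
  }
  if (length(profiles) > 0) {
    write.csv(mean_profile(unname(profiles)),
              file.path(cfg$out_dir, "mean_profile.csv"), row.names = FALSE)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("graintomo")),
    seed = cfg$seed,
    parameters = list(segmentation = unclass(cfg$segmentation),
                      se_radius = cfg$se_radius, downsample = cfg$downsample,
                      target_dims = cfg$target_dims, n_slices = cfg$n_slices,
                      crease = cfg$crease),
    grains = grains)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

#' Read a pipeline configuration from YAML
#'
#' Thin adapter from a YAML document to [pipeline_config()]; every field has
#' the same name and default as the function arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  gt_assert(file.exists(path), "io", sprintf("config not found: %s", path))
  y <- yaml::read_yaml(path)
  gt_assert(!is.null(y$inputs), "argument", "config must list inputs")
  seg <- do.call(segmentation_params, as.list(y$segmentation %||% list()))
  crease_defaults <- list(chord_lengths = c(10L, 20L, 30L), threshold = 0.2,
                          depth_mode = "chord", k = 100L)
  crease <- utils::modifyList(crease_defaults, as.list(y$crease %||% list()))
  pipeline_config(inputs = y$inputs,
                  out_dir = y$out_dir %||% "graintomo-out",
                  segmentation = seg,
                  se_radius = y$se_radius,
                  downsample = as.integer(y$downsample %||% 2L),
                  target_dims = y$target_dims,
                  n_slices = as.integer(y$n_slices %||% 200L),
                  crease = crease,
                  write_volumes = y$write_volumes %||% TRUE,
                  seed = as.integer(y$seed %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
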