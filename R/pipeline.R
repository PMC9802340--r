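# convert a config (possibly holding functions) into a JSON-serializable list
config_serializable <- function(x) {
  if (is.function(x)) return(paste(deparse(x), collapse = "\n"))
  if (is.list(x)) {
    out <- lapply(x, config_serializable)
    attributes(out) <- attributes(x)[intersect(names(attributes(x)), "names")]
    return(out)
  }
  x
}

#' Pipeline configuration
#'
#' Bundles the inputs and every tunable of the full analysis chain
#' (synthesis, boundary tracking, PIV, traction reconstruction, figures)
#' into one validated object. Every parameter that affects a number in an
#' output file lives here, and the fully resolved configuration is
#' serialized next to the outputs.
#'
#' @param out_dir output directory (created if missing).
#' @param colony a [colony_scenario()] or NULL to skip the colony arm.
#' @param beads a [bead_scenario()] (with `model`) or NULL to skip the
#'   TFM arm.
#' @param model a [displacement_model()] for the bead arm.
#' @param substrate a [substrate_spec()]; required when `tfm$enabled`.
#' @param n_bead_frames frames in the synthetic bead stack.
#' @param track stage parameters: `dt_min`, `n_windows`, `n_rays`.
#' @param piv stage parameters: `mode`, `window_size`, `overlap`,
#'   `drift_region` (um rectangle or NULL).
#' @param tfm stage parameters: `enabled`, `reg`, `pad`.
#' @param figures logical: render figure files.
#' @param seed integer master seed, overriding scenario seeds so one number
#'   reproduces the whole run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            colony = NULL, beads = NULL, model = NULL,
                            substrate = NULL, n_bead_frames = 6,
                            track = list(), piv = list(), tfm = list(),
                            figures = TRUE, seed = 1L) {
  track <- utils::modifyList(list(dt_min = 20, n_windows = 4, n_rays = 50),
                             track)
  piv <- utils::modifyList(list(mode = "first_frame", window_size = 32,
                                overlap = 0.5, drift_region = NULL), piv)
  tfm <- utils::modifyList(list(enabled = TRUE, reg = "lcurve", pad = 1), tfm)
  if (isTRUE(tfm$enabled) && !is.null(beads) &&
      !inherits(substrate, "substrate_spec"))
    stopf("validation: `substrate` (with G') is required when tfm is enabled",
          class = "biofilmtfm_config_error")
  if (!is.null(beads) && is.null(model))
    stopf("validation: bead synthesis needs a `model`",
          class = "biofilmtfm_config_error")
  cfg <- list(out_dir = out_dir, colony = colony, beads = beads,
              model = model, substrate = substrate,
              n_bead_frames = as.integer(n_bead_frames),
              track = track, piv = piv, tfm = tfm,
              figures = isTRUE(figures), seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Build a pipeline configuration from a YAML file
#'
#' Reads a YAML document whose top-level sections mirror the
#' [pipeline_config()] arguments (`colony`, `beads`, `model`, `substrate`,
#' `track`, `piv`, `tfm`, `out_dir`, `seed`, `figures`, `n_bead_frames`);
#' scenario sections are passed to their constructors, so every scenario
#' field is available from the file. Flags already parsed by a caller can
#' be layered on top via `overrides`.
#'
#' @param path YAML file path.
#' @param overrides named list merged over the file's values.
#' @return A validated [pipeline_config()].
#' @export
config_from_yaml <- function(path, overrides = list()) {
  y <- utils::modifyList(yaml::read_yaml(path), overrides)
  build <- function(section, ctor) {
    if (is.null(y[[section]])) return(NULL)
    args <- y[[section]]
    if (section == "model" && !is.null(args$hotspots))
      args$hotspots <- dplyr::bind_rows(lapply(args$hotspots, as_tibble))
    do.call(ctor, args)
  }
  pipeline_config(
    out_dir = y$out_dir %||% "biofilmtfm-out",
    colony = build("colony", colony_scenario),
    beads = build("beads", bead_scenario),
    model = build("model", displacement_model),
    substrate = build("substrate", substrate_spec),
    n_bead_frames = y$n_bead_frames %||% 6,
    track = y$track %||% list(),
    piv = y$piv %||% list(),
    tfm = y$tfm %||% list(),
    figures = y$figures %||% TRUE,
    seed = y$seed %||% 1L)
}

write_csv_det <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes synthesis (when scenarios are configured), boundary tracking,
#' PIV with optional drift correction, traction reconstruction with strain
#' and stress summaries, and figure rendering; writes all CSV/TIFF/JSON
#' outputs plus a run manifest with per-file checksums. Identical
#' configuration and seed reproduce identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `manifest` (artifact version, config
#'   hash, file checksums, warnings) and the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  warnings <- character()
  results <- list()
  note <- function(p) paths[length(paths) + 1L] <<- p

  withCallingHandlers({
    # --- synth ---------------------------------------------------------
    colony_stack <- NULL; bead_stack <- NULL; bead_truth <- NULL
    if (!is.null(config$colony)) {
      sc <- config$colony; sc$seed <- config$seed
      gen <- generate_colony_stack(sc)
      colony_stack <- gen$stack
      note(write_stack(colony_stack, file.path(config$out_dir, "colony.tif")))
      note(write_csv_det(gen$truth$boundary,
                         file.path(config$out_dir, "colony_truth.csv")))
      results$colony_truth <- gen$truth$boundary
    }
    if (!is.null(config$beads)) {
      bs <- config$beads; bs$seed <- config$seed + 1L
      gen <- generate_bead_stack(bs, config$model, config$n_bead_frames)
      bead_stack <- gen$stack; bead_truth <- gen$truth
      note(write_stack(bead_stack, file.path(config$out_dir, "beads.tif")))
      note(write_csv_det(gen$truth$grid,
                         file.path(config$out_dir, "beads_truth.csv")))
    }

    # --- track ---------------------------------------------------------
    if (!is.null(colony_stack)) {
      bnds <- list(); arcs <- list(); prior <- NULL
      for (t in seq_len(n_frames(colony_stack))) {
        b <- detect_boundary(colony_stack$frames[[t]],
                             colony_stack$pixel_size, prior = prior)
        prior <- b
        a <- fit_arc(b)
        bnds[[t]] <- dplyr::mutate(
          tibble(point = seq_len(nrow(b)), x_px = b$x_px, y_px = b$y_px),
          frame = t - 1L, .before = 1)
        arcs[[t]] <- tibble(frame = t - 1L,
                            center_x_px = a$center[1],
                            center_y_px = a$center[2],
                            radius_px = a$radius,
                            residual_px = a$residual)
      }
      results$boundaries <- dplyr::bind_rows(bnds)
      results$arcs <- dplyr::bind_rows(arcs)
      note(write_csv_det(results$boundaries,
                         file.path(config$out_dir, "boundaries.csv")))
      note(write_csv_det(results$arcs, file.path(config$out_dir, "arcs.csv")))
      results$expansion <- expansion_curve(
        colony_stack, n_windows = config$track$n_windows,
        dt_min = config$track$dt_min, n_rays = config$track$n_rays)
      results$expansion_summary <- expansion_summary(results$expansion)
      note(write_csv_det(results$expansion,
                         file.path(config$out_dir, "velocities.csv")))
      note(write_csv_det(results$expansion_summary,
                         file.path(config$out_dir, "velocity_summary.csv")))
    }

    # --- piv -----------------------------------------------------------
    if (!is.null(bead_stack)) {
      field <- accumulate_series(bead_stack, mode = config$piv$mode,
                                 window_size = config$piv$window_size,
                                 overlap = config$piv$overlap)
      if (!is.null(config$piv$drift_region))
        field <- drift_correct(field, config$piv$drift_region)
      results$displacement <- field
      note(write_csv_det(as_tibble(field),
                         file.path(config$out_dir, "displacement.csv")))
      results$divergence <- divergence(field)
      note(write_csv_det(results$divergence,
                         file.path(config$out_dir, "divergence.csv")))

      # --- tfm ---------------------------------------------------------
      if (isTRUE(config$tfm$enabled)) {
        tr <- reconstruct_traction(field, config$substrate,
                                   reg = config$tfm$reg,
                                   pad = config$tfm$pad)
        tr <- strain_from_stress(tr, config$substrate)
        results$traction <- tr
        note(write_csv_det(as_tibble(tr),
                           file.path(config$out_dir, "traction.csv")))
        results$stress_summary <- stress_summary(tr)
        note(write_csv_det(results$stress_summary,
                           file.path(config$out_dir, "stress_summary.csv")))
      }
    }

    # --- figures -------------------------------------------------------
    if (config$figures) {
      figs <- render_figures(results, config$out_dir,
                             stack = colony_stack)
      results$figures <- figs
    }
  }, warning = function(w) {
    warnings[length(warnings) + 1L] <<- conditionMessage(w)
    invokeRestart("muffleWarning")
  })

  cfg_ser <- config_serializable(unclass(config))
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(cfg_ser, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  note(cfg_path)

  sums <- tools::md5sum(paths)
  manifest <- list(
    artifact_version = as.character(utils::packageVersion("biofilmtfm")),
    config_hash = digest::digest(cfg_ser, algo = "md5"),
    checksums = as.list(stats::setNames(unname(sums), basename(paths))),
    warnings = warnings
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, results = results))
}
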