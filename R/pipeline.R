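## End-to-end orchestration: simulate -> phase-correct -> fit -> select
## -> ROI statistics -> group comparison, with a file-based report
## bundle.

#' Default pipeline configuration
#'
#' @param groups phantom groups to simulate and compare (first vs second
#'   in the comparison table).
#' @param models models to fit.
#' @param b_max_grid b-value ceilings for the model-comparison sweep.
#' @param n_hearts hearts per group (`NULL` = cohort defaults).
#' @param roi_n ROI voxel count per heart.
#' @param grid_dim phantom grid.
#' @param seed master seed.
#' @param scheme_directions DW direction count (257 or 514 emulate the
#'   two protocols).
#' @param fit an optional [fit_config()] override.
#' @return a named list, accepted by [run_pipeline()].
#' @export
pipeline_config <- function(groups = c("tac", "sham"),
                            models = c("dt", "beta"),
                            b_max_grid = c(2000, 10000),
                            n_hearts = NULL, roi_n = 30,
                            grid_dim = c(14, 14, 3),
                            seed = 1L, scheme_directions = 257,
                            fit = NULL) {
  bad <- setdiff(models, setdiff(MODEL_IDS, "monoexp"))
  if (length(bad))
    stop("unknown model name(s): ", paste(bad, collapse = ", "))
  list(groups = groups, models = models, b_max_grid = b_max_grid,
       n_hearts = n_hearts, roi_n = roi_n, grid_dim = grid_dim,
       seed = seed, scheme_directions = scheme_directions, fit = fit)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates the configured phantom groups, phase-corrects the complex
#' data, fits the requested models voxelwise in the ROIs, compares them
#' by AICc at each b-value ceiling, summarises per-heart ROI moments and
#' compares the groups by exact Mann-Whitney tests. When `out_dir` is
#' given, tables are written as TSV and a JSON manifest records the
#' seed and configuration.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return a report bundle: `sweep` (model x b_max table), `summaries`
#'   (per-heart ROI means), `comparison` (group test table), `pdfs`
#'   (group-average diffusivity profiles), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  bad <- setdiff(config$models, setdiff(MODEL_IDS, "monoexp"))
  if (length(bad))
    stop("unknown model name(s): ", paste(bad, collapse = ", "))
  scheme <- make_scheme(config$scheme_directions,
                        style = if (config$scheme_directions > 300)
                          "grid_full" else "grid_half")
  sweep_rows <- list(); summ_rows <- list(); pdf_rows <- list()
  for (gi in seq_along(config$groups)) {
    grp <- config$groups[gi]
    spec <- phantom_spec(grp, n_hearts = config$n_hearts,
                         grid_dim = config$grid_dim, roi_n = config$roi_n,
                         r_outer = min(config$grid_dim[1:2]) / 2 - 1,
                         r_inner = min(config$grid_dim[1:2]) / 4)
    gt <- make_phantom(spec, seed = config$seed + 1000L * gi)
    fit_cfg <- config$fit %||% fit_config(seed = config$seed)
    beta_pars <- list()
    for (h in seq_len(spec$n_hearts)) {
      sim <- simulate_signals(gt, scheme, heart = h,
                              seed = config$seed + 1000L * gi + h)
      sig <- corrected_signals(sim)
      roi <- as.vector(sim$roi_mask)
      for (bm in config$b_max_grid) {
        cfg <- fit_cfg; cfg$b_max <- bm
        fits <- fit_volume(sig, roi, scheme, config$models, cfg)
        sig_roi <- sig[fits$voxels, , drop = FALSE]
        sel <- lapply(seq_len(fits$n_voxels), function(j)
          select_voxel(lapply(fits$fits, `[[`, j), sig_roi[j, ],
                       scheme, bm))
        sel_all <- do.call(rbind, sel)
        for (m in config$models) {
          sm <- sel_all[sel_all$model == m, ]
          sweep_rows[[length(sweep_rows) + 1L]] <- data.frame(
            group = grp, heart = h, b_max = bm, model = m,
            mean_rmse = mean(sm$rmse),
            mean_rel_likelihood = mean(sm$rel_likelihood), n = sm$n[1])
        }
        if (bm == max(config$b_max_grid)) {
          for (m in intersect(config$models,
                              c("beta", "gamma", "truncgauss", "dk",
                                "biexp"))) {
            mom <- fit_moments(fits, m)
            agg <- stats::aggregate(
              mom[c("mean_diffusivity", "kurtosis", "skewness")],
              by = list(axis = mom$axis), FUN = mean)
            for (i in seq_len(nrow(agg))) {
              for (qn in c("mean_diffusivity", "kurtosis", "skewness")) {
                summ_rows[[length(summ_rows) + 1L]] <- data.frame(
                  group = grp, heart = h, model = m,
                  parameter = paste0(m, "_", qn, "_", agg$axis[i]),
                  value = agg[[qn]][i])
              }
            }
            if (m == "beta") {
              ag2 <- stats::aggregate(mom[c("alpha", "beta", "Dmax")],
                                      by = list(axis = mom$axis),
                                      FUN = mean)
              beta_pars[[length(beta_pars) + 1L]] <- ag2
            }
          }
        }
      }
    }
    if (length(beta_pars)) {
      allp <- do.call(rbind, beta_pars)
      avg <- stats::aggregate(allp[c("alpha", "beta", "Dmax")],
                              by = list(axis = allp$axis), FUN = mean)
      pd <- reconstruct_pdfs(avg, "beta")
      pd$group <- grp
      pdf_rows[[length(pdf_rows) + 1L]] <- pd
    }
  }
  sweep <- do.call(rbind, sweep_rows)
  summaries <- do.call(rbind, summ_rows)
  comparison <- if (length(config$groups) >= 2) {
    group_compare(summaries, config$groups[1], config$groups[2])
  } else NULL
  bundle <- list(sweep = sweep, summaries = summaries,
                 comparison = comparison,
                 pdfs = if (length(pdf_rows)) do.call(rbind, pdf_rows),
                 config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(sweep, file.path(out_dir, "sweep.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(summaries, file.path(out_dir, "roi_summaries.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(comparison))
      utils::write.table(comparison, file.path(out_dir, "comparison.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    manifest <- list(package = "cardiffusion",
                     version = as.character(utils::packageVersion("cardiffusion")),
                     seed = config$seed,
                     config = config[setdiff(names(config), "fit")])
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

# ---- NIfTI map export ---------------------------------------------------

#' Write a 3-D map as NIfTI
#'
#' @param map numeric 3-D array (e.g. an angle or scalar map).
#' @param file output path (`.nii` or `.nii.gz`).
#' @param reference optional NIfTI object or path whose affine/header is
#'   copied.
#' @return the path, invisibly.
#' @export
write_map_nifti <- function(map, file, reference = NULL) {
  img <- if (is.null(reference)) RNifti::asNifti(map)
         else RNifti::asNifti(map, reference = RNifti::asNifti(reference))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname write_map_nifti
#' @param file path of a NIfTI volume to read.
#' @export
read_map_nifti <- function(file) {
  RNifti::readNifti(file)
}
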