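# Orchestration of the three processing arms compared throughout the
# package: raw (no processing), decon (deconvolution only), and
# blur_decon (Gaussian prefilter, then deconvolution).

#' Experiment configuration
#'
#' One declarative object driving [run_experiment()]: the simulation,
#' the optics for the excitation/emission PSF pair, the prefilter, the
#' deconvolution settings, and which pipeline arms to run.
#'
#' @param sim A [sim_config()].
#' @param excitation_wavelength,emission_wavelength Wavelengths in nm of
#'   the PSF pair (defaults 488 and 510).
#' @param numerical_aperture,refractive_index Optics shared by the pair.
#' @param blur A [blur_config()] or `NULL` (required by the
#'   `blur_decon` arm).
#' @param deconv_iterations RL iteration count for the deconvolving arms.
#' @param deconv_background `"auto"` or photons/voxel for the
#'   deconvolving arms.
#' @param snr_hint Optional provenance annotation for the deconvolver.
#' @param roi_size Quantification ROI side in pixels (default 20).
#' @param pipelines Character subset of
#'   `c("raw", "decon", "blur_decon")`.
#' @param out_dir Output directory, or `NULL` to keep results in memory
#'   only.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              excitation_wavelength = 488,
                              emission_wavelength = 510,
                              numerical_aperture = 1.4,
                              refractive_index = 1.5,
                              blur = blur_config(sigma = 0.75, mode = "2d"),
                              deconv_iterations = 40L,
                              deconv_background = "auto",
                              snr_hint = NULL,
                              roi_size = 20L,
                              pipelines = c("raw", "blur_decon"),
                              out_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  if (!length(pipelines)) stop("at least one pipeline arm is required", call. = FALSE)
  pipelines <- match.arg(pipelines, c("raw", "decon", "blur_decon"),
                         several.ok = TRUE)
  if ("blur_decon" %in% pipelines && is.null(blur)) {
    stop("the blur_decon arm needs a blur_config", call. = FALSE)
  }
  structure(
    list(sim = sim,
         optics_ex = optical_params(numerical_aperture, refractive_index,
                                    excitation_wavelength, sim$voxel_pitch,
                                    sim$grid_dims),
         optics_em = optical_params(numerical_aperture, refractive_index,
                                    emission_wavelength, sim$voxel_pitch,
                                    sim$grid_dims),
         blur = blur, deconv_iterations = as.integer(deconv_iterations),
         deconv_background = deconv_background, snr_hint = snr_hint,
         roi_size = as.integer(roi_size),
         pipelines = pipelines, out_dir = out_dir),
    class = "experiment_config"
  )
}

log_stage <- function(verbose, stage, t0, detail = "") {
  if (!verbose) return(invisible())
  dt <- (proc.time() - t0)[["elapsed"]]
  message(sprintf("INFO [%s] %.2fs %s", stage, dt, detail))
}

array_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  writeBin(as.vector(as.numeric(x)), con)
  close(con)
  unname(tools::md5sum(f))
}

#' Run a simulated deconvolution experiment
#'
#' Simulates one encoded Z-stack, then runs each requested arm:
#' `raw` (decode, project, quantify), `decon` (decode, RL deconvolve,
#' flux-correct, project, quantify) and `blur_decon` (Gaussian blur of
#' the encoded stack, decode, RL deconvolve, flux-correct, project,
#' quantify).  Identical configuration and master seed give identical
#' outputs; if an arm fails, its error is recorded and the remaining
#' arms still run.
#'
#' @param config An [experiment_config()].
#' @param psf Optional precomputed effective confocal `psf_volume` on
#'   the simulation grid (built from the config's optics when missing);
#'   pass one when running several experiments with the same optics.
#' @param verbose Emit per-stage log lines.
#' @return A list of class `experiment_result`: `simulation` (see
#'   [simulate_stack()]), `arms` (named list with `projection`,
#'   `report`, and for deconvolving arms the `rl_decon` fit), `psf`,
#'   `provenance`, and `errors`.
#' @export
run_experiment <- function(config, psf = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- proc.time()
  if (is.null(psf)) {
    ex <- born_wolf_psf(config$optics_ex)
    em <- born_wolf_psf(config$optics_em)
    psf <- effective_confocal_psf(ex, em)
    log_stage(verbose, "psf", t0)
  }
  sim <- simulate_stack(config$sim, psf)
  log_stage(verbose, "simulate", t0,
            sprintf("stack checksum %s", array_checksum(sim$encoded$values)))

  arms <- list()
  errors <- list()
  run_arm <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[name]] <<- conditionMessage(res)
      message(sprintf("WARN [%s] arm failed: %s", name, conditionMessage(res)))
    } else {
      arms[[name]] <<- res
      log_stage(verbose, name, t0)
    }
  }

  quantify_projection <- function(projection, correction = 1) {
    rep <- count_preserved(projection, sim$layout, roi_size = config$roi_size)
    if (correction != 1) rep <- apply_correction_factor(rep, correction)
    rep
  }

  deconv_arm <- function(stack) {
    fit <- richardson_lucy(stack, psf,
                           iterations = config$deconv_iterations,
                           background = config$deconv_background,
                           snr_hint = config$snr_hint)
    fit <- flux_correction(fit, stack)
    proj <- average_project(fit)
    list(projection = proj, report = quantify_projection(proj), fit = fit)
  }

  if ("raw" %in% config$pipelines) {
    run_arm("raw", function() {
      proj <- average_project(sim$encoded)
      list(projection = proj, report = quantify_projection(proj))
    })
  }
  if ("decon" %in% config$pipelines) {
    run_arm("decon", function() deconv_arm(sim$encoded))
  }
  if ("blur_decon" %in% config$pipelines) {
    run_arm("blur_decon", function() {
      blurred <- gaussian_blur(sim$encoded, config$blur)
      deconv_arm(blurred)
    })
  }

  provenance <- list(
    master_seed = config$sim$seed,
    stage_seeds = sim$seeds,
    sim_config = config$sim,
    pipelines = config$pipelines,
    blur = config$blur,
    deconv_iterations = config$deconv_iterations,
    deconv_background = config$deconv_background,
    snr_hint = config$snr_hint,
    encoded_checksum = array_checksum(sim$encoded$values),
    projection_checksums = lapply(arms, function(a) array_checksum(a$projection))
  )

  out <- structure(
    list(simulation = sim, arms = arms, psf = psf,
         provenance = provenance, errors = errors, config = config),
    class = "experiment_result"
  )
  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment (master seed %d): arms %s\n",
              x$provenance$master_seed, paste(names(x$arms), collapse = ", ")))
  for (nm in names(x$arms)) {
    r <- x$arms[[nm]]$report
    cat(sprintf("  %-11s %d/%d objects preserved, median density %.4g\n",
                nm, r$n_preserved, nrow(r$per_object),
                stats::median(r$per_object$integrated_density)))
  }
  if (length(x$errors)) {
    cat("  failed arms:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

# Persist an experiment: encoded stack + sidecar, per-arm projection
# TIFFs (float, rescaled to [0,1] with the scale in the sidecar) and
# report CSVs, plus a provenance text file.
write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(result$simulation$encoded, file.path(dir, "stack.tif"),
              extra = list(master_seed = result$provenance$master_seed,
                           poisson_seed = result$provenance$stage_seeds[["poisson"]]))
  for (nm in names(result$arms)) {
    arm <- result$arms[[nm]]
    proj <- arm$projection
    scale <- max(proj, 1e-12)
    tif <- file.path(dir, paste0("projection_", nm, ".tif"))
    tiff::writeTIFF(t(proj) / scale, tif, bits.per.sample = 32L)
    write_sidecar(tif, list(kind = "average_projection", arm = nm,
                            scale = format(scale, digits = 17)))
    write_quant_report(arm$report, file.path(dir, paste0("report_", nm, ".csv")))
  }
  prov <- result$provenance
  lines <- c(
    sprintf("master_seed: %s", prov$master_seed),
    sprintf("poisson_seed: %s", prov$stage_seeds[["poisson"]]),
    sprintf("pipelines: %s", paste(prov$pipelines, collapse = ",")),
    sprintf("grid_dims: %s", paste(prov$sim_config$grid_dims, collapse = ",")),
    sprintf("voxel_pitch: %s", paste(prov$sim_config$voxel_pitch, collapse = ",")),
    sprintf("background: %s", prov$sim_config$background),
    sprintf("blur_sigma: %s", if (is.null(prov$blur)) "none" else prov$blur$sigma),
    sprintf("deconv_iterations: %s", prov$deconv_iterations),
    sprintf("deconv_background: %s", prov$deconv_background),
    sprintf("encoded_checksum: %s", prov$encoded_checksum),
    vapply(names(prov$projection_checksums), function(nm) {
      sprintf("projection_checksum_%s: %s", nm, prov$projection_checksums[[nm]])
    }, character(1))
  )
  writeLines(lines, file.path(dir, "provenance.txt"))
  invisible(dir)
}

#' Compare quantification reports between pipeline arms
#'
#' Per-object integrated-density ratios between two reports over the
#' same object layout, the median ratio, and the preserved-count delta.
#'
#' @param report_a,report_b `quant_report`s over the same layout
#'   (`report_a` is the reference/denominator).
#' @return A list of class `report_comparison`: `per_object` data frame
#'   (x, y, density_a, density_b, ratio), `median_ratio`,
#'   `n_preserved_a`, `n_preserved_b`, `preserved_delta`.
#' @export
compare_reports <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "quant_report"), inherits(report_b, "quant_report"))
  a <- report_a$per_object
  b <- report_b$per_object
  if (nrow(a) != nrow(b) || any(a$x != b$x) || any(a$y != b$y)) {
    stop("reports cover different object layouts", call. = FALSE)
  }
  ratio <- b$integrated_density / a$integrated_density
  structure(
    list(
      per_object = data.frame(x = a$x, y = a$y,
                              density_a = a$integrated_density,
                              density_b = b$integrated_density,
                              ratio = ratio),
      median_ratio = stats::median(ratio),
      n_preserved_a = report_a$n_preserved,
      n_preserved_b = report_b$n_preserved,
      preserved_delta = report_b$n_preserved - report_a$n_preserved
    ),
    class = "report_comparison"
  )
}

#' @export
print.report_comparison <- function(x, ...) {
  cat(sprintf(
    "Report comparison over %d objects: median density ratio %.4g\n  preserved %d vs %d (delta %+d)\n",
    nrow(x$per_object), x$median_ratio, x$n_preserved_a, x$n_preserved_b,
    x$preserved_delta
  ))
  invisible(x)
}
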