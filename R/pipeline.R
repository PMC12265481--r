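default_config <- function() {
  list(
    paths = list(frames = NULL, dark = NULL, output_dir = "sio_output"),
    optical = list(pupil_diameter = 6.7, imaging_wavelength = 850,
                   pixel_scale = 1 / 403, oversampling_factor = 2,
                   defocus_infocus = 0, defocus_background = 1.5,
                   retinal_scale = 300),
    illumination = list(modulation_frequency_cpd = 34,
                        orientations = c(45, -45), phase = 0,
                        contrast_infocus = 0.7, contrast_background = 0,
                        mean_level = 1),
    phantom = list(cone_spacing = 5, spacing_jitter = 0.12, cone_sigma = 1.1,
                   reflectance_cv = 0.2, background_correlation_length = 15,
                   background_to_signal_ratio = 1, field_of_view = 256 / 403),
    acquisition = list(n_frames = 100, frame_rate = 100, switching_rate = 2,
                       noise_sigma = 0.05, drift_step = 1,
                       microsaccade_rate = 0.5, microsaccade_amplitude = 30,
                       blink_fraction = 0.05, dark_offset = 100, n_dark = 100),
    preprocess = list(crop_size = NULL, taper_fraction = 0.2),
    selection = list(window_seconds = 2, quality_quantile = 0.5,
                     tolerance_bins = 3),
    shifts = list(notch_radius_bins = NULL, upsample_factor = 32),
    reconstruction = list(lambda = 0.3, max_iter = 300, tol = 1e-6),
    metrics = list(background_low_cut = 15, background_high_cut = 150,
                   min_separation_px = 4, density_window = 64,
                   fovea_center = c(0, 0), ecc_bin = 0.1),
    seed = 1
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    key <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base)) stop(sprintf("unknown config key: %s", key))
    if (is.list(base[[k]]) && !is.null(user[[k]]) && is.list(user[[k]]) &&
        !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], key)
    } else {
      base[k] <- list(user[[k]])   # keeps explicit NULLs instead of dropping them
    }
  }
  base
}

#' Pipeline configuration
#'
#' Builds a validated nested configuration from defaults plus overrides;
#' unknown keys are rejected. Configurations round-trip identically through
#' [write_config()] / [read_config()].
#'
#' @param ... Named overrides, each a list matching a config section (e.g.
#'   `optical = list(oversampling_factor = 1)`), or top-level scalars
#'   (`seed`, `paths`).
#' @return Nested list of class `sio_config`.
#' @export
sio_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(default_config(), user)
  structure(cfg, class = c("sio_config", "list"))
}

#' Read / write a pipeline configuration (JSON)
#'
#' @param config An [sio_config()].
#' @param path JSON file path.
#' @return `path` invisibly (writer); an [sio_config()] (reader).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sio_config, raw)
}

config_objects <- function(config) {
  opt <- do.call(optical_model, config$optical)
  il <- do.call(illumination_model, c(config$illumination,
                                      list(frames_per_block =
                                        round(config$acquisition$frame_rate /
                                              config$acquisition$switching_rate))))
  list(optical = opt, illum = il)
}

# rolling polynomial hash of a string, as 8 hex digits (manifest fingerprint)
fnv1a <- function(s) {
  h <- 5381
  for (b in as.integer(charToRaw(s))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Simulate an acquisition and write it to disk
#'
#' Writes the raw frame stack, the dark stack and the ground truth (floating
#' point layers + metadata sidecars) under `dir`, in the layout
#' [run_pipeline()] consumes.
#'
#' @param config An [sio_config()].
#' @param dir Output directory.
#' @return Invisibly, the list returned by [simulate_acquisition()].
#' @export
simulate_to_files <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- config_objects(config)
  ph <- do.call(phantom_spec, c(config$phantom, list(rng_seed = config$seed)))
  acq <- do.call(acquisition_spec, config$acquisition)
  sim <- simulate_acquisition(ph, acq, co$optical, co$illum, seed = config$seed)
  write_stack(sim$stack, file.path(dir, "frames.tif"), dtype = "uint16",
              extra = list(seed = config$seed,
                           true_dy = sim$trajectory$dy,
                           true_dx = sim$trajectory$dx,
                           saccade = sim$trajectory$saccade,
                           snr = sim$snr))
  write_stack(sim$dark, file.path(dir, "dark.tif"), dtype = "uint16")
  truth <- array(0, c(dim(sim$phantom$o0), 2))
  truth[, , 1] <- sim$phantom$o0
  truth[, , 2] <- sim$phantom$od
  write_tiff(truth, file.path(dir, "truth.tif"), dtype = "float32")
  jsonlite::write_json(
    list(seed = config$seed, cones = attr(sim$phantom, "cones"),
         config = unclass(config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sim)
}

#' Run the full reconstruction pipeline
#'
#' Executes pre-processing, frame selection, shift estimation, MAP
#' reconstruction and metrics in order, writing all outputs plus a run
#' manifest under `config$paths$output_dir`. Deterministic: re-running with
#' the same inputs yields bit-identical reconstructions.
#'
#' @param config An [sio_config()] whose `paths$frames` / `paths$dark` point
#'   to stacks readable by [read_stack()].
#' @return Invisibly, a list with the selection report, trajectory,
#'   reconstruction, wide-field image, spectra and cone-density results.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  out_dir <- config$paths$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  co <- config_objects(config)
  optical <- co$optical; illum <- co$illum

  raw <- stage("read", {
    if (is.null(config$paths$frames)) stop("paths$frames is not set")
    read_stack(config$paths$frames,
               frame_rate = config$acquisition$frame_rate,
               switching_rate = config$acquisition$switching_rate,
               orientations = illum$orientations)
  })
  dark <- stage("read", read_stack(config$paths$dark,
                                   frame_rate = config$acquisition$frame_rate,
                                   switching_rate = config$acquisition$switching_rate))

  pre <- stage("preprocess",
               preprocess_stack(raw, dark, crop_size = config$preprocess$crop_size,
                                taper_fraction = config$preprocess$taper_fraction))

  sel <- stage("select",
               select_frames(pre, illum, optical$pixel_scale,
                             window_seconds = config$selection$window_seconds,
                             quality_quantile = config$selection$quality_quantile,
                             tolerance_bins = config$selection$tolerance_bins))
  # reconstruct() itself warns when the per-orientation frame count drops
  # below the phase-diversity minimum of 7

  traj <- stage("shifts", {
    ns <- notch_spec(illum$modulation_frequency_cpd, illum$orientations,
                     optical$pixel_scale,
                     radius_bins = config$shifts$notch_radius_bins)
    filt <- sel$selected
    for (j in seq_len(n_frames(filt))) {
      filt$frames[, , j] <- notch_filter(filt$frames[, , j], ns)
    }
    estimate_shifts(filt, upsample_factor = config$shifts$upsample_factor,
                    pixel_scale = optical$pixel_scale,
                    max_freq_cpd = cutoff_cpd(optical))
  })

  rec <- stage("reconstruct",
               reconstruct(sel$selected, traj, optical, illum,
                           lambda = config$reconstruction$lambda,
                           max_iter = config$reconstruction$max_iter,
                           tol = config$reconstruction$tol))

  met <- stage("metrics", {
    wf <- rec$widefield
    spec_wf <- radial_psd(wf, optical$pixel_scale)
    # noise PSD of the wide-field average, measured on its pure-noise band
    # above the optical cutoff; the same floor serves both images
    fc <- cutoff_cpd(optical)
    nyq <- 1 / (2 * optical$pixel_scale)
    floor_band <- spec_wf$freq > fc & spec_wf$freq <= nyq
    floor_wf <- mean(spec_wf$psd[floor_band])
    d_obj <- object_pixel_scale(optical)
    spec_sio <- radial_psd(rec$object$o0, d_obj)
    cut_wf <- effective_cutoff(spec_wf, floor_wf)
    cut_sio <- effective_cutoff(spec_sio, floor_wf)
    bc <- background_correct(rec$object$o0, config$metrics$background_low_cut,
                             config$metrics$background_high_cut, d_obj)
    cones <- detect_cones(bc, config$metrics$min_separation_px *
                                optical$oversampling_factor)
    dens <- cone_density_map(cones, dim(bc), d_obj,
                             fovea_center = config$metrics$fovea_center,
                             window_size = config$metrics$density_window *
                                             optical$oversampling_factor,
                             ecc_bin = config$metrics$ecc_bin,
                             retinal_scale = optical$retinal_scale)
    list(widefield = wf, spectrum_widefield = spec_wf, spectrum_sio = spec_sio,
         noise_floor = floor_wf, cutoff_widefield = cut_wf,
         cutoff_sio = cut_sio, cones = cones, density = dens)
  })

  stage("write", {
    write_tiff(rec$object$o0, file.path(out_dir, "o0.tif"), dtype = "float32")
    write_tiff(rec$object$od, file.path(out_dir, "od.tif"), dtype = "float32")
    write_tiff(met$widefield, file.path(out_dir, "widefield.tif"), dtype = "float32")
    jsonlite::write_json(
      list(gradient_energy = sel$gradient_energy,
           fringe_contrast_energy = sel$fringe_contrast_energy,
           retained_step1 = sel$retained_step1,
           retained_step2 = sel$retained_step2,
           retained_step3 = sel$retained_step3,
           counts = as.list(sel$counts)),
      file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
    write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
    utils::write.csv(
      rbind(data.frame(image = "widefield", met$spectrum_widefield),
            data.frame(image = "sio", met$spectrum_sio)),
      file.path(out_dir, "spectra.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(met$density),
                     file.path(out_dir, "density_windows.csv"), row.names = FALSE)
    utils::write.csv(attr(met$density, "profile"),
                     file.path(out_dir, "density_profile.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(hyper = list(sigma2 = rec$hyper$sigma2, S0 = rec$hyper$S0,
                        Sd = rec$hyper$Sd, lambda = rec$hyper$lambda),
           trace = rec$trace, iterations = rec$iterations,
           converged = rec$converged),
      file.path(out_dir, "reconstruction.json"), auto_unbox = TRUE, digits = NA)
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                                 null = "null")
    jsonlite::write_json(
      list(package = "sior",
           version = as.character(utils::packageVersion("sior")),
           r_version = as.character(getRversion()),
           seed = config$seed,
           config_hash = fnv1a(as.character(cfg_json)),
           stages = c("preprocess", "select", "shifts", "reconstruct", "metrics"),
           frames_in = n_frames(raw),
           frames_selected = n_frames(sel$selected),
           counts_per_orientation = as.list(sel$counts),
           cutoff_widefield = met$cutoff_widefield,
           cutoff_sio = met$cutoff_sio,
           config = unclass(config)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  })

  invisible(list(selection = sel, trajectory = traj, reconstruction = rec,
                 metrics = met, config = config))
}
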