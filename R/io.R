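## Readers and writers for the package's external formats.
##
## Events: 4-column CSV (tether_id, time_s, censored, replicate_id) with an
## optional JSON sidecar carrying t_end / frame_interval / time_zero.
## Trajectories: multi-model PDB (angstrom, interoperable) or XYZ plus a
## JSON topology sidecar (full precision, lossless round trip).
## Movies: multi-frame float TIFF plus a JSON acquisition sidecar.
## Column headers carry units (time_s, rho_nm, theta_deg, ...).

events_sidecar_path <- function(path) paste0(path, ".json")

#' Write a dissociation dataset to CSV (+ JSON metadata sidecar)
#'
#' @param events a `dissociation_data` object.
#' @param path output CSV path.
#' @param sidecar write the metadata sidecar (`<path>.json`)? Default TRUE.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, sidecar = TRUE) {
  stopifnot(inherits(events, "dissociation_data"))
  df <- as.data.frame(events)
  df$censored <- as.integer(df$censored)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(t_end = attr(events, "t_end"),
                 frame_interval = attr(events, "frame_interval"),
                 time_zero = attr(events, "time_zero"))
    meta <- lapply(meta, function(v) if (is.numeric(v) && !is.finite(v))
      "Inf" else v)
    jsonlite::write_json(meta, events_sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a dissociation dataset from CSV
#'
#' @param path CSV path (schema: tether_id, time_s, censored, replicate_id).
#' @return A `dissociation_data` object, with metadata restored from the
#'   JSON sidecar when present.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stopf("cannot parse events CSV %s: %s", path, conditionMessage(e)))
  need <- c("tether_id", "time_s", "censored", "replicate_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("events CSV %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  if (any(df$time_s < 0, na.rm = TRUE)) stopf("negative times in %s", path)
  meta <- list(t_end = Inf, frame_interval = NA_real_, time_zero = 0)
  sp <- events_sidecar_path(path)
  if (file.exists(sp)) {
    got <- jsonlite::read_json(sp, simplifyVector = TRUE)
    for (k in names(meta)) if (!is.null(got[[k]]))
      meta[[k]] <- if (identical(got[[k]], "Inf")) Inf else as.numeric(got[[k]])
  }
  dissociation_data(df, t_end = meta$t_end,
                    frame_interval = meta$frame_interval,
                    time_zero = meta$time_zero)
}

traj_sidecar <- function(traj, units) {
  list(n_frames = traj$n_frames, frame_dt_ps = traj$frame_dt,
       temperature_K = traj$temperature, units = units,
       atoms = traj$atoms, states = traj$states,
       interface = traj$interface)
}

#' Write an interface trajectory
#'
#' `format = "xyz"` writes an XYZ-style multi-frame file at full precision
#' plus a JSON topology sidecar (`<path>.json`); coordinates stay in the
#' package's internal nm (recorded in the sidecar) so this route
#' round-trips bit-exactly. `format = "pdb"` writes a multi-model PDB
#' (3-decimal angstrom by format definition) plus the same sidecar.
#'
#' @param traj an `interface_trajectory`.
#' @param path output path.
#' @param format `"xyz"` or `"pdb"`; default from the file extension.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = NULL) {
  stopifnot(inherits(traj, "interface_trajectory"))
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(format, c("xyz", "pdb"))
  na <- nrow(traj$atoms)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz") {
    xyz <- traj$coords                         # nm, full precision
    for (f in seq_len(traj$n_frames)) {
      writeLines(c(as.character(na), sprintf("frame %d (nm)", f)), con)
      writeLines(sprintf("%s %.17g %.17g %.17g", traj$atoms$elety,
                         xyz[, 1, f], xyz[, 2, f], xyz[, 3, f]), con)
    }
    units <- "nm"
  } else {
    ang <- traj$coords * 10                    # nm -> angstrom
    at <- traj$atoms
    for (f in seq_len(traj$n_frames)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        at$eleno, at$elety, at$resname, at$chain, at$resid,
        ang[, 1, f], ang[, 2, f], ang[, 3, f]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    units <- "angstrom"
  }
  jsonlite::write_json(traj_sidecar(traj, units), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an interface trajectory
#'
#' Accepts the XYZ+JSON or multi-model PDB layout written by
#' [write_trajectory()] (PDB reading goes through `bio3d`). The frame count
#' is validated against the sidecar and atom names against the ring-atom
#' vocabulary.
#'
#' @param path file path.
#' @param topology optional sidecar path (default `<path>.json`).
#' @param format `"xyz"` or `"pdb"`; default from the extension.
#' @return An `interface_trajectory`.
#' @export
read_trajectory <- function(path, topology = NULL, format = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(format, c("xyz", "pdb"))
  topology <- topology %||% paste0(path, ".json")
  if (!file.exists(topology))
    stopf("missing topology sidecar: %s", topology)
  meta <- jsonlite::read_json(topology, simplifyVector = TRUE)
  atoms <- as.data.frame(meta$atoms)
  na <- nrow(atoms)
  bad <- setdiff(unique(atoms$elety), RING_ATOMS)
  if (length(bad))
    stopf("unknown atom name(s) in topology: %s", paste(bad, collapse = ", "))
  if (format == "xyz") {
    lines <- readLines(path)
    per <- na + 2L
    n_frames <- length(lines) %/% per
    if (length(lines) %% per != 0L)
      stopf("truncated XYZ file: partial frame after frame %d", n_frames)
    coords <- array(NA_real_, dim = c(na, 3L, n_frames))
    for (f in seq_len(n_frames)) {
      block <- lines[((f - 1L) * per + 3L):((f - 1L) * per + 2L + na)]
      parts <- strsplit(trimws(block), "\\s+")
      m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
      if (anyNA(m)) stopf("unparseable coordinates in frame %d", f)
      coords[, , f] <- m
    }
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    xyz <- pdb$xyz
    n_frames <- nrow(xyz)
    if (ncol(xyz) != 3L * na)
      stopf("PDB atom count (%d) does not match topology (%d)",
            ncol(xyz) / 3L, na)
    coords <- array(NA_real_, dim = c(na, 3L, n_frames))
    for (f in seq_len(n_frames))
      coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  if (!is.null(meta$n_frames) && n_frames != meta$n_frames)
    stopf("frame count mismatch: file has %d frames, sidecar says %d",
          n_frames, meta$n_frames)
  if (format == "pdb") coords <- coords / 10   # angstrom -> nm
  structure(list(coords = coords, atoms = atoms, n_frames = n_frames,
                 frame_dt = meta$frame_dt_ps %||% NA_real_,
                 temperature = meta$temperature_K %||% NA_real_,
                 states = meta$states,
                 interface = as.list(meta$interface),
                 params = NULL),
            class = "interface_trajectory")
}

#' Write an image stack as a multi-frame 32-bit TIFF (+ JSON sidecar)
#'
#' Frames are stored as 32-bit samples after scaling by
#' `1 / intensity_scale` (values clamped to \[0, 1\]), so the round trip is
#' exact to ~1e-10 of the intensity scale.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @param intensity_scale divisor applied before writing (default 65535).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, intensity_scale = 65535) {
  stopifnot(inherits(stack, "image_stack"))
  n <- dim(stack$frames)[3]
  d <- dim(stack$frames)
  frames <- lapply(seq_len(n), function(f)
    matrix(pmin(1, pmax(0, stack$frames[, , f] / intensity_scale)),
           d[1], d[2]))
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, compression = "none")
  meta <- list(frame_interval = stack$frame_interval,
               time_zero = stack$time_zero,
               intensity_scale = intensity_scale,
               truth = stack$truth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path.
#' @param meta optional sidecar path (default `<path>.json`).
#' @return An `image_stack`.
#' @export
read_image_stack <- function(path, meta = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  meta_path <- meta %||% paste0(path, ".json")
  m <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  scale <- m$intensity_scale %||% 1
  arr <- array(0, dim = c(dim(frames[[1]])[1:2], length(frames)))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (length(dim(fr)) == 3L) fr <- fr[, , 1]
    arr[, , f] <- fr * scale
  }
  truth <- if (!is.null(m$truth)) as.data.frame(m$truth) else NULL
  image_stack(arr, frame_interval = m$frame_interval %||% NA_real_,
              time_zero = m$time_zero %||% 0, truth = truth)
}

#' Write a rho-theta series to CSV
#'
#' @param series a `rho_theta` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rho_theta <- function(series, path) {
  stopifnot(inherits(series, "rho_theta"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a rho-theta series CSV
#'
#' @param path CSV path.
#' @param temperature optional temperature label (K).
#' @return A `rho_theta` object.
#' @export
read_rho_theta <- function(path, temperature = NA_real_) {
  df <- utils::read.csv(path)
  df$flag <- as.logical(df$flag)
  rho_theta(df, temperature = temperature)
}

#' Run configuration with documented defaults
#'
#' A single container for the experimental constants and pipeline settings:
#' temperature (K), gas constant (kcal/mol/K), rotor speed (rpm), rotor
#' radius (m), effective bead mass (g), bin count, detector thresholds,
#' geometry options and seeds. Defaults are the calibrated instrument
#' values (1291 rpm, 0.119 m, 6.9e-12 g) and the package's analysis
#' defaults.
#'
#' @param ... overrides of any default field.
#' @return An object of class `run_config` (named list).
#' @export
run_config <- function(...) {
  defaults <- list(
    temperature_K = 298.15,
    gas_constant_kcal = R_KCAL,
    rpm = 1291,
    rotor_radius_m = 0.119,
    bead_mass_g = 6.9e-12,
    n_bins = 50,
    frame_interval_s = 5,
    detect_score_threshold = 0.35,
    screen_min_separation_px = 15,
    screen_circularity = 0.8,
    call_drop_frac = 0.5,
    call_persistence_frames = 5,
    rho_cutoff_nm = 0.75,
    cluster_rho_max_nm = 0.9,
    cluster_ic_margin = 10,
    geometry_source = "idealized fiber B-form, regular-hexagon base rings",
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  ## Normalize numeric storage so configs compare equal after a
  ## serialization round trip (YAML reads whole numbers as integers).
  defaults <- lapply(defaults, function(v) if (is.numeric(v)) as.numeric(v)
                     else v)
  for (f in c("temperature_K", "rpm", "rotor_radius_m", "bead_mass_g",
              "n_bins", "frame_interval_s"))
    if (!is.numeric(defaults[[f]]) || defaults[[f]] <= 0)
      stopf("config field `%s` must be positive", f)
  structure(defaults, class = "run_config")
}

#' Write / read a run configuration (YAML)
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}
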