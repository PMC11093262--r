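# ---- single-scan text files -------------------------------------------

#' Write a scan to a plain-text file
#'
#' Header comment lines (`# key: value`) carry the acquisition metadata;
#' the body is a tab-separated table whose first column is `radius_cm`
#' (6 decimals) and remaining columns are counts per emission
#' wavelength, with the wavelength header row.
#'
#' @param scan An `mwe_scan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  hdr <- c(instrument = "mweauc",
           laser_nm = scan$meta$laser_nm %||% NA,
           grating_lmm = scan$meta$grating_lmm %||% NA,
           exposure_ms = scan$exposure, z_mm = scan$z,
           speed_rpm = scan$speed, time_s = scan$time,
           temperature_C = scan$meta$temperature_C %||% NA,
           seed = scan$meta$seed %||% NA)
  lines <- sprintf("# %s: %s", names(hdr), as.character(hdr))
  lines <- c(lines, paste(c("radius_cm", format(scan$wavelength)),
                          collapse = "\t"))
  body <- apply(cbind(sprintf("%.6f", scan$radius),
                      matrix(sprintf("%.10g", scan$counts),
                             nrow(scan$counts))),
                1, paste, collapse = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a scan from a plain-text file
#'
#' @param path File written by [write_scan()].
#' @return An `mwe_scan`.
#' @export
read_scan <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && any(diff(hdr_idx) != 1))
    abort(sprintf("parse error in %s: header lines must be contiguous at the top", path))
  hdr <- list()
  for (i in hdr_idx) {
    m <- regmatches(lines[i], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3)
      abort(sprintf("parse error at line %d of %s: malformed header", i, path))
    hdr[[trimws(m[2])]] <- trimws(m[3])
  }
  first <- length(hdr_idx) + 1
  cols <- strsplit(lines[first], "\t")[[1]]
  if (cols[1] != "radius_cm")
    abort(sprintf("parse error at line %d of %s: expected 'radius_cm' header row",
                  first, path))
  wl <- as.numeric(cols[-1])
  body <- lines[-seq_len(first)]
  body <- body[nzchar(body)]
  vals <- lapply(seq_along(body), function(k) {
    v <- suppressWarnings(as.numeric(strsplit(body[k], "\t")[[1]]))
    if (length(v) != length(cols) || anyNA(v))
      abort(sprintf("parse error at line %d of %s: expected %d numeric fields",
                    first + k, path, length(cols)))
    v
  })
  M <- do.call(rbind, vals)
  radius <- M[, 1]
  counts <- M[, -1, drop = FALSE]
  if (is.unsorted(radius, strictly = TRUE))
    abort(sprintf("parse error in %s: radii must be strictly increasing (line %d)",
                  path, first + which(diff(radius) <= 0)[1] + 1))
  if (any(counts > 65535) || any(counts < 0))
    abort(sprintf("count overflow in %s: values must lie in [0, 65535]", path))
  num <- function(x, default = NA_real_)
    if (is.null(x) || identical(x, "NA")) default else as.numeric(x)
  new_scan(radius, wl, counts,
           time = num(hdr$time_s, 0),
           speed = num(hdr$speed_rpm, 0),
           z = num(hdr$z_mm), exposure = num(hdr$exposure_ms),
           meta = hdr[setdiff(names(hdr),
                              c("time_s", "speed_rpm", "z_mm", "exposure_ms"))])
}

# ---- dataset container ------------------------------------------------

#' Write a scan set to a plain-text dataset directory
#'
#' The container is a directory holding one TSV scan file per scan (the
#' [write_scan()] dialect) and a JSON manifest with the instrument,
#' protocol and — for synthetic data — the ground-truth sidecar (species
#' table, injected TI/RI noise, seed). Plain text keeps every dataset
#' inspectable with standard tools; the round trip is lossless.
#'
#' @param scanset An `mwe_scan_set`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(scanset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  inst <- scanset$instrument
  prot <- scanset$protocol
  manifest <- list(
    format = "mweauc-dataset-1",
    n_scans = length(scanset$scans),
    wavelength = scanset$wavelength,
    instrument = inst[setdiff(names(inst), c("window", "resolution",
                                             "collection_spot",
                                             "confocal_depth", "n_pixels",
                                             "adc_bits", "adc_max"))],
    protocol = prot[c("speed", "meniscus", "bottom", "radial_step",
                      "scan_interval", "n_scans", "start_delay")],
    ground_truth = scanset$ground_truth)
  if (!is.null(manifest$ground_truth$species))
    manifest$ground_truth$species <-
      as.list(as.data.frame(manifest$ground_truth$species))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (i in seq_along(scanset$scans))
    write_scan(scanset$scans[[i]],
               file.path(path, sprintf("scan_%04d.tsv", i)))
  invisible(path)
}

#' Read a scan-set dataset directory
#'
#' @param path Directory written by [write_dataset()].
#' @param wavelengths Optional wavelengths (nm) to load; slicing on read
#'   equals slicing after a full read.
#' @return An `mwe_scan_set`.
#' @export
read_dataset <- function(path, wavelengths = NULL) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) abort("missing manifest.json: not a dataset directory")
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (is.null(mf$instrument) || is.null(mf$protocol))
    abort("dataset manifest is missing the instrument or protocol group")
  inst_args <- mf$instrument[intersect(names(mf$instrument),
                                       names(formals(instrument_model)))]
  inst <- do.call(instrument_model, inst_args)
  prot <- do.call(rotor_protocol, mf$protocol[names(mf$protocol) != "n_scans_actual"])
  files <- sort(list.files(path, pattern = "^scan_\\d+\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0) abort("dataset contains no scan files")
  scans <- lapply(files, read_scan)
  wl <- scans[[1]]$wavelength
  if (!is.null(wavelengths)) {
    j <- unique(vapply(wavelengths, function(w) which.min(abs(wl - w)),
                       integer(1)))
    scans <- lapply(scans, function(sc)
      new_scan(sc$radius, sc$wavelength[j],
               sc$counts[, j, drop = FALSE], time = sc$time,
               speed = sc$speed, z = sc$z, exposure = sc$exposure,
               meta = sc$meta))
    wl <- wl[j]
  }
  gt <- mf$ground_truth
  if (!is.null(gt$species)) gt$species <- as_tibble(gt$species)
  new_scan_set(scans, inst, prot, wl, ground_truth = gt)
}

# ---- run configuration ------------------------------------------------

.config_sections <- c("instrument", "protocol", "solvent", "species",
                      "fit", "simulate", "qc")

#' Read and validate a run configuration file
#'
#' YAML key-value configuration with strict schema validation: unknown
#' sections or keys are rejected, so typos cannot silently fall back to
#' defaults. Recognised sections: `instrument`, `protocol`, `solvent`,
#' `species` (a list; `emission_center`/`emission_fwhm` build a Gaussian
#' band), `fit`, `simulate` (extra [simulate_sv_dataset()] arguments) and
#' `qc`.
#'
#' @param path YAML file.
#' @return List with constructed `instrument`, `protocol`, `solvent`,
#'   `species`, `fit` objects, plus raw `simulate` and `qc` lists.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), .config_sections)
  if (length(bad))
    abort(sprintf("unknown configuration section(s): %s",
                  paste(bad, collapse = ", ")))
  check_keys <- function(x, fun, what, extra = character()) {
    bad <- setdiff(names(x), c(names(formals(fun)), extra))
    if (length(bad))
      abort(sprintf("unknown %s key(s): %s", what,
                    paste(bad, collapse = ", ")))
    x
  }
  inst <- do.call(instrument_model,
                  check_keys(cfg$instrument %||% list(), instrument_model,
                             "instrument"))
  prot <- do.call(rotor_protocol,
                  check_keys(cfg$protocol %||% list(), rotor_protocol,
                             "protocol"))
  solv <- do.call(solvent,
                  check_keys(cfg$solvent %||% list(), solvent, "solvent"))
  sp <- purrr::map(cfg$species %||% list(), function(s) {
    s <- check_keys(s, species, "species",
                    extra = c("emission_center", "emission_fwhm"))
    if (!is.null(s$emission_center)) {
      s$emission <- gaussian_emission(s$emission_center,
                                      s$emission_fwhm %||% 50)
      s$emission_center <- NULL; s$emission_fwhm <- NULL
    }
    if (is.null(s$name)) s$name <- "species"
    do.call(species, s)
  })
  fit <- do.call(fit_config,
                 check_keys(cfg$fit %||% list(), fit_config, "fit"))
  list(instrument = inst, protocol = prot, solvent = solv, species = sp,
       fit = fit, simulate = cfg$simulate %||% list(),
       qc = cfg$qc %||% list(), raw = cfg)
}
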