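# Plain-format serialization: TIFF for rasters (normalized, with a JSON
# sidecar carrying the scale), PNG + JSON for binary masks, CSV for pattern
# stacks and measurement vectors, JSON manifests for everything.

#' Read and write masks, rasters, patterns and measurement bundles
#'
#' All artifacts are inspectable plain formats: binary masks as 8-bit
#' grayscale PNG plus a JSON sidecar (grid, power ratio), float rasters as
#' TIFF normalized to \[0, 1\] with the scale in the sidecar, pattern stacks
#' as row-per-pattern CSV of 0/1, measurements as one-column CSV in
#' acquisition order. A measurement bundle couples a pattern stack with its
#' aligned measurement vector and a manifest sufficient to regenerate it.
#'
#' @param mask,gray,image Matrices to write.
#' @param path File path (sidecars get `.json` appended).
#' @param patterns A [random_patterns()] set.
#' @param measurements A [acquire_measurements()] set or numeric vector.
#' @param dir Bundle directory.
#' @param meta Extra metadata stored in the manifest.
#' @return Writers return the path invisibly; readers return the object.
#' @name cfocus-io
NULL

#' @rdname cfocus-io
#' @export
write_mask_png <- function(mask, path, meta = list()) {
  mask <- as.matrix(mask) != 0
  png::writePNG(mask * 1, path)
  meta <- c(list(grid = dim(mask), on_count = sum(mask),
                 power_ratio = power_ratio(mask)), meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname cfocus-io
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' @rdname cfocus-io
#' @export
write_float_tiff <- function(image, path, meta = list()) {
  image <- as.matrix(image)
  mx <- max(abs(image))
  scaled <- if (mx > 0) image / mx else image
  tiff::writeTIFF(pmin(pmax(scaled, 0), 1), path, bits.per.sample = 16)
  meta <- c(list(scale = mx, dim = dim(image), clip_negative = any(image < 0)),
            meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname cfocus-io
#' @export
read_float_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m * meta$scale
}

#' @rdname cfocus-io
#' @export
write_pattern_csv <- function(patterns, path) {
  A <- pattern_matrix(patterns)
  utils::write.table(A, path, sep = ",", row.names = FALSE, col.names = FALSE)
  if (inherits(patterns, "pattern_set")) {
    jsonlite::write_json(list(grid = patterns$grid, sparsity = patterns$sparsity,
                              on_count = patterns$on_count, seed = patterns$seed,
                              n = nrow(A)),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname cfocus-io
#' @export
read_pattern_csv <- function(path) {
  A <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(A) <- NULL
  if (!all(A %in% c(0, 1))) stopf("pattern file contains non-binary values")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    structure(list(patterns = A, grid = as.integer(meta$grid),
                   sparsity = meta$sparsity, on_count = meta$on_count,
                   seed = meta$seed),
              class = "pattern_set")
  } else A
}

#' @rdname cfocus-io
#' @export
save_measurement_bundle <- function(patterns, measurements, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pattern_csv(patterns, file.path(dir, "patterns.csv"))
  I <- measurement_vector(measurements)
  write.csv(data.frame(intensity = I), file.path(dir, "measurements.csv"),
            row.names = FALSE)
  manifest <- c(list(n_patterns = nrow(pattern_matrix(patterns)),
                     n_measurements = length(I)),
                if (inherits(measurements, "measurement_set"))
                  list(dwell_ms = measurements$dwell_ms,
                       total_time_s = measurements$total_time_s,
                       seed = measurements$seed),
                meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname cfocus-io
#' @export
load_measurement_bundle <- function(dir) {
  ps <- read_pattern_csv(file.path(dir, "patterns.csv"))
  I <- read.csv(file.path(dir, "measurements.csv"))$intensity
  n <- nrow(pattern_matrix(ps))
  if (length(I) != n)
    stopf("bundle mismatch: %d patterns but %d measurements", n, length(I))
  if (any(I < 0)) stopf("bundle contains negative intensities")
  list(patterns = ps, measurements = I,
       manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                      simplifyVector = TRUE))
}

# ---- fixtures ---------------------------------------------------------------

fixture_registry <- c("bead_weak", "bead_strong", "two_beads_memory_effect",
                      "filament_field", "attenuation_stack")

#' Deterministic on-disk test fixtures
#'
#' Generates small, fully reproducible experiment bundles (medium, phantom,
#' patterns and - for acquisition fixtures - measurements) standing in for
#' bead-through-skull experiments. Media and phantoms are synthetic; every
#' artifact carries a manifest with all seeds and parameters.
#'
#' Registry: `bead_weak` (mild single screen), `bead_strong` (strong
#' screen), `two_beads_memory_effect` (two beads separated beyond the
#' memory-effect range of a defocused screen), `filament_field` (filament
#' phantom), `attenuation_stack` (depth series with a configured EAL).
#'
#' @param name Fixture name (see registry above).
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param n_patterns Patterns for the acquisition fixtures (default 200).
#' @return The manifest list, invisibly; files under `dir`.
#' @export
make_fixture <- function(name, seed, dir, n_patterns = 200) {
  if (!name %in% fixture_registry)
    stopf("unknown fixture '%s' (known: %s)", name,
          paste(fixture_registry, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- optical_config(superpixels = 16, superpixel_size = 4, fft_grid = 128,
                        na = 0.8)
  corr <- 8 * cfg$focal_pitch
  manifest <- list(fixture = name, seed = seed,
                   cfg = list(superpixels = cfg$superpixels,
                              superpixel_size = cfg$superpixel_size,
                              fft_grid = cfg$fft_grid, na = cfg$na))
  if (name %in% c("bead_weak", "bead_strong")) {
    strength <- if (name == "bead_strong") 2.5 else 0.8
    med <- make_phase_screen(cfg, corr, strength, z_position = 30,
                             seed = derive_seed(seed, 1))
    ph <- make_phantom(cfg, "bead", extent = 32, diameter = 0.71)
    ps <- random_patterns(n_patterns, grid = cfg$superpixels, sparsity = 0.4,
                          seed = derive_seed(seed, 2))
    ms <- acquire_measurements(ps, med, cfg)
    save_measurement_bundle(ps, ms, dir, meta = manifest)
    write_float_tiff(med$screens[[1]]$phase, file.path(dir, "screen.tiff"),
                     meta = list(z = med$screens[[1]]$z, phase_std = strength,
                                 correlation_length = corr,
                                 seed = derive_seed(seed, 1)))
    write_float_tiff(ph$conc[, , 1], file.path(dir, "phantom.tiff"),
                     meta = list(kind = "bead", diameter = 0.71))
  } else if (name == "two_beads_memory_effect") {
    med <- make_phase_screen(cfg, corr, 2.0, z_position = 40,
                             seed = derive_seed(seed, 1))
    # memory-effect range is set by the screen correlation length; place the
    # beads well beyond it
    sep <- 3 * corr
    ph <- make_phantom(cfg, "bead_field", extent = 48, diameter = 0.71,
                       positions = rbind(c(-sep / 2, 0), c(sep / 2, 0)))
    stopifnot(sep > corr)  # generator self-check
    manifest$bead_separation_um <- sep
    manifest$memory_range_um <- corr
    write_float_tiff(ph$conc[, , 1], file.path(dir, "phantom.tiff"),
                     meta = list(kind = "two_beads", separation = sep))
    write_float_tiff(med$screens[[1]]$phase, file.path(dir, "screen.tiff"),
                     meta = list(z = 40, phase_std = 2.0,
                                 correlation_length = corr))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (name == "filament_field") {
    ph <- make_phantom(cfg, "filament", extent = 48, diameter = 1.5,
                       seed = derive_seed(seed, 3))
    write_float_tiff(ph$conc[, , 1], file.path(dir, "phantom.tiff"),
                     meta = list(kind = "filament", diameter = 1.5))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  } else if (name == "attenuation_stack") {
    eal <- 150
    depths <- seq(0, 300, by = 50)
    med <- make_phase_screen(cfg, corr, 0, z_position = 0,
                             seed = derive_seed(seed, 1), eal = eal)
    u <- transfer_vector(med, cfg)
    sig <- vapply(depths, function(z)
      mask_peak_signal(blank_mask(cfg$superpixels), u, equal_power = FALSE,
                       depth = z, eal = eal), 0)
    # generator self-check: signals follow the configured EAL exactly
    stopifnot(max(abs(sig / sig[1] - exp(-2 * depths / eal))) < 1e-6)
    write.csv(data.frame(depth_um = depths, signal = sig),
              file.path(dir, "stack.csv"), row.names = FALSE)
    manifest$eal_um <- eal
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest)
}
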