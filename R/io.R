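#' Persist a pattern stack to a directory container
#'
#' Writes the stack payload (`patterns.rds`) together with a YAML manifest
#' (`manifest.yaml`) describing the grid, normalisation, provenance, seed
#' and rotation metadata, so the stack round-trips exactly.
#'
#' @param stack A `pattern_stack`.
#' @param dir Directory to create/write into.
#' @return `dir`, invisibly.
#' @export
write_pattern_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "pattern_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(stack$patterns, file.path(dir, "patterns.rds"))
  meta <- list(np = stack$np, side = stack$grid$side,
               pitch = stack$grid$pitch, radius = stack$grid$radius,
               normalization = stack$normalization,
               provenance = stack$provenance,
               seed = stack$seed, rotation = stack$rotation)
  yaml::write_yaml(meta, file.path(dir, "manifest.yaml"), precision = 15)
  invisible(dir)
}

#' Read a pattern stack written by [write_pattern_stack()]
#'
#' @param dir Container directory.
#' @return A `pattern_stack`.
#' @export
read_pattern_stack <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  patterns <- readRDS(file.path(dir, "patterns.rds"))
  grid <- grid_spec(meta$side, meta$pitch, meta$radius)
  new_pattern_stack(patterns, grid, meta$normalization, meta$provenance,
                    seed = meta$seed, rotation = meta$rotation)
}

#' Export patterns as PNG images
#'
#' Each selected pattern is min-max normalised and written as a 16-bit
#' greyscale PNG.
#'
#' @param stack A `pattern_stack`.
#' @param dir Output directory.
#' @param which Indices of patterns to export (default: all).
#' @return The written paths, invisibly.
#' @export
export_patterns_png <- function(stack, dir, which = seq_len(stack$np)) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("package 'png' is required to export PNGs")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- stack$grid$side
  paths <- character(0)
  for (i in which) {
    m <- display_normalize(matrix(stack$patterns[i, ], s, s))
    path <- file.path(dir, sprintf("pattern_%04d.png", i))
    png::writePNG(m, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write measurements to CSV (with a YAML sidecar)
#'
#' Columns `pattern_id`, `signal`; the sidecar records `noise_sigma`,
#' `epsilon`, `isnr_db` and `seed`.
#'
#' @param measurements A `measurement_set`.
#' @param path CSV path; the sidecar is `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  stopifnot(inherits(measurements, "measurement_set"))
  df <- data.frame(pattern_id = seq_len(measurements$np),
                   signal = measurements$y)
  utils::write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(noise_sigma = measurements$noise_sigma,
                        epsilon = measurements$epsilon,
                        isnr_db = measurements$isnr_db,
                        seed = measurements$seed),
                   paste0(path, ".yaml"), precision = 15)
  invisible(path)
}

#' Read measurements written by [write_measurements()]
#'
#' @param path CSV path.
#' @return A `measurement_set`.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  new_measurement_set(df$signal, meta$noise_sigma %||% 0,
                      meta$epsilon, meta$isnr_db, meta$seed)
}

#' Write a reconstruction and its run report
#'
#' The image goes to `<name>.tiff` as 32-bit float if the `tiff` package is
#' available (falling back to `<name>.csv`), and a JSON report
#' (`<name>_report.json`) records the method, epsilon, iteration count,
#' final residual, convergence flag and traces.
#'
#' @param estimate An `image_estimate`.
#' @param dir Output directory.
#' @param name Basename for the files.
#' @return The image path, invisibly.
#' @export
write_reconstruction <- function(estimate, dir, name = estimate$method) {
  stopifnot(inherits(estimate, "image_estimate"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- if (requireNamespace("tiff", quietly = TRUE)) {
    p <- file.path(dir, paste0(name, ".tiff"))
    # 32-bit float samples: raw reconstruction values are stored as-is
    # (ghost images are signed), which writeTIFF warns about but supports
    suppressWarnings(tiff::writeTIFF(estimate$x, p, bits.per.sample = 32))
    p
  } else {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.table(estimate$x, p, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    p
  }
  report <- list(method = estimate$method, epsilon = estimate$epsilon,
                 iterations = estimate$iterations,
                 final_residual = estimate$final_residual,
                 converged = estimate$converged,
                 objective_trace = estimate$objective_trace,
                 feasibility_trace = estimate$feasibility_trace)
  jsonlite::write_json(report, file.path(dir, paste0(name, "_report.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(img_path)
}

#' Write a phantom (PNG + parameter record)
#'
#' @param phantom A `phantom`.
#' @param dir Output directory.
#' @param name Basename.
#' @return The parameter-record path, invisibly.
#' @export
write_phantom <- function(phantom, dir, name = phantom$kind) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (requireNamespace("png", quietly = TRUE))
    png::writePNG(phantom$image, file.path(dir, paste0(name, ".png")))
  saveRDS(phantom$image, file.path(dir, paste0(name, ".rds")))
  params <- rapply(phantom$params, function(p)
    if (is.matrix(p) || is.data.frame(p)) as.list(as.data.frame(p)) else p,
    how = "replace")
  meta_path <- file.path(dir, paste0(name, "_params.yaml"))
  yaml::write_yaml(list(kind = phantom$kind, side = phantom$grid$side,
                        radius = phantom$grid$radius, params = params),
                   meta_path, precision = 15)
  invisible(meta_path)
}
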