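#' Write a sensor-epochs container to a directory dataset
#'
#' Persists the epoched MEG data as a small self-describing container of
#' named datasets: `meta.json` carries the shapes, sampling rate, per-trial
#' labels and geometry; `data.bin` carries the `trial x channel x time`
#' array as little-endian float64 in column-major order.
#'
#' @param epochs A [sensor_epochs()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sensor_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format = "nvcouple-epochs-v1",
    dim = dim(epochs$data), rate = epochs$rate, eye = epochs$eye,
    labels = epochs$labels,
    sensor_positions = epochs$array$positions,
    sensor_orientations = epochs$array$orientations,
    sensor_radius = epochs$array$radius,
    head_center = epochs$head$center, head_radius = epochs$head$radius)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  invisible(dir)
}

#' Read a sensor-epochs container written by [write_sensor_epochs()]
#'
#' @param dir Container directory.
#' @return A [sensor_epochs()] object.
#' @export
read_sensor_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "nvcouple-epochs-v1")) {
    abort("not an nvcouple epochs container")
  }
  n <- prod(meta$dim)
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  data <- array(readBin(con, "double", n, size = 8L, endian = "little"),
                dim = meta$dim)
  arr <- structure(list(positions = meta$sensor_positions,
                        orientations = meta$sensor_orientations,
                        radius = meta$sensor_radius,
                        center = meta$head_center),
                   class = "sensor_array")
  sensor_epochs(data, meta$rate, tibble::as_tibble(meta$labels), arr,
                head_model(meta$head_center, meta$head_radius), meta$eye)
}

#' Write a dual-echo ASL acquisition as NIfTI plus a sidecar
#'
#' One NIfTI file per echo plus a JSON sidecar with TR, tag/control parity
#' and the block schedule.
#'
#' @param asl List with `echo1` and `echo2` [asl_series()] (as from
#'   [simulate_asl()]).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_asl_series <- function(asl, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (e in 1:2) {
    s <- asl[[paste0("echo", e)]]
    RNifti::writeNifti(RNifti::asNifti(s$volumes, pixdim = c(rep(1, 3), s$tr)),
                       file.path(dir, sprintf("echo%d.nii.gz", e)))
  }
  sched <- asl$echo1$schedule
  jsonlite::write_json(list(
    format = "nvcouple-asl-v1", tr = asl$echo1$tr,
    parity = asl$echo1$parity, eye = attr(sched, "eye"),
    schedule = as.data.frame(sched),
    roi = which(as.vector(asl$geometry$roi)),
    dim = asl$geometry$dim),
    file.path(dir, "sidecar.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a dual-echo ASL acquisition written by [write_asl_series()]
#'
#' @param dir Container directory.
#' @return List with `echo1`, `echo2` and `geometry`.
#' @export
read_asl_series <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                              simplifyVector = TRUE)
  sched <- tibble::as_tibble(side$schedule)
  sched <- structure(sched, class = c("block_schedule", class(sched)),
                     eye = side$eye, total_s = sum(sched$duration))
  rd <- function(e) {
    vols <- array(as.array(RNifti::readNifti(
      file.path(dir, sprintf("echo%d.nii.gz", e)))),
      dim = c(side$dim, length(side$parity)))
    asl_series(vols, side$tr, e, side$parity, sched)
  }
  roi <- array(FALSE, side$dim)
  roi[side$roi] <- TRUE
  list(echo1 = rd(1), echo2 = rd(2),
       geometry = asl_geometry(side$dim, roi))
}

#' Write a gamma power-change map as NIfTI with a JSON peak report
#'
#' Resamples the scanned grid onto its bounding box and writes the percent
#' change volume plus a sidecar with the peak location and value.
#'
#' @param map A `gamma_power_map` from [scan_percent_change()].
#' @param path Output NIfTI path (`.nii` or `.nii.gz`); the peak report goes
#'   next to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_power_map <- function(map, path) {
  stopifnot(inherits(map, "gamma_power_map"))
  g <- map$grid
  ux <- sort(unique(g$locations[, 1]))
  uy <- sort(unique(g$locations[, 2]))
  uz <- sort(unique(g$locations[, 3]))
  vol <- array(NA_real_, c(length(ux), length(uy), length(uz)))
  idx <- cbind(match(g$locations[, 1], ux), match(g$locations[, 2], uy),
               match(g$locations[, 3], uz))
  vol[idx] <- map$map$pct
  RNifti::writeNifti(RNifti::asNifti(vol, pixdim = rep(g$spacing * 1000, 3)),
                     path)
  jsonlite::write_json(list(
    peak_loc_m = as.numeric(map$peak_loc),
    peak_pct = map$map$pct[map$peak_index],
    band_hz = map$band, lambda_reg = map$lambda_reg),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write a cohort results bundle
#'
#' Emits the derived tables (per-point measures, per-subject coupling fits,
#' group tests, ANOVA tables) as TSV plus a JSON summary, mirroring the
#' layout of a study results appendix.
#'
#' @param results An `nvc_results` from [group_statistics()].
#' @param measures The measures table the results were computed from.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results_bundle <- function(results, measures, dir) {
  stopifnot(inherits(results, "nvc_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(measures, "measures.tsv")
  wt(results$coupling, "coupling_fits.tsv")
  wt(results$coupling_tests, "coupling_tests.tsv")
  wt(results$simple_effects, "gamma_simple_effects.tsv")
  anova_tables <- purrr::imap_dfr(results$anova, function(a, nm) {
    dplyr::mutate(a$table, measure = nm, epsilon = a$epsilon, .before = 1)
  })
  wt(anova_tables, "anova.tsv")
  jsonlite::write_json(list(
    format = "nvcouple-results-v1",
    alpha = results$alpha,
    epsilon = purrr::map_dbl(results$anova, "epsilon"),
    files = c("measures.tsv", "coupling_fits.tsv", "coupling_tests.tsv",
              "gamma_simple_effects.tsv", "anova.tsv")),
    file.path(dir, "results.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
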