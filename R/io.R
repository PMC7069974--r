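# File formats: trajectories and titrations travel as plain CSV,
# kymographs and height maps as 32-bit float TIFF with a JSON sidecar
# carrying the physical calibration (TIFF stores values scaled to [0,1];
# the sidecar records the scale in nm or photons).

#' Write / read a particle trajectory as CSV
#'
#' Columns: `frame`, `time_s`, `position_nm`, `valid`, `sd_nm`.
#'
#' @param traj An `sm_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); an `sm_trajectory` (reader).
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "sm_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  dt <- stats::median(diff(df$time_s))
  trajectory(df$position_nm, as.logical(df$valid), dt, df$sd_nm)
}

#' Write / read a binding titration as CSV
#'
#' Columns `protein_nM`, `fraction_bound_pct`; the DNA concentration is
#' carried in a `# dna_nM:` comment line.
#'
#' @param iso A [binding_isotherm()].
#' @param path CSV path.
#' @return `path`, invisibly (writer); a [binding_isotherm()] (reader).
#' @export
write_titration_csv <- function(iso, path) {
  stopifnot(inherits(iso, "binding_isotherm"))
  con <- file(path, "w")
  writeLines(sprintf("# dna_nM: %.6g", attr(iso, "dna_nM")), con)
  utils::write.csv(as.data.frame(iso), con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_titration_csv
#' @export
read_titration_csv <- function(path) {
  first <- readLines(path, n = 1)
  dna <- if (grepl("^# dna_nM:", first))
    as.numeric(sub("^# dna_nM:", "", first)) else 8
  df <- utils::read.csv(path, comment.char = "#")
  binding_isotherm(df$protein_nM, df$fraction_bound_pct, dna)
}

.write_scaled_tiff <- function(values, path, sidecar_extra = list()) {
  lo <- min(values); hi <- max(values)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((values - lo) / scale, path, bits.per.sample = 32)
  side <- c(list(offset = lo, scale = scale), sidecar_extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.read_scaled_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- tiff::readTIFF(path) * side$scale + side$offset
  list(values = vals, sidecar = side)
}

#' Write / read an AFM height map as TIFF plus JSON sidecar
#'
#' @param map A [height_map()].
#' @param path TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly (writer); a [height_map()] (reader).
#' @export
write_height_map <- function(map, path) {
  stopifnot(inherits(map, "height_map"))
  .write_scaled_tiff(map$heights, path,
                     list(pixel_size_nm = map$pixel_size_nm,
                          units = "nm"))
}

#' @rdname write_height_map
#' @export
read_height_map <- function(path) {
  x <- .read_scaled_tiff(path)
  height_map(x$values, x$sidecar$pixel_size_nm)
}

#' Write / read a kymograph as TIFF plus JSON sidecar
#'
#' @param kymo A [kymograph()].
#' @param path TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly (writer); a [kymograph()] (reader).
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  .write_scaled_tiff(kymo$intensity, path,
                     list(pixel_size_nm = kymo$pixel_size_nm,
                          frame_interval_s = kymo$frame_interval_s))
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  x <- .read_scaled_tiff(path)
  kymograph(x$values, x$sidecar$pixel_size_nm, x$sidecar$frame_interval_s)
}

#' Write an analysis report as JSON
#'
#' Serializes a [run_tightrope_pipeline()] / [run_afm_pipeline()] report
#' (including its manifest) to JSON.
#'
#' @param report A report list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(path)
}
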