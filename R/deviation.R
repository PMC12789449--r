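#' Euclidean deviation magnitude
#'
#' `sqrt(dx^2 + dy^2 + dz^2)`: the 3D distance corresponding to a triple of
#' per-axis positional deviations. Vectorised over its arguments.
#'
#' @param dx,dy,dz per-axis deviations, mm.
#' @return Deviation magnitude(s), mm (>= 0).
#' @examples
#' deviation_magnitude(3, 4, 0)  # 5
#' @export
deviation_magnitude <- function(dx, dy, dz) {
  if (!all(is.finite(dx), is.finite(dy), is.finite(dz))) {
    stop("deviation components must be finite", call. = FALSE)
  }
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Angle between two implant long axes
#'
#' Unsigned 3D angle between two unit axes (both oriented coronal to
#' apical), in degrees, range [0, 180].
#'
#' @param axis_planned,axis_placed unit 3-vectors (`|norm - 1| < 1e-6`).
#' @return Angle in degrees.
#' @examples
#' angular_deviation(c(0, 0, 1), c(0, sin(pi / 90), cos(pi / 90)))  # 2 degrees
#' @export
angular_deviation <- function(axis_planned, axis_placed) {
  axis_planned <- as.numeric(axis_planned)
  axis_placed <- as.numeric(axis_placed)
  if (length(axis_planned) != 3 || length(axis_placed) != 3 ||
      abs(sqrt(sum(axis_planned^2)) - 1) > 1e-6 ||
      abs(sqrt(sum(axis_placed^2)) - 1) > 1e-6) {
    stop("axes must be unit 3-vectors", call. = FALSE)
  }
  d <- max(-1, min(1, sum(axis_planned * axis_placed)))
  acos(d) * 180 / pi
}

#' Per-implant deviation record
#'
#' Compares a planned and a placed implant pose (in the same registered
#' coordinate frame) and returns one row of the standard guided-surgery
#' accuracy table: signed per-axis differences (placed minus planned) at the
#' coronal and apical centres, the two deviation magnitudes
#' (`deviation_a` = coronal, `deviation_b` = apical) and the angular
#' deviation of the long axes.
#'
#' @param planned,placed [implant_pose()] objects in a common frame.
#' @param block model / block identifier.
#' @param position implant position label (e.g. "a".."d").
#' @return A one-row data frame with columns `block`, `position`,
#'   `dx_coronal`, `dy_coronal`, `dz_coronal`, `dx_apical`, `dy_apical`,
#'   `dz_apical`, `deviation_a`, `deviation_b`, `angle_error`.
#' @export
compare_implants <- function(planned, placed, block = NA, position = NA) {
  stopifnot(is_implant_pose(planned), is_implant_pose(placed))
  dc <- placed$coronal - planned$coronal
  da <- placed$apical - planned$apical
  data.frame(
    block = block, position = position,
    dx_coronal = dc[1], dy_coronal = dc[2], dz_coronal = dc[3],
    dx_apical = da[1], dy_apical = da[2], dz_apical = da[3],
    deviation_a = deviation_magnitude(dc[1], dc[2], dc[3]),
    deviation_b = deviation_magnitude(da[1], da[2], da[3]),
    angle_error = angular_deviation(planned$axis, placed$axis),
    stringsAsFactors = FALSE)
}

# canonical <-> published column names for the per-implant table
table1_columns <- c(
  block = "Block", position = "Position",
  deviation_a = "Coronal Deviation A (mm)",
  deviation_b = "Apical Deviation B (mm)",
  angle_error = "Angle Error (Degrees)")
component_columns <- c("dx_coronal", "dy_coronal", "dz_coronal",
                       "dx_apical", "dy_apical", "dz_apical")

#' Write a per-implant deviation table
#'
#' Writes deviation records as CSV with the published column set (`Block`,
#' `Position`, `Coronal Deviation A (mm)`, `Apical Deviation B (mm)`,
#' `Angle Error (Degrees)`), optionally keeping the signed XYZ component
#' columns. Values are written at full precision.
#'
#' @param records data frame as returned by [compare_implants()] (rows
#'   bound together), or at minimum with the canonical metric columns.
#' @param path output CSV path.
#' @param components keep the per-axis component columns (default: write
#'   them when present).
#' @return `path`, invisibly.
#' @export
write_deviation_table <- function(records, path,
                                  components = all(component_columns %in%
                                                     names(records))) {
  need <- names(table1_columns)
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- records[need]
  names(out) <- unname(table1_columns)
  if (components) out <- cbind(out, records[component_columns])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a per-implant deviation table
#'
#' Reads a CSV in the published layout (see [write_deviation_table()]) into
#' canonical column names (`block`, `position`, `deviation_a`,
#' `deviation_b`, `angle_error`, plus any per-axis component columns
#' present).
#'
#' @param path CSV file path.
#' @return A data frame of deviation records.
#' @export
read_deviation_table <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  pub2canon <- stats::setNames(names(table1_columns), table1_columns)
  hit <- names(d) %in% names(pub2canon)
  names(d)[hit] <- pub2canon[names(d)[hit]]
  need <- names(table1_columns)
  if (!all(need %in% names(d))) {
    stop("not a deviation table: missing columns ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  d$position <- tolower(as.character(d$position))
  d
}

#' Packaged per-implant study table
#'
#' The packaged 40-implant deviation table from the in-vitro comparison of a
#' screw-retained (blocks 1-5) versus a mucosa-supported (blocks 6-10)
#' edentulous surgical guide: four implants (positions a-d) in each of ten
#' mandible models, with coronal deviation A, apical deviation B and angular
#' deviation per implant.
#'
#' @return A data frame of 40 deviation records.
#' @examples
#' head(example_deviation_table())
#' @export
example_deviation_table <- function() {
  read_deviation_table(system.file("extdata", "deviation_table.csv",
                                   package = "implacc", mustWork = TRUE))
}
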