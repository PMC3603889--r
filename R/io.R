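#' Write a surface mesh as Wavefront OBJ
#'
#' @param vertices n x 3 matrix, metres.
#' @param triangles m x 3 integer matrix (1-based).
#' @param path output file.
#' @export
write_obj <- function(vertices, triangles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", vertices[, 1], vertices[, 2],
                     vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", triangles[, 1], triangles[, 2],
                     triangles[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ surface mesh
#'
#' Only `v` and triangular `f` records are interpreted.
#'
#' @param path OBJ file.
#' @return List with `vertices` and `triangles`.
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  vs <- ln[startsWith(ln, "v ")]
  fs <- ln[startsWith(ln, "f ")]
  vertices <- do.call(rbind, lapply(strsplit(vs, "\\s+"), function(x)
    as.numeric(x[2:4])))
  triangles <- do.call(rbind, lapply(strsplit(fs, "\\s+"), function(x)
    as.integer(sub("/.*", "", x[2:4]))))
  list(vertices = vertices, triangles = triangles)
}

#' Write a sensor layout as TSV
#'
#' Columns: name, x, y, z, ox, oy, oz (metres / unit orientation).
#'
#' @param sensors a `dba_sensor_array`.
#' @param path output file.
#' @export
write_sensors_tsv <- function(sensors, path) {
  d <- data.frame(name = sprintf("MEG%03d", seq_len(nrow(sensors$positions))),
                  x = sensors$positions[, 1], y = sensors$positions[, 2],
                  z = sensors$positions[, 3],
                  ox = sensors$orientations[, 1],
                  oy = sensors$orientations[, 2],
                  oz = sensors$orientations[, 3])
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sensor layout TSV written by [write_sensors_tsv()]
#'
#' @param path TSV file.
#' @param sphere_center,sphere_radius conductor geometry to attach; the
#'   radius defaults to the mean sensor distance from the centre.
#' @return A `dba_sensor_array`.
#' @export
read_sensors_tsv <- function(path, sphere_center = c(0, 0, 0),
                             sphere_radius = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  pos <- as.matrix(d[, c("x", "y", "z")])
  if (is.null(sphere_radius))
    sphere_radius <- mean(row_norms(sweep(pos, 2, sphere_center)))
  structure(list(positions = pos,
                 orientations = as.matrix(d[, c("ox", "oy", "oz")]),
                 sphere_center = sphere_center,
                 sphere_radius = sphere_radius),
            class = "dba_sensor_array")
}

#' Export a per-source map as TSV
#'
#' Columns: source_id, structure, value. Works for sensitivity maps,
#' resolution maps and raw vectors.
#'
#' @param values per-source values, or a `dba_sensitivity` /
#'   `dba_resolution_map` object.
#' @param space the source space (for structure labels).
#' @param path output file.
#' @export
write_source_map_tsv <- function(values, space, path) {
  if (is.list(values)) values <- values$values
  d <- data.frame(source_id = seq_along(values),
                  structure = space$structure_labels, value = values)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
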