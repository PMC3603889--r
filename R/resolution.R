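#' Point-spread function map of a source
#'
#' Absolute values of the resolution-matrix column of the given source:
#' how a unit point source at that location is imaged over the whole
#' source space by the inverse operator.
#'
#' @param R a [resolution_matrix()].
#' @param source_index source whose PSF is mapped.
#' @param normalize divide by the maximum (default `TRUE`).
#' @return Object of class `dba_resolution_map`: `kind = "psf"`,
#'   `source_scope`, `values`, `normalized`.
#' @export
psf_map <- function(R, source_index, normalize = TRUE) {
  Rm <- resolution_values(R)
  if (source_index < 1 || source_index > ncol(Rm)) stop("invalid index")
  v <- abs(Rm[, source_index])
  if (normalize && max(v) > 0) v <- v / max(v)
  structure(list(kind = "psf", source_scope = source_index, values = v,
                 normalized = normalize),
            class = "dba_resolution_map")
}

#' Cross-talk function map of a source
#'
#' Absolute values of the resolution-matrix row of the given source: how
#' strongly activity at every other location leaks into this source's
#' estimate. CTF shapes are identical across minimum-norm, dSPM and
#' sLORETA kernels because the noise normalisations only rescale rows.
#'
#' @inheritParams psf_map
#' @return `dba_resolution_map` with `kind = "ctf"`.
#' @export
ctf_map <- function(R, source_index, normalize = TRUE) {
  Rm <- resolution_values(R)
  if (source_index < 1 || source_index > nrow(Rm)) stop("invalid index")
  v <- abs(Rm[source_index, ])
  if (normalize && max(v) > 0) v <- v / max(v)
  structure(list(kind = "ctf", source_scope = source_index, values = v,
                 normalized = normalize),
            class = "dba_resolution_map")
}

#' Average resolution maps over a structure
#'
#' Normalises each map to unit maximum, averages elementwise, and
#' renormalises, mirroring how per-source PSF maps are pooled into a
#' structure-level map.
#'
#' @param maps list of `dba_resolution_map` objects on the same source
#'   space.
#' @return A `dba_resolution_map` with `source_scope = "average"`.
#' @export
average_structure_map <- function(maps) {
  if (length(maps) == 0) stop("empty structure: no maps to average")
  vals <- vapply(maps, function(m) {
    v <- m$values
    if (max(v) > 0) v / max(v) else v
  }, numeric(length(maps[[1]]$values)))
  avg <- rowMeans(vals)
  if (max(avg) > 0) avg <- avg / max(avg)
  structure(list(kind = maps[[1]]$kind, source_scope = "average",
                 values = avg, normalized = TRUE),
            class = "dba_resolution_map")
}

#' Threshold a resolution map
#'
#' Keeps only values at or above a fraction of the map maximum (others
#' set to zero); the maximum itself always survives.
#'
#' @param map a `dba_resolution_map`.
#' @param threshold_fraction default 0.5.
#' @return The thresholded map.
#' @export
threshold_map <- function(map, threshold_fraction = 0.5) {
  v <- map$values
  v[v < threshold_fraction * max(v)] <- 0
  map$values <- v
  map$threshold_fraction <- threshold_fraction
  map
}
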