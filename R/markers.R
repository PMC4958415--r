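#' Labelled fiducial marker sets
#'
#' A `marker_set` is a labelled set of 3D bead coordinates (world mm)
#' belonging to one rigid body, either the pelvis or the cup. It is a
#' data frame with columns `marker_id`, `x`, `y`, `z` plus `body` and
#' `source` attributes. `source` records provenance: `"ground_truth"`
#' (simulated), `"detected"` (CT bead detection) or `"reconstructed"`
#' (stereo X-ray reconstruction).
#'
#' @param coords An n x 3 matrix of world coordinates (mm).
#' @param body `"pelvis"` or `"cup"`.
#' @param ids Unique marker labels; default `"p1"`, `"p2"`, ... /
#'   `"c1"`, ... according to body.
#' @param source Provenance tag.
#' @return A `marker_set`.
#' @examples
#' ms <- marker_set(matrix(rnorm(9), 3, 3), body = "cup")
#' marker_coords(ms)
#' @export
marker_set <- function(coords, body = c("pelvis", "cup"), ids = NULL,
                       source = c("ground_truth", "detected",
                                  "reconstructed")) {
  body <- match.arg(body)
  source <- match.arg(source)
  coords <- as_point_matrix(coords)
  if (any(!is.finite(coords)))
    stop("marker coordinates must be finite", call. = FALSE)
  n <- nrow(coords)
  if (is.null(ids))
    ids <- paste0(substr(body, 1, 1), seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("one id per marker required", call. = FALSE)
  if (anyDuplicated(ids))
    stop("marker ids must be unique within a set", call. = FALSE)
  out <- data.frame(marker_id = ids, x = coords[, 1], y = coords[, 2],
                    z = coords[, 3], stringsAsFactors = FALSE)
  structure(out, body = body, source = source,
            class = c("marker_set", "data.frame"))
}

#' @rdname marker_set
#' @param ms A `marker_set`.
#' @export
marker_coords <- function(ms) {
  m <- as.matrix(ms[, c("x", "y", "z")])
  rownames(m) <- ms$marker_id
  m
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> body=%s, source=%s, %d markers\n",
              attr(x, "body"), attr(x, "source"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

# subset a marker_set by id, preserving attributes
subset_markers <- function(ms, ids) {
  keep <- match(ids, ms$marker_id)
  if (anyNA(keep))
    stop(sprintf("marker ids not present: %s",
                 paste(ids[is.na(keep)], collapse = ", ")), call. = FALSE)
  marker_set(marker_coords(ms)[keep, , drop = FALSE], body = attr(ms, "body"),
             ids = ms$marker_id[keep], source = attr(ms, "source"))
}

# replace coordinates, keeping labels/attributes
set_marker_coords <- function(ms, coords) {
  marker_set(coords, body = attr(ms, "body"), ids = ms$marker_id,
             source = attr(ms, "source"))
}

#' Read and write marker tables
#'
#' Marker tables are plain CSV with columns
#' `body, marker_id, x_mm, y_mm, z_mm`. One file may hold several bodies;
#' `read_markers()` returns a named list of [marker_set()] objects, one per
#' body present.
#'
#' @param path CSV file path.
#' @param source Provenance tag attached to the sets read.
#' @return `read_markers()`: named list of [marker_set()]s.
#' @export
read_markers <- function(path, source = "ground_truth") {
  if (!file.exists(path))
    stop(sprintf("marker table '%s' does not exist", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("body", "marker_id", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop(sprintf("marker table '%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  out <- lapply(split(df, df$body), function(part) {
    marker_set(as.matrix(part[, c("x_mm", "y_mm", "z_mm")]),
               body = part$body[1], ids = part$marker_id, source = source)
  })
  out[order(names(out), decreasing = TRUE)] # pelvis first
}

#' @rdname read_markers
#' @param markers A [marker_set()] or a (possibly named) list of them.
#' @export
write_markers <- function(markers, path) {
  if (inherits(markers, "marker_set")) markers <- list(markers)
  rows <- lapply(markers, function(ms) {
    data.frame(body = attr(ms, "body"), marker_id = ms$marker_id,
               x_mm = ms$x, y_mm = ms$y, z_mm = ms$z,
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
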