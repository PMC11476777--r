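# Plain-text mesh readers/writers: ascii PLY and OFF for geometry, legacy
# VTK (POLYDATA) for snapshots carrying scalar fields. Coordinates are
# written with 17 significant digits so a write/read round trip is
# bit-identical for doubles.

num17 <- function(x) sprintf("%.17g", x)

#' Write a mesh to an ascii PLY or OFF file
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @param format `"ply"` or `"off"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "off")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.off$", path, ignore.case = TRUE)) "off" else "ply"
  n <- nrow(mesh$V); m <- nrow(mesh$F)
  vl <- paste(num17(mesh$V[, 1]), num17(mesh$V[, 2]), num17(mesh$V[, 3]))
  fl <- paste(3L, mesh$F[, 1] - 1L, mesh$F[, 2] - 1L, mesh$F[, 3] - 1L)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", n),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", m),
                 "property list uchar int vertex_indices",
                 "end_header", vl, fl), con)
  } else {
    writeLines(c("OFF", sprintf("%d %d 0", n, m), vl, fl), con)
  }
  invisible(path)
}

#' Read a mesh from an ascii PLY or OFF file
#'
#' Rest state is initialised from the geometry as read (the file carries
#' only positions and connectivity).
#'
#' @param path input file path.
#' @return a `surface_mesh`.
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (identical(lines[1], "ply")) {
    hdr_end <- which(lines == "end_header")[1]
    hdr <- lines[seq_len(hdr_end)]
    n <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
    m <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
    body <- lines[(hdr_end + 1):length(lines)]
  } else if (identical(toupper(lines[1]), "OFF")) {
    counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    n <- counts[1]; m <- counts[2]
    body <- lines[-(1:2)]
  } else stop("unrecognised mesh format (expected ascii PLY or OFF): ", path)
  vparts <- do.call(rbind, strsplit(trimws(body[seq_len(n)]), "\\s+"))
  V <- matrix(as.numeric(vparts[, 1:3]), n, 3)
  fparts <- do.call(rbind, strsplit(trimws(body[n + seq_len(m)]), "\\s+"))
  if (any(fparts[, 1] != "3")) stop("non-triangular face in ", path)
  F <- matrix(as.integer(fparts[, 2:4]), m, 3) + 1L
  surface_mesh(V, F)
}

#' Write a simulation snapshot as a legacy VTK file
#'
#' Writes geometry plus per-vertex scalar fields (e.g. active Cdc42
#' concentration) and per-face fields (region label, cue value, growth
#' eligibility) in legacy VTK POLYDATA format, readable by ParaView.
#'
#' @param mesh a `surface_mesh`.
#' @param path output `.vtk` path.
#' @param point_data named list of numeric per-vertex vectors.
#' @param cell_data named list of numeric per-face vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$V); m <- nrow(mesh$F)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "budmorph snapshot", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n),
               paste(num17(mesh$V[, 1]), num17(mesh$V[, 2]), num17(mesh$V[, 3])),
               sprintf("POLYGONS %d %d", m, 4L * m),
               paste(3L, mesh$F[, 1] - 1L, mesh$F[, 2] - 1L, mesh$F[, 3] - 1L)), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      stopifnot(length(point_data[[nm]]) == n)
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default",
                   num17(as.numeric(point_data[[nm]]))), con)
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      stopifnot(length(cell_data[[nm]]) == m)
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default",
                   num17(as.numeric(cell_data[[nm]]))), con)
    }
  }
  invisible(path)
}
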