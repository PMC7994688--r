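# Legacy ASCII VTK polydata reader/writer for skeleton meshes.  Point-data
# arrays carried: NORMALS "normal", SCALARS "half_thickness", plus any
# extra per-vertex scalar arrays (t maps, cluster labels) for
# visualization.  Numbers are written with 17 significant digits so that a
# write -> read round trip is lossless at double precision.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a skeleton mesh as legacy VTK polydata
#'
#' @param mesh a `skeleton_mesh`.
#' @param path output file path (ASCII `.vtk`).
#' @param point_data optional named list of extra per-vertex numeric
#'   arrays written as SCALARS.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, point_data = NULL) {
  validate_mesh(mesh)
  n <- nrow(mesh$vertices); m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(..., con = con)
  wl("# vtk DataFile Version 3.0")
  wl(sprintf("tractsa skeleton tract=%s", mesh$tract))
  wl("ASCII")
  wl("DATASET POLYDATA")
  wl(sprintf("POINTS %d double", n))
  wl(apply(mesh$vertices, 1, function(v) paste(fmt_num(v), collapse = " ")))
  wl(sprintf("POLYGONS %d %d", m, 4 * m))
  wl(apply(mesh$triangles, 1, function(tr)
    paste(c(3, tr - 1L), collapse = " ")))
  wl(sprintf("POINT_DATA %d", n))
  wl("NORMALS normal double")
  wl(apply(mesh$normals, 1, function(v) paste(fmt_num(v), collapse = " ")))
  wl("SCALARS half_thickness double 1")
  wl("LOOKUP_TABLE default")
  wl(fmt_num(mesh$half_thickness))
  for (nm in names(point_data)) {
    wl(sprintf("SCALARS %s double 1", nm))
    wl("LOOKUP_TABLE default")
    wl(fmt_num(as.numeric(point_data[[nm]])))
  }
  invisible(path)
}

#' Read a legacy VTK polydata skeleton mesh
#'
#' Accepts ASCII legacy polydata with POINTS, POLYGONS (triangles only)
#' and POINT_DATA carrying a `normal` NORMALS array and a
#' `half_thickness` SCALARS array; extra SCALARS arrays are returned in
#' attribute `"point_data"`.
#'
#' @param path file path.
#' @param tract tract name to assign (default: parsed from the title line
#'   when present, else the file stem).
#' @return a `skeleton_mesh`.
#' @export
read_vtk_mesh <- function(path, tract = NULL) {
  if (!file.exists(path))
    abort(sprintf("no such file: %s", path), "tractsa_io_error")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5 || !grepl("^# vtk DataFile", lines[1]))
    abort(sprintf("%s: not a legacy VTK file (bad magic at line 1)", path),
          "tractsa_vtk_error")
  if (is.null(tract)) {
    m <- regmatches(lines[2], regexec("tract=(\\S+)", lines[2]))[[1]]
    tract <- if (length(m) == 2) m[2] else sub("\\.vtk$", "", basename(path))
  }
  if (toupper(trimws(lines[3])) != "ASCII")
    abort(sprintf("%s: only ASCII legacy VTK is supported (line 3)", path),
          "tractsa_vtk_error")
  if (!grepl("POLYDATA", lines[4]))
    abort(sprintf("%s: DATASET POLYDATA expected at line 4", path),
          "tractsa_vtk_error")
  i <- 5
  toks_after <- function(i, count) {
    # collect `count` whitespace-separated numbers starting at line i
    vals <- numeric(0)
    while (length(vals) < count) {
      if (i > length(lines))
        abort(sprintf("%s: truncated at line %d", path, i), "tractsa_vtk_error")
      vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      i <- i + 1
    }
    list(vals = vals, nexti = i)
  }
  verts <- NULL; tris <- NULL; normals <- NULL; ht <- NULL
  extra <- list()
  npts <- NA_integer_
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1; next }
    f <- strsplit(ln, "\\s+")[[1]]
    key <- toupper(f[1])
    if (key == "POINTS") {
      npts <- as.integer(f[2])
      r <- toks_after(i + 1, 3 * npts)
      verts <- matrix(r$vals, ncol = 3, byrow = TRUE)
      i <- r$nexti
    } else if (key == "POLYGONS") {
      m <- as.integer(f[2])
      r <- toks_after(i + 1, as.integer(f[3]))
      raw <- matrix(r$vals, ncol = 4, byrow = TRUE)
      if (any(raw[, 1] != 3))
        abort(sprintf("%s: non-triangle polygon near line %d", path, i),
              "tractsa_vtk_error")
      tris <- raw[, 2:4, drop = FALSE] + 1L
      i <- r$nexti
    } else if (key == "POINT_DATA") {
      if (as.integer(f[2]) != npts)
        abort(sprintf("%s: POINT_DATA count mismatch at line %d", path, i),
              "tractsa_vtk_error")
      i <- i + 1
    } else if (key == "NORMALS") {
      r <- toks_after(i + 1, 3 * npts)
      normals <- matrix(r$vals, ncol = 3, byrow = TRUE)
      i <- r$nexti
    } else if (key == "SCALARS") {
      nm <- f[2]
      i <- i + 1
      if (i <= length(lines) && grepl("^LOOKUP_TABLE", trimws(lines[i]),
                                      ignore.case = TRUE)) i <- i + 1
      r <- toks_after(i, npts)
      if (nm == "half_thickness") ht <- r$vals else extra[[nm]] <- r$vals
      i <- r$nexti
    } else {
      abort(sprintf("%s: unsupported section '%s' at line %d", path, f[1], i),
            "tractsa_vtk_error")
    }
  }
  if (is.null(verts) || is.null(tris))
    abort(sprintf("%s: missing POINTS or POLYGONS", path), "tractsa_vtk_error")
  if (is.null(normals) || is.null(ht))
    abort(sprintf("%s: missing 'normal' or 'half_thickness' point data", path),
          "tractsa_vtk_error")
  mesh <- skeleton_mesh(tract, verts, tris, normals, ht)
  if (length(extra)) attr(mesh, "point_data") <- extra
  mesh
}
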