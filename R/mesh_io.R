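#' Read a triangle mesh from file
#'
#' Supports STL (ASCII and binary), OFF and PLY (ASCII). Coordinates are
#' taken to be millimetres by contract; no unit metadata is read or written.
#' Winding is returned as stored in the file; use [validate_mesh()] /
#' [orient_outward()] to enforce outward orientation.
#'
#' @param path file path.
#' @param format `"auto"` (from extension) or one of `"stl"`, `"off"`,
#'   `"ply"`.
#' @param weld merge duplicate vertices (STL stores one vertex per corner,
#'   so welding defaults to `TRUE` for STL).
#' @return a `trimesh`.
#' @export
read_mesh <- function(path, format = c("auto", "stl", "off", "ply"),
                      weld = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_mesh: file not found: ", path)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("stl", "off", "ply"))
      stop("read_mesh: cannot infer format from extension '", format, "'")
  }
  switch(format,
         stl = read_stl(path, weld = if (is.null(weld)) TRUE else weld),
         off = read_off(path),
         ply = read_ply(path))
}

#' Write a triangle mesh to file
#'
#' @param mesh a `trimesh`.
#' @param path output path.
#' @param format `"auto"` (from extension) or `"stl"`, `"off"`, `"ply"`.
#' @param binary write binary STL (ignored for OFF/PLY, which are ASCII).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "off", "ply"),
                       binary = FALSE) {
  stopifnot(is_trimesh(mesh))
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("stl", "off", "ply"))
      stop("write_mesh: cannot infer format from extension")
  }
  switch(format,
         stl = write_stl(mesh, path, binary = binary),
         off = write_off(mesh, path),
         ply = write_ply(mesh, path))
  invisible(path)
}

# -- STL ------------------------------------------------------------------

read_stl <- function(path, weld = TRUE) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80L)
  close(con)
  # ASCII STL starts with "solid" and contains "facet" soon after; binary
  # files may also start with "solid", so check the triangle count instead.
  is_ascii <- identical(rawToChar(head[1:5]), "solid")
  if (is_ascii) {
    sz <- file.size(path)
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80L)
    if (sz >= 84L) {
      ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      if (!is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)) is_ascii <- FALSE
    }
  }
  if (is_ascii) read_stl_ascii(path, weld) else read_stl_binary(path, weld)
}

read_stl_ascii <- function(path, weld) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("read_mesh: malformed ASCII STL (vertex count not multiple of 3)")
  toks <- strsplit(trimws(vl), "\\s+")
  if (any(lengths(toks) != 4L)) stop("read_mesh: malformed STL vertex line")
  v <- matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))), ncol = 3L,
              byrow = TRUE)
  if (anyNA(v)) stop("read_mesh: non-numeric STL vertex")
  f <- matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE)
  trimesh(v, f, weld = weld, weld_tol = 1e-7)
}

read_stl_binary <- function(path, weld) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (sz != 84 + 50 * as.numeric(ntri))
    stop("read_mesh: corrupt binary STL (size mismatch)")
  rec <- readBin(con, "raw", 50L * ntri)
  dim(rec) <- c(50L, ntri)
  fl <- apply(rec[1:48, , drop = FALSE], 2L, function(r)
    readBin(r, "numeric", 12L, size = 4L, endian = "little"))
  v <- matrix(as.numeric(fl[4:12, , drop = FALSE]), ncol = 3L, byrow = TRUE)
  f <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  trimesh(v, f, weld = weld, weld_tol = 1e-7)
}

write_stl <- function(mesh, path, binary = FALSE) {
  fc <- face_corners(mesh)
  fg <- face_geometry(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(mesh$faces)), con, size = 4L,
             endian = "little")
    for (i in seq_len(nrow(mesh$faces))) {
      writeBin(as.numeric(c(fg$normals[i, ], fc$a[i, ], fc$b[i, ],
                            fc$c[i, ])), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    out <- character(7L * nrow(mesh$faces) + 2L)
    out[1L] <- "solid mesh"
    k <- 2L
    fmt <- function(p) sprintf("%.9g %.9g %.9g", p[1L], p[2L], p[3L])
    for (i in seq_len(nrow(mesh$faces))) {
      out[k:(k + 6L)] <- c(
        paste0("  facet normal ", fmt(fg$normals[i, ])),
        "    outer loop",
        paste0("      vertex ", fmt(fc$a[i, ])),
        paste0("      vertex ", fmt(fc$b[i, ])),
        paste0("      vertex ", fmt(fc$c[i, ])),
        "    endloop",
        "  endfacet")
      k <- k + 7L
    }
    out[k] <- "endsolid mesh"
    writeLines(out, path)
  }
}

# -- OFF ------------------------------------------------------------------

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (toupper(trimws(lines[1L])) != "OFF")
    stop("read_mesh: not an OFF file")
  hd <- as.numeric(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  nv <- hd[1L]; nf <- hd[2L]
  vtok <- strsplit(trimws(lines[3:(2 + nv)]), "\\s+")
  v <- matrix(as.numeric(unlist(lapply(vtok, `[`, 1:3))), ncol = 3L,
              byrow = TRUE)
  ftok <- strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]), "\\s+")
  cnt <- as.integer(vapply(ftok, `[`, "", 1L))
  if (any(cnt != 3L))
    stop("read_mesh: OFF contains non-triangular faces")
  f <- matrix(as.integer(unlist(lapply(ftok, `[`, 2:4))), ncol = 3L,
              byrow = TRUE) + 1L
  trimesh(v, f)
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1L] - 1L,
                     mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
}

# -- PLY (ASCII) ----------------------------------------------------------

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (trimws(lines[1L]) != "ply") stop("read_mesh: not a PLY file")
  endh <- which(trimws(lines) == "end_header")[1L]
  if (is.na(endh)) stop("read_mesh: PLY header not terminated")
  header <- lines[1:endh]
  if (!any(grepl("format\\s+ascii", header)))
    stop("read_mesh: only ASCII PLY is supported")
  nv <- as.integer(sub(".*element\\s+vertex\\s+(\\d+).*", "\\1",
                       grep("element\\s+vertex", header, value = TRUE)[1L]))
  nf <- as.integer(sub(".*element\\s+face\\s+(\\d+).*", "\\1",
                       grep("element\\s+face", header, value = TRUE)[1L]))
  vtok <- strsplit(trimws(lines[(endh + 1):(endh + nv)]), "\\s+")
  v <- matrix(as.numeric(unlist(lapply(vtok, `[`, 1:3))), ncol = 3L,
              byrow = TRUE)
  ftok <- strsplit(trimws(lines[(endh + nv + 1):(endh + nv + nf)]), "\\s+")
  cnt <- as.integer(vapply(ftok, `[`, "", 1L))
  if (any(cnt != 3L))
    stop("read_mesh: PLY contains non-triangular faces")
  f <- matrix(as.integer(unlist(lapply(ftok, `[`, 2:4))), ncol = 3L,
              byrow = TRUE) + 1L
  trimesh(v, f)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1L] - 1L,
                     mesh$faces[, 2L] - 1L, mesh$faces[, 3L] - 1L), con)
}
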