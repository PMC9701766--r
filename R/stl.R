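#' Read and write STL mesh files
#'
#' Both binary and ASCII STL are supported; `write_stl` defaults to binary.
#' STL stores a triangle soup, so `read_stl` merges coincident vertices to
#' restore shared topology. The vertebral label follows the filename
#' convention `<case>_<label>.stl` when not given explicitly.
#'
#' @param path file path.
#' @param label optional vertebral label; if `NULL`, parsed from the
#'   filename when it matches the convention.
#' @param mesh a `triangle_mesh`.
#' @param ascii write ASCII STL instead of binary.
#' @return `read_stl` returns a `triangle_mesh`.
#' @export
read_stl <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(label)) {
    m <- regmatches(basename(path),
                    regexec("_(L[1-5]|S)\\.stl$", basename(path),
                            ignore.case = TRUE))[[1]]
    if (length(m) == 2) label <- toupper(m[2])
  }
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  close(con)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    is_probably_ascii_stl(path)
  tv <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  n_tri <- nrow(tv) / 3
  mesh <- triangle_mesh(tv, matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE),
                        label = label)
  merge_vertices(mesh)
}

# A binary STL may legally start with "solid"; check for "facet" in the body.
is_probably_ascii_stl <- function(path) {
  txt <- readChar(path, min(file.info(path)$size, 2000), useBytes = TRUE)
  grepl("facet", txt, fixed = TRUE)
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  need <- 84 + n * 50
  if (is.na(n) || n <= 0 || sz < need)
    stop(sprintf("malformed binary STL %s: %d triangles declared but file has %d bytes (expected %d); error near byte offset 80",
                 path, if (is.na(n)) -1L else n, sz, need))
  raw <- readBin(con, "raw", n * 50)
  m <- matrix(raw, nrow = 50)
  vals <- readBin(as.raw(m[1:48, ]), "numeric", size = 4, n = 12 * n,
                  endian = "little")
  vm <- matrix(vals, ncol = 12, byrow = TRUE)  # normal xyz + 3 vertices
  out <- matrix(0, 3 * n, 3)
  out[seq(1, 3 * n, by = 3), ] <- vm[, 4:6, drop = FALSE]
  out[seq(2, 3 * n, by = 3), ] <- vm[, 7:9, drop = FALSE]
  out[seq(3, 3 * n, by = 3), ] <- vm[, 10:12, drop = FALSE]
  out
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed ASCII STL ", path, ": ", length(vl),
         " vertex lines (must be a positive multiple of 3)")
  parts <- strsplit(trimws(vl), "\\s+")
  v <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(v)) stop("malformed ASCII STL ", path, ": non-numeric vertex")
  v
}

#' @rdname read_stl
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  f <- mesh$faces
  n <- nrow(f)
  nrm <- face_normals(mesh)
  p1 <- mesh$vertices[f[, 1], , drop = FALSE]
  p2 <- mesh$vertices[f[, 2], , drop = FALSE]
  p3 <- mesh$vertices[f[, 3], , drop = FALSE]
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid spinereg", con)
    for (i in seq_len(n)) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", p1[i, 1], p1[i, 2], p1[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", p2[i, 1], p2[i, 2], p2[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", p3[i, 1], p3[i, 2], p3[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid spinereg", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0, 80)), con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    dat <- cbind(nrm, p1, p2, p3)
    for (i in seq_len(n)) {
      writeBin(as.numeric(dat[i, ]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}
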