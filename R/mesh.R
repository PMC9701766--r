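#' Triangle mesh container
#'
#' A surface triangle mesh in millimetres, optionally carrying a vertebral
#' label (`L1`..`L5`, `S`) and a per-face region factor (e.g. `body`,
#' `arch`, `transverse_left`, `transverse_right`, `spinous`). Degenerate
#' faces (area below `1e-9` mm^2) are dropped on construction.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param label optional vertebral label, one of `L1,L2,L3,L4,L5,S`.
#' @param regions optional character/factor of length m tagging faces.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, label = NULL, regions = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (nrow(faces) == 0L) stop("mesh has no faces")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  if (!is.null(label)) label <- match.arg(label, vertebra_labels())
  a <- face_areas(vertices, faces)
  keep <- a > 1e-9
  faces <- faces[keep, , drop = FALSE]
  if (!is.null(regions)) regions <- as.character(regions)[keep]
  if (nrow(faces) == 0L || sum(a[keep]) <= 0)
    stop("mesh has no non-degenerate faces")
  structure(list(vertices = vertices, faces = faces, label = label,
                 regions = regions),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh%s> %d vertices, %d faces, area %.1f mm^2\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Vertebral labels in anatomical (cranial to caudal) order
#' @return `c("L1","L2","L3","L4","L5","S")`
#' @export
vertebra_labels <- function() c("L1", "L2", "L3", "L4", "L5", "S")

face_areas <- function(vertices, faces) {
  p1 <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - p1
  e2 <- vertices[faces[, 3], , drop = FALSE] - p1
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Mesh surface area, face normals, centroid and volume
#'
#' `mesh_area` is the total triangle area (mm^2); `face_normals` returns
#' unit outward normals (m x 3); `mesh_centroid` is the area-weighted
#' surface centroid; `mesh_volume` the enclosed volume (mm^3, summed over
#' closed components via the divergence theorem).
#'
#' @param mesh a `triangle_mesh`.
#' @return numeric scalar, or matrix for `face_normals`.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh$vertices, mesh$faces))

#' @rdname mesh_area
#' @export
face_normals <- function(mesh) {
  p1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  e1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - p1
  e2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - p1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / sqrt(rowSums(n^2))
}

#' @rdname mesh_area
#' @export
mesh_centroid <- function(mesh) {
  a <- face_areas(mesh$vertices, mesh$faces)
  ctr <- (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
          mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
          mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
  as.numeric(colSums(ctr * a) / sum(a))
}

#' @rdname mesh_area
#' @export
mesh_volume <- function(mesh) {
  comp <- mesh_components(mesh)
  tot <- 0
  for (k in seq_len(max(comp))) {
    f <- mesh$faces[comp == k, , drop = FALSE]
    p1 <- mesh$vertices[f[, 1], , drop = FALSE]
    p2 <- mesh$vertices[f[, 2], , drop = FALSE]
    p3 <- mesh$vertices[f[, 3], , drop = FALSE]
    v6 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
          p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
          p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
    tot <- tot + abs(sum(v6) / 6)
  }
  tot
}

# Connected components over faces sharing vertices (union-find).
# Returns a 1-based component id per face.
mesh_components <- function(mesh) {
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh$faces
  for (k in seq_len(nrow(f))) {
    a <- find(f[k, 1]); b <- find(f[k, 2]); c <- find(f[k, 3])
    parent[b] <- a; parent[find(c)] <- a
  }
  root <- vapply(f[, 1], find, integer(1))
  as.integer(factor(root))
}

# Unique undirected edges with their (<=2) adjacent faces.
# Returns list(edges = e x 2 vertex idx, f1, f2 = face idx, f2 NA if boundary).
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fid <- rep(seq_len(nrow(f)), 3)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  grp <- match(key, unique(key))
  ord <- order(grp)
  grp_o <- grp[ord]; fid_o <- fid[ord]; e_o <- e[ord, , drop = FALSE]
  first <- !duplicated(grp_o)
  n_e <- sum(first)
  f1 <- fid_o[first]
  f2 <- rep(NA_integer_, n_e)
  dup <- which(!first)
  f2[grp_o[dup]] <- fid_o[dup]
  list(edges = e_o[first, , drop = FALSE], f1 = f1, f2 = f2,
       count = tabulate(grp, nbins = n_e))
}

#' Check that every component of a mesh is a closed surface
#'
#' @param mesh a `triangle_mesh`.
#' @return TRUE if every edge is shared by exactly two faces.
#' @export
is_watertight <- function(mesh) {
  ed <- mesh_edges(mesh)
  all(ed$count == 2L)
}

#' Merge coincident vertices
#'
#' Collapses vertices closer than `tol` (as written by face-soup formats
#' such as STL) so that edge adjacency and components are well defined.
#'
#' @param mesh a `triangle_mesh`.
#' @param tol coordinate rounding tolerance (mm).
#' @return A `triangle_mesh` with shared vertices.
#' @export
merge_vertices <- function(mesh, tol = 1e-6) {
  key <- paste(round(mesh$vertices[, 1] / tol),
               round(mesh$vertices[, 2] / tol),
               round(mesh$vertices[, 3] / tol))
  id <- match(key, unique(key))
  keep <- !duplicated(id)
  v <- mesh$vertices[keep, , drop = FALSE]
  f <- matrix(id[mesh$faces], ncol = 3)
  triangle_mesh(v, f, label = mesh$label, regions = mesh$regions)
}

#' Sample points uniformly over a mesh surface
#'
#' Stratified per-triangle sampling proportional to area: triangle j
#' receives `ceiling(area_j * density)` uniform barycentric samples; the
#' returned weights `area_j / n_j` make weighted means area-weighted
#' surface integrals.
#'
#' @param mesh a `triangle_mesh`.
#' @param density samples per mm^2.
#' @param seed optional integer seed (sampling is deterministic given it).
#' @return list with `points` (n x 3), `weights`, `face` index per sample.
#' @export
sample_mesh_points <- function(mesh, density = 10, seed = NULL) {
  with_seed(seed, {
    a <- face_areas(mesh$vertices, mesh$faces)
    # round before ceiling so counts are stable under rigid-motion rounding
    n_j <- pmax(1L, as.integer(ceiling(round(a * density, 9))))
    fidx <- rep(seq_along(n_j), n_j)
    n <- length(fidx)
    r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
    b1 <- 1 - r1; b2 <- r1 * (1 - r2); b3 <- r1 * r2
    p1 <- mesh$vertices[mesh$faces[fidx, 1], , drop = FALSE]
    p2 <- mesh$vertices[mesh$faces[fidx, 2], , drop = FALSE]
    p3 <- mesh$vertices[mesh$faces[fidx, 3], , drop = FALSE]
    list(points = p1 * b1 + p2 * b2 + p3 * b3,
         weights = (a / n_j)[fidx],
         face = fidx)
  })
}

#' Bounding box of a mesh
#' @param mesh a `triangle_mesh`.
#' @return 2 x 3 matrix (rows: min, max).
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min),
        max = apply(mesh$vertices, 2, max))
}
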