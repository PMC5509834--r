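#' Candidate sampling domains
#'
#' A sample domain is the total candidate set `V` of points the planner may
#' map: a regular 2D grid for benchmarks, or the vertex set of a
#' triangulated surface mesh (an endocardial anatomy). Optional slots carry
#' per-vertex curvature and a ground-truth value field.
#'
#' @name sample_domain
NULL

new_sample_domain <- function(points, kind, faces = NULL, curvature = NULL,
                              truth = NULL, extent = NULL, n_per_side = NULL) {
  points <- as_point_matrix(points)
  if (nrow(points) < 2) stop("a sample domain needs at least 2 points")
  if (!is.null(faces)) {
    faces <- matrix(as.integer(faces), ncol = 3)
    if (any(faces < 1) || any(faces > nrow(points)))
      stop("face indices out of range")
  }
  structure(list(points = points, kind = kind, faces = faces,
                 curvature = curvature, truth = truth,
                 extent = extent, n_per_side = n_per_side,
                 pdist = NULL),
            class = "sample_domain")
}

#' @export
print.sample_domain <- function(x, ...) {
  cat(sprintf("<sample_domain> %s: %d points in %dD%s\n", x$kind,
              nrow(x$points), ncol(x$points),
              if (is.null(x$faces)) "" else sprintf(", %d faces", nrow(x$faces))))
  invisible(x)
}

#' Regular 2D grid domain
#'
#' Lays `n_per_side^2` candidate points on a regular lattice covering the
#' square `[0, extent]^2`. The defaults (extent 10, 60 points per side)
#' give the 3600-point benchmark grid with lattice spacing `extent/59`
#' (both boundaries included); `cell_centred = TRUE` instead centres points
#' in the `n_per_side^2` cells.
#'
#' @param extent side length of the square domain.
#' @param n_per_side points per side (>= 2).
#' @param cell_centred use cell-centred instead of boundary-inclusive
#'   lattice coordinates.
#' @return A `sample_domain` of kind `"grid"`.
#' @examples
#' g <- make_grid_domain(10, 60)
#' nrow(g$points)  # 3600
#' @export
make_grid_domain <- function(extent = 10, n_per_side = 60,
                             cell_centred = FALSE) {
  stopifnot(n_per_side >= 2, extent > 0)
  ax <- if (cell_centred) (seq_len(n_per_side) - 0.5) * extent / n_per_side
        else seq(0, extent, length.out = n_per_side)
  pts <- as.matrix(expand.grid(x = ax, y = ax))
  dimnames(pts) <- NULL
  new_sample_domain(pts, "grid", extent = extent, n_per_side = n_per_side)
}

# Cache the full pairwise distance matrix on the domain (used by the
# planner to avoid recomputing cross-distances every step/particle).
precompute_distances <- function(domain) {
  if (is.null(domain$pdist))
    domain$pdist <- cross_dist(domain$points, domain$points)
  domain
}

#' Load a triangulated surface mesh
#'
#' Reads ASCII PLY, Wavefront OBJ or legacy ASCII VTK POLYDATA meshes into
#' a `sample_domain`. Faces with more than three vertices are triangulated
#' by a fan split. Coordinate units pass through unchanged.
#'
#' @param path file path.
#' @param format `"auto"` (by extension) or one of `"ply"`, `"obj"`, `"vtk"`.
#' @return A `sample_domain` of kind `"mesh"`.
#' @export
load_mesh <- function(path, format = c("auto", "ply", "obj", "vtk")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", obj = "obj", vtk = "vtk",
                     stop("cannot infer mesh format from extension '.", ext,
                          "'; pass format explicitly"))
  }
  mesh <- switch(format,
    ply = read_ply_ascii(path),
    obj = read_obj(path),
    vtk = read_vtk_ascii(path))
  if (nrow(mesh$vertices) == 0) stop("mesh has no vertices: ", path)
  if (nrow(mesh$faces) == 0) stop("mesh has no faces: ", path)
  new_sample_domain(mesh$vertices, "mesh", faces = mesh$faces)
}

# Fan-split polygonal faces (list of integer vectors) into triangles.
fan_triangulate <- function(polys) {
  tris <- lapply(polys, function(p) {
    if (length(p) < 3) stop("face with fewer than 3 vertices")
    if (length(p) == 3) return(matrix(p, 1, 3))
    cbind(p[1], p[2:(length(p) - 1)], p[3:length(p)])
  })
  do.call(rbind, tris)
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  if (!any(grepl("^format\\s+ascii", lines)))
    stop("only ASCII PLY is supported: ", path)
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("PLY header has no end_header: ", path)
  hdr <- lines[seq_len(hdr_end)]
  el <- grep("^element\\s", hdr, value = TRUE)
  counts <- stats::setNames(
    as.integer(sub("^element\\s+\\S+\\s+(\\d+).*$", "\\1", el)),
    sub("^element\\s+(\\S+)\\s.*$", "\\1", el))
  nv <- counts[["vertex"]] %||% stop("PLY header lacks a vertex element")
  nf <- counts[["face"]] %||% 0L
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vtx <- t(vapply(body[seq_len(nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3]), numeric(3)))
  dimnames(vtx) <- NULL
  polys <- lapply(body[nv + seq_len(nf)], function(s) {
    f <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
    f[1 + seq_len(f[1])] + 1L   # PLY indices are 0-based
  })
  list(vertices = vtx, faces = fan_triangulate(polys))
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  vtx <- t(vapply(vl, function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][2:4]), numeric(3)))
  dimnames(vtx) <- NULL
  polys <- lapply(fl, function(s) {
    toks <- strsplit(trimws(s), "\\s+")[[1]][-1]
    as.integer(vapply(strsplit(toks, "/"), `[[`, "", 1))  # drop vt/vn refs
  })
  list(vertices = vtx, faces = fan_triangulate(polys))
}

read_vtk_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pl <- grep("^POINTS\\s", lines)[1]
  if (is.na(pl)) stop("VTK file has no POINTS section: ", path)
  np <- as.integer(strsplit(trimws(lines[pl]), "\\s+")[[1]][2])
  coords <- numeric(0)
  i <- pl + 1
  while (length(coords) < 3 * np && i <= length(lines)) {
    coords <- c(coords, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  vtx <- matrix(coords[seq_len(3 * np)], ncol = 3, byrow = TRUE)
  cl <- grep("^POLYGONS\\s|^CELLS\\s", lines)[1]
  if (is.na(cl)) stop("VTK file has no POLYGONS section: ", path)
  nc <- as.integer(strsplit(trimws(lines[cl]), "\\s+")[[1]][2])
  ints <- integer(0)
  i <- cl + 1
  while (i <= length(lines) && !grepl("^[A-Z]", trimws(lines[i]))) {
    ints <- c(ints, as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  polys <- vector("list", nc)
  pos <- 1
  for (j in seq_len(nc)) {
    k <- ints[pos]
    polys[[j]] <- ints[pos + seq_len(k)] + 1L   # VTK indices are 0-based
    pos <- pos + k + 1
  }
  list(vertices = vtx, faces = fan_triangulate(polys))
}

#' Icosphere mesh generator
#'
#' Subdivided-icosahedron approximation of the unit sphere, useful as a
#' synthetic closed-surface domain. Vertex count is `10 * 4^subdiv + 2`.
#'
#' @param subdiv number of 1-to-4 triangle subdivisions (>= 0).
#' @param radius sphere radius.
#' @return A `sample_domain` of kind `"mesh"`.
#' @export
icosphere <- function(subdiv = 2, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    midpoint_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- midpoint_cache[[key]]
      if (!is.null(idx)) return(idx)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1]] <<- m
      idx <- nv + length(newv)
      midpoint_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(t - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  new_sample_domain(v * radius, "mesh", faces = f)
}

#' Remove duplicate mapping points
#'
#' Points within `tol` of an earlier kept point are dropped (greedy
#' first-kept rule in input order) — repeated catheter contacts at one site
#' destabilize the GP Gram matrix.
#'
#' @param obs an [obs_set()].
#' @param tol non-negative distance tolerance; the default keeps only
#'   exact (to 1e-6 coordinate units) duplicates out.
#' @return The deduplicated `obs_set`, with attribute `"removed"` giving
#'   the number of dropped points.
#' @export
dedupe_points <- function(obs, tol = 1e-6) {
  stopifnot(tol >= 0)
  n <- n_obs(obs)
  if (n <= 1) {
    attr(obs, "removed") <- 0L
    return(obs)
  }
  keep <- logical(n)
  kept_idx <- integer(0)
  for (i in seq_len(n)) {
    if (length(kept_idx) == 0) {
      keep[i] <- TRUE; kept_idx <- i; next
    }
    d <- sqrt(colSums((t(obs$X[kept_idx, , drop = FALSE]) - obs$X[i, ])^2))
    if (all(d > tol)) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  out <- obs_set(obs$X[keep, , drop = FALSE], obs$y[keep], obs$case_id)
  attr(out, "removed") <- sum(!keep)
  out
}

#' Project mapping points onto mesh vertices by nearest neighbour
#'
#' Each point maps to its Euclidean-nearest mesh vertex; when several
#' points land on one vertex their values are averaged.
#'
#' @param mesh_domain a mesh `sample_domain`.
#' @param points n x d matrix of point positions.
#' @param values n-vector of values carried by the points.
#' @return A list with `vertex_index` (per-point nearest vertex),
#'   `vertex_value` (named numeric vector over hit vertices, averaged),
#'   and `vertex_count` (points per hit vertex).
#' @export
project_points_nn <- function(mesh_domain, points, values) {
  stopifnot(inherits(mesh_domain, "sample_domain"))
  points <- as_point_matrix(points)
  if (nrow(points) != length(values))
    stop("points and values lengths differ")
  D <- cross_dist(points, mesh_domain$points)
  nn <- max.col(-D, ties.method = "first")
  agg <- tapply(values, nn, mean)
  cnt <- table(nn)
  list(vertex_index = nn,
       vertex_value = stats::setNames(as.numeric(agg), names(agg)),
       vertex_count = stats::setNames(as.integer(cnt), names(cnt)))
}
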