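#' Triangulated surface mesh
#'
#' A `surface_mesh` holds vertex coordinates (mm), triangular faces, and a
#' `feature_map` assigning each vertex the indices of the data features
#' (voxels) it samples. The default feature map is the identity (one feature
#' per vertex).
#'
#' @param vertices numeric n x 3 matrix of coordinates in mm.
#' @param faces integer m x 3 matrix of vertex indices (1-based).
#' @param feature_map list of integer vectors, one per vertex.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, feature_map = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  n <- nrow(vertices)
  if (any(faces < 1L) || any(faces > n)) {
    stop("faces reference vertices outside the mesh")
  }
  if (is.null(feature_map)) feature_map <- as.list(seq_len(n))
  if (length(feature_map) != n) stop("feature_map must have one entry per vertex")
  structure(list(vertices = vertices, faces = faces,
                 feature_map = feature_map),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, %d features\n",
              nrow(x$vertices), nrow(x$faces),
              length(unique(unlist(x$feature_map)))))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Icosphere mesh fixture
#'
#' Builds a geodesic sphere by subdividing an icosahedron and projecting onto
#' a sphere of radius `radius_mm`. Subdivision level 0 gives 12 vertices,
#' level 1 gives 42, level 2 gives 162, level 3 gives 642. Serves as a
#' well-controlled stand-in for a cortical surface patch in simulations;
#' edge lengths (hence searchlight neighborhoods) scale linearly with the
#' radius.
#'
#' @param subdivisions subdivision level (>= 0).
#' @param radius_mm sphere radius in mm.
#' @return a [surface_mesh].
#' @export
icosphere_mesh <- function(subdivisions = 3L, radius_mm = 50) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  normalize <- function(m) m / sqrt(rowSums(m^2))
  v <- normalize(v)
  for (s in seq_len(subdivisions)) {
    midpoint_cache <- new.env(hash = TRUE)
    verts <- v
    get_mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      midpoint_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, 0L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; c_ <- f[i, 3L]
      ab <- get_mid(a, b); bc <- get_mid(b, c_); ca <- get_mid(c_, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                    c(ab, bc, ca))
    }
    v <- verts
    f <- newf
  }
  surface_mesh(v * radius_mm, f)
}

#' Read / write meshes as Wavefront OBJ
#'
#' Supports the `v x y z` / `f i j k` subset of the OBJ format. The feature
#' map is not part of OBJ and defaults to the identity on read.
#' @param mesh a [surface_mesh].
#' @param path file path.
#' @return `read_mesh_obj` returns a [surface_mesh].
#' @export
write_mesh_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.10g %.10g %.10g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                     mesh$faces[, 3L]), con)
  invisible(path)
}

#' @rdname write_mesh_obj
#' @export
read_mesh_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  parse_nums <- function(ls) {
    t(vapply(strsplit(trimws(sub("^[vf]", "", ls)), "\\s+"), function(p) {
      as.numeric(sub("/.*", "", p[p != ""]))[1:3]
    }, numeric(3L)))
  }
  surface_mesh(parse_nums(vl), parse_nums(fl))
}

#' Contiguous vertex patch around a center
#'
#' Returns the `size` vertices nearest to `center` by graph-geodesic
#' distance (including the center itself) — a contiguous patch suitable as
#' a plant region.
#'
#' @param mesh a [surface_mesh].
#' @param center center vertex index.
#' @param size number of vertices in the patch.
#' @return integer vector of vertex indices.
#' @export
mesh_patch <- function(mesh, center = 1L, size = 10L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (size > n_vertices(mesh)) stop("patch larger than the mesh")
  edges <- rbind(mesh$faces[, c(1L, 2L)], mesh$faces[, c(2L, 3L)],
                 mesh$faces[, c(3L, 1L)])
  edges <- unique(t(apply(edges, 1L, sort)))
  lens <- sqrt(rowSums((mesh$vertices[edges[, 1L], , drop = FALSE] -
                          mesh$vertices[edges[, 2L], , drop = FALSE])^2))
  g <- igraph::make_empty_graph(n = n_vertices(mesh), directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  d <- igraph::distances(g, v = center, weights = lens)[1L, ]
  sort(order(d)[seq_len(size)])
}

#' Build surface searchlights
#'
#' For every vertex, collects the feature indices of all vertices within
#' `diameter_mm / 2` graph-geodesic distance (shortest path along mesh edges
#' with Euclidean edge lengths) of that vertex; the vertex's own features are
#' always included. Vertices disconnected from the rest of the mesh receive
#' a singleton searchlight with a warning.
#'
#' @param mesh a [surface_mesh].
#' @param diameter_mm searchlight diameter in mm (default 10).
#' @return an object of class `searchlight_set`: list with `features`
#'   (per-vertex feature index vectors), `vertices` (per-vertex member
#'   vertex vectors) and `diameter_mm`.
#' @export
build_searchlights <- function(mesh, diameter_mm = 10) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (diameter_mm < 0) stop("diameter_mm must be >= 0")
  edges <- rbind(mesh$faces[, c(1L, 2L)], mesh$faces[, c(2L, 3L)],
                 mesh$faces[, c(3L, 1L)])
  edges <- t(apply(edges, 1L, sort))
  edges <- unique(edges)
  lens <- sqrt(rowSums((mesh$vertices[edges[, 1L], , drop = FALSE] -
                          mesh$vertices[edges[, 2L], , drop = FALSE])^2))
  g <- igraph::make_empty_graph(n = n_vertices(mesh), directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  gd <- igraph::distances(g, weights = lens)
  radius <- diameter_mm / 2
  nv <- n_vertices(mesh)
  members <- vector("list", nv)
  feats <- vector("list", nv)
  disconnected <- FALSE
  for (v in seq_len(nv)) {
    memb <- which(gd[v, ] <= radius)
    if (nv > 1L && all(is.infinite(gd[v, -v]))) {
      disconnected <- TRUE
    }
    members[[v]] <- memb
    feats[[v]] <- sort(unique(unlist(mesh$feature_map[memb])))
  }
  if (disconnected) {
    warning("mesh has disconnected vertices; their searchlights are singletons")
  }
  structure(list(features = feats, vertices = members,
                 diameter_mm = diameter_mm),
            class = "searchlight_set")
}

#' @export
print.searchlight_set <- function(x, ...) {
  sizes <- lengths(x$features)
  cat(sprintf(
    "<searchlight_set> %d searchlights, diameter %g mm, %d-%d features (median %g)\n",
    length(sizes), x$diameter_mm, min(sizes), max(sizes), stats::median(sizes)))
  invisible(x)
}
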