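#' Build an icosphere surface mesh
#'
#' Constructs a triangulated sphere by recursive edge-midpoint subdivision of
#' a regular icosahedron, projecting every new vertex back onto the sphere.
#' The result stands in for an inflated cortical surface: a closed, connected,
#' locally near-planar triangle mesh with coordinates in millimetres.
#'
#' An icosphere with `s` subdivisions has `10 * 4^s + 2` vertices and
#' `20 * 4^s` triangles.
#'
#' @param subdivisions Non-negative integer; number of 4-to-1 triangle
#'   subdivision rounds. 0 returns the raw icosahedron.
#' @param radius Sphere radius in mm; must be positive.
#'
#' @return A `surface_mesh` object: a list with `vertices` (numeric matrix,
#'   n x 3, mm) and `triangles` (integer matrix, m x 3, 1-based vertex
#'   indices).
#' @examples
#' mesh <- build_sphere_patch_mesh(1, radius = 25)
#' nrow(mesh$vertices) # 42
#' @export
build_sphere_patch_mesh <- function(subdivisions, radius) {
  if (length(subdivisions) != 1L || is.na(subdivisions) ||
      subdivisions < 0 || subdivisions != round(subdivisions)) {
    stop("`subdivisions` must be a single non-negative integer", call. = FALSE)
  }
  if (length(radius) != 1L || is.na(radius) || radius <= 0) {
    stop("`radius` must be a single positive number", call. = FALSE)
  }

  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  tri <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )

  for (round_i in seq_len(subdivisions)) {
    n_v <- nrow(v)
    # midpoint index cache keyed by the (sorted) endpoint pair
    edge_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    keys <- c(
      edge_key(tri[, 1], tri[, 2]),
      edge_key(tri[, 2], tri[, 3]),
      edge_key(tri[, 3], tri[, 1])
    )
    uk <- unique(keys)
    ends <- matrix(as.integer(unlist(strsplit(uk, "_", fixed = TRUE))),
                   ncol = 2, byrow = TRUE)
    mid <- (v[ends[, 1], , drop = FALSE] + v[ends[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    v <- rbind(v, mid)
    mid_idx <- n_v + match(keys, uk)
    m_ab <- mid_idx[seq_len(nrow(tri))]
    m_bc <- mid_idx[nrow(tri) + seq_len(nrow(tri))]
    m_ca <- mid_idx[2 * nrow(tri) + seq_len(nrow(tri))]
    tri <- rbind(
      cbind(tri[, 1], m_ab, m_ca),
      cbind(tri[, 2], m_bc, m_ab),
      cbind(tri[, 3], m_ca, m_bc),
      cbind(m_ab, m_bc, m_ca)
    )
  }

  new_surface_mesh(v * radius, tri)
}

#' Construct a surface mesh from vertices and triangles
#'
#' @param vertices Numeric matrix, n x 3, coordinates in mm.
#' @param triangles Integer matrix, m x 3, 1-based vertex indices.
#' @return A `surface_mesh` object.
#' @export
new_surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (any(triangles < 1L) || any(triangles > nrow(vertices))) {
    stop("triangle indices out of range", call. = FALSE)
  }
  dimnames(vertices) <- NULL
  structure(
    list(vertices = vertices, triangles = triangles),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles\n", sep = "")
  invisible(x)
}

#' Number of vertices in a mesh
#' @param mesh A `surface_mesh`.
#' @return Integer vertex count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

# Unique undirected edges of the mesh with Euclidean lengths.
mesh_edges <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  d <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  list(edges = e, lengths = d)
}

# igraph view of the edge graph, cached on the mesh object by callers.
mesh_graph <- function(mesh) {
  if (!is.null(attr(mesh, "graph"))) return(attr(mesh, "graph"))
  ed <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(ed$edges, directed = FALSE)
  igraph::E(g)$weight <- ed$lengths
  g
}

#' Geodesic distance between two mesh vertices
#'
#' Shortest-path distance along mesh edges with Euclidean edge weights
#' (Dijkstra's algorithm). This is the graph geodesic, the standard
#' approximation for cortical surface distance on triangulated meshes.
#'
#' @param mesh A `surface_mesh`.
#' @param a,b 1-based vertex indices.
#' @return Distance in mm. Errors if the vertices are not connected.
#' @examples
#' mesh <- build_sphere_patch_mesh(0, 1)
#' geodesic_distance(mesh, 1, 1) # 0
#' @export
geodesic_distance <- function(mesh, a, b) {
  nv <- n_vertices(mesh)
  if (any(c(a, b) < 1) || any(c(a, b) > nv)) {
    stop("vertex index out of range", call. = FALSE)
  }
  if (a == b) return(0)
  g <- mesh_graph(mesh)
  d <- igraph::distances(g, v = a, to = b, algorithm = "dijkstra")[1, 1]
  if (!is.finite(d)) stop("vertices are not connected on the mesh", call. = FALSE)
  d
}

#' Geodesic distances from one vertex to all vertices
#'
#' @param mesh A `surface_mesh`.
#' @param from 1-based source vertex index.
#' @return Numeric vector of distances (mm), one per vertex.
#' @export
geodesic_distances_from <- function(mesh, from) {
  g <- mesh_graph(mesh)
  as.numeric(igraph::distances(g, v = from, algorithm = "dijkstra")[1, ])
}

# Full vertex-by-vertex geodesic distance matrix. Fine at desk scale
# (<= a few thousand vertices); cached by callers that reuse it.
geodesic_distance_matrix <- function(mesh) {
  g <- mesh_graph(mesh)
  unname(igraph::distances(g, algorithm = "dijkstra"))
}

#' Write / read a mesh as an OFF file
#'
#' Plain-text Object File Format: portable interchange for triangle meshes.
#' Vertex indices are 0-based on disk (the OFF convention) and 1-based in R.
#'
#' @param mesh A `surface_mesh`.
#' @param path File path.
#' @return `write_mesh_off` returns `path` invisibly; `read_mesh_off`
#'   returns a `surface_mesh`.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(mesh$vertices), nrow(mesh$triangles), 0L), con)
  utils::write.table(format(mesh$vertices, digits = 17, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (trimws(lines[1]) != "OFF") stop("not an OFF file", call. = FALSE)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  v <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE),
              ncol = 3, byrow = TRUE)
  f <- matrix(scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE),
              ncol = 4, byrow = TRUE)
  new_surface_mesh(v, f[, 2:4] + 1L)
}
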