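# Triangulations of the elliptical cell domain.
#
# A `pnp_mesh` stores P1 nodes and counter-clockwise triangles together with
# the membrane/interior node partition: boundary nodes are those lying on
# edges that belong to exactly one triangle (the cell membrane), interior
# nodes the complement. `h` is the mesh size, the maximum over triangles of
# the longest edge length.

#' Construct a triangular mesh object
#'
#' Builds a `pnp_mesh` from node coordinates and a triangle connectivity
#' table, classifying membrane (boundary) versus interior nodes from the mesh
#' topology and computing the mesh size `h`.
#'
#' @param nodes numeric matrix, one row per node, columns `x`, `y`
#'   (simulation length units).
#' @param triangles integer matrix, one row per triangle, three node indices
#'   (1-based). Triangles are re-oriented counter-clockwise if needed.
#' @return An object of class `pnp_mesh`: a list with elements `nodes`,
#'   `triangles`, `boundary` (index set of membrane nodes), `interior`
#'   (complementary index set) and `h` (max over triangles of the longest
#'   edge).
#' @examples
#' tri <- pnp_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)), matrix(1:3, 1))
#' tri$h
#' @export
pnp_mesh <- function(nodes, triangles) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 2L) stop("`nodes` must have two columns (x, y)")
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(triangles) != 3L) stop("`triangles` must have three columns")
  m <- nrow(nodes)
  if (any(triangles < 1L) || any(triangles > m)) {
    stop("triangle connectivity refers to nodes outside 1..", m)
  }
  # enforce counter-clockwise orientation and strictly positive areas
  ar <- signed_areas(nodes, triangles)
  flip <- ar < 0
  if (any(flip)) {
    tmp <- triangles[flip, 2L]
    triangles[flip, 2L] <- triangles[flip, 3L]
    triangles[flip, 3L] <- tmp
    ar <- abs(ar)
  }
  if (any(ar <= 0)) stop("mesh contains degenerate (zero-area) triangles")
  cls <- classify_boundary(list(nodes = nodes, triangles = triangles))
  mesh <- structure(
    list(
      nodes = nodes, triangles = triangles,
      boundary = cls$boundary, interior = cls$interior,
      h = max_edge_length(nodes, triangles)
    ),
    class = "pnp_mesh"
  )
  mesh
}

signed_areas <- function(nodes, triangles) {
  x1 <- nodes[triangles[, 1L], 1L]; y1 <- nodes[triangles[, 1L], 2L]
  x2 <- nodes[triangles[, 2L], 1L]; y2 <- nodes[triangles[, 2L], 2L]
  x3 <- nodes[triangles[, 3L], 1L]; y3 <- nodes[triangles[, 3L], 2L]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

max_edge_length <- function(nodes, triangles) {
  e <- 0
  for (k in 1:3) {
    i <- triangles[, k]
    j <- triangles[, if (k == 3L) 1L else k + 1L]
    d2 <- (nodes[i, 1L] - nodes[j, 1L])^2 + (nodes[i, 2L] - nodes[j, 2L])^2
    e <- max(e, d2)
  }
  sqrt(e)
}

#' Classify membrane and interior nodes
#'
#' Partitions the node indices of a conforming triangulation into the
#' membrane set (nodes on edges belonging to exactly one triangle) and the
#' interior set (the complement). The potential's homogeneous Dirichlet
#' condition is imposed on the membrane set.
#'
#' @param mesh a `pnp_mesh`, or any list with `nodes` and `triangles`.
#' @return list with integer vectors `boundary` and `interior`.
#' @export
classify_boundary <- function(mesh) {
  tri <- mesh$triangles
  m <- nrow(mesh$nodes)
  a <- c(tri[, 1L], tri[, 2L], tri[, 3L])
  b <- c(tri[, 2L], tri[, 3L], tri[, 1L])
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- (lo - 1) * m + hi                   # unique id per undirected edge
  cnt <- table(key)
  if (any(cnt > 2L)) {
    stop("non-conforming mesh: an edge is shared by more than two triangles")
  }
  bkey <- as.numeric(names(cnt)[cnt == 1L])
  bnodes <- sort(unique(c((bkey - 1) %/% m + 1, (bkey - 1) %% m + 1)))
  list(boundary = as.integer(bnodes),
       interior = setdiff(seq_len(m), as.integer(bnodes)))
}

#' Total mesh area
#'
#' Sum of triangle areas; converges to the continuous domain area (pi*a*b for
#' the ellipse) at second order in the mesh size.
#'
#' @param mesh a `pnp_mesh`.
#' @return scalar area.
#' @export
mesh_area <- function(mesh) sum(signed_areas(mesh$nodes, mesh$triangles))

#' @export
print.pnp_mesh <- function(x, ...) {
  cat("P1 triangular mesh\n")
  cat(sprintf("  nodes:     %d (%d membrane, %d interior)\n",
              nrow(x$nodes), length(x$boundary), length(x$interior)))
  cat(sprintf("  triangles: %d\n", nrow(x$triangles)))
  cat(sprintf("  h:         %.4g\n", x$h))
  cat(sprintf("  area:      %.6g\n", mesh_area(x)))
  invisible(x)
}

# Equal-arclength points on the ellipse (x/a)^2 + (y/b)^2 = 1.
# Returns the parameter angles t for n points starting at t = 0; positions
# are then exactly (a cos t, b sin t), so boundary nodes lie on the ellipse
# to machine precision.
ellipse_arc_angles <- function(a, b, n) {
  ngrid <- max(4096L, 64L * n)
  t <- seq(0, 2 * pi, length.out = ngrid + 1L)
  dx <- -a * sin(t); dy <- b * cos(t)
  sp <- sqrt(dx^2 + dy^2)
  # cumulative arclength by trapezoid rule
  s <- c(0, cumsum((sp[-1] + sp[-length(sp)]) / 2 * diff(t)))
  stot <- s[length(s)]
  target <- stot * (seq_len(n) - 1L) / n
  stats::approx(s, t, xout = target, ties = "ordered")$y
}

ellipse_perimeter <- function(a, b) {
  # Ramanujan's approximation; only used to choose node counts
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Stitch two concentric node loops (indices inner, outer, both ordered
# counter-clockwise and equally spaced in arc length) into a triangle band.
stitch_rings <- function(inner, outer) {
  mi <- length(inner); mo <- length(outer)
  tri <- matrix(0L, mi + mo, 3L)
  i <- 0L; o <- 0L; r <- 0L
  while (i < mi || o < mo) {
    r <- r + 1L
    if (o == mo || (i < mi && (i + 1) / mi <= (o + 1) / mo)) {
      tri[r, ] <- c(inner[i %% mi + 1L], outer[o %% mo + 1L],
                    inner[(i + 1L) %% mi + 1L])
      i <- i + 1L
    } else {
      tri[r, ] <- c(outer[o %% mo + 1L], outer[(o + 1L) %% mo + 1L],
                    inner[i %% mi + 1L])
      o <- o + 1L
    }
  }
  tri
}

#' Generate a triangular mesh of an elliptical cell
#'
#' Deterministic concentric-ring triangulation of the ellipse with semi-major
#' axis `a` and semi-minor axis `b`. Nodes are placed on concentric scaled
#' ellipses, equally spaced in arc length on each ring (so membrane nodes lie
#' exactly on the ellipse), and consecutive rings are stitched into
#' counter-clockwise triangle bands. The first node is the cell centre (0,0),
#' the natural probe anchor.
#'
#' @param a,b semi-major and semi-minor axis lengths (must be positive).
#' @param h_target requested mesh size; the resulting `h` satisfies
#'   `h <= 1.25 * h_target`.
#' @return a [pnp_mesh].
#' @examples
#' mesh <- mesh_ellipse(2, 1, 0.3)
#' abs(mesh_area(mesh) - 2 * pi) / (2 * pi)   # O(h^2)
#' @export
mesh_ellipse <- function(a, b, h_target) {
  if (!is.finite(a) || !is.finite(b) || !is.finite(h_target) ||
      a <= 0 || b <= 0 || h_target <= 0) {
    stop("`a`, `b` and `h_target` must be positive")
  }
  if (h_target >= min(a, b)) {
    stop("`h_target` must be smaller than min(a, b)")
  }
  # diagonal edges reach ~sqrt(2) times the ring spacing, so target a
  # spacing of h_target/1.32 to keep h <= 1.25 * h_target
  h_eff <- h_target / 1.32
  # ring j carries 6j nodes (hexagonal pattern): perimeters of the nested
  # scaled ellipses grow linearly, so the arc spacing is uniform, consecutive
  # rings align, and the 6-spoke centre fan is the one uniform fan whose P1
  # Laplace stencil is exact for quadratics (k tan(pi/k)/4 = k sin(2pi/k)/6
  # only at k = 6), which preserves the second-order spatial accuracy.
  m1 <- 6L
  nring <- max(2L,
               as.integer(ceiling(max(a, b) / h_eff)),
               as.integer(ceiling(ellipse_perimeter(a, b) / (m1 * h_eff))))
  ring_nodes <- vector("list", nring)
  coords <- list(matrix(c(0, 0), 1L))
  nnode <- 1L
  for (j in seq_len(nring)) {
    aj <- a * j / nring; bj <- b * j / nring
    mj <- j * m1
    tj <- ellipse_arc_angles(aj, bj, mj)
    coords[[j + 1L]] <- cbind(aj * cos(tj), bj * sin(tj))
    ring_nodes[[j]] <- nnode + seq_len(mj)
    nnode <- nnode + mj
  }
  nodes <- do.call(rbind, coords)
  # centre fan, then stitched bands
  r1 <- ring_nodes[[1L]]
  m1 <- length(r1)
  tris <- list(cbind(1L, r1, r1[c(2:m1, 1L)]))
  for (j in seq_len(nring - 1L)) {
    tris[[j + 1L]] <- stitch_rings(ring_nodes[[j]], ring_nodes[[j + 1L]])
  }
  mesh <- pnp_mesh(nodes, do.call(rbind, tris))
  if (mesh$h > 1.25 * h_target) {
    stop(sprintf("mesh generation produced h = %.4g > 1.25 * h_target", mesh$h))
  }
  mesh
}

#' Find the mesh node nearest a point
#'
#' The probe convention for "the centre of the cell": nearest node to the
#' requested point, ties broken by lowest node index.
#'
#' @param mesh a [pnp_mesh].
#' @param point numeric length-2 vector.
#' @return integer node index.
#' @export
nearest_node <- function(mesh, point = c(0, 0)) {
  d2 <- (mesh$nodes[, 1L] - point[1L])^2 + (mesh$nodes[, 2L] - point[2L])^2
  which.min(d2)   # which.min returns the first (lowest-index) minimum
}
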