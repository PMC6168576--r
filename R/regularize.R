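#' Regularise a triangle mesh
#'
#' Smooths out surface kinks and narrows the edge-length distribution while
#' keeping vertices on the input surface.  Each pass applies a tangential
#' Laplacian smoothing step (interior vertices move toward their neighbour
#' centroid within the local tangent plane; boundary vertices are smoothed
#' only along the boundary curve) followed by a re-projection of every
#' vertex onto the reference surface: the analytic substrate height field
#' when `surface` is supplied, otherwise the closest point on the original
#' input mesh.  Topology (vertex/face count, boundary, Euler characteristic)
#' is preserved.
#'
#' @param mesh a `tri_mesh`, an open height-field-like surface.
#' @param target_edge_length target mean edge length (mm); used to validate
#'   the request against the mesh extent.  The pass itself equalises edge
#'   lengths around the mean fixed by the input vertex density.
#' @param n_iterations number of smoothing/projection passes.
#' @param surface optional `substrate` object giving the closed-form
#'   reference surface; when absent the original mesh is the reference.
#' @param lambda smoothing step size in (0, 1].
#' @return a regularised `tri_mesh`.
#' @export
regularize_mesh <- function(mesh, target_edge_length = NULL,
                            n_iterations = 10, surface = NULL,
                            lambda = 0.6) {
  stopifnot(inherits(mesh, "tri_mesh"), n_iterations >= 0,
            lambda > 0, lambda <= 1)
  ext <- apply(mesh$vertices, 2, function(v) diff(range(v)))
  if (!is.null(target_edge_length)) {
    if (target_edge_length <= 0) stopf("target_edge_length must be > 0")
    if (target_edge_length > max(ext))
      stopf("target_edge_length (%g mm) exceeds the mesh extent (%g mm)",
            target_edge_length, max(ext))
  }
  v <- mesh$vertices
  n <- nrow(v)
  interior <- which(!mesh$boundary_vertex)
  boundary <- which(mesh$boundary_vertex)
  # neighbour lists
  nb <- vector("list", n)
  adj_ptr <- mesh$adj_ptr
  for (i in seq_len(n))
    nb[[i]] <- mesh$adj_idx[seq.int(adj_ptr[i], adj_ptr[i + 1] - 1L)]
  # boundary-only neighbours for boundary vertices
  be <- mesh$edges[mesh$boundary_edge, , drop = FALSE]
  bnb <- vector("list", n)
  for (k in seq_len(nrow(be))) {
    a <- be[k, 1]; b <- be[k, 2]
    bnb[[a]] <- c(bnb[[a]], b)
    bnb[[b]] <- c(bnb[[b]], a)
  }
  orig_boundary_segs <- be
  orig_v <- mesh$vertices
  # boundary corners (sharp turns of the boundary polyline) are pinned:
  # sliding them would round off genuine features, and a uniform mesh with
  # a jagged boundary must be a fixed point of the pass
  corner <- logical(n)
  for (i in boundary) {
    nbs <- bnb[[i]]
    if (length(nbs) != 2) { corner[i] <- TRUE; next }
    u <- orig_v[nbs[1], ] - orig_v[i, ]
    w <- orig_v[nbs[2], ] - orig_v[i, ]
    cosang <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
    if (cosang > -cos(20 * pi / 180)) corner[i] <- TRUE  # turn > 20 deg
  }
  boundary <- setdiff(boundary, which(corner))
  cur <- mesh
  for (it in seq_len(n_iterations)) {
    p <- cur$vertices
    nrm <- vertex_normals(cur)
    newp <- p
    for (i in interior) {
      nbp <- p[nb[[i]], , drop = FALSE]
      # length-weighted centroid: longer edges pull harder, driving the
      # 3D edge lengths (not just the in-plane spacing) toward uniformity
      w <- sqrt(rowSums((nbp - rep(p[i, ], each = nrow(nbp)))^2))
      if (sum(w) <= 0) next
      centroid <- colSums(nbp * w) / sum(w)
      d <- centroid - p[i, ]
      d <- d - sum(d * nrm[i, ]) * nrm[i, ]  # tangential component
      newp[i, ] <- p[i, ] + lambda * d
    }
    for (i in boundary) {
      nbs <- bnb[[i]]
      if (length(nbs) == 2) {
        centroid <- colMeans(p[nbs, , drop = FALSE])
        newp[i, ] <- p[i, ] + lambda * (centroid - p[i, ])
      }
    }
    # re-projection onto the reference surface
    if (!is.null(surface)) {
      z <- substrate_height(surface, newp[, 1], newp[, 2])
      newp[, 3] <- z
    } else {
      proj <- cpp_closest_mesh(newp, orig_v, mesh$faces)
      newp <- proj$points
    }
    # boundary vertices stay on the original boundary polyline
    if (length(boundary))
      newp[boundary, ] <- project_to_polyline(newp[boundary, , drop = FALSE],
                                              orig_v, orig_boundary_segs)
    cur$vertices <- newp
  }
  cur
}

# Closest points on a set of 3D segments (rows of `segs` index `verts`).
project_to_polyline <- function(pts, verts, segs) {
  out <- pts
  a <- verts[segs[, 1], , drop = FALSE]
  b <- verts[segs[, 2], , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    t <- rowSums(sweep(a, 2, p, function(x, y) y - x) * ab) / len2
    t <- pmin(pmax(t, 0), 1)
    q <- a + ab * t
    d2 <- rowSums(sweep(q, 2, p)^2)
    out[i, ] <- q[which.min(d2), ]
  }
  out
}
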