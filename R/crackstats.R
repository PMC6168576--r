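#' Planar crack / trough network
#'
#' A 2D network of nodes and straight segments, the common currency of the
#' junction statistics: simulated crack networks, Voronoi trough networks,
#' or externally supplied node/segment tables.
#'
#' @param nodes numeric n x 2 matrix of positions (mm).
#' @param segments integer m x 2 matrix of node index pairs.
#' @param provenance one of `"simulated-cracks"`, `"trough-lines"`,
#'   `"external-csv"`.
#' @return a `planar_network`.
#' @export
planar_network <- function(nodes, segments,
                           provenance = c("external-csv",
                                          "simulated-cracks",
                                          "trough-lines")) {
  provenance <- match.arg(provenance)
  nodes <- matrix(as.numeric(as.matrix(nodes)), ncol = 2)
  segments <- matrix(as.integer(as.matrix(segments)), ncol = 2)
  if (any(!is.finite(nodes))) stopf("non-finite node positions")
  if (nrow(segments) && any(segments[, 1] == segments[, 2]))
    stopf("self-loop segment")
  if (nrow(segments) &&
      (min(segments) < 1 || max(segments) > nrow(nodes)))
    stopf("segment node index out of range")
  structure(list(nodes = nodes, segments = segments,
                 provenance = provenance), class = "planar_network")
}

#' @export
print.planar_network <- function(x, ...) {
  cat(sprintf("planar_network (%s): %d nodes, %d segments\n",
              x$provenance, nrow(x$nodes), nrow(x$segments)))
  invisible(x)
}

#' Read / write the network CSV dialect
#'
#' `nodes.csv` columns: `id, x_mm, y_mm`; `segments.csv` columns:
#' `id_a, id_b`.
#'
#' @param nodes_path,segments_path CSV paths.
#' @return a `planar_network`.
#' @export
read_network_csv <- function(nodes_path, segments_path) {
  nd <- read.csv(nodes_path)
  sg <- read.csv(segments_path)
  idx <- match(c(sg$id_a, sg$id_b), nd$id)
  if (anyNA(idx)) stopf("segment references unknown node id")
  planar_network(cbind(nd$x_mm, nd$y_mm),
                 matrix(idx, ncol = 2), "external-csv")
}

#' @rdname read_network_csv
#' @param network a `planar_network`.
#' @export
write_network_csv <- function(network, nodes_path, segments_path) {
  write.csv(data.frame(id = seq_len(nrow(network$nodes)),
                       x_mm = network$nodes[, 1],
                       y_mm = network$nodes[, 2]),
            nodes_path, row.names = FALSE)
  write.csv(data.frame(id_a = network$segments[, 1],
                       id_b = network$segments[, 2]),
            segments_path, row.names = FALSE)
  invisible(NULL)
}

#' Project the broken-edge set to a 2D crack network
#'
#' One network node per broken mesh edge (the edge's rest midpoint,
#' orthographically projected by dropping height), and one segment between
#' broken edges that are adjacent on the mesh (sharing a face or a
#' vertex), so that seams of broken edges become crack lines.  Bond
#' breaking under tension severs the bonds crossing a seam, which touch
#' each other at shared vertices rather than across one face, so vertex
#' adjacency (a superset of face adjacency) is required to recover
#' connected crack lines.
#'
#' @param result a `sim_result` or `shell_state` with broken edges.
#' @return a `planar_network`; empty (with a warning) when nothing broke.
#' @export
project_crack_network <- function(result) {
  state <- if (inherits(result, "sim_result")) result$final_state else result
  m <- state$mesh
  br <- which(state$broken)
  if (!length(br)) {
    warning("no broken edges; empty crack network")
    return(planar_network(matrix(numeric(), 0, 2),
                          matrix(integer(), 0, 2), "simulated-cracks"))
  }
  mid <- (state$foot[m$edges[br, 1], 1:2, drop = FALSE] +
            state$foot[m$edges[br, 2], 1:2, drop = FALSE]) / 2
  id_of <- integer(length(state$broken))
  id_of[br] <- seq_along(br)
  segs <- list()
  bv <- m$edges[br, , drop = FALSE]
  for (v in unique(as.vector(bv))) {
    b <- br[bv[, 1] == v | bv[, 2] == v]
    if (length(b) >= 2) {
      prs <- utils::combn(sort(id_of[b]), 2)
      segs[[length(segs) + 1L]] <- t(prs)
    }
  }
  segments <- if (length(segs)) unique(do.call(rbind, segs))
              else matrix(integer(), 0, 2)
  planar_network(mid, segments, "simulated-cracks")
}

# adjacency list of a planar network
network_adjacency <- function(network) {
  n <- nrow(network$nodes)
  adj <- vector("list", n)
  s <- network$segments
  for (k in seq_len(nrow(s))) {
    adj[[s[k, 1]]] <- c(adj[[s[k, 1]]], s[k, 2])
    adj[[s[k, 2]]] <- c(adj[[s[k, 2]]], s[k, 1])
  }
  adj
}

#' Extract tri-junctions and their angles
#'
#' Junctions are nodes of degree 3 after contraction of degree-2 chains.
#' Each branch direction points from the junction to the position at arc
#' distance `r` along the incident chain (or the chain end when shorter);
#' the three junction angles are the circular gaps between the branch
#' bearings, sorted ascending (`theta1 <= theta2 <= theta3`, summing to
#' 360).  Nodes of degree 4 or more are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param network a `planar_network`.
#' @param r branch arc length (mm), > 0.
#' @return data frame with columns `x`, `y`, `theta1`, `theta2`, `theta3`;
#'   attribute `n_excluded`.
#' @export
extract_junctions <- function(network, r) {
  if (r <= 0) stopf("branch arc length r must be > 0")
  adj <- network_adjacency(network)
  deg <- lengths(adj)
  junctions <- which(deg == 3L)
  excluded <- sum(deg >= 4L)
  out <- vector("list", length(junctions))
  for (ji in seq_along(junctions)) {
    j <- junctions[ji]
    bearings <- numeric(3)
    ok <- TRUE
    for (b in 1:3) {
      tgt <- walk_chain(network, adj, deg, j, adj[[j]][b], r)
      dx <- tgt[1] - network$nodes[j, 1]
      dy <- tgt[2] - network$nodes[j, 2]
      if (dx^2 + dy^2 < 1e-20) { ok <- FALSE; break }
      bearings[b] <- atan2(dy, dx)
    }
    if (!ok) { excluded <- excluded + 1L; next }
    bearings <- sort(bearings * 180 / pi)
    gaps <- c(diff(bearings), 360 - (bearings[3] - bearings[1]))
    th <- sort(gaps)
    if (th[1] <= 1e-9) { excluded <- excluded + 1L; next }  # coincident branches
    out[[ji]] <- data.frame(x = network$nodes[j, 1],
                            y = network$nodes[j, 2],
                            theta1 = th[1], theta2 = th[2], theta3 = th[3])
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(x = numeric(), y = numeric(), theta1 = numeric(),
                         theta2 = numeric(), theta3 = numeric())
  attr(res, "n_excluded") <- excluded
  res
}

# Point at arc distance r from `start` walking into the chain through
# `first`; stops early at chain ends or at non-degree-2 nodes.
walk_chain <- function(network, adj, deg, start, first, r) {
  prev <- start
  cur <- first
  acc <- 0
  p_prev <- network$nodes[start, ]
  repeat {
    p_cur <- network$nodes[cur, ]
    seg <- sqrt(sum((p_cur - p_prev)^2))
    if (acc + seg >= r) {
      t <- (r - acc) / seg
      return(p_prev + t * (p_cur - p_prev))
    }
    acc <- acc + seg
    if (deg[cur] != 2L || cur == start) return(p_cur)
    nxt <- adj[[cur]][adj[[cur]] != prev][1]
    prev <- cur
    p_prev <- p_cur
    cur <- nxt
  }
}

#' Angular scatter of junctions
#'
#' Represents each tri-junction by the 2D point `(theta1, theta2)`
#' (information-lossless versus binned density profiles) and validates the
#' admissible region `theta1 <= theta2 <= 360 - theta1 - theta2`.
#'
#' @param junctions data frame from [extract_junctions()] (or any with
#'   `theta1`, `theta2` columns).
#' @return list with `points` (n x 2) and `mean` (2-vector).
#' @export
angular_scatter <- function(junctions) {
  if (!nrow(junctions)) stopf("no junctions")
  t1 <- junctions$theta1
  t2 <- junctions$theta2
  bad <- t1 > t2 + 1e-9 | t2 > 360 - t1 - t2 + 1e-9 | t1 <= 0
  if (any(bad))
    stopf("%d points outside the admissible region {0 < theta1 <= theta2 <= theta3}",
          sum(bad))
  pts <- cbind(theta1 = t1, theta2 = t2)
  list(points = pts, mean = colMeans(pts))
}

#' Angular spreading of a junction population
#'
#' Fits the sample mean and covariance of the `(theta1, theta2)` points
#' and reports `sigma_theta = sqrt(A / pi)`, with A the area of the
#' 68%-probability-mass error ellipse of the fitted Gaussian:
#' `A = pi * c * sqrt(det Sigma)`, `c = -2 ln(1 - 0.68)`, so
#' `sigma_theta = sqrt(c) * det(Sigma)^(1/4)`.  The 1-sigma Mahalanobis
#' ellipse (39% mass in 2D) is available via `ellipse = "mahalanobis1"`.
#'
#' @param junctions data frame with `theta1`, `theta2` (>= 3 rows for a
#'   non-degenerate covariance).
#' @param ellipse ellipse convention.
#' @return list with `sigma_theta` (degrees), `area`, `center`,
#'   `covariance`, `axes` (ellipse semi-axes), `angle` (ellipse
#'   orientation, radians), and `degenerate` flag.
#' @export
angular_spreading <- function(junctions,
                              ellipse = c("mass68", "mahalanobis1")) {
  ellipse <- match.arg(ellipse)
  pts <- angular_scatter(junctions)$points
  c2 <- if (ellipse == "mass68") -2 * log(1 - 0.68) else 1
  if (nrow(pts) < 3)
    return(list(sigma_theta = 0, area = 0, center = colMeans(pts),
                covariance = matrix(0, 2, 2), axes = c(0, 0), angle = 0,
                degenerate = TRUE))
  S <- cov(pts)
  dt <- det(S)
  if (!is.finite(dt) || dt <= 1e-12)
    return(list(sigma_theta = 0, area = 0, center = colMeans(pts),
                covariance = S, axes = c(0, 0), angle = 0,
                degenerate = TRUE))
  ev <- eigen(S, symmetric = TRUE)
  area <- pi * c2 * sqrt(dt)
  list(sigma_theta = sqrt(c2) * dt^(1 / 4), area = area,
       center = colMeans(pts), covariance = S,
       axes = sqrt(c2 * ev$values),
       angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
       degenerate = FALSE)
}

#' Classify a junction against the three archetypes
#'
#' Nearest archetype in the `(theta1, theta2)` plane (the Voronoi
#' partition generated by the archetypal junctions): `triple-120` at
#' (120, 120), `90-135-135` at (90, 135) and `T-junction` at (90, 90).
#' Exact ties resolve in that order.
#'
#' @param theta1,theta2 junction angles (degrees); vectorised.
#' @return character vector of archetype labels.
#' @examples
#' classify_junction(c(120, 100, 92), c(120, 130, 95))
#' @export
classify_junction <- function(theta1, theta2) {
  proto <- rbind(`triple-120` = c(120, 120),
                 `90-135-135` = c(90, 135),
                 `T-junction` = c(90, 90))
  d <- sapply(seq_len(nrow(proto)), function(k)
    (theta1 - proto[k, 1])^2 + (theta2 - proto[k, 2])^2)
  d <- matrix(d, ncol = 3)
  rownames(proto)[apply(d, 1, which.min)]
}

#' Junction population statistics
#'
#' Bundles the scatter, mean point, angular spreading, archetype counts
#' and pooled angle list of a junction set.
#'
#' @param junctions data frame from [extract_junctions()].
#' @inheritParams angular_spreading
#' @return a `junction_stats` list.
#' @export
junction_stats <- function(junctions, ellipse = "mass68") {
  sc <- angular_scatter(junctions)
  sp <- angular_spreading(junctions, ellipse)
  cls <- classify_junction(junctions$theta1, junctions$theta2)
  counts <- table(factor(cls, levels = c("triple-120", "90-135-135",
                                         "T-junction")))
  structure(list(points = sc$points, mean = sc$mean,
                 sigma_theta = sp$sigma_theta, ellipse = sp,
                 archetype_counts = counts,
                 angles = c(junctions$theta1, junctions$theta2,
                            junctions$theta3),
                 n = nrow(junctions)),
            class = "junction_stats")
}

#' @export
print.junction_stats <- function(x, ...) {
  cat(sprintf("junction_stats: %d junctions, mean (%.1f, %.1f), sigma_theta = %.2f deg\n",
              x$n, x$mean[1], x$mean[2], x$sigma_theta))
  print(x$archetype_counts)
  invisible(x)
}

#' Angle probability density with bootstrap confidence band
#'
#' Gaussian kernel density of the pooled junction angles on \\[0, 360\\]
#' degrees with boundary reflection at 0, plus a seeded bootstrap
#' pointwise 95% band.
#'
#' @param angles pooled angles (degrees), >= 2 values.
#' @param bw bandwidth; default Silverman's rule on the pooled angles.
#' @param n_bootstrap bootstrap replicates.
#' @param seed bootstrap seed.
#' @param n_grid evaluation grid size.
#' @return list with `x`, `y`, `lower`, `upper`, `bw`.
#' @export
angle_pdf <- function(angles, bw = NULL, n_bootstrap = 1000, seed = 1,
                      n_grid = 512) {
  stopifnot(length(angles) >= 2)
  bw <- bw %||% stats::bw.nrd0(angles)
  est <- function(a) {
    d <- density(c(a, -a), bw = bw, from = 0, to = 360, n = n_grid)
    2 * d$y
  }
  d0 <- density(c(angles, -angles), bw = bw, from = 0, to = 360,
                n = n_grid)
  y <- 2 * d0$y
  boots <- with_seed(seed, {
    replicate(n_bootstrap,
              est(sample(angles, length(angles), replace = TRUE)))
  })
  list(x = d0$x, y = y,
       lower = apply(boots, 1, quantile, probs = 0.025),
       upper = apply(boots, 1, quantile, probs = 0.975),
       bw = bw)
}

#' Empirical probability of an angle range
#'
#' @param angles pooled angles (degrees).
#' @param lo,hi range bounds, `lo < hi`.
#' @return fraction of angles in `[lo, hi]`.
#' @examples
#' prob_in_range(c(95, 110, 120, 135, 170), 100, 140)
#' @export
prob_in_range <- function(angles, lo = 100, hi = 140) {
  stopifnot(lo < hi)
  mean(angles >= lo & angles <= hi)
}

#' Trough-line network from papilla centres
#'
#' The valley lines between papillae are the Voronoi tessellation edges of
#' the papilla centres, clipped to the domain.  For unjittered hexagonal
#' centres every interior junction is the honeycomb (120, 120, 120).
#'
#' @param x a papilla `substrate` (with centres) or a [papilla_config()].
#' @return a `planar_network` with provenance `"trough-lines"`.
#' @examples
#' net <- generate_trough_network(papilla_config(jitter_sd = 0, seed = 1))
#' j <- extract_junctions(net, r = 0.4)
#' head(j)
#' @export
generate_trough_network <- function(x) {
  if (inherits(x, "papilla_config")) {
    centers <- papilla_centers(x)
    domain <- x$domain
  } else {
    if (is.null(x$centers)) stopf("substrate has no papilla centres")
    centers <- x$centers
    domain <- x$domain
  }
  if (nrow(centers) < 3) stopf("need at least 3 centres")
  segs <- voronoi_edges(centers, domain)
  if (!nrow(segs)) stopf("no Voronoi edges inside the domain")
  # merge endpoints into unique nodes
  pts <- rbind(segs[, 1:2], segs[, 3:4])
  key <- paste(round(pts[, 1], 7), round(pts[, 2], 7))
  uid <- match(key, unique(key))
  nodes <- pts[!duplicated(key), , drop = FALSE]
  m <- nrow(segs)
  planar_network(nodes, cbind(uid[seq_len(m)], uid[m + seq_len(m)]),
                 "trough-lines")
}

# Voronoi edges by per-cell half-plane clipping of the domain rectangle.
# Returns a matrix (x1, y1, x2, y2), one row per tessellation edge
# (domain-boundary pieces excluded), deduplicated across the two cells
# that share each edge.
voronoi_edges <- function(centers, domain) {
  n <- nrow(centers)
  seen <- character()
  out <- list()
  for (i in seq_len(n)) {
    poly <- rbind(c(0, 0), c(domain[1], 0), domain, c(0, domain[2]))
    for (j in seq_len(n)) {
      if (i == j) next
      d <- centers[j, ] - centers[i, ]
      c0 <- sum((centers[j, ]^2 - centers[i, ]^2)) / 2
      poly <- clip_halfplane(poly, d, c0)
      if (nrow(poly) < 3) break
    }
    if (nrow(poly) < 3) next
    k <- nrow(poly)
    for (e in seq_len(k)) {
      p1 <- poly[e, ]
      p2 <- poly[if (e == k) 1 else e + 1, ]
      mid <- (p1 + p2) / 2
      dd <- sqrt(rowSums(sweep(centers, 2, mid)^2))
      o <- order(dd)
      if (dd[o[2]] - dd[o[1]] > 1e-7) next  # domain-boundary piece
      key <- paste(sort(c(o[1], o[2])), collapse = "-")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- c(p1, p2)
    }
  }
  if (!length(out)) return(matrix(numeric(), 0, 4))
  do.call(rbind, out)
}

# Sutherland-Hodgman clip of polygon by half-plane {p : p . d <= c0}.
clip_halfplane <- function(poly, d, c0) {
  k <- nrow(poly)
  if (k == 0) return(poly)
  vals <- poly %*% d - c0
  out <- list()
  for (e in seq_len(k)) {
    a <- poly[e, ]; va <- vals[e]
    bidx <- if (e == k) 1 else e + 1
    b <- poly[bidx, ]; vb <- vals[bidx]
    if (va <= 1e-12) out[[length(out) + 1L]] <- a
    if ((va < -1e-12 && vb > 1e-12) || (va > 1e-12 && vb < -1e-12)) {
      t <- va / (va - vb)
      out[[length(out) + 1L]] <- a + t * (b - a)
    }
  }
  if (!length(out)) return(matrix(numeric(), 0, 2))
  do.call(rbind, out)
}

#' Plot helpers for junction statistics
#'
#' Base-graphics angular scatter with the archetype points and the fitted
#' error ellipse.
#'
#' @param x a `junction_stats`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.junction_stats <- function(x, ...) {
  graphics::plot(x$points, xlim = c(0, 180), ylim = c(0, 180),
                 xlab = expression(theta[1]), ylab = expression(theta[2]),
                 pch = 16, col = grDevices::adjustcolor("steelblue", 0.6),
                 ...)
  proto <- rbind(c(120, 120), c(90, 135), c(90, 90))
  graphics::points(proto, pch = 3, cex = 1.5, col = "black")
  if (!x$ellipse$degenerate) {
    tt <- seq(0, 2 * pi, length.out = 100)
    rot <- x$ellipse$angle
    exy <- cbind(x$ellipse$axes[1] * cos(tt), x$ellipse$axes[2] * sin(tt))
    exy <- exy %*% rbind(c(cos(rot), sin(rot)), c(-sin(rot), cos(rot)))
    graphics::lines(sweep(exy, 2, x$ellipse$center, `+`), col = "red")
  }
  graphics::points(x$mean[1], x$mean[2], pch = 17, col = "red")
  invisible(x)
}
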