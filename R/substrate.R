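#' Configuration for the synthetic papillary substrate
#'
#' Describes a quasi-regular lattice of smooth millimetric bumps (dermal
#' papillae) on a flat domain: a hexagonal arrangement of centres with
#' seeded Gaussian jitter, each carrying a compactly-supported smooth bump.
#'
#' @param mean_spacing average trough spacing `<d>` between papilla centres
#'   (mm).
#' @param amplitude papilla height A (mm); 0 gives a flat substrate.
#' @param radius bump support radius (mm); must be `< mean_spacing` so that
#'   flat-bottomed troughs exist between papillae.
#' @param jitter_sd standard deviation of the per-centre 2D Gaussian jitter
#'   (mm); must be `< mean_spacing / 2` to keep the lattice quasi-regular.
#' @param domain numeric 2-vector, domain size (mm x mm); the default
#'   holds roughly 15 papillae at the default spacing.
#' @param seed integer seed; centres are a pure function of the config.
#' @return a `papilla_config` list.
#' @export
papilla_config <- function(mean_spacing = 2, amplitude = 0.6,
                           radius = 0.8, jitter_sd = 0.2,
                           domain = c(7, 6), seed = 1L) {
  if (mean_spacing <= 0) stopf("mean_spacing must be > 0")
  if (amplitude < 0) stopf("amplitude must be >= 0")
  if (jitter_sd >= mean_spacing / 2)
    stopf("jitter_sd must be < mean_spacing / 2 for a quasi-regular lattice")
  if (radius >= mean_spacing)
    stopf("papilla radius must be < mean_spacing so that troughs exist")
  if (length(domain) != 2 || any(domain <= 0)) stopf("bad domain")
  if (any(domain < mean_spacing))
    stopf("domain too small to hold one lattice cell")
  structure(list(mean_spacing = mean_spacing, amplitude = amplitude,
                 radius = radius, jitter_sd = jitter_sd,
                 domain = as.numeric(domain), seed = as.integer(seed)),
            class = "papilla_config")
}

# Hexagonal lattice of centres covering [0, domain], jittered.
papilla_centers <- function(config) {
  d <- config$mean_spacing
  rowh <- d * sqrt(3) / 2
  jmax <- floor(config$domain[2] / rowh)
  pts <- list()
  for (j in 0:jmax) {
    x0 <- (j %% 2) * d / 2
    xs <- seq(x0, config$domain[1], by = d)
    pts[[j + 1]] <- cbind(xs, j * rowh)
  }
  centers <- do.call(rbind, pts)
  if (config$jitter_sd > 0) {
    centers <- with_seed(config$seed, {
      centers + matrix(rnorm(length(centers), sd = config$jitter_sd),
                       ncol = 2)
    })
  }
  colnames(centers) <- c("x", "y")
  centers
}

# Compactly-supported smooth bump, b(0) = A, b(r >= R) = 0, C^inf at r = R.
bump_kernel <- function(r, A, R) {
  out <- numeric(length(r))
  in_r <- r < R & A > 0
  u2 <- (r[in_r] / R)^2
  out[in_r] <- A * exp(1 - 1 / (1 - u2))
  out
}

bump_kernel_deriv <- function(r, A, R) {
  out <- numeric(length(r))
  in_r <- r < R & r > 0 & A > 0
  u <- r[in_r] / R
  b <- A * exp(1 - 1 / (1 - u^2))
  out[in_r] <- -b * 2 * u / (R * (1 - u^2)^2)
  out
}

#' Synthetic papillary substrate
#'
#' Generates the analytic height field of a jittered hexagonal lattice of
#' smooth bumps (the stand-in for micro-CT papilla geometry) together with
#' a triangulated sampling of it.  Overlapping bumps are combined with a
#' smooth maximum (p-norm, p = 8) so that troughs stay genuinely flat
#' between papillae and no spurious ridges appear where bumps overlap.
#'
#' @param config a [papilla_config()].
#' @param edge_length sampling mesh edge length (mm); default
#'   `mean_spacing / 20`.
#' @return list with components `substrate` (a `substrate` object) and
#'   `mesh` (a `tri_mesh` sampling it).
#' @examples
#' gen <- generate_papilla_substrate(papilla_config(seed = 1),
#'                                   edge_length = 0.5)
#' gen$mesh
#' mean(label_troughs(gen$substrate, gen$mesh, tau = 0.4))
#' @export
generate_papilla_substrate <- function(config,
                                       edge_length = config$mean_spacing / 20) {
  stopifnot(inherits(config, "papilla_config"))
  centers <- papilla_centers(config)
  sub <- substrate_papilla(centers, config)
  mesh <- substrate_mesh(sub, edge_length)
  list(substrate = sub, mesh = mesh)
}

substrate_papilla <- function(centers, config) {
  A <- config$amplitude
  R <- config$radius
  p <- 8
  height <- function(x, y) {
    if (A == 0) return(numeric(length(x)))
    acc <- numeric(length(x))
    for (k in seq_len(nrow(centers))) {
      r <- sqrt((x - centers[k, 1])^2 + (y - centers[k, 2])^2)
      acc <- acc + bump_kernel(r, A, R)^p
    }
    acc^(1 / p)
  }
  grad <- function(x, y) {
    gx <- gy <- numeric(length(x))
    if (A == 0) return(cbind(gx, gy))
    acc <- numeric(length(x))
    sx <- sy <- numeric(length(x))
    for (k in seq_len(nrow(centers))) {
      dx <- x - centers[k, 1]
      dy <- y - centers[k, 2]
      r <- sqrt(dx^2 + dy^2)
      b <- bump_kernel(r, A, R)
      db <- bump_kernel_deriv(r, A, R)
      acc <- acc + b^p
      w <- ifelse(r > 0, b^(p - 1) * db / pmax(r, 1e-300), 0)
      sx <- sx + w * dx
      sy <- sy + w * dy
    }
    pos <- acc > 0
    gx[pos] <- acc[pos]^(1 / p - 1) * sx[pos]
    gy[pos] <- acc[pos]^(1 / p - 1) * sy[pos]
    cbind(gx, gy)
  }
  structure(list(kind = "papilla", height = height, grad = grad,
                 centers = centers, amplitude = A, radius = R,
                 mean_spacing = config$mean_spacing,
                 domain = config$domain, config = config),
            class = "substrate")
}

#' Analytic test substrates
#'
#' `ridge_substrate()` builds sinusoidal ridges
#' `S(x, y) = A cos(2 pi x / d)` (troughs are the bands around
#' `x = d/2 + k d`); `flat_substrate()` is the zero-amplitude degenerate
#' case.  `rotate_substrate()` rotates any substrate in-plane about the
#' domain centre, for equivariance checks.
#'
#' @param amplitude ridge amplitude A (mm).
#' @param spacing ridge period d (mm).
#' @param domain numeric 2-vector (mm).
#' @return a `substrate` object.
#' @export
ridge_substrate <- function(amplitude = 0.5, spacing = 2, domain = c(8, 7)) {
  k <- 2 * pi / spacing
  structure(list(kind = "ridge",
                 height = function(x, y) amplitude * cos(k * x),
                 grad = function(x, y)
                   cbind(-amplitude * k * sin(k * x), 0 * y),
                 centers = NULL, amplitude = amplitude,
                 mean_spacing = spacing, domain = as.numeric(domain)),
            class = "substrate")
}

#' @rdname ridge_substrate
#' @export
flat_substrate <- function(domain = c(8, 7), spacing = 2) {
  structure(list(kind = "flat",
                 height = function(x, y) numeric(length(x)),
                 grad = function(x, y) cbind(0 * x, 0 * y),
                 centers = NULL, amplitude = 0,
                 mean_spacing = spacing, domain = as.numeric(domain)),
            class = "substrate")
}

#' @rdname ridge_substrate
#' @param substrate a `substrate`.
#' @param angle rotation angle (degrees, counter-clockwise).
#' @export
rotate_substrate <- function(substrate, angle) {
  th <- angle * pi / 180
  ctr <- substrate$domain / 2
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)  # columns
  base_h <- substrate$height
  base_g <- substrate$grad
  # point in rotated frame -> pull back to the original frame
  pull <- function(x, y) {
    dx <- x - ctr[1]; dy <- y - ctr[2]
    cbind(ctr[1] + cos(th) * dx + sin(th) * dy,
          ctr[2] - sin(th) * dx + cos(th) * dy)
  }
  out <- substrate
  out$height <- function(x, y) {
    p <- pull(x, y)
    base_h(p[, 1], p[, 2])
  }
  out$grad <- function(x, y) {
    p <- pull(x, y)
    g <- base_g(p[, 1], p[, 2])
    cbind(cos(th) * g[, 1] - sin(th) * g[, 2],
          sin(th) * g[, 1] + cos(th) * g[, 2])
  }
  if (!is.null(substrate$centers)) {
    d <- sweep(substrate$centers, 2, ctr)
    out$centers <- sweep(d %*% t(Rm), 2, ctr, `+`)
  }
  out
}

#' Substrate field queries
#'
#' Height, gradient and unit outward normal of a substrate at arbitrary
#' in-plane positions.
#'
#' @param substrate a `substrate`.
#' @param x,y coordinates (mm).
#' @return `substrate_height`: heights (mm); `substrate_normals`: an
#'   n x 3 matrix of unit normals.
#' @export
substrate_height <- function(substrate, x, y) substrate$height(x, y)

#' @rdname substrate_height
#' @export
substrate_normals <- function(substrate, x, y) {
  g <- substrate$grad(x, y)
  n <- cbind(-g[, 1], -g[, 2], 1)
  n / sqrt(rowSums(n^2))
}

#' Triangulated sampling of a substrate
#'
#' @param substrate a `substrate`.
#' @param edge_length mesh edge length (mm).
#' @return a `tri_mesh` whose vertices lie on the substrate surface.
#' @export
substrate_mesh <- function(substrate, edge_length) {
  stopifnot(edge_length > 0)
  nx <- max(2L, round(substrate$domain[1] / edge_length) + 1L)
  ny <- max(2L, round(substrate$domain[2] / (edge_length * sqrt(3) / 2)) + 1L)
  grid_mesh(nx, ny, spacing = edge_length,
            height = function(x, y) substrate$height(x, y))
}

#' Label trough vertices
#'
#' A vertex is a trough vertex iff its substrate height is below
#' `tau * amplitude`.  For a flat substrate (amplitude 0) the mask is empty
#' by convention.
#'
#' @param substrate a `substrate`.
#' @param mesh a `tri_mesh` (its vertex positions are queried in-plane).
#' @param tau height fraction threshold in (0, 1).
#' @return logical mask over mesh vertices.
#' @export
label_troughs <- function(substrate, mesh, tau = 0.4) {
  if (tau <= 0 || tau >= 1) stopf("tau must be in (0, 1)")
  if (substrate$amplitude == 0) return(rep(FALSE, nrow(mesh$vertices)))
  s <- substrate_height(substrate, mesh$vertices[, 1], mesh$vertices[, 2])
  s < tau * substrate$amplitude
}

# Trough membership of arbitrary in-plane points.
in_trough <- function(substrate, x, y, tau = 0.4) {
  if (substrate$amplitude == 0) return(rep(FALSE, length(x)))
  substrate_height(substrate, x, y) < tau * substrate$amplitude
}

#' Local trough (valley-line) direction
#'
#' Principal direction of smallest absolute curvature of the height field,
#' from the eigen-decomposition of the Hessian of S (central finite
#' differences on the closed-form height).  Directions are undirected
#' (modulo 180 degrees) and reported with a bearing in [0, 180).  Near
#' umbilic points (isotropic curvature) the direction is undefined and
#' flagged.
#'
#' @param substrate a `substrate`.
#' @param points n x 2 matrix of in-plane positions (mm).
#' @param step finite-difference step (mm); default `mean_spacing / 200`.
#' @param tol relative eigenvalue-separation tolerance below which a point
#'   is flagged umbilic.
#' @return n x 2 matrix of unit direction vectors with attribute `defined`
#'   (logical; FALSE rows are NA).
#' @export
local_trough_direction <- function(substrate, points,
                                   step = substrate$mean_spacing / 200,
                                   tol = 0.1) {
  points <- matrix(points, ncol = 2)
  x <- points[, 1]; y <- points[, 2]
  S <- substrate$height
  f0 <- S(x, y)
  sxx <- (S(x + step, y) - 2 * f0 + S(x - step, y)) / step^2
  syy <- (S(x, y + step) - 2 * f0 + S(x, y - step)) / step^2
  sxy <- (S(x + step, y + step) - S(x + step, y - step) -
            S(x - step, y + step) + S(x - step, y - step)) / (4 * step^2)
  n <- length(x)
  dirs <- matrix(NA_real_, n, 2)
  defined <- logical(n)
  for (i in seq_len(n)) {
    H <- matrix(c(sxx[i], sxy[i], sxy[i], syy[i]), 2)
    ev <- eigen(H, symmetric = TRUE)
    lam <- ev$values  # decreasing
    scale <- max(abs(lam))
    if (scale < 1e-10 || abs(abs(lam[1]) - abs(lam[2])) < tol * scale) next
    k <- which.min(abs(lam))
    v <- ev$vectors[, k]
    if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) v <- -v  # bearing in [0, 180)
    dirs[i, ] <- v
    defined[i] <- TRUE
  }
  attr(dirs, "defined") <- defined
  dirs
}

#' Measure trough spacing from a meshed substrate
#'
#' Mean nearest-neighbour distance between papilla apexes, the apexes being
#' local height maxima above `0.8 * amplitude`.  When the substrate carries
#' its generating centre list, that list is used directly.
#'
#' @param substrate a `substrate`.
#' @param mesh optional `tri_mesh` to detect apexes from.
#' @return mean spacing (mm).
#' @export
measure_trough_spacing <- function(substrate, mesh = NULL) {
  if (!is.null(substrate$centers)) {
    return(mean_nn_distance(substrate$centers))
  }
  stopifnot(!is.null(mesh))
  z <- mesh$vertices[, 3]
  n <- nrow(mesh$vertices)
  is_max <- z > 0.8 * max(z)
  keep <- logical(n)
  for (i in which(is_max)) {
    nbs <- mesh$adj_idx[seq.int(mesh$adj_ptr[i], mesh$adj_ptr[i + 1] - 1L)]
    keep[i] <- all(z[nbs] <= z[i])
  }
  apex <- mesh$vertices[keep, 1:2, drop = FALSE]
  if (nrow(apex) < 2) stopf("fewer than two apexes detected")
  mean_nn_distance(apex)
}

mean_nn_distance <- function(pts) {
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Substrate backed by a triangle mesh
#'
#' Wraps an arbitrary open height-field mesh (for example a regularised
#' micro-CT surface) as a `substrate`: height and gradient are evaluated by
#' barycentric interpolation on the (x, y) projection.
#'
#' @param mesh a `tri_mesh`.
#' @param mean_spacing trough spacing (mm); measured from apexes when
#'   omitted.
#' @return a `substrate` with `kind = "mesh"`.
#' @export
substrate_from_mesh <- function(mesh, mean_spacing = NULL) {
  verts <- mesh$vertices
  faces <- mesh$faces
  nrm <- vertex_normals(mesh)
  height <- function(x, y) {
    cpp_interp_xy(cbind(x, y), verts, faces,
                  matrix(verts[, 3], ncol = 1))[, 1]
  }
  grad <- function(x, y) {
    nz <- cpp_interp_xy(cbind(x, y), verts, faces, nrm)
    w <- pmax(nz[, 3], 1e-6)
    cbind(-nz[, 1] / w, -nz[, 2] / w)  # slope = -n_xy / n_z
  }
  dom <- c(max(verts[, 1]) - min(verts[, 1]),
           max(verts[, 2]) - min(verts[, 2]))
  sub <- structure(list(kind = "mesh", height = height, grad = grad,
                        centers = NULL,
                        amplitude = max(verts[, 3]) - min(verts[, 3]),
                        mean_spacing = mean_spacing %||% NA_real_,
                        domain = dom, mesh = mesh),
                   class = "substrate")
  if (is.null(mean_spacing)) {
    sp <- try(measure_trough_spacing(sub, mesh), silent = TRUE)
    sub$mean_spacing <- if (inherits(sp, "try-error")) NA_real_ else sp
  }
  sub
}

#' Export papilla centres as CSV
#'
#' @param substrate a papilla `substrate`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_centers_csv <- function(substrate, path) {
  stopifnot(!is.null(substrate$centers))
  df <- data.frame(x = substrate$centers[, 1], y = substrate$centers[, 2],
                   A = substrate$amplitude, R = substrate$radius %||% NA)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
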