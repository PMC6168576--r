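#' Shell material and interaction parameters
#'
#' Parameters of the lattice-spring shell.  `k_s` is the per-length spring
#' stiffness (energy/length): the spring energy is
#' `(k_s/2) * l0 * eps^2` per edge so that refinement does not change the
#' material behaviour.  `k_b` multiplies the squared deviation of each
#' hinge's signed dihedral angle from its rest value (energy).  `k_v`
#' penalises relative face-area change (energy/area).  `k_sub` tethers each
#' node to its substrate foot point offset by the growth height
#' (energy/length^2), and `k_c`/`contact_range` define the one-sided
#' node-face self-contact penalty.  `thickness` is the sheet thickness used
#' by the outer-fibre strain; `eps_c` the critical strain at which an edge
#' breaks.
#'
#' Defaults marked `NULL` are resolved against the mesh at
#' [init_shell()] time: `k_b` from thin-plate consistency
#' (`k_s * t^2 / (18 * lbar)` for mean edge length `lbar`), `k_v = k_s /
#' lbar`, `contact_range = lbar / 2`, and `gamma` near critical damping of
#' the slowest (tether) mode.
#'
#' @param k_s stretch stiffness (energy/length).
#' @param k_b bend stiffness (energy); `NULL` for the plate-consistent
#'   default.
#' @param k_v area stiffness (energy/area); `NULL` for `k_s / lbar`.
#' @param k_sub substrate tether stiffness (energy/length^2).
#' @param k_c contact stiffness (energy/length^2); 0 disables self-contact.
#' @param contact_range contact activation distance d_c (mm).
#' @param thickness sheet thickness t_s (mm).
#' @param eps_c critical strain for bond breaking (dimensionless).
#' @param mass node mass.
#' @param gamma damping coefficient; `NULL` for the critical-damping
#'   default.
#' @param strain_mode `"outer"` (membrane + outer-fibre bending term, the
#'   default fracture criterion) or `"membrane"`.
#' @return a `shell_params` list.
#' @export
shell_params <- function(k_s = 1, k_b = NULL, k_v = NULL, k_sub = 1.5,
                         k_c = 1, contact_range = NULL, thickness = 0.2,
                         eps_c = 0.3, mass = 1, gamma = NULL,
                         strain_mode = c("outer", "membrane")) {
  strain_mode <- match.arg(strain_mode)
  stopifnot(k_s >= 0, is.null(k_b) || k_b >= 0, is.null(k_v) || k_v >= 0,
            k_sub >= 0, k_c >= 0, thickness > 0, eps_c > 0, mass > 0)
  structure(list(k_s = k_s, k_b = k_b, k_v = k_v, k_sub = k_sub, k_c = k_c,
                 contact_range = contact_range, thickness = thickness,
                 eps_c = eps_c, mass = mass, gamma = gamma,
                 strain_mode = strain_mode),
            class = "shell_params")
}

resolve_params <- function(params, lbar) {
  p <- params
  p$k_b <- p$k_b %||% (p$k_s * p$thickness^2 / (18 * lbar))
  p$k_v <- p$k_v %||% (p$k_s / lbar)
  p$contact_range <- p$contact_range %||% (lbar / 2)
  p$gamma <- p$gamma %||% (2 * sqrt(p$mass * max(p$k_sub, 1e-3 * p$k_s / lbar)))
  p
}

#' Initialise the shell state from a substrate mesh
#'
#' The mesh's current geometry becomes the stress-free rest configuration:
#' rest lengths are the current edge lengths, rest hinge angles the current
#' dihedral angles (so a curved substrate yields a naturally curved shell
#' with zero initial energy), and every node is tethered to its initial
#' position (its substrate foot point) along the frozen substrate normal.
#'
#' @param mesh a `tri_mesh` (typically a substrate sampling).
#' @param substrate optional `substrate`; when given, tether normals are
#'   the substrate normals at the foot points, otherwise area-weighted
#'   vertex normals of the mesh.
#' @param params a [shell_params()]; `NULL` defaults are resolved here.
#' @return a `shell_state`.
#' @export
init_shell <- function(mesh, substrate = NULL, params = shell_params()) {
  stopifnot(inherits(mesh, "tri_mesh"))
  l0 <- edge_lengths(mesh)
  if (any(l0 <= 0)) stopf("zero-length edge in mesh")
  params <- resolve_params(params, mean(l0))
  pos <- mesh$vertices
  theta0 <- if (nrow(mesh$hinges)) cpp_hinge_angles(pos, mesh$hinges)
            else numeric()
  kappa0 <- cpp_edge_kappa(pos, mesh$edges, mesh$edge_hinge, mesh$hinges)
  nrm <- if (!is.null(substrate))
    substrate_normals(substrate, pos[, 1], pos[, 2])
  else vertex_normals(mesh)
  state <- structure(list(
    mesh = mesh, pos = pos, vel = matrix(0, nrow(pos), 3),
    fixed = rep(FALSE, nrow(pos)),
    l0 = l0, l0_init = l0,
    theta0 = theta0,
    A0 = face_areas(mesh), A0_init = face_areas(mesh),
    kappa0 = kappa0, kappa0_init = kappa0,
    broken = rep(FALSE, nrow(mesh$edges)),
    foot = pos, nrm = nrm, h = 0, s = 0,
    params = params), class = "shell_state")
  state
}

#' @export
print.shell_state <- function(x, ...) {
  cat(sprintf(paste0("shell_state: %d nodes, %d edges (%d broken), ",
                     "h = %.4g mm, s = %.4g\n"),
              nrow(x$pos), length(x$l0), sum(x$broken), x$h, x$s))
  invisible(x)
}

# Single gateway to the compiled force/energy assembly; `terms` selects
# which stiffnesses are active so each energy term is separately testable.
call_core <- function(state, terms = c("stretch", "bend", "area",
                                       "substrate", "contact")) {
  p <- state$params
  m <- state$mesh
  on <- function(t) t %in% terms
  cpp_forces_energy(state$pos, m$edges, state$l0, state$broken,
                    if (on("stretch")) p$k_s else 0,
                    m$hinges, state$theta0, m$hinge_edge, m$hinge_faces,
                    if (on("bend")) p$k_b else 0,
                    m$faces, state$A0, m$face_edges,
                    if (on("area")) p$k_v else 0,
                    state$foot, state$nrm, state$h,
                    if (on("substrate")) p$k_sub else 0,
                    if (on("contact")) p$k_c else 0, p$contact_range,
                    m$adj_ptr, m$adj_idx)
}

#' Shell energies and forces
#'
#' Each energy term and its analytic force (the negative energy gradient)
#' is available separately; `shell_energies()` returns all terms at once.
#'
#' @param state a `shell_state`.
#' @return energies are scalars (energy units); forces are n x 3 matrices.
#' @export
stretch_energy <- function(state) call_core(state, "stretch")$energy

#' @rdname stretch_energy
#' @export
stretch_forces <- function(state) call_core(state, "stretch")$forces

#' @rdname stretch_energy
#' @export
bend_energy <- function(state) call_core(state, "bend")$energy

#' @rdname stretch_energy
#' @export
bend_forces <- function(state) call_core(state, "bend")$forces

#' @rdname stretch_energy
#' @export
area_energy <- function(state) call_core(state, "area")$energy

#' @rdname stretch_energy
#' @export
area_forces <- function(state) call_core(state, "area")$forces

#' @rdname stretch_energy
#' @export
substrate_energy <- function(state) call_core(state, "substrate")$energy

#' @rdname stretch_energy
#' @export
substrate_forces <- function(state) call_core(state, "substrate")$forces

#' @rdname stretch_energy
#' @export
contact_energy <- function(state) call_core(state, "contact")$energy

#' @rdname stretch_energy
#' @export
contact_forces <- function(state) call_core(state, "contact")$forces

#' @rdname stretch_energy
#' @export
shell_energies <- function(state) {
  c(stretch = stretch_energy(state), bend = bend_energy(state),
    area = area_energy(state), substrate = substrate_energy(state),
    contact = contact_energy(state))
}

#' @rdname stretch_energy
#' @export
shell_forces <- function(state) call_core(state)$forces

#' Effective edge strain
#'
#' Outer-fibre strain of a sheet of thickness t_s:
#' `eps_eff = eps_membrane + (t_s / 2) * |kappa_e - kappa_e0|` with
#' `eps_membrane = (|e| - l0) / l0` and edge-wise curvature
#' `kappa_e = 2 theta / (h1 + h2)` (`h1`, `h2` the incident triangle
#' heights over the shared edge).  Boundary edges carry the membrane term
#' only, as do all edges under `strain_mode = "membrane"`.  Broken edges
#' give NA.
#'
#' @param state a `shell_state`.
#' @param mode override of the state's strain mode.
#' @return numeric vector over edges.
#' @export
effective_edge_strain <- function(state, mode = NULL) {
  mode <- mode %||% state$params$strain_mode
  m <- state$mesh
  cpp_edge_strain(state$pos, m$edges, state$l0, state$broken,
                  m$edge_hinge, m$hinges, m$hinge_faces, m$face_edges,
                  state$kappa0, state$params$thickness,
                  if (mode == "outer") 1L else 0L)
}

#' Per-face membrane strain tensors and per-edge effective strain
#'
#' Computes, for every face with three unbroken rest edges, the in-plane
#' deformation gradient from rest to current edge vectors, its Green strain
#' tensor, and the principal strains/directions (directions reported as 2D
#' unit vectors in the plane projection).
#'
#' @param state a `shell_state`.
#' @return list with `edge_strain` (vector over edges) and `faces`, a data
#'   frame with principal strains `e1 >= e2` and principal direction
#'   columns `d1x`, `d1y`.
#' @export
strain_field <- function(state) {
  m <- state$mesh
  scale <- 1 - state$s
  rest <- state$foot * scale
  pos <- state$pos
  f <- m$faces
  nf <- nrow(f)
  e1 <- e2 <- d1x <- d1y <- rep(NA_real_, nf)
  for (i in seq_len(nf)) {
    a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
    u_r <- rest[b, ] - rest[a, ]
    v_r <- rest[cc, ] - rest[a, ]
    u_c <- pos[b, ] - pos[a, ]
    v_c <- pos[cc, ] - pos[a, ]
    # local orthonormal frames
    fr <- local_frame(u_r, v_r)
    if (is.null(fr)) next
    fc <- local_frame(u_c, v_c)
    if (is.null(fc)) next
    Mr <- cbind(c(sum(u_r * fr$t1), sum(u_r * fr$t2)),
                c(sum(v_r * fr$t1), sum(v_r * fr$t2)))
    Mc <- cbind(c(sum(u_c * fc$t1), sum(u_c * fc$t2)),
                c(sum(v_c * fc$t1), sum(v_c * fc$t2)))
    Fm <- Mc %*% solve(Mr)
    E <- 0.5 * (t(Fm) %*% Fm - diag(2))
    ev <- eigen(E, symmetric = TRUE)
    e1[i] <- ev$values[1]
    e2[i] <- ev$values[2]
    # principal direction back in 3D (rest frame), projected in-plane
    v3 <- ev$vectors[1, 1] * fr$t1 + ev$vectors[2, 1] * fr$t2
    nv <- sqrt(v3[1]^2 + v3[2]^2)
    if (nv > 1e-12) {
      d1x[i] <- v3[1] / nv
      d1y[i] <- v3[2] / nv
    }
  }
  list(edge_strain = effective_edge_strain(state),
       faces = data.frame(e1 = e1, e2 = e2, d1x = d1x, d1y = d1y))
}

local_frame <- function(u, v) {
  t1 <- u / sqrt(sum(u^2))
  w <- v - sum(v * t1) * t1
  nw <- sqrt(sum(w^2))
  if (!is.finite(nw) || nw < 1e-12) return(NULL)
  list(t1 = t1, t2 = w / nw)
}

# Break a single edge: flag it; hinge and incident-face area terms
# deactivate automatically through the broken mask.
break_edge <- function(state, edge) {
  state$broken[edge] <- TRUE
  state
}
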