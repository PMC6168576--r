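#' Quasi-static simulation configuration
#'
#' @param protocol `"growth"` (quasi-static increase of the tether offset
#'   h, modelling addition of keratinous sheets below) or `"shrinkage"`
#'   (uniform reduction of rest lengths, modelling desiccation).
#' @param increment per-step increment: `delta h` in mm for growth,
#'   `delta s` (dimensionless) for shrinkage.  Defaults: `max_offset / 16`
#'   and `max_shrink / 16`.
#' @param max_offset growth stop offset h_max (mm); default `<d> / 6` of
#'   the substrate.
#' @param max_shrink shrinkage stop factor s_max in (0, 1).
#' @param target_broken_frac stop once this fraction of edges is broken.
#' @param dt integrator time step; `NULL` for the stability-bound default
#'   (auto-reduced on divergence).
#' @param tol_f,tol_v convergence tolerances on the max per-node force and
#'   speed.
#' @param max_iter relaxation iteration budget per call.
#' @param contact_every steps between contact-pair rebuilds.
#' @param snapshot_every store a state snapshot every this many protocol
#'   steps (`Inf` keeps only the final state).
#' @param seed run seed, recorded with every result.
#' @return a `sim_config` list.
#' @export
sim_config <- function(protocol = c("growth", "shrinkage"),
                       increment = NULL, max_offset = NULL,
                       max_shrink = 0.5, target_broken_frac = 0.03,
                       dt = NULL, tol_f = 1e-3, tol_v = 1e-3,
                       max_iter = 400000L, contact_every = 25L,
                       snapshot_every = Inf, seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(is.null(increment) || increment > 0,
            target_broken_frac > 0, target_broken_frac < 1,
            tol_f > 0, tol_v > 0, max_shrink > 0, max_shrink < 1)
  structure(list(protocol = protocol, increment = increment,
                 max_offset = max_offset, max_shrink = max_shrink,
                 target_broken_frac = target_broken_frac, dt = dt,
                 tol_f = tol_f, tol_v = tol_v,
                 max_iter = as.integer(max_iter),
                 contact_every = as.integer(contact_every),
                 snapshot_every = snapshot_every, seed = as.integer(seed)),
            class = "sim_config")
}

# Stability-bound time step: 0.5 * sqrt(m / k_max) over the stiffest
# single-node coupling (springs, tether, bending, area, contact).
stable_dt <- function(state) {
  p <- state$params
  lbar <- mean(state$l0)
  k_edge <- p$k_s / min(state$l0)
  k_node <- 6 * k_edge + p$k_sub + 16 * p$k_b / lbar^2 + 3 * p$k_v + p$k_c
  0.5 * sqrt(p$mass / k_node)
}

#' Relax the shell to its quasi-static steady state
#'
#' Damped Newtonian dynamics `m a = F - gamma v` integrated with
#' semi-implicit Euler until the maximum per-node force and speed drop
#' below tolerance.  The time step is capped at the stability bound and
#' automatically reduced if the integration diverges.
#'
#' @param state a `shell_state`.
#' @param config a [sim_config()] (tolerances, iteration budget).
#' @param method `"fire"` (default) accelerates the damped dynamics with
#'   FIRE-style adaptive damping and time step; `"damped"` integrates the
#'   plain equation with constant `gamma`.  Both share the stationary
#'   state `F = 0`, `v = 0`.
#' @return the converged `shell_state`; attributes `iterations`,
#'   `max_force` and `energy` report diagnostics.
#' @export
relax <- function(state, config = sim_config(),
                  method = c("fire", "damped")) {
  method <- match.arg(method)
  p <- state$params
  m <- state$mesh
  dt <- config$dt %||% stable_dt(state)
  for (attempt in 1:6) {
    res <- cpp_relax(state$pos, state$vel, state$fixed,
                     m$edges, state$l0, state$broken, p$k_s,
                     m$hinges, state$theta0, m$hinge_edge, m$hinge_faces,
                     p$k_b,
                     m$faces, state$A0, m$face_edges, p$k_v,
                     state$foot, state$nrm, state$h, p$k_sub,
                     p$k_c, p$contact_range, m$adj_ptr, m$adj_idx,
                     p$mass, p$gamma, dt, config$tol_f, config$tol_v,
                     config$max_iter, config$contact_every,
                     method == "fire")
    if (!res$diverged) break
    dt <- dt / 2
  }
  if (res$diverged)
    stopf("relaxation diverged even at dt = %g", dt)
  if (!res$converged)
    stopf(paste0("relaxation did not converge within %d iterations ",
                 "(max residual force %.3g at node %d)"),
          config$max_iter, res$max_force, res$worst_node)
  state$pos <- res$pos
  state$vel <- res$vel
  attr(state, "iterations") <- res$iterations
  attr(state, "max_force") <- res$max_force
  attr(state, "energy") <- res$energy
  state
}

#' Fraction of broken edges
#' @param state a `shell_state`.
#' @return scalar in \\[0, 1\\].
#' @export
broken_fraction <- function(state) mean(state$broken)

#' Break over-strained bonds one at a time
#'
#' Repeatedly computes the effective strain of every unbroken edge; while
#' the maximum exceeds the critical strain `eps_c`, breaks exactly the
#' single highest-strain edge (ties resolved to the lowest edge id),
#' deactivating its hinge and its incident faces' area terms, then
#' re-relaxes.  This one-bond-at-a-time rule yields crack propagation
#' rather than simultaneous shattering.
#'
#' @param state a relaxed `shell_state`.
#' @param config a [sim_config()].
#' @param max_breaks safety cap on breaks per call.
#' @return list with the updated `state` and `events`, a data frame of
#'   break events (edge id and strain at breaking, in order).
#' @export
break_bonds <- function(state, config = sim_config(), max_breaks = Inf) {
  eps_c <- state$params$eps_c
  edges <- ints <- numeric(0)
  repeat {
    eps <- effective_edge_strain(state)
    i <- which.max(eps)  # NA (broken) ignored; ties -> lowest id
    if (!length(i) || is.na(eps[i]) || eps[i] <= eps_c) break
    edges <- c(edges, i)
    ints <- c(ints, eps[i])
    state <- break_edge(state, i)
    state <- relax(state, config)
    if (length(edges) >= max_breaks) break
  }
  list(state = state,
       events = data.frame(edge = as.integer(edges), strain = ints))
}

#' Run the quasi-static growth protocol
#'
#' Alternates `h <- h + dh`, relaxation, and bond breaking until the
#' broken-edge fraction reaches its target or h reaches `h_max`
#' (default `<d> / 6`).
#'
#' @param substrate a `substrate`.
#' @param mesh a `tri_mesh` sampling of it.
#' @param params [shell_params()].
#' @param config [sim_config()].
#' @return a `sim_result`: final state, fracture event log, per-step
#'   summary, snapshots, and the resolved configuration.
#' @export
run_growth <- function(substrate, mesh, params = shell_params(),
                       config = sim_config("growth")) {
  run_protocol(substrate, mesh, params, config, "growth")
}

#' Run the quasi-static shrinkage (desiccation) protocol
#'
#' Uniformly scales all rest lengths by `(1 - s)` (rest areas by
#' `(1 - s)^2`; rest hinge angles unchanged, so rest curvatures scale as
#' `1 / (1 - s)`), relaxing and breaking bonds after each decrement, with
#' the tether offset held fixed.
#'
#' @inheritParams run_growth
#' @export
run_shrinkage <- function(substrate, mesh, params = shell_params(),
                          config = sim_config("shrinkage")) {
  run_protocol(substrate, mesh, params, config, "shrinkage")
}

run_protocol <- function(substrate, mesh, params, config, protocol) {
  stopifnot(inherits(config, "sim_config"))
  state <- init_shell(mesh, substrate, params)
  d <- substrate$mean_spacing
  if (protocol == "growth") {
    hmax <- config$max_offset %||% (d / 6)
    inc <- config$increment %||% (hmax / 16)
  } else {
    smax <- config$max_shrink
    inc <- config$increment %||% (smax / 16)
  }
  events <- list()
  summ <- list()
  snapshots <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    if (protocol == "growth") {
      state$h <- min(state$h + inc, hmax)
      ctrl <- state$h
      done_ctrl <- state$h >= hmax - 1e-12
    } else {
      state$s <- min(state$s + inc, smax)
      scale <- 1 - state$s
      state$l0 <- state$l0_init * scale
      state$A0 <- state$A0_init * scale^2
      ctrl <- state$s
      done_ctrl <- state$s >= smax - 1e-12
    }
    state <- relax(state, config)
    ne <- length(state$broken)
    remaining <- ceiling(config$target_broken_frac * ne) - sum(state$broken)
    bb <- break_bonds(state, config, max_breaks = max(remaining, 0))
    state <- bb$state
    if (nrow(bb$events))
      events[[length(events) + 1L]] <-
        cbind(step = step, control = ctrl, bb$events)
    en <- shell_energies(state)
    summ[[step]] <- data.frame(step = step, h = state$h, s = state$s,
                               E_stretch = en[["stretch"]],
                               E_bend = en[["bend"]],
                               E_area = en[["area"]],
                               E_substrate = en[["substrate"]],
                               E_contact = en[["contact"]],
                               broken_frac = broken_fraction(state),
                               iterations = attr(state, "iterations"))
    if (is.finite(config$snapshot_every) &&
        step %% config$snapshot_every == 0)
      snapshots[[length(snapshots) + 1L]] <- state
    if (broken_fraction(state) >= config$target_broken_frac || done_ctrl)
      break
  }
  structure(list(final_state = state,
                 events = if (length(events)) do.call(rbind, events)
                          else data.frame(step = integer(),
                                          control = numeric(),
                                          edge = integer(),
                                          strain = numeric()),
                 summary = do.call(rbind, summ),
                 snapshots = snapshots,
                 substrate = substrate,
                 config = config, params = state$params,
                 protocol = protocol),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  s <- x$final_state
  cat(sprintf(paste0("sim_result (%s): %d steps, %d broken edges ",
                     "(%.2f%%), final h = %.4g mm, s = %.4g\n"),
              x$protocol, nrow(x$summary), sum(s$broken),
              100 * broken_fraction(s), s$h, s$s))
  invisible(x)
}

#' Crack localisation and orientation metrics
#'
#' For every broken edge, evaluates whether its (rest) midpoint lies in
#' the trough mask and the acute angle between the edge direction and the
#' local trough direction; additionally measures the orientation of the
#' crack lines themselves (the seam segments of the projected crack
#' network, which run roughly perpendicular to the broken bonds they
#' sever) against the local trough direction.
#'
#' @param result a `sim_result` (or a `shell_state`).
#' @param substrate the substrate the run used.
#' @param tau trough threshold passed to [label_troughs()].
#' @return list with `broken_frac`, `trough_fraction` (fraction of broken
#'   edges with midpoint in a trough), `mean_angle` (degrees, broken-edge
#'   direction vs trough direction, over edges with a defined trough
#'   direction), `crack_angle` (degrees, crack-line segment direction vs
#'   trough direction), `angles`, `crack_angles`, and `n_broken`.
#' @export
crack_trough_metrics <- function(result, substrate, tau = 0.4) {
  state <- if (inherits(result, "sim_result")) result$final_state else result
  m <- state$mesh
  br <- which(state$broken)
  if (!length(br))
    return(list(broken_frac = 0, trough_fraction = NA_real_,
                mean_angle = NA_real_, crack_angle = NA_real_,
                angles = numeric(), crack_angles = numeric(),
                n_broken = 0L))
  a <- state$foot[m$edges[br, 1], 1:2, drop = FALSE]
  b <- state$foot[m$edges[br, 2], 1:2, drop = FALSE]
  mid <- (a + b) / 2
  trough <- in_trough(substrate, mid[, 1], mid[, 2], tau)
  dir_t <- local_trough_direction(substrate, mid)
  ok <- attr(dir_t, "defined")
  ang <- acute_angle((b - a)[ok, , drop = FALSE], dir_t[ok, , drop = FALSE])
  net <- project_crack_network(state)
  cang <- numeric()
  if (nrow(net$segments)) {
    sa <- net$nodes[net$segments[, 1], , drop = FALSE]
    sb <- net$nodes[net$segments[, 2], , drop = FALSE]
    smid <- (sa + sb) / 2
    sdir <- local_trough_direction(substrate, smid)
    sok <- attr(sdir, "defined")
    cang <- acute_angle((sb - sa)[sok, , drop = FALSE],
                        sdir[sok, , drop = FALSE])
  }
  list(broken_frac = broken_fraction(state),
       trough_fraction = mean(trough),
       mean_angle = if (length(ang)) mean(ang) else NA_real_,
       crack_angle = if (length(cang)) mean(cang) else NA_real_,
       angles = ang, crack_angles = cang, n_broken = length(br))
}

#' Virtual cross-section through the layered stratum corneum
#'
#' Cuts the simulation along a straight line in the substrate parameter
#' plane and emits a stack of profiles: the substrate, `n_sheets - 2`
#' interpolated intermediate sheets, and the deformed outer shell.  Broken
#' edges crossed by the cut open explicit gaps (of one local edge length)
#' in the sheets above the configured uncracked depth; the innermost
#' sheets are drawn continuous.
#'
#' @param result a `sim_result`.
#' @param substrate the substrate of the run.
#' @param from,to 2-vectors, cut endpoints (mm).
#' @param n_sheets number of sheet profiles (>= 2).
#' @param n_samples stations along the cut.
#' @param uncracked_frac sheets at depth fraction below this value stay
#'   continuous.
#' @return data frame with columns `sheet` (1 = substrate), `frac` (depth
#'   fraction), `arc` (mm along the cut), `x`, `y`, `z` (NA inside crack
#'   gaps); empty with a warning when the cut misses the mesh.
#' @export
virtual_section <- function(result, substrate, from, to, n_sheets = 4,
                            n_samples = 200, uncracked_frac = 0.5) {
  stopifnot(n_sheets >= 2)
  state <- result$final_state
  m <- state$mesh
  t <- seq(0, 1, length.out = n_samples)
  px <- from[1] + t * (to[1] - from[1])
  py <- from[2] + t * (to[2] - from[2])
  arc <- t * sqrt(sum((to - from)^2))
  zsub <- substrate_height(substrate, px, py)
  shell <- cpp_interp_xy(cbind(px, py), state$foot, m$faces,
                         state$pos)  # deformed position at material (x, y)
  if (all(is.na(shell[, 3]))) {
    warning("cut misses the mesh; empty section")
    return(data.frame(sheet = integer(), frac = numeric(), arc = numeric(),
                      x = numeric(), y = numeric(), z = numeric()))
  }
  # crack gaps: broken rest edges intersecting the cut segment
  gaps <- matrix(numeric(), 0, 2)
  br <- which(state$broken)
  if (length(br)) {
    e1 <- state$foot[m$edges[br, 1], 1:2, drop = FALSE]
    e2 <- state$foot[m$edges[br, 2], 1:2, drop = FALSE]
    for (i in seq_along(br)) {
      hit <- segment_intersect(from, to, e1[i, ], e2[i, ])
      if (!is.null(hit)) {
        half <- state$l0_init[br[i]] / 2
        gaps <- rbind(gaps, c(hit * arc[n_samples] - half,
                              hit * arc[n_samples] + half))
      }
    }
  }
  out <- list()
  fracs <- seq(0, 1, length.out = n_sheets)
  for (k in seq_len(n_sheets)) {
    f <- fracs[k]
    z <- (1 - f) * zsub + f * shell[, 3]
    x <- (1 - f) * px + f * shell[, 1]
    y <- (1 - f) * py + f * shell[, 2]
    if (f > uncracked_frac && nrow(gaps)) {
      for (g in seq_len(nrow(gaps))) {
        inside <- arc > gaps[g, 1] & arc < gaps[g, 2]
        z[inside] <- NA
      }
    }
    out[[k]] <- data.frame(sheet = k, frac = f, arc = arc, x = x, y = y,
                           z = z)
  }
  do.call(rbind, out)
}

# Parameter of intersection along segment (a1, a2), or NULL.
segment_intersect <- function(a1, a2, b1, b2) {
  r <- a2 - a1
  s <- b2 - b1
  denom <- r[1] * s[2] - r[2] * s[1]
  if (abs(denom) < 1e-14) return(NULL)
  q <- b1 - a1
  t <- (q[1] * s[2] - q[2] * s[1]) / denom
  u <- (q[1] * r[2] - q[2] * r[1]) / denom
  if (t < 0 || t > 1 || u < 0 || u > 1) return(NULL)
  t
}

#' Export a simulation snapshot as PLY with edge attributes
#'
#' Writes the deformed geometry with per-edge strain and broken flags as an
#' edge element, for external visualisation.
#'
#' @param state a `shell_state`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snapshot_ply <- function(state, path) {
  mesh <- state$mesh
  mesh$vertices <- state$pos
  eps <- effective_edge_strain(state)
  eps[is.na(eps)] <- 0
  write_mesh(mesh, path, format = "ply",
             edge_attr = data.frame(strain = eps,
                                    broken = as.numeric(state$broken)))
  invisible(path)
}
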