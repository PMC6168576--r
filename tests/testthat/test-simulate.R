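test_that("relaxation restores a displaced tethered sheet to its rest", {
  m <- grid_mesh(3, 3, 0.5)
  st <- init_shell(m, params = shell_params(k_sub = 2, k_c = 0))
  st$pos <- st$pos + 0.2
  out <- relax(st, sim_config(tol_f = 1e-8, tol_v = 1e-8))
  expect_lt(max(abs(out$pos - st$foot)), 1e-6)
  # plain damped-Newtonian integration reaches the same fixed point
  out2 <- relax(st, sim_config(tol_f = 1e-6, tol_v = 1e-6),
                method = "damped")
  expect_lt(max(abs(out2$pos - st$foot)), 1e-4)
})

test_that("growth of a flat sheet is a strain-free rigid lift", {
  sub <- flat_substrate(domain = c(3, 2))
  mesh <- substrate_mesh(sub, 0.25)
  st <- init_shell(mesh, sub, shell_params())
  st$h <- 1
  out <- relax(st, sim_config())
  expect_lt(max(abs(out$pos[, 3] - 1)), 0.01)
  expect_lt(max(abs(effective_edge_strain(out, mode = "membrane"))), 1e-6)
})

test_that("relaxation dissipates energy", {
  st <- random_state(21)
  e0 <- sum(shell_energies(st))
  out <- relax(st, sim_config())
  expect_lte(sum(shell_energies(out)), e0)
})

test_that("bonds break iff the imposed strain exceeds the threshold", {
  cfg <- sim_config()
  below <- relax(strained_strip(0.29), cfg)
  res <- break_bonds(below, cfg)
  expect_equal(nrow(res$events), 0)

  above <- relax(strained_strip(0.31), cfg)
  res <- break_bonds(above, cfg, max_breaks = 50)
  expect_gt(nrow(res$events), 0)
  expect_true(all(res$events$strain > 0.3))
  expect_true(all(res$state$broken[res$events$edge]))
})

test_that("a notch concentrates strain and seeds the next break there", {
  # uniformly strained clamped strip; a notch is cut in the centre and
  # only its neighbourhood released, so the strain redistribution (and
  # the brute-force strain ranking) is local to the notch tip
  st <- strained_strip(0.27, nx = 14, ny = 8)
  eps0 <- effective_edge_strain(st)
  m <- st$mesh
  mids <- (st$pos[m$edges[, 1], 1:2] + st$pos[m$edges[, 2], 1:2]) / 2
  ctr <- colMeans(st$pos[, 1:2])
  notch <- which.min((mids[, 1] - ctr[1])^2 + (mids[, 2] - ctr[2])^2)
  st <- shellcrack:::break_edge(st, notch)
  near <- sqrt((st$pos[, 1] - ctr[1])^2 + (st$pos[, 2] - ctr[2])^2) <
    3 * mean(st$l0)
  st$fixed <- !near
  st <- relax(st, sim_config())
  eps1 <- effective_edge_strain(st)
  nxt <- which.max(eps1)
  notch_verts <- m$edges[notch, ]
  # the released lips recoil and load the edges at the notch tip
  expect_gt(eps1[nxt], eps0[nxt])
  tip_nbrs <- unique(c(
    m$adj_idx[seq.int(m$adj_ptr[notch_verts[1]],
                      m$adj_ptr[notch_verts[1] + 1] - 1)],
    m$adj_idx[seq.int(m$adj_ptr[notch_verts[2]],
                      m$adj_ptr[notch_verts[2] + 1] - 1)],
    notch_verts))
  expect_true(any(m$edges[nxt, ] %in% tip_nbrs))
})

test_that("growth on a flat substrate produces no fracture", {
  sub <- flat_substrate(domain = c(3, 2), spacing = 2)
  mesh <- substrate_mesh(sub, 0.25)
  res <- run_growth(sub, mesh, shell_params(),
                    sim_config("growth", max_offset = 2 / 6))
  expect_equal(sum(res$final_state$broken), 0)
  expect_lt(max(abs(effective_edge_strain(res$final_state,
                                          mode = "membrane"))), 1e-6)
})

test_that("a free sheet shrinks without strain; a tethered one cracks", {
  mesh <- grid_mesh(8, 6, 0.3)
  free <- run_shrinkage(flat_substrate(domain = c(3, 2)), mesh,
                        shell_params(k_sub = 0, k_c = 0),
                        sim_config("shrinkage", max_shrink = 0.2))
  expect_equal(sum(free$final_state$broken), 0)
  expect_lt(max(abs(effective_edge_strain(free$final_state))), 1e-3)

  sub <- flat_substrate(domain = c(3, 2))
  mesh2 <- substrate_mesh(sub, 0.25)
  mud <- run_shrinkage(sub, mesh2, shell_params(),
                       sim_config("shrinkage", max_shrink = 0.45,
                                  target_broken_frac = 0.02))
  expect_gt(nrow(mud$events), 0)
  expect_true(all(mud$events$strain > 0.3))
})

test_that("broken fraction is monotone and event strains exceed eps_c", {
  sub <- ridge_substrate(amplitude = 0.6, spacing = 2, domain = c(4, 2))
  mesh <- substrate_mesh(sub, 0.2)
  res <- run_growth(sub, mesh, shell_params(),
                    sim_config("growth", target_broken_frac = 0.02))
  expect_true(all(diff(res$summary$broken_frac) >= 0))
  expect_true(all(res$events$strain > 0.3))
  expect_equal(sum(res$final_state$broken), nrow(res$events))
})

test_that("identical seeds and configs give bit-identical event logs", {
  sub <- ridge_substrate(amplitude = 0.6, spacing = 2, domain = c(4, 2))
  mesh <- substrate_mesh(sub, 0.2)
  r1 <- run_growth(sub, mesh, shell_params(),
                   sim_config("growth", target_broken_frac = 0.015))
  r2 <- run_growth(sub, mesh, shell_params(),
                   sim_config("growth", target_broken_frac = 0.015))
  expect_identical(r1$events, r2$events)
})

test_that("growth cracks on ridges start in the trough band", {
  sub <- ridge_substrate(amplitude = 0.6, spacing = 2, domain = c(4, 2))
  mesh <- substrate_mesh(sub, 0.2)
  res <- run_growth(sub, mesh, shell_params(),
                    sim_config("growth", target_broken_frac = 0.01))
  expect_gt(nrow(res$events), 0)
  first <- res$events$edge[1]
  mid <- colMeans(res$final_state$foot[mesh$edges[first, ], 1:2])
  expect_true(in_trough(sub, mid[1], mid[2], tau = 0.4))
  # strain concentrates across the troughs before breaking: among
  # top-decile edges the strain direction is perpendicular to the trough,
  # i.e. broken edges align with it
  met <- crack_trough_metrics(res, sub)
  expect_lt(met$mean_angle, 35)
})

test_that("virtual sections stack sheets and open gaps at cracks", {
  sub <- flat_substrate(domain = c(3, 2))
  mesh <- substrate_mesh(sub, 0.25)
  res <- run_growth(sub, mesh, shell_params(),
                    sim_config("growth", max_offset = 0.4))
  sec <- virtual_section(res, sub, from = c(0.2, 1), to = c(2.8, 1),
                         n_sheets = 4)
  expect_equal(length(unique(sec$sheet)), 4)
  for (k in unique(sec$sheet)) {
    z <- sec$z[sec$sheet == k]
    expect_false(anyNA(z))
    expect_lt(diff(range(z)), 0.02)  # parallel straight lines
  }

  # force a crack crossing the cut: break one edge that straddles the
  # cut line y = 1 near x = 1.5
  st <- res$final_state
  mids <- (st$foot[mesh$edges[, 1], 1:2] + st$foot[mesh$edges[, 2], 1:2]) / 2
  y1 <- st$foot[mesh$edges[, 1], 2]
  y2 <- st$foot[mesh$edges[, 2], 2]
  crossing <- (y1 - 1) * (y2 - 1) < 0
  cand <- which(crossing)[which.min(abs(mids[crossing, 1] - 1.5))]
  expect_false(is.na(cand))
  st$broken[cand] <- TRUE
  res$final_state <- st
  sec2 <- virtual_section(res, sub, from = c(0.2, 1), to = c(2.8, 1),
                          n_sheets = 4, n_samples = 400)
  outer <- sec2[sec2$sheet == 4, ]
  inner <- sec2[sec2$sheet == 1, ]
  expect_gt(sum(is.na(outer$z)), 0)   # one gap in the outer sheet
  expect_equal(sum(is.na(inner$z)), 0)  # innermost stays continuous
  gap_width <- diff(range(outer$arc[is.na(outer$z)]))
  lbar <- mean(st$l0)
  expect_gt(gap_width, 0.2 * lbar)
  expect_lt(gap_width, 3 * lbar)  # of the order of the mesh spacing

  # cut outside the mesh
  expect_warning(virtual_section(res, sub, from = c(10, 10),
                                 to = c(11, 11)),
                 "misses")
})

test_that("quasi-static runs write a faithful summary", {
  sub <- ridge_substrate(amplitude = 0.6, spacing = 2, domain = c(4, 2))
  mesh <- substrate_mesh(sub, 0.25)
  res <- run_shrinkage(sub, mesh, shell_params(),
                       sim_config("shrinkage", max_shrink = 0.3,
                                  target_broken_frac = 0.02))
  expect_true(all(c("step", "h", "s", "E_stretch", "E_bend",
                    "broken_frac", "iterations") %in%
                    names(res$summary)))
  expect_equal(res$summary$broken_frac[nrow(res$summary)],
               broken_fraction(res$final_state))
  expect_true(all(diff(res$summary$s) > 0))
})
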