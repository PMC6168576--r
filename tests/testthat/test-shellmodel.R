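# finite-difference gradient oracle used throughout this file
fd_force <- function(state, efun, i, c, h = 1e-6) {
  sp <- state; sp$pos[i, c] <- sp$pos[i, c] + h
  sm <- state; sm$pos[i, c] <- sm$pos[i, c] - h
  -(efun(sp) - efun(sm)) / (2 * h)
}

term_funs <- list(stretch = list(stretch_energy, stretch_forces),
                  bend = list(bend_energy, bend_forces),
                  area = list(area_energy, area_forces),
                  substrate = list(substrate_energy, substrate_forces),
                  contact = list(contact_energy, contact_forces))

test_that("initialisation freezes a zero-energy curved rest state", {
  flat <- init_shell(grid_mesh(5, 5, 0.4))
  expect_equal(flat$theta0, rep(0, nrow(flat$mesh$hinges)), tolerance = 1e-12)
  expect_equal(unname(shell_energies(flat)), rep(0, 5), tolerance = 1e-12)

  gen <- generate_papilla_substrate(papilla_config(seed = 3),
                                    edge_length = 0.4)
  st <- init_shell(gen$mesh, gen$substrate)
  expect_gt(max(abs(st$theta0)), 0.01)  # genuinely curved rest state
  expect_equal(sum(shell_energies(st)), 0, tolerance = 1e-12)
  st2 <- init_shell(gen$mesh, gen$substrate)
  expect_identical(st$theta0, st2$theta0)
  expect_identical(st$l0, st2$l0)
})

test_that("energy terms match their closed forms", {
  # stretched edge: l0 = 1, to 1.3, k_s = 2 -> E = (2/2)*1*0.3^2 = 0.09
  m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 10, 0)), rbind(1:3))
  st <- init_shell(m, params = shell_params(k_s = 2, k_sub = 0, k_c = 0))
  st$pos[2, 1] <- 1.3
  manual <- sum(2 / 2 * st$l0 * ((edge_lengths(m, st$pos) - st$l0) /
                                   st$l0)^2)
  expect_equal(stretch_energy(st), manual, tolerance = 1e-12)
  eps <- effective_edge_strain(st, mode = "membrane")
  expect_equal(eps[1], 0.3, tolerance = 1e-12)

  # hinge folded to 0.2 rad with k_b = 1 -> E = 0.04
  st <- init_shell(hinge_mesh(),
                   params = shell_params(k_b = 1, k_v = 0, k_sub = 0,
                                         k_c = 0))
  st$pos[3, ] <- c(0.5, cos(0.2), sin(0.2))
  expect_equal(bend_energy(st), 0.04, tolerance = 1e-10)

  # face scaled by 1.1 in plane: A/A0 = 1.21 -> E = (k_v/2)*A0*0.0441
  st <- init_shell(triangle_mesh(),
                   params = shell_params(k_v = 2, k_sub = 0, k_c = 0))
  A0 <- st$A0[1]
  st$pos <- st$pos * 1.1
  expect_equal(area_energy(st), 0.5 * 2 * A0 * (1.1^2 - 1)^2,
               tolerance = 1e-10)

  # flat substrate, h = 0.5, node lifted 0.3 -> (k_sub/2)*0.04 per node
  sub <- flat_substrate(domain = c(1, 1))
  m <- triangle_mesh()
  st <- init_shell(m, sub, shell_params(k_sub = 2, k_c = 0))
  st$h <- 0.5
  st$pos[, 3] <- 0.5
  expect_equal(substrate_energy(st), 0, tolerance = 1e-12)
  st$pos[1, 3] <- 0.3
  expect_equal(substrate_energy(st), 2 / 2 * 0.04, tolerance = 1e-12)
})

test_that("contact follows its closed form and Newton's third law", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(0.25, 0.25, 0.125), c(1.25, 0.25, 0.125),
             c(0.25, 1.25, 0.125))
  m <- tri_mesh(v, rbind(c(1, 2, 3), c(4, 5, 6)))
  st <- init_shell(m, params = shell_params(k_s = 0, k_b = 0, k_v = 0,
                                            k_sub = 0, k_c = 2,
                                            contact_range = 0.25))
  # node 4 sits 0.125 = d_c/2 above face 1 (the only in-range pair)
  expect_equal(contact_energy(st), 0.5 * 2 * 0.125^2, tolerance = 1e-12)
  F <- contact_forces(st)
  expect_equal(colSums(F), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(F[4, ], -(F[1, ] + F[2, ] + F[3, ]), tolerance = 1e-12)
  # out of range -> zero
  st$pos[4:6, 3] <- 1
  expect_equal(contact_energy(st), 0)

})

test_that("analytic forces equal finite-difference gradients for all terms", {
  for (seed in 1:3) {
    st <- random_state(seed)
    n <- nrow(st$pos)
    for (nm in names(term_funs)) {
      efun <- term_funs[[nm]][[1]]
      F <- term_funs[[nm]][[2]](st)
      scale <- max(abs(F), 1e-8)
      set.seed(seed + 100)
      for (k in 1:8) {
        i <- sample(n, 1); c <- sample(3, 1)
        fd <- fd_force(st, efun, i, c)
        expect_lt(abs(fd - F[i, c]) / max(abs(fd), abs(F[i, c]),
                                          1e-4 * scale),
                  1e-4)
      }
    }
  }
})

test_that("internal energies are rigid-motion invariant", {
  st <- random_state(9)
  e0 <- shell_energies(st)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  st2 <- st
  st2$pos <- st$pos %*% t(R) + rep(c(1, -2, 3), each = nrow(st$pos))
  e1 <- shell_energies(st2)
  for (nm in c("stretch", "bend", "area", "contact"))
    expect_equal(e1[[nm]], e0[[nm]], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(e1[["substrate"]], e0[["substrate"]])))
})

test_that("breaking an edge never increases any energy term", {
  st <- random_state(4)
  e0 <- shell_energies(st)
  eps <- effective_edge_strain(st)
  st <- shellcrack:::break_edge(st, which.max(eps))
  e1 <- shell_energies(st)
  expect_true(all(e1 <= e0 + 1e-12))
  expect_true(all(e1 >= 0))
})

test_that("effective strain captures stretch and outer-fibre bending", {
  # rest state -> all zero
  st <- init_shell(grid_mesh(6, 5, 0.3))
  expect_equal(max(abs(effective_edge_strain(st))), 0, tolerance = 1e-12)

  # pure uniaxial stretch by 10% -> 0.10 on x-aligned edges
  st$pos[, 1] <- st$pos[, 1] * 1.1
  eps <- effective_edge_strain(st)
  m <- st$mesh
  dir <- st$foot[m$edges[, 2], ] - st$foot[m$edges[, 1], ]
  xal <- abs(dir[, 2]) < 1e-9
  expect_equal(eps[xal], rep(0.1, sum(xal)), tolerance = 1e-9)

  # flat-rest sheet rolled onto a cylinder of radius R: membrane-free on
  # axis-parallel edges, which see eps -> t/(2R); bend energy ~ 1/R^2.
  # A rectangular-split grid provides the axis-parallel (y) edges.
  rect_grid <- function(nx, ny, a) {
    xy <- expand.grid(x = (seq_len(nx) - 1) * a, y = (seq_len(ny) - 1) * a)
    id <- function(i, j) (j - 1L) * nx + i
    fl <- list()
    for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1))
      fl[[length(fl) + 1L]] <- rbind(
        c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
        c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
    tri_mesh(cbind(xy$x, xy$y, 0), do.call(rbind, fl))
  }
  roll <- function(spacing, R) {
    mesh <- rect_grid(17, 9, spacing)
    st <- init_shell(mesh, params = shell_params(thickness = 0.2,
                                                 k_sub = 0, k_c = 0))
    x <- mesh$vertices[, 1]
    st$pos <- cbind(R * sin(x / R), mesh$vertices[, 2], R * (1 - cos(x / R)))
    st
  }
  for (R in c(2, 4)) {
    st <- roll(0.2, R)
    eps <- effective_edge_strain(st)
    m <- st$mesh
    dir <- st$foot[m$edges[, 2], ] - st$foot[m$edges[, 1], ]
    yal <- abs(dir[, 1]) < 1e-9 & !is.na(m$edge_hinge)
    expect_gt(sum(yal), 10)
    expect_equal(mean(eps[yal]), 0.2 / (2 * R), tolerance = 0.02)
  }
  eb <- c(bend_energy(roll(0.2, 2)), bend_energy(roll(0.2, 4)))
  expect_equal(eb[1] / eb[2], 4, tolerance = 0.03)
})

test_that("strain field recovers affine deformations exactly", {
  st <- init_shell(grid_mesh(6, 5, 0.4),
                   params = shell_params(k_sub = 0, k_c = 0))
  sf0 <- strain_field(st)
  expect_equal(max(abs(sf0$faces$e1)), 0, tolerance = 1e-12)

  # uniform 5% stretch along x
  st$pos[, 1] <- st$pos[, 1] * 1.05
  sf <- strain_field(st)
  expect_equal(sf$faces$e1, rep(0.5 * (1.05^2 - 1), nrow(sf$faces)),
               tolerance = 1e-9)
  expect_equal(abs(sf$faces$d1x), rep(1, nrow(sf$faces)), tolerance = 1e-6)

  # random in-plane affine map: Green strain (F^T F - I)/2
  A <- matrix(c(1.04, 0.03, -0.02, 0.97), 2)
  st2 <- init_shell(grid_mesh(6, 5, 0.4),
                    params = shell_params(k_sub = 0, k_c = 0))
  st2$pos[, 1:2] <- st2$pos[, 1:2] %*% t(A)
  E <- 0.5 * (t(A) %*% A - diag(2))
  ev <- sort(eigen(E, symmetric = TRUE)$values, decreasing = TRUE)
  sf2 <- strain_field(st2)
  expect_equal(sf2$faces$e1, rep(ev[1], nrow(sf2$faces)), tolerance = 1e-8)
  expect_equal(sf2$faces$e2, rep(ev[2], nrow(sf2$faces)), tolerance = 1e-8)
})
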