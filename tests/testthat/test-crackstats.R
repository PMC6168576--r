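# tiny star network: centre at origin with three straight branches at the
# given bearings (degrees), each of `len` mm in `k` segments
star_network <- function(bearings, len = 1, k = 3) {
  nodes <- matrix(c(0, 0), 1)
  segs <- NULL
  for (b in bearings) {
    th <- b * pi / 180
    prev <- 1L
    for (j in seq_len(k)) {
      nodes <- rbind(nodes, c(cos(th), sin(th)) * len * j / k)
      segs <- rbind(segs, c(prev, nrow(nodes)))
      prev <- nrow(nodes)
    }
  }
  planar_network(nodes, segs)
}

test_that("junction angles are the sorted circular gaps of the bearings", {
  j <- extract_junctions(star_network(c(90, 210, 330)), r = 0.5)
  expect_equal(nrow(j), 1)
  expect_equal(unlist(j[1, c("theta1", "theta2", "theta3")]),
               c(theta1 = 120, theta2 = 120, theta3 = 120),
               tolerance = 1e-9)

  j <- extract_junctions(star_network(c(0, 90, 180)), r = 0.5)
  expect_equal(unlist(j[1, 3:5]), c(theta1 = 90, theta2 = 90,
                                    theta3 = 180), tolerance = 1e-9)

  j <- extract_junctions(star_network(c(0, 135, 225)), r = 0.5)
  expect_equal(unlist(j[1, 3:5]), c(theta1 = 90, theta2 = 135,
                                    theta3 = 135), tolerance = 1e-9)

  # angle sum and sorting invariants on a jittered network
  set.seed(8)
  for (i in 1:10) {
    b <- sort(runif(3, 0, 360))
    if (min(diff(b)) < 5) next
    j <- extract_junctions(star_network(b), r = 0.5)
    th <- unlist(j[1, 3:5])
    expect_equal(sum(th), 360, tolerance = 1e-9)
    expect_true(th[1] <= th[2] && th[2] <= th[3])
  }
})

test_that("branch directions are sampled at the requested arc length", {
  # an L-shaped branch: leaves east then turns north after 0.2 mm
  nodes <- rbind(c(0, 0), c(0.2, 0), c(0.2, 1),
                 c(-1, 0.01), c(0, -1))
  segs <- rbind(c(1, 2), c(2, 3), c(1, 4), c(1, 5))
  net <- planar_network(nodes, segs)
  # with r = 0.6 the east branch target lies 0.4 up the north leg
  j <- extract_junctions(net, r = 0.6)
  expect_equal(nrow(j), 1)
  # independent oracle: gaps between the three branch bearings
  bearings <- sort(c(atan2(0.4, 0.2), atan2(0.01, -1), atan2(-1, 0) + 2 * pi) *
                     180 / pi)
  gaps <- sort(c(diff(bearings), 360 - diff(range(bearings))))
  expect_equal(unname(unlist(j[1, 3:5])), gaps, tolerance = 1e-9)
  expect_error(extract_junctions(net, r = 0), "r must be")
})

test_that("degree-4 nodes are excluded but counted", {
  net <- star_network(c(0, 90, 180, 270))
  j <- extract_junctions(net, r = 0.5)
  expect_equal(nrow(j), 0)
  expect_equal(attr(j, "n_excluded"), 1)
})

test_that("angular scatter validates the admissible region", {
  jx <- data.frame(theta1 = c(90, 120), theta2 = c(135, 120))
  sc <- angular_scatter(jx)
  expect_equal(unname(sc$mean), c(105, 127.5))
  expect_error(angular_scatter(data.frame(theta1 = 200, theta2 = 100)),
               "admissible")
})

test_that("sigma_theta matches the Gaussian closed form", {
  c2 <- -2 * log(1 - 0.68)
  # identical points: degenerate, flagged zero
  same <- data.frame(theta1 = rep(120, 5), theta2 = rep(120, 5))
  sp <- angular_spreading(same)
  expect_true(sp$degenerate)
  expect_equal(sp$sigma_theta, 0)

  # seeded Monte-Carlo oracle: isotropic and anisotropic Gaussians
  set.seed(123)
  n <- 10000
  s <- 3
  # means placed deep inside the admissible region so the Gaussian mass
  # stays admissible
  pts <- data.frame(theta1 = rnorm(n, 70, s), theta2 = rnorm(n, 110, 2 * s))
  sp <- angular_spreading(pts)
  expect_equal(sp$sigma_theta, sqrt(c2) * sqrt(s * 2 * s),
               tolerance = 0.05)
  expect_equal(sp$area, pi * sp$sigma_theta^2, tolerance = 1e-9)

  iso <- data.frame(theta1 = rnorm(n, 70, s), theta2 = rnorm(n, 110, s))
  expect_equal(angular_spreading(iso)$sigma_theta, sqrt(c2) * s,
               tolerance = 0.05)
  # Mahalanobis variant: c = 1
  expect_equal(angular_spreading(iso, ellipse = "mahalanobis1")$sigma_theta,
               s, tolerance = 0.05)
})

test_that("statistics are invariant under rotation and translation", {
  set.seed(5)
  nets <- star_network(c(10, 130, 260))
  j0 <- extract_junctions(nets, 0.5)
  th <- 77 * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  nets2 <- nets
  nets2$nodes <- sweep(nets$nodes %*% t(R), 2, c(3, -1), `+`)
  j1 <- extract_junctions(nets2, 0.5)
  expect_equal(unlist(j0[1, 3:5]), unlist(j1[1, 3:5]), tolerance = 1e-9)
})

test_that("archetype classification is the Voronoi partition", {
  expect_equal(classify_junction(120, 120), "triple-120")
  expect_equal(classify_junction(90, 135), "90-135-135")
  expect_equal(classify_junction(90, 90), "T-junction")
  expect_equal(classify_junction(100, 130), "90-135-135")
  expect_equal(classify_junction(92, 95), "T-junction")
  expect_equal(classify_junction(c(120, 92), c(120, 95)),
               c("triple-120", "T-junction"))
})

test_that("angle PDFs and range probabilities behave", {
  expect_equal(prob_in_range(rep(120, 50), 100, 140), 1)
  set.seed(77)
  a <- runif(100000, 0, 360)
  expect_equal(prob_in_range(a, 100, 140), 40 / 360, tolerance = 0.01)
  expect_error(prob_in_range(a, 140, 100), "lo < hi")

  set.seed(9)
  angs <- rnorm(400, 120, 15)
  pdf <- angle_pdf(angs, n_bootstrap = 200, seed = 4)
  expect_equal(sum(pdf$y) * diff(pdf$x[1:2]), 1, tolerance = 0.02)
  inside <- pdf$y >= pdf$lower - 1e-9 & pdf$y <= pdf$upper + 1e-9
  expect_gt(mean(inside), 0.95)
  # determinism of the seeded bootstrap
  pdf2 <- angle_pdf(angs, n_bootstrap = 200, seed = 4)
  expect_identical(pdf$lower, pdf2$lower)
})

test_that("honeycomb trough networks give pure triple-120 junctions", {
  cfg <- papilla_config(jitter_sd = 0, domain = c(10, 9))
  net <- generate_trough_network(cfg)
  j <- extract_junctions(net, r = 0.2 * 2)
  # keep interior junctions (away from the clipped domain boundary)
  interior <- j$x > 1 & j$x < 9 & j$y > 1 & j$y < 8
  expect_gt(sum(interior), 5)
  th <- as.matrix(j[interior, c("theta1", "theta2", "theta3")])
  expect_equal(as.vector(th), rep(120, length(th)), tolerance = 1e-6)
})

test_that("jittered trough networks stay near the triple-120 archetype", {
  cfg <- papilla_config(jitter_sd = 0.2, seed = 31, domain = c(10, 9))
  net <- generate_trough_network(cfg)
  j <- extract_junctions(net, r = 0.2 * 2)
  expect_gt(nrow(j), 5)
  st <- junction_stats(j)
  expect_lt(sqrt(sum((st$mean - c(120, 120))^2)), 15)
  expect_lt(st$sigma_theta, 30)
  expect_equal(sum(st$archetype_counts), st$n)
  expect_error(generate_trough_network(
    shellcrack:::substrate_papilla(matrix(c(1, 1), 1),
                                   papilla_config(domain = c(4, 4)))),
    "3 centres")
})

test_that("crack projection builds midpoint networks", {
  mesh <- grid_mesh(6, 5, 0.5)
  st <- init_shell(mesh)
  expect_warning(net0 <- project_crack_network(st), "no broken")
  expect_equal(nrow(net0$nodes), 0)

  # single broken edge
  st$broken[10] <- TRUE
  net1 <- project_crack_network(st)
  expect_equal(nrow(net1$nodes), 1)
  expect_equal(nrow(net1$segments), 0)
  mid <- colMeans(mesh$vertices[mesh$edges[10, ], 1:2])
  expect_equal(net1$nodes[1, ], unname(mid))  # orthographic projection

  # a chain of three adjacent broken edges forms a connected path
  v <- 9L  # interior vertex
  inc <- which(mesh$edges[, 1] == v | mesh$edges[, 2] == v)[1:3]
  st2 <- init_shell(mesh)
  st2$broken[inc] <- TRUE
  net2 <- project_crack_network(st2)
  expect_equal(nrow(net2$nodes), 3)
  expect_gte(nrow(net2$segments), 2)
})

test_that("network CSV dialect round-trips", {
  net <- star_network(c(0, 120, 240))
  np <- tempfile(fileext = ".csv")
  sp <- tempfile(fileext = ".csv")
  write_network_csv(net, np, sp)
  back <- read_network_csv(np, sp)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$segments, net$segments)
  unlink(c(np, sp))
})
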