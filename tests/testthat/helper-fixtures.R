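# Shared fixtures.  Small meshes are built in code; the standard papillary
# fixture used by the heavier end-to-end checks is computed once per test
# session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# single equilateral triangle
triangle_mesh <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
           rbind(c(1, 2, 3)))
}

# two unit right triangles sharing the edge 1-2
hinge_mesh <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(0.5, -1, 0)),
           rbind(c(1, 2, 3), c(2, 1, 4)))
}

# small randomised test state with every energy term active
random_state <- function(seed, n = 6, spacing = 0.5, displace = 0.05) {
  sub <- ridge_substrate(amplitude = 0.3, spacing = 2,
                         domain = c(spacing * n, spacing * n))
  mesh <- substrate_mesh(sub, spacing)
  st <- init_shell(mesh, sub, shell_params(k_sub = 0.8, k_c = 1,
                                           contact_range = 0.3 * spacing))
  set.seed(seed)
  st$pos <- st$pos + matrix(rnorm(length(st$pos), sd = displace * spacing),
                            ncol = 3)
  st$h <- 0.1
  st
}

# flat strip under uniform imposed uniaxial strain along x; every node is
# clamped so the imposed strain is exactly uniform (no necking near the
# grips redistributes it above the nominal value)
strained_strip <- function(strain, nx = 12, ny = 6, spacing = 0.25,
                           eps_c = 0.3) {
  mesh <- grid_mesh(nx, ny, spacing)
  st <- init_shell(mesh, params = shell_params(k_sub = 0, k_c = 0,
                                               eps_c = eps_c))
  st$pos[, 1] <- st$pos[, 1] * (1 + strain)
  st$fixed <- rep(TRUE, nrow(st$pos))
  st
}

# standard jittered-hexagonal papillary fixture (the acceptance operating
# point: ~15 papillae, ~5k vertices, eps_c = 0.3, h_max = <d>/6, stop at
# 3% broken edges) with growth and shrinkage runs, computed once.
standard_fixture <- function() {
  fixture("standard", function() {
    cfg <- papilla_config(seed = 101)
    gen <- generate_papilla_substrate(cfg)
    list(config = cfg, substrate = gen$substrate, mesh = gen$mesh)
  })
}

# One growth run continued past the 3%-broken snapshot (the mature crack
# network used for junction statistics); the standard 3% snapshot is its
# exact prefix because bond breaking is sequential and deterministic, so
# it is reconstructed from the event log instead of re-run.
mature_growth <- function() {
  fixture("mature_growth", function() {
    fx <- standard_fixture()
    run_growth(fx$substrate, fx$mesh, shell_params(eps_c = 0.3),
               sim_config("growth", increment = (2 / 6) / 16,
                          max_offset = 2 / 3, target_broken_frac = 0.08))
  })
}

standard_growth <- function() {
  fixture("growth", function() {
    fx <- standard_fixture()
    res <- mature_growth()
    ne <- nrow(fx$mesh$edges)
    k <- min(ceiling(0.03 * ne), nrow(res$events))
    st <- init_shell(fx$mesh, fx$substrate, shell_params(eps_c = 0.3))
    st$broken[res$events$edge[seq_len(k)]] <- TRUE
    st$h <- res$events$control[k]
    structure(list(final_state = st, events = res$events[seq_len(k), ]),
              class = "sim_result")
  })
}

standard_shrinkage <- function() {
  fixture("shrinkage", function() {
    fx <- standard_fixture()
    run_shrinkage(fx$substrate, fx$mesh, shell_params(eps_c = 0.3),
                  sim_config("shrinkage", target_broken_frac = 0.03))
  })
}
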