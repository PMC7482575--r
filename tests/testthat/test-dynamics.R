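test_that("aligned initialization is fully polarized for any heading", {
  for (h in c(0, pi / 2, -2.1, 3)) {
    st <- init_aligned(n_agents = 81L, heading = h)
    expect_equal(polarization(st), 1, tolerance = 1e-14)
  }
})

test_that("rest lengths are the initial inter-agent distances", {
  net <- interaction_network(3, rbind(c(1, 2), c(1, 3)))
  pos <- rbind(c(0, 0), c(3, 4), c(1, 1))
  net <- assign_rest_lengths(net, pos)
  expect_equal(net$rest_lengths, c(5, sqrt(2)))
  expect_error(assign_rest_lengths(net, rbind(c(0, 0), c(0, 0), c(1, 1))),
               "degenerate geometry")
})

test_that("VN update averages neighbourhood headings (self included)", {
  # two mutually linked agents at 0 and pi/2 meet at pi/4
  pair <- interaction_network(2, cbind(1, 2))
  st <- swarm_state(c(0, pi / 2))
  set.seed(1)
  out <- vn_step(st, pair, vn_params(0))
  expect_equal(out$headings, c(pi / 4, pi / 4), tolerance = 1e-14)
  # an isolated agent keeps its heading at zero noise
  lone <- interaction_network(1, matrix(integer(0), ncol = 2))
  out <- vn_step(swarm_state(0.7), lone, vn_params(0))
  expect_equal(out$headings, 0.7, tolerance = 1e-14)
  # the aligned state is a fixed point
  st <- init_aligned(n_agents = 9, heading = 1.1)
  out <- vn_step(st, build_nn_lattice(3)$network, vn_params(0))
  expect_equal(out$headings, rep(1.1, 9), tolerance = 1e-12)
})

test_that("exactly cancelling neighbourhoods keep the previous heading", {
  # focal agent at 0 linked to pi/2, -pi/2 and pi: the four unit
  # vectors (self included) cancel exactly
  net <- interaction_network(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
  st <- swarm_state(c(0, pi / 2, -pi / 2, pi))
  set.seed(2)
  out <- vn_step(st, net, vn_params(0))
  expect_equal(out$headings[1], 0, tolerance = 1e-14)
})

test_that("AE forces follow linear springs and Newton's third law", {
  p <- ae_params()
  # separation at rest length: no force
  net <- interaction_network(2, cbind(1, 2))
  net$rest_lengths <- 2
  st <- swarm_state(c(0, 0), positions = rbind(c(0, 0), c(0, 2)))
  expect_equal(ae_force(st, net, p), cbind(fx = c(0, 0), fy = c(0, 0)),
               ignore_attr = TRUE)
  # stretched spring: kappa * (d - l) toward the neighbour
  net$rest_lengths <- 1
  f <- ae_force(st, net, p)
  expect_equal(f[1, ], c(fx = 0, fy = 5))
  expect_equal(f[2, ], c(fx = 0, fy = -5))
  # random geometry: pairwise equal and opposite, swarm total zero
  set.seed(3)
  lat <- build_nn_lattice(4)
  net <- assign_rest_lengths(lat$network, lat$positions)
  st <- swarm_state(stats::runif(16, -pi, pi),
                    positions = lat$positions + matrix(stats::rnorm(32, 0, 0.2), ncol = 2))
  f <- ae_force(st, net, p)
  expect_equal(colSums(f), c(fx = 0, fy = 0), tolerance = 1e-12)
})

test_that("AE step turns toward a stretched spring at the derived rate", {
  net <- interaction_network(2, cbind(1, 2))
  net$rest_lengths <- 1
  st <- swarm_state(c(0, 0), positions = rbind(c(0, 0), c(0, 2)))
  set.seed(4)
  out <- ae_step(st, net, ae_params(eta = 0))
  # F = (0, 5) on agent 1; heading +x: F.n = 0, F.nperp = 5
  expect_equal(out$headings[1], 0.12 * 5 * 0.1, tolerance = 1e-14)
  expect_equal(out$positions[1, ] - c(0, 0), c(0.002 * 0.1, 0),
               tolerance = 1e-14)
})

test_that("a stretched two-agent spring relaxes to its rest length", {
  net <- interaction_network(2, cbind(1, 2))
  net$rest_lengths <- 1
  # headings along the spring axis so the force is longitudinal
  st <- swarm_state(c(0, pi), positions = rbind(c(0, 0), c(2, 0)))
  prm <- ae_params(eta = 0, v0 = 1e-6) # negligible drift, pure relaxation
  run <- run_model("ae", st, net, prm, n_steps = 20000, stride = 1000, seed = 5)
  sep <- abs(run$final$positions[2, 1] - run$final$positions[1, 1])
  expect_equal(sep, 1, tolerance = 0.01)
})

test_that("zero-noise runs hold the aligned state exactly", {
  lat <- build_nn_lattice(5)
  st <- init_aligned(positions = lat$positions, heading = pi / 2)
  rv <- run_model("vn", st, lat$network, vn_params(0), n_steps = 200, seed = 1)
  expect_true(all(abs(rv$psi - 1) < 1e-12))
  net <- assign_rest_lengths(lat$network, lat$positions)
  ra <- run_model("ae", st, net, ae_params(eta = 0), n_steps = 200, seed = 1)
  expect_true(all(abs(ra$psi - 1) < 1e-12))
})

test_that("compiled runs reproduce the R reference steps on one stream", {
  lat <- build_nn_lattice(3)
  st <- init_aligned(positions = lat$positions, heading = 0.3)
  set.seed(77)
  s <- st
  for (i in 1:20) s <- vn_step(s, lat$network, vn_params(1.5))
  run <- run_model("vn", st, lat$network, vn_params(1.5), n_steps = 20, seed = 77)
  expect_equal(run$final$headings, s$headings, tolerance = 1e-12)

  net <- assign_rest_lengths(lat$network, lat$positions)
  set.seed(78)
  s <- st
  for (i in 1:20) s <- ae_step(s, net, ae_params(eta = 2))
  run <- run_model("ae", st, net, ae_params(eta = 2), n_steps = 20, seed = 78)
  expect_equal(run$final$headings, s$headings, tolerance = 1e-12)
  expect_equal(run$final$positions, s$positions, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("same seed gives an identical polarization series", {
  lat <- build_nn_lattice(4)
  st <- init_aligned(positions = lat$positions)
  a <- run_model("vn", st, lat$network, vn_params(2), n_steps = 100, seed = 9)
  b <- run_model("vn", st, lat$network, vn_params(2), n_steps = 100, seed = 9)
  expect_identical(a$psi, b$psi)
  net <- assign_rest_lengths(lat$network, lat$positions)
  a <- run_model("ae", st, net, ae_params(eta = 1), n_steps = 100, seed = 9)
  b <- run_model("ae", st, net, ae_params(eta = 1), n_steps = 100, seed = 9)
  expect_identical(a$psi, b$psi)
})

test_that("dynamics are equivariant under a global rotation", {
  phi <- 0.83
  lat <- build_nn_lattice(3)
  th0 <- seq(-1, 1, length.out = 9)
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  # VN: same noise stream, rotated headings
  a <- run_model("vn", swarm_state(th0), lat$network, vn_params(1),
                 n_steps = 30, seed = 11)
  b <- run_model("vn", swarm_state(th0 + phi), lat$network, vn_params(1),
                 n_steps = 30, seed = 11)
  d <- (b$final$headings - a$final$headings - phi) %% (2 * pi)
  expect_true(all(pmin(d, 2 * pi - d) < 1e-10))
  expect_equal(a$psi, b$psi, tolerance = 1e-12)
  # AE: rotate positions and headings together
  net <- assign_rest_lengths(lat$network, lat$positions)
  sa <- swarm_state(th0, positions = lat$positions)
  sb <- swarm_state(th0 + phi, positions = lat$positions %*% t(rot))
  netb <- assign_rest_lengths(lat$network, sb$positions)
  a <- run_model("ae", sa, net, ae_params(eta = 1), n_steps = 30, seed = 12)
  b <- run_model("ae", sb, netb, ae_params(eta = 1), n_steps = 30, seed = 12)
  expect_equal(b$final$positions, a$final$positions %*% t(rot),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(a$psi, b$psi, tolerance = 1e-12)
})

test_that("noiseless VN reaches consensus on small connected networks", {
  set.seed(21)
  for (rep in 1:3) {
    net <- build_er(20, 30, seed = 500 + rep)
    st <- swarm_state(stats::runif(20, -2, 2)) # generic, within a half-circle
    run <- run_model("vn", st, net, vn_params(0), n_steps = 400, seed = rep)
    expect_gt(run$psi[length(run$psi)], 0.9999)
  }
})

test_that("full noise drives VN to the finite-size floor", {
  # at eta = 2*pi each heading is uniform, so psi matches the norm of a
  # mean of N independent unit vectors, ~ sqrt(pi / (4 N))
  N <- 625L
  lat <- build_nn_lattice(25)
  st <- init_aligned(positions = lat$positions)
  run <- run_model("vn", st, lat$network, vn_params(2 * pi),
                   n_steps = 400, seed = 31)
  obs <- stationary_mean(run$psi)
  set.seed(32) # independent oracle: random unit-vector sums
  oracle <- mean(replicate(400, {
    th <- stats::runif(N, -pi, pi)
    sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  }))
  expect_lt(abs(obs - oracle), 0.5 * oracle)
})

test_that("model/state mismatches raise errors", {
  lat <- build_nn_lattice(3)
  st <- init_aligned(n_agents = 4)
  expect_error(run_model("vn", st, lat$network, vn_params(1), 10),
               "node count")
  st9 <- init_aligned(n_agents = 9)
  expect_error(run_model("ae", st9, lat$network, ae_params(), 10),
               "positions")
  stp <- init_aligned(positions = lat$positions)
  expect_error(run_model("ae", stp, lat$network, ae_params(), 10),
               "rest lengths")
})
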