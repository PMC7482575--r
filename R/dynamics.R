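#' Swarm state
#'
#' Positions and heading angles of all agents at one instant. Headings
#' are stored wrapped to `(-pi, pi]`; positions are in lattice-spacing
#' units and are only needed by the AE model (the VN update depends on
#' headings alone).
#'
#' @param headings Numeric vector of heading angles (radians).
#' @param positions Optional `N x 2` matrix of coordinates.
#' @param time Time stamp (step index for VN, continuous time for AE).
#' @return A `swarm_state` object.
#' @export
swarm_state <- function(headings, positions = NULL, time = 0) {
  headings <- wrap_angle(as.numeric(headings))
  if (!is.null(positions)) {
    positions <- matrix(as.numeric(positions), ncol = 2L)
    if (nrow(positions) != length(headings))
      stop("positions and headings disagree on the number of agents")
  }
  structure(list(headings = headings, positions = positions, time = time),
            class = "swarm_state")
}

#' @export
print.swarm_state <- function(x, ...) {
  cat(sprintf("<swarm_state: %d agents%s, t = %g, psi = %.4f>\n",
              length(x$headings),
              if (is.null(x$positions)) " (headings only)" else "",
              x$time, polarization(x)))
  invisible(x)
}

# wrap to (-pi, pi]
wrap_angle <- function(t) {
  t <- (t + pi) %% (2 * pi)
  ifelse(t <= 0, t + 2 * pi, t) - pi
}

#' VN model parameters
#' @param eta Noise intensity in `[0, 2*pi]`; `eta = 0` is noiseless and
#'   `eta = 2*pi` makes each step's heading fully random.
#' @return A `vn_params` object.
#' @export
vn_params <- function(eta) {
  stopifnot(length(eta) == 1L, is.finite(eta), eta >= 0, eta <= 2 * pi)
  structure(list(eta = eta), class = "vn_params")
}

#' AE model parameters
#'
#' Defaults are the reference parameter set used throughout the noise
#' sweeps: `v0 = 0.002`, `alpha = 0.01`, `beta = 0.12`, `kappa = 5`,
#' `dt = 0.1`, which give rapid, reliable self-organization on
#' nearest-neighbour lattices.
#'
#' @param eta Noise intensity (enters the heading equation as
#'   `eta * xi` with `xi ~ U(-1/2, 1/2)`).
#' @param v0 Preferred self-propulsion speed (lattice units / time).
#' @param alpha Force-to-linear-speed coupling.
#' @param beta Force-to-angular-speed coupling.
#' @param kappa Spring constant (same for every link, independent of its
#'   rest length).
#' @param dt Forward-Euler time step.
#' @return An `ae_params` object.
#' @export
ae_params <- function(eta = 0, v0 = 0.002, alpha = 0.01, beta = 0.12,
                      kappa = 5, dt = 0.1) {
  stopifnot(v0 > 0, kappa > 0, dt > 0, alpha >= 0, beta >= 0, eta >= 0)
  structure(list(eta = eta, v0 = v0, alpha = alpha, beta = beta,
                 kappa = kappa, dt = dt), class = "ae_params")
}

#' Fully aligned initial state
#'
#' All sweeps start from the fully aligned state (`psi = 1`): with
#' lattice positions and lattice-distance rest lengths it is the
#' zero-force configuration of the AE model, and for the AE model it
#' tracks the ordered solution branch inside the bistable region.
#'
#' @param positions Optional `N x 2` coordinate matrix.
#' @param heading Common heading angle (radians).
#' @param n_agents Number of agents (required when `positions` is NULL).
#' @return A `swarm_state` with all headings equal.
#' @export
init_aligned <- function(positions = NULL, heading = pi / 2,
                         n_agents = NULL) {
  if (is.null(positions) && is.null(n_agents))
    stop("give positions or n_agents")
  n <- if (is.null(positions)) n_agents else nrow(positions)
  swarm_state(rep(heading, n), positions = positions, time = 0)
}

#' Assign spring rest lengths from initial positions
#'
#' Sets every link's natural length to the Euclidean distance between
#' its endpoints at `t = 0`, so the starting configuration carries no
#' elastic stress and all later stresses are produced by the
#' self-propulsion dynamics. Long-range links therefore get long rest
#' lengths.
#'
#' @param network An [interaction_network].
#' @param positions `N x 2` coordinate matrix.
#' @return The network with `rest_lengths` set.
#' @export
assign_rest_lengths <- function(network, positions) {
  stopifnot(inherits(network, "interaction_network"))
  positions <- matrix(as.numeric(positions), ncol = 2L)
  if (nrow(positions) != network$n_nodes)
    stop("positions must cover all nodes")
  d <- sqrt(rowSums((positions[network$edges[, 1L], , drop = FALSE] -
                     positions[network$edges[, 2L], , drop = FALSE])^2))
  if (any(d <= 0))
    stop("degenerate geometry: linked nodes coincide at t = 0")
  network$rest_lengths <- d
  network
}

# 0-based CSR adjacency (neighbours only; self handled in the update)
adjacency_csr <- function(network) {
  n <- network$n_nodes
  e <- network$edges
  src <- c(e[, 1L], e[, 2L])
  dst <- c(e[, 2L], e[, 1L])
  ord <- order(src, dst)
  list(ptr = c(0L, cumsum(tabulate(src, nbins = n))),
       idx = dst[ord] - 1L)
}

#' One synchronous VN update
#'
#' Each agent's new heading is the angle of the vector sum of the unit
#' heading vectors of itself and its network neighbours, plus angular
#' noise `eta * xi` with `xi ~ U(-1/2, 1/2)` drawn independently per
#' agent. If the neighbourhood sum cancels exactly, the previous heading
#' is kept (and noise still applied). Isolated agents therefore keep
#' their heading up to noise.
#'
#' @param state A `swarm_state`.
#' @param network An [interaction_network] with matching node count.
#' @param params A [vn_params] object.
#' @return The updated `swarm_state`.
#' @export
vn_step <- function(state, network, params) {
  stopifnot(inherits(state, "swarm_state"), inherits(params, "vn_params"))
  n <- length(state$headings)
  if (network$n_nodes != n) stop("network node count does not match state")
  cx <- cos(state$headings); cy <- sin(state$headings)
  e <- network$edges
  sx <- cx + unname(tapply2(c(cx[e[, 2L]], cx[e[, 1L]]),
                            c(e[, 1L], e[, 2L]), n))
  sy <- cy + unname(tapply2(c(cy[e[, 2L]], cy[e[, 1L]]),
                            c(e[, 1L], e[, 2L]), n))
  ang <- ifelse(abs(sx) < 1e-14 & abs(sy) < 1e-14,
                state$headings, atan2(sy, sx))
  xi <- stats::runif(n) - 0.5
  swarm_state(ang + params$eta * xi, positions = state$positions,
              time = state$time + 1)
}

# sum `values` by integer group over 1..n (dense)
tapply2 <- function(values, groups, n) {
  out <- numeric(n)
  agg <- rowsum(values, groups)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Elastic forces of the AE model
#'
#' For each agent, the vector sum over its links of linear-spring forces
#' `kappa * (|r_ij| - l_ij) * r_ij / |r_ij|`: attractive when the link
#' is stretched, repulsive when compressed. Pairs are equal and
#' opposite. Links whose endpoints coincide contribute zero force (the
#' direction is undefined).
#'
#' @param state A `swarm_state` with positions.
#' @param network An [interaction_network] with rest lengths assigned.
#' @param params An [ae_params] object.
#' @return `N x 2` matrix of force vectors.
#' @export
ae_force <- function(state, network, params) {
  stopifnot(inherits(state, "swarm_state"), inherits(params, "ae_params"))
  if (is.null(state$positions)) stop("AE dynamics needs positions")
  if (is.null(network$rest_lengths))
    stop("rest lengths not assigned; call assign_rest_lengths() first")
  pos <- state$positions
  e <- network$edges
  dvec <- pos[e[, 2L], , drop = FALSE] - pos[e[, 1L], , drop = FALSE]
  d <- sqrt(rowSums(dvec^2))
  f <- ifelse(d < 1e-12, 0, params$kappa * (d - network$rest_lengths) /
                pmax(d, 1e-12))
  n <- network$n_nodes
  fx <- tapply2(c(f * dvec[, 1L], -f * dvec[, 1L]), c(e[, 1L], e[, 2L]), n)
  fy <- tapply2(c(f * dvec[, 2L], -f * dvec[, 2L]), c(e[, 1L], e[, 2L]), n)
  cbind(fx, fy)
}

#' One forward-Euler AE update
#'
#' Overdamped update: the elastic force component along the heading
#' modulates the speed, the perpendicular component (with the
#' perpendicular taken as the +90 degree rotation of the heading, so the
#' torque turns agents toward the net force) steers the heading, and
#' angular noise `eta * xi` enters the heading rate. Positions are
#' unbounded (open boundary).
#'
#' @inheritParams ae_force
#' @return The updated `swarm_state`.
#' @export
ae_step <- function(state, network, params) {
  FF <- ae_force(state, network, params)
  th <- state$headings
  nx <- cos(th); ny <- sin(th)
  fpar <- FF[, 1L] * nx + FF[, 2L] * ny
  fperp <- -FF[, 1L] * ny + FF[, 2L] * nx
  sp <- params$v0 + params$alpha * fpar
  pos <- state$positions + params$dt * cbind(sp * nx, sp * ny)
  xi <- stats::runif(length(th)) - 0.5
  th <- th + params$dt * (params$beta * fperp + params$eta * xi)
  if (!all(is.finite(th)) || !all(is.finite(pos)))
    stop(sprintf("numerical blow-up: non-finite state at t = %g",
                 state$time + params$dt))
  swarm_state(th, positions = pos, time = state$time + params$dt)
}

#' Run a model and record the polarization time series
#'
#' Advances the VN or AE model `n_steps` steps from `state` on a fixed
#' network, recording the polarization every `stride` steps (including
#' the initial state). The loop runs in compiled code; given the same
#' seed the series is reproduced exactly.
#'
#' @param model `"vn"` or `"ae"`.
#' @param state Initial `swarm_state` (positions required for AE).
#' @param network An [interaction_network] (rest lengths required for
#'   AE).
#' @param params A [vn_params] or [ae_params] matching `model`.
#' @param n_steps Number of update steps.
#' @param stride Recording stride (default 1).
#' @param seed Optional integer seed for the noise stream.
#' @return A `model_run` list: `psi` (polarization series), `step`
#'   (step indexes of the records), `final` (final `swarm_state`), and
#'   `model`.
#' @export
run_model <- function(model = c("vn", "ae"), state, network, params,
                      n_steps, stride = 1L, seed = NULL) {
  model <- match.arg(model)
  n_steps <- as.integer(n_steps); stride <- as.integer(stride)
  stopifnot(n_steps >= 1L, stride >= 1L)
  n <- length(state$headings)
  if (network$n_nodes != n) stop("network node count does not match state")
  with_seed(seed, {
    if (model == "vn") {
      stopifnot(inherits(params, "vn_params"))
      csr <- adjacency_csr(network)
      out <- vn_run_cpp(csr$ptr, csr$idx, state$headings, params$eta,
                        n_steps, stride)
      final <- swarm_state(out$theta, positions = state$positions,
                           time = state$time + n_steps)
    } else {
      stopifnot(inherits(params, "ae_params"))
      if (is.null(state$positions)) stop("AE dynamics needs positions")
      if (is.null(network$rest_lengths))
        stop("rest lengths not assigned; call assign_rest_lengths() first")
      out <- ae_run_cpp(state$positions[, 1L], state$positions[, 2L],
                        state$headings, network$edges - 1L,
                        network$rest_lengths, params$v0, params$alpha,
                        params$beta, params$kappa, params$eta, params$dt,
                        n_steps, stride)
      final <- swarm_state(out$theta, positions = cbind(out$x, out$y),
                           time = state$time + n_steps * params$dt)
    }
    structure(list(psi = out$psi, step = out$step, final = final,
                   model = model),
              class = "model_run")
  })
}

#' @export
print.model_run <- function(x, ...) {
  cat(sprintf("<model_run: %s, %d records, final psi = %.4f>\n",
              toupper(x$model), length(x$psi), x$psi[length(x$psi)]))
  invisible(x)
}
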