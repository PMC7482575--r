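#' Polarization order parameter
#'
#' `psi = |sum_i n_i| / N`, the norm of the mean heading unit vector:
#' 1 when all agents point the same way, near 0 for disordered headings
#' (with a finite-size floor of order `N^(-1/2)`).
#'
#' @param x A `swarm_state` or a numeric vector of heading angles.
#' @return A number in `[0, 1]`.
#' @export
polarization <- function(x) {
  th <- if (inherits(x, "swarm_state")) x$headings else as.numeric(x)
  if (length(th) < 1L) stop("polarization needs at least one agent")
  sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

#' Stationary mean of a polarization series
#'
#' Discards the initial burn-in fraction of the series and averages the
#' rest; the burn-in absorbs the transient from the fully aligned start.
#'
#' @param psi Numeric polarization series.
#' @param burn_in Fraction of the series to discard (default 0.5).
#' @return Mean of the post-burn-in samples.
#' @export
stationary_mean <- function(psi, burn_in = 0.5) {
  mean(stationary_window(psi, burn_in))
}

stationary_window <- function(psi, burn_in) {
  stopifnot(burn_in >= 0, burn_in < 1)
  n <- length(psi)
  drop <- floor(burn_in * n)
  if (n < 1L || drop >= n)
    stop("insufficient data: series shorter than its burn-in window")
  psi[(drop + 1L):n]
}

#' Sweep stationary polarization over a noise grid
#'
#' For every `(p, eta)` cell, performs `runs` independent simulations:
#' each run draws a fresh random network realization (and, for
#' `0 < p < 1`, a fresh superposition with the NN lattice), starts from
#' the fully aligned state, and records the stationary mean and variance
#' of the polarization after burn-in. Lattice positions also provide the
#' AE rest lengths, so random links become long-range springs.
#'
#' @param model `"vn"` or `"ae"`.
#' @param L Lattice side; `N = L^2` agents and `K = 2(L-1)(2L-1)` links.
#' @param family `"nn2er"` or `"nn2sf"`: which random topology the
#'   lattice is interpolated with.
#' @param p Vector of topological control parameters in `[0, 1]`.
#' @param eta Sorted vector of noise intensities.
#' @param runs Simulations per `(p, eta)` cell.
#' @param steps Update steps per run.
#' @param b SF exponent (used when `family = "nn2sf"`).
#' @param burn_in Burn-in fraction (default 0.5).
#' @param stride Recording stride for the polarization series.
#' @param seed Integer root seed; every run derives its own stream.
#' @param params Optional [ae_params] template for AE runs (its `eta`
#'   is overridden cell by cell); VN needs none.
#' @return A `sweep_result` data frame with columns `model`, `family`,
#'   `b`, `p`, `eta`, `run`, `seed`, `psi_mean`, `psi_var`, `n_samples`,
#'   and metadata attributes (`L`, `steps`, `burn_in`, `stride`,
#'   `root_seed`).
#' @export
bifurcation_sweep <- function(model = c("vn", "ae"), L, family = c("nn2er", "nn2sf"),
                              p, eta, runs, steps, b = -2, burn_in = 0.5,
                              stride = NULL, seed = 1L, params = NULL) {
  model <- match.arg(model)
  family <- match.arg(family)
  stopifnot(length(eta) >= 1L, !is.unsorted(eta), runs >= 1L, steps >= 1L,
            all(p >= 0 & p <= 1))
  if (family == "nn2sf" && b >= 0) stop("nn2sf needs a negative exponent b")
  if (is.null(stride)) stride <- max(1L, as.integer(steps / 2000))
  lat <- build_nn_lattice(L)
  N <- lat$network$n_nodes
  K <- n_edges(lat$network)
  sf_seq <- if (family == "nn2sf") solve_sf_degree_sequence(N, K, b) else NULL
  if (model == "ae" && is.null(params)) params <- ae_params()

  grid <- expand.grid(run = seq_len(runs), eta = eta, p = p,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p_g <- grid$p[g]; eta_g <- grid$eta[g]; run_g <- grid$run[g]
    seed_g <- derive_seed(seed, match(p_g, p), match(eta_g, eta), run_g)
    net <- sweep_network(lat, family, p_g, sf_seq, derive_seed(seed_g, 1L))
    st <- init_aligned(positions = lat$positions)
    pr <- if (model == "vn") vn_params(eta_g) else
      ae_params(eta = eta_g, v0 = params$v0, alpha = params$alpha,
                beta = params$beta, kappa = params$kappa, dt = params$dt)
    if (model == "ae") net <- assign_rest_lengths(net, lat$positions)
    run <- run_model(model, st, net, pr, n_steps = steps, stride = stride,
                     seed = derive_seed(seed_g, 2L))
    w <- stationary_window(run$psi, burn_in)
    rows[[g]] <- data.frame(
      model = model, family = family, b = if (family == "nn2sf") b else NA_real_,
      p = p_g, eta = eta_g, run = run_g, seed = seed_g,
      psi_mean = mean(w), psi_var = stats::var(w), n_samples = length(w))
  }
  out <- do.call(rbind, rows)
  attr(out, "L") <- L; attr(out, "steps") <- steps
  attr(out, "burn_in") <- burn_in; attr(out, "stride") <- stride
  attr(out, "root_seed") <- seed
  class(out) <- c("sweep_result", "data.frame")
  out
}

# fresh network for one run: NN at p=0, pure random at p=1, otherwise a
# random superposition (fresh random net AND fresh superposition draw)
sweep_network <- function(lat, family, p, sf_seq, seed) {
  K <- n_edges(lat$network)
  N <- lat$network$n_nodes
  if (p == 0) return(lat$network)
  rnd <- if (family == "nn2er") {
    build_er(N, K, seed = derive_seed(seed, 11L))
  } else {
    realize_degree_sequence(sf_seq, seed = derive_seed(seed, 12L))
  }
  if (p == 1) return(rnd)
  superpose(lat$network, rnd, p, seed = derive_seed(seed, 13L))
}

#' Pooled per-cell variance of the order parameter
#'
#' Combines the post-burn-in samples of all runs at one grid cell into a
#' single variance, `Var(psi_eta)`: within-run fluctuations plus
#' between-run spread, the quantity whose peak locates the continuous
#' transition.
#'
#' @param psi_mean,psi_var,n_samples Per-run stationary means, variances
#'   and sample counts.
#' @return Pooled variance (denominator `n`, population form).
#' @export
pooled_variance <- function(psi_mean, psi_var, n_samples) {
  n_tot <- sum(n_samples)
  grand <- sum(psi_mean * n_samples) / n_tot
  # E[x^2] per run = var*(n-1)/n + mean^2 (population form)
  ex2 <- psi_var * (n_samples - 1) / n_samples + psi_mean^2
  ex2[n_samples == 1L] <- psi_mean[n_samples == 1L]^2
  sum(ex2 * n_samples) / n_tot - grand^2
}

#' Critical noise from the variance peak (continuous transition)
#'
#' Selects the grid point with the largest `Var(psi_eta)` and its two
#' neighbours, passes a parabola through the three `(eta, Var)` points,
#' and returns the abscissa of its vertex. Suited to the VN model,
#' whose order-disorder transition appears continuous.
#'
#' @param eta Sorted noise grid (length >= 3).
#' @param var_psi Variance of the order parameter at each grid point.
#' @return A `critical_noise_estimate`: list with `eta_c`, `method`
#'   (`"variance_peak"`) and `diagnostics` (the three points used).
#' @export
eta_c_variance_peak <- function(eta, var_psi) {
  stopifnot(length(eta) == length(var_psi), length(eta) >= 3L,
            !is.unsorted(eta))
  imax <- which(var_psi == max(var_psi))
  if (length(imax) > 1L)
    stop("flat variance profile: no unique maximum")
  if (imax == 1L || imax == length(eta))
    stop("variance peak at the grid boundary; widen the eta grid")
  i <- (imax - 1L):(imax + 1L)
  x <- eta[i]; y <- var_psi[i]
  d12 <- x[2] - x[1]; d32 <- x[2] - x[3]
  num <- d12^2 * (y[2] - y[3]) - d32^2 * (y[2] - y[1])
  den <- d12 * (y[2] - y[3]) - d32 * (y[2] - y[1])
  if (den == 0) stop("degenerate parabola through the variance points")
  eta_c <- x[2] - 0.5 * num / den
  structure(list(eta_c = eta_c, method = "variance_peak",
                 diagnostics = data.frame(eta = x, var_psi = y)),
            class = "critical_noise_estimate")
}

#' Critical noise from loss of the ordered branch (discontinuous
#' transition)
#'
#' Scans mean stationary polarization along the noise grid: a cell is
#' "ordered" when its mean psi is at or above `threshold`. The estimate
#' is the midpoint between the highest ordered noise value and the next
#' tested value. Suited to the AE model, whose ordered branch
#' disappears discontinuously.
#'
#' @param eta Sorted noise grid.
#' @param psi_mean Mean stationary polarization per grid point.
#' @param threshold Ordered-branch threshold (default 0.5).
#' @return A `critical_noise_estimate` with `eta_c`, `method`
#'   (`"branch_loss"`) and `diagnostics` (the bracketing pair).
#' @export
eta_c_branch_loss <- function(eta, psi_mean, threshold = 0.5) {
  stopifnot(length(eta) == length(psi_mean), length(eta) >= 2L,
            !is.unsorted(eta))
  ordered <- psi_mean >= threshold
  if (!any(ordered))
    stop("unbracketed: no ordered cell (first grid point already disordered)")
  i <- max(which(ordered))
  if (i == length(eta))
    stop("unbracketed: ordered branch persists to the end of the grid")
  structure(list(eta_c = (eta[i] + eta[i + 1L]) / 2,
                 method = "branch_loss",
                 diagnostics = data.frame(eta_ordered = eta[i],
                                          eta_disordered = eta[i + 1L],
                                          threshold = threshold)),
            class = "critical_noise_estimate")
}

#' @export
print.critical_noise_estimate <- function(x, ...) {
  cat(sprintf("<critical_noise_estimate: eta_c = %.5f (%s)>\n",
              x$eta_c, x$method))
  invisible(x)
}

#' Critical noise from a sweep result
#'
#' Aggregates a [bifurcation_sweep] at one `p` and applies the estimator
#' matched to the model: pooled-variance peak for VN, ordered-branch
#' loss for AE (overridable).
#'
#' @param sweep A `sweep_result`.
#' @param p Which topology parameter to extract (default: the single
#'   value present).
#' @param method `"auto"`, `"variance_peak"` or `"branch_loss"`.
#' @param threshold Ordered-branch threshold for `branch_loss`.
#' @return A `critical_noise_estimate`.
#' @export
eta_c_from_sweep <- function(sweep, p = NULL, method = "auto",
                             threshold = 0.5) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (is.null(p)) {
    p <- unique(sweep$p)
    if (length(p) > 1L) stop("sweep has several p values; pick one")
  }
  cells <- sweep[sweep$p == p, , drop = FALSE]
  if (nrow(cells) == 0L) stop("no cells at the requested p")
  if (method == "auto")
    method <- if (cells$model[1L] == "vn") "variance_peak" else "branch_loss"
  etas <- sort(unique(cells$eta))
  if (method == "variance_peak") {
    v <- vapply(etas, function(e) {
      cc <- cells[cells$eta == e, ]
      pooled_variance(cc$psi_mean, cc$psi_var, cc$n_samples)
    }, 0)
    eta_c_variance_peak(etas, v)
  } else {
    m <- vapply(etas, function(e) mean(cells$psi_mean[cells$eta == e]), 0)
    eta_c_branch_loss(etas, m, threshold = threshold)
  }
}

#' Critical noise as a function of topology
#'
#' Runs one [bifurcation_sweep] per estimator repetition over a `p`
#' grid and reports, for each `p`, the critical noise averaged over
#' repetitions. This is the curve that exposes the topology effect:
#' random links always help the VN model, while for the AE model the SF
#' family peaks at intermediate `p`.
#'
#' @inheritParams bifurcation_sweep
#' @param reps Estimator repetitions to average over (each uses an
#'   independent derived seed).
#' @param method Estimator (default `"auto"`: VN variance peak, AE
#'   branch loss).
#' @param threshold Ordered-branch threshold.
#' @return Data frame `p`, `eta_c` (mean over reps), `sd_eta_c`,
#'   `method`, `reps`; per-repetition values in attribute `per_rep`.
#' @export
eta_c_vs_p_curve <- function(model = c("vn", "ae"), L,
                             family = c("nn2er", "nn2sf"), p, eta, runs,
                             steps, b = -2, reps = 1L, burn_in = 0.5,
                             stride = NULL, seed = 1L, params = NULL,
                             method = "auto", threshold = 0.5) {
  model <- match.arg(model); family <- match.arg(family)
  per <- vector("list", reps)
  for (r in seq_len(reps)) {
    sw <- bifurcation_sweep(model, L, family, p = p, eta = eta,
                            runs = runs, steps = steps, b = b,
                            burn_in = burn_in, stride = stride,
                            seed = derive_seed(seed, 101L, r),
                            params = params)
    per[[r]] <- data.frame(
      rep = r, p = p,
      eta_c = vapply(p, function(pp)
        eta_c_from_sweep(sw, p = pp, method = method,
                         threshold = threshold)$eta_c, 0))
  }
  per <- do.call(rbind, per)
  agg <- do.call(rbind, lapply(split(per, per$p), function(d)
    data.frame(p = d$p[1L], eta_c = mean(d$eta_c),
               sd_eta_c = stats::sd(d$eta_c))))
  agg <- agg[order(agg$p), , drop = FALSE]
  rownames(agg) <- NULL
  agg$method <- if (method == "auto") {
    if (model == "vn") "variance_peak" else "branch_loss"
  } else method
  agg$reps <- reps
  attr(agg, "per_rep") <- per
  agg
}
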