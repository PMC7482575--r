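#' Nearest-neighbour lattice network
#'
#' Places `L * L` agents on a square lattice with unit spacing and links
#' each one to its horizontal, vertical and diagonal first neighbours
#' (Moore neighbourhood, no periodic wrapping). Corner agents get 3
#' links, side agents 5, bulk agents 8, and the total edge count is
#' `2 * (L - 1) * (2 * L - 1)`, fixed by the lattice side alone. This is
#' the only purely local topology of the three families; its edge count
#' `K` sets the budget that the ER and SF generators must match.
#'
#' @param L Lattice side length (integer, at least 2).
#' @return A list with `positions` (an `N x 2` matrix of lattice
#'   coordinates, row-major node order: node `i` sits at
#'   `(x, y) = ((i-1) %% L, (i-1) %/% L)`) and `network`
#'   (an [interaction_network]).
#' @examples
#' nn <- build_nn_lattice(9)
#' n_edges(nn$network) # 272
#' @export
build_nn_lattice <- function(L) {
  L <- as.integer(L)
  if (length(L) != 1L || is.na(L) || L < 2L)
    stop("invalid lattice spec: L must be an integer >= 2")
  N <- L * L
  idx <- function(r, c) (r - 1L) * L + c # row-major, 1-based
  r <- rep(seq_len(L), each = L)
  c <- rep(seq_len(L), times = L)
  # enumerate each undirected edge once: east, south, south-east, south-west
  e_list <- list(
    cbind(idx(r, c), idx(r, c + 1L))[c < L, , drop = FALSE],
    cbind(idx(r, c), idx(r + 1L, c))[r < L, , drop = FALSE],
    cbind(idx(r, c), idx(r + 1L, c + 1L))[r < L & c < L, , drop = FALSE],
    cbind(idx(r, c), idx(r + 1L, c - 1L))[r < L & c > 1L, , drop = FALSE]
  )
  edges <- do.call(rbind, e_list)
  pos <- cbind(x = (seq_len(N) - 1L) %% L, y = (seq_len(N) - 1L) %/% L)
  list(
    positions = pos,
    network = interaction_network(N, edges)
  )
}

#' Closed-form edge count of the NN lattice
#' @param L Lattice side length.
#' @return `2 * (L - 1) * (2 * L - 1)`.
#' @export
nn_edge_count <- function(L) as.integer(2 * (L - 1) * (2 * L - 1))

#' Erdos-Renyi network with exact node and edge counts
#'
#' Repeatedly draws uniformly random node pairs, discarding self-pairs
#' and already-present links, until exactly `n_edges` distinct edges are
#' placed; the draw is repeated from scratch until the result is
#' connected. The degree distribution is Poissonian with mean
#' `2 * n_edges / n_nodes`.
#'
#' @param n_nodes Number of nodes.
#' @param n_edges Number of edges; must satisfy
#'   `n_nodes - 1 <= n_edges <= choose(n_nodes, 2)`.
#' @param seed Optional integer seed (NULL uses the current RNG stream).
#' @param max_retries Cap on connectivity retries (default 100).
#' @return A connected [interaction_network]; attribute `attempts`
#'   records how many draws were needed.
#' @export
build_er <- function(n_nodes, n_edges, seed = NULL, max_retries = 100L) {
  n_nodes <- as.integer(n_nodes)
  n_edges <- as.integer(n_edges)
  max_pairs <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_pairs)
    stop("n_edges exceeds the number of distinct node pairs")
  if (n_edges < n_nodes - 1L)
    stop("n_edges < n_nodes - 1: a connected graph is impossible")
  with_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      net <- er_draw(n_nodes, n_edges)
      if (is_connected(net)) {
        attr(net, "attempts") <- attempt
        return(net)
      }
    }
    stop(sprintf(
      "ER generation failed: no connected draw in %d attempts (N=%d, K=%d)",
      max_retries, n_nodes, n_edges))
  })
}

# One exact-K uniform draw (may be disconnected). Pairs are sampled in
# vectorized batches; rejection of self-pairs and duplicates reproduces
# the sequential pair-by-pair scheme's distribution.
er_draw <- function(n_nodes, n_edges) {
  keys <- double(0)
  need <- n_edges
  while (need > 0L) {
    m <- max(64L, ceiling(need * 1.2))
    i <- sample.int(n_nodes, m, replace = TRUE)
    j <- sample.int(n_nodes, m, replace = TRUE)
    ok <- i != j
    a <- pmin(i[ok], j[ok]); b <- pmax(i[ok], j[ok])
    k <- (a - 1) * as.double(n_nodes) + (b - 1)
    k <- k[!duplicated(k)]
    k <- k[!(k %in% keys)]
    keys <- c(keys, k[seq_len(min(length(k), need))])
    need <- n_edges - length(keys)
  }
  a <- as.integer(keys %/% n_nodes) + 1L
  b <- as.integer(keys %% n_nodes) + 1L
  interaction_network(n_nodes, cbind(a, b))
}

#' Solve a truncated power-law degree sequence for exact N and K
#'
#' Builds the degree histogram `n_k = Round(C * k^b)` (floored at 1) over
#' `k = k_min .. k_max` and searches for the prefactor `C` and cut-off
#' `k_max` whose node and stub totals best match the targets, minimizing
#' the weighted objective
#' `J = w_n * (N_opt - n_nodes)^2 + w_k * (K_opt - 2 * n_edges)^2`,
#' where `N_opt = sum(n_k)` and `K_opt = sum(k * n_k)` is the stub
#' (degree) total, which must reach `2 * n_edges` for the realized
#' undirected network to have exactly `n_edges` links. A deterministic
#' final adjustment then enforces both totals exactly: first the flat
#' `n_k = 1` tail is extended or trimmed at the top until the node count
#' matches, then single nodes at the largest occupied degree are moved up
#' or down one degree at a time until the stub count matches.
#'
#' `k_min = 2` is the default because an agent held by a single spring is
#' mechanically unconstrained in the AE model (it can swing about its
#' anchor) and so can never be forced into alignment.
#'
#' @param n_nodes Target node count N.
#' @param n_edges Target edge count K.
#' @param b Power-law exponent (negative).
#' @param k_min Minimum degree (default 2).
#' @param w_n,w_k Objective weights (defaults 10 and 1).
#' @return A [degree_sequence] with `sum(n_k) == n_nodes` and
#'   `sum(k * n_k) == 2 * n_edges`, plus attributes `C`, `k_max`
#'   (optimizer values), `J` (objective at the optimum, before the final
#'   adjustment) and `adjustments` (log of the adjustment steps).
#' @examples
#' s <- solve_sf_degree_sequence(81, 272, b = -2)
#' sum(s)                            # 81
#' sum(as.integer(names(s)) * s)     # 544
#' @export
solve_sf_degree_sequence <- function(n_nodes, n_edges, b, k_min = 2L,
                                     w_n = 10, w_k = 1) {
  n_nodes <- as.integer(n_nodes); n_edges <- as.integer(n_edges)
  k_min <- as.integer(k_min)
  if (b >= 0) stop("b must be negative")
  if (k_min < 2L) stop("k_min must be >= 2")
  stubs_tgt <- 2 * as.double(n_edges)
  if (stubs_tgt < k_min * as.double(n_nodes))
    stop("infeasible targets: average degree below k_min")
  if (stubs_tgt > as.double(n_nodes) * (n_nodes - 1))
    stop("infeasible targets: average degree above n_nodes - 1")

  # cut-off scan range: once even the all-ones histogram's stub total
  # overshoots the target, both sums and hence J only grow with k_max
  kmax_hi <- k_min + 1L
  while (kmax_hi < n_nodes - 1L &&
         sum(as.double(k_min:kmax_hi)) <= stubs_tgt) {
    kmax_hi <- kmax_hi + 1L
  }
  kmax_hi <- min(n_nodes - 1L, kmax_hi + 5L)

  best <- list(J = Inf, C = NA_real_, k_max = NA_integer_, counts = NULL)
  for (k_max in (k_min + 1L):kmax_hi) {
    k <- k_min:k_max
    kb <- as.double(k)^b
    C0 <- n_nodes / sum(kb)
    fit <- sf_best_C(kb, k, C0, n_nodes, stubs_tgt, w_n, w_k)
    if (fit$J < best$J) { # strict: ties keep the smaller k_max
      best <- list(J = fit$J, C = fit$C, k_max = k_max, counts = fit$counts)
    }
  }

  counts <- best$counts
  k <- k_min:best$k_max
  log <- character(0)

  # phase 1: match the node count by growing/trimming the n_k = 1 tail
  while (sum(counts) < n_nodes) {
    k <- c(k, k[length(k)] + 1L); counts <- c(counts, 1L)
    log <- c(log, sprintf("added degree-%d entry (n=1)", k[length(k)]))
  }
  while (sum(counts) > n_nodes) {
    top <- length(counts)
    if (counts[top] == 1L) {
      log <- c(log, sprintf("removed degree-%d entry (n=1)", k[top]))
      counts <- counts[-top]; k <- k[-top]
    } else {
      counts[top] <- counts[top] - 1L
      log <- c(log, sprintf("decremented count at degree %d", k[top]))
    }
  }

  # phase 2: match the stub count by moving single top-degree nodes
  stub_sum <- function() sum(as.double(k) * counts)
  while (stub_sum() != stubs_tgt) {
    s <- stub_sum()
    top <- max(which(counts >= 1L))
    if (s < stubs_tgt) {
      if (k[top] + 1L > n_nodes - 1L)
        stop("degree-sequence adjustment hit the simple-graph degree cap")
      if (top == length(k)) { k <- c(k, k[top] + 1L); counts <- c(counts, 0L) }
      counts[top] <- counts[top] - 1L
      counts[top + 1L] <- counts[top + 1L] + 1L
      log <- c(log, sprintf("moved one node %d -> %d", k[top], k[top] + 1L))
    } else {
      if (k[top] - 1L < k_min)
        stop("infeasible: stub surplus cannot be removed above k_min")
      counts[top] <- counts[top] - 1L
      counts[top - 1L] <- counts[top - 1L] + 1L
      log <- c(log, sprintf("moved one node %d -> %d", k[top], k[top] - 1L))
    }
    while (length(counts) && counts[length(counts)] == 0L) {
      counts <- counts[-length(counts)]; k <- k[-length(k)]
    }
  }

  keep <- counts > 0L
  seq <- degree_sequence(stats::setNames(counts[keep], k[keep]))
  attr(seq, "C") <- best$C
  attr(seq, "k_max") <- best$k_max
  attr(seq, "J") <- best$J
  attr(seq, "adjustments") <- log
  seq
}

# rounded, 1-floored histogram for a given prefactor
sf_counts <- function(C, kb) {
  x <- C * kb
  n <- ifelse(x >= 1, floor(x + 0.5), 1) # round half away from zero
  as.integer(n)
}

# 1-D search over C at fixed k_max. J is piecewise constant in C, so use
# a two-stage deterministic grid refinement around the continuous guess.
sf_best_C <- function(kb, k, C0, n_tgt, stubs_tgt, w_n, w_k) {
  eval_grid <- function(Cs) {
    Js <- vapply(Cs, function(C) {
      n <- sf_counts(C, kb)
      w_n * (sum(n) - n_tgt)^2 + w_k * (sum(as.double(k) * n) - stubs_tgt)^2
    }, 0)
    i <- which.min(Js)
    list(C = Cs[i], J = Js[i])
  }
  coarse <- eval_grid(C0 * exp(seq(log(0.25), log(4), length.out = 160)))
  fine <- eval_grid(coarse$C * exp(seq(-0.05, 0.05, length.out = 200)))
  best <- if (fine$J <= coarse$J) fine else coarse
  list(C = best$C, J = best$J, counts = sf_counts(best$C, kb))
}

#' Realize a degree sequence as a random simple connected graph
#'
#' Assigns each node its prescribed number of link stubs and pairs them
#' at random, processing nodes from the highest degree down; each node's
#' remaining stubs are connected to distinct partners drawn with
#' probability proportional to their remaining stub counts. Dead ends
#' (a node that cannot place all its stubs simply) and disconnected
#' outcomes trigger a restart from scratch.
#'
#' @param seq A [degree_sequence]; its stub total must be even.
#' @param seed Optional integer seed.
#' @param max_retries Restart cap (default 100).
#' @return A connected [interaction_network] whose degree histogram
#'   equals `seq` exactly; attribute `attempts` records the restarts.
#' @export
realize_degree_sequence <- function(seq, seed = NULL, max_retries = 100L) {
  degs <- degrees_from_sequence(seq)
  n <- length(degs)
  if (sum(degs) %% 2L != 0L) stop("stub total must be even")
  if (any(degs > n - 1L)) stop("degree exceeds n_nodes - 1: not simple")
  with_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      net <- stub_match_once(degs, n)
      if (!is.null(net) && is_connected(net)) {
        attr(net, "attempts") <- attempt
        return(net)
      }
    }
    stop(sprintf(
      "degree-sequence realization failed after %d attempts", max_retries))
  })
}

# single highest-degree-first stub-matching pass; NULL on dead end.
# While node v (largest residual) is being wired, every current
# neighbour of v has residual zero, so "residual > 0" candidates are
# automatically non-adjacent to v and simplicity is preserved.
stub_match_once <- function(degs, n) {
  residual <- degs # descending order
  from <- integer(sum(degs) / 2L); to <- integer(length(from)); m <- 0L
  for (v in seq_len(n)) {
    need <- residual[v]
    if (need == 0L) next
    residual[v] <- 0L
    cand <- which(residual > 0L)
    if (length(cand) < need) return(NULL)
    w <- if (length(cand) == 1L) cand else
      sample(cand, need, prob = residual[cand])
    residual[w] <- residual[w] - 1L
    from[m + seq_len(need)] <- v
    to[m + seq_len(need)] <- w
    m <- m + need
  }
  interaction_network(n, cbind(from[seq_len(m)], to[seq_len(m)]))
}

#' Build a scale-free network with exact N and K
#'
#' Convenience wrapper: solves the degree sequence for the targets via
#' [solve_sf_degree_sequence] and realizes it with
#' [realize_degree_sequence].
#'
#' @inheritParams solve_sf_degree_sequence
#' @inheritParams realize_degree_sequence
#' @return A connected [interaction_network] with exactly `n_edges`
#'   edges and power-law-ish degree histogram.
#' @export
build_sf <- function(n_nodes, n_edges, b = -2, k_min = 2L, seed = NULL,
                     max_retries = 100L) {
  seq <- solve_sf_degree_sequence(n_nodes, n_edges, b, k_min)
  realize_degree_sequence(seq, seed = seed, max_retries = max_retries)
}

#' Superpose a lattice network with a random network
#'
#' Interpolates between the NN lattice (`p = 0`) and an ER or SF random
#' network (`p = 1`) at constant edge count: `round(p * K)` links are
#' deleted at random from the NN network, the complementary number from
#' the random network, and the two remainders are merged. Links present
#' in both retained sets collapse to one; the deficit is refilled with
#' uniformly random absent edges so the result has exactly `K` edges.
#' Draws are repeated until the superposed network is connected.
#'
#' @param nn The lattice [interaction_network].
#' @param rnd The random [interaction_network]; must have the same node
#'   and edge counts as `nn`.
#' @param p Topological control parameter in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param max_retries Connectivity retry cap (default 100).
#' @return A connected [interaction_network] with exactly `n_edges(nn)`
#'   edges; attributes `refilled` (edges added to compensate overlap)
#'   and `attempts`.
#' @export
superpose <- function(nn, rnd, p, seed = NULL, max_retries = 100L) {
  stopifnot(inherits(nn, "interaction_network"),
            inherits(rnd, "interaction_network"))
  if (nn$n_nodes != rnd$n_nodes)
    stop("superpose: node counts differ")
  K <- nrow(nn$edges)
  if (K != nrow(rnd$edges))
    stop("superpose: edge counts differ")
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("superpose: p must be a single value in [0, 1]")
  if (p == 0) return(nn)
  if (p == 1) return(rnd)
  n <- nn$n_nodes
  drop_nn <- as.integer(round(p * K))
  keep_rnd <- drop_nn            # delete (1 - p) K from the random net
  with_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      keep1 <- nn$edges[sample.int(K, K - drop_nn), , drop = FALSE]
      keep2 <- rnd$edges[sample.int(K, keep_rnd), , drop = FALSE]
      edges <- rbind(keep1, keep2)
      key <- (pmin(edges[, 1], edges[, 2]) - 1) * as.double(n) +
        (pmax(edges[, 1], edges[, 2]) - 1)
      edges <- edges[!duplicated(key), , drop = FALSE]
      refill <- 0L
      while (nrow(edges) < K) { # top up overlap losses
        need <- K - nrow(edges)
        i <- sample.int(n, 2 * need, replace = TRUE)
        j <- sample.int(n, 2 * need, replace = TRUE)
        ok <- i != j
        a <- pmin(i[ok], j[ok]); b <- pmax(i[ok], j[ok])
        knew <- (a - 1) * as.double(n) + (b - 1)
        fresh <- !duplicated(knew) & !(knew %in% key)
        add <- which(fresh)[seq_len(min(need, sum(fresh)))]
        refill <- refill + length(add)
        edges <- rbind(edges, cbind(a[add], b[add]))
        key <- c(key, knew[add])
      }
      net <- interaction_network(n, edges)
      if (is_connected(net)) {
        attr(net, "refilled") <- refill
        attr(net, "attempts") <- attempt
        return(net)
      }
    }
    stop(sprintf("superpose failed: no connected draw in %d attempts",
                 max_retries))
  })
}
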