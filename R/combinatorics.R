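#' Machine geometry
#'
#' Describes the partition of a distributed machine into `M` MPI processes
#' with `T` threads each.  Threads are "virtual processes" (VPs): each
#' thread keeps its own replica of the connection infrastructure, so all
#' sparseness expressions depend on the machine only through the product
#' `M * T`.
#'
#' @param M number of MPI processes (>= 1).
#' @param T_ threads per process (>= 1).  Named `T_` to avoid clashing with
#'   the `TRUE` shorthand.
#' @return an object of class `machine_grid` with fields `M`, `T` and the
#'   derived total VP count `VP = M * T`.
#' @examples
#' machine_grid(80000, 8)
#' @export
machine_grid <- function(M, T_ = 1) {
  if (length(M) != 1L || length(T_) != 1L || !is.finite(M) || !is.finite(T_))
    stop("M and T_ must be finite scalars")
  if (M < 1 || T_ < 1) stop("M and T_ must be >= 1")
  structure(list(M = M, T = T_, VP = M * T_), class = "machine_grid")
}

#' Network shape
#'
#' Total network size `N` and mean in-degree `K` (incoming synapses per
#' neuron), together with the derived per-virtual-process loads
#' `N_vp = N / (M T)` neurons and `K_vp = N_vp * K` synapses.  `K` may be
#' non-integer: the model treats it as a mean.
#'
#' @param N total number of neurons (>= 1).
#' @param K mean number of incoming synapses per neuron (>= 0).
#' @param grid a [machine_grid()].
#' @return object of class `network_shape` with fields `N`, `K`, `N_vp`,
#'   `K_vp`.
#' @export
network_shape <- function(N, K, grid) {
  stopifnot(inherits(grid, "machine_grid"))
  if (!is.finite(N) || N < 1) stop("N must be >= 1")
  if (!is.finite(K) || K < 0) stop("K must be >= 0")
  N_vp <- N / grid$VP
  structure(list(N = N, K = K, N_vp = N_vp, K_vp = N_vp * K),
            class = "network_shape")
}

new_target_list_stats <- function(p_empty, p_one, p_multi, N) {
  structure(list(
    p_empty = p_empty, p_one = p_one, p_multi = p_multi,
    n_empty = p_empty * N, n_one = p_one * N, n_multi = p_multi * N,
    n_nonempty = (p_one + p_multi) * N
  ), class = "target_list_stats")
}

#' Distribution of target-list lengths on one virtual process
#'
#' Each of the `N` neurons of a random network draws on average `K` source
#' neurons uniformly with replacement, so `K_vp = N K / (M T)` sources are
#' drawn on each virtual process.  The probability that a particular neuron
#' is never drawn as a source on a given VP (its local target list is
#' empty) is `p_empty = (1 - 1/N)^K_vp`; the probability of exactly one
#' local target is `p_one = (1 - 1/N)^(K_vp - 1) * K_vp / N`; the remainder
#' has more than one.  In the Poisson (large-`N`) limit these become
#' `exp(-K/(MT))` and `exp(-K/(MT)) * K/(MT)`.
#'
#' @param grid a [machine_grid()].
#' @param shape a [network_shape()].
#' @param mode `"exact"` for the binomial closed form (requires `N >= 2`)
#'   or `"poisson_limit"` for the large-`N` limit.
#' @return a `target_list_stats` object holding probabilities `p_empty`,
#'   `p_one`, `p_multi` (summing to 1) and expected per-VP counts
#'   `n_empty`, `n_one`, `n_multi`, `n_nonempty` (probability times `N`).
#' @examples
#' g <- machine_grid(80000, 8)
#' s <- network_shape(1e9, 1e4, g)
#' target_list_probabilities(g, s, mode = "poisson_limit")
#' @export
target_list_probabilities <- function(grid, shape,
                                      mode = c("exact", "poisson_limit")) {
  stopifnot(inherits(grid, "machine_grid"), inherits(shape, "network_shape"))
  mode <- match.arg(mode)
  N <- shape$N
  K_vp <- shape$K_vp
  if (shape$K == 0)
    return(new_target_list_stats(1, 0, 0, N))
  if (mode == "exact") {
    if (N < 2) stop("exact mode requires N >= 2")
    p0 <- (1 - 1 / N)^K_vp
    p1 <- (1 - 1 / N)^(K_vp - 1) * K_vp / N
  } else {
    lam <- shape$K / grid$VP
    p0 <- exp(-lam)
    p1 <- exp(-lam) * lam
  }
  new_target_list_stats(p0, p1, 1 - p0 - p1, N)
}

#' Conditional length distribution of non-empty target lists
#'
#' Given that a source neuron has at least one local target, the
#' probability that it has exactly one is `p_one / (p_one + p_multi)`;
#' in the sparse limit this approaches `1 - K/(2 M T)`.
#'
#' @inheritParams target_list_probabilities
#' @return named numeric vector `c(one = ..., multi = ...)` summing to 1.
#' @export
conditional_singleton_probability <- function(grid, shape,
                                              mode = c("exact", "poisson_limit")) {
  st <- target_list_probabilities(grid, shape, mode)
  denom <- st$p_one + st$p_multi
  if (denom <= 0)
    stop("conditional probabilities undefined: all target lists empty (K = 0)")
  c(one = st$p_one / denom, multi = st$p_multi / denom)
}

#' Expected per-VP counts of empty, singleton and longer target lists
#'
#' Multiplies the length probabilities by `N`.  The expected number of
#' non-empty lists `(1 - p_empty) N` approaches the local synapse count
#' `K_vp` under weak scaling (fixed `N_vp` and `K`, growing machine), at
#' which point every local synapse carries the overhead of a full target
#' list.
#'
#' @inheritParams target_list_probabilities
#' @return a `target_list_stats` object (see
#'   [target_list_probabilities()]).
#' @export
expected_list_counts <- function(grid, shape,
                                 mode = c("exact", "poisson_limit")) {
  target_list_probabilities(grid, shape, mode)
}

#' Network size at which a fraction of the target-list limit is reached
#'
#' Under weak scaling the number of non-empty target lists per VP
#' saturates at `K_vp`.  The network size `N_zeta` at which a fraction
#' `zeta` of that limit is reached solves
#' `zeta K_vp = (1 - exp(-K_vp / N)) N`.  The equation is solved by
#' bisection (the reference method), via the principal branch of the
#' Lambert-W function, or by the second-order approximation
#' `N_zeta ~ K_vp / (2 (1 - zeta))`, which becomes accurate as
#' `zeta -> 1`.
#'
#' @param K_vp local synapse count per virtual process (> 0).
#' @param zeta fill fraction, strictly between 0 and 1.
#' @param method `"bisect"` (default, reference), `"lambert"` or
#'   `"approx"`.
#' @return the network size `N_zeta` (real-valued).
#' @examples
#' network_size_at_fill_fraction(2000 * 10000, 0.95, "approx")
#' @export
network_size_at_fill_fraction <- function(K_vp, zeta,
                                          method = c("bisect", "lambert", "approx")) {
  method <- match.arg(method)
  if (!is.finite(K_vp) || K_vp <= 0) stop("K_vp must be > 0")
  if (!is.finite(zeta) || zeta <= 0 || zeta >= 1)
    stop("zeta must lie strictly between 0 and 1")
  if (method == "approx")
    return(K_vp / (2 * (1 - zeta)))
  if (method == "lambert") {
    # e^s = 1 + zeta*s with s = -K_vp/N; v = -(1 + zeta*s)/zeta puts the
    # nontrivial root on the principal branch: v = W0(-exp(-1/zeta)/zeta).
    v <- pracma::lambertWp(-exp(-1 / zeta) / zeta)
    return(K_vp / (v + 1 / zeta))
  }
  f <- function(N) (1 - exp(-K_vp / N)) * N - zeta * K_vp
  lo <- K_vp * 1e-8
  hi <- K_vp * 1e8
  # f is increasing in N: f(lo) ~ lo - zeta*K_vp < 0, f(hi) -> (1-zeta)K_vp > 0
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if ((hi - lo) / hi < 1e-13) break
  }
  (lo + hi) / 2
}
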