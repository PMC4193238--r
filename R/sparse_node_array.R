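#' Round-robin rank of a global node id
#'
#' Nodes are created with strictly increasing GIDs and distributed over
#' `M` ranks round-robin, so node `g` lives on rank `g mod M`.
#'
#' @param gid global node id (>= 0), vectorised.
#' @param M number of ranks (>= 1).
#' @return `gid %% M`.
#' @export
rank_of <- function(gid, M) {
  if (any(gid < 0)) stop("gid must be >= 0")
  if (M < 1) stop("M must be >= 1")
  gid %% M
}

#' Sparse node array: ordered local-node storage with linear lookup
#'
#' Stores the nodes local to one rank in creation (GID) order.  Because
#' regular nodes are assigned round-robin, neighbouring local GIDs differ
#' by `M`, so the local index of a GID can be estimated by linear
#' interpolation between the smallest and largest local GID.  Replicated
#' nodes (devices, subnets present on every rank) skew the estimate
#' slightly; the lookup scans from the estimate until it finds the GID or
#' brackets it.  The root node with GID 0, local to all ranks, is ignored
#' when computing the interpolation range.
#'
#' @param gids strictly increasing local GIDs.
#' @param nodes optional list of node payloads, same length as `gids`
#'   (defaults to the GIDs themselves).
#' @param max_gid largest GID in the whole network (defaults to
#'   `max(gids)`), used to detect invalid lookups.
#' @return object of class `sparse_node_array` with fields `gids`,
#'   `nodes`, `n_loc`, `g_loc_min`, `g_loc_max`, `alpha`, `max_gid`.
#'   `alpha = (n_loc - 2) / (g_loc_max - g_loc_min)`; degenerate arrays
#'   (fewer than 2 non-root entries) get `alpha = 0` and fall back to a
#'   direct scan.
#' @export
sparse_node_array <- function(gids, nodes = NULL, max_gid = NULL) {
  if (length(gids) > 1 && any(diff(gids) <= 0))
    stop("gids must be strictly increasing")
  if (any(gids < 0)) stop("gids must be >= 0")
  if (is.null(nodes)) nodes <- as.list(gids)
  if (length(nodes) != length(gids))
    stop("nodes must match gids in length")
  if (is.null(max_gid)) max_gid <- if (length(gids)) max(gids) else 0
  reg <- gids[gids > 0]  # root network GID 0 excluded from the range
  if (length(reg) >= 2 && max(reg) > min(reg)) {
    g_min <- min(reg)
    g_max <- max(reg)
    alpha <- (length(gids) - 2) / (g_max - g_min)
  } else {
    g_min <- if (length(reg)) min(reg) else NA_real_
    g_max <- if (length(reg)) max(reg) else NA_real_
    alpha <- 0
  }
  structure(list(gids = gids, nodes = nodes, n_loc = length(gids),
                 g_loc_min = g_min, g_loc_max = g_max, alpha = alpha,
                 max_gid = max_gid),
            class = "sparse_node_array")
}

#' Look up a node by GID
#'
#' Starts at the linear index estimate
#' `l* = floor(1 + alpha * (gid - g_loc_min))` (a zero-based position;
#' with the root node in slot 0 and pure round-robin GIDs the estimate
#' hits every local node exactly), clamped to the valid range, and scans
#' toward smaller or larger GIDs.  Returns the node if found; if a GID
#' bracketing the query is passed, the node is not local.  `steps` counts
#' the moves away from the initial estimate.
#'
#' @param array a [sparse_node_array()].
#' @param gid queried GID in `[0, max_gid]`.
#' @return list with `found` (logical), `node` (payload or `NULL`) and
#'   `steps`.
#' @export
node_lookup <- function(array, gid) {
  stopifnot(inherits(array, "sparse_node_array"))
  if (gid < 0 || gid > array$max_gid)
    stop("invalid GID: outside [0, max_gid]")
  n <- array$n_loc
  if (n == 0) return(list(found = FALSE, node = NULL, steps = 0))
  g <- array$gids
  l <- if (array$alpha > 0)
    floor(1 + array$alpha * (gid - array$g_loc_min)) + 1  # 0-based -> R index
  else 1
  l <- min(max(l, 1), n)
  steps <- 0
  if (g[l] == gid)
    return(list(found = TRUE, node = array$nodes[[l]], steps = steps))
  if (g[l] < gid) {
    while (l < n && g[l] < gid) {
      l <- l + 1
      steps <- steps + 1
      if (g[l] == gid)
        return(list(found = TRUE, node = array$nodes[[l]], steps = steps))
    }
  } else {
    while (l > 1 && g[l] > gid) {
      l <- l - 1
      steps <- steps + 1
      if (g[l] == gid)
        return(list(found = TRUE, node = array$nodes[[l]], steps = steps))
    }
  }
  list(found = FALSE, node = NULL, steps = steps)
}

#' Iterate over all local nodes in GID order
#'
#' @param array a [sparse_node_array()].
#' @return data frame with columns `gid` and list-column index `i`
#'   suitable for retrieving `array$nodes[[i]]`; exactly `n_loc` rows,
#'   ascending GIDs.
#' @export
iterate_local <- function(array) {
  stopifnot(inherits(array, "sparse_node_array"))
  data.frame(gid = if (array$n_loc) array$gids else numeric(0),
             i = seq_len(array$n_loc))
}

#' Memory overhead of a sparse node array
#'
#' One pointer and one long (8 B each) per local node; independent of the
#' total network size.
#'
#' @param array a [sparse_node_array()].
#' @return bytes.
#' @export
sna_overhead_bytes <- function(array) {
  stopifnot(inherits(array, "sparse_node_array"))
  array$n_loc * 16
}

#' Lookup instrumentation over a whole GID range
#'
#' Runs [node_lookup()] for every GID in `[0, max_gid]` (or a supplied
#' set) and reports search-step statistics, the report a simulator would
#' emit when validating the linear-estimate quality.
#'
#' @param array a [sparse_node_array()].
#' @param gids GIDs to probe (default all of `0:max_gid`).
#' @return list with `n_lookups`, `mean_steps`, `max_steps`,
#'   `mean_steps_local` (over local hits only).
#' @export
lookup_statistics <- function(array, gids = NULL) {
  stopifnot(inherits(array, "sparse_node_array"))
  if (is.null(gids)) gids <- 0:array$max_gid
  res <- lapply(gids, function(g) node_lookup(array, g))
  steps <- vapply(res, `[[`, numeric(1), "steps")
  found <- vapply(res, `[[`, logical(1), "found")
  list(n_lookups = length(gids),
       mean_steps = mean(steps),
       max_steps = if (length(steps)) max(steps) else 0,
       mean_steps_local = if (any(found)) mean(steps[found]) else NA_real_)
}

#' Generate a synthetic rank for lookup benchmarking
#'
#' Emulates the local GID set of one rank of an `M`-rank machine:
#' `n_regular` round-robin GIDs (congruent to `rank` modulo `M`) with
#' `n_replicated` replicated-node GIDs interleaved at uniformly spread
#' creation positions, as devices created throughout network setup
#' would be.
#'
#' @param M number of ranks.
#' @param rank rank id in `[0, M)`.
#' @param n_regular approximate number of regular (round-robin) local
#'   nodes; the machine creates `n_regular * M` nodes in total.
#' @param n_replicated replicated nodes, present on every rank, occupying
#'   GIDs spread uniformly over the creation order.
#' @return list with `gids` (sorted local GIDs, starting with the root
#'   GID 0 that every rank holds) and `max_gid`.
#' @export
synthetic_rank <- function(M, rank, n_regular, n_replicated = 0) {
  if (rank < 0 || rank >= M) stop("rank must lie in [0, M)")
  G <- n_regular * M
  rep_gids <- if (n_replicated > 0)
    unique(round(seq(1, G, length.out = n_replicated + 2))[-c(1, n_replicated + 2)])
  else numeric(0)
  all_g <- seq_len(G)
  reg <- all_g[all_g %% M == rank & !(all_g %in% rep_gids)]
  gids <- sort(unique(c(0, reg, rep_gids)))
  list(gids = gids, max_gid = G)
}
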