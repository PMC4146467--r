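#' Synchronous update of a logical network
#'
#' Applies every node's regulatory function simultaneously: each unclamped
#' node reads the values of its regulators at time `t` and takes the table
#' output as its value at `t + 1` (all reads happen before any write).
#' Clamped nodes take their clamp value; their truth tables are never
#' consulted.
#'
#' @inheritParams n_nodes
#' @param state an integer state vector (one value per node), or an integer
#'   matrix with one row per state for batched stepping.
#' @param clamps a [perturbation()] (possibly `NULL` for the wild type).
#' @return the successor state(s), same shape as `state`.
#' @export
step_network <- function(net, state, clamps = NULL) {
  cn <- compile_network(net)
  cl <- resolve_clamps(net, clamps)
  if (is.matrix(state)) {
    if (ncol(state) != cn$n) stop("state matrix must have one column per node", call. = FALSE)
    step_batch(cn, state, cl$idx, cl$val)
  } else {
    s <- network_state(net, state)
    out <- step_batch(cn, matrix(s, nrow = 1), cl$idx, cl$val)
    stats::setNames(as.integer(out[1, ]), cn$names)
  }
}

# Batched synchronous update. S: M x N integer matrix. Clamped nodes are
# skipped entirely (their tables are not read) and then set to clamp values.
step_batch <- function(cn, S, clamp_idx = integer(0), clamp_val = integer(0)) {
  S2 <- S
  clamped <- logical(cn$n)
  clamped[clamp_idx] <- TRUE
  for (i in which(!clamped)) {
    j <- cn$reg_idx[[i]]
    if (length(j) == 0) {
      S2[, i] <- cn$tables[[i]][1L]
    } else {
      idx <- S[, j, drop = FALSE] %*% cn$weights[[i]] + 1
      S2[, i] <- cn$tables[[i]][idx]
    }
  }
  for (k in seq_along(clamp_idx)) S2[, clamp_idx[k]] <- clamp_val[k]
  S2
}

resolve_clamps <- function(net, clamps) {
  if (is.null(clamps) || nrow(clamps) == 0) return(list(idx = integer(0), val = integer(0)))
  stopifnot(inherits(clamps, "perturbation"))
  idx <- node_index(net, clamps$node)
  ar <- net$nodes$arity[idx]
  if (any(clamps$value < 0L | clamps$value >= ar)) {
    stop("clamp value outside node arity", call. = FALSE)
  }
  list(idx = idx, val = as.integer(clamps$value))
}

# Mixed-radix encoding of full states; node 1 is the most significant digit,
# so lexicographic order on state vectors equals numeric order on encodings.
encoding_weights <- function(arities) {
  rev(cumprod(rev(c(as.numeric(arities[-1]), 1))))
}

encode_states <- function(S, arities) {
  as.vector(S %*% encoding_weights(arities))
}

decode_state <- function(enc, arities) {
  k <- length(arities)
  out <- integer(k)
  for (j in k:1) {
    out[j] <- enc %% arities[j]
    enc <- enc %/% arities[j]
  }
  out
}

#' Simulate a trajectory under synchronous update
#'
#' @inheritParams step_network
#' @param initial integer initial state (time 0).
#' @param t_max number of update steps; the trajectory has `t_max + 1` rows.
#' @return a tibble of class `network_trajectory` with a `t` column and one
#'   column per node; the active perturbation is stored in the
#'   `"clamps"` attribute.
#' @export
simulate_network <- function(net, initial, t_max, clamps = NULL) {
  stopifnot(t_max >= 0)
  cn <- compile_network(net)
  cl <- resolve_clamps(net, clamps)
  s <- network_state(net, initial)
  out <- matrix(NA_integer_, nrow = t_max + 1, ncol = cn$n,
                dimnames = list(NULL, cn$names))
  out[1, ] <- s
  S <- matrix(s, nrow = 1)
  for (t in seq_len(t_max)) {
    S <- step_batch(cn, S, cl$idx, cl$val)
    out[t + 1, ] <- S[1, ]
  }
  tr <- tibble::as_tibble(as.data.frame(out))
  tr <- dplyr::bind_cols(tibble::tibble(t = 0:t_max), tr)
  attr(tr, "clamps") <- clamps
  class(tr) <- c("network_trajectory", class(tr))
  tr
}

#' Locate the attractor reached from one initial condition
#'
#' Walks the trajectory, hashing every full state vector, until a state
#' repeats. Because the update is deterministic on a finite state space this
#' always terminates; the first revisited state closes the cycle, so the
#' returned period is automatically minimal and the transient is the first
#' time index lying on the cycle.
#'
#' @inheritParams simulate_network
#' @param max_steps safety bound on the walk length.
#' @return a list with elements `transient` (integer), and `attractor` — a
#'   list with `cycle` (period x N matrix, starting at the canonical, i.e.
#'   lexicographically smallest, member), `period`, and `representative`
#'   (the canonical state vector).
#' @export
find_attractor <- function(net, initial, clamps = NULL, max_steps = 1e6) {
  cn <- compile_network(net)
  cl <- resolve_clamps(net, clamps)
  s <- network_state(net, initial)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  states <- list()
  S <- matrix(s, nrow = 1)
  t <- 0L
  repeat {
    enc <- encode_states(S, cn$arity)
    key <- sprintf("%.0f", enc)
    first <- seen[[key]]
    if (!is.null(first)) {
      period <- t - first
      cycle <- do.call(rbind, states[(first + 1L):t])
      colnames(cycle) <- cn$names
      k <- which.min(encode_states(cycle, cn$arity))
      cycle <- cycle[c(k:period, seq_len(k - 1L)), , drop = FALSE]
      return(list(
        transient = first,
        attractor = list(cycle = cycle, period = period,
                         representative = stats::setNames(cycle[1, ], cn$names))
      ))
    }
    seen[[key]] <- t
    states[[t + 1L]] <- S[1, ]
    if (t >= max_steps) stop("no attractor found within max_steps", call. = FALSE)
    S <- step_batch(cn, S, cl$idx, cl$val)
    t <- t + 1L
  }
}

# Build the initial-condition matrix for an IC policy.
# ic_policy: named integer vector of nodes held fixed at t = 0 and excluded
# from the free dimensions (e.g. c(Speract = 1) for speract-activated ICs).
make_ics <- function(net, ic_policy = NULL, mode = c("sample", "exhaustive"),
                     n = 1e5, max_exhaustive = 2^22) {
  mode <- match.arg(mode)
  N <- n_nodes(net)
  ar <- net$nodes$arity
  fixed_idx <- if (is.null(ic_policy)) integer(0) else node_index(net, names(ic_policy))
  free_idx <- setdiff(seq_len(N), fixed_idx)
  if (mode == "sample") {
    stopifnot(n >= 1)
    S <- matrix(0L, nrow = n, ncol = N)
    for (i in free_idx) S[, i] <- sample.int(ar[i], n, replace = TRUE) - 1L
  } else {
    total <- prod(ar[free_idx])
    if (total > max_exhaustive) {
      stop(sprintf("exhaustive enumeration would need %.0f states (limit %.0f)",
                   total, max_exhaustive), call. = FALSE)
    }
    g <- expand.grid(rev(lapply(ar[free_idx], function(k) 0:(k - 1))),
                     KEEP.OUT.ATTRS = FALSE)
    S <- matrix(0L, nrow = total, ncol = N)
    S[, free_idx] <- as.matrix(g[, rev(seq_along(free_idx)), drop = FALSE])
  }
  for (k in seq_along(fixed_idx)) S[, fixed_idx[k]] <- as.integer(ic_policy[k])
  colnames(S) <- net$nodes$name
  S
}

#' Attractors, basins and transients over a space of initial conditions
#'
#' Evolves every initial condition (exhaustively enumerated or sampled
#' uniformly with replacement) past its transient, identifies the attractor
#' it lands on, and reports one row per distinct attractor with its period
#' and basin fraction. Attractor identity is canonical: two initial
#' conditions share an attractor exactly when their cycles contain the same
#' states; the representative is the lexicographically smallest cycle
#' member.
#'
#' The engine is fully vectorized: all initial conditions are stepped
#' together, the burn-in encodings are kept, and the period of each
#' trajectory is the first-return time of its post-burn-in state. The
#' transient of a trajectory is the number of leading time indices whose
#' state is not yet on the cycle (`state[t] != state[t + period]`).
#'
#' @inheritParams step_network
#' @param ic_policy named integer vector of nodes held fixed at time 0 and
#'   excluded from the free initial-condition dimensions (e.g.
#'   `c(Speract = 1)`); `NULL` means all nodes free.
#' @param mode `"sample"` (uniform with replacement, `n` draws) or
#'   `"exhaustive"` (every state of the free dimensions exactly once).
#' @param n sample size when `mode = "sample"`.
#' @param seed integer seed used for sampling; required in sample mode.
#' @param burn_in steps evolved before period detection; must exceed the
#'   longest transient (checked).
#' @param max_period largest detectable period (checked).
#' @return an `attractor_catalogue`: a tibble with columns `attractor_id`,
#'   `period`, `count`, `basin_fraction`, `max_transient`, `mean_transient`,
#'   carrying attributes `cycles` (named list of period x N matrices),
#'   `transient_stats` (overall max/mean), `sampling`, and `clamps`.
#' @export
basin_statistics <- function(net, clamps = NULL, ic_policy = NULL,
                             mode = c("sample", "exhaustive"), n = 1e5,
                             seed = NULL, burn_in = 200L, max_period = 128L) {
  mode <- match.arg(mode)
  cn <- compile_network(net)
  cl <- resolve_clamps(net, clamps)
  if (mode == "sample") {
    if (is.null(seed)) stop("sample mode requires a seed", call. = FALSE)
    set.seed(seed)
  }
  S <- make_ics(net, ic_policy, mode, n)
  M <- nrow(S)
  res <- engine_basin(S, cn$tables, cn$reg_idx, cn$weights, cl$idx, cl$val,
                      as.integer(burn_in), as.integer(max_period),
                      encoding_weights(cn$arity))
  period <- res$period
  transient <- res$transient
  canon <- res$canon
  if (any(transient >= burn_in)) {
    stop("burn_in too short: some trajectories were still transient", call. = FALSE)
  }
  key <- paste(period, sprintf("%.0f", canon))
  grp <- match(key, unique(key))
  agg <- tibble::tibble(grp = grp, period = period, canon = canon, transient = transient) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(period = .data$period[1], canon = .data$canon[1],
                     count = dplyr::n(),
                     max_transient = max(.data$transient),
                     mean_transient = mean(.data$transient), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count))
  cycles <- vector("list", nrow(agg))
  for (r in seq_len(nrow(agg))) {
    rep_state <- decode_state(agg$canon[r], cn$arity)
    cyc <- matrix(NA_integer_, nrow = agg$period[r], ncol = cn$n,
                  dimnames = list(NULL, cn$names))
    Sr <- matrix(rep_state, nrow = 1)
    for (q in seq_len(agg$period[r])) {
      cyc[q, ] <- Sr[1, ]
      Sr <- step_batch(cn, Sr, cl$idx, cl$val)
    }
    cycles[[r]] <- cyc
  }
  out <- tibble::tibble(
    attractor_id = seq_len(nrow(agg)),
    period = as.integer(agg$period),
    count = as.integer(agg$count),
    basin_fraction = agg$count / M,
    max_transient = as.integer(agg$max_transient),
    mean_transient = agg$mean_transient
  )
  names(cycles) <- paste0("attractor_", out$attractor_id)
  attr(out, "cycles") <- cycles
  attr(out, "transient_stats") <- list(max = max(transient), mean = mean(transient))
  attr(out, "sampling") <- list(mode = mode, n = M,
                                seed = if (mode == "sample") seed else NA_integer_)
  attr(out, "clamps") <- clamps
  class(out) <- c("attractor_catalogue", class(out))
  out
}

#' @export
print.attractor_catalogue <- function(x, ...) {
  s <- attr(x, "sampling")
  cat(sprintf("<attractor_catalogue> %d attractor(s), %s over %d initial conditions\n",
              nrow(x), s$mode, s$n))
  NextMethod()
}

#' Longest transient recorded in an attractor catalogue
#'
#' @param catalogue an [basin_statistics()] result.
#' @return integer: the maximum, over all covered initial conditions, of the
#'   number of steps taken before the trajectory first lies on its cycle.
#' @export
max_transient <- function(catalogue) {
  ts <- attr(catalogue, "transient_stats")
  if (is.null(ts) || nrow(catalogue) == 0) stop("empty catalogue", call. = FALSE)
  as.integer(ts$max)
}

#' Mean transient recorded in an attractor catalogue
#' @inheritParams max_transient
#' @export
mean_transient <- function(catalogue) {
  ts <- attr(catalogue, "transient_stats")
  if (is.null(ts) || nrow(catalogue) == 0) stop("empty catalogue", call. = FALSE)
  ts$mean
}

#' Effect of rewriting one truth-table row
#'
#' Replaces the output of a single row of one node's table and recomputes a
#' user-supplied observable on the modified network, returning it alongside
#' the unmodified reference. Sweeping this over every row of every table is
#' the robustness scan used to argue that the dynamics are insensitive to
#' single-rule changes.
#'
#' @inheritParams n_nodes
#' @param node name of the node whose table is modified.
#' @param row canonical row index (1-based) into that node's table.
#' @param new_output replacement output value, in `[0, arity)` of `node`.
#' @param observable a function `f(net)` returning any comparable value.
#' @return a list with `reference`, `perturbed`, `changed_rule` (logical:
#'   did the rewrite actually change the table), and the modified network.
#' @export
rule_perturbation_scan <- function(net, node, row, new_output, observable) {
  i <- node_index(net, node)
  tab <- net$tables[[node]]
  if (row < 1 || row > length(tab)) stop("row index out of range", call. = FALSE)
  if (new_output < 0 || new_output >= net$nodes$arity[i]) {
    stop("replacement value outside the node's range", call. = FALSE)
  }
  changed <- tab[row] != new_output
  net2 <- net
  net2$tables[[node]][row] <- as.integer(new_output)
  list(reference = observable(net),
       perturbed = observable(net2),
       changed_rule = changed,
       network = net2)
}
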