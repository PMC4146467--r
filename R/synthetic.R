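#' Random multi-valued logical network
#'
#' Generates a network of the same class as the signaling model: every node
#' is binary or ternary, has a fixed number of regulators drawn uniformly
#' without replacement (self-regulation allowed), and carries a complete
#' truth table with outputs drawn uniformly over the target's value range.
#' Useful as an unbiased test bed for the dynamics engine.
#'
#' @param n_nodes number of nodes.
#' @param arity_choices candidate arities, a subset of `c(2, 3)`.
#' @param in_degree regulators per node: a single value or a `c(min, max)`
#'   range sampled per node.
#' @param seed RNG seed (generation is reproducible given the seed).
#' @return a validated [logical_network].
#' @export
random_network <- function(n_nodes, arity_choices = c(2L, 3L), in_degree = 2L,
                           seed = NULL) {
  stopifnot(n_nodes >= 1, all(arity_choices %in% c(2L, 3L)))
  if (max(in_degree) > n_nodes) stop("in_degree cannot exceed n_nodes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  names_ <- sprintf("N%02d", seq_len(n_nodes))
  arity <- if (length(arity_choices) == 1) {
    rep(as.integer(arity_choices), n_nodes)
  } else {
    as.integer(arity_choices)[sample.int(length(arity_choices), n_nodes, replace = TRUE)]
  }
  k <- if (length(in_degree) == 1) rep(in_degree, n_nodes) else
    sample(seq(in_degree[1], in_degree[2]), n_nodes, replace = TRUE)
  regulators <- lapply(seq_len(n_nodes), function(i) sample(names_, k[i]))
  nodes <- tibble::tibble(name = names_, arity = arity, regulators = regulators,
                          role = "random")
  tables <- lapply(seq_len(n_nodes), function(i) {
    a <- arity[match(regulators[[i]], names_)]
    sample.int(arity[i], prod(a), replace = TRUE) - 1L
  })
  names(tables) <- names_
  logical_network(nodes, tables, metadata = "random_network")
}

#' Random signed regulatory network with a threshold-balance rule
#'
#' Generates a network whose truth tables are not random but derived from a
#' signed wiring, mirroring the construction principle of
#' activator/inhibitor signaling models. Every edge carries a sign; the
#' frozen balance rule is:
#'
#' * score = sum of activator values minus sum of inhibitor values
#'   (a ternary regulator contributes its level 0..2);
#' * binary target: output 1 when score > 0, else 0 (ties are 0);
#' * ternary target: output `min(max(score, 0), 2)`.
#'
#' The rule is monotone: raising any activator (or lowering any inhibitor)
#' never decreases the output. This is a test scaffold for property checks,
#' not a claim about any particular biological table.
#'
#' @inheritParams random_network
#' @param p_inhibitor probability that an edge is inhibitory.
#' @return a validated [logical_network]; edge signs are stored in the
#'   `"signs"` attribute (list of +1/-1 vectors per node).
#' @export
signed_random_network <- function(n_nodes, arity_choices = c(2L, 3L), in_degree = 2L,
                                  p_inhibitor = 0.3, seed = NULL) {
  stopifnot(n_nodes >= 1)
  if (max(in_degree) > n_nodes) stop("in_degree cannot exceed n_nodes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  names_ <- sprintf("N%02d", seq_len(n_nodes))
  arity <- if (length(arity_choices) == 1) {
    rep(as.integer(arity_choices), n_nodes)
  } else {
    as.integer(arity_choices)[sample.int(length(arity_choices), n_nodes, replace = TRUE)]
  }
  k <- if (length(in_degree) == 1) rep(in_degree, n_nodes) else
    sample(seq(in_degree[1], in_degree[2]), n_nodes, replace = TRUE)
  regulators <- lapply(seq_len(n_nodes), function(i) sample(names_, k[i]))
  signs <- lapply(seq_len(n_nodes), function(i) {
    ifelse(stats::runif(k[i]) < p_inhibitor, -1L, 1L)
  })
  nodes <- tibble::tibble(name = names_, arity = arity, regulators = regulators,
                          role = "signed")
  net0 <- structure(list(nodes = nodes, tables = NULL, metadata = ""),
                    class = "logical_network")
  tables <- lapply(seq_len(n_nodes), function(i) {
    grid <- regulator_grid(net0, i)
    score <- as.vector(grid %*% signs[[i]])
    balance_output(score, arity[i])
  })
  names(tables) <- names_
  net <- logical_network(nodes, tables, metadata = "signed_random_network")
  attr(net, "signs") <- stats::setNames(signs, names_)
  net
}

# The frozen threshold-balance rule shared by the signed generator.
balance_output <- function(score, target_arity) {
  if (target_arity == 2L) {
    as.integer(score > 0)
  } else {
    pmin(pmax(as.integer(score), 0L), target_arity - 1L)
  }
}

#' One-hot ring: a network with a known p-cycle
#'
#' A cyclic shift register of `p` binary nodes, each copying its
#' predecessor. Started from the one-hot state (1, 0, ..., 0) it cycles
#' with exact period `p` and zero transient, giving closed-form oracles for
#' attractor detection, periodograms and module-length analysis. For
#' `p = 1` it is a single self-copying node (a fixed point at 1).
#'
#' @param p ring length (the attractor period), `>= 1`.
#' @return a list with `network` (a [logical_network]) and `initial` (the
#'   designated one-hot initial state).
#' @export
ring_fixture <- function(p) {
  stopifnot(p >= 1)
  names_ <- sprintf("R%02d", seq_len(p))
  prev <- names_[c(p, seq_len(p - 1))]
  nodes <- tibble::tibble(name = names_, arity = 2L,
                          regulators = as.list(prev), role = "ring")
  tables <- stats::setNames(rep(list(c(0L, 1L)), p), names_)
  net <- logical_network(nodes, tables, metadata = sprintf("ring_fixture(%d)", p))
  list(network = net, initial = network_state(net, c(1L, rep(0L, p - 1))))
}
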