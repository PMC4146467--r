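#' Multi-valued logical networks
#'
#' A `logical_network` is a set of named nodes, each binary (values 0/1) or
#' ternary (values 0/1/2), together with one complete truth table per node
#' giving the node's value at time `t + 1` as a function of the values of its
#' regulators at time `t`. This is the generalized Boolean formalism used for
#' signaling and gene-regulatory modelling: the state of the whole network is
#' a vector of node values, and dynamics proceed by synchronous application of
#' every table at once (see [step_network()]).
#'
#' Truth tables are stored in a canonical row order: rows enumerate all
#' combinations of regulator values with the *first* regulator varying
#' slowest (most significant digit of a mixed-radix counter). Regulator order
#' is part of the network definition and is preserved by
#' [save_network()]/[load_network()].
#'
#' A node with no regulators is an input: its table is a single constant
#' value, normally overridden by a clamp (see [perturbation()]).
#'
#' @param nodes a data frame with columns `name` (character), `arity`
#'   (integer, 2 or 3), `regulators` (list column of character vectors) and
#'   optionally `role` (free-text label).
#' @param tables named list, one integer vector per node, in canonical row
#'   order; length must equal the product of the node's regulator arities
#'   (1 for an input node).
#' @param metadata free-text provenance string.
#' @return an object of class `logical_network`.
#' @seealso [load_network()], [validate_network()], [random_network()]
#' @examples
#' # one self-copying node: a 1-bit identity network
#' net <- logical_network(
#'   nodes = tibble::tibble(name = "A", arity = 2L,
#'                          regulators = list("A"), role = ""),
#'   tables = list(A = c(0L, 1L))
#' )
#' n_nodes(net)
#' @export
logical_network <- function(nodes, tables, metadata = "") {
  nodes <- tibble::as_tibble(nodes)
  if (!"role" %in% names(nodes)) nodes$role <- ""
  nodes$name <- unname(as.character(nodes$name))
  nodes$arity <- unname(as.integer(nodes$arity))
  nodes$role <- unname(as.character(nodes$role))
  if (!is.list(nodes$regulators)) nodes$regulators <- as.list(nodes$regulators)
  nodes$regulators <- unname(lapply(nodes$regulators, function(r) unname(as.character(r))))
  # canonical node order (locale-independent), so that save/load round-trips
  # and state-vector indexing are stable
  nodes <- nodes[order(nodes$name, method = "radix"), , drop = FALSE]
  tables <- lapply(tables, function(x) as.integer(x))
  net <- structure(
    list(nodes = nodes, tables = tables[nodes$name], metadata = metadata),
    class = "logical_network"
  )
  report <- validate_network(net)
  if (nrow(report) > 0) {
    stop("invalid logical_network:\n", paste0("  - ", report$message, collapse = "\n"),
         call. = FALSE)
  }
  net
}

#' @export
print.logical_network <- function(x, ...) {
  nt <- sum(x$nodes$arity == 3L)
  cat(sprintf("<logical_network> %d nodes (%d binary, %d ternary), %d truth-table rows\n",
              nrow(x$nodes), nrow(x$nodes) - nt, nt, total_table_rows(x)))
  if (nzchar(x$metadata)) cat("metadata:", x$metadata, "\n")
  invisible(x)
}

#' @rdname logical_network
#' @param net a `logical_network`.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname logical_network
#' @export
node_names <- function(net) net$nodes$name

#' @rdname logical_network
#' @export
node_arities <- function(net) stats::setNames(net$nodes$arity, net$nodes$name)

#' Total number of truth-table rows stored in a network
#'
#' Equals the sum over nodes of the product of regulator arities.
#' @inheritParams n_nodes
#' @export
total_table_rows <- function(net) sum(vapply(net$tables, length, integer(1)))

node_index <- function(net, name) {
  i <- match(name, net$nodes$name)
  if (anyNA(i)) stop("unknown node(s): ", paste(name[is.na(i)], collapse = ", "),
                     call. = FALSE)
  i
}

# number of rows the complete table of node i must have
expected_rows <- function(net, i) {
  regs <- net$nodes$regulators[[i]]
  if (length(regs) == 0) return(1L)
  j <- match(regs, net$nodes$name)
  if (anyNA(j)) return(NA_integer_)
  as.integer(prod(net$nodes$arity[j]))
}

#' Validate a logical network
#'
#' Checks every structural invariant and returns a report instead of
#' signalling: each row of the returned tibble is one violation, with the
#' node concerned (if any), a short code and a human-readable message. An
#' empty report means the network is valid.
#'
#' Checks performed: arities are 2 or 3; node names unique; every regulator
#' resolves to a declared node; each table has exactly one row per regulator
#' combination (count = product of regulator arities); all outputs lie in
#' `[0, arity)` of the target.
#'
#' @inheritParams n_nodes
#' @return a tibble with columns `node`, `code`, `message`.
#' @export
validate_network <- function(net) {
  out <- list()
  add <- function(node, code, message) {
    out[[length(out) + 1]] <<- tibble::tibble(node = node, code = code, message = message)
  }
  nm <- net$nodes$name
  if (anyDuplicated(nm)) {
    add(nm[duplicated(nm)][1], "duplicate_node",
        paste0("duplicated node name: ", nm[duplicated(nm)][1]))
  }
  bad_ar <- !net$nodes$arity %in% c(2L, 3L)
  for (i in which(bad_ar)) {
    add(nm[i], "bad_arity",
        sprintf("node %s has arity %d; only 2 or 3 are allowed", nm[i], net$nodes$arity[i]))
  }
  for (i in seq_len(nrow(net$nodes))) {
    regs <- net$nodes$regulators[[i]]
    unknown <- setdiff(regs, nm)
    for (u in unknown) {
      add(nm[i], "unresolved_regulator",
          sprintf("node %s lists regulator %s, which is not a declared node", nm[i], u))
    }
    tab <- net$tables[[nm[i]]]
    if (is.null(tab)) {
      add(nm[i], "missing_table", sprintf("node %s has no truth table", nm[i]))
      next
    }
    exp <- expected_rows(net, i)
    if (!is.na(exp) && length(tab) != exp) {
      # name one offending combination when the table is short
      msg <- sprintf("node %s: table has %d rows, expected %d (product of regulator arities)",
                     nm[i], length(tab), exp)
      add(nm[i], "incomplete_table", msg)
    }
    if (anyNA(tab) || any(tab < 0L | tab >= net$nodes$arity[i])) {
      add(nm[i], "output_out_of_range",
          sprintf("node %s: table outputs outside [0, %d)", nm[i], net$nodes$arity[i]))
    }
  }
  if (length(out) == 0) {
    tibble::tibble(node = character(), code = character(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Validate a state vector against a network
#'
#' @inheritParams n_nodes
#' @param state integer vector, one value per node in network node order.
#' @return the state, as a named integer vector.
#' @export
network_state <- function(net, state) {
  state <- as.integer(state)
  if (length(state) != n_nodes(net)) {
    stop(sprintf("state has length %d; network has %d nodes", length(state), n_nodes(net)),
         call. = FALSE)
  }
  if (anyNA(state) || any(state < 0L | state >= net$nodes$arity)) {
    stop("state values must lie in [0, arity) of each node", call. = FALSE)
  }
  stats::setNames(state, net$nodes$name)
}

# --- compiled form used by the dynamics engine -------------------------------

# Precomputes, per node: integer regulator indices and the mixed-radix row
# weights matching the canonical row order (first regulator most significant).
compile_network <- function(net) {
  nm <- net$nodes$name
  arity <- net$nodes$arity
  reg_idx <- lapply(net$nodes$regulators, function(r) match(r, nm))
  weights <- lapply(reg_idx, function(j) {
    k <- length(j)
    if (k == 0) return(numeric(0))
    a <- arity[j]
    rev(cumprod(rev(c(a[-1], 1))))
  })
  list(names = nm, arity = arity, reg_idx = reg_idx, weights = weights,
       tables = net$tables, n = length(nm))
}

# Enumerate all regulator combinations of node i in canonical row order.
# Returns an integer matrix, one column per regulator.
regulator_grid <- function(net, i) {
  regs <- net$nodes$regulators[[i]]
  if (length(regs) == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  a <- net$nodes$arity[node_index(net, regs)]
  g <- expand.grid(rev(lapply(a, function(k) 0:(k - 1))), KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(g[, rev(seq_along(a)), drop = FALSE])
  colnames(m) <- regs
  storage.mode(m) <- "integer"
  m
}
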