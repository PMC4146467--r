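# Small fixtures and independent oracles used across the suite.

# two binary nodes that copy each other (period-2 swap from (0,1))
two_node_swap <- function() {
  logical_network(
    nodes = tibble::tibble(name = c("A", "B"), arity = 2L,
                           regulators = list("B", "A"), role = ""),
    tables = list(A = c(0L, 1L), B = c(0L, 1L))
  )
}

# every node is an input pinned at a constant value
constant_network <- function(values = c(A = 1L, B = 0L)) {
  logical_network(
    nodes = tibble::tibble(name = names(values), arity = 2L,
                           regulators = rep(list(character(0)), length(values)),
                           role = "input"),
    tables = as.list(values)
  )
}

# Independent single-step oracle: reads the network back through its own
# on-disk dialect and evaluates each node by matching the regulator values
# against the file's rows, without the package's mixed-radix indexing.
oracle_step_from_files <- function(net, state, clamps = NULL) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  save_network(net, dir)
  out <- state
  for (nm in net$nodes$name) {
    lines <- readLines(file.path(dir, paste0(nm, ".txt")))
    regs <- strsplit(sub("^regulators:\\s*", "", grep("^regulators:", lines, value = TRUE)),
                     "\\s+")[[1]]
    regs <- regs[nzchar(regs)]
    body <- lines[!grepl("^[A-Za-z_]+:", lines) & nzchar(lines)]
    rows <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.integer))
    if (length(regs) == 0) {
      out[nm] <- rows[1, 1]
    } else {
      hit <- which(apply(rows[, seq_along(regs), drop = FALSE], 1,
                         function(r) all(r == state[regs])))
      stopifnot(length(hit) == 1)
      out[nm] <- rows[hit, length(regs) + 1]
    }
  }
  if (!is.null(clamps) && nrow(clamps) > 0) out[clamps$node] <- clamps$value
  out
}

# Naive attractor finder: walk, stringify states, detect first repeat.
oracle_find_attractor <- function(net, initial, clamps = NULL, max_steps = 10000) {
  s <- network_state(net, initial)
  keys <- character(0)
  states <- list()
  for (t in 0:max_steps) {
    k <- paste(s, collapse = ",")
    hit <- match(k, keys)
    if (!is.na(hit)) {
      cyc <- do.call(rbind, states[hit:length(states)])
      return(list(transient = hit - 1L, period = nrow(cyc), cycle = cyc))
    }
    keys <- c(keys, k)
    states[[t + 1]] <- s
    s <- step_network(net, s, clamps)
  }
  stop("oracle: no repeat found")
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

lcm_int <- function(v) Reduce(function(a, b) a * b / gcd_int(a, b), v)
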