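test_that("synchronous step matches forced examples and the file-lookup oracle", {
  # 1-node identity: fixed point
  id1 <- logical_network(
    nodes = tibble::tibble(name = "A", arity = 2L, regulators = list("A"), role = ""),
    tables = list(A = c(0L, 1L))
  )
  expect_equal(unname(step_network(id1, 1L)), 1L)

  # mutual copy: (0,1) -> (1,0), all reads before any write
  swap <- two_node_swap()
  expect_equal(unname(step_network(swap, c(0L, 1L))), c(1L, 0L))

  # arbitrary networks: per-node table lookup through the saved files
  for (seed in 1:4) {
    net <- random_network(5, in_degree = c(1L, 3L), seed = seed)
    set.seed(seed + 100)
    s <- network_state(net, vapply(node_arities(net),
                                   function(a) sample.int(a, 1) - 1L, integer(1)))
    expect_equal(step_network(net, s), oracle_step_from_files(net, s))
  }

  # SASP: one step against the independent oracle
  sasp <- sasp_network()
  set.seed(9)
  s <- network_state(sasp, vapply(node_arities(sasp),
                                  function(a) sample.int(a, 1) - 1L, integer(1)))
  expect_equal(step_network(sasp, s), oracle_step_from_files(sasp, s))
})

test_that("simulate_network reproduces step-by-step replay and is deterministic", {
  net <- random_network(3, in_degree = 2L, seed = 5)
  s0 <- network_state(net, c(1L, 0L, 1L))

  # t_max = 0: trajectory is just the initial state
  tr0 <- simulate_network(net, s0, t_max = 0)
  expect_equal(nrow(tr0), 1)
  expect_equal(unlist(tr0[1, -1]), s0)

  tr <- simulate_network(net, s0, t_max = 25)
  s <- s0
  for (t in 1:25) {
    s <- step_network(net, s)
    expect_equal(unlist(tr[t + 1, -1]), s)
  }
  # determinism
  expect_identical(tr, simulate_network(net, s0, t_max = 25))
})

test_that("find_attractor returns minimal periods, closed cycles and exact transients", {
  # fixed point of a constant network, transient 0 from the fixed point
  cn <- constant_network(c(A = 1L, B = 0L))
  r <- find_attractor(cn, c(1L, 0L))
  expect_equal(r$attractor$period, 1)
  expect_equal(r$transient, 0)

  for (p in c(1:9, 12)) {
    rf <- ring_fixture(p)
    r <- find_attractor(rf$network, rf$initial)
    expect_equal(r$attractor$period, p)
    expect_equal(r$transient, 0)
    # closure: one step maps cycle[j] to cycle[j+1], wrapping around
    cyc <- r$attractor$cycle
    for (j in seq_len(p)) {
      nxt <- step_network(rf$network, cyc[j, ])
      expect_equal(unname(nxt), unname(cyc[(j %% p) + 1, ]))
    }
    # minimality: no proper divisor of p maps the cycle onto itself
    divisors <- setdiff(which(p %% seq_len(p) == 0), p)
    for (d in divisors) {
      expect_false(all(cyc == cyc[((seq_len(p) - 1 + d) %% p) + 1, , drop = FALSE]))
    }
  }

  # random networks against the naive walk oracle
  for (seed in 1:6) {
    net <- random_network(4, in_degree = c(1L, 3L), seed = seed)
    set.seed(seed)
    s0 <- network_state(net, vapply(node_arities(net),
                                    function(a) sample.int(a, 1) - 1L, integer(1)))
    got <- find_attractor(net, s0)
    ora <- oracle_find_attractor(net, s0)
    expect_equal(got$attractor$period, ora$period)
    expect_equal(got$transient, ora$transient)
  }
})

test_that("basin statistics: exhaustive mode is exact and sums to the state space", {
  for (seed in c(2, 7, 11)) {
    net <- random_network(5, in_degree = c(1L, 3L), seed = seed)
    space <- prod(node_arities(net))
    cat_ex <- basin_statistics(net, mode = "exhaustive", burn_in = 100, max_period = 64)
    expect_equal(sum(cat_ex$count), space)
    expect_equal(sum(cat_ex$basin_fraction), 1)
    expect_true(all(cat_ex$basin_fraction > 0))

    # per-IC oracle on the same space: periods and transients must agree
    ics <- saspnet:::make_ics(net, NULL, "exhaustive")
    oracle_periods <- integer(0)
    oracle_trans <- integer(0)
    for (k in seq_len(nrow(ics))) {
      o <- oracle_find_attractor(net, ics[k, ])
      oracle_periods[k] <- o$period
      oracle_trans[k] <- o$transient
    }
    expect_equal(max_transient(cat_ex), max(oracle_trans))
    expect_equal(sort(unique(cat_ex$period)), sort(unique(oracle_periods)))
    # basin sizes by period agree with the oracle census
    expect_equal(
      tapply(cat_ex$count, cat_ex$period, sum)[as.character(sort(unique(cat_ex$period)))],
      table(oracle_periods)[as.character(sort(unique(oracle_periods)))],
      ignore_attr = TRUE
    )
  }
})

test_that("sampled basin fractions converge to exhaustive fractions", {
  # network with <= 2^14 states; 3-binomial-SE agreement at n = 1e4
  net <- random_network(7, in_degree = 2L, seed = 3)
  ex <- basin_statistics(net, mode = "exhaustive", burn_in = 100, max_period = 64)
  n <- 1e4
  sa <- basin_statistics(net, mode = "sample", n = n, seed = 21,
                         burn_in = 100, max_period = 64)
  for (r in seq_len(nrow(ex))) {
    p <- ex$basin_fraction[r]
    hit <- sa$period == ex$period[r] &
      vapply(seq_len(nrow(sa)), function(j) {
        identical(attr(sa, "cycles")[[j]][1, ], attr(ex, "cycles")[[r]][1, ])
      }, logical(1))
    phat <- if (any(hit)) sa$basin_fraction[hit] else 0
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(phat - p), max(3 * se, 1e-12))
  }
})

test_that("identical settings reproduce identical catalogues and series", {
  net <- sasp_network()
  a <- basin_statistics(net, ic_policy = speract_policy(), n = 2000, seed = 4)
  b <- basin_statistics(net, ic_policy = speract_policy(), n = 2000, seed = 4)
  expect_identical(tidy(a), tidy(b))
  s1 <- ensemble_average(net, n_ic = 1000, seed = 8, t_max = 60, transient = 50,
                         ic_policy = speract_policy())
  s2 <- ensemble_average(net, n_ic = 1000, seed = 8, t_max = 60, transient = 50,
                         ic_policy = speract_policy())
  expect_identical(s1$value, s2$value)
})

test_that("max_transient matches a brute-force maximum and errors on empty input", {
  rf <- ring_fixture(4)
  cat_ <- basin_statistics(rf$network, mode = "exhaustive", burn_in = 50, max_period = 16)
  ics <- saspnet:::make_ics(rf$network, NULL, "exhaustive")
  brute <- max(vapply(seq_len(nrow(ics)), function(k) {
    oracle_find_attractor(rf$network, ics[k, ])$transient
  }, integer(1)))
  expect_equal(max_transient(cat_), brute)

  empty <- cat_[0, ]
  attr(empty, "transient_stats") <- NULL
  expect_error(max_transient(empty), "empty")
})

test_that("single-row rule rewrites behave as a robustness scan", {
  net <- random_network(3, in_degree = 2L, seed = 13)
  observable <- function(n) {
    cat_ <- basin_statistics(n, mode = "exhaustive", burn_in = 60, max_period = 32)
    list(periods = sort(cat_$period), fractions = sort(cat_$basin_fraction))
  }
  # rewriting a row to its current output is a no-op
  cur <- net$tables[[1]][3]
  r0 <- rule_perturbation_scan(net, node_names(net)[1], 3, cur, observable)
  expect_false(r0$changed_rule)
  expect_identical(r0$reference, r0$perturbed)

  # sweep all single-row flips of node 1; each perturbed observable must
  # equal an independent recomputation on the manually modified network
  nm <- node_names(net)[1]
  ar <- node_arities(net)[nm]
  for (row in seq_along(net$tables[[nm]])) {
    new_out <- (net$tables[[nm]][row] + 1L) %% ar
    r <- rule_perturbation_scan(net, nm, row, new_out, observable)
    manual <- net
    manual$tables[[nm]][row] <- new_out
    expect_identical(r$perturbed, observable(manual))
  }
  expect_error(rule_perturbation_scan(net, nm, 1, 9L, observable), "range")
})
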