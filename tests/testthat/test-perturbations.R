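test_that("knockout and activation clamp nodes from the first update onward", {
  net <- sasp_network()
  set.seed(2)
  s0 <- saspnet:::make_ics(net, speract_policy(), "sample", 1)[1, ]
  s0["HCN"] <- 1L  # the IC may hold any value; the clamp takes over at t >= 1
  tr <- simulate_network(net, s0, t_max = 30, clamps = knockout("HCN"))
  expect_true(all(tr$HCN[-1] == 0))

  tr2 <- simulate_network(net, s0, t_max = 30,
                          clamps = constitutive_activation("CaKC"))
  expect_true(all(tr2$CaKC[-1] == 1))

  expect_error(simulate_network(net, s0, 5, clamps = knockout("NotANode")),
               "unknown node")
})

test_that("clamping is idempotent, commutes, and ignores the clamped table", {
  net <- sasp_network()
  set.seed(3)
  s0 <- saspnet:::make_ics(net, speract_policy(), "sample", 1)[1, ]

  ab <- combine_perturbations(knockout("HCN"), constitutive_activation("CaKC"))
  ba <- combine_perturbations(constitutive_activation("CaKC"), knockout("HCN"))
  tr_ab <- simulate_network(net, s0, 40, clamps = ab)
  tr_ba <- simulate_network(net, s0, 40, clamps = ba)
  expect_equal(dplyr::select(tr_ab, -t), dplyr::select(tr_ba, -t),
               ignore_attr = TRUE)

  # conflicting clamp values are rejected
  expect_error(combine_perturbations(knockout("HCN"), constitutive_activation("HCN")),
               "conflicting")

  # a clamped node's table is never consulted: replacing it wholesale with
  # garbage must not change the clamped dynamics
  garbage <- net
  garbage$tables$HCN[] <- 1L - garbage$tables$HCN
  tr1 <- simulate_network(net, s0, 40, clamps = knockout("HCN"))
  tr2 <- simulate_network(garbage, s0, 40, clamps = knockout("HCN"))
  expect_equal(tr1, tr2, ignore_attr = TRUE)
})

test_that("clamping an out-edge-free node leaves the rest untouched", {
  # B copies A; C copies A; A copies itself. C has no out-edges.
  net <- logical_network(
    nodes = tibble::tibble(name = c("A", "B", "C"), arity = 2L,
                           regulators = list("A", "A", "A"), role = ""),
    tables = list(A = c(0L, 1L), B = c(0L, 1L), C = c(0L, 1L))
  )
  s0 <- c(1L, 0L, 0L)
  free <- simulate_network(net, s0, 15)
  cut <- simulate_network(net, s0, 15, clamps = knockout("C"))
  expect_equal(free[, c("A", "B")], cut[, c("A", "B")], ignore_attr = TRUE)
  # whereas clamping a node WITH out-edges does propagate
  cut_a <- simulate_network(net, s0, 15, clamps = knockout("A"))
  expect_false(isTRUE(all.equal(free$B, cut_a$B)))
})

test_that("the intervention suite enumerates the 12 studied scenarios", {
  suite <- scenario_suite()
  expect_length(suite, 12)
  expect_equal(names(suite)[1], "WT")
  expect_equal(nrow(suite$WT), 0)

  sig <- vapply(suite, function(s) {
    if (nrow(s) == 0) return("")
    paste(sort(paste0(s$node, "=", s$value)), collapse = ",")
  }, character(1))
  expect_setequal(unname(sig), c(
    "", "HCN=0", "CaCC=0", "CaKC=0", "CaKC=1",
    "CaCC=0,HCN=0", "CaKC=0,HCN=0", "CaCC=0,CaKC=0",
    "CaKC=1,HCN=0", "CaCC=0,CaKC=1",
    "CaCC=0,CaKC=0,HCN=0", "CaCC=0,CaKC=1,HCN=0"
  ))

  # triple scenario 1: all three clamped closed; scenario 2: CaKC open
  s1 <- suite[["HCN- CaCC- CaKC- (scenario 1)"]]
  expect_true(all(s1$value == 0) && nrow(s1) == 3)
  s2 <- suite[["HCN- CaCC- CaKC+ (scenario 2)"]]
  expect_equal(stats::setNames(s2$value, s2$node)[c("HCN", "CaCC", "CaKC")],
               c(HCN = 0L, CaCC = 0L, CaKC = 1L))
  expect_equal(attr(s1, "scenario"), 1L)
  expect_equal(attr(s2, "scenario"), 2L)
})
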