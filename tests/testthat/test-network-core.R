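test_that("save/load round-trips networks bit-identically", {
  dir <- withr::local_tempdir()
  # identity one-node network
  net1 <- logical_network(
    nodes = tibble::tibble(name = "A", arity = 2L, regulators = list("A"), role = ""),
    tables = list(A = c(0L, 1L))
  )
  save_network(net1, file.path(dir, "id"))
  re1 <- load_network(file.path(dir, "id"), metadata = net1$metadata)
  expect_equal(re1$nodes, net1$nodes)
  expect_equal(re1$tables, net1$tables)

  # random 5-node synthetic network, mixed arities, field-by-field equality
  net2 <- random_network(5, arity_choices = c(2L, 3L), in_degree = 2L, seed = 42)
  save_network(net2, file.path(dir, "rand"))
  re2 <- load_network(file.path(dir, "rand"), metadata = net2$metadata)
  expect_equal(re2$nodes$name, net2$nodes$name)
  expect_equal(re2$nodes$arity, net2$nodes$arity)   # ternary arities preserved
  expect_equal(re2$nodes$regulators, net2$nodes$regulators)
  expect_equal(re2$tables, net2$tables)

  # SASP fixture round-trips too
  sasp <- sasp_network()
  save_network(sasp, file.path(dir, "sasp"))
  re3 <- load_network(file.path(dir, "sasp"), metadata = sasp$metadata)
  expect_equal(re3$tables, sasp$tables)
  expect_equal(re3$nodes, sasp$nodes)
})

test_that("loader reports structural defects precisely", {
  dir <- withr::local_tempdir()
  net <- two_node_swap()
  save_network(net, dir)

  # unresolved regulator: drop B's file
  file.remove(file.path(dir, "B.txt"))
  expect_error(load_network(dir), "no node file.*B")

  # incomplete table: remove one row, error names the missing combination
  save_network(net, dir)
  lines <- readLines(file.path(dir, "A.txt"))
  writeLines(lines[-length(lines)], file.path(dir, "A.txt"))
  expect_error(load_network(dir), "missing combination \\(1\\)")

  # duplicated row
  writeLines(c(lines, lines[length(lines)]), file.path(dir, "A.txt"))
  expect_error(load_network(dir), "duplicated regulator combination")

  # out-of-range output, error carries file and line
  save_network(net, dir)
  lines2 <- readLines(file.path(dir, "B.txt"))
  lines2[length(lines2)] <- "1 7"
  writeLines(lines2, file.path(dir, "B.txt"))
  expect_error(load_network(dir), "B\\.txt.*out of range.*line 2")
})

test_that("validate_network reports each violated invariant", {
  net <- two_node_swap()
  expect_equal(nrow(validate_network(net)), 0)

  # truncated table -> completeness violation
  broken <- net
  broken$tables$A <- broken$tables$A[-2]
  rep1 <- validate_network(broken)
  expect_true(any(rep1$code == "incomplete_table" & rep1$node == "A"))

  # unresolved regulator reference
  broken2 <- net
  broken2$nodes$regulators[[1]] <- "Z"
  rep2 <- validate_network(broken2)
  expect_true(any(rep2$code == "unresolved_regulator"))

  # out-of-range output
  broken3 <- net
  broken3$tables$B[1] <- 5L
  rep3 <- validate_network(broken3)
  expect_true(any(rep3$code == "output_out_of_range" & rep3$node == "B"))
})

test_that("stored rows always equal the sum of regulator-arity products", {
  for (seed in 1:5) {
    net <- random_network(6, in_degree = c(1L, 3L), seed = seed)
    expected <- sum(vapply(seq_len(n_nodes(net)), function(i) {
      regs <- net$nodes$regulators[[i]]
      prod(node_arities(net)[regs])
    }, numeric(1)))
    expect_equal(total_table_rows(net), expected)
  }
})

test_that("the bundled SASP fixture has the documented structure", {
  net <- sasp_network()
  expect_equal(n_nodes(net), 21)
  expect_setequal(net$nodes$name[net$nodes$arity == 3L], c("V", "LVA", "HVA", "Ca"))
  expect_equal(length(net$tables$Ca), 432)
  # the six canonical calcium regulators are all present, in their roles
  expect_true(all(c("LVA", "HVA", "cAMPCC", "CaP", "NCE", "Ca") %in%
                    net$nodes$regulators[[which(net$nodes$name == "Ca")]]))
  expect_equal(nrow(validate_network(net)), 0)
})

test_that("fixture files agree with the programmatic reconstruction", {
  expect_equal(sasp_network()$tables, sasp_reconstruction()$tables)
  expect_equal(sasp_network()$nodes, sasp_reconstruction()$nodes)
})
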