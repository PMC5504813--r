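test_that("numeric, categorical and record degrees match the worked examples", {
  age <- demo$schemas$age; sex <- demo$schemas$sex; zip <- demo$schemas$zipcode
  expect_equal(round(degree_numeric(gvi(35, 66), age), 2), 0.31)
  expect_equal(round(degree_numeric(gvi(22071, 55324), zip), 2), 0.33)
  expect_equal(degree_numeric(gvi(37, 37), age), 0)
  expect_equal(degree_categorical(generalize_value("F", sex, 1), sex), 1)
  expect_equal(degree_categorical(generalize_value("F", sex, 0), sex), 0)
  # a 9-leaf tree with a 3-leaf internal node: (3-1)/(9-1)
  tree <- taxonomy_tree(list(label = "root", children = list(
    list(label = "a", children = lapply(1:3, function(i) list(label = paste0("a", i)))),
    list(label = "b", children = lapply(1:6, function(i) list(label = paste0("b", i)))))))
  nine <- attribute_schema("x", "quasi_identifier", "categorical", taxonomy = tree)
  a_node <- anonceil:::gv_node(match("a", tree$labels), "a")
  expect_equal(degree_categorical(a_node, nine), 0.25)

  sig <- list(age = gvi(35, 66), sex = generalize_value("F", sex, 1),
              zipcode = gvi(22071, 55324))
  expect_equal(round(degree_record(sig, demo$schemas), 2), 0.55)
  sig1 <- list(age = gvi(35, 37), sex = generalize_value("F", sex, 0),
               zipcode = gvi(22071, 23061))
  expect_equal(round(degree_record(sig1, demo$schemas), 2), 0.01)
  sig2 <- list(age = gvi(61, 66), sex = generalize_value("M", sex, 0),
               zipcode = gvi(55099, 55324))
  expect_equal(round(degree_record(sig2, demo$schemas), 2), 0.02)
  expect_error(degree_record(sig[1:2], demo$schemas), "quasi-identifiers")
})

test_that("apply_node forms the expected classes and partitions the table", {
  cls <- suppressMessages(apply_node(demo$table, c(2, 0, 3), demo$schemas))
  expect_length(cls, 2)
  sigs <- vapply(cls, function(cl)
    paste(vapply(cl$signature, format, ""), collapse = ","), "")
  expect_setequal(sigs, c("[35-37],F,[22071-23061]", "[61-66],M,[55099-55324]"))
  expect_equal(vapply(cls, function(cl) nrow(cl$members), numeric(1)), c(3, 4))

  bottom <- suppressMessages(apply_node(demo$table, c(0, 0, 0), demo$schemas))
  expect_length(bottom, 7)  # all raw QI tuples are distinct
  top <- suppressMessages(apply_node(demo$table, c(4, 1, 4), demo$schemas))
  expect_length(top, 1)

  # partition property: member rows across classes are exactly the input rows
  for (cls_i in list(cls, bottom, top)) {
    rows <- sort(unlist(lapply(cls_i, function(cl) cl$members$row)))
    expect_equal(rows, seq_len(nrow(demo$table)))
  }
})

test_that("tightening collapses numeric signatures without changing membership", {
  loose <- suppressMessages(apply_node(demo$table, c(2, 0, 3), demo$schemas,
                                       tighten = FALSE))
  tight <- suppressMessages(apply_node(demo$table, c(2, 0, 3), demo$schemas))
  expect_equal(lapply(loose, function(cl) cl$members$row),
               lapply(tight, function(cl) cl$members$row))
  expect_equal(format(loose[[1]]$signature$age), "[30-39]")
  expect_equal(format(tight[[1]]$signature$age), "[35-37]")
})

test_that("h-ceiling feasibility follows the worked example", {
  expect_true(suppressMessages(
    node_feasible_h(demo$table, c(2, 0, 3), demo$schemas, h = 0.02)))
  expect_false(suppressMessages(
    node_feasible_h(demo$table, c(4, 1, 4), demo$schemas, h = 0.02)))
  expect_true(suppressMessages(
    node_feasible_h(demo$table, c(0, 0, 0), demo$schemas, h = 0)))
})

test_that("record degree is monotone along lattice edges", {
  nodes <- anonceil:::lattice_nodes(demo$schemas)
  max_deg <- function(nd) {
    cls <- suppressMessages(apply_node(demo$table, nd, demo$schemas))
    max(vapply(cls, function(cl) degree_record(cl$signature, demo$schemas),
               numeric(1)))
  }
  degs <- apply(nodes, 1, max_deg)
  key <- apply(nodes, 1, paste, collapse = ",")
  for (r in seq_len(nrow(nodes))) {
    nd <- nodes[r, ]
    for (i in seq_along(nd)) {
      child <- nd; child[i] <- child[i] - 1L
      if (child[i] < 0) next
      j <- match(paste(child, collapse = ","), key)
      expect_gte(degs[r] + 1e-12, degs[j])
    }
  }
})

test_that("pruned lattice equals brute-force feasibility filtering", {
  for (h in c(0.02, 0.1, 0.5, 1)) {
    lat <- suppressMessages(build_lattice(demo$schemas, demo$table, h = h))
    nodes <- anonceil:::lattice_nodes(demo$schemas)
    brute <- nodes[apply(nodes, 1, function(nd)
      suppressMessages(node_feasible_h(demo$table, nd, demo$schemas, h))), ,
      drop = FALSE]
    expect_setequal(apply(lat, 1, paste, collapse = ","),
                    apply(brute, 1, paste, collapse = ","))
  }
  # full lattice size = product of level counts
  expect_equal(nrow(build_lattice(demo$schemas, demo$table)), 5 * 2 * 5)
})
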