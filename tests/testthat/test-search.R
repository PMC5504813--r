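test_that("the demo table anonymizes to the two-class published result", {
  hits <- 0
  for (s in 1:5) {
    res <- suppressMessages(anonymize(demo$table, demo$schemas, k = 4,
                                      h = 0.02, seed = s))
    expect_lte(max(vapply(res$classes, function(cl)
      degree_record(cl$signature, demo$schemas), numeric(1))), 0.02 + 1e-9)
    expect_gte(min(vapply(res$classes, function(cl) nrow(cl$members),
                          numeric(1))), 4)
    if (length(res$classes) != 2) next  # the rare unconcealable draw
    hits <- hits + 1
    sigs <- vapply(res$classes, function(cl)
      paste(vapply(cl$signature, format, ""), collapse = ","), "")
    expect_setequal(sigs,
                    c("[35-37],F,[22071-23061]", "[61-66],M,[55099-55324]"))
    expect_equal(sum(res$ledger$count), 1)
    expect_equal(nrow(res$table), 8)
    expect_equal(res$catalog$entries$class_ids, "1;2")
    expect_equal(res$catalog$entries$count, 1L)
    # three real records of either concealable value: counterfeit odds 25%
    scale <- anonceil:::catalog_scale_fn(res$classes, res$catalog)
    expect_equal(scale(1, res$catalog$entries$sensitive), 0.75)
  }
  expect_gte(hits, 1)
})

test_that("the winner attains the exhaustive minimum RCE and pruning is sound", {
  for (seed in c(1, 2)) {
    res <- suppressMessages(anonymize(demo$table, demo$schemas, k = 4,
                                      h = 0.02, seed = seed))
    brute <- suppressMessages(
      brute_force_scores(demo$table, demo$schemas, k = 4, h = 0.02,
                         seed = seed))
    expect_equal(res$metrics$rce, min(brute$rce, na.rm = TRUE))
    lat <- suppressMessages(build_lattice(demo$schemas, demo$table, h = 0.02))
    expect_setequal(apply(lat, 1, paste, collapse = ","),
                    brute$node[brute$feasible])
  }
})

test_that("search optimality holds on a second, synthetic instance", {
  spec <- default_ehr_spec(30, seed = 17)
  tab <- generate_table(spec)
  sch <- synthetic_schemas(spec)
  res <- anonymize(tab, sch, k = 3, h = 0.4, seed = 17)
  brute <- brute_force_scores(tab, sch, k = 3, h = 0.4, seed = 17)
  expect_equal(res$metrics$rce, min(brute$rce, na.rm = TRUE))
})

test_that("anonymize is deterministic for fixed inputs", {
  a <- suppressMessages(anonymize(demo$table, demo$schemas, k = 4, h = 0.02,
                                  seed = 9))
  b <- suppressMessages(anonymize(demo$table, demo$schemas, k = 4, h = 0.02,
                                  seed = 9))
  expect_identical(a$table, b$table)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$catalog, b$catalog)
})

test_that("h search mode reports the winner's maximum degree as h_used", {
  res <- suppressMessages(anonymize(demo$table, demo$schemas, k = 2, h = NULL,
                                    seed = 1))
  max_deg <- max(vapply(res$classes, function(cl)
    degree_record(cl$signature, demo$schemas), numeric(1)))
  expect_equal(res$h_used, max_deg)
})

test_that("an impossible instance raises the no-feasible-anonymization error", {
  # a single record under h = 0: its class needs a counterfeit, but there is
  # no other class whose real records could conceal it
  sch <- schema_set(list(
    x = attribute_schema("x", "quasi_identifier", "numeric",
                         domain = c(0, 9), level_widths = c(1, 10)),
    s = attribute_schema("s", "sensitive", "categorical")))
  tab <- data.frame(x = 0, s = "A", stringsAsFactors = FALSE)
  expect_error(anonymize(tab, sch, k = 2, h = 0, seed = 1),
               "no feasible anonymization")
})

test_that("duplicated records need no generalization or counterfeits", {
  tab <- demo$table[rep(1, 4), ]
  res <- suppressMessages(anonymize(tab, demo$schemas, k = 2, h = 1, seed = 1))
  expect_equal(sum(res$ledger$count), 0)
  expect_equal(res$metrics$rce, 0)
  expect_equal(sum(res$node), 0)
})
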