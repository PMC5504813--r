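#' Anonymize a table under k-anonymity and an h-ceiling
#'
#' Bottom-up search of the full-domain generalization lattice. Every node
#' satisfying the h-ceiling (pruning by degree monotonicity) is evaluated:
#' records are generalized and grouped, classes short of `k` members receive
#' counterfeit records, and the counterfeit counts are grouped into a
#' privacy-safe catalog. Nodes whose catalog cannot be made safe are
#' discarded. Among the remaining candidates the result minimizing RCE is
#' returned (ties broken by LM, then total generalization level, then the
#' lexicographic node vector). When `h` is `NULL` the whole lattice is
#' searched and `h_used` reports the maximum record degree of the winner.
#'
#' Counterfeit sampling uses an independent substream per lattice node keyed
#' by the node vector, so results do not depend on evaluation order.
#'
#' @param table data.frame conforming to `schemas`; identifier columns are
#'   dropped.
#' @param schemas a `schema_set`.
#' @param k anonymity parameter, `k >= 2`.
#' @param h ceiling on the record generalization degree in `[0, 1]`, or
#'   `NULL` to search for the best node over the whole lattice.
#' @param strategy sensitive-value sampling for counterfeits, `"empirical"`
#'   (default) or `"uniform"`.
#' @param seed integer master seed for counterfeit sampling.
#' @param tighten collapse numeric class signatures to member min/max.
#' @return an object of class `anon_result` with fields `node`, `classes`,
#'   `table` (published rows incl. provenance), `catalog`, `ledger`,
#'   `metrics` (`lm`, `dm`, `rce`), `h_used`, `k`, `seed`, `schemas`.
#' @examples
#' fx <- demo_ehr_fixture()
#' res <- anonymize(fx$table, fx$schemas, k = 4, h = 0.02, seed = 1)
#' res$metrics$lm
#' @export
anonymize <- function(table, schemas, k, h = NULL,
                      strategy = c("empirical", "uniform"),
                      seed = 1L, tighten = TRUE) {
  strategy <- match.arg(strategy)
  stopifnot(nrow(table) > 0, k >= 2)
  if (!is.null(h)) stopifnot(h >= 0, h <= 1)
  prep <- prepare_table(table, schemas)
  codes <- precompute_codes(prep$data, schemas, prep$qi)
  nodes <- lattice_nodes(schemas)
  n_real <- nrow(prep$data)

  best <- NULL
  infeasible <- list()
  for (r in seq_len(nrow(nodes))) {
    nd <- nodes[r, ]
    if (any(vapply(infeasible, function(b) all(nd >= b), logical(1)))) next
    part <- partition_node(prep, codes, nd, schemas, tighten)
    max_deg <- max(part$rec_deg)
    if (!is.null(h) && max_deg > h + 1e-9) {
      infeasible[[length(infeasible) + 1L]] <- nd
      next
    }
    deficit <- sum(pmax(0L, k - part$sizes))
    if (deficit > n_real) next  # more counterfeits than real records: no
                                # pledging can conceal them, catalog is null
    classes <- classes_from_partition(prep, part, schemas)
    ins <- insert_counterfeits(classes, k, schemas, strategy = strategy,
                               seed = node_seed(seed, nd))
    catalog <- group_catalog(ins$classes)
    if (is.null(catalog)) next
    met <- list(lm = loss_metric(ins$classes, schemas),
                dm = discernibility_metric(ins$classes),
                rce = reconstruction_error(ins$classes, schemas, catalog))
    cand <- list(node = nd, classes = ins$classes, ledger = ins$ledger,
                 catalog = catalog, metrics = met, max_deg = max_deg)
    if (is.null(best) || better_candidate(cand, best)) best <- cand
  }
  if (is.null(best))
    stop("no feasible anonymization: no lattice node yields a safe catalog; ",
         "try a larger h or a different k", call. = FALSE)
  result <- structure(
    list(node = best$node, classes = best$classes,
         table = published_table(best$classes, schemas),
         catalog = best$catalog, ledger = best$ledger,
         metrics = best$metrics,
         h_used = if (is.null(h)) best$max_deg else h,
         k = k, seed = seed, strategy = strategy, tighten = tighten,
         schemas = schemas),
    class = "anon_result")
  min_size <- min(vapply(result$classes, function(cl) nrow(cl$members),
                         numeric(1)))
  stopifnot(min_size >= k, best$max_deg <= result$h_used + 1e-9)
  result
}

# utility ordering: ascending RCE, then LM, then total level, then lexicographic
better_candidate <- function(a, b) {
  if (a$metrics$rce != b$metrics$rce) return(a$metrics$rce < b$metrics$rce)
  if (a$metrics$lm != b$metrics$lm) return(a$metrics$lm < b$metrics$lm)
  if (sum(a$node) != sum(b$node)) return(sum(a$node) < sum(b$node))
  cmp <- a$node - b$node
  nz <- which(cmp != 0)
  length(nz) > 0 && cmp[nz[1]] < 0
}

# independent per-node substream seed, kept below 2^31
node_seed <- function(seed, node) {
  hash <- 0
  for (lv in node) hash <- (hash * 131 + lv + 1) %% 1009
  as.integer((abs(seed) %% 2000000) * 1021 + hash)
}

#' @export
print.anon_result <- function(x, ...) {
  counterfeits <- sum(x$ledger$count)
  cat("<anon_result>\n")
  cat(sprintf("  node: (%s)   k = %d, h = %.4g\n",
              paste(x$node, collapse = ", "), x$k, x$h_used))
  cat(sprintf("  %d classes, %d published rows (%d counterfeit)\n",
              length(x$classes), nrow(x$table), counterfeits))
  cat(sprintf("  LM = %.4f  DM = %d  RCE = %.4f\n",
              x$metrics$lm, x$metrics$dm, x$metrics$rce))
  if (nrow(x$catalog$entries)) {
    cat("  catalog:\n")
    print(x$catalog$entries, row.names = FALSE)
  } else cat("  catalog: empty\n")
  invisible(x)
}

#' Plain k-anonymity baseline (generalization only)
#'
#' Same lattice machinery with no counterfeits and no catalog: a node is
#' feasible iff every equivalence class has at least `k` members, and the
#' feasible node minimizing LM is returned. This is the conventional
#' full-domain algorithm the ceiling method is compared against.
#'
#' @inheritParams anonymize
#' @return an `anon_result` with an empty ledger and catalog; `h_used` is the
#'   maximum record degree of the chosen node.
#' @export
baseline_k_anonymize <- function(table, schemas, k, tighten = TRUE) {
  stopifnot(nrow(table) > 0, k >= 2)
  prep <- prepare_table(table, schemas)
  codes <- precompute_codes(prep$data, schemas, prep$qi)
  nodes <- lattice_nodes(schemas)
  best <- NULL
  for (r in seq_len(nrow(nodes))) {
    nd <- nodes[r, ]
    part <- partition_node(prep, codes, nd, schemas, tighten)
    if (min(part$sizes) < k) next
    lm <- sum(part$sizes * part$rec_deg) / sum(part$sizes)
    if (is.null(best) || lm < best$lm - 1e-12 ||
        (abs(lm - best$lm) <= 1e-12 && sum(nd) < sum(best$node))) {
      best <- list(node = nd, part = part, lm = lm)
    }
  }
  if (is.null(best))
    stop("no k-anonymous generalization exists for this table", call. = FALSE)
  classes <- classes_from_partition(prep, best$part, schemas)
  catalog <- structure(list(groups = list(), entries = empty_entries()),
                       class = "counterfeit_catalog")
  structure(
    list(node = best$node, classes = classes,
         table = published_table(classes, schemas),
         catalog = catalog,
         ledger = data.frame(class_id = integer(0), sensitive = character(0),
                             count = integer(0)),
         metrics = list(lm = loss_metric(classes, schemas),
                        dm = discernibility_metric(classes),
                        rce = reconstruction_error(classes, schemas)),
         h_used = max(best$part$rec_deg),
         k = k, seed = NA_integer_, strategy = "none", tighten = tighten,
         schemas = schemas),
    class = "anon_result")
}

#' Write the published anonymized table as CSV
#'
#' Provenance and source-row bookkeeping are internal and never written.
#'
#' @param result an `anon_result`.
#' @param path output file path.
#' @export
write_anonymized <- function(result, path) {
  stopifnot(inherits(result, "anon_result"))
  out <- result$table[, setdiff(names(result$table),
                                c("provenance", "source_row"))]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the metrics report as JSON
#'
#' @param result an `anon_result`.
#' @param path output file path.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "anon_result"))
  rep <- list(lm = result$metrics$lm, dm = result$metrics$dm,
              rce = result$metrics$rce,
              counterfeit_total = sum(result$ledger$count),
              node = as.integer(result$node),
              h_used = result$h_used, k = result$k)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
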