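# shared fixtures and independent oracles

gvi <- function(lo, hi) anonceil:::gv_interval(lo, hi)

demo <- demo_ehr_fixture()

# the 0.02-ceiled two-class partition of the demo table, with the known
# Diabetes counterfeit added to class 1 (the published 8-row table)
make_ceiled_demo_classes <- function() {
  cls <- suppressMessages(apply_node(demo$table, c(2, 0, 3), demo$schemas))
  cls[[1]]$members <- rbind(
    cls[[1]]$members,
    data.frame(row = NA_integer_, sensitive = "Diabetes",
               provenance = "counterfeit", stringsAsFactors = FALSE))
  cls
}

# minimal synthetic classes carrying only tallies (for catalog logic tests):
# o and p are lists of named integer vectors per class
make_classes_from_tallies <- function(o, p) {
  lapply(seq_along(o), function(t) {
    sens <- c(rep(names(o[[t]]), o[[t]]), rep(names(p[[t]]), p[[t]]))
    prov <- c(rep("real", sum(o[[t]])), rep("counterfeit", sum(p[[t]])))
    structure(list(class_id = t,
                   signature = list(x = gvi(t, t)),
                   members = data.frame(row = ifelse(prov == "real",
                                                     seq_along(sens), NA),
                                        sensitive = sens, provenance = prov,
                                        stringsAsFactors = FALSE)),
              class = "equivalence_class")
  })
}

# Brute-force adversary elimination: for each catalog entry (group G, value s,
# count c), enumerate every assignment of counterfeit counts q_t(s) over the
# classes of G with 0 <= q_t <= (rows of s in class t) and sum q_t = c.
# Returns TRUE iff the true assignment is consistent and, for every class in
# the group, some consistent assignment places no counterfeit of s there --
# i.e. counterfeit positions are never uniquely identifiable.
adversary_cannot_identify <- function(classes, catalog) {
  for (e in seq_len(nrow(catalog$entries))) {
    g <- as.integer(strsplit(catalog$entries$class_ids[e], ";")[[1]])
    s <- catalog$entries$sensitive[e]
    cc <- catalog$entries$count[e]
    n_s <- vapply(g, function(t) {
      sum(classes[[t]]$members$sensitive == s)
    }, integer(1))
    true_q <- vapply(g, function(t) {
      sum(classes[[t]]$members$sensitive == s &
            classes[[t]]$members$provenance == "counterfeit")
    }, integer(1))
    grid <- expand.grid(lapply(n_s, function(m) 0:m))
    grid <- grid[rowSums(grid) == cc, , drop = FALSE]
    if (!nrow(grid)) return(FALSE)
    truth_seen <- any(apply(grid, 1, function(q) all(q == true_q)))
    if (!truth_seen) return(FALSE)
    for (i in seq_along(g)) {
      if (!any(grid[[i]] == 0)) return(FALSE)  # class i is implicated
    }
  }
  TRUE
}

# exhaustive search over all partitions of classes into groups: does ANY
# grouping conceal all counterfeits (every group safe)? Independent check
# that a NULL catalog really is unattainable.
any_safe_grouping_exists <- function(classes) {
  tal <- class_tallies(classes)
  n <- length(tal)
  parts <- set_partitions(n)
  for (pt in parts) {
    ok <- all(vapply(pt, function(g) is_safe_group(tal[g]), logical(1)))
    if (ok) return(TRUE)
  }
  FALSE
}

# all set partitions of 1..n (n small)
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (pt in set_partitions(n - 1L)) {
    for (i in seq_along(pt)) {
      new <- pt
      new[[i]] <- c(new[[i]], n)
      out[[length(out) + 1L]] <- new
    }
    out[[length(out) + 1L]] <- c(pt, list(n))
  }
  out
}

# independent exhaustive re-scoring of every lattice node (no pruning, no
# search logic): returns data.frame of node label, feasibility and rce
brute_force_scores <- function(table, schemas, k, h, seed) {
  nodes <- anonceil:::lattice_nodes(schemas)
  rows <- lapply(seq_len(nrow(nodes)), function(r) {
    nd <- nodes[r, ]
    cls <- suppressMessages(apply_node(table, nd, schemas))
    degs <- vapply(cls, function(cl) degree_record(cl$signature, schemas),
                   numeric(1))
    feasible <- max(degs) <= h + 1e-9
    rce <- NA_real_
    if (feasible) {
      ins <- insert_counterfeits(cls, k, schemas,
                                 seed = anonceil:::node_seed(seed, nd))
      cat <- group_catalog(ins$classes)
      if (!is.null(cat))
        rce <- reconstruction_error(ins$classes, schemas, cat)
    }
    data.frame(node = paste(nd, collapse = ","), feasible = feasible,
               rce = rce, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
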