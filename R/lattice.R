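# Full-domain generalization lattice: one generalization level per
# quasi-identifier, bottom node = all zeros (exact data), top node = all
# maximum levels. Record degree is monotone along lattice edges -- a class at
# a parent node is a union of classes at the child node, so its (tightened)
# signature region contains theirs -- which is what makes bottom-up pruning
# by the h-ceiling sound.

# all lattice nodes as an integer matrix (one row per node), ordered by
# level sum then lexicographically, so parents always come after children
lattice_nodes <- function(schemas) {
  qi <- qi_names(schemas)
  levels <- lapply(qi, function(a) 0:(n_levels(schemas[[a]]) - 1L))
  names(levels) <- qi
  grid <- as.matrix(do.call(expand.grid, levels))
  grid <- grid[order(rowSums(grid), apply(grid, 1, paste, collapse = ",")), ,
               drop = FALSE]
  rownames(grid) <- NULL
  storage.mode(grid) <- "integer"
  grid
}

# per-attribute generalization codes for all rows at all levels, computed once
precompute_codes <- function(data, schemas, qi) {
  codes <- lapply(qi, function(a) {
    sc <- schemas[[a]]
    nl <- n_levels(sc)
    if (sc$kind == "numeric") {
      v <- data[[a]]
      m <- vapply(seq_len(nl) - 1L, function(lv) {
        if (lv == 0L) as.integer(match(v, sort(unique(v))))
        else as.integer(floor((v - sc$domain[1]) / sc$level_widths[lv + 1L]))
      }, integer(nrow(data)))
    } else {
      tree <- sc$taxonomy
      leaf_id <- tree$leaves[match(as.character(data[[a]]),
                                   tree$labels[tree$leaves])]
      m <- vapply(seq_len(nl) - 1L, function(lv) {
        id <- leaf_id
        steps <- lv
        while (steps > 0L) { id <- tree$parent[id]; steps <- steps - 1L }
        id
      }, integer(nrow(data)))
    }
    matrix(m, nrow = nrow(data))
  })
  names(codes) <- qi
  codes
}

# Partition the table at one lattice node. Returns the compact class layout:
# grp (class index per row, numbered in order of first appearance), sizes,
# split row indices, per-class per-QI signature bounds/nodes, per-class
# per-QI degrees and record degrees.
partition_node <- function(prep, codes, node, schemas, tighten = TRUE) {
  qi <- prep$qi
  n <- nrow(prep$data)
  keycols <- lapply(seq_along(qi), function(i) codes[[qi[i]]][, node[i] + 1L])
  key <- do.call(paste, c(keycols, sep = "\r"))
  grp <- match(key, unique(key))
  m <- max(grp)
  sizes <- tabulate(grp, m)
  idx <- split(seq_len(n), grp)
  first <- vapply(idx, `[`, integer(1), 1L)

  deg <- matrix(0, nrow = m, ncol = length(qi))
  sig_num_lo <- sig_num_hi <- vector("list", length(qi))
  sig_node <- vector("list", length(qi))
  for (i in seq_along(qi)) {
    sc <- schemas[[qi[i]]]
    lv <- node[i]
    if (sc$kind == "numeric") {
      v <- prep$data[[qi[i]]]
      if (tighten || lv == 0L) {
        lo <- vapply(idx, function(j) min(v[j]), numeric(1))
        hi <- vapply(idx, function(j) max(v[j]), numeric(1))
      } else {
        w <- sc$level_widths[lv + 1L]
        b <- codes[[qi[i]]][first, lv + 1L]
        lo <- sc$domain[1] + b * w
        hi <- pmin(sc$domain[1] + (b + 1) * w - 1, sc$domain[2])
      }
      sig_num_lo[[i]] <- lo; sig_num_hi[[i]] <- hi
      deg[, i] <- (hi - lo) / (sc$domain[2] - sc$domain[1])
    } else {
      nodes_i <- codes[[qi[i]]][first, lv + 1L]
      sig_node[[i]] <- nodes_i
      M <- length(sc$taxonomy$leaves)
      deg[, i] <- (sc$taxonomy$n_leaves[nodes_i] - 1) / (M - 1)
    }
  }
  list(grp = grp, sizes = sizes, idx = idx,
       sig_num_lo = sig_num_lo, sig_num_hi = sig_num_hi, sig_node = sig_node,
       deg = deg, rec_deg = rowMeans(deg))
}

# materialize equivalence-class objects from a compact partition
classes_from_partition <- function(prep, part, schemas) {
  qi <- prep$qi
  prov <- if (!is.null(prep$data$.provenance)) prep$data$.provenance
          else rep("real", nrow(prep$data))
  lapply(seq_along(part$sizes), function(c_id) {
    sig <- lapply(seq_along(qi), function(i) {
      sc <- schemas[[qi[i]]]
      if (sc$kind == "numeric")
        gv_interval(part$sig_num_lo[[i]][c_id], part$sig_num_hi[[i]][c_id])
      else
        gv_node(part$sig_node[[i]][c_id],
                sc$taxonomy$labels[part$sig_node[[i]][c_id]])
    })
    names(sig) <- qi
    rows <- part$idx[[c_id]]
    structure(
      list(class_id = c_id,
           signature = sig,
           members = data.frame(row = rows,
                                sensitive = prep$data[[prep$sens]][rows],
                                provenance = prov[rows],
                                stringsAsFactors = FALSE)),
      class = "equivalence_class")
  })
}

#' @export
print.equivalence_class <- function(x, ...) {
  cat(sprintf("<equivalence_class %d> <%s> %d member(s)\n", x$class_id,
              paste(vapply(x$signature, format, ""), collapse = ", "),
              nrow(x$members)))
  invisible(x)
}

#' Apply a lattice node to a table
#'
#' Generalizes every record at the node's per-attribute levels and groups
#' records with identical generalized signatures into equivalence classes.
#' With `tighten = TRUE` (the default) the numeric signature of each class is
#' collapsed to the `[min, max]` of the members' raw values after grouping;
#' membership is unchanged, only the published interval (and the degrees
#' derived from it) narrows.
#'
#' @param table a data.frame conforming to `schemas` (identifier columns, if
#'   present, are dropped).
#' @param node integer vector of generalization levels, one per
#'   quasi-identifier in schema order.
#' @param schemas a `schema_set`.
#' @param tighten collapse numeric intervals to member min/max after grouping.
#' @return a list of `equivalence_class` objects, numbered in order of first
#'   member appearance.
#' @export
apply_node <- function(table, node, schemas, tighten = TRUE) {
  prep <- prepare_table(table, schemas)
  if (!is.null(table$.provenance)) prep$data$.provenance <- table$.provenance
  codes <- precompute_codes(prep$data, schemas, prep$qi)
  part <- partition_node(prep, codes, as.integer(node), schemas, tighten)
  classes_from_partition(prep, part, schemas)
}

#' Test whether a lattice node satisfies the h-ceiling
#'
#' A node is feasible iff the maximum record degree over its equivalence
#' classes is at most `h`. Degrees are computed on the tightened signatures
#' when `tighten = TRUE` (matching the degrees of the published table).
#'
#' @inheritParams apply_node
#' @param h ceiling on the record generalization degree, in `[0, 1]`.
#' @return `TRUE` or `FALSE`.
#' @export
node_feasible_h <- function(table, node, schemas, h, tighten = TRUE) {
  stopifnot(h >= 0, h <= 1)
  prep <- prepare_table(table, schemas)
  codes <- precompute_codes(prep$data, schemas, prep$qi)
  part <- partition_node(prep, codes, as.integer(node), schemas, tighten)
  max(part$rec_deg) <= h + 1e-9
}

#' Build the h-feasible part of the generalization lattice
#'
#' Generates lattice nodes bottom-up and returns exactly those satisfying the
#' h-ceiling. Nodes dominated by a known-infeasible node (componentwise >= in
#' every level) are pruned without evaluation: record degree is monotone along
#' lattice edges, so an infeasible node's ancestors are all infeasible.
#'
#' @inheritParams node_feasible_h
#' @param h ceiling in `[0, 1]`, or `NULL` to return the full lattice.
#' @return an integer matrix of feasible nodes, one row per node, columns
#'   named by quasi-identifier.
#' @export
build_lattice <- function(schemas, table, h = NULL, tighten = TRUE) {
  nodes <- lattice_nodes(schemas)
  if (is.null(h)) return(nodes)
  stopifnot(h >= 0, h <= 1)
  prep <- prepare_table(table, schemas)
  codes <- precompute_codes(prep$data, schemas, prep$qi)
  feasible <- matrix(integer(0), ncol = ncol(nodes),
                     dimnames = list(NULL, colnames(nodes)))
  infeasible <- list()
  for (r in seq_len(nrow(nodes))) {
    nd <- nodes[r, ]
    dominated <- any(vapply(infeasible, function(b) all(nd >= b), logical(1)))
    if (dominated) next
    part <- partition_node(prep, codes, nd, schemas, tighten)
    if (max(part$rec_deg) <= h + 1e-9) {
      feasible <- rbind(feasible, nd)
    } else {
      infeasible[[length(infeasible) + 1L]] <- nd
    }
  }
  rownames(feasible) <- NULL
  feasible
}
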