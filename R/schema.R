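#' Attribute schemas for anonymization
#'
#' An attribute schema describes one column of the table to be anonymized:
#' its role in the privacy model (identifier, quasi-identifier or sensitive),
#' its kind, and -- for quasi-identifiers -- the full-domain generalization
#' hierarchy. Numeric hierarchies are fixed-width bins anchored at the domain
#' minimum, one width per generalization level (level 0 is the exact value,
#' width 1 on the integer grid). Categorical hierarchies are taxonomy trees
#' with all leaves at the same depth, so that one generalization level applies
#' uniformly to the whole column.
#'
#' @param name column name (must match the data header).
#' @param role one of `"identifier"`, `"quasi_identifier"`, `"sensitive"`.
#' @param kind one of `"numeric"`, `"categorical"`.
#' @param domain numeric length-2 vector `c(L, U)` with `L < U`
#'   (numeric attributes only).
#' @param level_widths strictly increasing integer bin widths, one per level;
#'   the first must be 1 (exact values) and the last must cover the whole
#'   domain, i.e. be at least `U - L + 1`.
#' @param taxonomy a [taxonomy_tree()] (categorical quasi-identifiers only).
#' @return an object of class `attribute_schema`.
#' @seealso [load_schema()], [generalize_value()]
#' @export
attribute_schema <- function(name, role, kind,
                             domain = NULL, level_widths = NULL,
                             taxonomy = NULL) {
  role <- match.arg(role, c("identifier", "quasi_identifier", "sensitive"))
  kind <- match.arg(kind, c("numeric", "categorical"))
  fail <- function(rule) {
    stop(sprintf("attribute '%s': %s", name, rule), call. = FALSE)
  }
  if (role == "quasi_identifier") {
    if (kind == "numeric") {
      if (is.null(domain) || length(domain) != 2 || !is.numeric(domain))
        fail("numeric quasi-identifier requires a domain c(L, U)")
      if (!(domain[1] < domain[2]))
        fail("domain must satisfy L < U")
      if (is.null(level_widths) || length(level_widths) < 1)
        fail("numeric quasi-identifier requires level_widths")
      if (any(diff(level_widths) <= 0))
        fail("level_widths must be strictly increasing")
      if (level_widths[1] != 1)
        fail("level 0 width must be 1 (exact values on the integer grid)")
      if (level_widths[length(level_widths)] < domain[2] - domain[1] + 1)
        fail("the last level width must cover the full domain [L, U]")
    } else {
      if (is.null(taxonomy) || !inherits(taxonomy, "taxonomy_tree"))
        fail("categorical quasi-identifier requires a taxonomy tree")
    }
  }
  structure(
    list(name = name, role = role, kind = kind,
         domain = if (!is.null(domain)) as.numeric(domain),
         level_widths = if (!is.null(level_widths)) as.numeric(level_widths),
         taxonomy = taxonomy),
    class = "attribute_schema")
}

#' Number of generalization levels of an attribute
#'
#' Level 0 is the exact value. Numeric attributes have one level per
#' configured bin width; categorical attributes have one level per taxonomy
#' depth step up to the root. Attributes that are never generalized
#' (identifier, sensitive) have a single level.
#'
#' @param attribute an [attribute_schema()].
#' @return integer number of levels (>= 1).
#' @export
n_levels <- function(attribute) {
  stopifnot(inherits(attribute, "attribute_schema"))
  if (attribute$role != "quasi_identifier") return(1L)
  if (attribute$kind == "numeric") length(attribute$level_widths)
  else attribute$taxonomy$height + 1L
}

#' @export
print.attribute_schema <- function(x, ...) {
  cat(sprintf("<attribute_schema> %s (%s, %s)\n", x$name, x$role, x$kind))
  if (!is.null(x$domain))
    cat(sprintf("  domain: [%s, %s], %d levels\n",
                x$domain[1], x$domain[2], n_levels(x)))
  if (!is.null(x$taxonomy))
    cat(sprintf("  taxonomy: %d leaves, height %d\n",
                length(x$taxonomy$leaves), x$taxonomy$height))
  invisible(x)
}

#' Build a taxonomy tree from a nested node list
#'
#' The tree is used for full-domain generalization of a categorical attribute:
#' a value at level `l` is replaced by its ancestor `l` steps above the leaf.
#' Every leaf must sit at the same depth so that levels are well defined for
#' the whole column; ragged trees are rejected.
#'
#' @param x a nested list with elements `label` and optional `children`
#'   (a list of nodes of the same shape), as produced by a YAML config.
#' @return an object of class `taxonomy_tree` with fields `labels`, `parent`,
#'   `depth`, `n_leaves` (subtree leaf counts), `leaves` (leaf node ids),
#'   `height`.
#' @examples
#' sex <- taxonomy_tree(list(label = "*",
#'   children = list(list(label = "M"), list(label = "F"))))
#' @export
taxonomy_tree <- function(x) {
  labels <- character(); parent <- integer(); depth <- integer()
  add <- function(node, par, d) {
    if (is.null(node$label)) stop("taxonomy node without a label", call. = FALSE)
    labels[[length(labels) + 1L]] <<- as.character(node$label)
    parent[[length(parent) + 1L]] <<- par
    depth[[length(depth) + 1L]] <<- d
    id <- length(labels)
    for (ch in node$children) add(ch, id, d + 1L)
    id
  }
  add(x, NA_integer_, 0L)
  is_leaf <- !(seq_along(labels) %in% parent)
  leaves <- which(is_leaf)
  if (length(unique(depth[leaves])) != 1L)
    stop("taxonomy tree has leaves at different depths; full-domain levels require uniform depth",
         call. = FALSE)
  if (anyDuplicated(labels[leaves]))
    stop("duplicate leaf labels in taxonomy tree", call. = FALSE)
  # subtree leaf counts, accumulated leaf-to-root
  n_leaves <- integer(length(labels))
  for (lf in leaves) {
    v <- lf
    while (!is.na(v)) { n_leaves[v] <- n_leaves[v] + 1L; v <- parent[v] }
  }
  structure(
    list(labels = labels, parent = parent, depth = depth,
         n_leaves = n_leaves, leaves = leaves,
         height = max(depth)),
    class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree> %d nodes, %d leaves, height %d; root '%s'\n",
              length(x$labels), length(x$leaves), x$height, x$labels[1]))
  invisible(x)
}

# ancestor node id `steps` levels above the leaf with this label
tax_ancestor <- function(tree, leaf_label, steps) {
  id <- tree$leaves[match(leaf_label, tree$labels[tree$leaves])]
  if (is.na(id))
    stop(sprintf("value '%s' is not a leaf of the taxonomy", leaf_label),
         call. = FALSE)
  while (steps > 0L) { id <- tree$parent[id]; steps <- steps - 1L }
  id
}

#' Load attribute schemas from a YAML config file
#'
#' The config has a top-level `attributes` list; each entry carries `name`,
#' `role`, and for quasi-identifiers either `domain` + `level_widths`
#' (numeric) or a nested `taxonomy` (categorical). Exactly one attribute must
#' have the sensitive role.
#'
#' @param config_path path to the YAML file.
#' @return a `schema_set`: a named list of [attribute_schema()] objects.
#' @export
load_schema <- function(config_path) {
  if (!file.exists(config_path))
    stop(sprintf("schema config '%s' not found", config_path), call. = FALSE)
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$attributes))
    stop("schema config has no 'attributes' block", call. = FALSE)
  schemas <- lapply(cfg$attributes, function(a) {
    attribute_schema(
      name = a$name,
      role = a$role,
      kind = if (is.null(a$kind)) "categorical" else a$kind,
      domain = if (!is.null(a$domain)) unlist(a$domain),
      level_widths = if (!is.null(a$level_widths)) unlist(a$level_widths),
      taxonomy = if (!is.null(a$taxonomy)) taxonomy_tree(a$taxonomy))
  })
  names(schemas) <- vapply(schemas, `[[`, "", "name")
  schema_set(schemas)
}

#' Assemble and validate a schema set
#'
#' @param schemas named list of [attribute_schema()] objects.
#' @return the validated list, classed `schema_set`.
#' @export
schema_set <- function(schemas) {
  roles <- vapply(schemas, `[[`, "", "role")
  if (sum(roles == "sensitive") != 1L)
    stop(sprintf("schema set must have exactly one sensitive attribute (found %d)",
                 sum(roles == "sensitive")), call. = FALSE)
  if (sum(roles == "quasi_identifier") < 1L)
    stop("schema set has no quasi-identifier attributes", call. = FALSE)
  structure(schemas, class = "schema_set")
}

#' @export
print.schema_set <- function(x, ...) {
  cat(sprintf("<schema_set> %d attributes: %d QI, sensitive = '%s'\n",
              length(x), length(qi_names(x)), sensitive_name(x)))
  invisible(x)
}

qi_names <- function(schemas) {
  names(schemas)[vapply(schemas, `[[`, "", "role") == "quasi_identifier"]
}

sensitive_name <- function(schemas) {
  names(schemas)[vapply(schemas, `[[`, "", "role") == "sensitive"]
}

# Drop identifier columns, check header and value domains.
# Returns list(data, qi, sens).
prepare_table <- function(table, schemas) {
  stopifnot(is.data.frame(table), inherits(schemas, "schema_set"))
  known <- names(schemas)
  missing_cols <- setdiff(known, names(table))
  if (length(missing_cols))
    stop(sprintf("data is missing schema column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  ids <- names(schemas)[vapply(schemas, `[[`, "", "role") == "identifier"]
  if (length(ids)) {
    message(sprintf("dropping identifier column(s): %s",
                    paste(ids, collapse = ", ")))
  }
  qi <- qi_names(schemas)
  sens <- sensitive_name(schemas)
  data <- table[, c(qi, sens), drop = FALSE]
  for (a in qi) {
    sc <- schemas[[a]]
    if (sc$kind == "numeric") {
      v <- data[[a]]
      if (!is.numeric(v))
        stop(sprintf("attribute '%s': expected numeric values", a), call. = FALSE)
      bad <- which(v < sc$domain[1] | v > sc$domain[2])
      if (length(bad))
        stop(sprintf("attribute '%s': value %s outside domain [%s, %s] (row %d)",
                     a, v[bad[1]], sc$domain[1], sc$domain[2], bad[1]),
             call. = FALSE)
    } else {
      lv <- sc$taxonomy$labels[sc$taxonomy$leaves]
      bad <- which(!(as.character(data[[a]]) %in% lv))
      if (length(bad))
        stop(sprintf("attribute '%s': value '%s' is not a taxonomy leaf (row %d)",
                     a, data[[a]][bad[1]], bad[1]), call. = FALSE)
      data[[a]] <- as.character(data[[a]])
    }
  }
  data[[sens]] <- as.character(data[[sens]])
  list(data = data, qi = qi, sens = sens)
}
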