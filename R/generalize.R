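#' Generalized values
#'
#' A generalized value is either a closed integer interval `[lo, hi]`
#' (numeric attributes) or a taxonomy node (categorical attributes). Exact
#' values are the degenerate cases `lo == hi` and a leaf node.
#'
#' @param lo,hi interval bounds.
#' @return an object of class `generalized_value`.
#' @keywords internal
gv_interval <- function(lo, hi) {
  structure(list(type = "interval", lo = lo, hi = hi),
            class = "generalized_value")
}

gv_node <- function(node_id, label) {
  structure(list(type = "node", node = node_id, label = label),
            class = "generalized_value")
}

#' @export
format.generalized_value <- function(x, ...) {
  if (x$type == "interval") {
    if (x$lo == x$hi) as.character(x$lo) else sprintf("[%s-%s]", x$lo, x$hi)
  } else {
    x$label
  }
}

#' @export
print.generalized_value <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Generalize a single value to a given level
#'
#' Numeric values at level `l > 0` are replaced by the fixed-width bin that
#' contains them, with bins of the configured level width anchored at the
#' domain minimum `L` (half-open `[L + i*w, L + (i+1)*w)` on the real line,
#' reported as the closed integer interval and clipped at the domain maximum).
#' Level 0 returns the exact value. Categorical values are replaced by the
#' taxonomy ancestor `level` steps above the leaf.
#'
#' @param value a raw value within the attribute's domain.
#' @param attribute an [attribute_schema()] quasi-identifier.
#' @param level integer generalization level, `0 <= level < n_levels(attribute)`.
#' @return a `generalized_value` containing `value`.
#' @examples
#' age <- attribute_schema("age", "quasi_identifier", "numeric",
#'                         domain = c(0, 99),
#'                         level_widths = c(1, 5, 10, 20, 100))
#' format(generalize_value(37, age, 2))  # "[30-39]"
#' @export
generalize_value <- function(value, attribute, level) {
  stopifnot(inherits(attribute, "attribute_schema"))
  if (attribute$role != "quasi_identifier")
    stop(sprintf("attribute '%s' is not a quasi-identifier", attribute$name),
         call. = FALSE)
  if (level < 0L || level >= n_levels(attribute))
    stop(sprintf("attribute '%s': level %d out of range [0, %d]",
                 attribute$name, level, n_levels(attribute) - 1L),
         call. = FALSE)
  if (attribute$kind == "numeric") {
    L <- attribute$domain[1]; U <- attribute$domain[2]
    if (value < L || value > U)
      stop(sprintf("attribute '%s': value %s outside domain [%s, %s]",
                   attribute$name, value, L, U), call. = FALSE)
    if (level == 0L) return(gv_interval(value, value))
    w <- attribute$level_widths[level + 1L]
    i <- floor((value - L) / w)
    gv_interval(L + i * w, min(L + (i + 1) * w - 1, U))
  } else {
    tree <- attribute$taxonomy
    id <- tax_ancestor(tree, as.character(value), level)
    gv_node(id, tree$labels[id])
  }
}
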