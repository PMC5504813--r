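#' Generalization degree of a numeric interval
#'
#' The fraction of the attribute's domain spanned by the generalized
#' interval, `(U_q - L_q) / (U - L)`: 0 for an exact value, 1 for the full
#' domain.
#'
#' @param gv a `generalized_value` interval (see [generalize_value()]).
#' @param attribute the numeric [attribute_schema()] the interval belongs to.
#' @return a number in `[0, 1]`.
#' @examples
#' age <- attribute_schema("age", "quasi_identifier", "numeric",
#'                         domain = c(0, 99),
#'                         level_widths = c(1, 5, 10, 20, 100))
#' degree_numeric(gv <- generalize_value(37, age, 0), age)  # 0
#' @export
degree_numeric <- function(gv, attribute) {
  stopifnot(inherits(gv, "generalized_value"), gv$type == "interval")
  L <- attribute$domain[1]; U <- attribute$domain[2]
  if (U == L)
    stop(sprintf("attribute '%s': degenerate domain U = L", attribute$name),
         call. = FALSE)
  if (gv$lo < L || gv$hi > U || gv$lo > gv$hi)
    stop(sprintf("attribute '%s': interval [%s, %s] outside domain",
                 attribute$name, gv$lo, gv$hi), call. = FALSE)
  (gv$hi - gv$lo) / (U - L)
}

#' Generalization degree of a taxonomy node
#'
#' `(|M_p| - 1) / (|M| - 1)` where `M` is the leaf set of the taxonomy and
#' `M_p` the leaves under the generalized node: 0 for a leaf, 1 for the root.
#'
#' @param gv a `generalized_value` taxonomy node.
#' @param attribute the categorical [attribute_schema()].
#' @return a number in `[0, 1]`.
#' @export
degree_categorical <- function(gv, attribute) {
  stopifnot(inherits(gv, "generalized_value"), gv$type == "node")
  tree <- attribute$taxonomy
  M <- length(tree$leaves)
  if (M < 2L)
    stop(sprintf("attribute '%s': degree undefined for a single-leaf taxonomy",
                 attribute$name), call. = FALSE)
  if (gv$node < 1L || gv$node > length(tree$labels))
    stop(sprintf("attribute '%s': node not in taxonomy", attribute$name),
         call. = FALSE)
  (tree$n_leaves[gv$node] - 1) / (M - 1)
}

degree_value <- function(gv, attribute) {
  if (gv$type == "interval") degree_numeric(gv, attribute)
  else degree_categorical(gv, attribute)
}

#' Generalization degree of a record signature
#'
#' The arithmetic mean of the per-attribute degrees over the
#' quasi-identifiers; the sensitive attribute is excluded. This is the
#' quantity bounded by the ceiling parameter `h`.
#'
#' @param signature a list with one `generalized_value` per quasi-identifier,
#'   in schema order (named or unnamed).
#' @param schemas a `schema_set`.
#' @return a number in `[0, 1]`.
#' @export
degree_record <- function(signature, schemas) {
  qi <- qi_names(schemas)
  if (length(signature) != length(qi))
    stop(sprintf("signature has %d values but there are %d quasi-identifiers",
                 length(signature), length(qi)), call. = FALSE)
  if (!is.null(names(signature))) signature <- signature[qi]
  mean(vapply(seq_along(qi), function(i) {
    degree_value(signature[[i]], schemas[[qi[i]]])
  }, numeric(1)))
}
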