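# Utility metrics. LM and DM are the standard generalization metrics; RCE
# compares, record by record, the probability density a recipient would
# assign to the original value with the density implied by the published
# (generalized, catalog-annotated) record, integrating the squared difference
# over the attribute's cells. Counterfeits enter RCE only through the catalog
# down-weighting of real records' densities.

#' Loss metric (LM)
#'
#' Mean per-cell generalization degree over all records (real and
#' counterfeit) and all quasi-identifier attributes. Equal to the class-size
#' weighted mean of the record degrees, so any table satisfying the h-ceiling
#' has LM <= h.
#'
#' @param classes list of `equivalence_class` objects.
#' @param schemas a `schema_set`.
#' @return a number in `[0, 1]`.
#' @export
loss_metric <- function(classes, schemas) {
  sizes <- vapply(classes, function(cl) nrow(cl$members), numeric(1))
  degs <- vapply(classes, function(cl) degree_record(cl$signature, schemas),
                 numeric(1))
  sum(sizes * degs) / sum(sizes)
}

#' Discernibility metric (DM)
#'
#' Sum of squared equivalence-class sizes: each record is charged the size of
#' the class it is indistinguishable within.
#'
#' @param classes list of `equivalence_class` objects.
#' @return a number `>= number of records`.
#' @export
discernibility_metric <- function(classes) {
  sum(vapply(classes, function(cl) nrow(cl$members), numeric(1))^2)
}

# per-(class_id, sensitive value) catalog down-weighting scale:
# real_count(s in group) / (real + counterfeit count of s in group).
# Returns a lookup function scale(class_id, s) -> numeric in (0, 1].
catalog_scale_fn <- function(classes, catalog) {
  if (is.null(catalog) || nrow(catalog$entries) == 0)
    return(function(class_id, s) 1)
  tal <- class_tallies(classes)
  ids <- vapply(tal, `[[`, integer(1), "class_id")
  key <- character(); val <- numeric()
  for (e in seq_len(nrow(catalog$entries))) {
    g <- as.integer(strsplit(catalog$entries$class_ids[e], ";")[[1]])
    s <- catalog$entries$sensitive[e]
    cc <- catalog$entries$count[e]
    o_g <- sum(vapply(match(g, ids), function(t) tal[[t]]$o[[s]], numeric(1)))
    key <- c(key, paste(g, s, sep = "\r"))
    val <- c(val, rep(o_g / (o_g + cc), length(g)))
  }
  lookup <- structure(val, names = key)
  function(class_id, s) {
    v <- lookup[paste(class_id, s, sep = "\r")]
    if (is.na(v)) 1 else unname(v)
  }
}

# squared-difference integral for one attribute: original density is a unit
# mass on one of w cells, anonymized density is uniform s/w over the w cells
# of the generalized region (s = catalog scale). Cells have unit width.
attr_sq_diff <- function(w, s) {
  (1 - s / w)^2 + (w - 1) * (s / w)^2
}

# cell count of a generalized value
gv_width <- function(gv, attribute) {
  if (gv$type == "interval") gv$hi - gv$lo + 1
  else attribute$taxonomy$n_leaves[gv$node]
}

#' Per-record probability density profile
#'
#' The density model behind RCE, materialized for inspection: for one member
#' record of a class, returns a discrete density per attribute over the
#' attribute's cells (integers `L..U` for numeric, leaves for categorical,
#' sensitive-domain values for the sensitive attribute). The `"original"`
#' view is a unit mass on the record's exact cells. The `"anonymized"` view
#' is uniform over each generalized region; when the record's class belongs
#' to a catalog group holding counterfeits of the record's sensitive value,
#' every attribute density is multiplied by the catalog scale
#' `real / (real + counterfeit)` for that value in the group.
#'
#' @param classes list of `equivalence_class` objects.
#' @param class_id class of the record.
#' @param member row index within the class's members.
#' @param schemas a `schema_set`.
#' @param view `"original"` or `"anonymized"`.
#' @param catalog optional `counterfeit_catalog` providing the down-weighting.
#' @param original optional data.frame of the original table (needed for the
#'   `"original"` view's exact numeric cells).
#' @return named list of numeric density vectors, one per attribute.
#' @export
record_density <- function(classes, class_id, member, schemas,
                           view = c("original", "anonymized"),
                           catalog = NULL, original = NULL) {
  view <- match.arg(view)
  ids <- vapply(classes, `[[`, integer(1), "class_id")
  cl <- classes[[match(class_id, ids)]]
  if (is.null(cl)) stop(sprintf("unknown class %d", class_id), call. = FALSE)
  rec <- cl$members[member, ]
  qi <- qi_names(schemas)
  sens <- sensitive_name(schemas)
  scale <- if (view == "anonymized")
    catalog_scale_fn(classes, catalog)(class_id, rec$sensitive) else 1
  out <- list()
  for (a in qi) {
    sc <- schemas[[a]]
    if (sc$kind == "numeric") {
      cells <- sc$domain[1]:sc$domain[2]
      d <- numeric(length(cells)); names(d) <- cells
      if (view == "original") {
        if (is.null(original))
          stop("the original view needs the original table", call. = FALSE)
        d[as.character(original[[a]][rec$row])] <- 1
      } else {
        gv <- cl$signature[[a]]
        d[as.character(gv$lo:gv$hi)] <- scale / (gv$hi - gv$lo + 1)
      }
    } else {
      leaves <- sc$taxonomy$labels[sc$taxonomy$leaves]
      d <- numeric(length(leaves)); names(d) <- leaves
      if (view == "original") {
        if (is.null(original))
          stop("the original view needs the original table", call. = FALSE)
        d[as.character(original[[a]][rec$row])] <- 1
      } else {
        gv <- cl$signature[[a]]
        under <- leaves_under(sc$taxonomy, gv$node)
        d[under] <- scale / length(under)
      }
    }
    out[[a]] <- d
  }
  values <- sort(unique(unlist(lapply(classes, function(x) x$members$sensitive))))
  d <- numeric(length(values)); names(d) <- values
  d[rec$sensitive] <- if (view == "original") 1 else scale
  out[[sens]] <- d
  out
}

leaves_under <- function(tree, node) {
  keep <- logical(length(tree$labels))
  for (lf in tree$leaves) {
    v <- lf
    while (!is.na(v)) {
      if (v == node) { keep[lf] <- TRUE; break }
      v <- tree$parent[v]
    }
  }
  tree$labels[tree$leaves[keep[tree$leaves]]]
}

#' Reconstruction error (RCE)
#'
#' Summed squared difference between each real record's original and
#' anonymized probability densities, integrated over every attribute's cells
#' (quasi-identifiers and the sensitive attribute; unit cell width). The
#' anonymized density of a record is uniform over its generalized regions,
#' scaled down by the catalog factor `real / (real + counterfeit)` when the
#' record's class group holds counterfeits of the record's sensitive value.
#' Counterfeit records contribute no terms of their own. Identity
#' anonymization with no counterfeits gives 0.
#'
#' @param classes list of `equivalence_class` objects (with provenance).
#' @param schemas a `schema_set`.
#' @param catalog optional `counterfeit_catalog` (`NULL` = no down-weighting).
#' @param per_record return the per-record error vector instead of the total.
#' @return total RCE (or per-record vector), `>= 0`.
#' @export
reconstruction_error <- function(classes, schemas, catalog = NULL,
                                 per_record = FALSE) {
  qi <- qi_names(schemas)
  scale <- catalog_scale_fn(classes, catalog)
  out <- unlist(lapply(classes, function(cl) {
    real <- which(cl$members$provenance == "real")
    if (!length(real)) return(numeric(0))
    widths <- vapply(qi, function(a) gv_width(cl$signature[[a]], schemas[[a]]),
                     numeric(1))
    vapply(real, function(i) {
      s <- scale(cl$class_id, cl$members$sensitive[i])
      sum(attr_sq_diff(widths, s)) + (1 - s)^2
    }, numeric(1))
  }))
  if (per_record) out else sum(out)
}
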