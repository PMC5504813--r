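# Range/aggregation queries on original and anonymized views. Generalized
# rows contribute fractionally under the uniformity assumption: a record
# whose region overlaps a predicate contributes the overlap fraction
# |region \cap predicate| / |region|, multiplied over filtered attributes --
# the same uniformity the RCE density model assumes.

#' Specify an aggregation query
#'
#' @param aggregate `"count"` or `"mean"`.
#' @param target attribute to average (for `"mean"`).
#' @param filters named list of per-attribute predicates: a numeric
#'   `c(lo, hi)` range for numeric attributes, or a character vector of
#'   admissible values for categorical/sensitive attributes.
#' @param group_by `NULL`, or `list(attribute =, width =)`: numeric group
#'   bins of the given width anchored at the attribute's domain minimum, or
#'   `list(attribute =)` alone to group by categorical leaf.
#' @return an object of class `query_spec`.
#' @export
query_spec <- function(aggregate = c("count", "mean"), target = NULL,
                       filters = list(), group_by = NULL) {
  aggregate <- match.arg(aggregate)
  if (aggregate == "mean" && is.null(target))
    stop("mean queries need a target attribute", call. = FALSE)
  if (!is.null(group_by) && !is.null(group_by$width) && group_by$width <= 0)
    stop("group_by width must be > 0", call. = FALSE)
  structure(list(aggregate = aggregate, target = target,
                 filters = filters, group_by = group_by),
            class = "query_spec")
}

# normalize a queryable view into per-row regions:
#   numeric attr -> n x 2 matrix of closed integer bounds
#   categorical attr -> list of leaf-label vectors
#   sensitive -> exact character vector
view_regions <- function(x, schemas) {
  qi <- qi_names(schemas)
  sens <- sensitive_name(schemas)
  if (inherits(x, "anon_result")) {
    rows <- x$table
    out <- list()
    for (a in qi) out[[a]] <- parse_region_col(rows[[a]], schemas[[a]])
    out[[sens]] <- rows[[sens]]
    return(out)
  }
  stopifnot(is.data.frame(x))
  out <- list()
  for (a in qi) {
    sc <- schemas[[a]]
    col <- x[[a]]
    if (is.numeric(col)) {
      out[[a]] <- cbind(col, col)
    } else {
      out[[a]] <- parse_region_col(as.character(col), sc)
    }
  }
  out[[sens]] <- as.character(x[[sens]])
  out
}

# parse a published display column ("37", "[30-39]", "*", leaf/node labels)
parse_region_col <- function(col, sc) {
  col <- as.character(col)
  if (sc$kind == "numeric") {
    lo <- hi <- numeric(length(col))
    star <- col == "*"
    lo[star] <- sc$domain[1]; hi[star] <- sc$domain[2]
    rng <- grepl("^\\[", col)
    if (any(rng)) {
      m <- regmatches(col[rng],
                      regexec("^\\[(-?[0-9.]+)-(-?[0-9.]+)\\]$", col[rng]))
      lo[rng] <- as.numeric(vapply(m, `[`, "", 2))
      hi[rng] <- as.numeric(vapply(m, `[`, "", 3))
    }
    plain <- !star & !rng
    lo[plain] <- hi[plain] <- as.numeric(col[plain])
    cbind(lo, hi)
  } else {
    tree <- sc$taxonomy
    uniq <- unique(col)
    sets <- lapply(uniq, function(lab) {
      id <- match(lab, tree$labels)
      if (is.na(id))
        stop(sprintf("attribute '%s': unknown node label '%s'", sc$name, lab),
             call. = FALSE)
      leaves_under(tree, id)
    })
    names(sets) <- uniq
    sets[col]
  }
}

# per-row overlap fraction of a predicate with the row regions
overlap_fraction <- function(region, pred, sc) {
  if (sc$kind == "numeric" || is.matrix(region)) {
    lo <- region[, 1]; hi <- region[, 2]
    inter <- pmin(hi, pred[2]) - pmax(lo, pred[1]) + 1
    pmax(inter, 0) / (hi - lo + 1)
  } else {
    vapply(region, function(ls) length(intersect(ls, pred)) / length(ls),
           numeric(1))
  }
}

#' Run an aggregation query on a table view
#'
#' Works on the original data.frame (exact evaluation), an `anon_result`
#' (published generalized rows, counterfeits included) or a truthful-view
#' data.frame (suppressed rows span the full domain). Generalized rows
#' contribute fractionally by the uniform-overlap ratio.
#'
#' @param x the view to query.
#' @param query a [query_spec()].
#' @param schemas a `schema_set`.
#' @return a data.frame with columns `group` (bin lower bound or leaf label;
#'   `"all"` when there is no grouping) and `value`.
#' @export
run_query <- function(x, query, schemas) {
  stopifnot(inherits(query, "query_spec"))
  regions <- view_regions(x, schemas)
  sens <- sensitive_name(schemas)
  n <- if (is.matrix(regions[[1]])) nrow(regions[[1]]) else length(regions[[1]])
  w <- rep(1, n)
  for (a in names(query$filters)) {
    if (!a %in% names(schemas))
      stop(sprintf("filter references unknown attribute '%s'", a),
           call. = FALSE)
    pred <- query$filters[[a]]
    if (a == sens) {
      w <- w * (regions[[sens]] %in% pred)
    } else {
      w <- w * overlap_fraction(regions[[a]], pred, schemas[[a]])
    }
  }
  target_mid <- NULL
  if (query$aggregate == "mean") {
    tr <- regions[[query$target]]
    target_mid <- if (is.matrix(tr)) (tr[, 1] + tr[, 2]) / 2
                  else stop("mean target must be numeric", call. = FALSE)
  }
  gb <- query$group_by
  if (is.null(gb)) {
    val <- if (query$aggregate == "count") sum(w)
           else if (sum(w) > 0) sum(w * target_mid) / sum(w) else NA_real_
    return(data.frame(group = "all", value = val, stringsAsFactors = FALSE))
  }
  a <- gb$attribute
  sc <- schemas[[a]]
  if (a == sens || sc$kind == "categorical") {
    reg <- regions[[a]]
    leaves <- if (a == sens) sort(unique(reg))
              else sc$taxonomy$labels[sc$taxonomy$leaves]
    rows <- lapply(leaves, function(lf) {
      frac <- if (a == sens) as.numeric(reg == lf)
              else vapply(reg, function(ls) (lf %in% ls) / length(ls),
                          numeric(1))
      ww <- w * frac
      if (query$aggregate == "count")
        data.frame(group = lf, value = sum(ww), stringsAsFactors = FALSE)
      else if (sum(ww) > 0)
        data.frame(group = lf, value = sum(ww * target_mid) / sum(ww),
                   stringsAsFactors = FALSE)
      else NULL
    })
    out <- do.call(rbind, rows)
  } else {
    width <- gb$width
    L <- sc$domain[1]
    reg <- regions[[a]]
    bins <- seq(0, floor((sc$domain[2] - L) / width))
    rows <- lapply(bins, function(b) {
      pred <- c(L + b * width, L + (b + 1) * width - 1)
      frac <- overlap_fraction(reg, pred, sc)
      ww <- w * frac
      if (sum(ww) == 0) return(NULL)
      if (query$aggregate == "count")
        data.frame(group = pred[1], value = sum(ww))
      else
        data.frame(group = pred[1], value = sum(ww * target_mid) / sum(ww))
    })
    out <- do.call(rbind, rows)
  }
  if (is.null(out))
    out <- data.frame(group = character(0), value = numeric(0))
  rownames(out) <- NULL
  out
}

#' Query error rate between two views
#'
#' Runs the query on both views and reports the mean over groups of
#' `|estimate - truth| / max(truth, 1)`; groups absent from one view count
#' with value 0 there.
#'
#' @param original the original table (data.frame).
#' @param anonymized the anonymized view (`anon_result` or truthful-view
#'   data.frame).
#' @param query a [query_spec()].
#' @param schemas a `schema_set`.
#' @return a number `>= 0`.
#' @export
query_error_rate <- function(original, anonymized, query, schemas) {
  truth <- run_query(original, query, schemas)
  est <- run_query(anonymized, query, schemas)
  groups <- union(truth$group, est$group)
  t_val <- truth$value[match(groups, truth$group)]
  e_val <- est$value[match(groups, est$group)]
  t_val[is.na(t_val)] <- 0; e_val[is.na(e_val)] <- 0
  if (!length(groups)) return(0)
  mean(abs(e_val - t_val) / pmax(t_val, 1))
}
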