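# Publishing counterfeit counts safely. The catalog row (ClassID list,
# sensitive value, count) tells recipients how many counterfeits of each
# sensitive value were inserted in a *group* of equivalence classes. A group
# conceals its counterfeits when, for every member class and sensitive value,
# the counterfeits there are matched by at least as many real records of that
# value in the group's other classes -- then no adversary can pin down where
# the counterfeits sit (pigeonhole), and effective k-anonymity survives
# catalog disclosure.

#' Per-class sensitive-value tallies
#'
#' For each class: `o(s)` = real-record count and `p(s)` = counterfeit count
#' per sensitive value `s`. These are the quantities the group-safety
#' condition and the grouping algorithm operate on.
#'
#' @param classes list of `equivalence_class` objects (after counterfeit
#'   insertion).
#' @return a list with one element per class: `list(class_id, o, p)` where
#'   `o`, `p` are named integer vectors over the sensitive values present.
#' @export
class_tallies <- function(classes) {
  cls_idx <- rep(seq_along(classes),
                 vapply(classes, function(cl) nrow(cl$members), integer(1)))
  sens <- unlist(lapply(classes, function(cl) cl$members$sensitive))
  real <- unlist(lapply(classes, function(cl)
    cl$members$provenance == "real"))
  values <- sort(unique(sens))
  f_cls <- factor(cls_idx, levels = seq_along(classes))
  f_sens <- factor(sens, levels = values)
  o_mat <- unclass(table(f_cls[real], f_sens[real]))
  p_mat <- unclass(table(f_cls[!real], f_sens[!real]))
  lapply(seq_along(classes), function(t) {
    list(class_id = classes[[t]]$class_id,
         o = structure(as.integer(o_mat[t, ]), names = values),
         p = structure(as.integer(p_mat[t, ]), names = values))
  })
}

#' Is a candidate group of classes safe to publish?
#'
#' True iff for every class in the group and every sensitive value `s`, the
#' counterfeit count `p(s)` in that class is at most the total real-record
#' count of `s` in the *other* classes of the group. A single class holding
#' counterfeits is never safe on its own.
#'
#' @param tallies list of per-class tallies (see [class_tallies()]) belonging
#'   to one candidate group.
#' @return `TRUE` or `FALSE`.
#' @export
is_safe_group <- function(tallies) {
  if (!length(tallies)) return(TRUE)
  values <- names(tallies[[1]]$o)
  o_mat <- do.call(rbind, lapply(tallies, `[[`, "o"))
  p_mat <- do.call(rbind, lapply(tallies, `[[`, "p"))
  o_tot <- colSums(o_mat)
  for (t in seq_along(tallies)) {
    others <- o_tot - o_mat[t, ]
    if (any(p_mat[t, ] > others)) return(FALSE)
  }
  TRUE
}

#' Matched concealment count between two classes
#'
#' How many of one class's unconcealed counterfeits can be concealed by
#' another class's still-available real records: the sum over sensitive
#' values of `min(unconcealed p_i(s), available o_j(s))`. Availability
#' excludes real records already pledged to conceal other counterfeits in the
#' candidate's current group.
#'
#' @param p_unconcealed named integer vector of the seeking class's
#'   unconcealed counterfeit counts per sensitive value.
#' @param o_available named integer vector of the candidate class's unpledged
#'   real-record counts per sensitive value.
#' @return integer matched count.
#' @export
counterfeit_matching <- function(p_unconcealed, o_available) {
  values <- union(names(p_unconcealed), names(o_available))
  p <- p_unconcealed[values]; p[is.na(p)] <- 0L
  o <- o_available[values]; o[is.na(o)] <- 0L
  sum(pmin(p, o))
}

#' Group equivalence classes into a publishable catalog
#'
#' Greedy grouping: classes are seeded in descending order of total
#' counterfeit count (the hardest to conceal first, ties by class id). Each
#' seed repeatedly merges with the class maximizing the matched concealment
#' count -- real records are pledged one-per-counterfeit, so every emitted
#' group satisfies the safety condition by construction -- until all of its
#' counterfeits are concealed. Among equally matching candidates the one with
#' fewest own counterfeits, then the lowest class id, is preferred. If at any
#' point no candidate can conceal anything, or the merge count for a seed
#' exceeds the number of classes, the function returns `NULL`: the node
#' cannot be published and the search discards it.
#'
#' @param classes list of `equivalence_class` objects after counterfeit
#'   insertion.
#' @return `NULL`, or an object of class `counterfeit_catalog`: a list with
#'   `groups` (list of integer class-id vectors) and `entries` (data.frame
#'   with `class_ids` (semicolon-joined sorted ids), `sensitive`, `count`).
#'   Classes without counterfeits that were never recruited are omitted. An
#'   empty catalog (no counterfeits anywhere) has zero groups and entries.
#' @export
group_catalog <- function(classes) {
  tal <- class_tallies(classes)
  values <- names(tal[[1]]$o)
  nc <- length(tal)
  o_avail <- do.call(rbind, lapply(tal, `[[`, "o"))
  p_all <- do.call(rbind, lapply(tal, `[[`, "p"))
  unconc <- p_all
  storage.mode(o_avail) <- "numeric"; storage.mode(unconc) <- "numeric"
  total_p <- rowSums(p_all)

  if (sum(total_p) == 0)
    return(structure(list(groups = list(), entries = empty_entries()),
                     class = "counterfeit_catalog"))
  # quick infeasibility screens (necessary conditions for pledging)
  o_tot <- colSums(o_avail)
  if (any(colSums(p_all) > o_tot)) return(NULL)
  for (t in which(total_p > 0))
    if (any(p_all[t, ] > o_tot - o_avail[t, ])) return(NULL)

  group_of <- seq_len(nc)               # singleton groups initially
  seeds <- order(-total_p, seq_len(nc))
  seeds <- seeds[total_p[seeds] > 0]
  for (i in seeds) {
    merges <- 0L
    while (sum(unconc[i, ]) > 0) {
      merges <- merges + 1L
      if (merges > nc) return(NULL)
      cand <- which(group_of != group_of[i])
      if (!length(cand)) return(NULL)
      score <- colSums(pmin(t(o_avail[cand, , drop = FALSE]), unconc[i, ]))
      if (max(score) <= 0) return(NULL)
      best <- cand[order(-score, total_p[cand], cand)][1]
      group_of[group_of == group_of[best]] <- group_of[i]
      # conceal within the merged group: every unconcealed counterfeit is
      # pledged a distinct real record from another class of the group
      g <- which(group_of == group_of[i])
      for (t in g[order(g)]) {
        if (sum(unconc[t, ]) == 0) next
        for (u in g[order(g)]) {
          if (u == t) next
          m <- pmin(unconc[t, ], o_avail[u, ])
          unconc[t, ] <- unconc[t, ] - m
          o_avail[u, ] <- o_avail[u, ] - m
          if (sum(unconc[t, ]) == 0) break
        }
      }
    }
  }
  if (any(unconc > 0)) return(NULL)

  used <- unique(group_of[total_p > 0])
  groups <- lapply(used, function(g) sort(which(group_of == g)))
  entries <- do.call(rbind, lapply(groups, function(g) {
    cnt <- colSums(p_all[g, , drop = FALSE])
    keep <- cnt > 0
    if (!any(keep)) return(NULL)
    data.frame(class_ids = paste(g, collapse = ";"),
               sensitive = values[keep], count = as.integer(cnt[keep]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(entries)) entries <- empty_entries()
  rownames(entries) <- NULL
  for (g in groups)
    stopifnot(is_safe_group(tal[g]))
  structure(list(groups = groups, entries = entries),
            class = "counterfeit_catalog")
}

empty_entries <- function() {
  data.frame(class_ids = character(0), sensitive = character(0),
             count = integer(0), stringsAsFactors = FALSE)
}

#' @export
print.counterfeit_catalog <- function(x, ...) {
  cat(sprintf("<counterfeit_catalog> %d group(s), %d entr%s\n",
              length(x$groups), nrow(x$entries),
              if (nrow(x$entries) == 1) "y" else "ies"))
  if (nrow(x$entries)) print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Write a catalog as CSV
#'
#' Columns `class_id_list` (semicolon-joined ids), `sensitive_value`, `count`.
#'
#' @param catalog a `counterfeit_catalog`.
#' @param path output file path.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "counterfeit_catalog"))
  out <- catalog$entries
  names(out) <- c("class_id_list", "sensitive_value", "count")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reconstruct a truthful dataset from an anonymized table and its catalog
#'
#' Mirrors what a data recipient does with the published table and catalog:
#' for each catalog entry (group `G`, sensitive value `s`, count `c`), up to
#' `c` records with value `s` have their quasi-identifiers suppressed in each
#' class of `G`; `c` of the suppressed rows -- exactly the counterfeits --
#' are then deleted, and the remaining suppressed rows are kept with masked
#' quasi-identifiers. Every surviving row corresponds to a real original
#' record, so the output has exactly the original number of real records.
#'
#' @param classes list of `equivalence_class` objects after insertion.
#' @param catalog the non-`NULL` `counterfeit_catalog` for these classes.
#' @param schemas a `schema_set`.
#' @return a data.frame with columns `class_id`, one display column per
#'   quasi-identifier, and the sensitive attribute; suppressed rows have
#'   `class_id = NA` and `"*"` in every quasi-identifier column.
#' @export
truthful_view <- function(classes, catalog, schemas) {
  stopifnot(inherits(catalog, "counterfeit_catalog"))
  pub <- published_table(classes, schemas)
  pub$.suppress <- FALSE
  qi <- qi_names(schemas)
  sens <- sensitive_name(schemas)
  for (e in seq_len(nrow(catalog$entries))) {
    g <- as.integer(strsplit(catalog$entries$class_ids[e], ";")[[1]])
    missing_cls <- setdiff(g, pub$class_id)
    if (length(missing_cls))
      stop(sprintf("catalog entry references missing class %d", missing_cls[1]),
           call. = FALSE)
    s <- catalog$entries$sensitive[e]
    cc <- catalog$entries$count[e]
    for (t in g) {
      rows <- which(pub$class_id == t & pub[[sens]] == s & !pub$.suppress)
      rows <- rows[order(pub$provenance[rows] != "counterfeit")]
      pub$.suppress[utils::head(rows, cc)] <- TRUE
    }
  }
  drop <- pub$.suppress & pub$provenance == "counterfeit"
  stopifnot(sum(drop) == sum(pub$provenance == "counterfeit"))
  out <- pub[!drop, , drop = FALSE]
  masked <- out$.suppress
  out$class_id[masked] <- NA_integer_
  for (a in qi) out[[a]][masked] <- "*"
  out <- out[, c("class_id", qi, sens)]
  rownames(out) <- NULL
  out
}

# display form of the anonymized table: class_id, formatted QI signatures,
# sensitive value and (in-memory only) provenance
published_table <- function(classes, schemas) {
  qi <- qi_names(schemas)
  sens <- sensitive_name(schemas)
  rows <- lapply(classes, function(cl) {
    n <- nrow(cl$members)
    df <- data.frame(class_id = rep(cl$class_id, n),
                     stringsAsFactors = FALSE)
    for (a in qi) df[[a]] <- rep(format(cl$signature[[a]]), n)
    df[[sens]] <- cl$members$sensitive
    df$provenance <- cl$members$provenance
    df$source_row <- cl$members$row
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
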