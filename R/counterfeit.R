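# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Insert counterfeit records to restore k-anonymity
#'
#' Every equivalence class that satisfies the ceiling but has fewer than `k`
#' members receives exactly `k - |members|` counterfeit records. A
#' counterfeit carries the class signature as its quasi-identifiers (so class
#' signatures and degrees are unchanged) and a sensitive value drawn with the
#' seeded generator: `"empirical"` draws from the whole table's
#' sensitive-value frequencies, `"uniform"` draws uniformly over the sensitive
#' domain. Classes already at or above `k` are untouched.
#'
#' @param classes list of `equivalence_class` objects (all members real).
#' @param k anonymity parameter, `k >= 2`.
#' @param schemas a `schema_set`.
#' @param strategy `"empirical"` (default) or `"uniform"`.
#' @param seed integer seed; a fixed seed makes the output bit-reproducible.
#' @param sensitive_domain optional character vector of admissible sensitive
#'   values; defaults to the values observed in `classes`.
#' @return a list with `classes` (members extended, counterfeit rows have
#'   `row = NA` and `provenance = "counterfeit"`) and `ledger`, a data.frame
#'   with one row per (class_id, sensitive value) insertion and its count.
#' @export
insert_counterfeits <- function(classes, k, schemas,
                                strategy = c("empirical", "uniform"),
                                seed = 1L, sensitive_domain = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(k >= 2)
  real_sens <- unlist(lapply(classes, function(cl) cl$members$sensitive))
  domain <- if (!is.null(sensitive_domain)) sensitive_domain
            else sort(unique(real_sens))
  probs <- if (strategy == "empirical") {
    tab <- table(factor(real_sens, levels = domain))
    as.numeric(tab) / sum(tab)
  } else {
    rep(1 / length(domain), length(domain))
  }
  ledger <- list()
  classes <- with_seed(seed, {
    lapply(classes, function(cl) {
      need <- k - nrow(cl$members)
      if (need <= 0) return(cl)
      drawn <- sample(domain, need, replace = TRUE, prob = probs)
      cl$members <- rbind(cl$members,
                          data.frame(row = NA_integer_, sensitive = drawn,
                                     provenance = "counterfeit",
                                     stringsAsFactors = FALSE))
      tab <- table(drawn)
      ledger[[length(ledger) + 1L]] <<- data.frame(
        class_id = cl$class_id, sensitive = names(tab),
        count = as.integer(tab), stringsAsFactors = FALSE)
      cl
    })
  })
  ledger <- if (length(ledger)) do.call(rbind, ledger)
            else data.frame(class_id = integer(0), sensitive = character(0),
                            count = integer(0), stringsAsFactors = FALSE)
  rownames(ledger) <- NULL
  list(classes = classes, ledger = ledger)
}
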