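#' Sweep utility metrics over k and h grids
#'
#' Runs the ceiling method for every (k, h) combination and, optionally, the
#' plain k-anonymity baseline for every k, collecting LM, DM, RCE and the
#' counterfeit total -- the desk-scale analogue of the experimental protocol
#' used to compare the two methods.
#'
#' @param table data.frame conforming to `schemas`.
#' @param schemas a `schema_set`.
#' @param k_grid integer vector of k values.
#' @param h_grid numeric vector of ceiling values.
#' @param seed master seed for counterfeit sampling.
#' @param strategy counterfeit sensitive-value strategy.
#' @param include_baseline also run [baseline_k_anonymize()] per k.
#' @return a data.frame with columns `method`, `k`, `h`, `lm`, `dm`, `rce`,
#'   `counterfeits`, `node`; rows where no feasible anonymization exists
#'   carry `NA` metrics.
#' @export
utility_sweep <- function(table, schemas, k_grid, h_grid, seed = 1L,
                          strategy = "empirical", include_baseline = TRUE) {
  rows <- list()
  push <- function(method, k, h, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, k = k, h = if (is.null(h)) NA_real_ else h,
      lm = if (is.null(res)) NA_real_ else res$metrics$lm,
      dm = if (is.null(res)) NA_real_ else res$metrics$dm,
      rce = if (is.null(res)) NA_real_ else res$metrics$rce,
      counterfeits = if (is.null(res)) NA_integer_ else sum(res$ledger$count),
      node = if (is.null(res)) NA_character_
             else paste(res$node, collapse = ","),
      stringsAsFactors = FALSE)
  }
  for (k in k_grid) {
    for (h in h_grid) {
      res <- tryCatch(anonymize(table, schemas, k = k, h = h,
                                strategy = strategy, seed = seed),
                      error = function(e) NULL)
      push("h_ceiling", k, h, res)
    }
    if (include_baseline) {
      res <- tryCatch(baseline_k_anonymize(table, schemas, k = k),
                      error = function(e) NULL)
      push("baseline", k, NULL, res)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
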