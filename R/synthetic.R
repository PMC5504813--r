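#' The seven-record demo EHR table and its schema
#'
#' A tiny original EHR table (name, age, sex, zipcode, disease) used
#' throughout the documentation and tests: three women in their 30s with
#' zipcodes around 22-23 thousand and four men in their 60s around 55
#' thousand, with diseases Pneumonia/Diabetes/Anemia. Age has domain
#' `[0, 99]` with level widths 1/5/10/20/100, zipcode `[1, 100000]` with
#' widths 1/100/1000/10000/100000, sex a two-leaf taxonomy under `*`.
#'
#' @return a list with `table` (7-row data.frame, identifier column `name`
#'   included) and `schemas` (a `schema_set` of 4 attributes, 3 of them
#'   quasi-identifiers).
#' @export
demo_ehr_fixture <- function() {
  table <- data.frame(
    name = c("Mary", "Alice", "Betsy", "David", "Tom", "James", "Eric"),
    age = c(37, 35, 36, 61, 63, 66, 62),
    sex = c("F", "F", "F", "M", "M", "M", "M"),
    zipcode = c(22071, 22098, 23061, 55107, 55099, 55324, 55229),
    disease = c("Pneumonia", "Diabetes", "Anemia", "Pneumonia", "Diabetes",
                "Diabetes", "Pneumonia"),
    stringsAsFactors = FALSE)
  schemas <- schema_set(list(
    name = attribute_schema("name", "identifier", "categorical"),
    age = attribute_schema("age", "quasi_identifier", "numeric",
                           domain = c(0, 99),
                           level_widths = c(1, 5, 10, 20, 100)),
    sex = attribute_schema("sex", "quasi_identifier", "categorical",
                           taxonomy = taxonomy_tree(list(
                             label = "*",
                             children = list(list(label = "M"),
                                             list(label = "F"))))),
    zipcode = attribute_schema("zipcode", "quasi_identifier", "numeric",
                               domain = c(1, 100000),
                               level_widths = c(1, 100, 1000, 10000, 100000)),
    disease = attribute_schema("disease", "sensitive", "categorical")))
  list(table = table, schemas = schemas)
}

#' Specification of a synthetic EHR-like table
#'
#' Describes the statistical structure the anonymization experiments assume:
#' numeric quasi-identifiers drawn from a mixture of clusters plus a fraction
#' of outliers scattered uniformly over the domain (outliers are what forces
#' plain k-anonymity to over-generalize), categorical quasi-identifiers with
#' given leaf probabilities, and a skewed categorical sensitive attribute.
#'
#' @param n_records number of rows to generate.
#' @param numeric_qis list of specs: each
#'   `list(name, domain, level_widths, cluster_means, cluster_sds,
#'   cluster_weights, outlier_frac)`.
#' @param categorical_qis list of specs: each `list(name, leaves, probs)`
#'   (a flat one-level taxonomy under root `"*"` is assumed).
#' @param sensitive `list(name, values, probs)`; the probabilities may be
#'   skewed.
#' @param seed integer seed used by [generate_table()].
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_records, numeric_qis, categorical_qis,
                           sensitive, seed = 1L) {
  chk_probs <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
      stop(sprintf("%s probabilities must be nonnegative and sum to 1", what),
           call. = FALSE)
  }
  for (q in numeric_qis) {
    chk_probs(q$cluster_weights, q$name)
    if (q$outlier_frac < 0 || q$outlier_frac >= 1)
      stop(sprintf("%s: outlier fraction must be in [0, 1)", q$name),
           call. = FALSE)
  }
  for (q in categorical_qis) chk_probs(q$probs, q$name)
  chk_probs(sensitive$probs, sensitive$name)
  structure(list(n_records = n_records, numeric_qis = numeric_qis,
                 categorical_qis = categorical_qis, sensitive = sensitive,
                 seed = seed),
            class = "synthetic_spec")
}

#' Default EHR-like synthetic spec
#'
#' Mirrors the shape of the demo table at scale: an age-like attribute with
#' two clusters (around 32 and 63) and 10% uniform outliers, a binary
#' sex-like attribute, a zipcode-like attribute with two tight clusters and
#' 5% uniform outliers, and a five-valued disease attribute with heavily
#' skewed frequencies.
#'
#' @param n_records number of rows (default 1000).
#' @param seed integer seed.
#' @return a [synthetic_spec()].
#' @export
default_ehr_spec <- function(n_records = 1000, seed = 1L) {
  synthetic_spec(
    n_records = n_records,
    numeric_qis = list(
      list(name = "age", domain = c(0, 99),
           level_widths = c(1, 5, 10, 20, 100),
           cluster_means = c(32, 63), cluster_sds = c(4, 5),
           cluster_weights = c(0.5, 0.5), outlier_frac = 0.10),
      list(name = "zipcode", domain = c(1, 100000),
           level_widths = c(1, 100, 1000, 10000, 100000),
           cluster_means = c(22500, 55200), cluster_sds = c(400, 250),
           cluster_weights = c(0.5, 0.5), outlier_frac = 0.05)),
    categorical_qis = list(
      list(name = "sex", leaves = c("M", "F"), probs = c(0.5, 0.5))),
    sensitive = list(name = "disease",
                     values = c("Pneumonia", "Diabetes", "Anemia", "Stroke",
                                "Leukemia"),
                     probs = c(0.55, 0.25, 0.12, 0.05, 0.03)),
    seed = seed)
}

#' Generate a synthetic table from a spec
#'
#' Seeded and reproducible: the same spec (including its seed) always yields
#' the same table. Numeric values are drawn from the cluster mixture, rounded
#' to the integer grid and clipped to the domain; the outlier fraction is
#' drawn uniformly over the whole domain.
#'
#' @param spec a [synthetic_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return a data.frame with one column per specified attribute.
#' @export
generate_table <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(seed)) seed <- spec$seed
  n <- spec$n_records
  with_seed(seed, {
    out <- list()
    for (q in spec$numeric_qis) {
      comp <- sample(seq_along(q$cluster_weights), n, replace = TRUE,
                     prob = q$cluster_weights)
      v <- round(stats::rnorm(n, q$cluster_means[comp], q$cluster_sds[comp]))
      is_out <- stats::runif(n) < q$outlier_frac
      v[is_out] <- round(stats::runif(sum(is_out), q$domain[1], q$domain[2]))
      out[[q$name]] <- pmin(pmax(v, q$domain[1]), q$domain[2])
    }
    for (q in spec$categorical_qis)
      out[[q$name]] <- sample(q$leaves, n, replace = TRUE, prob = q$probs)
    out[[spec$sensitive$name]] <- sample(spec$sensitive$values, n,
                                         replace = TRUE,
                                         prob = spec$sensitive$probs)
    as.data.frame(out, stringsAsFactors = FALSE)
  })
}

#' Schema set matching a synthetic spec
#'
#' @param spec a [synthetic_spec()].
#' @return a `schema_set` whose hierarchies match the spec's attributes.
#' @export
synthetic_schemas <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  schemas <- list()
  for (q in spec$numeric_qis)
    schemas[[q$name]] <- attribute_schema(q$name, "quasi_identifier",
                                          "numeric", domain = q$domain,
                                          level_widths = q$level_widths)
  for (q in spec$categorical_qis)
    schemas[[q$name]] <- attribute_schema(
      q$name, "quasi_identifier", "categorical",
      taxonomy = taxonomy_tree(list(
        label = "*",
        children = lapply(q$leaves, function(l) list(label = l)))))
  schemas[[spec$sensitive$name]] <-
    attribute_schema(spec$sensitive$name, "sensitive", "categorical")
  schema_set(schemas)
}
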