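#' Hypergeometric survival function P(X >= j)
#'
#' Probability of drawing at least `j` successes in `n` draws without
#' replacement from a population of `N` containing `K` successes. Edge
#' cases are exact: `j <= 0` gives 1 and `j > min(K, n)` gives 0. The
#' tail itself is delegated to [stats::phyper()].
#'
#' @param N Population size.
#' @param K Successes in the population (`0 <= K <= N`).
#' @param n Number of draws (`0 <= n <= N`).
#' @param j Observed successes.
#' @return P(X >= j) in `[0, 1]`.
#' @examples
#' hypergeom_sf(5, 2, 2, 1)  # 0.7
#' @export
hypergeom_sf <- function(N, K, n, j) {
  check_number(N, "N", lower = 0, integer = TRUE)
  check_number(K, "K", lower = 0, upper = N, integer = TRUE)
  check_number(n, "n", lower = 0, upper = N, integer = TRUE)
  check_number(j, "j", lower = -Inf, integer = TRUE)
  if (j <= 0) return(1)
  if (j > min(K, n)) return(0)
  stats::phyper(j - 1, K, N - K, n, lower.tail = FALSE)
}

#' Proportion of query-expressed instances with conserved expression
#'
#' The headline per-family statistic: of the instances expressed in the
#' query species, the fraction whose target-species ortholog is also
#' expressed. `NA` when nothing is expressed in the query.
#'
#' @param n_both Instances expressed in query whose ortholog is expressed
#'   in the target.
#' @param n_expressed_query Instances expressed in the query species.
#' @return Proportion in `[0, 1]`, or `NA` if `n_expressed_query == 0`.
#' @examples
#' round(conservation_proportion(20, 39), 2)  # 0.51
#' @export
conservation_proportion <- function(n_both, n_expressed_query) {
  ifelse(n_expressed_query > 0, n_both / n_expressed_query, NA_real_)
}

#' Summarise per-instance conservation/expression flags for one family
#'
#' Records must all belong to one family and one target species and carry
#' logical columns `expressed_query`, `lifted`, `te_annotated_in_target`,
#' `expressed_in_target`. An instance is *conserved* when it lifts and is
#' TE-annotated in the target. The summary feeds both the proportion
#' column and the hypergeometric test.
#'
#' @param records Per-instance flag data.frame.
#' @param family,te_class,target_species Optional labels (taken from the
#'   records when present).
#' @return One-row data.frame: `family`, `te_class`, `target_species`,
#'   `total`, `n_expressed_query`, `n_conserved`,
#'   `n_expr_query_conserved`, `n_target_expressed`, `n_both_expressed`,
#'   `proportion`.
#' @export
summarize_family <- function(records, family = NULL, te_class = NULL,
                             target_species = NULL) {
  pick <- function(given, col) {
    if (!is.null(given)) given
    else if (col %in% names(records) && nrow(records)) records[[col]][1L]
    else NA_character_
  }
  conserved <- records$lifted & records$te_annotated_in_target
  n_expr_q <- sum(records$expressed_query)
  n_both <- sum(records$expressed_query & conserved & records$expressed_in_target)
  out <- data.frame(
    family = pick(family, "family"),
    te_class = pick(te_class, "te_class"),
    target_species = pick(target_species, "target_species"),
    total = nrow(records),
    n_expressed_query = n_expr_q,
    n_conserved = sum(conserved),
    n_expr_query_conserved = sum(records$expressed_query & conserved),
    n_target_expressed = sum(conserved & records$expressed_in_target),
    n_both_expressed = n_both,
    proportion = conservation_proportion(n_both, n_expr_q),
    stringsAsFactors = FALSE
  )
  stopifnot(out$n_both_expressed <= min(out$n_expressed_query, out$n_target_expressed),
            out$n_target_expressed <= out$n_conserved,
            out$n_conserved <= out$total)
  out
}

#' Summaries for all (family, target species) groups
#'
#' @param records Per-instance flag data.frame with `family`, `te_class`,
#'   `target_species` columns and the flag columns of
#'   [summarize_family()].
#' @return data.frame of family summaries, one row per group.
#' @export
family_summaries <- function(records) {
  dt <- data.table::as.data.table(records)
  out <- dt[, {
    conserved <- lifted & te_annotated_in_target
    n_expr_q <- sum(expressed_query)
    n_both <- sum(expressed_query & conserved & expressed_in_target)
    list(total = .N,
         n_expressed_query = n_expr_q,
         n_conserved = sum(conserved),
         n_expr_query_conserved = sum(expressed_query & conserved),
         n_target_expressed = sum(conserved & expressed_in_target),
         n_both_expressed = n_both,
         proportion = conservation_proportion(n_both, n_expr_q))
  }, by = .(family, te_class, target_species)]
  as.data.frame(out)
}

#' Family filters for the enrichment table
#'
#' Defaults follow the analysis conventions: only large families
#' (`total >= 100`) from the four main repeat classes, with at least 30
#' query-expressed instances; simple repeats and low-complexity repeats
#' are excluded; `min_conserved` (>= 10) is applied where conservation
#' scatter plots are built.
#'
#' @param min_total Minimum family size.
#' @param min_expressed_query Minimum query-expressed instances.
#' @param min_conserved Minimum conserved instances (plotting sets).
#' @param class_whitelist TE classes retained.
#' @param exclude_classes Classes dropped regardless of size.
#' @return A list of class `enrichment_filters`.
#' @export
enrichment_filters <- function(min_total = 100, min_expressed_query = 30,
                               min_conserved = 10,
                               class_whitelist = c("DNA", "SINE", "LINE", "LTR"),
                               exclude_classes = c("Simple_repeat", "Low_complexity")) {
  check_number(min_total, "min_total", lower = 0)
  check_number(min_expressed_query, "min_expressed_query", lower = 0)
  check_number(min_conserved, "min_conserved", lower = 0)
  structure(list(min_total = min_total,
                 min_expressed_query = min_expressed_query,
                 min_conserved = min_conserved,
                 class_whitelist = class_whitelist,
                 exclude_classes = exclude_classes),
            class = "enrichment_filters")
}

#' Per-family enrichment table for one species pair
#'
#' Applies [enrichment_filters()], attaches the hypergeometric p-value
#' and sorts by conserved-expression proportion (descending), ties broken
#' by p-value then family name.
#'
#' The default test is restricted to the family's conserved instances:
#' population `N = n_conserved`, successes `K = n_target_expressed`,
#' draws `n = n_expr_query_conserved`, observed `j = n_both_expressed` —
#' the probability of seeing j or more target-expressed orthologs among
#' the query-expressed conserved instances under independence. Setting
#' `population = "all"` instead treats the whole family as the
#' population (`N = total`, `K = n_conserved`, `n = n_expressed_query`,
#' `j = n_expr_query_conserved`), testing whether expressed instances are
#' enriched for being conserved.
#'
#' @param summaries data.frame from [family_summaries()] (one target
#'   species).
#' @param filters An [enrichment_filters()] object.
#' @param population `"conserved"` (default) or `"all"`; see Details.
#' @param adjust If `TRUE`, add a Benjamini-Hochberg adjusted column.
#' @return Filtered, sorted data.frame with a `p_value` column.
#' @export
family_enrichment_table <- function(summaries, filters = enrichment_filters(),
                                    population = c("conserved", "all"),
                                    adjust = FALSE) {
  population <- match.arg(population)
  keep <- summaries$total >= filters$min_total &
    summaries$n_expressed_query >= filters$min_expressed_query &
    summaries$te_class %in% filters$class_whitelist &
    !summaries$te_class %in% filters$exclude_classes
  tab <- summaries[keep, , drop = FALSE]
  if (nrow(tab) == 0L) {
    tab$p_value <- numeric(0)
    return(tab)
  }
  tab$p_value <- vapply(seq_len(nrow(tab)), function(i) {
    with(tab[i, ], if (population == "conserved") {
      hypergeom_sf(n_conserved, n_target_expressed,
                   n_expr_query_conserved, n_both_expressed)
    } else {
      hypergeom_sf(total, n_conserved, n_expressed_query,
                    n_expr_query_conserved)
    })
  }, numeric(1))
  if (adjust) tab$p_adj <- stats::p.adjust(tab$p_value, method = "BH")
  ord <- order(-tab$proportion, tab$p_value, tab$family)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Combined conservation across target species
#'
#' Sums the both-expressed count of each family over all target species;
#' families missing from a species contribute 0 there. Used to rank the
#' most expression-conserved families overall.
#'
#' @param summaries data.frame of family summaries across multiple
#'   target species.
#' @param top_k Optionally keep only the top `k` families.
#' @return data.frame `family`, `te_class`, `combined_both_expressed`,
#'   sorted descending.
#' @export
combined_conservation <- function(summaries, top_k = NULL) {
  dt <- data.table::as.data.table(summaries)
  n_targets <- dt[, data.table::uniqueN(target_species)]
  miss <- dt[, .N, by = family][N < n_targets]
  if (nrow(miss)) {
    message(sprintf("%d families missing from some target species; treated as 0 there",
                    nrow(miss)))
  }
  out <- dt[, .(combined_both_expressed = sum(n_both_expressed)),
            by = .(family, te_class)]
  data.table::setorder(out, -combined_both_expressed, family)
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  as.data.frame(out)
}

#' Family age versus sequence conservation table
#'
#' Joins family ages (mean scaled similarity score) with the fraction of
#' a family's instances that are conserved in the target species, for
#' families with enough query-expressed instances. No fitting is done:
#' the table backs the age-conservation scatter where younger (higher
#' scoring) families show lower conserved fractions.
#'
#' @param ages data.frame from [family_ages()].
#' @param summaries Family summaries for one target species.
#' @param filters [enrichment_filters()]; only `min_expressed_query`
#'   is applied here.
#' @return data.frame `family`, `mean_scaled_score`, `total`,
#'   `n_conserved`, `lifted_fraction`.
#' @export
age_vs_conservation <- function(ages, summaries, filters = enrichment_filters()) {
  keep <- summaries$n_expressed_query >= filters$min_expressed_query &
    summaries$total > 0
  tab <- merge(summaries[keep, c("family", "total", "n_conserved")],
               ages[, c("family", "mean_scaled_score")], by = "family")
  tab$lifted_fraction <- tab$n_conserved / tab$total
  tab[order(tab$family), , drop = FALSE]
}
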