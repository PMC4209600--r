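#' Hypergeometric upper-tail p-value
#'
#' Probability of observing an overlap of `k` or more between a query list
#' of size `n` and a gene set of size `K` drawn from a universe of size
#' `N`: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Computed via
#' [stats::phyper()], which works in log space and is numerically stable
#' for extreme tails.
#'
#' @param k Observed overlap.
#' @param K Gene-set size.
#' @param n Query-list size.
#' @param N Universe size.
#' @return p-value in `(0, 1]`; `k = 0` always yields 1.
#' @examples
#' hypergeom_upper_tail(4, 5, 4, 10)  # 5 / choose(10, 4)
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(K > N) || any(n > N) || any(k > pmin(K, n)) || any(k < 0)) {
    stop("inconsistent counts: need 0 <= k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment via [stats::p.adjust()], with
#' input validation (p-values must lie in `(0, 1]`).
#'
#' @param p_values Numeric vector of p-values.
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1 | is.na(p_values))) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Build a gene-set collection over a universe
#'
#' Gene identifiers are matched case-insensitively (upper-cased at this
#' boundary); set members outside the universe are dropped, and sets left
#' empty are removed with a warning.
#'
#' @param sets Named list of character vectors of gene symbols (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of gene symbols, typically all genes
#'   with detectable expression in the counts table.
#' @return Object of class `gene_set_collection`: list with `sets`
#'   (restricted) and `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets),
            !anyDuplicated(names(sets)))
  universe <- unique(toupper(universe))
  sets <- lapply(sets, function(s) intersect(unique(toupper(s)), universe))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sum(empty), " gene set(s) empty after restriction to the universe; dropped",
            call. = FALSE)
    sets <- sets[!empty]
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene-set collection: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Over-representation test of one query list against a collection
#'
#' @param query Character vector of gene symbols; genes outside the
#'   universe are dropped (their number is messaged).
#' @param collection A [gene_set_collection()].
#' @return data.frame ranked by ascending p (ties: descending overlap
#'   `k`, then set name) with columns `set`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`.
#' @export
enrich_query <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(toupper(query))
  dropped <- sum(!query %in% collection$universe)
  if (dropped > 0) {
    message(dropped, " query gene(s) outside the universe dropped")
  }
  query <- intersect(query, collection$universe)
  N <- length(collection$universe)
  n <- length(query)
  empty <- data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    warning("query list empty after restriction to the universe", call. = FALSE)
    return(empty)
  }
  if (!length(collection$sets)) {
    warning("gene-set collection is empty", call. = FALSE)
    return(empty)
  }
  k <- vapply(collection$sets, function(s) length(intersect(s, query)), integer(1))
  K <- lengths(collection$sets)
  p <- hypergeom_upper_tail(k, K, n, N)
  out <- data.frame(set = names(collection$sets), k = as.integer(k),
                    K = as.integer(K), n = n, N = N,
                    p_value = p, q_value = bh_adjust(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -out$k, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank pathways for the three screen gene lists
#'
#' Runs [enrich_query()] for each of the up-regulated, down-regulated and
#' seed-containing gene lists, mirroring the three-column pathway view of
#' the screen.
#'
#' @param query_lists Named list with elements `up`, `down`,
#'   `seed_containing` (character vectors of gene symbols).
#' @param collection A [gene_set_collection()].
#' @return Named list of three ranked enrichment tables.
#' @export
rank_pathways <- function(query_lists, collection) {
  need <- c("up", "down", "seed_containing")
  if (!all(need %in% names(query_lists))) {
    stop("query_lists must contain ", paste(need, collapse = ", "), call. = FALSE)
  }
  lapply(query_lists[need], enrich_query, collection = collection)
}
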