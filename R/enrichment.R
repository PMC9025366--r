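# Hypergeometric over-representation of gene sets in a query DEG list.

#' One-sided hypergeometric over-representation test
#'
#' Tests whether a gene set overlaps a query list more than expected by chance
#' from a finite background: with `N` background genes of which `K` belong to
#' the set (after intersecting the set with the background) and a query of
#' `n` genes drawn from the background with `k` of them in the set, the
#' p-value is the inclusive upper tail `P(X >= k)` for `X` hypergeometric
#' (equivalently Fisher's one-sided exact test).
#'
#' @param query Character vector of query genes (no duplicates); must be a
#'   subset of `background`.
#' @param gene_set Character vector of set members; genes outside the
#'   background are ignored.
#' @param background Character vector: the gene universe actually examined
#'   (typically all protein-coding genes tested for differential expression).
#' @return One-row tibble: `k`, `K`, `n`, `N`, `p_value`, `overlap` (list
#'   column with the overlapping genes).
#' @export
#' @examples
#' hypergeom_test(letters[1:5], letters[c(1:4, 10)], letters[1:10])
hypergeom_test <- function(query, gene_set, background) {
  if (anyDuplicated(query)) abort("`query` contains duplicate genes")
  if (anyDuplicated(background)) abort("`background` contains duplicate genes")
  if (!all(query %in% background)) {
    abort("`query` must be contained in `background`")
  }
  set_bg <- intersect(unique(gene_set), background)
  overlap <- intersect(query, set_bg)
  k <- length(overlap)
  K <- length(set_bg)
  n <- length(query)
  N <- length(background)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(k = k, K = K, n = n, N = N, p_value = p,
         overlap = list(sort(overlap)))
}

#' Over-representation analysis across a gene-set collection
#'
#' Runs [hypergeom_test()] for every set with at least `min_set` members in
#' the background, adjusts p-values across the tested sets by
#' Benjamini-Hochberg, flags sets with `q_value < alpha` as enriched, and
#' sorts by ascending p-value.
#'
#' @inheritParams hypergeom_test
#' @param collection A `gene_set_collection` (see [read_gmt()]) or a named
#'   list of gene vectors.
#' @param min_set Minimum in-background set size for a set to be tested.
#' @param alpha Enrichment threshold on the q-value.
#' @return Tibble, one row per tested set: `set`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`, `enriched`, `overlap` (list column).
#' @export
enrich <- function(query, collection, background, min_set = 3L, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  if (length(collection) == 0) {
    inform("empty gene-set collection; nothing to test")
    return(tibble(set = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p_value = numeric(),
                  q_value = numeric(), enriched = logical(),
                  overlap = list()))
  }
  rows <- purrr::imap(collection, function(genes, nm) {
    K <- length(intersect(unique(genes), background))
    if (K < min_set) return(NULL)
    mutate(hypergeom_test(query, genes, background), set = nm)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    inform(paste("no gene set has at least", min_set, "background members"))
    return(tibble(set = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p_value = numeric(),
                  q_value = numeric(), enriched = logical(),
                  overlap = list()))
  }
  out %>%
    mutate(q_value = bh_adjust(.data$p_value),
           enriched = .data$q_value < alpha) %>%
    relocate("set") %>%
    arrange(.data$p_value, desc(.data$k), .data$set)
}

#' Dot plot of enrichment results
#'
#' @param result Tibble from [enrich()].
#' @param top Number of top sets (by p-value) to show.
#' @return A ggplot.
#' @export
plot_enrichment <- function(result, top = 15L) {
  df <- head(result, top)
  df$set <- factor(df$set, levels = rev(df$set))
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$q_value), .data$set,
                                   size = .data$k, colour = .data$enriched)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "-log10 q", y = NULL, size = "overlap")
}
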