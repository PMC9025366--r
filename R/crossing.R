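# Crossing the three DEG sets: Venn partition and trend-concordance labels.

TREND_LEVELS <- c("none", "unique", "ad_concordant", "ad_discordant",
                  "aging_concordant", "aging_discordant", "reversal",
                  "transient_concordant", "triple")

as_deg_tibble <- function(degs) {
  if (is.data.frame(degs)) return(degs)
  tabs <- lapply(degs, function(d) if (is.data.frame(d)) d else tidy(d))
  cmps <- unlist(lapply(tabs, function(d) unique(d$comparison)))
  if (anyDuplicated(cmps)) {
    abort("duplicate comparison names; the three DEG sets must be distinct")
  }
  bind_rows(tabs)
}

check_comparison_names <- function(comparisons) {
  bad <- setdiff(comparisons, names(COMPARISONS))
  if (length(bad) > 0) {
    abort(paste0("unknown comparison name(s): ", paste(bad, collapse = ", "),
                 "; expected ", paste(names(COMPARISONS), collapse = ", ")))
  }
}

# Pure classification of one membership/sign pattern. Membership order:
# YoungVsOld, OldVsOAD, YoungVsOAD; signs are +1/-1 (NA where absent).
trend_label <- function(in_yo, in_oo, in_ya, s_yo, s_oo, s_ya) {
  k <- in_yo + in_oo + in_ya
  if (k == 3) return("triple")
  if (k == 0) return("none")
  if (k == 1) return("unique")
  if (in_ya && in_oo) {
    return(if (s_ya == s_oo) "ad_concordant" else "ad_discordant")
  }
  if (in_ya && in_yo) {
    return(if (s_ya == s_yo) "aging_concordant" else "aging_discordant")
  }
  # shared by YoungVsOld and OldVsOAD
  if (s_yo != s_oo) "reversal" else "transient_concordant"
}

#' Classify every gene's trend pattern across the three comparisons
#'
#' Each gene's membership triple (significant in YoungVsOld? OldVsOAD?
#' YoungVsOAD?) and fold-change signs determine one archetype:
#' * shared by YoungVsOAD and OldVsOAD only: `ad_concordant` when the signs
#'   agree (the AD-attributable class), else `ad_discordant`;
#' * shared by YoungVsOAD and YoungVsOld only: `aging_concordant` /
#'   `aging_discordant` (the aging-attributable class);
#' * shared by YoungVsOld and OldVsOAD only: `reversal` when the signs are
#'   opposite (down with aging, back up with disease — the sphingolipid
#'   pattern), else `transient_concordant`;
#' * in all three: `triple`; in exactly one: `unique`; in none: `none`.
#'
#' Only the sign of the fold change matters; magnitudes are ignored.
#'
#' @param degs Output of [select_degs()] for the three comparisons, either
#'   row-bound into one tibble (`comparison`, `gene`, `sign`) or as a list of
#'   three such tibbles / `deg_result`s.
#' @param universe Optional gene universe; genes in it but in no DEG set are
#'   reported with archetype `none`.
#' @return A `trend_table` tibble: `gene`, membership flags `in_young_old`,
#'   `in_old_oad`, `in_young_oad`, the three signs, and `archetype`.
#' @export
#' @examples
#' degs <- tibble::tribble(
#'   ~comparison,  ~gene,   ~sign,
#'   "YoungVsOld", "CERS2", -1L,
#'   "OldVsOAD",   "CERS2",  1L
#' )
#' classify_trends(degs)
classify_trends <- function(degs, universe = NULL) {
  degs <- as_deg_tibble(degs)
  check_comparison_names(unique(degs$comparison))
  if (nrow(degs) > 0 && anyDuplicated(degs[c("comparison", "gene")])) {
    abort("a gene appears twice in the same DEG set")
  }
  genes <- union(unique(degs$gene), universe)
  lk <- function(cmp) {
    d <- degs[degs$comparison == cmp, ]
    setNames(d$sign, d$gene)[genes]
  }
  s_yo <- lk("YoungVsOld")
  s_oo <- lk("OldVsOAD")
  s_ya <- lk("YoungVsOAD")
  out <- tibble(
    gene = genes,
    in_young_old = !is.na(s_yo),
    in_old_oad = !is.na(s_oo),
    in_young_oad = !is.na(s_ya),
    sign_young_old = as.integer(s_yo),
    sign_old_oad = as.integer(s_oo),
    sign_young_oad = as.integer(s_ya)
  )
  labels <- if (nrow(out) == 0) character(0) else
    mapply(trend_label, out$in_young_old, out$in_old_oad, out$in_young_oad,
           out$sign_young_old, out$sign_old_oad, out$sign_young_oad)
  out$archetype <- factor(labels, levels = TREND_LEVELS)
  out <- arrange(out, .data$gene)
  class(out) <- c("trend_table", class(out))
  out
}

#' Venn partition of the three DEG sets
#'
#' Counts the seven regions of the three-set Venn diagram: genes exclusive to
#' each comparison, each pairwise-only intersection, and the triple
#' intersection. The counts sum to the size of the union.
#'
#' @inheritParams classify_trends
#' @return Tibble (`region`, `n`) with seven rows.
#' @export
venn_partition <- function(degs) {
  tt <- classify_trends(degs)
  count_region <- function(yo, oo, ya) {
    sum(tt$in_young_old == yo & tt$in_old_oad == oo & tt$in_young_oad == ya)
  }
  tibble(
    region = c("YoungVsOld_only", "OldVsOAD_only", "YoungVsOAD_only",
               "YoungVsOld_and_OldVsOAD", "YoungVsOld_and_YoungVsOAD",
               "OldVsOAD_and_YoungVsOAD", "all_three"),
    n = c(count_region(TRUE, FALSE, FALSE),
          count_region(FALSE, TRUE, FALSE),
          count_region(FALSE, FALSE, TRUE),
          count_region(TRUE, TRUE, FALSE),
          count_region(TRUE, FALSE, TRUE),
          count_region(FALSE, TRUE, TRUE),
          count_region(TRUE, TRUE, TRUE))
  )
}

#' Summarize a trend table into per-archetype gene lists
#'
#' @param table A `trend_table` from [classify_trends()].
#' @return A `trend_report` list: `summary` (tibble `archetype`, `n`, one row
#'   per archetype level), `genes` (the full trend table) and `gene_lists`
#'   (named list of gene vectors per archetype).
#' @export
trend_report <- function(table) {
  lists <- split(table$gene, table$archetype)
  summary <- tibble(
    archetype = factor(TREND_LEVELS, levels = TREND_LEVELS),
    n = as.integer(lengths(lists)[TREND_LEVELS])
  )
  structure(list(summary = summary, genes = table, gene_lists = lists),
            class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat("Trend report over", nrow(x$genes), "genes\n")
  print(as.data.frame(x$summary[x$summary$n > 0, ]), row.names = FALSE)
  invisible(x)
}

#' Write a trend report to tab-separated files
#'
#' Writes `<stem>_genes.tsv` (per-gene memberships, signs, archetype) and
#' `<stem>_summary.tsv` (archetype counts).
#'
#' @param report A `trend_report`.
#' @param stem Output path stem.
#' @export
write_trend_report <- function(report, stem) {
  genes <- as.data.frame(report$genes)
  genes$archetype <- as.character(genes$archetype)
  write.table(genes, paste0(stem, "_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(report$summary), paste0(stem, "_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' Bar chart of archetype counts
#'
#' @param object A `trend_table`.
#' @param ... Unused.
#' @export
autoplot.trend_table <- function(object, ...) {
  df <- as_tibble(object) %>% dplyr::count(.data$archetype)
  ggplot2::ggplot(df, ggplot2::aes(.data$archetype, .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
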