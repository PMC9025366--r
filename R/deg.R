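#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: for each sample, the median over genes
#' of the ratio between the gene's count and its geometric mean across all
#' samples. Only genes with strictly positive counts in every sample enter the
#' median (the geometric mean must be positive). Strict mode: if no such gene
#' exists the function errors rather than falling back to a pseudo-reference.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Named positive numeric vector, one factor per sample.
#' @export
#' @examples
#' m <- rbind(g1 = c(10, 20), g2 = c(20, 40), g3 = c(30, 60))
#' colnames(m) <- c("a", "b")
#' size_factors(m)  # c(1, 2) / sqrt(2)
size_factors <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    abort(paste("no gene has positive counts in every sample;",
                "median-of-ratios is undefined in strict mode"))
  }
  loggeo <- rowMeans(log(counts[ok, , drop = FALSE]))
  sf <- apply(counts[ok, , drop = FALSE], 2, function(col) {
    median(exp(log(col) - loggeo))
  })
  setNames(as.numeric(sf), colnames(counts))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR q-values: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1 and mapped back to the
#' input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no missing values")
  }
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

#' Define a two-cohort comparison
#'
#' The three study comparisons are `YoungVsOld` (reference Young, test Old),
#' `OldVsOAD` (reference Old, test OAD) and `YoungVsOAD` (reference Young,
#' test OAD). Fold changes are always oriented `log2(test / reference)` with
#' the reference the younger / healthier cohort named first.
#'
#' @param name Comparison name.
#' @param reference,test Cohort labels; filled in automatically for the three
#'   standard names.
#' @return A `comparison_spec` list.
#' @export
comparison_spec <- function(name, reference = NULL, test = NULL) {
  if (is.null(reference) || is.null(test)) {
    if (!name %in% names(COMPARISONS)) {
      abort_config(paste0("unknown comparison '", name,
                          "'; give `reference` and `test` explicitly"))
    }
    return(structure(COMPARISONS[[name]], class = "comparison_spec"))
  }
  if (identical(reference, test)) abort_config("reference and test cohorts must differ")
  structure(list(name = name, reference = reference, test = test),
            class = "comparison_spec")
}

# Method-of-moments dispersion on normalized counts, pooled across the two
# groups with df weights; raw estimate (v - m * mean(1/s)) / m^2 since
# var(K/s) = mu/s + alpha * mu^2. Clamped to [1e-8, 10].
estimate_dispersion <- function(counts, sf, is_test) {
  norm <- sweep(counts, 2, sf, "/")
  mom_group <- function(cols) {
    k <- norm[, cols, drop = FALSE]
    ng <- ncol(k)
    m <- rowMeans(k)
    v <- rowSums((k - m)^2) / (ng - 1)
    est <- (v - m * mean(1 / sf[cols])) / m^2
    est[m == 0] <- NA_real_
    list(est = est, w = ng - 1)
  }
  g0 <- mom_group(!is_test)
  g1 <- mom_group(is_test)
  est <- cbind(g0$est, g1$est)
  w <- c(g0$w, g1$w)
  pooled <- apply(est, 1, function(e) {
    keep <- !is.na(e)
    if (!any(keep)) return(NA_real_)
    sum(e[keep] * w[keep]) / sum(w[keep])
  })
  pmin(pmax(pooled, 1e-8), 10)
}

# Vectorized IRLS for the per-gene NB GLM  mu_ij = s_j * exp(b0 + b1 * x_j)
# with log link and known dispersion alpha_g; returns Wald statistics.
fit_nb_glm <- function(Y, x, sf, alpha, max_iter = 100L, tol = 1e-8) {
  G <- nrow(Y)
  n <- ncol(Y)
  off <- matrix(log(sf), G, n, byrow = TRUE)
  is_test <- x == 1
  norm <- sweep(Y, 2, sf, "/")
  m0 <- rowMeans(norm[, !is_test, drop = FALSE])
  m1 <- rowMeans(norm[, is_test, drop = FALSE])
  beta0 <- log(pmax(m0, 1e-3))
  beta1 <- log(pmax(m1, 1e-3)) - beta0

  size_vec <- ifelse(alpha > 0, 1 / alpha, Inf)
  loglik <- function(mu) {
    ll <- matrix(NA_real_, G, n)
    fin <- is.finite(size_vec)
    if (any(fin)) {
      ll[fin, ] <- dnbinom(Y[fin, , drop = FALSE],
                           mu = mu[fin, , drop = FALSE],
                           size = rep(size_vec[fin], n), log = TRUE)
    }
    if (any(!fin)) {
      ll[!fin, ] <- dpois(Y[!fin, , drop = FALSE],
                          lambda = mu[!fin, , drop = FALSE], log = TRUE)
    }
    rowSums(ll)
  }

  eta <- pmin(pmax(beta0 + tcrossprod(beta1, x) + off, -30), 30)
  mu <- exp(eta)
  ll_old <- loglik(mu)
  converged <- rep(FALSE, G)
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (Y - mu) / mu
    wz <- w * z
    sw0 <- rowSums(w[, !is_test, drop = FALSE])
    sw1 <- rowSums(w[, is_test, drop = FALSE])
    swz0 <- rowSums(wz[, !is_test, drop = FALSE])
    swz1 <- rowSums(wz[, is_test, drop = FALSE])
    beta0 <- swz0 / sw0
    beta1 <- swz1 / sw1 - beta0
    eta <- pmin(pmax(beta0 + tcrossprod(beta1, x) + off, -30), 30)
    mu <- exp(eta)
    ll <- loglik(mu)
    converged <- 2 * abs(ll - ll_old) < tol  # absolute change in deviance
    ll_old <- ll
    if (all(converged)) break
  }
  w <- mu / (1 + alpha * mu)
  sw0 <- rowSums(w[, !is_test, drop = FALSE])
  sw1 <- rowSums(w[, is_test, drop = FALSE])
  se <- sqrt(1 / sw0 + 1 / sw1)
  list(beta0 = beta0, beta1 = beta1, se = se, converged = converged)
}

#' Negative-binomial Wald test for one two-cohort comparison
#'
#' Normalizes the comparison's samples by median-of-ratios size factors,
#' estimates a per-gene dispersion by method of moments on normalized counts
#' (pooled within cohorts, clamped to \[1e-8, 10\]), fits the per-gene NB GLM
#' `mu = s_j * exp(b0 + b1 * [test cohort])` by IRLS (at most 100 iterations,
#' log-likelihood tolerance 1e-8) and reports the two-sided Wald test on `b1`
#' with `log2_fc = b1 / ln 2` and BH q-values over all tested genes. Genes
#' with zero counts in every sample of the comparison, or whose fit does not
#' converge, are flagged untested and excluded from the BH family. No
#' dispersion or fold-change shrinkage, no outlier handling, no independent
#' filtering.
#'
#' @param counts Integer count matrix, genes x samples.
#' @param samples Sample sheet tibble (`sample_id`, `cohort`).
#' @param comparison A comparison name (`"YoungVsOld"`, `"OldVsOAD"`,
#'   `"YoungVsOAD"`) or a [comparison_spec()].
#' @param dispersion Optional fixed dispersion (single non-negative value)
#'   overriding the per-gene estimate; `0` gives the Poisson limit.
#' @param max_iter,tol IRLS iteration cap and log-likelihood tolerance.
#'
#' @return A `deg_result`; see [tidy.deg_result()] for the per-gene table.
#' @export
#' @examples
#' sim <- simulate_counts(cohort_design(n_genes = 200), seed = 7)
#' res <- deg_test(sim$counts, sim$samples, "YoungVsOld")
#' glance(res)
deg_test <- function(counts, samples, comparison,
                     dispersion = NULL, max_iter = 100L, tol = 1e-8) {
  if (!inherits(comparison, "comparison_spec")) {
    comparison <- comparison_spec(comparison)
  }
  keep <- samples$cohort %in% c(comparison$reference, comparison$test)
  sub <- samples[keep, , drop = FALSE]
  n_ref <- sum(sub$cohort == comparison$reference)
  n_test <- sum(sub$cohort == comparison$test)
  if (n_ref < 2 || n_test < 2) {
    abort(paste0("comparison ", comparison$name,
                 ": both cohorts must be present with at least 2 samples"))
  }
  if (!all(sub$sample_id %in% colnames(counts))) {
    abort("sample sheet contains samples absent from the count matrix")
  }
  Y <- counts[, sub$sample_id, drop = FALSE]
  x <- as.numeric(sub$cohort == comparison$test)

  sf <- size_factors(Y)
  tested <- rowSums(Y) > 0
  Yt <- Y[tested, , drop = FALSE]

  if (is.null(dispersion)) {
    alpha <- estimate_dispersion(Yt, sf, x == 1)
    alpha[is.na(alpha)] <- 1e-8
  } else {
    if (length(dispersion) != 1 || dispersion < 0) {
      abort("`dispersion` override must be a single non-negative value")
    }
    alpha <- rep(as.numeric(dispersion), nrow(Yt))
  }

  fit <- fit_nb_glm(Yt, x, sf, alpha, max_iter = max_iter, tol = tol)
  base_mean <- rowMeans(sweep(Y, 2, sf, "/"))

  G <- nrow(Y)
  log2_fc <- lfc_se <- stat <- p <- rep(NA_real_, G)
  ok <- which(tested)[fit$converged]
  log2_fc[ok] <- (fit$beta1 / log(2))[fit$converged]
  lfc_se[ok] <- (fit$se / log(2))[fit$converged]
  stat[ok] <- (fit$beta1 / fit$se)[fit$converged]
  p[ok] <- 2 * pnorm(-abs(stat[ok]))
  q <- rep(NA_real_, G)
  q[ok] <- bh_adjust(p[ok])

  disp_full <- rep(NA_real_, G)
  disp_full[tested] <- alpha

  table <- tibble(
    gene = rownames(Y),
    base_mean = base_mean,
    log2_fc = log2_fc,
    lfc_se = lfc_se,
    stat = stat,
    p_value = p,
    q_value = q,
    dispersion = disp_full,
    tested = seq_len(G) %in% ok
  )
  n_nonconv <- sum(tested) - sum(fit$converged)
  if (n_nonconv > 0) {
    inform(paste0(comparison$name, ": ", n_nonconv,
                  " gene(s) did not converge and were flagged untested"))
  }
  structure(
    list(table = table, comparison = comparison$name,
         reference = comparison$reference, test = comparison$test,
         n_ref = n_ref, n_test = n_test, size_factors = sf),
    class = "deg_result"
  )
}

#' @export
print.deg_result <- function(x, ...) {
  cat("NB Wald differential expression:", x$comparison,
      sprintf("(%s n=%d vs %s n=%d)\n", x$reference, x$n_ref, x$test, x$n_test))
  cat(sum(x$table$tested), "of", nrow(x$table), "genes tested;",
      sum(x$table$q_value < 0.05, na.rm = TRUE), "with q < 0.05\n")
  invisible(x)
}

#' Tidy a differential-expression result
#'
#' @param x A `deg_result`.
#' @param ... Unused.
#' @return Per-gene tibble: `gene`, `base_mean`, `log2_fc`, `lfc_se`, `stat`,
#'   `p_value`, `q_value`, `dispersion`, `tested`.
#' @export
tidy.deg_result <- function(x, ...) x$table

#' One-row summary of a differential-expression result
#'
#' @param x A `deg_result`.
#' @param ... Unused.
#' @export
glance.deg_result <- function(x, ...) {
  tibble(
    comparison = x$comparison,
    n_genes = nrow(x$table),
    n_tested = sum(x$table$tested),
    n_q05 = sum(x$table$q_value < 0.05, na.rm = TRUE),
    n_ref = x$n_ref,
    n_test = x$n_test
  )
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `deg_result`.
#' @param alpha Significance threshold drawn on the q-value scale.
#' @param ... Unused.
#' @export
autoplot.deg_result <- function(object, alpha = 0.05, ...) {
  df <- dplyr::filter(tidy(object), .data$tested)
  df$significant <- !is.na(df$q_value) & df$q_value < alpha
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fc, -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = object$comparison,
                  colour = paste0("q < ", alpha))
}

#' Select differentially expressed genes
#'
#' Keeps genes with `q_value` strictly below `alpha` (a gene at exactly
#' `alpha` is excluded) that are annotated protein-coding, and tags each with
#' the sign of its log2 fold change. Genes missing from the annotation are
#' treated as non-coding with a warning.
#'
#' @param result A `deg_result` (or its tidy tibble with a `comparison`
#'   attribute).
#' @param annotation Tibble with columns `gene`, `protein_coding`.
#' @param alpha Significance threshold on the q-value; default 0.05.
#' @return Tibble (`comparison`, `gene`, `log2_fc`, `q_value`, `sign`), one
#'   row per retained DEG.
#' @export
select_degs <- function(result, annotation, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  tab <- tidy(result)
  missing <- setdiff(tab$gene, annotation$gene)
  if (length(missing) > 0) {
    warn(paste0(length(missing),
                " gene(s) absent from the annotation; treated as non-coding"))
  }
  coding <- annotation$gene[annotation$protein_coding]
  out <- tab %>%
    filter(.data$tested, !is.na(.data$q_value), .data$q_value < alpha,
           .data$gene %in% coding) %>%
    mutate(comparison = result$comparison,
           sign = as.integer(sign(.data$log2_fc))) %>%
    select("comparison", "gene", "log2_fc", "q_value", "sign")
  out
}
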