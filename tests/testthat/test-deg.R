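# Normalization, BH, NB Wald test and DEG selection.

test_that("size factors follow the median-of-ratios definition", {
  # identical columns -> unit factors
  m <- cbind(a = c(5L, 8L, 12L), b = c(5L, 8L, 12L))
  expect_equal(size_factors(m), c(a = 1, b = 1))

  # hand computation: one column doubled -> factors (1, 2)/sqrt(2)
  m2 <- cbind(a = c(10L, 20L, 30L), b = c(20L, 40L, 60L))
  expect_equal(size_factors(m2), c(a = 1 / sqrt(2), b = sqrt(2)),
               tolerance = 1e-12)

  # scale equivariance: multiplying one sample by 4 multiplies its factor by 4
  m3 <- matrix(rpois(50 * 4, 60), 50, 4,
               dimnames = list(NULL, paste0("s", 1:4)))
  sf <- size_factors(m3)
  m4 <- m3
  m4[, 2] <- m4[, 2] * 4L
  sf4 <- size_factors(m4)
  expect_equal(sf4[2], 4 * sf[2] * (sf4[1] / sf[1]), tolerance = 1e-9)
  expect_equal(unname(sf4[c(1, 3, 4)] / sf[c(1, 3, 4)]),
               rep(unname(sf4[1] / sf[1]), 3), tolerance = 1e-9)

  # strict mode: no gene positive everywhere
  m5 <- cbind(a = c(0L, 5L), b = c(5L, 0L))
  expect_error(size_factors(m5), "strict")
})

test_that("BH adjustment matches hand values and the definitional oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "\\[0, 1\\]")

  set.seed(101)
  for (i in 1:100) {
    m <- sample(1:20, 1)
    p <- round(runif(m), 3)  # ties exercised
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }

  # permutation equivariance
  set.seed(7)
  p <- runif(15)
  perm <- sample(15)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("a gene with identical counts in both cohorts gets lfc 0 and p 1", {
  counts <- rbind(
    flat = c(10L, 14L, 9L, 10L, 14L, 9L),
    other = c(30L, 35L, 28L, 30L, 35L, 28L)
  )
  colnames(counts) <- c("Young_1", "Young_2", "Young_3", "Old_1", "Old_2", "Old_3")
  samples <- tiny_samples(3, 3, 0)[, c("sample_id", "cohort")]
  samples <- samples[samples$cohort != "OAD", ]
  res <- deg_test(counts, samples, "YoungVsOld", dispersion = 0.05)
  tab <- tidy(res)
  flat <- tab[tab$gene == "flat", ]
  expect_equal(flat$log2_fc, 0, tolerance = 1e-10)
  expect_equal(flat$p_value, 1, tolerance = 1e-10)
})

test_that("in the dispersion-zero limit the Wald test matches a Poisson GLM oracle", {
  set.seed(33)
  n_per <- 6
  counts <- matrix(rnbinom(40 * 2 * n_per, mu = 80, size = 10), nrow = 40)
  colnames(counts) <- c(paste0("Young_", 1:n_per), paste0("Old_", 1:n_per))
  rownames(counts) <- paste0("g", 1:40)
  samples <- tibble::tibble(sample_id = colnames(counts),
                            cohort = rep(c("Young", "Old"), each = n_per))
  res <- deg_test(counts, samples, "YoungVsOld", dispersion = 0)
  tab <- tidy(res)

  sf <- size_factors(counts)
  x <- rep(c(0, 1), each = n_per)
  for (i in seq_len(nrow(counts))) {
    fit <- stats::glm(counts[i, ] ~ x, family = stats::poisson(),
                      offset = log(sf),
                      control = stats::glm.control(epsilon = 1e-12))
    sm <- summary(fit)$coefficients
    expect_lt(abs(tab$log2_fc[i] - sm["x", "Estimate"] / log(2)), 1e-6)
    expect_lt(abs(tab$p_value[i] - sm["x", "Pr(>|z|)"]), 1e-6)
  }
})

test_that("the NB Wald test recovers a planted fold change", {
  set.seed(55)
  n_per <- 20
  mu <- c(ref = 100, test = 100 * 2^2)
  counts <- rbind(
    sig = c(rnbinom(n_per, mu = mu["ref"], size = 10),
            rnbinom(n_per, mu = mu["test"], size = 10)),
    matrix(rnbinom(30 * 2 * n_per, mu = 100, size = 10), nrow = 30)
  )
  rownames(counts) <- c("sig", paste0("null", 1:30))
  colnames(counts) <- c(paste0("Young_", 1:n_per), paste0("Old_", 1:n_per))
  samples <- tibble::tibble(sample_id = colnames(counts),
                            cohort = rep(c("Young", "Old"), each = n_per))
  res <- deg_test(counts, samples, "YoungVsOld")
  tab <- tidy(res)
  expect_lt(abs(tab$log2_fc[tab$gene == "sig"] - 2), 0.3)
  expect_lt(tab$q_value[tab$gene == "sig"], 0.05)
})

test_that("swapping reference and test negates fold changes and keeps p-values", {
  sim <- simulate_counts(cohort_design(n_genes = 150), default_archetypes(),
                         seed = 17)
  fwd <- deg_test(sim$counts, sim$samples, "YoungVsOld")
  rev <- deg_test(sim$counts, sim$samples,
                  comparison_spec("OldVsYoung", reference = "Old", test = "Young"))
  ft <- tidy(fwd)
  rt <- tidy(rev)
  ok <- ft$tested & rt$tested
  expect_gt(mean(ok), 0.95)
  expect_equal(ft$log2_fc[ok], -rt$log2_fc[ok], tolerance = 1e-6)
  expect_equal(ft$p_value[ok], rt$p_value[ok], tolerance = 1e-6)
})

test_that("rescaling one sample's library leaves fold changes nearly unchanged", {
  sim <- simulate_counts(cohort_design(n_genes = 300), default_archetypes(),
                         seed = 23)
  base <- tidy(deg_test(sim$counts, sim$samples, "OldVsOAD"))
  scaled <- sim$counts
  scaled[, "OAD_1"] <- scaled[, "OAD_1"] * 3L
  res <- tidy(deg_test(scaled, sim$samples, "OldVsOAD"))
  ok <- base$tested & res$tested
  expect_true(all(abs(base$log2_fc[ok] - res$log2_fc[ok]) < 0.05))
})

test_that("zero-count genes are excluded from testing and the BH family", {
  counts <- rbind(
    zero = rep(0L, 6),
    g1 = c(10L, 12L, 9L, 50L, 60L, 52L),
    g2 = c(20L, 22L, 19L, 21L, 20L, 22L)
  )
  colnames(counts) <- c(paste0("Young_", 1:3), paste0("Old_", 1:3))
  samples <- tibble::tibble(sample_id = colnames(counts),
                            cohort = rep(c("Young", "Old"), each = 3))
  tab <- tidy(deg_test(counts, samples, "YoungVsOld", dispersion = 0.02))
  expect_false(tab$tested[tab$gene == "zero"])
  expect_true(is.na(tab$p_value[tab$gene == "zero"]))
  expect_true(is.na(tab$q_value[tab$gene == "zero"]))
  # BH family = the two tested genes only
  p <- tab$p_value[tab$tested]
  expect_equal(sort(tab$q_value[tab$tested]), sort(bh_adjust(p)))
})

test_that("deg_test validates cohorts and comparison names", {
  sim <- simulate_counts(cohort_design(n_genes = 20), list(), seed = 1)
  no_old <- sim$samples[sim$samples$cohort != "Old", ]
  expect_error(deg_test(sim$counts, no_old, "YoungVsOld"), "at least 2")
  expect_error(comparison_spec("Nonsense"), "unknown comparison")
  expect_error(comparison_spec("X", "Young", "Young"), "differ")
})

test_that("select_degs applies the strict threshold and the coding filter", {
  tab <- tibble::tibble(
    gene = paste0("g", 1:10),
    base_mean = 10, log2_fc = rep(c(1, -1), 5), lfc_se = 0.1, stat = 1,
    p_value = 0.01,
    q_value = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.2, 0.3, 0.5, 0.9, 1),
    dispersion = 0.05,
    tested = TRUE
  )
  res <- structure(list(table = tab, comparison = "YoungVsOld"),
                   class = "deg_result")
  ann <- tibble::tibble(gene = paste0("g", 1:10),
                        protein_coding = c(TRUE, FALSE, rep(TRUE, 8)))

  out <- select_degs(res, ann, alpha = 0.05)
  # 4 genes with q < 0.05, one of them non-coding -> 3 kept;
  # q = 0.05 exactly is excluded (strict "lower than")
  expect_setequal(out$gene, c("g1", "g3", "g4"))
  expect_equal(out$sign, c(1L, 1L, -1L))

  # missing annotation -> treated non-coding, with a warning
  expect_warning(out2 <- select_degs(res, ann[-1, ], alpha = 0.05),
                 "non-coding")
  expect_setequal(out2$gene, c("g3", "g4"))

  # empty result -> empty set
  res0 <- structure(list(table = tab[0, ], comparison = "YoungVsOld"),
                    class = "deg_result")
  expect_equal(nrow(select_degs(res0, ann)), 0)

  expect_error(select_degs(res, ann, alpha = 1), "alpha")
})

test_that("glance and tidy expose the fit summary", {
  sim <- simulate_counts(cohort_design(n_genes = 60), default_archetypes(),
                         seed = 5)
  res <- deg_test(sim$counts, sim$samples, "YoungVsOAD")
  g <- glance(res)
  expect_equal(g$comparison, "YoungVsOAD")
  expect_equal(g$n_genes, 60)
  expect_lte(g$n_tested, 60)
  tab <- tidy(res)
  ok <- !is.na(tab$q_value)
  expect_true(all(tab$q_value[ok] >= tab$p_value[ok]))
})
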