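#' Describe a three-cohort RNA-seq design
#'
#' Captures the study layout the simulator emulates: a Young, an Old and an
#' Old-with-AD (OAD) cohort profiled by bulk RNA-seq, with negative-binomial
#' count noise and log-normal baseline expression. Defaults follow the
#' reference design of 8 Young, 10 Old and 12 OAD brains.
#'
#' @param group_sizes Named integer vector with names exactly
#'   `Young`, `Old`, `OAD`; every cohort needs at least 2 samples.
#' @param n_genes Number of genes to simulate.
#' @param mean_log_location,mean_log_scale Location and scale of the log-normal
#'   baseline mean distribution (natural-log units); means are truncated below
#'   at 1.
#' @param dispersion Negative-binomial dispersion alpha (variance
#'   `mu + alpha * mu^2`); a single positive value shared by all genes.
#' @param size_factor_range Range of the uniform per-sample library-size
#'   factors multiplied into the means, so normalization is exercised.
#'
#' @return A `cohort_design` list.
#' @export
#' @examples
#' cohort_design(n_genes = 100)
cohort_design <- function(group_sizes = c(Young = 8L, Old = 10L, OAD = 12L),
                          n_genes = 3000L,
                          mean_log_location = log(200),
                          mean_log_scale = 1,
                          dispersion = 0.05,
                          size_factor_range = c(0.7, 1.4)) {
  if (!setequal(names(group_sizes), COHORTS)) {
    abort_config("`group_sizes` must be named exactly Young, Old, OAD")
  }
  group_sizes <- group_sizes[COHORTS]
  if (any(group_sizes < 2)) {
    abort_config("every cohort needs at least 2 samples (two-group tests need replication)")
  }
  if (n_genes < 1) abort_config("`n_genes` must be a positive integer")
  if (!is.finite(dispersion) || dispersion <= 0) {
    abort_config("`dispersion` must be a positive real")
  }
  if (mean_log_scale < 0 || !is.finite(mean_log_location)) {
    abort_config("baseline mean parameters must be finite with non-negative scale")
  }
  if (length(size_factor_range) != 2 || any(size_factor_range <= 0) ||
      diff(size_factor_range) < 0) {
    abort_config("`size_factor_range` must be an increasing pair of positive reals")
  }
  structure(
    list(
      group_sizes = setNames(as.integer(group_sizes), COHORTS),
      n_genes = as.integer(n_genes),
      mean_log_location = mean_log_location,
      mean_log_scale = mean_log_scale,
      dispersion = dispersion,
      size_factor_range = size_factor_range
    ),
    class = "cohort_design"
  )
}

#' Specify a planted expression archetype
#'
#' An archetype fixes the two cohort shifts of a gene class, in log2 units:
#' `lfc_aging` moves Old (and OAD) relative to Young, `lfc_ad` moves OAD
#' relative to Old. The cohort means are
#' `mean_Old = mean_Young * 2^lfc_aging` and
#' `mean_OAD = mean_Young * 2^(lfc_aging + lfc_ad)`, so
#' * `aging_concordant` (`lfc_ad = 0`) shifts Old and OAD equally vs Young,
#' * `ad_concordant` (`lfc_aging = 0`) shifts OAD identically vs Young and Old,
#' * `reversal` requires opposite nonzero signs: down with aging, back up with
#'   disease (the CERS2/UGT8/PLPP2 pattern).
#'
#' @param archetype One of `"null"`, `"aging_concordant"`, `"ad_concordant"`,
#'   `"reversal"`.
#' @param fraction Fraction of genes planted with this archetype.
#' @param lfc_aging,lfc_ad Log2 fold changes (see above).
#'
#' @return An `archetype_spec` list.
#' @export
#' @examples
#' archetype_spec("reversal", 0.05, lfc_aging = -1.5, lfc_ad = 1.2)
archetype_spec <- function(archetype, fraction, lfc_aging = 0, lfc_ad = 0) {
  archetype <- arg_match(archetype,
                         c("null", "aging_concordant", "ad_concordant", "reversal"))
  if (fraction < 0 || fraction > 1) abort_config("`fraction` must lie in [0, 1]")
  ok <- switch(archetype,
    null = lfc_aging == 0 && lfc_ad == 0,
    aging_concordant = lfc_ad == 0 && lfc_aging != 0,
    ad_concordant = lfc_aging == 0 && lfc_ad != 0,
    reversal = lfc_aging != 0 && lfc_ad != 0 &&
      sign(lfc_aging) != sign(lfc_ad)
  )
  if (!ok) {
    abort_config(paste0("log fold changes are inconsistent with archetype '",
                        archetype, "'"))
  }
  structure(list(archetype = archetype, fraction = fraction,
                 lfc_aging = lfc_aging, lfc_ad = lfc_ad),
            class = "archetype_spec")
}

#' Default planted archetypes
#'
#' 5% reversal genes (down 1.5 log2 units with aging, up 1.2 with disease,
#' magnitudes in the range of the sphingolipid genes), 5% aging-concordant
#' (down 0.85, the steroid-biosynthesis range) and 5% AD-concordant (up 0.8);
#' the remaining 85% of genes are null.
#'
#' @return List of [archetype_spec()] objects.
#' @export
default_archetypes <- function() {
  list(
    archetype_spec("reversal", 0.05, lfc_aging = -1.5, lfc_ad = 1.2),
    archetype_spec("aging_concordant", 0.05, lfc_aging = -0.85),
    archetype_spec("ad_concordant", 0.05, lfc_ad = 0.8)
  )
}

#' Simulate a three-cohort count matrix with planted truth
#'
#' Draws a genes-by-samples negative-binomial count matrix under the cohort
#' design, plants the requested archetypes in deterministic gene blocks
#' (`floor(fraction * n_genes)` genes each, remainder null), and returns the
#' full ground-truth ledger needed to score every downstream stage.
#'
#' @param design A [cohort_design()].
#' @param archetypes List of [archetype_spec()]; fractions must sum to at most 1.
#' @param seed Integer seed; identical `(design, archetypes, seed)` give
#'   bit-identical output.
#' @param noncoding_fraction Fraction of *null* genes flagged non-protein-coding
#'   in the annotation, to exercise the coding filter. Default 0.
#'
#' @return A `cohort_simulation` list with elements
#'   `counts` (integer matrix, genes x samples), `samples` (tibble:
#'   `sample_id`, `cohort`, `sex`), `truth` (tibble: `gene`, `archetype`,
#'   `lfc_aging`, `lfc_ad`, `mean_Young`, `mean_Old`, `mean_OAD`),
#'   `annotation` (tibble: `gene`, `protein_coding`) and `size_factors`
#'   (true per-sample factors).
#' @export
#' @examples
#' sim <- simulate_counts(cohort_design(n_genes = 50), seed = 1)
#' dim(sim$counts)
#' dplyr::count(sim$truth, archetype)
simulate_counts <- function(design = cohort_design(),
                            archetypes = default_archetypes(),
                            seed,
                            noncoding_fraction = 0) {
  if (!inherits(design, "cohort_design")) design <- do.call(cohort_design, design)
  if (inherits(archetypes, "archetype_spec")) archetypes <- list(archetypes)
  fractions <- vapply(archetypes, `[[`, numeric(1), "fraction")
  if (sum(fractions) > 1 + 1e-12) {
    abort_config("archetype fractions must sum to at most 1")
  }
  if (noncoding_fraction < 0 || noncoding_fraction > 1) {
    abort_config("`noncoding_fraction` must lie in [0, 1]")
  }

  G <- design$n_genes
  sizes <- design$group_sizes
  n <- sum(sizes)
  genes <- sprintf("G%05d", seq_len(G))
  cohort <- rep(COHORTS, sizes)
  samples <- tibble(
    sample_id = paste0(cohort, "_", unlist(lapply(sizes, seq_len))),
    cohort = cohort,
    # one female per cohort, as in the reference design (3 of 30 samples)
    sex = unname(unlist(lapply(sizes, function(k) c("F", rep("M", k - 1L)))))
  )

  # deterministic block assignment keeps archetype counts exact
  label <- rep("null", G)
  lfc_aging <- numeric(G)
  lfc_ad <- numeric(G)
  at <- 0L
  for (a in archetypes) {
    k <- floor(a$fraction * G)
    if (k > 0) {
      idx <- at + seq_len(k)
      label[idx] <- a$archetype
      lfc_aging[idx] <- a$lfc_aging
      lfc_ad[idx] <- a$lfc_ad
      at <- at + k
    }
  }

  ss <- stream_seeds(seed)
  base <- with_seed(ss[1],
    pmax(rlnorm(G, design$mean_log_location, design$mean_log_scale), 1))
  sf <- with_seed(ss[2],
    runif(n, design$size_factor_range[1], design$size_factor_range[2]))
  names(sf) <- samples$sample_id

  mean_young <- base
  mean_old <- base * 2^lfc_aging
  mean_oad <- base * 2^(lfc_aging + lfc_ad)
  mu_by_cohort <- cbind(Young = mean_young, Old = mean_old, OAD = mean_oad)
  mu <- mu_by_cohort[, cohort, drop = FALSE] *
    matrix(sf, nrow = G, ncol = n, byrow = TRUE)

  counts <- with_seed(ss[3],
    matrix(rnbinom(G * n, mu = mu, size = 1 / design$dispersion), nrow = G))
  dimnames(counts) <- list(genes, samples$sample_id)
  storage.mode(counts) <- "integer"

  coding <- rep(TRUE, G)
  if (noncoding_fraction > 0) {
    null_idx <- which(label == "null")
    k <- floor(noncoding_fraction * length(null_idx))
    if (k > 0) coding[null_idx[seq_len(k)]] <- FALSE
  }

  structure(
    list(
      counts = counts,
      samples = samples,
      truth = tibble(
        gene = genes, archetype = label,
        lfc_aging = lfc_aging, lfc_ad = lfc_ad,
        mean_Young = mean_young, mean_Old = mean_old, mean_OAD = mean_oad
      ),
      annotation = tibble(gene = genes, protein_coding = coding),
      size_factors = sf,
      design = design
    ),
    class = "cohort_simulation"
  )
}

#' @export
print.cohort_simulation <- function(x, ...) {
  cat("Three-cohort count simulation:", nrow(x$counts), "genes x",
      ncol(x$counts), "samples\n")
  print(table(x$truth$archetype))
  invisible(x)
}

#' Build a gene-set collection around a planted archetype
#'
#' Emulates a pathway database: one set contains exactly the genes of the
#' designated archetype (the signal an enrichment stage must recover) and the
#' remaining sets are random decoys drawn from the simulated genes.
#'
#' @param truth Truth tibble from [simulate_counts()] (columns `gene`,
#'   `archetype`).
#' @param planted_archetype Archetype whose genes form the planted set;
#'   `NULL` builds a decoys-only collection.
#' @param n_decoy_sets Number of random decoy sets.
#' @param set_size_range Integer range of decoy set sizes.
#' @param seed Integer seed.
#' @param exclude_planted If `TRUE`, decoys are drawn only from genes outside
#'   the planted set (guaranteeing empty intersection with it).
#'
#' @return A `gene_set_collection`: named list of gene vectors with a
#'   `description` attribute; writable with [write_gmt()].
#' @export
simulate_gene_sets <- function(truth,
                               planted_archetype = "reversal",
                               n_decoy_sets = 50L,
                               set_size_range = c(10L, 50L),
                               seed,
                               exclude_planted = FALSE) {
  planted <- if (is.null(planted_archetype)) character() else
    truth$gene[truth$archetype == planted_archetype]
  if (!is.null(planted_archetype) && length(planted) == 0) {
    abort_config(paste0("no genes carry archetype '", planted_archetype, "'"))
  }
  pool <- if (exclude_planted) setdiff(truth$gene, planted) else truth$gene
  if (max(set_size_range) > length(pool)) {
    abort_config("`set_size_range` exceeds the number of available genes")
  }
  if (min(set_size_range) < 1) abort_config("set sizes must be positive")

  sets <- list()
  if (length(planted) > 0) {
    sets[[paste0("planted_", planted_archetype)]] <- planted
  }
  if (n_decoy_sets > 0) {
    ss <- stream_seeds(seed)
    decoys <- with_seed(ss[4], {
      sizes <- sample(seq(set_size_range[1], set_size_range[2]),
                      n_decoy_sets, replace = TRUE)
      lapply(sizes, function(k) sort(sample(pool, k)))
    })
    names(decoys) <- sprintf("decoy_%03d", seq_len(n_decoy_sets))
    sets <- c(sets, decoys)
  }
  desc <- rep("random decoy set", length(sets))
  names(desc) <- names(sets)
  if (length(planted) > 0) {
    desc[[paste0("planted_", planted_archetype)]] <-
      paste0("planted ", planted_archetype, " genes")
  }
  structure(sets, description = desc, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x), "sets, sizes",
      paste(range(lengths(x)), collapse = "-"), "\n")
  invisible(x)
}

#' Simulate a community-structured interactome with planted bridge hubs
#'
#' Partitions the member genes into communities with dense random edges
#' inside each community and *no* direct edges between communities; every
#' bridge gene is connected to all other nodes. All inter-community shortest
#' paths therefore run through bridges, which makes the planted bridges the
#' top-betweenness nodes by construction. Each edge carries the constant
#' per-channel evidence scores of `channel_profile`.
#'
#' @param members Character vector of node genes.
#' @param n_communities Number of communities (>= 1).
#' @param bridge_genes Genes acting as inter-community bridges; must be a
#'   subset of `members` and non-empty whenever `n_communities > 1`.
#' @param intra_edge_prob Edge probability within a community, in (0, 1].
#' @param channel_profile Named integer scores (0-1000) per evidence channel.
#' @param seed Integer seed.
#'
#' @return Tibble with columns `protein1`, `protein2` and one column per
#'   channel; writable with [write_string_edges()].
#' @export
simulate_interactome <- function(members,
                                 n_communities = 3L,
                                 bridge_genes = character(),
                                 intra_edge_prob = 0.3,
                                 channel_profile = c(experiments = 700L,
                                                     database = 500L,
                                                     textmining = 0L),
                                 seed) {
  if (n_communities < 1) abort_config("`n_communities` must be at least 1")
  if (!all(bridge_genes %in% members)) {
    abort_config("`bridge_genes` must be a subset of `members`")
  }
  if (n_communities > 1 && length(bridge_genes) == 0) {
    abort_config("multi-community interactomes need at least one bridge gene")
  }
  if (intra_edge_prob <= 0 || intra_edge_prob > 1) {
    abort_config("`intra_edge_prob` must lie in (0, 1]")
  }
  if (is.null(names(channel_profile)) || any(names(channel_profile) == "")) {
    abort_config("`channel_profile` must be a named score vector")
  }

  others <- setdiff(members, bridge_genes)
  ss <- stream_seeds(seed)
  perm <- with_seed(ss[5], sample(others))
  community <- split(perm, rep_len(seq_len(n_communities), length(perm)))

  intra <- with_seed(ss[6], {
    do.call(rbind, lapply(community, function(nodes) {
      if (length(nodes) < 2) return(NULL)
      pairs <- t(utils::combn(sort(nodes), 2))
      pairs[runif(nrow(pairs)) <= intra_edge_prob, , drop = FALSE]
    }))
  })

  bridge_edges <- NULL
  if (length(bridge_genes) > 0) {
    targets <- setdiff(members, NA)
    bridge_edges <- do.call(rbind, lapply(bridge_genes, function(b) {
      to <- setdiff(targets, b)
      cbind(rep(b, length(to)), to)
    }))
  }

  e <- rbind(intra, bridge_edges)
  if (is.null(e) || nrow(e) == 0) {
    edges <- tibble(protein1 = character(), protein2 = character())
  } else {
    edges <- tibble(protein1 = pmin(e[, 1], e[, 2]),
                    protein2 = pmax(e[, 1], e[, 2])) %>%
      filter(.data$protein1 != .data$protein2) %>%
      distinct() %>%
      arrange(.data$protein1, .data$protein2)
  }
  for (ch in names(channel_profile)) {
    edges[[ch]] <- as.integer(rep(channel_profile[[ch]], nrow(edges)))
  }
  attr(edges, "communities") <- community
  attr(edges, "bridges") <- bridge_genes
  edges
}
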