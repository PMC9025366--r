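# End-to-end orchestration: inputs (real or simulated) -> differential
# expression x3 -> trend crossing -> per-region enrichment -> dual networks
# and shared hubs -> machine-readable summary.

#' Validate a pipeline configuration
#'
#' A configuration is a YAML file (or equivalent list) with
#' * either an `inputs:` block (paths to `counts`, `samples`, `annotation`,
#'   `gene_sets`, `edges`, relative to the config file) or a `simulate:` block
#'   (a [cohort_design()] plus archetypes, gene-set and interactome settings)
#'   — never both;
#' * `seed` (required with `simulate:`), `alpha` (default 0.05), `outdir`;
#' * optional `enrichment:` (`min_set`) and `hubs:` (`channels`, `min_score`,
#'   `z_threshold`) blocks.
#'
#' @param config Path to a YAML file or a list.
#' @param outdir,seed Optional overrides applied before validation.
#' @return The normalized configuration list (class `pipeline_config`).
#' @export
pipeline_config <- function(config, outdir = NULL, seed = NULL) {
  base_dir <- "."
  if (is.character(config)) {
    base_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort_config("configuration must be a list or a YAML path")
  if (!is.null(outdir)) config$outdir <- outdir
  if (!is.null(seed)) config$seed <- seed

  has_inputs <- !is.null(config$inputs)
  has_sim <- !is.null(config$simulate)
  if (has_inputs == has_sim) {
    abort_config("give exactly one of an `inputs:` block or a `simulate:` block")
  }
  if (is.null(config$seed)) {
    if (has_sim) abort_config("`seed` is required with a `simulate:` block")
    config$seed <- 0L
  }
  config$alpha <- config$alpha %||% 0.05
  if (config$alpha <= 0 || config$alpha >= 1) {
    abort_config("`alpha` must lie in (0, 1)")
  }
  config$enrichment <- config$enrichment %||% list()
  config$enrichment$min_set <- config$enrichment$min_set %||% 3L
  config$hubs <- config$hubs %||% list()
  config$hubs$channels <- config$hubs$channels %||% c("experiments", "database")
  config$hubs$min_score <- config$hubs$min_score %||% 1L
  config$hubs$z_threshold <- config$hubs$z_threshold %||% 1.96
  if (config$hubs$z_threshold <= 0) abort_config("`z_threshold` must be positive")
  if (config$hubs$min_score < 0 || config$hubs$min_score > 1000) {
    abort_config("`min_score` must lie in [0, 1000]")
  }
  if (is.null(config$outdir)) abort_config("`outdir` is required")

  if (has_inputs) {
    needed <- c("counts", "samples", "annotation", "gene_sets", "edges")
    missing <- setdiff(needed, names(config$inputs))
    if (length(missing) > 0) {
      abort_config(paste("`inputs:` is missing", paste(missing, collapse = ", ")))
    }
    config$inputs[needed] <- lapply(config$inputs[needed], function(p) {
      if (startsWith(p, "/")) p else file.path(base_dir, p)
    })
  } else {
    sim <- config$simulate
    sim$n_genes <- sim$n_genes %||% 3000L
    sim$dispersion <- sim$dispersion %||% 0.05
    sim$group_sizes <- unlist(sim$group_sizes %||%
                                c(Young = 8L, Old = 10L, OAD = 12L))
    sim$noncoding_fraction <- sim$noncoding_fraction %||% 0
    sim$archetypes <- sim$archetypes %||%
      lapply(default_archetypes(), unclass)
    sim$gene_sets <- sim$gene_sets %||% list()
    sim$gene_sets$planted_archetype <- sim$gene_sets$planted_archetype %||% "reversal"
    sim$gene_sets$n_decoy_sets <- sim$gene_sets$n_decoy_sets %||% 50L
    sim$gene_sets$set_size_range <-
      unlist(sim$gene_sets$set_size_range %||% c(10L, 50L))
    sim$interactome <- sim$interactome %||% list()
    sim$interactome$n_communities <- sim$interactome$n_communities %||% 3L
    sim$interactome$intra_edge_prob <- sim$interactome$intra_edge_prob %||% 0.25
    sim$interactome$n_bridges <- sim$interactome$n_bridges %||% 4L
    sim$interactome$n_null_members <- sim$interactome$n_null_members %||% 200L
    config$simulate <- sim
  }
  structure(config, class = "pipeline_config")
}

simulate_pipeline_inputs <- function(sim, seed, outdir) {
  design <- cohort_design(
    group_sizes = sim$group_sizes,
    n_genes = sim$n_genes,
    dispersion = sim$dispersion
  )
  archetypes <- lapply(sim$archetypes, function(a) do.call(archetype_spec, a))
  cs <- simulate_counts(design, archetypes, seed = seed,
                        noncoding_fraction = sim$noncoding_fraction)

  planted_arch <- sim$gene_sets$planted_archetype
  if (!any(cs$truth$archetype == planted_arch)) planted_arch <- NULL
  gs <- simulate_gene_sets(
    cs$truth,
    planted_archetype = planted_arch,
    n_decoy_sets = sim$gene_sets$n_decoy_sets,
    set_size_range = sim$gene_sets$set_size_range,
    seed = seed + 1L
  )

  # network members: every planted (non-null) gene plus a block of null genes;
  # bridges come from the AD-concordant class so both DEG networks contain them
  nonnull <- cs$truth$gene[cs$truth$archetype != "null"]
  nulls <- cs$truth$gene[cs$truth$archetype == "null"]
  members <- c(nonnull, head(nulls, sim$interactome$n_null_members))
  ad_genes <- cs$truth$gene[cs$truth$archetype == "ad_concordant"]
  if (length(ad_genes) == 0) ad_genes <- members
  bridges <- head(ad_genes, sim$interactome$n_bridges)
  edges <- simulate_interactome(
    members,
    n_communities = sim$interactome$n_communities,
    bridge_genes = bridges,
    intra_edge_prob = sim$interactome$intra_edge_prob,
    seed = seed + 2L
  )

  dir.create(file.path(outdir, "inputs"), recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(cs$counts, file.path(outdir, "inputs", "counts.tsv"))
  write_sample_sheet(cs$samples, file.path(outdir, "inputs", "samples.tsv"))
  write_annotation(cs$annotation, file.path(outdir, "inputs", "annotation.tsv"))
  write_gmt(gs, file.path(outdir, "inputs", "gene_sets.gmt"))
  write_string_edges(edges, file.path(outdir, "inputs", "edges.txt"))
  write.table(as.data.frame(cs$truth), file.path(outdir, "inputs", "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  list(counts = cs$counts, samples = cs$samples, annotation = cs$annotation,
       gene_sets = gs, edges = edges, truth = cs$truth, bridges = bridges)
}

load_pipeline_inputs <- function(paths) {
  list(
    counts = read_count_matrix(paths$counts),
    samples = read_sample_sheet(paths$samples),
    annotation = read_annotation(paths$annotation),
    gene_sets = read_gmt(paths$gene_sets),
    edges = read_string_edges(paths$edges),
    truth = NULL, bridges = NULL
  )
}

empty_hub_table <- function(name) {
  out <- tibble(node = character(), betweenness = numeric(),
                degree = integer(), z = numeric(), selected = logical())
  attr(out, "network") <- name
  class(out) <- c("hub_table", class(out))
  out
}

#' Assemble the machine-readable run summary
#'
#' Collapses the stage outputs into one plain list: the seven Venn counts,
#' the per-archetype counts, enrichment toplines per shared region, network
#' sizes and hub counts, and the shared-hub list. Errors if a stage output is
#' missing, naming the stage.
#'
#' @param stages Named list with elements `venn`, `trend`, `enrichment`
#'   (named list of [enrich()] tibbles), `networks` (named list of
#'   `interaction_network`s), `hubs` (named list of `hub_table`s) and
#'   `shared_hubs` (tibble).
#' @return Summary list, writable with [yaml::write_yaml()].
#' @export
summarize_run <- function(stages) {
  needed <- c("venn", "trend", "enrichment", "networks", "hubs", "shared_hubs")
  missing <- setdiff(needed, names(stages))
  if (length(missing) > 0) {
    abort(paste("missing stage output(s):", paste(missing, collapse = ", ")))
  }
  report <- trend_report(stages$trend)
  list(
    venn = as.list(setNames(as.integer(stages$venn$n), stages$venn$region)),
    archetypes = as.list(setNames(as.integer(report$summary$n),
                                  as.character(report$summary$archetype))),
    enrichment = lapply(stages$enrichment, function(e) {
      list(
        n_tested = nrow(e),
        n_enriched = as.integer(sum(e$enriched)),
        top_set = if (nrow(e) > 0) e$set[1] else NA,
        top_q = if (nrow(e) > 0) as.numeric(e$q_value[1]) else NA
      )
    }),
    networks = lapply(names(stages$networks), function(nm) {
      g <- stages$networks[[nm]]$graph
      h <- stages$hubs[[nm]]
      list(name = nm,
           nodes = as.integer(igraph::vcount(g)),
           edges = as.integer(igraph::ecount(g)),
           n_hubs = as.integer(sum(h$selected)))
    }),
    shared_hubs = as.list(stages$shared_hubs$gene)
  )
}

#' Run the full three-cohort analysis pipeline
#'
#' Executes, in order: input acquisition (simulation or files), the three
#' two-cohort NB Wald tests, DEG selection, Venn crossing and trend
#' classification, over-representation on each pairwise-shared region
#' (background: protein-coding genes tested in both of the region's
#' comparisons), evidence-filtered network induction on the YoungVsOAD and
#' OldVsOAD DEG lists with z-score hub selection, and hub intersection. Every
#' stage artifact is written under `outdir` and a YAML summary closes the
#' run. Identical configuration and seed give byte-identical outputs.
#'
#' @param config Path to a YAML configuration or a list (see
#'   [pipeline_config()]).
#' @param outdir,seed,alpha,z_threshold,channels,min_score Optional overrides
#'   of the corresponding configuration fields.
#' @return Invisibly, the summary list (with attribute `"outdir"`).
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL, alpha = NULL,
                         z_threshold = NULL, channels = NULL,
                         min_score = NULL) {
  config <- pipeline_config(config, outdir = outdir, seed = seed)
  if (!is.null(alpha)) config$alpha <- alpha
  if (!is.null(z_threshold)) config$hubs$z_threshold <- z_threshold
  if (!is.null(channels)) config$hubs$channels <- channels
  if (!is.null(min_score)) config$hubs$min_score <- min_score
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  log_msg <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = stderr())
    cat(msg, "\n", file = file.path(outdir, "pipeline.log"), append = TRUE)
  }
  if (file.exists(file.path(outdir, "pipeline.log"))) {
    unlink(file.path(outdir, "pipeline.log"))
  }

  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e) {
      if (inherits(e, "tritrend_stage_error")) stop(e)
      abort_stage(stage, e)
    })
  }

  inputs <- run_stage("inputs", {
    if (!is.null(config$simulate)) {
      x <- simulate_pipeline_inputs(config$simulate, config$seed, outdir)
      log_msg("inputs: simulated ", nrow(x$counts), " genes x ",
              ncol(x$counts), " samples, ", length(x$gene_sets),
              " gene sets, ", nrow(x$edges), " interactions")
      x
    } else {
      x <- load_pipeline_inputs(config$inputs)
      log_msg("inputs: loaded ", nrow(x$counts), " genes x ",
              ncol(x$counts), " samples, ", length(x$gene_sets),
              " gene sets, ", nrow(x$edges), " interactions")
      x
    }
  })

  de <- run_stage("deg_testing", {
    res <- lapply(names(COMPARISONS), function(nm) {
      r <- deg_test(inputs$counts, inputs$samples, nm)
      write_de_table(r, file.path(outdir, paste0("de_", nm, ".tsv")))
      r
    })
    names(res) <- names(COMPARISONS)
    for (r in res) {
      log_msg("deg_testing: ", r$comparison, " tested ",
              sum(r$table$tested), " genes")
    }
    res
  })

  degs <- run_stage("deg_selection", {
    d <- bind_rows(lapply(de, select_degs,
                          annotation = inputs$annotation,
                          alpha = config$alpha))
    write.table(as.data.frame(d), file.path(outdir, "degs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_msg("deg_selection: ", nrow(d), " DEG records at q < ", config$alpha)
    d
  })

  crossing <- run_stage("comparison_crossing", {
    trend <- classify_trends(degs)
    venn <- venn_partition(degs)
    report <- trend_report(trend)
    write_trend_report(report, file.path(outdir, "trend"))
    write.table(as.data.frame(venn), file.path(outdir, "venn_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_msg("comparison_crossing: ", nrow(trend), " genes in the union")
    list(trend = trend, venn = venn)
  })

  enrichment <- run_stage("pathway_enrichment", {
    trend <- crossing$trend
    coding <- inputs$annotation$gene[inputs$annotation$protein_coding]
    tested <- lapply(de, function(r) r$table$gene[r$table$tested])
    regions <- list(
      aging = list(
        genes = trend$gene[trend$in_young_old & trend$in_young_oad & !trend$in_old_oad],
        background = intersect(intersect(tested$YoungVsOld, tested$YoungVsOAD), coding)
      ),
      ad = list(
        genes = trend$gene[trend$in_old_oad & trend$in_young_oad & !trend$in_young_old],
        background = intersect(intersect(tested$OldVsOAD, tested$YoungVsOAD), coding)
      ),
      reversal = list(
        genes = trend$gene[trend$in_young_old & trend$in_old_oad & !trend$in_young_oad],
        background = intersect(intersect(tested$YoungVsOld, tested$OldVsOAD), coding)
      )
    )
    out <- lapply(names(regions), function(nm) {
      r <- regions[[nm]]
      e <- enrich(r$genes, inputs$gene_sets, r$background,
                  min_set = config$enrichment$min_set, alpha = config$alpha)
      flat <- as.data.frame(e[setdiff(names(e), "overlap")])
      flat$overlap <- vapply(e$overlap, paste, character(1), collapse = ",")
      write.table(flat, file.path(outdir, paste0("enrichment_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      log_msg("pathway_enrichment: region ", nm, " query ", length(r$genes),
              " genes, ", sum(e$enriched), " enriched set(s)")
      e
    })
    names(out) <- names(regions)
    out
  })

  networks <- run_stage("network_hubs", {
    filtered <- filter_edges(inputs$edges, channels = config$hubs$channels,
                             min_score = config$hubs$min_score)
    nets <- hubs <- list()
    for (nm in c("YoungVsOAD", "OldVsOAD")) {
      deg_list <- degs$gene[degs$comparison == nm]
      net <- if (length(deg_list) == 0) {
        warn(paste0("no DEGs for '", nm, "'; empty network"))
        structure(list(graph = igraph::make_empty_graph(directed = FALSE),
                       name = nm),
                  class = "interaction_network")
      } else {
        induce_network(filtered, deg_list, name = nm)
      }
      h <- if (igraph::vcount(net$graph) < 2) {
        empty_hub_table(nm)
      } else {
        network_hubs(net, z_threshold = config$hubs$z_threshold)
      }
      write.table(as.data.frame(h), file.path(outdir, paste0("hubs_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (igraph::vcount(net$graph) > 0) {
        write_graphml(net, file.path(outdir, paste0("network_", nm, ".graphml")))
      }
      log_msg("network_hubs: ", nm, " has ", igraph::vcount(net$graph),
              " nodes, ", igraph::ecount(net$graph), " edges, ",
              sum(h$selected), " hub(s)")
      nets[[nm]] <- net
      hubs[[nm]] <- h
    }
    shared <- intersect_hubs(hubs)
    write.table(as.data.frame(shared), file.path(outdir, "shared_hubs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_msg("network_hubs: ", nrow(shared), " shared hub(s)")
    list(networks = nets, hubs = hubs, shared = shared)
  })

  summary <- run_stage("summary", {
    s <- summarize_run(list(
      venn = crossing$venn,
      trend = crossing$trend,
      enrichment = enrichment,
      networks = networks$networks,
      hubs = networks$hubs,
      shared_hubs = networks$shared
    ))
    s$parameters <- list(
      seed = as.integer(config$seed),
      alpha = as.numeric(config$alpha),
      min_set = as.integer(config$enrichment$min_set),
      channels = as.list(config$hubs$channels),
      min_score = as.integer(config$hubs$min_score),
      z_threshold = as.numeric(config$hubs$z_threshold)
    )
    yaml::write_yaml(s, file.path(outdir, "summary.yaml"), precision = 15)
    s
  })
  log_msg("summary written to ", file.path(outdir, "summary.yaml"))

  attr(summary, "outdir") <- outdir
  invisible(summary)
}
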