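# DEG-induced interaction networks, betweenness hubs and their intersection.

#' Filter interaction edges by evidence channel
#'
#' Keeps an edge when its score in *any* of the named channels is at least
#' `max(min_score, 1)` — i.e. the edge has positive evidence of the requested
#' kind. Endpoints are canonicalized to unordered pairs; self-loops and
#' duplicate pairs are dropped.
#'
#' @param edges Edge tibble from [read_string_edges()] or
#'   [simulate_interactome()]: `protein1`, `protein2` plus one integer score
#'   column (0-1000) per channel.
#' @param channels Channel column names to consider; default the
#'   curated-evidence pair `experiments` and `database`.
#' @param min_score Minimum channel score, in \[0, 1000\].
#' @return Filtered edge tibble.
#' @export
filter_edges <- function(edges, channels = c("experiments", "database"),
                         min_score = 1L) {
  if (length(channels) == 0) abort("`channels` must name at least one channel")
  if (min_score < 0 || min_score > 1000) {
    abort("`min_score` must lie in [0, 1000]")
  }
  available <- setdiff(names(edges), c("protein1", "protein2"))
  missing <- setdiff(channels, available)
  if (length(missing) > 0) {
    abort(paste0("unknown channel(s) ", paste(missing, collapse = ", "),
                 "; available: ", paste(available, collapse = ", ")))
  }
  threshold <- max(min_score, 1)
  best <- do.call(pmax, unname(as.list(edges[channels])))
  edges[best >= threshold, , drop = FALSE] %>%
    mutate(a = pmin(.data$protein1, .data$protein2),
           b = pmax(.data$protein1, .data$protein2)) %>%
    filter(.data$a != .data$b) %>%
    distinct(.data$a, .data$b, .keep_all = TRUE) %>%
    mutate(protein1 = .data$a, protein2 = .data$b) %>%
    select(-"a", -"b") %>%
    arrange(.data$protein1, .data$protein2)
}

#' Induce the interaction network of a DEG list
#'
#' Subgraph on the edges whose *both* endpoints are differentially expressed;
#' DEGs without any surviving connection are excluded (no isolated nodes).
#'
#' @param edges Filtered edge tibble (see [filter_edges()]).
#' @param degs Character vector of DEG identifiers.
#' @param name Provenance label (comparison name).
#' @return An `interaction_network` wrapping an undirected simple
#'   \pkg{igraph} graph.
#' @export
induce_network <- function(edges, degs, name = "network") {
  if (length(degs) == 0) abort("`degs` must be non-empty")
  keep <- edges$protein1 %in% degs & edges$protein2 %in% degs
  sub <- edges[keep, c("protein1", "protein2")]
  if (nrow(sub) == 0) {
    warn(paste0("no interaction connects two DEGs of '", name,
                "'; returning an empty network"))
  }
  g <- igraph::simplify(igraph::graph_from_data_frame(sub, directed = FALSE))
  structure(list(graph = g, name = name), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network '", x$name, "': ", igraph::vcount(x$graph),
      " nodes, ", igraph::ecount(x$graph), " edges\n", sep = "")
  invisible(x)
}

#' Normalized betweenness centrality
#'
#' Exact unweighted betweenness (endpoints excluded, each unordered pair
#' counted once, pairs in different components contributing zero), normalized
#' by the number of orderable pairs `(n - 1)(n - 2) / 2` so values lie in
#' \[0, 1\].
#'
#' @param network An `interaction_network`.
#' @return Tibble (`node`, `betweenness`, `degree`).
#' @export
betweenness_centrality <- function(network) {
  g <- network$graph
  nv <- igraph::vcount(g)
  if (nv == 0) abort("network is empty")
  raw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  norm <- if (nv > 2) (nv - 1) * (nv - 2) / 2 else 1
  tibble(node = igraph::V(g)$name,
         betweenness = as.numeric(raw) / norm,
         degree = as.integer(igraph::degree(g)))
}

#' Select hubs by betweenness z-score
#'
#' Standardizes the betweenness values with the *population* standard
#' deviation over all nodes of the network and selects nodes with
#' `z > z_threshold` strictly (default 1.96, the upper 2.5% of a standard
#' normal). If all values are equal (zero standard deviation) no node is
#' selected.
#'
#' @param centrality Tibble from [betweenness_centrality()], or a named
#'   numeric vector of centrality values.
#' @param z_threshold Strict selection threshold on the z-score.
#' @param name Provenance label attached to the result.
#' @return A `hub_table` tibble: `node`, `betweenness`, `degree` (when
#'   available), `z`, `selected`.
#' @export
#' @examples
#' zscore_hubs(c(a = 0, b = 0, c = 0, d = 0, e = 0.5))
zscore_hubs <- function(centrality, z_threshold = 1.96, name = NULL) {
  if (is.numeric(centrality)) {
    centrality <- tibble(node = names(centrality),
                         betweenness = as.numeric(centrality))
  }
  if (nrow(centrality) < 2) {
    abort("z-score hub selection needs at least 2 nodes")
  }
  x <- centrality$betweenness
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) {
    inform("all betweenness values are equal; no hub selected")
    z <- rep(0, length(x))
    sel <- rep(FALSE, length(x))
  } else {
    z <- (x - mu) / sigma
    sel <- z > z_threshold
  }
  out <- mutate(centrality, z = z, selected = sel)
  attr(out, "network") <- name
  class(out) <- c("hub_table", class(out))
  out
}

#' Betweenness hubs of an interaction network
#'
#' Convenience wrapper: [betweenness_centrality()] followed by
#' [zscore_hubs()], carrying the network's provenance name.
#'
#' @param network An `interaction_network`.
#' @param z_threshold Strict z-score threshold; default 1.96.
#' @return A `hub_table`.
#' @export
network_hubs <- function(network, z_threshold = 1.96) {
  zscore_hubs(betweenness_centrality(network), z_threshold = z_threshold,
              name = network$name)
}

#' Intersect hub selections across networks
#'
#' Genes selected as hubs in *every* table, sorted lexicographically, with
#' each network's betweenness, z-score and degree attached.
#'
#' @param tables List of `hub_table`s (at least 2); names (or the tables'
#'   provenance) label the per-network statistic columns.
#' @return Tibble with one row per shared hub.
#' @export
intersect_hubs <- function(tables) {
  if (length(tables) < 2) abort("hub intersection needs at least 2 tables")
  nms <- names(tables)
  if (is.null(nms)) nms <- rep("", length(tables))
  nms <- ifelse(nzchar(nms), nms,
                vapply(seq_along(tables), function(i) {
                  nm <- attr(tables[[i]], "network")
                  if (is.null(nm)) paste0("network", i) else nm
                }, character(1)))
  shared <- sort(Reduce(intersect,
                        lapply(tables, function(t) t$node[t$selected])))
  out <- tibble(gene = shared)
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    idx <- match(shared, t$node)
    out[[paste0("betweenness_", nms[i])]] <- t$betweenness[idx]
    out[[paste0("z_", nms[i])]] <- t$z[idx]
    if ("degree" %in% names(t)) out[[paste0("degree_", nms[i])]] <- t$degree[idx]
  }
  out
}

#' Export a network
#'
#' @param network An `interaction_network`.
#' @param path Output path.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edge_list <- function(network, path) {
  e <- igraph::as_data_frame(network$graph, what = "edges")
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("protein1", "protein2"))
  invisible(path)
}

#' Degree versus betweenness, hubs highlighted
#'
#' @param object A `hub_table`.
#' @param ... Unused.
#' @export
autoplot.hub_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$degree, .data$betweenness,
                               colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "degree", y = "normalized betweenness",
                  colour = "hub (z > threshold)")
}
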