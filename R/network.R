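#' Pairwise Pearson correlations between expression profiles
#'
#' Computes the full symmetric correlation matrix between entities' z-score
#' profiles, with two-sided p-values from the t transform
#' `t = r sqrt((n-2) / (1 - r^2))` on n-2 degrees of freedom (n = number of
#' timepoints, so df = 8 in the canonical 10-timepoint design).
#'
#' @param profiles Profile tibble (`entity_id` + timepoint columns); no
#'   profile may be constant (constant genes are excluded upstream by
#'   [zscore_profiles()]).
#' @return A list of class `pairwise_pearson` with elements `r` and `p`
#'   (matrices with entity ids as dimnames) and `n_obs` (profile length).
#' @export
pairwise_pearson <- function(profiles) {
  profiles <- as_tibble(profiles)
  if (nrow(profiles) < 2) {
    abort("need at least two profiles to correlate",
      class = "bgcdiel_argument_error"
    )
  }
  sc <- setdiff(names(profiles), "entity_id")
  x <- t(as.matrix(profiles[sc])) # timepoints x entities
  colnames(x) <- profiles$entity_id
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0(
      "constant profile(s) reached correlation stage: ",
      paste(head(profiles$entity_id[sds == 0], 5), collapse = ", ")
    ), class = "bgcdiel_contract_error")
  }
  n <- nrow(x)
  r <- cor(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  structure(list(r = r, p = p, n_obs = n), class = "pairwise_pearson")
}

#' @export
print.pairwise_pearson <- function(x, ...) {
  cat(
    "<pairwise_pearson>", ncol(x$r), "entities,", x$n_obs,
    "timepoints per profile\n"
  )
  invisible(x)
}

#' @rdname pairwise_pearson
#' @param x A `pairwise_pearson` object.
#' @param ... Unused.
#' @return `tidy()` returns one row per unordered pair: `item1`, `item2`,
#'   `r`, `p`.
#' @export
tidy.pairwise_pearson <- function(x, ...) {
  ids <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    item1 = ids[idx[, 1]],
    item2 = ids[idx[, 2]],
    r = x$r[idx],
    p = x$p[idx]
  )
}

#' Build a BGC co-occurrence network
#'
#' Nodes are BGCs; an undirected edge joins two clusters when the Pearson
#' correlation of their z-score profiles strictly exceeds `r_threshold`
#' (default 0.8). Edge inclusion uses only the correlation; adjusted
#' p-values (over all pairs considered) are reported on the edges but play
#' no part in inclusion. Isolated nodes are retained.
#'
#' @param profiles BGC-level profile tibble.
#' @param node_attrs Optional tibble of node attributes (`bgc_id`, `phylum`,
#'   `bgc_class`).
#' @param r_threshold Strict correlation threshold for edges.
#' @param correction Multiple-testing correction for edge p-values:
#'   `"bonferroni"` (one-step, default) or `"bh"` (Benjamini-Hochberg FDR).
#' @return A `bgc_network`: list with `nodes` and `edges` tibbles,
#'   `r_threshold`, and `correction`.
#' @export
build_bgc_network <- function(profiles, node_attrs = NULL, r_threshold = 0.8,
                              correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  pc <- pairwise_pearson(profiles)
  pairs <- tidy(pc) %>%
    mutate(p_adj = p.adjust(.data$p, method = ifelse(correction == "bh", "BH", "bonferroni")))
  edges <- pairs %>%
    filter(.data$r > r_threshold) %>%
    rename(from = "item1", to = "item2")
  nodes <- tibble(id = profiles$entity_id)
  if (!is.null(node_attrs)) {
    nodes <- nodes %>%
      left_join(
        as_tibble(node_attrs) %>%
          select(id = "bgc_id", any_of(c("phylum", "bgc_class"))),
        by = "id"
      )
  }
  if (!"phylum" %in% names(nodes)) nodes$phylum <- NA_character_
  if (!"bgc_class" %in% names(nodes)) nodes$bgc_class <- NA_character_
  structure(
    list(
      nodes = nodes, edges = edges,
      r_threshold = r_threshold, correction = correction
    ),
    class = "bgc_network"
  )
}

#' @export
print.bgc_network <- function(x, ...) {
  cat(
    "<bgc_network>", nrow(x$nodes), "nodes,", nrow(x$edges),
    "edges (r >", x$r_threshold, ",", x$correction, "correction)\n"
  )
  invisible(x)
}

#' @rdname build_bgc_network
#' @param x,net A `bgc_network`.
#' @param ... Unused.
#' @return `tidy()` returns the edge tibble; `glance()` a one-row summary
#'   (`n_nodes`, `n_edges`, `density`, `n_components`, `r_threshold`).
#' @export
tidy.bgc_network <- function(x, ...) x$edges

#' @rdname build_bgc_network
#' @export
glance.bgc_network <- function(x, ...) {
  n <- nrow(x$nodes)
  tibble(
    n_nodes = n,
    n_edges = nrow(x$edges),
    density = if (n > 1) nrow(x$edges) / choose(n, 2) else NA_real_,
    n_components = length(unique(network_components(x)$component)),
    r_threshold = x$r_threshold
  )
}

#' Convert a network to igraph
#'
#' @rdname build_bgc_network
#' @return `as_igraph()` returns an igraph graph with node attributes
#'   `phylum`/`bgc_class` and edge attributes `r`, `p`, `p_adj`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "bgc_network"))
  igraph::graph_from_data_frame(
    d = as.data.frame(net$edges),
    directed = FALSE,
    vertices = as.data.frame(net$nodes)
  )
}

#' Connected components of a co-occurrence network
#'
#' @param net A `bgc_network`.
#' @return A tibble (`entity_id`, `component`), isolated nodes in singleton
#'   components.
#' @export
network_components <- function(net) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  tibble(
    entity_id = igraph::V(g)$name,
    component = as.integer(comp$membership)
  )
}

#' Phylum-level correlation table
#'
#' Averages member BGC profiles into one mean profile per phylum (each BGC
#' weighted equally), computes all pairwise Pearson correlations between
#' phyla, applies the chosen multiple-testing correction over that set of
#' pairs, and sorts by descending correlation.
#'
#' @param profiles BGC-level profile tibble.
#' @param taxonomy Tibble with `bgc_id` and `phylum`.
#' @param correction `"bonferroni"` (one-step, default) or `"bh"`.
#' @return A tibble (`phylum_a`, `phylum_b`, `n_a`, `n_b`, `r`, `p`,
#'   `p_adj`) sorted by descending `r`.
#' @export
phylum_correlations <- function(profiles, taxonomy,
                                correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  prof <- phylum_mean_profiles(profiles, taxonomy)
  if (nrow(prof$profiles) < 2) {
    abort("fewer than 2 phyla with usable BGC profiles",
      class = "bgcdiel_insufficient_groups_error"
    )
  }
  pc <- pairwise_pearson(prof$profiles)
  tidy(pc) %>%
    rename(phylum_a = "item1", phylum_b = "item2") %>%
    left_join(prof$sizes %>% rename(phylum_a = "phylum", n_a = "n"), by = "phylum_a") %>%
    left_join(prof$sizes %>% rename(phylum_b = "phylum", n_b = "n"), by = "phylum_b") %>%
    mutate(p_adj = p.adjust(.data$p, method = ifelse(correction == "bh", "BH", "bonferroni"))) %>%
    select("phylum_a", "phylum_b", "n_a", "n_b", "r", "p", "p_adj") %>%
    arrange(desc(.data$r))
}

#' Mean z-score profile per phylum
#'
#' @param profiles BGC-level profile tibble.
#' @param taxonomy Tibble with `bgc_id` and `phylum`.
#' @return A list: `profiles` (tibble, `entity_id` = phylum) and `sizes`
#'   (tibble `phylum`, `n` member BGCs).
#' @export
phylum_mean_profiles <- function(profiles, taxonomy) {
  sc <- setdiff(names(profiles), "entity_id")
  joined <- as_tibble(profiles) %>%
    inner_join(
      as_tibble(taxonomy) %>% select(entity_id = "bgc_id", "phylum"),
      by = "entity_id"
    )
  means <- joined %>%
    group_by(.data$phylum) %>%
    summarise(across(all_of(sc), mean), .groups = "drop") %>%
    rename(entity_id = "phylum")
  sizes <- joined %>% count(.data$phylum, name = "n")
  list(profiles = means, sizes = sizes)
}

#' Export / import a co-occurrence network
#'
#' `edge_list_tsv` writes a TSV of edges (`node_a`, `node_b`, `r`, `p`,
#' `p_adj`) preceded by commented `#node` lines carrying the node table (so
#' isolated nodes and attributes survive the round trip) and a `#meta` line
#' with the threshold. `graphml` delegates to igraph.
#'
#' @param net A `bgc_network`.
#' @param path Output file.
#' @param format `"edge_list_tsv"` or `"graphml"`.
#' @return `export_network()` returns `path` invisibly; `read_network()` the
#'   reconstructed `bgc_network`.
#' @export
export_network <- function(net, path, format = c("edge_list_tsv", "graphml")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    abort(paste0("unknown network format: ", format[1]),
      class = "bgcdiel_argument_error"
    )
  })
  stopifnot(inherits(net, "bgc_network"))
  if (format == "graphml") {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  header <- c(
    paste("#meta", "r_threshold", net$r_threshold, sep = "\t"),
    paste("#meta", "correction", net$correction, sep = "\t"),
    paste("#node", net$nodes$id, net$nodes$phylum, net$nodes$bgc_class, sep = "\t")
  )
  edge_lines <- paste(
    net$edges$from, net$edges$to,
    format(net$edges$r, digits = 15),
    format(net$edges$p, digits = 15),
    format(net$edges$p_adj, digits = 15),
    sep = "\t"
  )
  readr::write_lines(
    c(header, paste("node_a", "node_b", "r", "p", "p_adj", sep = "\t"), edge_lines),
    path
  )
  invisible(path)
}

#' @rdname export_network
#' @export
read_network <- function(path, format = c("edge_list_tsv", "graphml")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    abort(paste0("unknown network format: ", format[1]),
      class = "bgcdiel_argument_error"
    )
  })
  if (!file.exists(path)) io_abort("no such network file: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble(
      id = igraph::V(g)$name,
      phylum = igraph::V(g)$phylum %||% NA_character_,
      bgc_class = igraph::V(g)$bgc_class %||% NA_character_
    )
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- tibble(
      from = el$from, to = el$to,
      r = el$r %||% rep(NA_real_, nrow(el)),
      p = el$p %||% rep(NA_real_, nrow(el)),
      p_adj = el$p_adj %||% rep(NA_real_, nrow(el))
    )
    return(structure(
      list(nodes = nodes, edges = edges, r_threshold = NA_real_, correction = NA_character_),
      class = "bgc_network"
    ))
  }
  lines <- readr::read_lines(path)
  meta <- strsplit(lines[startsWith(lines, "#meta\t")], "\t", fixed = TRUE)
  meta_val <- setNames(
    purrr::map_chr(meta, 3),
    purrr::map_chr(meta, 2)
  )
  node_rows <- strsplit(lines[startsWith(lines, "#node\t")], "\t", fixed = TRUE)
  nodes <- tibble(
    id = purrr::map_chr(node_rows, 2),
    phylum = purrr::map_chr(node_rows, ~ .x[3] %||% NA_character_),
    bgc_class = purrr::map_chr(node_rows, ~ .x[4] %||% NA_character_)
  ) %>%
    mutate(across(
      c("phylum", "bgc_class"),
      ~ ifelse(.x == "NA", NA_character_, .x)
    ))
  body <- lines[!startsWith(lines, "#")]
  edges <- readr::read_tsv(I(paste(body, collapse = "\n")),
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      node_a = "c", node_b = "c", r = "d", p = "d", p_adj = "d"
    )
  ) %>%
    rename(from = "node_a", to = "node_b")
  structure(
    list(
      nodes = nodes, edges = edges,
      r_threshold = as.numeric(meta_val[["r_threshold"]]),
      correction = unname(meta_val[["correction"]])
    ),
    class = "bgc_network"
  )
}
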