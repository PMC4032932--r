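#' Resolve networks and annotations onto a common gene universe
#'
#' Establishes the run's gene universe as the union of genes appearing in
#' any input network, after applying an optional synonym table (alternate ->
#' canonical identifiers). Ambiguous alternates — those mapping to more than
#' one canonical identifier — are discarded entirely and every edge touching
#' them is skipped, mirroring the conservative identifier-mapping rule used
#' in production function-prediction pipelines. Annotation genes outside the
#' universe are dropped.
#'
#' @param networks List of `gba_network` objects (at least one).
#' @param annotations An `annotation_set`.
#' @param synonyms Optional result of [read_synonym_file()].
#' @return A list with elements `index` (the shared `gene_index`),
#'   `networks` (re-indexed networks), `annotations` (resolved set),
#'   `dropped_edges` (count of edges lost to discarded identifiers) and
#'   `dropped_genes` (identifiers discarded as ambiguous).
#' @export
resolve_inputs <- function(networks, annotations, synonyms = NULL) {
  stopifnot(length(networks) >= 1L)
  map <- if (is.null(synonyms)) character() else synonyms$map
  ambiguous <- if (is.null(synonyms)) character() else synonyms$ambiguous

  rename <- function(ids) {
    hit <- match(ids, names(map))
    ids[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
    ids
  }

  edge_tables <- lapply(networks, function(net) {
    e <- network_edges(net)
    e$from <- rename(e$from)
    e$to <- rename(e$to)
    drop <- e$from %in% ambiguous | e$to %in% ambiguous
    loops <- !drop & e$from == e$to  # synonym collapse can create loops
    list(edges = e[!(drop | loops), , drop = FALSE],
         dropped = sum(drop) + sum(loops))
  })
  dropped_edges <- sum(vapply(edge_tables, `[[`, numeric(1), "dropped"))

  all_genes <- unlist(lapply(edge_tables, function(t) {
    c(t$edges$from, t$edges$to)
  }), use.names = FALSE)
  if (length(all_genes) == 0L) {
    stop("no genes remain after identifier resolution", call. = FALSE)
  }
  index <- gene_index(sort(unique(all_genes)))

  resolved_nets <- Map(function(net, tab) {
    e <- tab$edges
    adj <- edges_to_adjacency(gene_position(index, e$from),
                              gene_position(index, e$to),
                              e$weight, length(index))
    gba_network(net$name, net$group, adj, index)
  }, networks, edge_tables)
  names(resolved_nets) <- vapply(networks, `[[`, character(1), "name")

  terms <- lapply(annotations$terms, function(g) {
    g <- rename(g)
    g <- g[!(g %in% ambiguous)]
    sort(unique(g[!is.na(gene_position(index, g))]))
  })
  resolved_ann <- annotation_set(terms, branch = annotations$branch)

  list(index = index,
       networks = resolved_nets,
       annotations = resolved_ann,
       dropped_edges = dropped_edges,
       dropped_genes = ambiguous)
}
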