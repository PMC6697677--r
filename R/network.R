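#' Build the direction-concordant circRNA-miRNA-mRNA regulatory network
#'
#' A regulatory triple is a tuple `(circRNA, miRNA, mRNA)` in which the
#' circRNA is dysregulated in `direction`, both target-map edges exist, and
#' the mRNA is dysregulated in the *same* direction — the signature of sponge
#' disinhibition. The bridging miRNA's own DE status is deliberately ignored:
#' sequestration changes miRNA availability, not abundance. Triples are
#' tuple-distinct, so the same `(circRNA, mRNA)` pair reached via two
#' different miRNAs contributes two triples. Networks are built separately per
#' direction (and per time point).
#'
#' @param circ_de,mrna_de DE tables from [call_de()].
#' @param circ2mir,mir2mrna Target maps.
#' @param direction `"up"` or `"down"`.
#' @return A tibble of triples (`circ_id`, `mirna_id`, `mrna_id`,
#'   `direction`) with class `cerna_network`; possibly empty.
#' @export
build_network <- function(circ_de, mrna_de, circ2mir, mir2mrna,
                          direction = c("up", "down")) {
  direction <- match.arg(direction)
  circ_dys <- circ_de$feature_id[circ_de$direction == direction]
  mrna_dys <- mrna_de$feature_id[mrna_de$direction == direction]
  triples <- downstream_mrnas(circ_dys, circ2mir, mir2mrna, quiet = TRUE)
  triples <- dplyr::filter(triples, .data$mrna_id %in% mrna_dys)
  triples$direction <- rep(direction, nrow(triples))
  structure(dplyr::arrange(triples, .data$circ_id, .data$mirna_id, .data$mrna_id),
            class = c("cerna_network", class(triples)))
}

#' Summarize the complexity of a regulatory network
#'
#' Counts triples and distinct nodes per layer and computes the three degree
#' distributions that describe network complexity: per-miRNA in-degree (how
#' many distinct dysregulated circRNAs sponge it), per-miRNA out-degree (how
#' many distinct dysregulated mRNAs it bridges to), and per-mRNA in-degree
#' (how many distinct miRNAs target it). Medians and interquartile ranges use
#' R's default interpolating quantile (type 7), which yields fractional IQR
#' endpoints such as 54.25.
#'
#' @param triples A `cerna_network` (or any tibble of `circ_id`, `mirna_id`,
#'   `mrna_id`).
#' @return A `cerna_network_summary`: counts, per-node degree tibbles, and a
#'   `stats` tibble of median/IQR/max per degree type. Empty networks yield
#'   all-zero counts and empty degree tables.
#' @export
summarize_network <- function(triples) {
  triples <- as_tibble(triples)
  empty_stats <- tibble(degree = c("mirna_in", "mirna_out", "mrna_in"),
                        median = 0, q1 = 0, q3 = 0, max = 0)
  if (!nrow(triples)) {
    return(structure(
      list(n_triples = 0L, n_circ = 0L, n_mirna = 0L, n_mrna = 0L,
           mirna_degrees = tibble(mirna_id = character(), in_degree = integer(),
                                  out_degree = integer()),
           mrna_in_degree = tibble(mrna_id = character(), in_degree = integer()),
           stats = empty_stats),
      class = "cerna_network_summary"))
  }
  mirna_deg <- triples |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(in_degree = dplyr::n_distinct(.data$circ_id),
                     out_degree = dplyr::n_distinct(.data$mrna_id),
                     .groups = "drop")
  mrna_deg <- triples |>
    dplyr::group_by(.data$mrna_id) |>
    dplyr::summarise(in_degree = dplyr::n_distinct(.data$mirna_id),
                     .groups = "drop")
  qstats <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(median = q[2], q1 = q[1], q3 = q[3], max = max(x))
  }
  st <- rbind(qstats(mirna_deg$in_degree), qstats(mirna_deg$out_degree),
              qstats(mrna_deg$in_degree))
  stats_tbl <- dplyr::bind_cols(
    tibble(degree = c("mirna_in", "mirna_out", "mrna_in")),
    as_tibble(st)
  )
  structure(
    list(n_triples = nrow(triples),
         n_circ = dplyr::n_distinct(triples$circ_id),
         n_mirna = dplyr::n_distinct(triples$mirna_id),
         n_mrna = dplyr::n_distinct(triples$mrna_id),
         mirna_degrees = mirna_deg,
         mrna_in_degree = mrna_deg,
         stats = stats_tbl),
    class = "cerna_network_summary")
}

#' @export
print.cerna_network_summary <- function(x, ...) {
  cat("<cerna_network_summary>\n")
  cat(sprintf("  %d triples: %d circRNA, %d miRNA, %d mRNA\n",
              x$n_triples, x$n_circ, x$n_mirna, x$n_mrna))
  print(x$stats)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cerna_network_summary <- function(x, ...) x$stats

#' @exportS3Method generics::glance
glance.cerna_network_summary <- function(x, ...) {
  tibble(n_triples = x$n_triples, n_circ = x$n_circ,
         n_mirna = x$n_mirna, n_mrna = x$n_mrna)
}

network_edges <- function(triples) {
  triples <- as_tibble(triples)
  dplyr::bind_rows(
    dplyr::distinct(tibble(from = triples$circ_id, interaction = "sponges",
                           to = triples$mirna_id)),
    dplyr::distinct(tibble(from = triples$mirna_id, interaction = "targets",
                           to = triples$mrna_id))
  )
}

network_node_attributes <- function(triples, circ_de = NULL, mrna_de = NULL) {
  triples <- as_tibble(triples)
  dir <- if (nrow(triples)) triples$direction[1] else NA_character_
  nodes <- dplyr::bind_rows(
    tibble(node_id = unique(triples$circ_id), layer = "circRNA", direction = dir),
    tibble(node_id = unique(triples$mirna_id), layer = "miRNA",
           direction = NA_character_),
    tibble(node_id = unique(triples$mrna_id), layer = "mRNA", direction = dir)
  )
  fc <- dplyr::bind_rows(
    if (!is.null(circ_de)) dplyr::select(circ_de, node_id = "feature_id",
                                         fold_change = "fold_change"),
    if (!is.null(mrna_de)) dplyr::select(mrna_de, node_id = "feature_id",
                                         fold_change = "fold_change")
  )
  if (!is.null(fc) && nrow(fc)) {
    nodes <- dplyr::left_join(nodes, fc, by = "node_id")
  } else {
    nodes$fold_change <- NA_real_
  }
  nodes
}

#' Export a regulatory network in Cytoscape-ready formats
#'
#' Writes a SIF file (`circRNA sponges miRNA`, `miRNA targets mRNA`; one
#' unique edge per line), a node-attribute TSV (`node_id`, `layer`,
#' `direction`, `fold_change`), and optionally a GraphML file carrying the
#' same nodes, edges and attributes. Every triple contributes exactly one
#' sponge edge and one targeting edge, so distinct SIF edges never exceed
#' twice the triple count.
#'
#' @param triples A `cerna_network` from [build_network()].
#' @param dir Output directory (created if needed).
#' @param circ_de,mrna_de Optional DE tables used to attach fold changes to
#'   the node-attribute table.
#' @param graphml Also write `network.graphml` (default `TRUE`).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(triples, dir, circ_de = NULL, mrna_de = NULL,
                           graphml = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edges <- network_edges(triples)
  nodes <- network_node_attributes(triples, circ_de, mrna_de)

  sif_path <- file.path(dir, "network.sif")
  writeLines(
    if (nrow(edges)) paste(edges$from, edges$interaction, edges$to) else character(0),
    sif_path)
  attr_path <- file.path(dir, "node_attributes.tsv")
  readr::write_tsv(nodes, attr_path)

  paths <- c(sif_path, attr_path)
  if (graphml) {
    gml_path <- file.path(dir, "network.graphml")
    if (nrow(edges)) {
      g <- igraph::graph_from_data_frame(
        edges[, c("from", "to", "interaction")], directed = TRUE,
        vertices = nodes)
    } else {
      g <- igraph::make_empty_graph(directed = TRUE)
    }
    igraph::write_graph(g, gml_path, format = "graphml")
    paths <- c(paths, gml_path)
  }
  invisible(paths)
}

#' Re-import a GraphML network export as a triple set
#'
#' Reconstructs the regulatory triples from a file written by
#' [export_network()] by joining the `sponges` and `targets` edges on the
#' bridging miRNA. For networks built with [build_network()] this is a lossless
#' round trip, because such networks are closed under that join.
#'
#' @param path Path to a `network.graphml` file.
#' @return A tibble with `circ_id`, `mirna_id`, `mrna_id`, `direction`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::ecount(g) == 0) {
    return(tibble(circ_id = character(), mirna_id = character(),
                  mrna_id = character(), direction = character()))
  }
  ed <- igraph::as_data_frame(g, what = "edges")
  vd <- igraph::as_data_frame(g, what = "vertices")
  sponges <- ed[ed$interaction == "sponges", c("from", "to")]
  targets <- ed[ed$interaction == "targets", c("from", "to")]
  names(sponges) <- c("circ_id", "mirna_id")
  names(targets) <- c("mirna_id", "mrna_id")
  triples <- dplyr::inner_join(as_tibble(sponges), as_tibble(targets),
                               by = "mirna_id", relationship = "many-to-many")
  dir_map <- vd$direction[match(triples$circ_id, vd$name)]
  triples$direction <- dir_map
  dplyr::arrange(triples, .data$circ_id, .data$mirna_id, .data$mrna_id)
}
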