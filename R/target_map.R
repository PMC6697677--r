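#' Construct a validated target map between adjacent RNA layers
#'
#' A target map is a directed bipartite edge set, either circRNA->miRNA
#' (miRNA response elements on circRNAs) or miRNA->mRNA (predicted miRNA
#' targets). Duplicate edges are dropped; only the two adjacent layer pairs
#' are permitted. Identifier matching throughout the package is exact string
#' equality — no alias resolution.
#'
#' @param edges A data frame whose first two columns are source and target
#'   identifiers (renamed to `source_id`, `target_id`).
#' @param source_layer,target_layer Layer labels; must be
#'   `("circRNA", "miRNA")` or `("miRNA", "mRNA")`.
#' @param quiet Suppress the dropped-duplicate message.
#' @return A tibble of distinct edges with class `cerna_target_map` and
#'   `source_layer` / `target_layer` attributes.
#' @export
#' @examples
#' target_map(data.frame(a = c("c1", "c1"), b = c("m1", "m2")),
#'            "circRNA", "miRNA")
target_map <- function(edges, source_layer, target_layer, quiet = FALSE) {
  allowed <- list(c("circRNA", "miRNA"), c("miRNA", "mRNA"))
  if (!any(vapply(allowed, identical, logical(1), c(source_layer, target_layer)))) {
    abort(sprintf(
      "Layer pair (%s -> %s) is not an adjacent pair: expected circRNA -> miRNA or miRNA -> mRNA.",
      source_layer, target_layer))
  }
  edges <- as_tibble(edges)
  if (ncol(edges) < 2) abort("`edges` needs at least two columns (source, target).")
  edges <- edges[, 1:2]
  names(edges) <- c("source_id", "target_id")
  edges$source_id <- as.character(edges$source_id)
  edges$target_id <- as.character(edges$target_id)
  bad <- !nzchar(edges$source_id) | !nzchar(edges$target_id) |
    is.na(edges$source_id) | is.na(edges$target_id)
  if (any(bad)) {
    abort(sprintf("Edges with empty/missing identifiers at rows: %s.",
                  paste(which(bad), collapse = ", ")))
  }
  if (any(edges$source_id == edges$target_id)) {
    abort("Self-pairs (source_id == target_id) are not allowed across layers.")
  }
  n0 <- nrow(edges)
  edges <- dplyr::distinct(edges)
  if (!quiet && nrow(edges) < n0) {
    inform(sprintf("Dropped %d duplicate edge(s).", n0 - nrow(edges)))
  }
  structure(edges,
            class = c("cerna_target_map", class(edges)),
            source_layer = source_layer, target_layer = target_layer)
}

#' Read a target map from a two-column TSV edge list
#'
#' The file must have exactly two tab-separated fields per row; a header row
#' is detected (and skipped) when both its fields match common header names
#' such as `source_id`/`target_id`. Duplicate edges are dropped with a
#' message.
#'
#' @param path Path to the TSV file.
#' @inheritParams target_map
#' @return A `cerna_target_map` tibble (possibly empty, with a warning).
#' @export
read_edge_list <- function(path, source_layer, target_layer) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warn(sprintf("Edge list '%s' is empty; returning an empty map.", path))
    return(target_map(tibble(source_id = character(), target_id = character()),
                      source_layer, target_layer, quiet = TRUE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 2)
  if (length(bad)) {
    abort(sprintf(
      "Malformed edge list '%s': expected 2 tab-separated fields but found %s on line(s) %s.",
      path, paste(unique(nf[bad]), collapse = "/"),
      paste(head(bad, 10), collapse = ", ")))
  }
  first <- tolower(trimws(fields[[1]]))
  header_names <- c("source", "target", "source_id", "target_id", "from", "to",
                    "circrna", "mirna", "mrna", "circ_id", "mirna_id", "mrna_id")
  is_header <- all(first %in% header_names)
  if (is_header) fields <- fields[-1]
  edges <- tibble(
    source_id = vapply(fields, `[`, character(1), 1),
    target_id = vapply(fields, `[`, character(1), 2)
  )
  missing_rows <- which(!nzchar(trimws(edges$source_id)) |
                          !nzchar(trimws(edges$target_id)))
  if (length(missing_rows)) {
    abort(sprintf("Edge list '%s' has missing fields on line(s) %s.",
                  path, paste(missing_rows + is_header, collapse = ", ")))
  }
  target_map(edges, source_layer, target_layer)
}

#' Enumerate downstream mRNAs of a circRNA set via bridging miRNAs
#'
#' Relational join of the two target maps restricted to `circ_ids`: a
#' `(circRNA, mRNA)` pair appears once per distinct bridging miRNA, so the
#' result rows are distinct `(circ_id, mirna_id, mrna_id)` tuples. circRNAs
#' absent from the circRNA->miRNA map contribute no rows (reported with a
#' message).
#'
#' @param circ_ids Character vector of circRNA identifiers.
#' @param circ2mir,mir2mrna Target maps from [target_map()] (or any data frame
#'   with `source_id`, `target_id` columns).
#' @param quiet Suppress the absent-circRNA message.
#' @return A tibble with columns `circ_id`, `mirna_id`, `mrna_id`.
#' @export
#' @examples
#' c2m <- target_map(data.frame(s = "c1", t = c("m1", "m2")), "circRNA", "miRNA")
#' m2g <- target_map(data.frame(s = c("m1", "m2"), t = "g1"), "miRNA", "mRNA")
#' downstream_mrnas("c1", c2m, m2g)  # g1 reachable via two distinct miRNAs
downstream_mrnas <- function(circ_ids, circ2mir, mir2mrna, quiet = FALSE) {
  circ_ids <- unique(as.character(circ_ids))
  sl <- attr(circ2mir, "source_layer")
  tl <- attr(mir2mrna, "target_layer")
  if (!is.null(sl) && sl != "circRNA") {
    abort(sprintf("`circ2mir` has source layer '%s'; expected 'circRNA'.", sl))
  }
  if (!is.null(tl) && tl != "mRNA") {
    abort(sprintf("`mir2mrna` has target layer '%s'; expected 'mRNA'.", tl))
  }
  absent <- setdiff(circ_ids, circ2mir$source_id)
  if (!quiet && length(absent)) {
    inform(sprintf("%d circRNA id(s) absent from the circRNA->miRNA map (e.g. %s); they yield no downstream mRNAs.",
                   length(absent), paste(head(absent, 3), collapse = ", ")))
  }
  hop1 <- dplyr::filter(as_tibble(circ2mir), .data$source_id %in% circ_ids)
  hop1 <- dplyr::rename(hop1, circ_id = "source_id", mirna_id = "target_id")
  hop2 <- dplyr::rename(as_tibble(mir2mrna),
                        mirna_id = "source_id", mrna_id = "target_id")
  dplyr::distinct(dplyr::inner_join(hop1, hop2, by = "mirna_id",
                                    relationship = "many-to-many"))
}
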