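#' Read an annotation collection from a GMT file
#'
#' Each GMT line is `term_id <TAB> description <TAB> member1 <TAB> member2 ...`.
#' The namespace (GO biological process, molecular function, cellular
#' component, or pathway) is taken from the `description` field when it equals
#' one of `BP`, `MF`, `CC`, `pathway`; otherwise the `namespace` argument
#' applies to every term in the file.
#'
#' @param path Path to a GMT file.
#' @param namespace Fallback namespace label (default `"BP"`).
#' @return A long annotation tibble: `term_id`, `term_name`, `namespace`,
#'   `member_id` (one row per term-member pair).
#' @export
read_gmt <- function(path, namespace = "BP") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warn(sprintf("GMT file '%s' is empty.", path))
    return(tibble(term_id = character(), term_name = character(),
                  namespace = character(), member_id = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    abort(sprintf("GMT '%s': line(s) %s have fewer than 3 fields.",
                  path, paste(head(short, 10), collapse = ", ")))
  }
  purrr::map_dfr(fields, function(f) {
    ns <- if (f[2] %in% c("BP", "MF", "CC", "pathway")) f[2] else namespace
    tibble(term_id = f[1], term_name = f[1], namespace = ns,
           member_id = unique(f[-(1:2)]))
  })
}

#' Build an annotation collection from a named list of member sets
#'
#' Convenience constructor mainly used with simulated data.
#'
#' @param sets Named list of character vectors (term members).
#' @param namespace Single namespace label or vector, recycled over terms.
#' @return A long annotation tibble as produced by [read_gmt()].
#' @export
annotation_collection <- function(sets, namespace = "BP") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be a fully named list.")
  }
  if (anyDuplicated(names(sets))) abort("Term ids must be unique.")
  if (any(lengths(sets) == 0)) abort("Member sets must be nonempty.")
  ns <- rep_len(namespace, length(sets))
  purrr::imap_dfr(sets, function(members, id) {
    tibble(term_id = id, term_name = id,
           namespace = ns[match(id, names(sets))],
           member_id = unique(as.character(members)))
  })
}

#' Annotation-set over-representation of a query gene set
#'
#' For each term with at least one query hit, computes the fold enrichment
#' `(k/n) / (K/N)` — hits over query size, relative to term size over
#' background size — together with a one-sided over-representation p-value:
#' the exact hypergeometric upper tail (Fisher) or a Pearson chi-square on the
#' 2x2 table. Benjamini-Hochberg FDR is computed over the emitted terms only;
#' zero-hit terms are excluded from the family (they are untestable for
#' over-representation and would only dilute the FDR).
#'
#' @param query_mrnas Character vector of query identifiers (e.g. the mRNAs of
#'   a regulatory network); must be a subset of `background`.
#' @param collection Long annotation tibble from [read_gmt()] or
#'   [annotation_collection()].
#' @param background Character vector: the assayed feature universe. Term
#'   members outside the background are not counted.
#' @param method `"fisher"` (exact hypergeometric, default) or `"chisq"`.
#' @return A tibble with one row per term with >= 1 hit: `term_id`,
#'   `term_name`, `namespace`, `k`, `n`, `K`, `N`, `fold_enrichment`,
#'   `p_value`, `fdr`, sorted by ascending p.
#' @export
#' @examples
#' coll <- annotation_collection(list(T1 = paste0("g", 1:10)))
#' enrich(paste0("g", 1:5), coll, paste0("g", 1:100))
enrich <- function(query_mrnas, collection, background,
                   method = c("fisher", "chisq")) {
  method <- match.arg(method)
  query <- unique(as.character(query_mrnas))
  background <- unique(as.character(background))
  outside <- setdiff(query, background)
  if (length(outside)) {
    abort(sprintf("Query ids outside the background: %s%s.",
                  paste(head(outside, 5), collapse = ", "),
                  if (length(outside) > 5) sprintf(" (+%d more)", length(outside) - 5) else ""))
  }
  n <- length(query)
  N <- length(background)
  collection <- dplyr::filter(as_tibble(collection),
                              .data$member_id %in% background)

  res <- collection |>
    dplyr::group_by(.data$term_id, .data$term_name, .data$namespace) |>
    dplyr::summarise(K = dplyr::n_distinct(.data$member_id),
                     k = sum(unique(.data$member_id) %in% query),
                     .groups = "drop")
  n_zero <- sum(res$k == 0)
  if (n_zero) {
    inform(sprintf("%d term(s) with zero query hits omitted.", n_zero))
  }
  res <- dplyr::filter(res, .data$k > 0)
  if (!nrow(res)) {
    return(tibble(term_id = character(), term_name = character(),
                  namespace = character(), k = integer(), n = integer(),
                  K = integer(), N = integer(), fold_enrichment = numeric(),
                  p_value = numeric(), fdr = numeric()))
  }
  res$n <- n
  res$N <- N
  res$fold_enrichment <- (res$k / n) / (res$K / N)
  res$p_value <- if (method == "fisher") {
    phyper(res$k - 1, res$K, N - res$K, n, lower.tail = FALSE)
  } else {
    vapply(seq_len(nrow(res)), function(i) {
      tab <- matrix(c(res$k[i], res$K[i] - res$k[i],
                      n - res$k[i], N - res$K[i] - n + res$k[i]),
                    2, byrow = TRUE)
      suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }, numeric(1))
  }
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res |>
    dplyr::select("term_id", "term_name", "namespace", "k", "n", "K", "N",
                  "fold_enrichment", "p_value", "fdr") |>
    dplyr::arrange(.data$p_value, .data$term_id)
}

#' Top enriched terms per namespace, ranked by fold enrichment
#'
#' Within each namespace, keeps the significant terms (`p_value < 0.05` and
#' `fdr < 0.05`) and returns the top `per_namespace` by descending fold
#' enrichment; ties are broken by ascending p-value, then term id. Namespaces
#' with fewer significant terms return what they have.
#'
#' @param results Enrichment tibble from [enrich()].
#' @param per_namespace Terms to keep per namespace (default 5).
#' @param p_threshold,fdr_threshold Significance cut-offs (default 0.05 both).
#' @return A tibble in ranked order with an added `rank` column.
#' @export
top_terms <- function(results, per_namespace = 5,
                      p_threshold = 0.05, fdr_threshold = 0.05) {
  results <- as_tibble(results)
  if (!nrow(results)) return(dplyr::mutate(results, rank = integer()))
  results |>
    dplyr::filter(.data$p_value < p_threshold, .data$fdr < fdr_threshold) |>
    dplyr::arrange(.data$namespace, dplyr::desc(.data$fold_enrichment),
                   .data$p_value, .data$term_id) |>
    dplyr::group_by(.data$namespace) |>
    dplyr::slice_head(n = per_namespace) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}
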