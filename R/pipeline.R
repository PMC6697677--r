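#' Read a pipeline run configuration from YAML (or JSON)
#'
#' @param path Path to a YAML file; JSON is accepted as a fallback since every
#'   JSON document is valid YAML.
#' @return A plain list suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full ceRNA analysis pipeline
#'
#' Orchestrates simulate (or load) -> quantile-normalize -> differential
#' expression per layer -> tri-layer concordance statistics -> regulatory
#' network construction and export (both directions) -> optional annotation
#' enrichment, writing every stage output under `outdir` together with a JSON
#' run manifest (parameters, seed, per-stage row counts, and an MD5 content
#' hash per file). Re-running with the same configuration reproduces
#' byte-identical outputs.
#'
#' The configuration list understands:
#' \describe{
#'   \item{simulation}{named list of [simulation_config()] arguments
#'     (mutually exclusive with `input`);}
#'   \item{input}{named list of paths: `circRNA`, `miRNA`, `mRNA` expression
#'     TSVs, `samples` sheet, `circ2mir` and `mir2mrna` edge lists;}
#'   \item{fc_threshold, p_threshold}{DE thresholds (defaults 1.5, 0.05);}
#'   \item{normalize}{quantile-normalize each matrix first (default `TRUE`);}
#'   \item{annotations}{optional GMT path or long annotation tibble;}
#'   \item{seed}{optional master seed overriding the simulation seed.}
#' }
#'
#' @param config Configuration list (see Details) or a path understood by
#'   [read_run_config()].
#' @param outdir Output directory.
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  has_sim <- !is.null(config$simulation)
  has_input <- !is.null(config$input)
  if (has_sim == has_input) {
    abort("Supply exactly one of `simulation` or `input` in the configuration.")
  }
  fc_threshold <- config$fc_threshold %||% 1.5
  p_threshold <- config$p_threshold %||% 0.05
  normalize <- config$normalize %||% TRUE
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  counts <- list()

  # -- stage: inputs --------------------------------------------------------
  if (has_sim) {
    sim <- run_stage("simulate", {
      args <- config$simulation
      if (!is.null(config$seed)) args$seed <- config$seed
      generate_expression(do.call(simulation_config, args))
    })
    files <- c(files, write_simulation(sim, file.path(outdir, "simulated")))
    expr <- sim$expression
    samples <- sim$samples
    maps <- sim$maps
    seed_used <- sim$config$seed
  } else {
    inp <- config$input
    needed <- c("circRNA", "miRNA", "mRNA", "samples", "circ2mir", "mir2mrna")
    miss <- setdiff(needed, names(inp))
    if (length(miss)) {
      abort(sprintf("`input` is missing: %s.", paste(miss, collapse = ", ")))
    }
    expr <- run_stage("load", lapply(
      c(circRNA = "circRNA", miRNA = "miRNA", mRNA = "mRNA"),
      function(l) readr::read_tsv(inp[[l]], show_col_types = FALSE)))
    samples <- run_stage("load",
                         readr::read_tsv(inp$samples, show_col_types = FALSE))
    maps <- run_stage("load", list(
      circ2mir = read_edge_list(inp$circ2mir, "circRNA", "miRNA"),
      mir2mrna = read_edge_list(inp$mir2mrna, "miRNA", "mRNA")))
    seed_used <- config$seed %||% NA_integer_
  }

  # -- stage: normalize + differential expression ---------------------------
  de <- run_stage("diffexpr", lapply(expr, function(x) {
    if (normalize) x <- quantile_normalize(x)
    call_de(x, samples, fc_threshold = fc_threshold, p_threshold = p_threshold)
  }))
  for (layer in names(de)) {
    path <- file.path(outdir, sprintf("de_%s.tsv", layer))
    readr::write_tsv(de[[layer]], path)
    files <- c(files, path)
    counts[[sprintf("n_dysregulated_%s", layer)]] <-
      sum(de[[layer]]$direction != "none")
  }

  # -- stage: concordance statistics ----------------------------------------
  conc <- run_stage("concordance", dplyr::bind_rows(
    concordance_table(de$circRNA, de$miRNA, de$mRNA,
                      maps$circ2mir, maps$mir2mrna, "up"),
    concordance_table(de$circRNA, de$miRNA, de$mRNA,
                      maps$circ2mir, maps$mir2mrna, "down")))
  conc_path <- file.path(outdir, "concordance.tsv")
  readr::write_tsv(conc, conc_path)
  files <- c(files, conc_path)
  counts$n_concordance_tests <- nrow(conc)

  # -- stage: regulatory networks -------------------------------------------
  annotations <- config$annotations
  if (is.character(annotations)) annotations <- read_gmt(annotations)
  for (dirn in c("up", "down")) {
    net <- run_stage("network",
                     build_network(de$circRNA, de$mRNA, maps$circ2mir,
                                   maps$mir2mrna, dirn))
    net_dir <- file.path(outdir, sprintf("network_%s", dirn))
    files <- c(files, export_network(net, net_dir, de$circRNA, de$mRNA))
    smry <- summarize_network(net)
    counts[[sprintf("n_triples_%s", dirn)]] <- smry$n_triples
    counts[[sprintf("n_network_mrna_%s", dirn)]] <- smry$n_mrna

    if (!is.null(annotations) && smry$n_mrna > 0) {
      enr <- run_stage("enrich",
                       enrich(unique(net$mrna_id), annotations,
                              de$mRNA$feature_id))
      enr_path <- file.path(outdir, sprintf("enrichment_%s.tsv", dirn))
      readr::write_tsv(enr, enr_path)
      files <- c(files, enr_path)
      counts[[sprintf("n_enriched_terms_%s", dirn)]] <- nrow(enr)
    }
  }

  # -- manifest -------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("cernascope")),
    seed = seed_used,
    parameters = list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                      normalize = normalize,
                      simulation = if (has_sim) unclass(sim$config) else NULL),
    counts = counts,
    files = lapply(setNames(files, sub(paste0("^", outdir, "/?"), "", files)),
                   function(f) list(md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  inform(sprintf("Pipeline complete: %d files under '%s' (seed %s).",
                 length(files) + 1, outdir, seed_used))
  invisible(manifest)
}
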