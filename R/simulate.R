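#' Configuration for the tri-layer sponge-effect simulator
#'
#' Bundles and validates every tunable of the synthetic-data generator: layer
#' sizes, group sizes, the log-normal intensity model, the fraction and size of
#' planted circRNA effects, the penetrance with which those effects propagate
#' to downstream mRNAs, background (off-target) differential expression, and
#' the topology of the two target maps.
#'
#' The defaults describe a desk-scale version of an 8 x 15K circRNA /
#' miRNA / 4 x 44K mRNA microarray study comparing four case against four
#' control brains: layers of 1,000 circRNAs, 100 miRNAs and 5,000 mRNAs,
#' log2-normal intensity noise (`noise_sd = 0.25`), 5% of circRNAs planted up
#' and 5% down at a 4-fold change, each circRNA binding at most five miRNAs
#' (`mre_cap = 5`), and sponge propagation that shifts downstream mRNAs 2-fold
#' in the *same* direction as the planted circRNA with probability 0.5 while
#' leaving miRNA abundance untouched.
#'
#' @param n_circ,n_mirna,n_mrna Number of features per layer.
#' @param n_case,n_control Samples per group (default 4 vs 4).
#' @param baseline_log2_mean_range Length-2 numeric; per-feature baseline
#'   log2 intensities are drawn uniformly from this interval.
#' @param noise_sd Log2-scale standard deviation of the intensity noise.
#' @param frac_circ_up,frac_circ_down Proportions of circRNAs planted as up-
#'   or down-regulated; their sum must not exceed 1.
#' @param circ_effect_fc Fold change (>= 1) applied to planted circRNAs.
#' @param penetrance Probability that an mRNA downstream of a planted circRNA
#'   receives the concordant effect.
#' @param mrna_effect_fc Fold change (>= 1) applied to affected mRNAs (and,
#'   with random sign, to background-dysregulated mRNAs).
#' @param background_de_rate Proportion of mRNAs *outside* the downstream
#'   closure of planted circRNAs that are independently dysregulated with a
#'   random direction.
#' @param mre_cap Maximum number of miRNA targets per circRNA (miRNA response
#'   elements retained per circRNA; default 5).
#' @param mirna_outdegree_range Length-2 integer interval from which each
#'   miRNA's number of mRNA targets is drawn.
#' @param seed Master seed; all layer-specific RNG streams are derived from it
#'   so that, e.g., changing `n_mrna` does not perturb the circRNA draws.
#'
#' @return A `simulation_config` object (a validated named list).
#' @seealso [generate_target_maps()], [generate_expression()]
#' @export
#' @examples
#' cfg <- simulation_config(n_circ = 50, n_mirna = 10, n_mrna = 200,
#'                          mirna_outdegree_range = c(2, 10), seed = 7)
#' cfg$mre_cap
simulation_config <- function(n_circ = 1000,
                              n_mirna = 100,
                              n_mrna = 5000,
                              n_case = 4,
                              n_control = 4,
                              baseline_log2_mean_range = c(6, 12),
                              noise_sd = 0.25,
                              frac_circ_up = 0.05,
                              frac_circ_down = 0.05,
                              circ_effect_fc = 4,
                              penetrance = 0.5,
                              mrna_effect_fc = 2,
                              background_de_rate = 0.01,
                              mre_cap = 5,
                              mirna_outdegree_range = c(10, 50),
                              seed = 1L) {
  cfg <- list(
    n_circ = as.integer(n_circ), n_mirna = as.integer(n_mirna),
    n_mrna = as.integer(n_mrna), n_case = as.integer(n_case),
    n_control = as.integer(n_control),
    baseline_log2_mean_range = as.numeric(baseline_log2_mean_range),
    noise_sd = as.numeric(noise_sd),
    frac_circ_up = as.numeric(frac_circ_up),
    frac_circ_down = as.numeric(frac_circ_down),
    circ_effect_fc = as.numeric(circ_effect_fc),
    penetrance = as.numeric(penetrance),
    mrna_effect_fc = as.numeric(mrna_effect_fc),
    background_de_rate = as.numeric(background_de_rate),
    mre_cap = as.integer(mre_cap),
    mirna_outdegree_range = as.integer(mirna_outdegree_range),
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  counts <- c("n_circ", "n_mirna", "n_mrna", "n_case", "n_control", "mre_cap")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1 || is.na(cfg[[nm]]) || cfg[[nm]] < 1) {
      abort(sprintf("`%s` must be a single count >= 1 (got %s).",
                    nm, deparse(cfg[[nm]])))
    }
  }
  if (cfg$n_case < 2 || cfg$n_control < 2) {
    abort("`n_case` and `n_control` must each be >= 2 for two-group testing.")
  }
  props <- c("frac_circ_up", "frac_circ_down", "penetrance", "background_de_rate")
  for (nm in props) {
    if (length(cfg[[nm]]) != 1 || is.na(cfg[[nm]]) ||
        cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      abort(sprintf("`%s` must be a proportion in [0, 1] (got %s).",
                    nm, deparse(cfg[[nm]])))
    }
  }
  if (cfg$frac_circ_up + cfg$frac_circ_down > 1) {
    abort("`frac_circ_up` + `frac_circ_down` must not exceed 1.")
  }
  for (nm in c("circ_effect_fc", "mrna_effect_fc")) {
    if (length(cfg[[nm]]) != 1 || is.na(cfg[[nm]]) || cfg[[nm]] < 1) {
      abort(sprintf("`%s` must be a fold change >= 1 (got %s).",
                    nm, deparse(cfg[[nm]])))
    }
  }
  if (length(cfg$baseline_log2_mean_range) != 2 ||
      diff(cfg$baseline_log2_mean_range) < 0) {
    abort("`baseline_log2_mean_range` must be a non-decreasing length-2 interval.")
  }
  if (length(cfg$noise_sd) != 1 || is.na(cfg$noise_sd) || cfg$noise_sd <= 0) {
    abort("`noise_sd` must be a single positive number.")
  }
  if (length(cfg$mirna_outdegree_range) != 2 ||
      any(cfg$mirna_outdegree_range < 1) ||
      diff(cfg$mirna_outdegree_range) < 0) {
    abort("`mirna_outdegree_range` must be a non-decreasing length-2 interval of counts >= 1.")
  }
  if (cfg$mirna_outdegree_range[2] > cfg$n_mrna) {
    abort(sprintf(
      "`mirna_outdegree_range` upper bound (%d) exceeds `n_mrna` (%d): each miRNA needs that many distinct mRNA targets.",
      cfg$mirna_outdegree_range[2], cfg$n_mrna))
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) {
    abort("`seed` must be a single integer.")
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  layers: %d circRNA / %d miRNA / %d mRNA; %d case vs %d control\n",
              x$n_circ, x$n_mirna, x$n_mrna, x$n_case, x$n_control))
  cat(sprintf("  planted circRNAs: %.1f%% up, %.1f%% down at FC %.2g; penetrance %.2g -> mRNA FC %.2g\n",
              100 * x$frac_circ_up, 100 * x$frac_circ_down,
              x$circ_effect_fc, x$penetrance, x$mrna_effect_fc))
  cat(sprintf("  noise sd (log2): %.3g; background DE rate: %.3g; seed: %d\n",
              x$noise_sd, x$background_de_rate, x$seed))
  invisible(x)
}

# One sub-seed per independent RNG stream, derived once from the master seed.
# Streams are fixed-name so adding layers later cannot silently reshuffle draws.
derive_stream_seeds <- function(seed) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, 7L),
           c("map_c2m", "map_m2g", "plant", "circ", "mirna", "mrna", "truth"))
}

feature_ids <- function(prefix, n) {
  sprintf("%s_%0*d", prefix, nchar(as.character(n)), seq_len(n))
}

#' Generate circRNA->miRNA and miRNA->mRNA target maps
#'
#' Draws the two directed bipartite target maps used by the simulator. Each
#' circRNA receives between 1 and `mre_cap` distinct miRNA partners (the
#' retained miRNA response elements); each miRNA receives an mRNA out-degree
#' drawn uniformly from `mirna_outdegree_range`, giving the many-to-many
#' miRNA->mRNA layer its emergent in-degree distribution.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `circ2mir` and `mir2mrna`, each a
#'   [target_map()] tibble of `source_id`, `target_id` edges.
#' @export
generate_target_maps <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  streams <- derive_stream_seeds(config$seed)
  circ_ids <- feature_ids("circ", config$n_circ)
  mirna_ids <- feature_ids("mir", config$n_mirna)
  mrna_ids <- feature_ids("mrna", config$n_mrna)

  set.seed(streams[["map_c2m"]])
  cap <- min(config$mre_cap, config$n_mirna)
  out_c <- sample.int(cap, config$n_circ, replace = TRUE)
  c2m <- tibble(
    source_id = rep(circ_ids, out_c),
    target_id = unlist(lapply(out_c, function(k) sample(mirna_ids, k)))
  )

  set.seed(streams[["map_m2g"]])
  rng <- config$mirna_outdegree_range
  out_m <- rng[1] + sample.int(rng[2] - rng[1] + 1L, config$n_mirna,
                               replace = TRUE) - 1L
  m2g <- tibble(
    source_id = rep(mirna_ids, out_m),
    target_id = unlist(lapply(out_m, function(k) sample(mrna_ids, k)))
  )

  list(
    circ2mir = target_map(c2m, "circRNA", "miRNA"),
    mir2mrna = target_map(m2g, "miRNA", "mRNA")
  )
}

# 2^rnorm intensities around per-feature baselines; case-group columns get the
# per-feature log2 offset in `case_shift`.
simulate_layer <- function(ids, n_case, n_control, baseline_range, noise_sd,
                           case_shift) {
  n <- length(ids)
  baseline <- runif(n, baseline_range[1], baseline_range[2])
  total <- n_case + n_control
  noise <- matrix(rnorm(n * total, sd = noise_sd), nrow = n)
  mu <- matrix(baseline, nrow = n, ncol = total)
  mu[, seq_len(n_case)] <- mu[, seq_len(n_case)] + case_shift
  vals <- 2^(mu + noise)
  colnames(vals) <- c(sprintf("case_%d", seq_len(n_case)),
                      sprintf("control_%d", seq_len(n_control)))
  dplyr::bind_cols(tibble(feature_id = ids), as_tibble(vals))
}

#' Simulate tri-layer expression with planted sponge effects
#'
#' Generates one two-group expression matrix per RNA layer under a log2-normal
#' intensity model, plants up-/down-regulated circRNAs, and propagates each
#' planted effect through the target maps as a ceRNA sponge would: downstream
#' mRNAs (reachable via a bridging miRNA) shift in the *same* direction with
#' probability `penetrance`, while miRNA means are never altered — a sponge
#' changes miRNA availability, not miRNA abundance. mRNAs outside the
#' downstream closure are independently dysregulated with a random sign at
#' rate `background_de_rate`. A machine-readable truth record makes every
#' planted and affected feature recoverable for parameter-recovery testing.
#'
#' @param config A [simulation_config()].
#' @param maps Optional list as returned by [generate_target_maps()]; if
#'   omitted, maps are generated from `config` (same seed-derived streams, so
#'   both call patterns agree).
#' @return An object of class `cerna_simulation`: a list with
#'   \describe{
#'     \item{expression}{named list of three wide tibbles (`circRNA`, `miRNA`,
#'       `mRNA`), first column `feature_id`, one column per sample;}
#'     \item{samples}{sample sheet tibble (`sample_id`, `group`);}
#'     \item{maps}{the two target maps;}
#'     \item{truth}{planted/affected feature-id sets and the seed;}
#'     \item{config}{the configuration used.}
#'   }
#' @export
#' @examples
#' sim <- generate_expression(simulation_config(
#'   n_circ = 40, n_mirna = 10, n_mrna = 200,
#'   mirna_outdegree_range = c(2, 8), seed = 11))
#' names(sim$expression)
#' length(sim$truth$planted_circ_up)
generate_expression <- function(config, maps = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(maps)) maps <- generate_target_maps(config)
  streams <- derive_stream_seeds(config$seed)

  circ_ids <- feature_ids("circ", config$n_circ)
  mirna_ids <- feature_ids("mir", config$n_mirna)
  mrna_ids <- feature_ids("mrna", config$n_mrna)

  # -- plant circRNA effects and propagate them through the maps ------------
  set.seed(streams[["plant"]])
  n_up <- round(config$frac_circ_up * config$n_circ)
  n_down <- round(config$frac_circ_down * config$n_circ)
  planted <- sample(circ_ids, n_up + n_down)
  circ_up <- planted[seq_len(n_up)]
  circ_down <- setdiff(planted, circ_up)

  closure <- downstream_mrnas(planted, maps$circ2mir, maps$mir2mrna,
                              quiet = TRUE)
  down_up <- unique(closure$mrna_id[closure$circ_id %in% circ_up])
  down_down <- unique(closure$mrna_id[closure$circ_id %in% circ_down])
  # an mRNA reachable from both planted directions is assigned one at random
  both <- intersect(down_up, down_down)
  if (length(both)) {
    to_up <- as.logical(rbinom(length(both), 1, 0.5))
    down_up <- setdiff(down_up, both[!to_up])
    down_down <- setdiff(down_down, both[to_up])
  }
  hit_up <- down_up[as.logical(rbinom(length(down_up), 1, config$penetrance))]
  hit_down <- down_down[as.logical(rbinom(length(down_down), 1, config$penetrance))]

  downstream_all <- union(down_up, down_down)
  bg_pool <- setdiff(mrna_ids, downstream_all)
  bg_sel <- bg_pool[as.logical(rbinom(length(bg_pool), 1, config$background_de_rate))]
  bg_dir <- if (length(bg_sel)) {
    ifelse(as.logical(rbinom(length(bg_sel), 1, 0.5)), "up", "down")
  } else character(0)

  # -- per-layer intensity draws (independent streams) ----------------------
  d_circ <- log2(config$circ_effect_fc)
  circ_shift <- numeric(config$n_circ)
  circ_shift[match(circ_up, circ_ids)] <- d_circ
  circ_shift[match(circ_down, circ_ids)] <- -d_circ

  d_mrna <- log2(config$mrna_effect_fc)
  mrna_shift <- numeric(config$n_mrna)
  mrna_shift[match(hit_up, mrna_ids)] <- d_mrna
  mrna_shift[match(hit_down, mrna_ids)] <- -d_mrna
  if (length(bg_sel)) {
    mrna_shift[match(bg_sel, mrna_ids)] <- ifelse(bg_dir == "up", d_mrna, -d_mrna)
  }

  set.seed(streams[["circ"]])
  circ_expr <- simulate_layer(circ_ids, config$n_case, config$n_control,
                              config$baseline_log2_mean_range, config$noise_sd,
                              circ_shift)
  set.seed(streams[["mirna"]])
  mirna_expr <- simulate_layer(mirna_ids, config$n_case, config$n_control,
                               config$baseline_log2_mean_range, config$noise_sd,
                               0)
  set.seed(streams[["mrna"]])
  mrna_expr <- simulate_layer(mrna_ids, config$n_case, config$n_control,
                              config$baseline_log2_mean_range, config$noise_sd,
                              mrna_shift)

  samples <- tibble(
    sample_id = c(sprintf("case_%d", seq_len(config$n_case)),
                  sprintf("control_%d", seq_len(config$n_control))),
    group = rep(c("case", "control"), c(config$n_case, config$n_control))
  )

  truth <- list(
    planted_circ_up = circ_up,
    planted_circ_down = circ_down,
    affected_mrna_up = hit_up,
    affected_mrna_down = hit_down,
    background_de_mrna = tibble(mrna_id = bg_sel, direction = bg_dir),
    seed = config$seed
  )

  structure(
    list(
      expression = list(circRNA = circ_expr, miRNA = mirna_expr,
                        mRNA = mrna_expr),
      samples = samples,
      maps = maps,
      truth = truth,
      config = config
    ),
    class = "cerna_simulation"
  )
}

#' @export
print.cerna_simulation <- function(x, ...) {
  cat("<cerna_simulation>\n")
  cat(sprintf("  %d circRNA x %d samples; %d miRNA; %d mRNA\n",
              nrow(x$expression$circRNA), nrow(x$samples),
              nrow(x$expression$miRNA), nrow(x$expression$mRNA)))
  cat(sprintf("  planted circRNAs: %d up / %d down; affected mRNAs: %d up / %d down; background DE: %d\n",
              length(x$truth$planted_circ_up), length(x$truth$planted_circ_down),
              length(x$truth$affected_mrna_up), length(x$truth$affected_mrna_down),
              nrow(x$truth$background_de_mrna)))
  invisible(x)
}

#' Write a simulation to disk as plain-text files
#'
#' Writes one TSV expression matrix per layer, a sample sheet TSV, the two
#' target maps as two-column TSV edge lists, and the truth record as JSON.
#'
#' @param sim A `cerna_simulation` from [generate_expression()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cerna_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    circRNA = file.path(dir, "expr_circRNA.tsv"),
    miRNA = file.path(dir, "expr_miRNA.tsv"),
    mRNA = file.path(dir, "expr_mRNA.tsv"),
    samples = file.path(dir, "samples.tsv"),
    circ2mir = file.path(dir, "map_circ2mir.tsv"),
    mir2mrna = file.path(dir, "map_mir2mrna.tsv"),
    truth = file.path(dir, "truth.json")
  )
  for (layer in names(sim$expression)) {
    readr::write_tsv(sim$expression[[layer]], paths[[layer]])
  }
  readr::write_tsv(sim$samples, paths[["samples"]])
  readr::write_tsv(sim$maps$circ2mir, paths[["circ2mir"]])
  readr::write_tsv(sim$maps$mir2mrna, paths[["mir2mrna"]])
  truth <- sim$truth
  truth$background_de_mrna <- as.list(truth$background_de_mrna)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = FALSE, digits = NA)
  invisible(unname(paths))
}
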