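#' Direction rules for "relevant dysregulation"
#'
#' A direct miRNA target is *relevantly* dysregulated when it moves opposite
#' to its upstream regulator (repression), whereas an mRNA downstream of a
#' circRNA via a bridging miRNA is relevantly dysregulated when it moves in
#' the *same* direction (sponge disinhibition). These defaults can be
#' overridden per analysis through the `rule` argument of
#' [build_contingency()].
#'
#' @return A named character vector of the default rules.
#' @export
direction_rules <- function() {
  c("miRNA->mRNA" = "inverse",
    "circRNA->miRNA" = "inverse",
    "circRNA->mRNA" = "same")
}

relevant_direction <- function(direction, rule) {
  direction <- match.arg(direction, c("up", "down"))
  rule <- match.arg(rule, c("same", "inverse"))
  if (rule == "same") direction else if (direction == "up") "down" else "up"
}

#' Build a 2x2 contingency table of targeting vs relevant dysregulation
#'
#' Cross-classifies every feature of the downstream universe by (i) whether it
#' is targeted by at least one dysregulated upstream feature and (ii) whether
#' it is dysregulated in the direction the rule deems *relevant* (same as the
#' upstream direction under the sponge rule, opposite under direct miRNA
#' repression). The four cells partition the universe.
#'
#' @param downstream_de DE table ([call_de()]) for the downstream layer.
#' @param targeted_ids Identifiers of downstream features targeted by at least
#'   one dysregulated upstream feature (e.g. from [downstream_mrnas()] or a
#'   single [target_map()]).
#' @param direction Direction of the upstream dysregulation, `"up"` or
#'   `"down"`.
#' @param rule `"same"` or `"inverse"`; see [direction_rules()].
#' @param universe Downstream feature universe; defaults to every feature in
#'   `downstream_de`. Must contain all `targeted_ids`.
#' @return A `cerna_contingency` object holding the cells `a` (targeted &
#'   relevantly dysregulated), `b` (targeted & not), `c` (untargeted &
#'   relevantly dysregulated), `d` (untargeted & not), plus direction
#'   metadata and degeneracy flags.
#' @export
build_contingency <- function(downstream_de, targeted_ids,
                              direction = c("up", "down"),
                              rule = c("same", "inverse"),
                              universe = NULL) {
  direction <- match.arg(direction)
  rule <- match.arg(rule)
  universe <- unique(as.character(universe %||% downstream_de$feature_id))
  if (!length(universe)) abort("`universe` is empty.")
  targeted_ids <- unique(as.character(targeted_ids))
  outside <- setdiff(targeted_ids, universe)
  if (length(outside)) {
    abort(sprintf("%d targeted id(s) outside the universe (e.g. %s).",
                  length(outside), paste(head(outside, 3), collapse = ", ")))
  }
  rel_dir <- relevant_direction(direction, rule)
  rel_ids <- downstream_de$feature_id[downstream_de$direction == rel_dir]
  rel_ids <- intersect(rel_ids, universe)

  targeted <- universe %in% targeted_ids
  relevant <- universe %in% rel_ids
  a <- sum(targeted & relevant)
  b <- sum(targeted & !relevant)
  c_ <- sum(!targeted & relevant)
  d <- sum(!targeted & !relevant)

  degenerate <- (a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0
  structure(
    list(a = a, b = b, c = c_, d = d,
         universe_size = length(universe),
         upstream_direction = direction, rule = rule,
         relevant_direction = rel_dir, degenerate = degenerate),
    class = "cerna_contingency"
  )
}

#' @export
print.cerna_contingency <- function(x, ...) {
  cat("<cerna_contingency>",
      sprintf("upstream %s, rule %s -> relevant direction: %s\n",
              x$upstream_direction, x$rule, x$relevant_direction))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("targeted", "untargeted"),
                              c("relevant DE", "not")))
  print(m)
  if (x$degenerate) cat("(degenerate margin: association test undefined)\n")
  invisible(x)
}

as_contingency <- function(x) {
  if (inherits(x, "cerna_contingency")) return(x)
  if (is.numeric(x) && length(x) == 4) {
    x <- as.list(x)
    names(x) <- c("a", "b", "c", "d")
  }
  stopifnot(all(c("a", "b", "c", "d") %in% names(x)))
  cells <- as.numeric(x[c("a", "b", "c", "d")])
  if (any(cells < 0)) abort("Contingency cells must be nonnegative.")
  degenerate <- (cells[1] + cells[2]) == 0 || (cells[3] + cells[4]) == 0 ||
    (cells[1] + cells[3]) == 0 || (cells[2] + cells[4]) == 0
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4],
                 universe_size = sum(cells),
                 upstream_direction = x$upstream_direction %||% NA_character_,
                 rule = x$rule %||% NA_character_,
                 relevant_direction = x$relevant_direction %||% NA_character_,
                 degenerate = degenerate),
            class = "cerna_contingency")
}

#' Odds ratio with Woolf confidence interval and Pearson chi-square p-value
#'
#' Computes the cross-product odds ratio `(a*d)/(b*c)` with the Woolf
#' (log-normal) 95% confidence interval
#' `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))` and a Pearson
#' chi-square p-value without continuity correction. If any cell is zero, the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied for the OR and
#' CI only — the result is flagged — while the p-value still comes from the
#' uncorrected chi-square. A table with a zero row or column margin carries no
#' information about association: the OR is undefined and `p = 1`.
#'
#' @param table A `cerna_contingency` from [build_contingency()], or a numeric
#'   vector/list of the four cells `(a, b, c, d)`.
#' @param conf_level Confidence level for the Woolf interval (default 0.95).
#' @return A `cerna_or_test` object; use [tidy()] for a one-row tibble with
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `correction_applied`,
#'   `undefined`.
#' @export
#' @examples
#' tidy(odds_ratio_test(c(20, 80, 10, 890)))  # OR 22.25, CI ~ (10.07, 49.17)
odds_ratio_test <- function(table, conf_level = 0.95) {
  ct <- as_contingency(table)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- list(table = ct, conf_level = conf_level,
              correction_applied = FALSE, undefined = FALSE)

  if (ct$degenerate) {
    out$odds_ratio <- NA_real_
    out$ci_low <- NA_real_
    out$ci_high <- NA_real_
    out$p_value <- 1
    out$undefined <- TRUE
    return(structure(out, class = "cerna_or_test"))
  }

  cells <- c(ct$a, ct$b, ct$c, ct$d)
  or_cells <- cells
  if (any(cells == 0)) {
    or_cells <- cells + 0.5
    out$correction_applied <- TRUE
  }
  or <- (or_cells[1] * or_cells[4]) / (or_cells[2] * or_cells[3])
  se <- sqrt(sum(1 / or_cells))
  out$odds_ratio <- or
  out$ci_low <- exp(log(or) - z * se)
  out$ci_high <- exp(log(or) + z * se)
  out$p_value <- suppressWarnings(
    chisq.test(matrix(cells, 2, byrow = TRUE), correct = FALSE)$p.value
  )
  structure(out, class = "cerna_or_test")
}

#' @export
print.cerna_or_test <- function(x, ...) {
  cat("<cerna_or_test>\n")
  if (x$undefined) {
    cat("  OR undefined (zero margin); p = 1\n")
  } else {
    cat(sprintf("  OR %.3f  %g%% CI (%.3f, %.3f)  p = %.4g%s\n",
                x$odds_ratio, 100 * x$conf_level, x$ci_low, x$ci_high,
                x$p_value,
                if (x$correction_applied) "  [Haldane-Anscombe +0.5]" else ""))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cerna_or_test <- function(x, ...) {
  tibble(
    odds_ratio = x$odds_ratio,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    p_value = x$p_value,
    correction_applied = x$correction_applied,
    undefined = x$undefined
  )
}

#' @exportS3Method generics::glance
glance.cerna_or_test <- function(x, ...) {
  dplyr::bind_cols(
    tidy(x),
    tibble(a = x$table$a, b = x$table$b, c = x$table$c, d = x$table$d,
           universe_size = x$table$universe_size)
  )
}

# Firth-penalized logistic regression (Jeffreys prior) via modified-score
# Newton iterations; used as the fallback under (quasi-)complete separation,
# where plain ML estimates diverge.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    XtW <- t(X * w)
    info <- XtW %*% X
    inv_info <- solve(info)
    h <- rowSums((X %*% inv_info) * (X * w))
    score <- t(X) %*% (y - p + h * (0.5 - p))
    step <- inv_info %*% score
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  w <- p * (1 - p)
  info <- t(X * w) %*% X
  list(coefficients = beta, vcov = solve(info), iter = iter)
}

#' miRNA-adjusted logistic odds ratio for circRNA targeting
#'
#' Fits a logistic regression of the relevant-dysregulation indicator on two
#' binary predictors — targeted by a dysregulated circRNA (via a bridging
#' miRNA) and targeted directly by a dysregulated miRNA — and reports the
#' exponentiated circRNA coefficient with its Wald confidence interval. This
#' asks whether the sponge association survives adjustment for direct miRNA
#' targeting. A constant miRNA indicator is dropped (the fit then reduces to
#' the univariate model). Under (quasi-)complete separation the maximum-
#' likelihood estimate diverges, so a Firth-penalized fit is substituted and
#' flagged.
#'
#' @param downstream_de DE table for the mRNA layer.
#' @param direction Upstream circRNA direction (`"up"` or `"down"`); the
#'   outcome is dysregulation in the same direction (sponge rule).
#' @param circ_targeted Ids of mRNAs downstream of >= 1 dysregulated circRNA.
#' @param mirna_targeted Ids of mRNAs targeted by >= 1 dysregulated miRNA.
#' @param universe Feature universe (default: all features of
#'   `downstream_de`).
#' @param rule Direction rule linking the upstream circRNA direction to the
#'   relevant downstream direction; default `"same"`.
#' @return A `cerna_adjusted_or` object; [tidy()] gives one row per model term
#'   (odds-ratio scale), [glance()] the circRNA-term summary with fit
#'   metadata.
#' @export
adjusted_logistic <- function(downstream_de, direction = c("up", "down"),
                              circ_targeted, mirna_targeted,
                              universe = NULL, rule = "same") {
  direction <- match.arg(direction)
  universe <- unique(as.character(universe %||% downstream_de$feature_id))
  if (!length(universe)) abort("`universe` is empty.")
  rel_dir <- relevant_direction(direction, rule)
  rel_ids <- intersect(
    downstream_de$feature_id[downstream_de$direction == rel_dir], universe)

  y <- as.integer(universe %in% rel_ids)
  x_circ <- as.integer(universe %in% as.character(circ_targeted))
  x_mir <- as.integer(universe %in% as.character(mirna_targeted))

  drop_mirna <- length(unique(x_mir)) == 1
  if (drop_mirna) {
    inform("miRNA-targeting indicator is constant; fitting the univariate circRNA model.")
  }
  if (length(unique(x_circ)) == 1) {
    abort("circRNA-targeting indicator is constant over the universe; adjusted OR undefined.")
  }

  df <- data.frame(y = y, circ = x_circ, mirna = x_mir)
  form <- if (drop_mirna) y ~ circ else y ~ circ + mirna
  sep_warning <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_warning <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  separated <- sep_warning || !fit$converged || any(abs(coef(fit)) > 15)

  if (separated) {
    X <- stats::model.matrix(form, df)
    ff <- firth_logistic(X, df$y)
    beta <- setNames(ff$coefficients, colnames(X))
    vc <- ff$vcov
    dimnames(vc) <- list(colnames(X), colnames(X))
    method <- "firth"
  } else {
    beta <- coef(fit)
    vc <- vcov(fit)
    method <- "ml"
  }
  se <- unname(sqrt(diag(vc)))
  beta_names <- names(beta)
  beta <- unname(beta)
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  terms <- tibble(
    term = beta_names,
    estimate = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p_value = p
  )
  structure(
    list(terms = terms, method = method, separated = separated,
         mirna_dropped = drop_mirna, direction = direction,
         n = length(universe), fit = if (method == "ml") fit else NULL),
    class = "cerna_adjusted_or"
  )
}

#' @export
print.cerna_adjusted_or <- function(x, ...) {
  ci <- x$terms[x$terms$term == "circ", ]
  cat("<cerna_adjusted_or>\n")
  cat(sprintf("  circRNA-targeting OR %.3f  95%% CI (%.3f, %.3f)  p = %.4g  [%s%s]\n",
              ci$estimate, ci$ci_low, ci$ci_high, ci$p_value, x$method,
              if (x$mirna_dropped) ", univariate" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cerna_adjusted_or <- function(x, ...) x$terms

#' @exportS3Method generics::glance
glance.cerna_adjusted_or <- function(x, ...) {
  ci <- x$terms[x$terms$term == "circ", ]
  tibble(
    odds_ratio = ci$estimate, ci_low = ci$ci_low, ci_high = ci$ci_high,
    p_value = ci$p_value, method = x$method, separated = x$separated,
    mirna_dropped = x$mirna_dropped, n = x$n
  )
}

#' Run the three concordance analyses for one upstream direction
#'
#' Reproduces, per direction, the tri-layer concordance battery:
#' (1) direct miRNA->mRNA — are targets of dysregulated miRNAs enriched for
#' *opposite* dysregulation; (2) circRNA->miRNA — are miRNA targets of
#' dysregulated circRNAs themselves dysregulated (expected null: sponging
#' leaves miRNA abundance unchanged); (3) circRNA->mRNA via bridging miRNAs —
#' are downstream mRNAs enriched for *same*-direction dysregulation, with a
#' miRNA-adjusted logistic OR alongside the univariate chi-square OR.
#'
#' @param circ_de,mirna_de,mrna_de DE tables for the three layers.
#' @param circ2mir,mir2mrna Target maps.
#' @param direction Upstream direction, `"up"` or `"down"`.
#' @return A tibble with one row per analysis: cells, OR, Woolf CI, chi-square
#'   p, and (for the circRNA->mRNA row) adjusted OR, CI and p.
#' @export
concordance_table <- function(circ_de, mirna_de, mrna_de, circ2mir, mir2mrna,
                              direction = c("up", "down")) {
  direction <- match.arg(direction)
  circ_dys <- circ_de$feature_id[circ_de$direction == direction]
  mirna_dys <- mirna_de$feature_id[mirna_de$direction == direction]

  # (1) direct miRNA -> mRNA, inverse rule
  mir_targets <- unique(mir2mrna$target_id[mir2mrna$source_id %in% mirna_dys])
  ct1 <- build_contingency(mrna_de, mir_targets, direction, "inverse")
  r1 <- tidy(odds_ratio_test(ct1))

  # (2) circRNA -> miRNA, inverse rule
  circ_mir_targets <- unique(circ2mir$target_id[circ2mir$source_id %in% circ_dys])
  circ_mir_targets <- intersect(circ_mir_targets, mirna_de$feature_id)
  ct2 <- build_contingency(mirna_de, circ_mir_targets, direction, "inverse")
  r2 <- tidy(odds_ratio_test(ct2))

  # (3) circRNA -> mRNA via bridging miRNAs, same-direction rule + adjustment
  closure <- downstream_mrnas(circ_dys, circ2mir, mir2mrna, quiet = TRUE)
  circ_mrna_targets <- intersect(unique(closure$mrna_id), mrna_de$feature_id)
  ct3 <- build_contingency(mrna_de, circ_mrna_targets, direction, "same")
  r3 <- tidy(odds_ratio_test(ct3))
  adj <- if (length(circ_mrna_targets) &&
             length(circ_mrna_targets) < nrow(mrna_de)) {
    glance(adjusted_logistic(mrna_de, direction, circ_mrna_targets,
                             mir_targets))
  } else {
    tibble(odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           p_value = NA_real_, method = NA_character_, separated = NA,
           mirna_dropped = NA, n = NA_integer_)
  }

  cells <- function(ct) tibble(a = ct$a, b = ct$b, c = ct$c, d = ct$d)
  dplyr::bind_rows(
    dplyr::bind_cols(tibble(analysis = "miRNA->mRNA", direction = direction,
                            relevant = ct1$relevant_direction), cells(ct1), r1),
    dplyr::bind_cols(tibble(analysis = "circRNA->miRNA", direction = direction,
                            relevant = ct2$relevant_direction), cells(ct2), r2),
    dplyr::bind_cols(tibble(analysis = "circRNA->mRNA", direction = direction,
                            relevant = ct3$relevant_direction), cells(ct3), r3,
                     tibble(adjusted_or = adj$odds_ratio,
                            adjusted_ci_low = adj$ci_low,
                            adjusted_ci_high = adj$ci_high,
                            adjusted_p = adj$p_value,
                            adjusted_method = adj$method))
  )
}
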