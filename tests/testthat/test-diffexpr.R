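make_expr <- function(values, ids = sprintf("f%d", seq_len(nrow(values)))) {
  dplyr::bind_cols(tibble::tibble(feature_id = ids),
                   tibble::as_tibble(values, .name_repair = "minimal"))
}

samples_4v4 <- tibble::tibble(
  sample_id = c(paste0("case_", 1:4), paste0("control_", 1:4)),
  group = rep(c("case", "control"), each = 4)
)

test_that("quantile normalization matches the rank-mean worked example", {
  x <- tibble::tibble(feature_id = c("a", "b", "c"),
                      s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  qn <- quantile_normalize(x)
  expect_equal(qn$s1, c(2.5, 3.5, 4.5))
  expect_equal(qn$s2, c(2.5, 3.5, 4.5))

  # two identical columns are already normalized: output equals input
  y <- tibble::tibble(feature_id = c("a", "b"), s1 = c(2, 1), s2 = c(2, 1))
  expect_equal(quantile_normalize(y), y)
})

test_that("after quantile normalization all columns share one sorted multiset", {
  set.seed(9)
  m <- matrix(2^rnorm(60, 8), nrow = 10)
  colnames(m) <- paste0("s", 1:6)
  qn <- quantile_normalize(make_expr(m))
  sorted <- apply(as.matrix(qn[, -1]), 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1])
  expect_equal(qn$feature_id, sprintf("f%d", 1:10))
})

test_that("single-sample matrices pass through with a warning", {
  x <- tibble::tibble(feature_id = "a", s1 = 3)
  expect_warning(out <- quantile_normalize(x), "one sample")
  expect_equal(out, x)
})

test_that("exact test reproduces complete-separation and tied worked examples", {
  expect_equal(mann_whitney_exact(c(8, 9, 10, 11), c(1, 2, 3, 4)), 2 / 70)
  expect_equal(mann_whitney_exact(c(1, 2, 3, 4), c(8, 9, 10, 11)), 2 / 70)
  expect_equal(mann_whitney_exact(c(5, 5, 5, 5), c(5, 5, 5, 5)), 1)
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(1, 2, 3)), 1)
})

test_that("attainable 4-vs-4 p-values form a finite set with minimum 2/70", {
  set.seed(101)
  ps <- replicate(300, {
    v <- sample(100, 8)
    mann_whitney_exact(v[1:4], v[5:8])
  })
  expect_gte(min(ps), 2 / 70)
  # untied 4 vs 4: attainable two-sided p-values are k/70 for even k
  expect_true(all(abs(ps * 70 - round(ps * 70)) < 1e-9))
  expect_lte(length(unique(round(ps * 70))), 35)
})

test_that("exact test agrees with enumeration oracle and wilcox.test", {
  set.seed(202)
  for (i in 1:100) {
    v <- sample(1000, 8)
    case <- v[1:4]; ctrl <- v[5:8]
    p <- mann_whitney_exact(case, ctrl)
    expect_equal(p, oracle_mw_p(case, ctrl))
    expect_equal(p, stats::wilcox.test(case, ctrl, exact = TRUE)$p.value)
  }
  # with ties the enumeration oracle (midranks) is still matched
  for (i in 1:50) {
    v <- sample(5, 8, replace = TRUE)
    expect_equal(mann_whitney_exact(v[1:4], v[5:8]), oracle_mw_p(v[1:4], v[5:8]))
  }
  # unbalanced group sizes
  for (i in 1:25) {
    v <- sample(1000, 9)
    expect_equal(mann_whitney_exact(v[1:3], v[4:9]), oracle_mw_p(v[1:3], v[4:9]))
  }
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(303)
  x <- rnorm(20, 1); y <- rnorm(20)
  p <- mann_whitney_exact(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(p, ref, tolerance = 1e-10)
})

test_that("call_de applies the joint fold-change + p rule per direction", {
  # feature 1: strong up with complete separation; feature 2: FC below 1.5;
  # feature 3: strong down; feature 4: flat
  m <- rbind(c(40, 41, 42, 43, 10, 11, 12, 13),
             c(14, 14.2, 14.1, 14.3, 10, 10.1, 10.2, 10.3),
             c(10, 11, 12, 13, 40, 41, 42, 43),
             c(10, 11, 12, 13, 10.5, 11.5, 12.5, 13.4))
  colnames(m) <- samples_4v4$sample_id
  de <- call_de(make_expr(m), samples_4v4)
  expect_equal(de$direction, c("up", "none", "down", "none"))
  expect_equal(de$fold_change[1], mean(m[1, 1:4]) / mean(m[1, 5:8]))
  expect_equal(de$p_value[1], 2 / 70)
  # BH FDR dominates p and is reported for every feature
  expect_true(all(de$fdr >= de$p_value))
})

test_that("fold change is symmetric under group relabeling", {
  set.seed(404)
  m <- matrix(2^rnorm(80, 8), nrow = 10)
  colnames(m) <- samples_4v4$sample_id
  flipped <- samples_4v4
  flipped$group <- rev(flipped$group)
  de1 <- call_de(make_expr(m), samples_4v4)
  de2 <- call_de(make_expr(m), flipped)
  expect_equal(de1$fold_change, 1 / de2$fold_change)
  expect_equal(de1$p_value, de2$p_value)
  swap <- c(up = "down", down = "up", none = "none")
  expect_equal(unname(swap[de1$direction]), de2$direction)
})

test_that("raising the fold-change threshold never adds calls", {
  sim <- generate_expression(tiny_config(seed = 51))
  expr <- sim$expression$mRNA
  n_calls <- vapply(c(1.2, 1.5, 2, 3), function(th) {
    sum(call_de(expr, sim$samples, fc_threshold = th)$direction != "none")
  }, numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("log-scale fold change option uses geometric means", {
  m <- rbind(c(8, 16, 8, 16, 2, 4, 2, 4))
  colnames(m) <- samples_4v4$sample_id
  de <- call_de(make_expr(m), samples_4v4, log_scale_fc = TRUE)
  expect_equal(de$fold_change, 2^(mean(log2(m[1, 1:4])) - mean(log2(m[1, 5:8]))))
})

test_that("null exact p-values are uniform over the attainable set at 4 vs 4", {
  # under H0 each of the 70 rank assignments is equally likely, so the
  # two-sided p-value P takes value p with probability p - (previous p)
  set.seed(77)
  cfg <- tiny_config(seed = 66, frac_circ_up = 0, frac_circ_down = 0,
                     background_de_rate = 0, n_mrna = 2000)
  sim <- generate_expression(cfg)
  de <- call_de(sim$expression$mRNA, sim$samples)
  # attainable two-sided p at untied 4 vs 4, from the rank-sum null counts
  # (1, 1, 2, 3, 5 for W = 10..14): doubled cumulative tails over 70
  attainable <- c(2, 4, 8, 14, 24) / 70
  for (p0 in attainable) {
    expect_equal(mean(de$p_value <= p0 + 1e-9), p0, tolerance = 0.2)
  }
  expect_equal(mean(de$p_value <= 1), 1)
})

test_that("time specificity reproduces count arithmetic and flags mismatches", {
  expect_equal(specificity_from_counts(101, 12, 2)$fraction_specific,
               100 * 109 / 111)
  expect_equal(specificity_from_counts(163, 121, 65)$fraction_specific,
               100 * 154 / 219)
  s <- specificity_from_counts(10, 5, 0)
  expect_equal(s$fraction_specific, 100)
  expect_error(specificity_from_counts(3, 2, 4), "n_both")

  de1 <- tibble::tibble(feature_id = c("a", "b", "c"),
                        direction = c("up", "none", "down"))
  de2 <- tibble::tibble(feature_id = c("a", "b", "c"),
                        direction = c("up", "up", "none"))
  s <- time_specificity(de1, de2)
  expect_equal(s$n_time1, 2)
  expect_equal(s$n_time2, 2)
  expect_equal(s$n_both, 1)
  expect_equal(s$n_distinct, 3)
  expect_equal(s$fraction_specific, 100 * 2 / 3)

  de3 <- tibble::tibble(feature_id = c("a", "x"), direction = c("up", "none"))
  expect_error(time_specificity(de1, de3), "universes")
})
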