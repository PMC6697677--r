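de_table <- function(ids, direction) {
  tibble::tibble(feature_id = ids, fold_change = 1, p_value = 1, fdr = 1,
                 direction = direction)
}

test_that("contingency cells match the manual worked example", {
  # universe of 10 mRNAs, 4 targeted of which 2 up, 6 untargeted of which 1 up
  ids <- sprintf("g%d", 1:10)
  de <- de_table(ids, c("up", "up", "none", "none",   # targeted g1..g4
                        "up", "none", "none", "none", "none", "none"))
  ct <- build_contingency(de, targeted_ids = ids[1:4], direction = "up",
                          rule = "same")
  expect_equal(c(ct$a, ct$b, ct$c, ct$d), c(2, 2, 1, 5))
  expect_equal(ct$universe_size, 10)
  expect_false(ct$degenerate)

  # inverse rule: relevant direction flips to "down"
  ct2 <- build_contingency(de, ids[1:4], "up", "inverse")
  expect_equal(c(ct2$a, ct2$b), c(0, 4))
})

test_that("degenerate margins are flagged and give p = 1", {
  ids <- sprintf("g%d", 1:6)
  de <- de_table(ids, c("up", "none", "none", "up", "none", "none"))
  # no targeted features
  ct <- build_contingency(de, character(0), "up", "same")
  expect_true(ct$degenerate)
  res <- odds_ratio_test(ct)
  expect_true(res$undefined)
  expect_equal(res$p_value, 1)
  expect_true(is.na(res$odds_ratio))
  # targeted set = universe
  ct <- build_contingency(de, ids, "up", "same")
  expect_true(ct$degenerate)
  expect_equal(odds_ratio_test(ct)$p_value, 1)
})

test_that("cells always partition the universe", {
  set.seed(808)
  for (i in 1:20) {
    n <- sample(10:100, 1)
    ids <- sprintf("g%d", seq_len(n))
    de <- de_table(ids, sample(c("up", "down", "none"), n, replace = TRUE))
    targeted <- sample(ids, sample(0:n, 1))
    ct <- build_contingency(de, targeted, sample(c("up", "down"), 1),
                            sample(c("same", "inverse"), 1))
    expect_equal(ct$a + ct$b + ct$c + ct$d, n)
  }
})

test_that("targeted ids outside the universe are an error", {
  de <- de_table(c("g1", "g2"), c("up", "none"))
  expect_error(build_contingency(de, c("g1", "zz"), "up", "same"), "universe")
})

test_that("odds ratio and Woolf CI match hand arithmetic", {
  res <- odds_ratio_test(c(20, 80, 10, 890))
  expect_equal(res$odds_ratio, 22.25)
  expect_equal(res$ci_low, exp(log(22.25) - qnorm(0.975) *
                                 sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 890)))
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 890)
  expect_equal(round(res$ci_low, 1), round(exp(log(22.25) - 1.96 * se), 1))
  expect_equal(round(res$ci_high, 1), round(exp(log(22.25) + 1.96 * se), 1))
  # symmetric table: no association
  for (k in c(1, 5, 50)) {
    res <- odds_ratio_test(c(k, k, k, k))
    expect_equal(res$odds_ratio, 1)
    expect_equal(res$p_value, 1)
  }
})

test_that("zero cells trigger the flagged Haldane-Anscombe correction", {
  res <- odds_ratio_test(c(0, 10, 5, 85))
  expect_true(res$correction_applied)
  expect_equal(res$odds_ratio, (0.5 * 85.5) / (10.5 * 5.5))
  expect_false(res$undefined)
  # p still from the uncorrected chi-square on the raw cells
  expect_equal(res$p_value, oracle_chisq_p(0, 10, 5, 85))
})

test_that("OR/CI/chi-square agree with direct-formula oracles on random tables", {
  set.seed(909)
  for (i in 1:200) {
    cells <- sample(1:50, 4, replace = TRUE)
    res <- odds_ratio_test(cells)
    expect_equal(res$odds_ratio, (cells[1] * cells[4]) / (cells[2] * cells[3]))
    se <- sqrt(sum(1 / cells))
    expect_equal(res$ci_low, exp(log(res$odds_ratio) - qnorm(0.975) * se))
    expect_equal(res$ci_high, exp(log(res$odds_ratio) + qnorm(0.975) * se))
    expect_equal(res$p_value, oracle_chisq_p(cells[1], cells[2], cells[3], cells[4]))
  }
})

test_that("OR transforms correctly under row/column swaps", {
  set.seed(919)
  for (i in 1:25) {
    cells <- sample(1:40, 4, replace = TRUE)
    or <- odds_ratio_test(cells)$odds_ratio
    both <- odds_ratio_test(cells[c(4, 3, 2, 1)])$odds_ratio # swap rows+cols
    rows <- odds_ratio_test(cells[c(3, 4, 1, 2)])$odds_ratio # swap rows only
    expect_equal(both, or)
    expect_equal(rows, 1 / or)
  }
})

test_that("adjusted logistic matches glm and reduces to univariate when unconfounded", {
  set.seed(111)
  n <- 2000
  ids <- sprintf("g%d", seq_len(n))
  x_circ <- rbinom(n, 1, 0.3)
  x_mir <- rbinom(n, 1, 0.4)  # independent of x_circ
  pr <- plogis(-2 + 1.2 * x_circ)
  y <- rbinom(n, 1, pr)
  de <- de_table(ids, ifelse(y == 1, "up", "none"))
  fit <- adjusted_logistic(de, "up", ids[x_circ == 1], ids[x_mir == 1])
  ref <- glm(y ~ x_circ + x_mir, family = binomial())
  expect_equal(glance(fit)$odds_ratio, unname(exp(coef(ref)["x_circ"])),
               tolerance = 1e-6)
  expect_equal(fit$method, "ml")

  # no miRNA-targeted genes at all: indicator dropped, equals univariate fit
  expect_message(fit0 <- adjusted_logistic(de, "up", ids[x_circ == 1],
                                           character(0)),
                 "constant")
  uni <- glm(y ~ x_circ, family = binomial())
  expect_equal(glance(fit0)$odds_ratio, unname(exp(coef(uni)["x_circ"])),
               tolerance = 1e-6)
  expect_true(fit0$mirna_dropped)

  # adjusted and univariate agree when predictors are independent
  expect_equal(glance(fit)$odds_ratio, glance(fit0)$odds_ratio, tolerance = 0.15)
})

test_that("complete separation falls back to a flagged Firth fit", {
  n <- 200
  ids <- sprintf("g%d", seq_len(n))
  x_circ <- rep(c(1, 0), each = n / 2)
  y <- x_circ  # perfectly separated outcome
  de <- de_table(ids, ifelse(y == 1, "up", "none"))
  fit <- suppressMessages(
    adjusted_logistic(de, "up", ids[x_circ == 1], character(0)))
  expect_true(fit$separated)
  expect_equal(fit$method, "firth")
  expect_true(is.finite(glance(fit)$odds_ratio))
  expect_gt(glance(fit)$odds_ratio, 1)
})

test_that("concordance_table reproduces the sponge asymmetry on one run", {
  sim <- generate_expression(tiny_config(seed = 99, n_circ = 200,
                                         n_mirna = 40, n_mrna = 1500))
  de <- lapply(sim$expression, call_de, samples = sim$samples)
  tab <- suppressMessages(
    concordance_table(de$circRNA, de$miRNA, de$mRNA,
                      sim$maps$circ2mir, sim$maps$mir2mrna, "up"))
  expect_equal(tab$analysis,
               c("miRNA->mRNA", "circRNA->miRNA", "circRNA->mRNA"))
  cm <- tab[tab$analysis == "circRNA->mRNA", ]
  expect_gt(cm$odds_ratio, 1)
  expect_lt(cm$p_value, 0.05)
  expect_gt(cm$adjusted_or, 1)
  # circRNA->miRNA row: miRNA layer is null by construction
  expect_gte(tab$p_value[tab$analysis == "circRNA->miRNA"], 0.05)
  # partition invariant on every row
  expect_true(all(tab$a + tab$b + tab$c + tab$d %in%
                    c(nrow(de$mRNA), nrow(de$miRNA))))
})
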