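# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: plain loops over enumerated
# permutations, edge pairs and hypergeometric terms.

# Two-sided Mann-Whitney p by direct enumeration over group relabelings of
# the raw values (rank-sum computed per relabeling from scratch).
oracle_mw_p <- function(case, control) {
  pooled <- c(case, control)
  n <- length(pooled)
  n1 <- length(case)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(n, n1)
  sums <- apply(sets, 2, function(idx) sum(r[idx]))
  lo <- mean(sums <= obs + 1e-9)
  hi <- mean(sums >= obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Pearson chi-square p-value from expected counts, no continuity correction.
oracle_chisq_p <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  n <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  if (any(expd == 0)) return(NA_real_)
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# circ -> mRNA reachability by a double loop over all edge pairs.
oracle_join <- function(circ_ids, c2m, m2g) {
  out <- list()
  k <- 0
  for (i in seq_len(nrow(c2m))) {
    if (!(c2m$source_id[i] %in% circ_ids)) next
    for (j in seq_len(nrow(m2g))) {
      if (m2g$source_id[j] == c2m$target_id[i]) {
        k <- k + 1
        out[[k]] <- c(c2m$source_id[i], c2m$target_id[i], m2g$target_id[j])
      }
    }
  }
  if (!k) {
    return(tibble::tibble(circ_id = character(), mirna_id = character(),
                          mrna_id = character()))
  }
  m <- unique(do.call(rbind, out))
  tibble::tibble(circ_id = m[, 1], mirna_id = m[, 2], mrna_id = m[, 3])
}

# Regulatory triples by a triple loop over (circ, miRNA, mRNA) candidates.
oracle_triples <- function(circ_de, mrna_de, c2m, m2g, direction) {
  circs <- circ_de$feature_id[circ_de$direction == direction]
  mrnas <- mrna_de$feature_id[mrna_de$direction == direction]
  mirnas <- unique(c(c2m$target_id, m2g$source_id))
  out <- list(); k <- 0
  for (ci in circs) for (mi in mirnas) for (gi in mrnas) {
    if (any(c2m$source_id == ci & c2m$target_id == mi) &&
        any(m2g$source_id == mi & m2g$target_id == gi)) {
      k <- k + 1
      out[[k]] <- c(ci, mi, gi)
    }
  }
  if (!k) {
    return(tibble::tibble(circ_id = character(), mirna_id = character(),
                          mrna_id = character()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(circ_id = m[, 1], mirna_id = m[, 2], mrna_id = m[, 3])
}

# Hypergeometric upper-tail P(X >= k) by direct summation of choose() terms.
oracle_hyper_p <- function(k, K, n, N) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Small, fast simulation used in several tests.
tiny_config <- function(seed = 1, ...) {
  args <- list(
    n_circ = 60, n_mirna = 15, n_mrna = 300,
    mirna_outdegree_range = c(3, 10),
    frac_circ_up = 0.1, frac_circ_down = 0.1,
    background_de_rate = 0.02, seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

sort_triples <- function(x) {
  df <- data.frame(circ_id = as.character(x$circ_id),
                   mirna_id = as.character(x$mirna_id),
                   mrna_id = as.character(x$mrna_id))
  df <- df[order(df$circ_id, df$mirna_id, df$mrna_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
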