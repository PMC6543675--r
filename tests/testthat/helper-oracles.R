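# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to the two groups (no ties assumed).
mw_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  u_of <- function(a) {
    xa <- pooled[a]
    ya <- pooled[-a]
    sum(outer(xa, ya, ">"))
  }
  u_all <- apply(idx, 2, u_of)
  u_obs <- sum(outer(x, y, ">"))
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# Textbook Benjamini-Hochberg step-up, written independently of p.adjust.
bh_step_up_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Permutation null for the log-rank statistic.
logrank_perm_p <- function(data, n_perm, seed) {
  obs <- logrank_test(data)$chi_square
  g <- data$group
  withr::with_seed(seed, {
    stats <- replicate(n_perm, {
      d2 <- data
      d2$group <- sample(g)
      logrank_test(d2)$chi_square
    })
  })
  mean(stats >= obs)
}

# Largest fraction of `planted` ids found in any window of length
# length(planted) along a leaf ordering.
block_purity <- function(ord, planted) {
  w <- length(planted)
  hit <- as.numeric(ord %in% planted)
  if (length(ord) < w) return(NA_real_)
  runsum <- stats::filter(hit, rep(1, w), sides = 1)
  max(runsum, na.rm = TRUE) / w
}

# Small exchangeable survival data set.
random_surv_data <- function(n, seed, rate = 0.05, cens_rate = 0.03,
                             p_group = 0.5, round_digits = NULL) {
  withr::with_seed(seed, {
    t_ev <- rexp(n, rate)
    t_c <- rexp(n, cens_rate)
    time <- pmin(t_ev, t_c)
    if (!is.null(round_digits)) time <- round(time, round_digits) + 10^(-round_digits - 1)
    data.frame(
      time = time,
      event = t_ev <= t_c,
      group = runif(n) < p_group
    )
  })
}

# Tiny LFQ fixture with hand-planted patterns over the standard 5-line,
# 3x2-replicate design.
toy_lfq <- function(patterns, noise_sd = 0.05, seed = 1, base = 25) {
  sim <- simulate_lfq(sim_config(n_proteins = 1, n_basal_up = 0,
                                 missing_rate = 0), seed = 1)
  samples <- sim$samples
  withr::with_seed(seed, {
    rows <- lapply(names(patterns), function(id) {
      by_line <- patterns[[id]]
      mu <- base + by_line[samples$cell_line]
      rnorm(nrow(samples), mu, noise_sd)
    })
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(patterns)
  colnames(m) <- samples$sample_id
  lfq <- dplyr::bind_cols(tibble::tibble(protein_id = rownames(m)),
                          tibble::as_tibble(m))
  list(lfq = lfq, samples = samples)
}

screen_sim_config <- function(planted_combos = list(), n_basal = 400) {
  sim_config(
    n_genes = 20, n_diff_genes = 0,
    n_patients_by_subtype = c(Basal = n_basal, LumA = 50, LumB = 50,
                              Her2 = 20, Normal = 10),
    planted_combos = planted_combos
  )
}

planted_screen_combos <- function() {
  list(
    list(genes = sprintf("G%04d", 1:4), fraction = 0.15, hr = 3),
    list(genes = sprintf("G%04d", 5:8), fraction = 0.15, hr = 3),
    list(genes = sprintf("G%04d", 9:12), fraction = 0.15, hr = 3)
  )
}
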