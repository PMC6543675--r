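#' Screen configuration
#'
#' Bundles the thresholds of the co-overexpression combination screen.
#' Defaults reproduce the overall-survival screen: combinations of up to 5
#' genes, log-rank p < 0.05 and lower 95% CI of the hazard ratio > 1 in
#' every cohort, and an altered-subpopulation floor of 8% of the analysis
#' population. The distant-relapse screen variant uses a 10% floor (see
#' [drfs_screen()]).
#'
#' @param max_k Largest combination size (default 5).
#' @param alpha Log-rank significance threshold (default 0.05).
#' @param require_ci_low_gt_1 Require the lower Wald CI bound of the hazard
#'   ratio to exceed 1 (default `TRUE`).
#' @param min_altered_fraction Minimum altered fraction of the analysis
#'   population, applied to the altered group and its complement
#'   (default 0.08).
#' @param subtype_scope PAM50 labels defining the analysis population
#'   (default `"Basal"`).
#' @param median_scope `"subtype"` (default): the per-gene overexpression
#'   threshold is the median z over the subtype-scoped analysis population;
#'   `"cohort"`: median over all patients of the cohort.
#' @param prune Skip survival tests for combinations failing the fraction
#'   floor, and skip later cohorts once one fails (default `TRUE`). Pruning
#'   never changes which combinations pass; `prune = FALSE` is the slow
#'   oracle path that evaluates everything.
#' @param report_all Keep one row per evaluated combination (default) or
#'   only passing rows.
#' @return A list of class `secep_screen_config`.
#' @export
screen_config <- function(max_k = 5, alpha = 0.05, require_ci_low_gt_1 = TRUE,
                          min_altered_fraction = 0.08,
                          subtype_scope = "Basal",
                          median_scope = c("subtype", "cohort"),
                          prune = TRUE, report_all = TRUE) {
  stopifnot(max_k >= 1, alpha > 0, alpha < 1,
            min_altered_fraction >= 0, min_altered_fraction < 1)
  structure(
    list(max_k = max_k, alpha = alpha,
         require_ci_low_gt_1 = require_ci_low_gt_1,
         min_altered_fraction = min_altered_fraction,
         subtype_scope = subtype_scope,
         median_scope = match.arg(median_scope),
         prune = prune, report_all = report_all),
    class = "secep_screen_config"
  )
}

#' Altered-patient mask for a gene combination
#'
#' A patient is "altered" for a combination when their z-score exceeds
#' (strictly) the per-gene median z over the analysis population for
#' *every* gene in the combination.
#'
#' @param cohort A [secep_cohort()].
#' @param genes Character vector of gene ids.
#' @param population Patient ids forming the analysis population (default:
#'   all patients in the cohort).
#' @param median_population Patient ids over which the per-gene medians are
#'   taken (default: `population`).
#' @return Named logical vector over `population`.
#' @export
altered_mask <- function(cohort, genes, population = NULL,
                         median_population = NULL) {
  missing_g <- setdiff(genes, rownames(cohort$z))
  if (length(missing_g)) {
    stop_secepr(paste0("gene(s) not in cohort '", cohort$name, "': ",
                       paste(missing_g, collapse = ", ")))
  }
  population <- population %||% colnames(cohort$z)
  if (!length(population)) stop_secepr("analysis population is empty")
  median_population <- median_population %||% population
  z_pop <- cohort$z[genes, population, drop = FALSE]
  med <- apply(cohort$z[genes, median_population, drop = FALSE], 1, median)
  mask <- colSums(z_pop > med) == length(genes)
  setNames(mask, population)
}

#' Number of gene combinations of size 1..max_k
#'
#' @param n Number of candidate genes.
#' @param max_k Largest combination size.
#' @return `sum(choose(n, 1:min(max_k, n)))`, computed analytically.
#' @export
n_combinations <- function(n, max_k) {
  sum(choose(n, seq_len(min(max_k, n))))
}

#' Enumerate gene combinations
#'
#' All subsets of size 1..`max_k` of the (deduplicated, sorted) gene list,
#' in lexicographic order within and across sizes; deterministic.
#'
#' @param genes Character vector of candidate genes.
#' @param max_k Largest subset size; capped at `length(genes)` with a
#'   warning if larger.
#' @return Tibble with a list-column `genes` (sorted tuples) and `k`.
#' @export
enumerate_combinations <- function(genes, max_k) {
  genes <- sort(unique(genes))
  n <- length(genes)
  if (max_k > n) {
    rlang::warn(paste0("max_k > number of genes; capped at ", n))
    max_k <- n
  }
  out <- purrr::map_dfr(seq_len(max_k), function(k) {
    cmb <- combn(genes, k, simplify = FALSE)
    tibble::tibble(genes = cmb, k = k)
  })
  out
}

# Per-cohort precomputation shared by every combination: scoped analysis
# population, per-gene overexpression masks, and the survival sort order.
cohort_screen_data <- function(cohort, genes, config) {
  missing_g <- setdiff(genes, rownames(cohort$z))
  if (length(missing_g)) {
    stop_secepr(paste0("gene(s) not in cohort '", cohort$name, "': ",
                       paste(missing_g, collapse = ", ")))
  }
  cl <- cohort$clinical
  scoped <- cl$pam50 %in% config$subtype_scope & cl$has_survival
  if (!any(scoped)) {
    stop_secepr(paste0("no patients with survival in scope for cohort '",
                       cohort$name, "'"))
  }
  pop <- cl$patient_id[scoped]
  med_pop <- if (config$median_scope == "subtype") pop else cl$patient_id
  z_pop <- cohort$z[genes, pop, drop = FALSE]
  med <- apply(cohort$z[genes, med_pop, drop = FALSE], 1, median)
  masks <- z_pop > med # genes x scoped patients
  pre <- surv_precompute(cl$time[scoped], cl$event[scoped])
  list(
    name = cohort$name, masks = masks, pre = pre,
    event = as.integer(cl$event[scoped]), n = length(pop)
  )
}

# Evaluate one combination (row indices into the mask matrix) in one
# prepared cohort. Returns a numeric vector of the per-cohort record plus
# a character fail reason ("" if the cohort's criteria are all met).
eval_combo_cohort <- function(prep, idx, config, run_survival = TRUE,
                              strict_fraction = FALSE,
                              survival_criteria = TRUE) {
  k <- length(idx)
  mask <- if (k == 1) prep$masks[idx, ] else colSums(prep$masks[idx, , drop = FALSE]) == k
  n_alt <- sum(mask)
  frac <- n_alt / prep$n
  ok_frac <- if (strict_fraction) {
    frac > config$min_altered_fraction && (1 - frac) > config$min_altered_fraction
  } else {
    frac >= config$min_altered_fraction && (1 - frac) >= config$min_altered_fraction
  }
  rec <- c(n = prep$n, n_altered = n_alt, altered_fraction = frac,
           n_events_altered = NA_real_, n_events_unaltered = NA_real_,
           logrank_p = NA_real_, hr = NA_real_, ci_low = NA_real_,
           ci_high = NA_real_)
  if (!ok_frac && config$prune) {
    return(list(rec = rec, pass = FALSE, reason = "min_fraction"))
  }
  reasons <- character()
  if (!ok_frac) reasons <- "min_fraction"
  if (run_survival && n_alt > 0 && n_alt < prep$n) {
    g <- as.integer(mask)
    rec["n_events_altered"] <- sum(prep$event[mask])
    rec["n_events_unaltered"] <- prep$pre$n_events - rec["n_events_altered"]
    lr <- tryCatch(logrank_core(prep$pre, g), error = function(e) NULL)
    cx <- tryCatch(cox_core(prep$pre, g), error = function(e) NULL)
    if (!is.null(lr)) {
      rec["logrank_p"] <- lr$p
      if (survival_criteria && !(lr$p < config$alpha)) reasons <- c(reasons, "logrank_p")
    } else if (survival_criteria) reasons <- c(reasons, "logrank_failed")
    if (!is.null(cx)) {
      rec["hr"] <- cx$hr
      rec["ci_low"] <- cx$ci_low
      rec["ci_high"] <- cx$ci_high
      if (survival_criteria && config$require_ci_low_gt_1 &&
          !(isTRUE(cx$converged) && cx$ci_low > 1)) {
        reasons <- c(reasons, "ci_low")
      }
    } else if (survival_criteria && config$require_ci_low_gt_1) {
      reasons <- c(reasons, "cox_failed")
    }
  } else if (run_survival) {
    reasons <- c(reasons, "degenerate_mask")
  }
  list(rec = rec, pass = length(reasons) == 0, reason = paste(reasons, collapse = "+"))
}

#' Evaluate one gene combination in one cohort
#'
#' @param genes Character vector (the combination).
#' @param cohort A [secep_cohort()].
#' @param config A [screen_config()].
#' @return One-row tibble with the per-cohort record, `passes` and
#'   `fail_reasons`.
#' @export
evaluate_combo <- function(genes, cohort, config = screen_config()) {
  prep <- cohort_screen_data(cohort, genes, config)
  res <- eval_combo_cohort(prep, seq_along(genes), config)
  out <- tibble::as_tibble(as.list(res$rec))
  dplyr::bind_cols(
    tibble::tibble(genes = paste(sort(genes), collapse = "+"), k = length(genes)),
    out,
    tibble::tibble(passes = res$pass, fail_reasons = res$reason)
  )
}

#' Exhaustive dual-cohort combination screen
#'
#' Enumerates every combination of 1..`max_k` SeCEP genes and tests, in
#' each cohort, whether the co-overexpressing ("altered") subpopulation has
#' significantly worse survival than its complement. A combination passes
#' when it meets the fraction floor, the log-rank threshold and (by
#' default) hazard-ratio lower-CI > 1 in *every* cohort; with a discovery +
#' validation cohort pair this is the dual-cohort replication criterion.
#' Results come back in deterministic (lexicographic) order.
#'
#' @param cohorts A [secep_cohort()] or (named) list of them, ordered
#'   discovery first.
#' @param genes Candidate (SeCEP) gene ids.
#' @param config A [screen_config()].
#' @return A `secep_screen` tibble: `genes`, `k`, per-cohort columns
#'   (`<name>_n`, `<name>_n_altered`, `<name>_altered_fraction`,
#'   `<name>_n_events_altered`, `<name>_n_events_unaltered`,
#'   `<name>_logrank_p`, `<name>_hr`, `<name>_ci_low`, `<name>_ci_high`),
#'   `passes`, `fail_reasons`. Attribute `"config"` holds the
#'   configuration; attribute `"n_enumerated"` the combination count.
#' @export
screen_combos <- function(cohorts, genes, config = screen_config()) {
  if (inherits(cohorts, "secep_cohort")) cohorts <- list(cohorts)
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts)))) {
    names(cohorts) <- vapply(cohorts, function(x) x$name, character(1))
  }
  genes <- sort(unique(genes))
  if (!length(genes)) stop_secepr("empty SeCEP gene list")
  max_k <- config$max_k
  if (max_k > length(genes)) {
    rlang::warn(paste0("max_k > number of genes; capped at ", length(genes)))
    max_k <- length(genes)
  }
  preps <- lapply(cohorts, cohort_screen_data, genes = genes, config = config)
  n_total <- n_combinations(length(genes), max_k)
  nc <- length(preps)
  fields <- c("n", "n_altered", "altered_fraction", "n_events_altered",
              "n_events_unaltered", "logrank_p", "hr", "ci_low", "ci_high")
  store <- lapply(seq_len(nc), function(i) {
    matrix(NA_real_, nrow = n_total, ncol = length(fields))
  })
  combo_id <- character(n_total)
  combo_k <- integer(n_total)
  passes <- logical(n_total)
  reasons <- character(n_total)
  row <- 0L
  for (k in seq_len(max_k)) {
    cmb <- combn(seq_along(genes), k)
    for (j in seq_len(ncol(cmb))) {
      row <- row + 1L
      idx <- cmb[, j]
      combo_id[row] <- paste(genes[idx], collapse = "+")
      combo_k[row] <- k
      ok <- TRUE
      rs <- character()
      for (ci in seq_len(nc)) {
        if (!ok && config$prune) {
          rs <- c(rs, paste0(names(preps)[ci], ":not_evaluated"))
          next
        }
        res <- eval_combo_cohort(preps[[ci]], idx, config)
        store[[ci]][row, ] <- res$rec
        if (!res$pass) {
          ok <- FALSE
          rs <- c(rs, paste0(names(preps)[ci], ":", res$reason))
        }
      }
      passes[row] <- ok
      reasons[row] <- paste(rs, collapse = ";")
    }
  }
  cohort_cols <- purrr::imap(store, function(m, i) {
    colnames(m) <- paste(names(preps)[as.integer(i)], fields, sep = "_")
    tibble::as_tibble(m)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(genes = combo_id, k = combo_k),
    cohort_cols,
    tibble::tibble(passes = passes, fail_reasons = reasons)
  )
  if (!config$report_all) out <- out[out$passes, ]
  attr(out, "config") <- config
  attr(out, "n_enumerated") <- n_total
  class(out) <- c("secep_screen", class(out))
  out
}

#' Combinations passing in exactly one PAM50 scope
#'
#' Given screens of the same gene pool run separately per PAM50 scope,
#' returns the combinations that pass in the target scope and fail in
#' every contrast scope — the subtype-specific prognostic combinations.
#'
#' @param results_by_scope Named list of [screen_combos()] results.
#' @param target Name of the target scope.
#' @param contrasts Names of contrast scopes (default: all others).
#' @return The target-scope rows whose combination passes only there.
#' @export
subtype_specificity <- function(results_by_scope, target,
                                contrasts = setdiff(names(results_by_scope), target)) {
  for (nm in c(target, contrasts)) {
    if (!nm %in% names(results_by_scope)) {
      stop_secepr(paste0("scope missing from results: ", nm))
    }
  }
  tgt <- results_by_scope[[target]]
  keep <- tgt$passes
  for (nm in contrasts) {
    other <- results_by_scope[[nm]]
    m <- match(tgt$genes, other$genes)
    keep <- keep & !(!is.na(m) & other$passes[m])
  }
  tgt[keep, ]
}

#' Distant-relapse screen against a trial cohort
#'
#' Variant of the combination screen for a neoadjuvant-trial cohort with a
#' distant relapse-free survival (DRFS) endpoint: a combination passes when
#' strictly more than `min_altered_fraction` (default 10%) of patients are
#' altered in *both* the trial cohort and the reference cohort, and DRFS
#' differs significantly (log-rank p < alpha) in the trial cohort. The
#' reference cohort contributes only its fraction constraint unless
#' `require_reference_significance = TRUE`, in which case its own survival
#' criteria must hold too.
#'
#' @param trial_cohort [secep_cohort()] with endpoint `"DRFS"`.
#' @param reference_cohort [secep_cohort()] supplying the second fraction
#'   constraint (e.g. the discovery cohort).
#' @param genes Candidate gene ids.
#' @param config A [screen_config()]; `min_altered_fraction` defaults to
#'   0.10 here and the CI criterion is off unless requested.
#' @param require_reference_significance Also require the reference
#'   cohort's survival criteria? Default `FALSE`.
#' @return A `secep_screen` tibble as in [screen_combos()].
#' @export
drfs_screen <- function(trial_cohort, reference_cohort, genes,
                        config = screen_config(min_altered_fraction = 0.10,
                                               require_ci_low_gt_1 = FALSE),
                        require_reference_significance = FALSE) {
  if (trial_cohort$endpoint != "DRFS") {
    stop_secepr("trial cohort endpoint must be DRFS")
  }
  genes <- sort(unique(genes))
  if (!length(genes)) stop_secepr("empty SeCEP gene list")
  max_k <- min(config$max_k, length(genes))
  preps <- list(
    trial = cohort_screen_data(trial_cohort, genes, config),
    reference = cohort_screen_data(reference_cohort, genes, config)
  )
  names(preps) <- c(trial_cohort$name, reference_cohort$name)
  n_total <- n_combinations(length(genes), max_k)
  fields <- c("n", "n_altered", "altered_fraction", "n_events_altered",
              "n_events_unaltered", "logrank_p", "hr", "ci_low", "ci_high")
  store <- lapply(1:2, function(i) matrix(NA_real_, n_total, length(fields)))
  combo_id <- character(n_total)
  combo_k <- integer(n_total)
  passes <- logical(n_total)
  reasons <- character(n_total)
  row <- 0L
  for (k in seq_len(max_k)) {
    cmb <- combn(seq_along(genes), k)
    for (j in seq_len(ncol(cmb))) {
      row <- row + 1L
      idx <- cmb[, j]
      combo_id[row] <- paste(genes[idx], collapse = "+")
      combo_k[row] <- k
      res_t <- eval_combo_cohort(preps[[1]], idx, config,
                                 strict_fraction = TRUE)
      store[[1]][row, ] <- res_t$rec
      rs <- character()
      ok <- res_t$pass
      if (!ok) rs <- paste0(names(preps)[1], ":", res_t$reason)
      if (ok || !config$prune) {
        res_r <- eval_combo_cohort(
          preps[[2]], idx, config, strict_fraction = TRUE,
          run_survival = require_reference_significance || !config$prune,
          survival_criteria = require_reference_significance
        )
        store[[2]][row, ] <- res_r$rec
        if (!res_r$pass) {
          ok <- FALSE
          rs <- c(rs, paste0(names(preps)[2], ":", res_r$reason))
        }
      } else {
        rs <- c(rs, paste0(names(preps)[2], ":not_evaluated"))
      }
      passes[row] <- ok
      reasons[row] <- paste(rs, collapse = ";")
    }
  }
  cohort_cols <- purrr::imap(store, function(m, i) {
    colnames(m) <- paste(names(preps)[as.integer(i)], fields, sep = "_")
    tibble::as_tibble(m)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(genes = combo_id, k = combo_k),
    cohort_cols,
    tibble::tibble(passes = passes, fail_reasons = reasons)
  )
  if (!config$report_all) out <- out[out$passes, ]
  attr(out, "config") <- config
  attr(out, "n_enumerated") <- n_total
  class(out) <- c("secep_screen", class(out))
  out
}

#' @method tidy secep_screen
#' @export
tidy.secep_screen <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance secep_screen
#' @export
glance.secep_screen <- function(x, ...) {
  tibble::tibble(
    n_enumerated = attr(x, "n_enumerated"),
    n_reported = nrow(x),
    n_passing = sum(x$passes)
  )
}
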