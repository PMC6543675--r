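#' Mann-Whitney-Wilcoxon test between two patient groups
#'
#' Two-sided rank-sum test as used for per-gene differential expression on
#' z-scores: exact enumeration when both groups have at most 7 observations
#' and there are no ties, otherwise the normal approximation with tie
#' correction and continuity correction. All values tied across both groups
#' give p = 1.
#'
#' @param x,y Numeric vectors (group A and group B).
#' @return Tibble: `u_stat` (U for x vs y), `median_a`, `median_b`, `p`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (!length(x) || !length(y)) {
    stop_secepr("both groups need at least one observed value")
  }
  if (length(unique(c(x, y))) == 1) {
    u <- length(x) * length(y) / 2
    return(tibble::tibble(u_stat = u, median_a = median(x),
                          median_b = median(y), p = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- max(length(x), length(y)) <= 7 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  tibble::tibble(
    u_stat = unname(wt$statistic),
    median_a = median(x),
    median_b = median(y),
    p = min(1, wt$p.value)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment over a p-value family, with
#' enforced monotonicity and capping at 1; input order is preserved. The
#' family should be *all* genes measured in the cohort, not only the
#' secretome genes — shrinking the family can only make adjusted p-values
#' smaller, so the family choice is logged by the pipeline.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\] (`NA` allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_secepr("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-gene differential expression between PAM50 groups
#'
#' Runs [mann_whitney()] for every gene between two PAM50-defined patient
#' populations (default Basal vs LumA+LumB) and adjusts the p-values by
#' Benjamini-Hochberg over the whole gene family present in the cohort.
#'
#' @param cohort A [secep_cohort()].
#' @param group_a,group_b PAM50 labels defining the two populations.
#' @param genes Optional subset of genes to report (the BH family is still
#'   every tested gene in the cohort unless `family = "subset"`).
#' @param family `"cohort"` (default: adjust over all genes in the cohort)
#'   or `"subset"` (adjust over `genes` only; for small synthetic runs).
#' @return Tibble: `gene_id`, `median_a`, `median_b`, `u_stat`, `raw_p`,
#'   `adjusted_p`, `n_a`, `n_b`, with attribute `bh_family_size`.
#' @export
subtype_de <- function(cohort, group_a = "Basal", group_b = c("LumA", "LumB"),
                       genes = NULL, family = c("cohort", "subset")) {
  family <- match.arg(family)
  stopifnot(inherits(cohort, "secep_cohort"))
  ia <- cohort$clinical$pam50 %in% group_a
  ib <- cohort$clinical$pam50 %in% group_b
  if (!any(ia) || !any(ib)) stop_secepr("both PAM50 populations must be non-empty")
  test_genes <- if (family == "subset" && !is.null(genes)) {
    intersect(genes, rownames(cohort$z))
  } else {
    rownames(cohort$z)
  }
  za <- cohort$z[test_genes, ia, drop = FALSE]
  zb <- cohort$z[test_genes, ib, drop = FALSE]
  res <- purrr::map_dfr(seq_along(test_genes), function(i) {
    mann_whitney(za[i, ], zb[i, ])
  })
  out <- tibble::tibble(
    gene_id = test_genes,
    median_a = res$median_a, median_b = res$median_b,
    u_stat = res$u_stat, raw_p = res$p,
    adjusted_p = bh_adjust(res$p),
    n_a = sum(ia), n_b = sum(ib)
  )
  if (!is.null(genes)) out <- out[out$gene_id %in% genes, ]
  attr(out, "bh_family_size") <- length(test_genes)
  out
}

#' Classify SeCEP genes
#'
#' A gene shows a Secretion-Correlated mRNA Expression Pattern (SeCEP) for
#' a subtype when its mRNA differs significantly between the two PAM50
#' populations (adjusted p < `alpha`) with the higher median on that
#' subtype's side, and (optionally) its protein shows *increased* secretion
#' in the same subtype's cell lines. Group A of the input statistics is the
#' basal population, group B the luminal population.
#'
#' @param stats Output of [subtype_de()] (group A = Basal, group B = LumA+LumB).
#' @param secretion_calls Optional calls from [call_subtype_secretion()]
#'   whose `protein_id` shares the gene namespace; required when
#'   `require_concordance = TRUE`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param require_concordance Keep only genes whose secretion direction is
#'   `"increased"` in the matching subtype (default `TRUE`).
#' @return Tibble: `gene_id`, `secep_subtype`, `adjusted_p`,
#'   `median_difference` (positive toward the assigned subtype),
#'   `secretion_direction`, `concordant`. Discordant-but-significant genes
#'   are attached as attribute `"discordant"`; genes in the calls but absent
#'   from `stats` as attribute `"not_measured"` (with a warning).
#' @export
classify_secep <- function(stats, secretion_calls = NULL, alpha = 0.05,
                           require_concordance = TRUE) {
  if (require_concordance && is.null(secretion_calls)) {
    stop_secepr("secretion_calls needed when require_concordance = TRUE")
  }
  not_measured <- character()
  if (!is.null(secretion_calls)) {
    not_measured <- setdiff(secretion_calls$protein_id, stats$gene_id)
    if (length(not_measured)) {
      rlang::warn(paste0(length(not_measured),
                         " called gene(s) not measured in the cohort"))
    }
  }
  sig <- dplyr::filter(stats, !is.na(.data$adjusted_p), .data$adjusted_p < alpha,
                       .data$median_a != .data$median_b)
  sig$secep_subtype <- ifelse(sig$median_a > sig$median_b, "basal", "luminal")
  sig$median_difference <- abs(sig$median_a - sig$median_b)
  if (!is.null(secretion_calls)) {
    calls <- dplyr::select(secretion_calls, gene_id = "protein_id",
                           call_subtype = "subtype",
                           secretion_direction = "direction")
    calls <- dplyr::distinct(calls, .data$gene_id, .keep_all = TRUE)
    sig <- dplyr::left_join(sig, calls, by = "gene_id")
    sig$concordant <- !is.na(sig$secretion_direction) &
      sig$secretion_direction == "increased" &
      sig$call_subtype == sig$secep_subtype
  } else {
    sig$secretion_direction <- NA_character_
    sig$concordant <- NA
  }
  out <- dplyr::select(sig, "gene_id", "secep_subtype", "adjusted_p",
                       "median_difference", "secretion_direction", "concordant")
  if (require_concordance) {
    discordant <- out[!out$concordant %in% TRUE, ]
    out <- out[out$concordant %in% TRUE, ]
    attr(out, "discordant") <- discordant
  }
  attr(out, "not_measured") <- not_measured
  out
}

#' Intersect SeCEP classifications across cohorts
#'
#' The working SeCEP set is the strict intersection: genes classified with
#' the same subtype in every cohort (consistency across discovery and
#' validation cohorts).
#'
#' @param secep_list Named list of [classify_secep()] outputs.
#' @return Tibble `gene_id`, `secep_subtype` plus one `adjusted_p_<cohort>`
#'   column per cohort.
#' @export
secep_intersect <- function(secep_list) {
  stopifnot(length(secep_list) >= 1)
  keyed <- purrr::imap(secep_list, function(tb, nm) {
    tb <- dplyr::select(tb, "gene_id", "secep_subtype", "adjusted_p")
    names(tb)[3] <- paste0("adjusted_p_", nm)
    tb
  })
  out <- purrr::reduce(keyed, dplyr::inner_join,
                       by = c("gene_id", "secep_subtype"))
  dplyr::arrange(out, .data$secep_subtype, .data$gene_id)
}
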