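#' Reference secretion profiles
#'
#' Builds the pattern library used to assign each protein a subtype-specific
#' secretion profile from its per-cell-line mean z-scores. Four subtype-level
#' profiles (basal-up/-down, luminal-up/-down; the control line grouped with
#' the non-target level) capture proteins altered in *both* lines of a
#' subtype, and one up/down profile per cancer cell line captures proteins
#' altered in a single line. Subtype-level profiles come first so that ties
#' resolve toward the stronger `both_lines` claim. Pearson correlation is
#' location/scale invariant, so profiles are encoded as 0/1 target levels.
#'
#' @param samples Sample sheet tibble (`cell_line`, `subtype`).
#' @param include_single_line Include per-cancer-line profiles? Default TRUE.
#' @return A list with `target`: matrix profiles x cell lines, and `meta`:
#'   tibble (`profile`, `subtype`, `direction`, `support`,
#'   `supporting_cell_lines`).
#' @export
reference_profiles <- function(samples, include_single_line = TRUE) {
  ann <- dplyr::distinct(samples, .data$cell_line, .data$subtype)
  lines <- ann$cell_line
  sub <- ann$subtype
  rows <- list()
  meta <- list()
  add <- function(name, vec, subtype, direction, support, supp_lines) {
    rows[[name]] <<- vec
    meta[[name]] <<- tibble::tibble(
      profile = name, subtype = subtype, direction = direction,
      support = support,
      supporting_cell_lines = paste(supp_lines, collapse = ";")
    )
  }
  for (st in c("basal", "luminal")) {
    in_st <- as.numeric(sub == st)
    st_lines <- lines[sub == st]
    add(paste0(st, "_up"), in_st, st, "increased", "both_lines", st_lines)
    add(paste0(st, "_down"), 1 - in_st, st, "decreased", "both_lines", st_lines)
  }
  if (include_single_line) {
    for (i in which(sub != "control")) {
      one <- as.numeric(seq_along(lines) == i)
      add(paste0(lines[i], "_up"), one, sub[i], "increased", "one_line", lines[i])
      add(paste0(lines[i], "_down"), 1 - one, sub[i], "decreased", "one_line", lines[i])
    }
  }
  target <- do.call(rbind, rows)
  colnames(target) <- lines
  list(target = target, meta = dplyr::bind_rows(meta))
}

#' Match proteins to reference secretion profiles
#'
#' Assigns each protein the reference profile maximizing the Pearson
#' correlation between its per-cell-line mean z-score vector and the
#' profile's target levels, or leaves it unmatched when the best correlation
#' falls below `r_threshold` (or the mean-z vector has zero variance). Ties
#' are broken by profile list order, so assignment is deterministic.
#'
#' @param z_lfq Row z-scored LFQ tibble (see [lfq_zscore()]).
#' @param samples Sample sheet tibble.
#' @param profiles Profile library from [reference_profiles()]; built with
#'   defaults when `NULL`.
#' @param r_threshold Minimum Pearson r to accept a match (default 0.8).
#' @return Tibble: `protein_id`, `profile` (`NA` if unmatched), `pattern_r`,
#'   `subtype`, `direction`, `support`, `supporting_cell_lines`, plus one
#'   `mean_z_<cell line>` column per line.
#' @export
profile_match <- function(z_lfq, samples, profiles = NULL, r_threshold = 0.8) {
  stopifnot(r_threshold > -1, r_threshold < 1)
  profiles <- profiles %||% reference_profiles(samples)
  mz <- cell_line_means(z_lfq, samples)
  mz <- mz[, colnames(profiles$target), drop = FALSE]
  # rowwise Pearson r between mean-z vectors and each profile
  ctr <- mz - rowMeans(mz)
  denom <- sqrt(rowSums(ctr^2))
  p <- profiles$target
  pc <- p - rowMeans(p)
  pden <- sqrt(rowSums(pc^2))
  r <- (ctr %*% t(pc)) / outer(denom, pden)
  r[!is.finite(r)] <- NA_real_ # zero-variance rows -> correlation undefined
  best <- unname(apply(r, 1, function(x) {
    if (all(is.na(x))) NA_integer_ else which.max(x)
  }))
  best_r <- ifelse(is.na(best), NA_real_, r[cbind(seq_len(nrow(r)), best)])
  matched <- !is.na(best_r) & best_r >= r_threshold
  meta <- profiles$meta
  out <- tibble::tibble(
    protein_id = rownames(mz),
    profile = ifelse(matched, meta$profile[best], NA_character_),
    pattern_r = best_r,
    subtype = ifelse(matched, meta$subtype[best], NA_character_),
    direction = ifelse(matched, meta$direction[best], NA_character_),
    support = ifelse(matched, meta$support[best], NA_character_),
    supporting_cell_lines = ifelse(matched, meta$supporting_cell_lines[best],
                                   NA_character_)
  )
  mz_tbl <- tibble::as_tibble(mz)
  names(mz_tbl) <- paste0("mean_z_", names(mz_tbl))
  dplyr::bind_cols(out, mz_tbl)
}

#' One-way ANOVA across cell lines
#'
#' Validates per-protein abundance differences across cell lines with a
#' classical one-way ANOVA (equal-variance F test) on log2 intensities.
#' Technical replicates are averaged into their biological replicate by
#' default, so each cell line contributes its biological replicates as
#' independent observations and technical duplicates do not inflate
#' degrees of freedom. Proteins lacking two groups with two observations
#' each get `NA`.
#'
#' @param lfq LFQ tibble (log2 intensities, not z-scores).
#' @param samples Sample sheet tibble.
#' @param average_tech_reps Average technical replicates within each
#'   biological replicate first? Default `TRUE`.
#' @return Tibble: `protein_id`, `f_stat`, `anova_p`.
#' @export
anova_validate <- function(lfq, samples, average_tech_reps = TRUE) {
  m <- lfq_values(lfq)
  ann <- samples[match(colnames(m), samples$sample_id), ]
  if (average_tech_reps) {
    unit <- paste(ann$cell_line, ann$bio_rep, sep = "//")
    groups_of_unit <- ann$cell_line[!duplicated(unit)]
    units <- unit[!duplicated(unit)]
    m <- vapply(units, function(u) {
      rowMeans(m[, unit == u, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(m)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    group <- groups_of_unit
  } else {
    group <- ann$cell_line
  }
  group <- factor(group)
  res <- apply(m, 1, function(x) {
    ok <- is.finite(x)
    g <- droplevels(group[ok])
    if (nlevels(g) < 2 || any(table(g) < 2)) return(c(NA_real_, NA_real_))
    x <- x[ok]
    if (all(vapply(split(x, g), function(v) length(unique(v)) == 1, logical(1))) &&
        length(unique(x)) == 1) {
      return(c(NA_real_, NA_real_)) # no variance anywhere
    }
    ft <- tryCatch(oneway.test(x ~ g, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(ft) || !is.finite(ft$statistic)) c(NA_real_, NA_real_)
    else c(unname(ft$statistic), unname(ft$p.value))
  })
  tibble::tibble(
    protein_id = lfq$protein_id,
    f_stat = unname(res[1, ]),
    anova_p = unname(res[2, ])
  )
}

#' Call proteins with subtype-specific secretion
#'
#' The full calling pipeline: missing-value filtering, row z-scoring,
#' reference-profile pattern matching, and one-way ANOVA validation.
#' A call requires (i) a matched profile at `r_threshold`, (ii) ANOVA
#' p below `anova_p`, and (iii) the direction to hold line-wise at margin
#' `z_margin`: for a `both_lines` call every cell line of the subtype must
#' show the direction (mean z beyond the margin) while all other lines stay
#' neutral or opposite; a `one_line` call needs exactly that line elevated
#' (or depressed) with the other cancer lines neutral.
#'
#' @inheritParams anova_validate
#' @param anova_p ANOVA p-value threshold (default 0.05, uncorrected; set
#'   `bh = TRUE` for a Benjamini-Hochberg-adjusted threshold instead).
#' @param r_threshold Profile-match correlation cutoff (default 0.8).
#' @param z_margin Per-line mean-z margin defining "shows the direction"
#'   (default 0.5).
#' @param profiles Optional profile library; defaults to
#'   [reference_profiles()].
#' @param min_valid_per_group Missing-value filter, see [handle_missing()].
#' @param bh Apply BH adjustment to the ANOVA p-values before thresholding?
#'   Default `FALSE` (no multiplicity correction at this stage).
#' @return Tibble of calls: `protein_id`, `subtype`, `direction`, `support`,
#'   `supporting_cell_lines`, `pattern_r`, `anova_p`.
#' @export
call_subtype_secretion <- function(lfq, samples, anova_p = 0.05,
                                   r_threshold = 0.8, z_margin = 0.5,
                                   profiles = NULL, min_valid_per_group = 3,
                                   average_tech_reps = TRUE, bh = FALSE) {
  filt <- handle_missing(lfq, samples, min_valid_per_group = min_valid_per_group)
  z <- suppressWarnings(lfq_zscore(filt))
  filt <- filt[filt$protein_id %in% z$protein_id, ]
  pm <- profile_match(z, samples, profiles = profiles, r_threshold = r_threshold)
  av <- anova_validate(filt, samples, average_tech_reps = average_tech_reps)
  if (bh) av$anova_p <- p.adjust(av$anova_p, method = "BH")
  p_threshold <- anova_p # avoid data-masking the threshold inside filter()
  res <- dplyr::inner_join(pm, av, by = "protein_id")
  res <- dplyr::filter(res, !is.na(.data$profile),
                       !is.na(.data$anova_p), .data$anova_p < !!p_threshold)
  if (nrow(res) == 0) {
    return(tibble::tibble(
      protein_id = character(), subtype = character(), direction = character(),
      support = character(), supporting_cell_lines = character(),
      pattern_r = double(), anova_p = double()
    ))
  }
  ann <- dplyr::distinct(samples, .data$cell_line, .data$subtype)
  mzcols <- paste0("mean_z_", ann$cell_line)
  mz <- as.matrix(res[mzcols])
  sgn <- ifelse(res$direction == "increased", 1, -1)
  dmz <- mz * sgn # flip so "shows the direction" means > z_margin
  supp_lines <- strsplit(res$supporting_cell_lines, ";", fixed = TRUE)
  ok <- vapply(seq_len(nrow(res)), function(i) {
    in_supp <- ann$cell_line %in% supp_lines[[i]]
    all(dmz[i, in_supp] >= z_margin) && all(dmz[i, !in_supp] < z_margin)
  }, logical(1))
  res <- res[ok, ]
  dplyr::select(res, "protein_id", "subtype", "direction", "support",
                "supporting_cell_lines", "pattern_r", "anova_p")
}

#' Ward/euclidean leaf ordering
#'
#' Hierarchical clustering with euclidean distance and Ward linkage on
#' unsquared distances (`ward.D2`), returning the leaf order used to lay
#' out heatmap rows or columns. Input must be complete; impute first
#' (see [handle_missing()]).
#'
#' @param x Matrix or LFQ-style tibble (first column taken as ids).
#' @param axis `"rows"` (default) or `"cols"`.
#' @return Character vector of ids in leaf order, with the `hclust` tree in
#'   attribute `"tree"`.
#' @export
ward_cluster_order <- function(x, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (is.data.frame(x)) x <- lfq_values(x)
  if (axis == "cols") x <- t(x)
  if (anyNA(x)) {
    stop_secepr("matrix contains missing values; impute first (handle_missing(impute = TRUE))")
  }
  if (nrow(x) < 2) stop_secepr("need >= 2 rows (or columns) to cluster")
  hc <- hclust(dist(x), method = "ward.D2")
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  out <- ids[hc$order]
  attr(out, "tree") <- hc
  out
}

#' Overlap of called proteins with reference secretome sets
#'
#' Purity-style QC: intersects an identifier set (e.g. all identified
#' proteins, or the subtype-specific calls) with named reference sets in
#' the same namespace and reports counts and fractions.
#'
#' @param ids Character vector of identified protein/gene ids.
#' @param reference_sets Named list of character vectors.
#' @return Tibble: `set`, `n_identified`, `n_set`, `n_overlap`, `fraction`
#'   (of identified ids found in the set).
#' @export
overlap_report <- function(ids, reference_sets) {
  ids <- unique(ids)
  purrr::imap_dfr(reference_sets, function(set, nm) {
    if (length(set) == 0) {
      rlang::warn(paste0("reference set '", nm, "' is empty"))
    }
    ov <- length(intersect(ids, set))
    tibble::tibble(
      set = nm, n_identified = length(ids), n_set = length(unique(set)),
      n_overlap = ov,
      fraction = if (length(ids)) ov / length(ids) else 0
    )
  })
}
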