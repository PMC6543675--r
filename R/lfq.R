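#' LFQ intensity tables
#'
#' An LFQ table is a tibble whose first column is `protein_id` and whose
#' remaining columns are samples holding log2 label-free quantification
#' intensities (possibly `NA`). A companion sample sheet describes each
#' column: `sample_id`, `cell_line`, `subtype` (one of `"basal"`,
#' `"luminal"`, `"control"`), `bio_rep`, `tech_rep`.
#'
#' @param lfq LFQ tibble (first column `protein_id`).
#' @param samples Sample sheet tibble.
#' @return `validate_lfq()` returns `lfq` invisibly after checking that the
#'   sample sheet covers every intensity column, protein ids are unique and
#'   each cell line contributes at least two replicate columns.
#' @export
validate_lfq <- function(lfq, samples) {
  if (names(lfq)[1] != "protein_id") {
    stop_secepr("first column of an LFQ table must be `protein_id`")
  }
  if (anyDuplicated(lfq$protein_id)) {
    stop_secepr("protein ids must be unique")
  }
  value_cols <- names(lfq)[-1]
  missing_ann <- setdiff(value_cols, samples$sample_id)
  if (length(missing_ann)) {
    stop_secepr(paste0(
      "sample sheet does not annotate column(s): ",
      paste(missing_ann, collapse = ", ")
    ))
  }
  per_line <- table(samples$cell_line[samples$sample_id %in% value_cols])
  if (any(per_line < 2)) {
    stop_secepr("every cell line needs >= 2 replicate columns")
  }
  bad <- vapply(lfq[value_cols], function(x) any(is.infinite(x)), logical(1))
  if (any(bad)) stop_secepr("LFQ intensities must be finite where present")
  invisible(lfq)
}

# numeric matrix (proteins x samples) from an LFQ tibble
lfq_values <- function(lfq) {
  m <- as.matrix(lfq[-1])
  storage.mode(m) <- "double"
  rownames(m) <- lfq$protein_id
  m
}

matrix_to_lfq <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(protein_id = rownames(m)),
    tibble::as_tibble(m)
  )
}

#' Row z-score an LFQ table
#'
#' Standardizes every protein row to mean 0, sd 1 over its observed entries,
#' using the population standard deviation (divide by n). Missing entries
#' stay missing. Rows with fewer than two observed values or zero spread
#' cannot be standardized; they are dropped with a warning.
#'
#' @param lfq LFQ tibble (first column `protein_id`).
#' @return A z-scored LFQ tibble.
#' @examples
#' lfq <- tibble::tibble(protein_id = "P1", s1 = 1, s2 = 2, s3 = 3)
#' lfq_zscore(lfq)
#' @export
lfq_zscore <- function(lfq) {
  m <- lfq_values(lfq)
  n_obs <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  # population sd over observed entries
  sd_pop <- sqrt(rowMeans((m - mu)^2, na.rm = TRUE))
  drop <- n_obs < 2 | sd_pop == 0 | !is.finite(sd_pop)
  if (any(drop)) {
    rlang::warn(paste0(
      sum(drop), " protein row(s) dropped before z-scoring ",
      "(<2 observed values or zero spread): ",
      paste(head(rownames(m)[drop], 5), collapse = ", "),
      if (sum(drop) > 5) ", ..." else ""
    ))
    m <- m[!drop, , drop = FALSE]
    mu <- mu[!drop]
    sd_pop <- sd_pop[!drop]
  }
  if (nrow(m) == 0) stop_secepr("no rows left to z-score")
  z <- (m - mu) / sd_pop
  matrix_to_lfq(z)
}

#' Filter and optionally impute missing LFQ values
#'
#' Mirrors the common Perseus-style missing-value policy: a protein is
#' quantifiable if it was observed in at least `min_valid_per_group` samples
#' of at least one cell line. With `impute = TRUE` the remaining missing
#' entries are drawn from a down-shifted normal per protein row
#' (mean = row mean - `downshift` * row sd, sd = `width` * row sd), the
#' standard stand-in for intensities below the detection limit.
#'
#' @param lfq,samples LFQ tibble and its sample sheet.
#' @param min_valid_per_group Minimum observed values in some cell line
#'   (default 3 of the 6 replicate columns).
#' @param impute Impute remaining missing values? Default `FALSE` so that
#'   downstream tests run on observed data; imputation is needed only for
#'   clustering, which cannot tolerate `NA`.
#' @param downshift,width Down-shifted-normal parameters in row-sd units.
#' @param seed Optional integer seed making imputation reproducible.
#' @return Filtered (and possibly imputed) LFQ tibble.
#' @export
handle_missing <- function(lfq, samples, min_valid_per_group = 3,
                           impute = FALSE, downshift = 1.8, width = 0.3,
                           seed = NULL) {
  stopifnot(min_valid_per_group >= 1)
  m <- lfq_values(lfq)
  line_of <- samples$cell_line[match(colnames(m), samples$sample_id)]
  obs_by_line <- vapply(
    split(seq_len(ncol(m)), line_of),
    function(j) rowSums(!is.na(m[, j, drop = FALSE])),
    numeric(nrow(m))
  )
  if (nrow(m) == 1) obs_by_line <- matrix(obs_by_line, nrow = 1)
  keep <- apply(obs_by_line, 1, max) >= min_valid_per_group
  if (!any(keep)) stop_secepr("no quantifiable proteins after missing-value filtering")
  m <- m[keep, , drop = FALSE]
  if (impute && anyNA(m)) {
    draw <- function() {
      mu <- rowMeans(m, na.rm = TRUE)
      s <- apply(m, 1, sd, na.rm = TRUE)
      s[is.na(s) | s == 0] <- 0
      for (i in which(rowSums(is.na(m)) > 0)) {
        j <- is.na(m[i, ])
        m[i, j] <<- rnorm(sum(j), mean = mu[i] - downshift * s[i],
                          sd = width * s[i])
      }
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  matrix_to_lfq(m)
}

#' Per-cell-line means of a (z-scored) LFQ table
#'
#' @inheritParams handle_missing
#' @return Matrix proteins x cell lines of row means over each line's
#'   replicate columns (observed entries only).
#' @export
cell_line_means <- function(lfq, samples) {
  m <- lfq_values(lfq)
  line_of <- samples$cell_line[match(colnames(m), samples$sample_id)]
  lines <- unique(samples$cell_line[samples$sample_id %in% colnames(m)])
  out <- vapply(lines, function(cl) {
    rowMeans(m[, line_of == cl, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m)))
  if (nrow(m) == 1) out <- matrix(out, nrow = 1, dimnames = list(rownames(m), lines))
  out
}
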