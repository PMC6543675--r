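#' Patient expression cohorts
#'
#' A cohort bundles a gene x patient mRNA z-score matrix with a clinical
#' table (PAM50 subtype, survival time in months, event status). Clinical
#' column dialects from cBioPortal-style exports are normalized by
#' [normalize_clinical()]. Patients lacking survival data are kept in the
#' cohort (they still contribute to expression statistics) but flagged and
#' excluded from survival operations.
#'
#' @param expr Tibble/data frame whose first column is `gene_id` and whose
#'   remaining columns are patients (z-scores), or a numeric matrix with
#'   gene rownames.
#' @param clinical Clinical tibble; see [normalize_clinical()] for accepted
#'   column dialects.
#' @param name Cohort name used in reports.
#' @param endpoint `"OS"` (overall survival, default) or `"DRFS"` (distant
#'   relapse-free survival).
#' @return A `secep_cohort` object.
#' @export
secep_cohort <- function(expr, clinical, name = "cohort",
                         endpoint = c("OS", "DRFS")) {
  endpoint <- match.arg(endpoint)
  if (is.data.frame(expr)) {
    z <- as.matrix(expr[-1])
    storage.mode(z) <- "double"
    rownames(z) <- expr[[1]]
  } else {
    z <- expr
  }
  clin <- normalize_clinical(clinical, endpoint = endpoint)
  missing_pat <- setdiff(colnames(z), clin$patient_id)
  if (length(missing_pat)) {
    stop_secepr(paste0("clinical table lacks patient(s): ",
                       paste(head(missing_pat, 5), collapse = ", ")))
  }
  clin <- clin[match(colnames(z), clin$patient_id), ]
  if (anyNA(clin$pam50)) stop_secepr("pam50 must be defined for every patient")
  bad_t <- !is.na(clin$time) & clin$time < 0
  if (any(bad_t)) stop_secepr("survival times must be >= 0")
  clin$has_survival <- !is.na(clin$time) & !is.na(clin$event)
  structure(
    list(name = name, z = z, clinical = clin, endpoint = endpoint),
    class = "secep_cohort"
  )
}

#' @export
print.secep_cohort <- function(x, ...) {
  cat(sprintf(
    "<secep_cohort '%s'> %d genes x %d patients, endpoint %s (%d with survival)\n",
    x$name, nrow(x$z), ncol(x$z), x$endpoint, sum(x$clinical$has_survival)
  ))
  print(table(x$clinical$pam50))
  invisible(x)
}

pam50_levels <- c("Basal", "LumA", "LumB", "Her2", "Normal")

#' Normalize clinical-table dialects
#'
#' Maps cBioPortal-style clinical exports onto the canonical columns
#' `patient_id`, `pam50`, `time` (months), `event` (logical). Recognized
#' dialects: `PATIENT_ID`/`SAMPLE_ID`; `PAM50`/`SUBTYPE`/`PAM50_SUBTYPE`
#' with values such as `"Basal-like"`, `"Luminal A"`, `"HER2-enriched"`,
#' `"Normal-like"`; `OS_MONTHS` + `OS_STATUS` (`"DECEASED"`, `"1:DECEASED"`,
#' `"LIVING"`, `"0:LIVING"`, 0/1) for the OS endpoint and `DRFS_MONTHS` +
#' `DRFS_STATUS`/`DRFS_EVENT` (0/1) for DRFS. Already-canonical columns
#' pass through.
#'
#' @param clinical Clinical tibble.
#' @param endpoint `"OS"` or `"DRFS"`.
#' @return Tibble with canonical columns (extra columns preserved).
#' @export
normalize_clinical <- function(clinical, endpoint = c("OS", "DRFS")) {
  endpoint <- match.arg(endpoint)
  cl <- tibble::as_tibble(clinical)
  pick <- function(cands) {
    hit <- intersect(cands, names(cl))
    if (length(hit)) hit[1] else NULL
  }
  idc <- pick(c("patient_id", "PATIENT_ID", "SAMPLE_ID", "sample_id"))
  if (is.null(idc)) stop_secepr("no patient id column found in clinical table")
  pamc <- pick(c("pam50", "PAM50", "PAM50_SUBTYPE", "SUBTYPE"))
  if (is.null(pamc)) stop_secepr("no PAM50 column found in clinical table")
  if (endpoint == "OS") {
    tc <- pick(c("time", "os_months", "OS_MONTHS"))
    ec <- pick(c("event", "os_status", "OS_STATUS", "os_event"))
  } else {
    tc <- pick(c("time", "drfs_months", "DRFS_MONTHS"))
    ec <- pick(c("event", "drfs_status", "DRFS_STATUS", "drfs_event", "DRFS_EVENT"))
  }
  if (is.null(tc) || is.null(ec)) {
    stop_secepr(paste0("no survival time/status columns for endpoint ", endpoint))
  }
  pam_map <- c(
    "basal" = "Basal", "basal-like" = "Basal", "blbc" = "Basal",
    "luma" = "LumA", "luminal a" = "LumA", "lum a" = "LumA",
    "lumb" = "LumB", "luminal b" = "LumB", "lum b" = "LumB",
    "her2" = "Her2", "her2-enriched" = "Her2", "her2+" = "Her2",
    "normal" = "Normal", "normal-like" = "Normal"
  )
  pam_raw <- tolower(trimws(as.character(cl[[pamc]])))
  pam <- unname(pam_map[pam_raw])
  unknown <- !is.na(cl[[pamc]]) & is.na(pam)
  if (any(unknown)) {
    stop_secepr(paste0("unrecognized PAM50 label(s): ",
                       paste(unique(cl[[pamc]][unknown]), collapse = ", ")))
  }
  ev_raw <- cl[[ec]]
  if (is.logical(ev_raw)) {
    event <- ev_raw
  } else if (is.numeric(ev_raw)) {
    event <- ev_raw > 0
  } else {
    s <- toupper(trimws(as.character(ev_raw)))
    event <- dplyr::case_when(
      s %in% c("DECEASED", "1:DECEASED", "1", "EVENT", "RECURRED", "TRUE") ~ TRUE,
      s %in% c("LIVING", "0:LIVING", "0", "CENSORED", "DISEASEFREE", "FALSE") ~ FALSE,
      TRUE ~ NA
    )
  }
  out <- tibble::tibble(
    patient_id = as.character(cl[[idc]]),
    pam50 = pam,
    time = as.numeric(cl[[tc]]),
    event = event
  )
  extra <- setdiff(names(cl), c(idc, pamc, tc, ec))
  dplyr::bind_cols(out, cl[extra])
}

#' Read a cohort from TSV files
#'
#' Expression TSV: first column gene ids, remaining columns patients,
#' z-scored values (`NA` or empty for missing). Clinical TSV: any dialect
#' accepted by [normalize_clinical()].
#'
#' @param expr_path,clinical_path File paths.
#' @inheritParams secep_cohort
#' @export
read_cohort <- function(expr_path, clinical_path, name = "cohort",
                        endpoint = c("OS", "DRFS")) {
  for (p in c(expr_path, clinical_path)) {
    if (!file.exists(p)) stop_secepr(paste0("input file not found: ", p))
  }
  expr <- readr::read_tsv(expr_path, show_col_types = FALSE, progress = FALSE)
  clin <- readr::read_tsv(clinical_path, show_col_types = FALSE, progress = FALSE)
  secep_cohort(expr, clin, name = name, endpoint = match.arg(endpoint))
}

#' Read an LFQ matrix and sample sheet from TSV files
#'
#' @param matrix_path LFQ TSV (first column protein ids, header of sample
#'   ids; missing values empty or `NA`).
#' @param samples_path Sample sheet TSV (`sample_id`, `cell_line`,
#'   `subtype`, `bio_rep`, `tech_rep`).
#' @return List with elements `lfq` and `samples`.
#' @export
read_lfq <- function(matrix_path, samples_path) {
  for (p in c(matrix_path, samples_path)) {
    if (!file.exists(p)) stop_secepr(paste0("input file not found: ", p))
  }
  lfq <- readr::read_tsv(matrix_path, show_col_types = FALSE, progress = FALSE)
  names(lfq)[1] <- "protein_id"
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE, progress = FALSE)
  validate_lfq(lfq, samples)
  list(lfq = lfq, samples = samples)
}
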