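#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data generator:
#' a five-cell-line secretome design (two basal, two luminal, one
#' non-malignant control; 3 biological x 2 technical replicates), and a
#' pair of patient cohorts with PAM50 labels, z-scored expression,
#' subtype-differential genes, latent co-overexpressing risk subgroups and
#' right-censored exponential survival.
#'
#' @param n_proteins Number of proteins in the LFQ matrix (default 500).
#' @param n_basal_up,n_basal_down,n_luminal_up,n_luminal_down Planted
#'   subtype-specific secretion proteins (defaults 50, 0, 0, 0).
#' @param secretion_shift Planted shift of the target lines on the log2
#'   intensity scale (default 1.5; row z-profiles land near +/-1).
#' @param lfq_noise_sd Replicate noise sd on the log2 scale (default 0.4).
#' @param lfq_baseline_mean,lfq_baseline_sd Distribution of per-protein
#'   baseline log2 intensity across proteins (defaults 25, 2).
#' @param missing_rate Average missingness of LFQ values (default 0.05).
#' @param missing_intensity_bias Logistic slope making low intensities more
#'   likely to be missing (default 1; 0 = missing completely at random).
#' @param n_patients_by_subtype Named integer vector of patients per PAM50
#'   subtype and cohort (default Basal 150, LumA 150, LumB 150, Her2 60,
#'   Normal 40).
#' @param n_genes Genes per cohort (default 2000).
#' @param n_diff_genes Genes shifted in Basal patients (default 100).
#' @param diff_shift Shift of planted differential genes in z units
#'   (default 1.0).
#' @param planted_combos List of lists with elements `genes` (character),
#'   `fraction` (latent risk-subgroup fraction of the scoped subtype) and
#'   `hr` (hazard ratio of subgroup members); default none.
#' @param combo_subtype PAM50 subtype carrying the risk subgroups
#'   (default `"Basal"`).
#' @param baseline_hazard Exponential event rate per month (default 0.01).
#' @param censor_horizon Administrative censoring horizon in months
#'   (default 120).
#' @param dropout_rate Fraction of patients with an additional uniform
#'   dropout time on (0, horizon) (default 0.5).
#' @param endpoint Endpoint label for generated cohorts (default `"OS"`).
#' @return A list of class `secep_sim_config`.
#' @export
sim_config <- function(n_proteins = 500,
                       n_basal_up = 50, n_basal_down = 0,
                       n_luminal_up = 0, n_luminal_down = 0,
                       secretion_shift = 1.5, lfq_noise_sd = 0.4,
                       lfq_baseline_mean = 25, lfq_baseline_sd = 2,
                       missing_rate = 0.05, missing_intensity_bias = 1,
                       n_patients_by_subtype = c(Basal = 150, LumA = 150,
                                                 LumB = 150, Her2 = 60,
                                                 Normal = 40),
                       n_genes = 2000, n_diff_genes = 100, diff_shift = 1.0,
                       planted_combos = list(), combo_subtype = "Basal",
                       baseline_hazard = 0.01, censor_horizon = 120,
                       dropout_rate = 0.5, endpoint = c("OS", "DRFS")) {
  stopifnot(baseline_hazard > 0, censor_horizon > 0,
            dropout_rate >= 0, dropout_rate <= 1,
            missing_rate >= 0, missing_rate < 1)
  for (pc in planted_combos) {
    stopifnot(pc$fraction > 0, pc$fraction < 1, pc$hr > 0)
  }
  structure(
    list(n_proteins = n_proteins, n_basal_up = n_basal_up,
         n_basal_down = n_basal_down, n_luminal_up = n_luminal_up,
         n_luminal_down = n_luminal_down,
         secretion_shift = secretion_shift, lfq_noise_sd = lfq_noise_sd,
         lfq_baseline_mean = lfq_baseline_mean,
         lfq_baseline_sd = lfq_baseline_sd,
         missing_rate = missing_rate,
         missing_intensity_bias = missing_intensity_bias,
         n_patients_by_subtype = n_patients_by_subtype,
         n_genes = n_genes, n_diff_genes = n_diff_genes,
         diff_shift = diff_shift, planted_combos = planted_combos,
         combo_subtype = combo_subtype,
         baseline_hazard = baseline_hazard,
         censor_horizon = censor_horizon, dropout_rate = dropout_rate,
         endpoint = match.arg(endpoint)),
    class = "secep_sim_config"
  )
}

sim_cell_lines <- function() {
  tibble::tibble(
    cell_line = c("BAS1", "BAS2", "LUM1", "LUM2", "CTRL"),
    subtype = c("basal", "basal", "luminal", "luminal", "control")
  )
}

sim_gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate an LFQ secretome matrix
#'
#' Per-protein baseline log2 intensity ~ Normal; planted subtype-up/-down
#' proteins shifted by `secretion_shift` in the target cell lines;
#' replicate noise ~ Normal(0, `lfq_noise_sd`); missingness probability
#' increases as intensity decreases (logistic in the within-row z of the
#' intensity, slope `missing_intensity_bias`). Protein ids are gene symbols
#' shared with [simulate_cohort_pair()] so the stages link up.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; all randomness flows from it.
#' @return List: `lfq` (tibble), `samples` (sample sheet), `truth` (tibble
#'   `protein_id`, `subtype`, `direction` for planted proteins).
#' @export
simulate_lfq <- function(config = sim_config(), seed = 1) {
  lines <- sim_cell_lines()
  samples <- tidyr::expand_grid(
    cell_line = lines$cell_line, bio_rep = 1:3, tech_rep = 1:2
  )
  samples <- dplyr::left_join(samples, lines, by = "cell_line")
  samples$sample_id <- sprintf("%s_b%d_t%d", samples$cell_line,
                               samples$bio_rep, samples$tech_rep)
  samples <- dplyr::select(samples, "sample_id", "cell_line", "subtype",
                           "bio_rep", "tech_rep")
  np <- config$n_proteins
  ids <- sim_gene_ids(np)
  n_pl <- c(basal_up = config$n_basal_up, basal_down = config$n_basal_down,
            luminal_up = config$n_luminal_up,
            luminal_down = config$n_luminal_down)
  if (sum(n_pl) > np) stop_secepr("more planted proteins than proteins")
  classes <- rep(c(names(n_pl), "null"), c(n_pl, np - sum(n_pl)))
  truth <- tibble::tibble(
    protein_id = ids[classes != "null"],
    subtype = sub("_(up|down)$", "", classes[classes != "null"]),
    direction = ifelse(grepl("_up$", classes[classes != "null"]),
                       "increased", "decreased")
  )
  ns <- nrow(samples)
  m <- withr::with_seed(child_seed(seed, 1), {
    base <- rnorm(np, config$lfq_baseline_mean, config$lfq_baseline_sd)
    m <- matrix(rnorm(np * ns, 0, config$lfq_noise_sd), np, ns) + base
    shift_sign <- ifelse(grepl("_up$", classes), 1,
                         ifelse(grepl("_down$", classes), -1, 0))
    target_sub <- sub("_(up|down)$", "", classes)
    for (st in c("basal", "luminal")) {
      rows <- which(target_sub == st & shift_sign != 0)
      cols <- which(samples$subtype == st)
      if (length(rows)) {
        m[rows, cols] <- m[rows, cols] +
          shift_sign[rows] * config$secretion_shift
      }
    }
    if (config$missing_rate > 0) {
      zrow <- (m - rowMeans(m)) / apply(m, 1, sd)
      pmiss <- config$missing_rate * 2 *
        stats::plogis(-config$missing_intensity_bias * zrow)
      miss <- matrix(runif(np * ns), np, ns) < pmiss
      # never delete a full row: keep at least 2 observed values
      too_few <- rowSums(!miss) < 2
      miss[too_few, ] <- FALSE
      m[miss] <- NA_real_
    }
    m
  })
  rownames(m) <- ids
  colnames(m) <- samples$sample_id
  list(lfq = matrix_to_lfq(m), samples = samples, truth = truth)
}

# Per-gene overexpression threshold t and the subgroup shift delta such
# that the expected AND-mask altered fraction hits the target subgroup
# fraction f: solve (1-f)*pnorm(t) + f*pnorm(t - delta) = 1/2 for t, then
# E(delta) = f*(1 - pnorm(t - delta))^k + (1-f)*(1 - pnorm(t))^k = f.
solve_combo_shift <- function(f, k, capture = 0.95) {
  threshold_of <- function(delta) {
    uniroot(function(t) (1 - f) * pnorm(t) + f * pnorm(t - delta) - 0.5,
            c(-10, 10 + delta))$root
  }
  expected <- function(delta) {
    t <- threshold_of(delta)
    f * (1 - pnorm(t - delta))^k + (1 - f) * (1 - pnorm(t))^k
  }
  lo <- 0.01
  hi <- 8
  if (expected(hi) < f) {
    stop_secepr(paste0(
      "subgroup fraction ", f, " not reachable for a ", k,
      "-gene combination; lower the fraction or the combination size"
    ))
  }
  # delta that captures `capture` of the subgroup members jointly — the
  # quantity carrying the planted hazard signal into the altered mask
  d_cap <- uniroot(function(d) pnorm(d - threshold_of(d))^k - capture,
                   c(lo, hi + 4))$root
  # delta whose expected altered fraction equals f exactly (when the
  # background joint exceedance has not already overshot f); take the
  # larger so the subgroup is never silently diluted out of the mask
  if (expected(lo) < f) {
    d_f <- uniroot(function(d) expected(d) - f, c(lo, hi))$root
    max(d_f, d_cap)
  } else {
    d_cap
  }
}

simulate_one_cohort <- function(config, seed, name) {
  nps <- config$n_patients_by_subtype
  n <- sum(nps)
  pam50 <- rep(names(nps), nps)
  ids <- sprintf("%s_P%04d", toupper(name), seq_len(n))
  genes <- sim_gene_ids(config$n_genes)
  if (config$n_diff_genes > config$n_genes) {
    stop_secepr("more differential genes than genes")
  }
  diff_genes <- genes[seq_len(config$n_diff_genes)]
  combo_genes <- unique(unlist(lapply(config$planted_combos, `[[`, "genes")))
  if (length(setdiff(combo_genes, genes))) {
    stop_secepr("planted combo genes must be in the simulated gene set")
  }
  out <- withr::with_seed(seed, {
    z <- matrix(rnorm(config$n_genes * n), config$n_genes, n,
                dimnames = list(genes, ids))
    basal <- pam50 == "Basal"
    if (length(diff_genes)) {
      z[diff_genes, basal] <- z[diff_genes, basal] + config$diff_shift
    }
    scope <- pam50 == config$combo_subtype
    member_any <- rep(FALSE, n)
    log_hr <- rep(0, n)
    membership <- list()
    for (ci in seq_along(config$planted_combos)) {
      pc <- config$planted_combos[[ci]]
      k <- length(pc$genes)
      delta <- solve_combo_shift(pc$fraction, k)
      idx_scope <- which(scope)
      n_sub <- round(pc$fraction * length(idx_scope))
      if (n_sub < 1) stop_secepr("subgroup fraction too small for cohort size")
      members <- sample(idx_scope, n_sub)
      z[pc$genes, members] <- z[pc$genes, members] + delta
      member_any[members] <- TRUE
      log_hr[members] <- log_hr[members] + log(pc$hr)
      membership[[ci]] <- ids[members]
    }
    hazard <- config$baseline_hazard * exp(log_hr)
    t_event <- rexp(n, hazard)
    c_admin <- rep(config$censor_horizon, n)
    has_drop <- runif(n) < config$dropout_rate
    c_drop <- ifelse(has_drop, runif(n, 0, config$censor_horizon), Inf)
    cens <- pmin(c_admin, c_drop)
    time <- pmin(t_event, cens)
    event <- t_event <= cens
    list(z = z, time = time, event = event, member = member_any,
         membership = membership)
  })
  clinical <- tibble::tibble(
    patient_id = ids, pam50 = pam50,
    time = round(out$time, 3), event = out$event
  )
  cohort <- secep_cohort(out$z, clinical, name = name,
                         endpoint = config$endpoint)
  truth <- list(
    diff_genes = diff_genes,
    combos = config$planted_combos,
    membership = out$membership,
    member = setNames(out$member, ids)
  )
  list(cohort = cohort, truth = truth)
}

#' Simulate a discovery/validation cohort pair
#'
#' Draws two independent cohorts from the same configuration using derived
#' child seeds, so the pair emulates a discovery + validation design with
#' shared planted structure but independent sampling noise.
#'
#' @inheritParams simulate_lfq
#' @return List: `discovery`, `validation` (both [secep_cohort()]) and
#'   `truth` (planted differential genes, combos and per-cohort risk
#'   subgroup membership).
#' @export
simulate_cohort_pair <- function(config = sim_config(), seed = 1) {
  disc <- simulate_one_cohort(config, child_seed(seed, 2), "discovery")
  val <- simulate_one_cohort(config, child_seed(seed, 3), "validation")
  list(
    discovery = disc$cohort,
    validation = val$cohort,
    truth = list(
      diff_genes = disc$truth$diff_genes,
      combos = config$planted_combos,
      membership = list(discovery = disc$truth$membership,
                        validation = val$truth$membership),
      member = list(discovery = disc$truth$member,
                    validation = val$truth$member)
    )
  )
}

#' Simulate a linked secretome + cohort study
#'
#' Generates an LFQ matrix and a cohort pair over a shared gene namespace:
#' planted basal-up secretome proteins are (a subset of) the planted
#' basal-differential genes, so the full pipeline — secretion calls, SeCEP
#' classification, combination screen — can be exercised end to end.
#'
#' @inheritParams simulate_lfq
#' @return List: `lfq`, `samples`, `cohorts` (discovery/validation),
#'   `truth`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  if (config$n_proteins > config$n_genes) {
    stop_secepr("n_proteins must be <= n_genes for a linked study")
  }
  lfq_sim <- simulate_lfq(config, seed = seed)
  pair <- simulate_cohort_pair(config, seed = seed)
  list(
    lfq = lfq_sim$lfq, samples = lfq_sim$samples,
    discovery = pair$discovery, validation = pair$validation,
    truth = c(list(secretion = lfq_sim$truth), pair$truth)
  )
}

#' Write a synthetic fixture bundle to disk
#'
#' Emits the full input set in the pipeline's TSV dialects: LFQ matrix +
#' sample sheet, per-cohort expression and clinical TSVs, truth tables, and
#' the configuration as YAML. Round-trips losslessly through [read_lfq()]
#' and [read_cohort()]; two calls with the same seed produce byte-identical
#' files.
#'
#' @inheritParams simulate_lfq
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named vector of written file paths.
#' @export
write_fixture_bundle <- function(config = sim_config(), out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(config, seed = seed)
  paths <- c(
    lfq = file.path(out_dir, "lfq_matrix.tsv"),
    samples = file.path(out_dir, "lfq_samples.tsv"),
    discovery_expr = file.path(out_dir, "discovery_expr.tsv"),
    discovery_clinical = file.path(out_dir, "discovery_clinical.tsv"),
    validation_expr = file.path(out_dir, "validation_expr.tsv"),
    validation_clinical = file.path(out_dir, "validation_clinical.tsv"),
    truth_secretion = file.path(out_dir, "truth_secretion.tsv"),
    truth_diff_genes = file.path(out_dir, "truth_diff_genes.tsv"),
    truth_combos = file.path(out_dir, "truth_combos.tsv"),
    config = file.path(out_dir, "sim_config.yaml")
  )
  wt <- function(x, p) readr::write_tsv(x, p, progress = FALSE)
  wt(study$lfq, paths["lfq"])
  wt(study$samples, paths["samples"])
  expr_tbl <- function(cohort) {
    dplyr::bind_cols(tibble::tibble(gene_id = rownames(cohort$z)),
                     tibble::as_tibble(cohort$z))
  }
  clin_tbl <- function(cohort) {
    dplyr::select(cohort$clinical, "patient_id", "pam50", "time", "event")
  }
  wt(expr_tbl(study$discovery), paths["discovery_expr"])
  wt(clin_tbl(study$discovery), paths["discovery_clinical"])
  wt(expr_tbl(study$validation), paths["validation_expr"])
  wt(clin_tbl(study$validation), paths["validation_clinical"])
  wt(study$truth$secretion, paths["truth_secretion"])
  wt(tibble::tibble(gene_id = study$truth$diff_genes), paths["truth_diff_genes"])
  combos_tbl <- if (length(study$truth$combos)) {
    purrr::map_dfr(study$truth$combos, function(pc) {
      tibble::tibble(genes = paste(sort(pc$genes), collapse = "+"),
                     fraction = pc$fraction, hr = pc$hr)
    })
  } else {
    tibble::tibble(genes = character(), fraction = double(), hr = double())
  }
  wt(combos_tbl, paths["truth_combos"])
  cfg <- unclass(config)
  cfg$n_patients_by_subtype <- as.list(cfg$n_patients_by_subtype)
  cfg$seed <- seed
  yaml::write_yaml(cfg, paths["config"])
  invisible(paths)
}
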