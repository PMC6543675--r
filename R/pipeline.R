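#' Run the full secreto-transcriptomic pipeline
#'
#' Executes the stages in order — subtype-specific secretion calling from
#' the LFQ matrix, SeCEP classification against each cohort (intersected
#' across cohorts), and the dual-cohort co-overexpression combination
#' screen — persisting each stage's table as TSV plus a JSON run manifest.
#' Every stage is also runnable standalone through its own function; this
#' wrapper just wires them together and logs the three decisions most
#' likely to change results (BH family size, median scope, fraction floor).
#'
#' @param inputs Either the result of [simulate_study()] /
#'   [write_fixture_bundle()] paths, given as a named list with elements
#'   `lfq`, `samples`, `cohorts` (named list of [secep_cohort()]), or a
#'   directory containing a fixture bundle.
#' @param out_dir Output directory.
#' @param config A [screen_config()] for the combination screen.
#' @param anova_p,r_threshold Secretion-calling thresholds.
#' @param alpha SeCEP adjusted-p threshold.
#' @param secep_subtype Which SeCEP class feeds the screen (`"basal"` or
#'   `"luminal"`; default follows `config$subtype_scope`).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return Invisibly, a list with `calls`, `secep` (per cohort),
#'   `secep_set`, `screen`, `manifest` and the written file paths.
#' @export
run_pipeline <- function(inputs, out_dir, config = screen_config(),
                         anova_p = 0.05, r_threshold = 0.8, alpha = 0.05,
                         secep_subtype = NULL, seed = NA_integer_) {
  t0 <- Sys.time()
  if (is.character(inputs) && length(inputs) == 1) {
    inputs <- read_fixture_bundle(inputs)
  }
  stopifnot(is.list(inputs$cohorts), length(inputs$cohorts) >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  tic <- function(stage, expr) {
    s <- Sys.time()
    val <- force(expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    val
  }
  calls <- tic("secretome", call_subtype_secretion(
    inputs$lfq, inputs$samples, anova_p = anova_p, r_threshold = r_threshold
  ))
  secep <- tic("classify", lapply(inputs$cohorts, function(co) {
    de <- subtype_de(co)
    classify_secep(de, calls, alpha = alpha, require_concordance = TRUE)
  }))
  secep_set <- secep_intersect(secep)
  secep_subtype <- secep_subtype %||%
    if (identical(config$subtype_scope, "Basal")) "basal" else "luminal"
  screen_genes <- secep_set$gene_id[secep_set$secep_subtype == secep_subtype]
  screen_res <- if (length(screen_genes)) {
    tic("screen", screen_combos(inputs$cohorts, screen_genes, config))
  } else {
    rlang::warn("no SeCEP genes for the screen scope; screen skipped")
    NULL
  }
  paths <- c(
    calls = file.path(out_dir, "secretome_calls.tsv"),
    secep = file.path(out_dir, "secep_genes.tsv"),
    screen = file.path(out_dir, "screen_results.tsv"),
    manifest = file.path(out_dir, "run_manifest.json")
  )
  readr::write_tsv(calls, paths["calls"], progress = FALSE)
  readr::write_tsv(secep_set, paths["secep"], progress = FALSE)
  if (!is.null(screen_res)) {
    readr::write_tsv(tibble::as_tibble(screen_res), paths["screen"],
                     progress = FALSE)
  }
  bh_family <- vapply(inputs$cohorts, function(co) nrow(co$z), numeric(1))
  manifest <- list(
    tool = "secepr",
    version = as.character(utils::packageVersion("secepr")),
    seed = seed,
    config = unclass(config),
    thresholds = list(anova_p = anova_p, r_threshold = r_threshold,
                      alpha = alpha),
    bh_family_size = as.list(bh_family),
    median_scope = config$median_scope,
    min_altered_fraction = config$min_altered_fraction,
    counts = list(
      n_calls = nrow(calls),
      n_secep = nrow(secep_set),
      n_screened = if (is.null(screen_res)) 0 else attr(screen_res, "n_enumerated"),
      n_passing = if (is.null(screen_res)) 0 else sum(screen_res$passes)
    ),
    outputs = as.list(basename(paths[file.exists(paths)])),
    timings_sec = lapply(timings, function(x) round(x, 3)),
    total_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  inform_settings <- sprintf(
    "pipeline settings: BH family = %s; median_scope = %s; min_altered_fraction = %g",
    paste(bh_family, collapse = "/"), config$median_scope,
    config$min_altered_fraction
  )
  rlang::inform(inform_settings)
  invisible(list(calls = calls, secep = secep, secep_set = secep_set,
                 screen = screen_res, manifest = manifest, paths = paths))
}

# Load a fixture bundle directory written by write_fixture_bundle().
read_fixture_bundle <- function(dir) {
  need <- c("lfq_matrix.tsv", "lfq_samples.tsv",
            "discovery_expr.tsv", "discovery_clinical.tsv",
            "validation_expr.tsv", "validation_clinical.tsv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      stop_secepr(paste0("fixture bundle is missing ", file.path(dir, f)))
    }
  }
  lfq <- read_lfq(file.path(dir, "lfq_matrix.tsv"),
                  file.path(dir, "lfq_samples.tsv"))
  cfg <- file.path(dir, "sim_config.yaml")
  endpoint <- if (file.exists(cfg)) yaml::read_yaml(cfg)$endpoint %||% "OS" else "OS"
  cohorts <- list(
    discovery = read_cohort(file.path(dir, "discovery_expr.tsv"),
                            file.path(dir, "discovery_clinical.tsv"),
                            name = "discovery", endpoint = endpoint),
    validation = read_cohort(file.path(dir, "validation_expr.tsv"),
                             file.path(dir, "validation_clinical.tsv"),
                             name = "validation", endpoint = endpoint)
  )
  list(lfq = lfq$lfq, samples = lfq$samples, cohorts = cohorts)
}

#' Export a two-group Kaplan-Meier table for a combination
#'
#' Produces the figure-style export for one gene combination in one
#' cohort: per-group survival steps plus the annotation block (N, NE,
#' log-rank p, HR with 95% CI) that accompanies each plot.
#'
#' @param genes Character vector (the combination).
#' @param cohort A [secep_cohort()].
#' @param config A [screen_config()] (controls scope and median
#'   population).
#' @param file Optional TSV path; the annotation block is written as
#'   `# key: value` header lines.
#' @return Tibble of KM steps with attribute `"annotation"`.
#' @export
km_export <- function(genes, cohort, config = screen_config(), file = NULL) {
  prep <- cohort_screen_data(cohort, sort(unique(genes)), config)
  k <- nrow(prep$masks)
  mask <- if (k == 1) prep$masks[1, ] else colSums(prep$masks) == k
  if (!any(mask)) stop_secepr("altered group is empty for this combination")
  if (all(mask)) stop_secepr("not-altered group is empty for this combination")
  df <- tibble::tibble(
    time = prep$pre$t_sorted[order(prep$pre$o)], # original order
    event = rep(NA, prep$n)
  )
  # rebuild original-order time/event from the precompute inputs
  time <- numeric(prep$n)
  event <- integer(prep$n)
  time[prep$pre$o] <- prep$pre$t_sorted
  event[prep$pre$o] <- prep$pre$e_sorted
  dat <- tibble::tibble(
    time = time, event = event == 1L,
    group = ifelse(mask, "altered", "not_altered")
  )
  km <- km_fit(dat, group = "group")
  lr <- logrank_core(prep$pre, as.integer(mask))
  cx <- cox_core(prep$pre, as.integer(mask))
  ann <- tibble::tibble(
    group = names(km$n),
    n = as.integer(km$n),
    n_events = as.integer(km$n_events)
  )
  steps <- km$steps
  attr(steps, "annotation") <- list(
    genes = paste(sort(unique(genes)), collapse = "+"),
    cohort = cohort$name, endpoint = cohort$endpoint,
    N = setNames(ann$n, ann$group),
    NE = setNames(ann$n_events, ann$group),
    logrank_p = lr$p, hr = cx$hr, ci_low = cx$ci_low, ci_high = cx$ci_high
  )
  if (!is.null(file)) {
    a <- attr(steps, "annotation")
    hdr <- c(
      paste0("# genes: ", a$genes),
      paste0("# cohort: ", a$cohort, " (", a$endpoint, ")"),
      paste0("# N: ", paste(names(a$N), a$N, sep = "=", collapse = ", ")),
      paste0("# NE: ", paste(names(a$NE), a$NE, sep = "=", collapse = ", ")),
      sprintf("# logrank_p: %.6g", a$logrank_p),
      sprintf("# HR: %.4f [%.4f, %.4f]", a$hr, a$ci_low, a$ci_high)
    )
    writeLines(hdr, file)
    suppressWarnings(
      readr::write_tsv(steps, file, append = TRUE, col_names = TRUE,
                       progress = FALSE)
    )
  }
  steps
}

#' Command-line entry point
#'
#' Thin dispatcher backing the `inst/cli/secep` script. Subcommands:
#' `simulate` (write a fixture bundle), `run` (full pipeline on a bundle
#' directory), and `screen` (combination screen from cohort TSVs and a
#' gene list). All accept `--seed`, `--out` and stage-specific flags;
#' `--help` prints usage.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
secep_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: secep <command> [options]",
    "commands:",
    "  simulate --out DIR [--seed N]          write a synthetic fixture bundle",
    "  run --in DIR --out DIR [--seed N]      full pipeline on a fixture bundle",
    "  screen --genes F --discovery E,C --validation E,C --out DIR",
    "         [--scope Basal] [--max-k 5] [--min-frac 0.08] [--alpha 0.05]",
    sep = "\n"
  )
  if (!length(args) || args[1] %in% c("--help", "-h", "help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  if (!is.null(opts$help)) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  seed <- as.integer(opts$seed %||% 1)
  status <- tryCatch({
    switch(cmd,
      simulate = {
        if (is.null(opts$out)) stop_secepr("simulate needs --out")
        write_fixture_bundle(sim_config(), opts$out, seed = seed)
        0L
      },
      run = {
        if (is.null(opts$`in`) || is.null(opts$out)) {
          stop_secepr("run needs --in and --out")
        }
        run_pipeline(opts$`in`, opts$out, seed = seed)
        0L
      },
      screen = {
        for (o in c("genes", "discovery", "validation", "out")) {
          if (is.null(opts[[o]])) stop_secepr(paste0("screen needs --", o))
        }
        genes <- readr::read_tsv(opts$genes, show_col_types = FALSE,
                                 progress = FALSE)[[1]]
        parse_cohort <- function(spec, nm) {
          parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
          if (length(parts) != 2) stop_secepr("cohort spec must be expr,clinical")
          read_cohort(parts[1], parts[2], name = nm)
        }
        cohorts <- list(
          discovery = parse_cohort(opts$discovery, "discovery"),
          validation = parse_cohort(opts$validation, "validation")
        )
        cfg <- screen_config(
          max_k = as.integer(opts$`max-k` %||% 5),
          alpha = as.numeric(opts$alpha %||% 0.05),
          min_altered_fraction = as.numeric(opts$`min-frac` %||% 0.08),
          subtype_scope = opts$scope %||% "Basal"
        )
        res <- screen_combos(cohorts, genes, cfg)
        dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
        readr::write_tsv(tibble::as_tibble(res),
                         file.path(opts$out, "screen_results.tsv"),
                         progress = FALSE)
        0L
      },
      {
        cat("unknown command:", cmd, "\n", usage, "\n")
        2L
      }
    )
  }, secepr_error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% c("--help", "-h")) {
      opts$help <- TRUE
      i <- i + 1
    } else if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
        opts[[key]] <- args[i + 1]
        i <- i + 2
      } else {
        opts[[key]] <- TRUE
        i <- i + 1
      }
    } else {
      stop_secepr(paste0("unexpected argument: ", a))
    }
  }
  opts
}
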