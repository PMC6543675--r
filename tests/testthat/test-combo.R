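make_cohort <- function(z, pam50 = NULL, time = NULL, event = NULL,
                        name = "toy") {
  n <- ncol(z)
  clin <- tibble::tibble(
    patient_id = colnames(z),
    pam50 = pam50 %||% rep("Basal", n),
    time = time %||% seq_len(n),
    event = event %||% rep(TRUE, n)
  )
  secep_cohort(z, clin, name = name)
}

test_that("altered masks implement the strict median split and AND semantics", {
  z <- rbind(g1 = c(0, 1, 2, 3), g2 = c(3, 0, 2, 1), flat = c(1, 1, 1, 1))
  colnames(z) <- paste0("p", 1:4)
  co <- make_cohort(z)
  expect_equal(unname(altered_mask(co, "g1")), c(FALSE, FALSE, TRUE, TRUE))
  m1 <- altered_mask(co, "g1")
  m2 <- altered_mask(co, "g2")
  expect_equal(altered_mask(co, c("g1", "g2")), m1 & m2)
  # all-equal gene: strict inequality gives an empty altered set
  expect_false(any(altered_mask(co, "flat")))
  expect_error(altered_mask(co, "missing_gene"), "missing_gene")
})

test_that("adding a gene never increases the altered fraction", {
  z <- withr::with_seed(31, matrix(rnorm(10 * 60), 10,
                                   dimnames = list(paste0("g", 1:10),
                                                   paste0("p", 1:60))))
  co <- make_cohort(z)
  for (i in 1:20) {
    genes <- withr::with_seed(500 + i, sample(rownames(z), 3))
    f2 <- mean(altered_mask(co, genes[1:2]))
    f3 <- mean(altered_mask(co, genes))
    expect_lte(f3, f2)
    expect_lte(f3, min(mean(altered_mask(co, genes[1])),
                       mean(altered_mask(co, genes[2]))))
  }
})

test_that("combination enumeration is complete, sorted and deduplicated", {
  combos <- enumerate_combinations(c("E", "B", "A", "D", "C"), 2)
  expect_equal(nrow(combos), 15) # 5 + 10
  ids <- vapply(combos$genes, paste, character(1), collapse = "+")
  expect_equal(anyDuplicated(ids), 0)
  expect_true(all(vapply(combos$genes, function(g) !is.unsorted(g), logical(1))))
  # lexicographic within each size
  expect_equal(ids[1:5], c("A", "B", "C", "D", "E"))
  expect_warning(big <- enumerate_combinations(c("A", "B"), 5), "capped")
  expect_equal(nrow(big), 3)
  expect_equal(n_combinations(5, 2), 15)
  expect_equal(n_combinations(2, 5), 3)
})

test_that("fraction pruning short-circuits the survival tests", {
  # one gene altered in 2% of 100 patients at an 8% floor
  z <- matrix(c(rep(2, 2), rep(0, 98)), 1,
              dimnames = list("g1", paste0("p", 1:100)))
  co <- make_cohort(z, time = withr::with_seed(32, rexp(100, 0.05)))
  res <- evaluate_combo("g1", co, screen_config(max_k = 1))
  expect_false(res$passes)
  expect_match(res$fail_reasons, "min_fraction")
  expect_true(is.na(res$logrank_p)) # survival tests never ran
})

test_that("pruning never changes the passing set (no-prune oracle)", {
  cfg <- screen_sim_config(planted_combos = list(
    list(genes = c("G0001", "G0002"), fraction = 0.2, hr = 2.5)
  ), n_basal = 150)
  pair <- simulate_cohort_pair(cfg, seed = 33)
  genes <- sprintf("G%04d", 1:10)
  cohorts <- list(d = pair$discovery, v = pair$validation)
  fast <- screen_combos(cohorts, genes, screen_config(max_k = 3, prune = TRUE))
  slow <- screen_combos(cohorts, genes, screen_config(max_k = 3, prune = FALSE))
  expect_equal(fast$genes, slow$genes)
  expect_equal(fast$passes, slow$passes)
  expect_gt(sum(fast$passes), 0) # the planted pair does pass
})

test_that("screen results are deterministic across reruns", {
  cfg <- screen_sim_config(n_basal = 120)
  pair <- simulate_cohort_pair(cfg, seed = 34)
  cohorts <- list(d = pair$discovery, v = pair$validation)
  r1 <- screen_combos(cohorts, sprintf("G%04d", 1:8), screen_config(max_k = 2))
  r2 <- screen_combos(cohorts, sprintf("G%04d", 1:8), screen_config(max_k = 2))
  expect_identical(r1, r2)
})

test_that("a planted risk combination passes the dual-cohort screen", {
  cfg <- screen_sim_config(planted_combos = planted_screen_combos()[1])
  pair <- simulate_cohort_pair(cfg, seed = 35)
  res <- screen_combos(list(d = pair$discovery, v = pair$validation),
                       sprintf("G%04d", 1:12), screen_config(max_k = 4))
  planted_id <- paste(sprintf("G%04d", 1:4), collapse = "+")
  row <- res[res$genes == planted_id, ]
  expect_true(row$passes)
  expect_lt(row$d_logrank_p, 0.05)
  expect_gt(row$d_ci_low, 1)
  expect_gt(row$d_altered_fraction, 0.08)
  # single-cohort screen: validation criterion vacuous
  solo <- screen_combos(pair$discovery, sprintf("G%04d", 1:4),
                        screen_config(max_k = 4))
  expect_true(solo$passes[solo$genes == planted_id])
})

test_that("subtype specificity keeps combos passing only in the target scope", {
  mk <- function(genes, passes) tibble::tibble(genes = genes, passes = passes)
  results <- list(
    LumA = mk(c("A+B", "C+D", "E"), c(TRUE, TRUE, FALSE)),
    LumB = mk(c("A+B", "C+D", "E"), c(FALSE, TRUE, FALSE)),
    Basal = mk(c("A+B", "C+D", "E"), c(FALSE, FALSE, TRUE))
  )
  spec <- subtype_specificity(results, "LumA")
  expect_equal(spec$genes, "A+B") # C+D also passes in LumB -> excluded
  expect_error(subtype_specificity(results, "Her2"), "missing")
})

test_that("a planted LumA-only subgroup shows up only in the LumA scope", {
  cfg <- sim_config(
    n_genes = 8, n_diff_genes = 0,
    n_patients_by_subtype = c(Basal = 40, LumA = 250, LumB = 250,
                              Her2 = 20, Normal = 10),
    planted_combos = list(list(genes = c("G0001", "G0002"),
                               fraction = 0.18, hr = 3.5)),
    combo_subtype = "LumA"
  )
  pair <- simulate_cohort_pair(cfg, seed = 36)
  genes <- sprintf("G%04d", 1:8)
  scopes <- lapply(c(LumA = "LumA", LumB = "LumB"), function(sc) {
    screen_combos(list(d = pair$discovery, v = pair$validation), genes,
                  screen_config(max_k = 2, subtype_scope = sc))
  })
  spec <- subtype_specificity(scopes, "LumA")
  expect_true("G0001+G0002" %in% spec$genes)
  expect_false(scopes$LumB$passes[scopes$LumB$genes == "G0001+G0002"])
})

test_that("the DRFS screen applies strict dual fractions and trial-side significance", {
  combo <- list(list(genes = c("G0001", "G0002"), fraction = 0.2, hr = 3.5))
  cfg_trial <- sim_config(
    n_genes = 6, n_diff_genes = 0, endpoint = "DRFS",
    n_patients_by_subtype = c(Basal = 350, LumA = 30, LumB = 30,
                              Her2 = 10, Normal = 5),
    planted_combos = combo
  )
  cfg_ref <- sim_config(
    n_genes = 6, n_diff_genes = 0,
    n_patients_by_subtype = c(Basal = 350, LumA = 30, LumB = 30,
                              Her2 = 10, Normal = 5),
    planted_combos = combo
  )
  trial <- simulate_cohort_pair(cfg_trial, seed = 37)$discovery
  ref <- simulate_cohort_pair(cfg_ref, seed = 38)$validation
  res <- drfs_screen(trial, ref, sprintf("G%04d", 1:6),
                     config = screen_config(max_k = 2,
                                            min_altered_fraction = 0.10,
                                            require_ci_low_gt_1 = FALSE))
  row <- res[res$genes == "G0001+G0002", ]
  expect_true(row$passes)
  expect_gt(row$discovery_altered_fraction, 0.10)
  expect_gt(row$validation_altered_fraction, 0.10)
  expect_lt(row$discovery_logrank_p, 0.05)
  # reference-side fraction floor is binding: raising it above the planted
  # fraction kills the combination without touching trial significance
  res_hi <- drfs_screen(trial, ref, c("G0001", "G0002"),
                        config = screen_config(max_k = 2,
                                               min_altered_fraction = 0.35,
                                               require_ci_low_gt_1 = FALSE))
  expect_false(res_hi$passes[res_hi$genes == "G0001+G0002"])
  # endpoint guard
  expect_error(drfs_screen(ref, trial, c("G0001", "G0002")), "DRFS")
})
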