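# Population tallies, efficiency percentages and the end-to-end pipeline.

test_that("percent formatting rounds half away from zero at one decimal", {
  expect_equal(round_half_up(100 * 45 / 61, 1), 73.8)
  expect_equal(round_half_up(100 * 124 / 138, 1), 89.9)
  expect_equal(round_half_up(79.85, 1), 79.9)
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(-0.05, 1), -0.1)
})

test_that("efficiency summaries compute per-type and aggregate ratios", {
  tally <- population_tally(tibble::tibble(
    germination_type = c("Type-0", "Type-1", "Type-2", "Type-3"),
    mutant = c(1L, 2L, 0L, 5L),
    total = c(3L, 4L, 0L, 5L)
  ), label = "toy")
  rep <- efficiency_summary(tally)
  tab <- rep$table
  expect_equal(tab$percent[tab$category == "Type-0"], 33.3)
  expect_true(is.na(tab$percent[tab$category == "Type-2"]))  # n/a, never 0%
  expect_equal(tab$percent[tab$category == "Type-0+1"], 42.9)  # 3/7
  expect_equal(tab$percent[tab$category == "germinated"], 42.9)
  expect_equal(tab$percent[tab$category == "all"], 66.7)  # 8/12
  expect_equal(tab$mutant[tab$category == "all"], 8L)

  expect_error(population_tally(tibble::tibble(
    germination_type = "Type-0", mutant = 5L, total = 3L)), "\\[0, total\\]")
})

test_that("zero-mutant cells report 0.0 percent when the total is positive", {
  tally <- population_tally(tibble::tibble(
    germination_type = "Type-0", mutant = 0L, total = 50L))
  expect_equal(efficiency_summary(tally)$table$percent[1], 0)
})

test_that("population tallies join genotypes with germination records", {
  genes <- c("HAI1", "HAI2")
  ho <- function() list(class = "Ho", keys = "D:60:4", reads = 100L)
  he <- function() list(class = "He", keys = "D:60:4", reads = 50L,
                        wt_reads = 50L)
  plants <- c(
    lapply(1:4, function(i) fixture_plant(sprintf("m%d", i),
                                          list(HAI1 = ho(), HAI2 = ho()))),
    lapply(1:2, function(i) fixture_plant(sprintf("n%d", i),
                                          list(HAI1 = ho(), HAI2 = he())))
  )
  germ <- tibble::tibble(
    plant_id = c("m1", "m2", "m3", "m4", "n1", "n2", "dead1", "seed1", "seed2"),
    germinated = c(rep(TRUE, 7), FALSE, FALSE),
    day_of_germination = c(7L, 7L, 14L, 21L, 7L, 14L, 14L, NA, NA),
    stunted = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  # dead1 germinated but was never genotyped ("not recovered" -> nonmutant);
  # seed1/seed2 never germinated (Type-3)
  tally <- tally_population(plants, germ, presume_type3_mutant = FALSE)
  ct <- tally$counts
  expect_identical(ct$total, c(3L, 3L, 1L, 2L))
  expect_identical(ct$mutant[ct$germination_type == "Type-0"], 2L)  # m1 m2 (n1 is He)
  expect_identical(ct$mutant[ct$germination_type == "Type-1"], 1L)  # m3 of m3,n2,dead1
  expect_identical(ct$mutant[ct$germination_type == "Type-2"], 1L)  # m4
  expect_identical(ct$mutant[ct$germination_type == "Type-3"], 0L)

  tally2 <- tally_population(plants, germ, presume_type3_mutant = TRUE)
  expect_identical(
    tally2$counts$mutant[tally2$counts$germination_type == "Type-3"], 2L)

  dup <- rbind(germ, germ[1, ])
  expect_error(tally_population(plants, dup), "duplicate")
})

test_that("tallies match an independent count on simulated truth", {
  cfg <- simulation_config(n_plants = 80, depth = 1,
                           substitution_error_rate = 0, seed = 33)
  sim <- simulate_population(cfg)
  germ <- simulate_germination(sim$truth, seed = 33)
  flags <- cas12mux:::truth_plant_flags(sim$truth)
  plants <- lapply(flags$plant_id, function(pid) {
    sub <- sim$truth[sim$truth$plant_id == pid, ]
    spec <- lapply(split(sub, sub$gene_id), function(x) {
      mut <- x[x$key != "WT", ]
      list(class = x$true_class[1], keys = mut$key,
           reads = rep(10L, nrow(mut)),
           wt_reads = if (any(x$key == "WT")) 10L else 0L)
    })
    fixture_plant(pid, spec)
  })
  tally <- tally_population(plants, germ, presume_type3_mutant = TRUE)

  # independent counting: loop over records, no package tally machinery
  for (tp in c("Type-0", "Type-1", "Type-2", "Type-3")) {
    ids <- germ$plant_id[germ$germination_type == tp]
    want_total <- length(ids)
    want_mut <- sum(flags$is_sextuple_no_wt[match(ids, flags$plant_id)])
    row <- tally$counts[tally$counts$germination_type == tp, ]
    expect_identical(row$total, as.integer(want_total))
    expect_identical(row$mutant, as.integer(want_mut))
  }

  # permutation invariance of the tally and summary
  perm <- withr::with_seed(9, sample(seq_along(plants)))
  tally_p <- tally_population(plants[perm],
                              germ[withr::with_seed(10, sample(nrow(germ))), ],
                              presume_type3_mutant = TRUE)
  expect_identical(tally_p$counts, tally$counts)
  expect_identical(efficiency_summary(tally_p)$table,
                   efficiency_summary(tally)$table)
})

test_that("run_pipeline reproduces the truth-derived report end to end", {
  dir <- withr::local_tempdir()
  sites <- synthetic_pp2c_sites()
  cfg <- simulation_config(n_plants = 12, depth = 50,
                           substitution_error_rate = 0, seed = 77,
                           genes = sites)
  sim <- simulate_population(cfg, outdir = file.path(dir, "reads"))
  germ <- simulate_germination(sim$truth, seed = 77)
  write_germination_table(germ, file.path(dir, "germination.tsv"))
  write_target_manifest(sites, file.path(dir, "manifest.tsv"))
  amps <- vapply(sites, `[[`, "", "amplicon_seq")
  writeLines(paste0(">", vapply(sites, `[[`, "", "amplicon_id"), "\n", amps),
             file.path(dir, "amplicons.fasta"))
  config <- list(
    manifest = file.path(dir, "manifest.tsv"),
    amplicons = file.path(dir, "amplicons.fasta"),
    reads_dir = file.path(dir, "reads"),
    germination = file.path(dir, "germination.tsv"),
    out_dir = file.path(dir, "out"),
    label = "sim-check"
  )
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  res <- run_pipeline(file.path(dir, "config.json"))

  # with zero sequencing error the pipeline must match the truth exactly
  flags <- cas12mux:::truth_plant_flags(sim$truth)
  for (i in seq_len(nrow(flags))) {
    p <- res$plants[[flags$plant_id[i]]]
    expect_identical(p$is_sextuple_no_wt, flags$is_sextuple_no_wt[i])
    expect_identical(p$predicted_type3, flags$predicted_type3[i])
  }
  truth_tally <- tally_population(res$plants, germ,
                                  presume_type3_mutant = TRUE,
                                  label = "sim-check")
  expect_identical(res$tally$counts, truth_tally$counts)
  expect_true(all(file.exists(unlist(res$paths))))

  # determinism: a rerun writes byte-identical reports
  h1 <- tools::md5sum(c(res$paths$report_tsv, res$paths$calls))
  run_pipeline(file.path(dir, "config.json"))
  h2 <- tools::md5sum(c(res$paths$report_tsv, res$paths$calls))
  expect_identical(h1, h2)

  config$reads_dir <- file.path(dir, "nowhere")
  expect_error(run_pipeline(config), "calling stage")
  expect_error(run_pipeline(file.path(dir, "missing.json")), "config stage")
})
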