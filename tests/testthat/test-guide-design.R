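# PAM scanning, dual-target discovery, off-target enumeration, array
# assembly and Golden Gate oligo design.

test_that("PAM scanning finds forced sites and nothing else", {
  expect_identical(nrow(scan_pam_sites(strrep("AC", 50))), 0L)

  seq <- paste0("TTTC", rand_dna(23, seed = 2))
  hits <- scan_pam_sites(seq, both_strands = FALSE)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$spacer_start, 4L)
  expect_identical(hits$spacer_end, 27L)
  expect_identical(hits$pam_seq, "TTTC")
  expect_error(scan_pam_sites(seq, pam_pattern = "TTTX"), "IUPAC")
})

test_that("PAM scanning matches a regex oracle on random sequences", {
  withr::with_seed(31, {
    for (i in 1:10) {
      seq <- rand_dna(2000)
      hits <- scan_pam_sites(seq)
      plus <- hits[hits$strand == "+", ]
      minus <- hits[hits$strand == "-", ]
      expect_identical(sort(plus$pam_start), oracle_scan_plus(seq))
      expect_identical(sort(minus$pam_start), oracle_scan_plus(revcomp(seq)))
      # spacer sequences re-derivable from coordinates
      expect_identical(
        plus$spacer_seq,
        substr(rep(seq, nrow(plus)), plus$spacer_start + 1, plus$spacer_end))
      expect_identical(
        minus$spacer_seq,
        revcomp(substr(rep(seq, nrow(minus)), minus$spacer_start + 1,
                       minus$spacer_end)))
    }
  })
})

test_that("dual-target search keeps distal mismatches, drops proximal", {
  base <- rand_dna(300, seed = 41)
  spacer <- rand_dna(23, seed = 43)
  plant <- function(seq, insert, at) {
    paste0(substr(seq, 1, at), insert, substr(seq, at + nchar(insert) + 1,
                                              nchar(seq)))
  }
  seq_a <- plant(base, paste0("TTTC", spacer), 100)

  # identical homologs: shared site reported with zero mismatches
  same <- find_dual_targets(seq_a, seq_a)
  expect_true(any(same$n_mismatch == 0 & same$spacer_a == spacer))

  flip <- function(s, i) {
    old <- substr(s, i, i)
    new <- c(A = "C", C = "G", G = "T", T = "A")[[old]]
    paste0(substr(s, 1, i - 1), new, substr(s, i + 1, nchar(s)))
  }
  # mismatch at spacer position 21 (PAM-distal)
  seq_b <- plant(base, paste0("TTTC", flip(spacer, 21)), 100)
  pairs <- find_dual_targets(seq_a, seq_b)
  hit <- pairs[pairs$spacer_a == spacer & pairs$n_mismatch == 1, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$mismatch_positions[[1]], 21L)

  # mismatch at spacer position 3 (PAM-proximal): rejected
  seq_c <- plant(base, paste0("TTTC", flip(spacer, 3)), 100)
  pairs_c <- find_dual_targets(seq_a, seq_c)
  expect_false(any(pairs_c$spacer_a == spacer & pairs_c$n_mismatch > 0))

  # three distal mismatches exceed the default budget
  seq_d <- plant(base, paste0("TTTC", flip(flip(flip(spacer, 20), 21), 23)), 100)
  pairs_d <- find_dual_targets(seq_a, seq_d)
  expect_false(any(pairs_d$spacer_a == spacer & pairs_d$n_mismatch > 0))
  expect_true(any(find_dual_targets(seq_a, seq_d, max_mm = 3)$n_mismatch == 3))

  expect_error(find_dual_targets(seq_a, seq_b, distal_zone_start = 24),
               "spacer length")
})

test_that("dual-target search is symmetric under swapping the genes", {
  a <- rand_dna(400, seed = 51)
  b <- rand_dna(400, seed = 52)
  ab <- find_dual_targets(a, b, symmetric = TRUE)
  ba <- find_dual_targets(b, a, symmetric = TRUE)
  key <- function(x) sort(paste(x$spacer_a, x$spacer_b, x$n_mismatch))
  expect_identical(key(ab), sort(paste(ba$spacer_b, ba$spacer_a,
                                       ba$n_mismatch)))
})

test_that("off-target enumeration matches the Hamming oracle", {
  spacer <- rand_dna(23, seed = 61)
  withr::with_seed(62, {
    for (i in 1:6) {
      subj <- rand_dna(1500)
      for (pam_gate in c(TRUE, FALSE)) {
        hits <- enumerate_offtargets(spacer, c(s1 = subj), max_mm = 12,
                                     require_pam = pam_gate)
        plus_or <- oracle_offtargets_strand(spacer, subj, 12, pam_gate)
        minus_or <- oracle_offtargets_strand(spacer, revcomp(subj), 12, pam_gate)
        expect_identical(nrow(hits), length(plus_or) + length(minus_or))
        plus <- hits[hits$strand == "+", ]
        expect_identical(sort(plus$position),
                         as.integer(sort(vapply(plus_or, `[[`, 1, "start1") - 1)))
        expect_identical(sort(plus$mismatches),
                         as.integer(sort(vapply(plus_or, `[[`, 1, "mm"))))
      }
    }
  })
})

test_that("planted off-targets are gated by the mismatch budget", {
  spacer <- rand_dna(23, seed = 71)
  mm5 <- spacer
  for (i in c(2, 6, 10, 14, 18)) {
    substr(mm5, i, i) <- c(A = "C", C = "G", G = "T", T = "A")[[substr(spacer, i, i)]]
  }
  mm2 <- paste0(substr(spacer, 1, 19),
                chartr("ACGT", "CATG", substr(spacer, 20, 20)),
                substr(spacer, 21, 21),
                chartr("ACGT", "CATG", substr(spacer, 22, 22)),
                substr(spacer, 23, 23))
  subjects <- c(
    on = paste0(rand_dna(50, seed = 72), "TTTC", spacer, rand_dna(50, seed = 73)),
    near = paste0(rand_dna(50, seed = 74), "TTTA", mm2, rand_dna(50, seed = 75)),
    far = paste0(rand_dna(50, seed = 76), "TTTG", mm5, rand_dna(50, seed = 77))
  )
  hits <- enumerate_offtargets(spacer, subjects, max_mm = 3)
  expect_setequal(hits$subject_id, c("on", "near"))
  expect_identical(hits$mismatches[hits$subject_id == "on"], 0L)
  expect_identical(hits$mismatches[hits$subject_id == "near"], 2L)
  expect_identical(hits$position[hits$subject_id == "on"], 54L)

  expect_identical(nrow(enumerate_offtargets(spacer, character(0))), 0L)
  expect_warning(enumerate_offtargets(spacer, c(tiny = "ACGT")), "skipped")
})

test_that("zero-mismatch PAM-gated search reduces to the PAM scan", {
  seq <- rand_dna(2000, seed = 81)
  sites <- scan_pam_sites(seq)
  for (i in withr::with_seed(82, sample(seq_len(nrow(sites)), 5))) {
    hits <- enumerate_offtargets(sites$spacer_seq[i], c(x = seq), max_mm = 0)
    match_scan <- sites[sites$spacer_seq == sites$spacer_seq[i], ]
    expect_identical(nrow(hits), nrow(match_scan))
    expect_setequal(hits$position, match_scan$spacer_start)
  }
})

test_that("six spacers split across the two promoters preserving order", {
  sp <- vapply(1:6, function(i) rand_dna(23, seed = 90 + i), "")
  arrays <- split_six(sp)
  expect_named(arrays, c("U6-26", "U6-29"))
  expect_identical(arrays[["U6-26"]]$spacers, sp[1:3])
  expect_identical(arrays[["U6-29"]]$spacers, sp[4:6])
  # swapped layout keeps the same multiset of spacers
  swapped <- split_six(rev(sp))
  expect_setequal(c(swapped[[1]]$spacers, swapped[[2]]$spacers), sp)
  expect_error(split_six(sp[1:5]), "exactly 6")
})

test_that("array assembly and parsing are inverse operations", {
  parts <- default_parts()
  withr::with_seed(101, {
    for (i in 1:10) {
      sp <- replicate(3, rand_dna(23))
      arr <- crrna_array("U6-26", sp, parts)
      cassette <- assemble_array(arr)
      expect_identical(parse_array(cassette, parts), sp)
      expect_true(startsWith(cassette, parts$tgly))
      expect_true(endsWith(cassette, parts$hdv))
    }
  })
  bad <- crrna_array("U6-26", c(paste0("AC", default_parts()$direct_repeat),
                                rand_dna(23, seed = 1)))
  expect_error(assemble_array(bad), "ambiguous")
})

test_that("single-spacer oligo pairs follow the annealed-duplex layout", {
  sp <- rand_dna(23, seed = 111)
  pair <- design_oligos(sp)[[1]]
  expect_identical(pair$top, paste0("AGAT", sp))
  expect_identical(pair$bottom, paste0(revcomp("CTTG"), revcomp(sp)))
  expect_identical(pair$overhang_5, "AGAT")
  expect_identical(pair$overhang_3, "CTTG")
  expect_identical(ligate_oligos(list(pair)), sp)
})

test_that("colliding junction overhangs are re-cut, hard collisions refused", {
  # two spacers sharing a boundary 4-mer: the second junction cut slides
  # into the core and the assembly still ligates exactly
  sp1 <- paste0(rand_dna(19, seed = 121), "GTAC")
  sp2 <- paste0(rand_dna(19, seed = 122), "GTAC")
  sp3 <- rand_dna(23, seed = 123)
  pairs <- design_oligos(c(sp1, sp2, sp3))
  oh <- vapply(pairs, `[[`, "", "overhang_5")
  expect_false(anyDuplicated(c(oh, pairs[[3]]$overhang_3)) > 0)
  expect_identical(ligate_oligos(pairs), paste0(sp1, sp2, sp3))
  # identical terminal overhangs can never be disambiguated
  expect_error(design_oligos(sp3, overhang_config = list(left = "AGAT",
                                                         right = "AGAT")),
               "collision")
})

test_that("two-level Golden Gate reconstructs both U6 arrays exactly", {
  parts <- default_parts()
  withr::with_seed(131, {
    for (i in 1:5) {
      sp <- replicate(6, rand_dna(23))
      design <- design_six_crrna_oligos(sp, parts)
      arrays <- split_six(sp, parts)
      for (prom in names(arrays)) {
        core <- cas12mux:::array_core(arrays[[prom]])
        pairs <- design$level2[[prom]]
        expect_identical(ligate_oligos(pairs), core)
        # input order must not matter for the simulated one-pot reaction
        expect_identical(ligate_oligos(rev(pairs)), core)
      }
      # level-1 spacer inserts reproduce each spacer
      for (j in 1:6) {
        expect_identical(ligate_oligos(design$level1[j]), sp[j])
      }
    }
  })
})
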