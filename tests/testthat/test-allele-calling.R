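# Read alignment, event extraction and allele collapsing.

test_that("wild-type and canonical in-frame deletion reads are extracted", {
  site <- fixture_site()
  amp <- site$amplicon_seq

  ev <- align_read(amp, site)
  expect_identical(nrow(ev), 0L)

  # 12-nt deletion at the PAM-distal end of the spacer (the canonical
  # in-frame case: a partially functional allele)
  del12 <- apply_events(amp, "D:70:12")
  ev <- align_read(del12, site)
  expect_identical(ev$kind, "deletion")
  expect_identical(ev$len, 12L)
  expect_identical(annotate_frame(ev), "in-frame-3x-candidate")
  expect_identical(apply_events(amp, ev), del12)
})

test_that("planted indels are recovered across a randomized suite", {
  site <- fixture_site()
  amp <- site$amplicon_seq
  cases <- withr::with_seed(7, {
    lapply(1:50, function(i) {
      kind <- sample(c("deletion", "insertion"), 1)
      len <- sample(1:15, 1)
      pos <- sample(site$spacer_start:(site$spacer_end - 1), 1)
      if (kind == "deletion") {
        list(key = sprintf("D:%d:%d", pos, len))
      } else {
        list(key = sprintf("I:%d:%d:%s", pos, len, rand_dna(len)))
      }
    })
  })
  for (cs in cases) {
    read <- apply_events(amp, cs$key)
    ev <- align_read(read, site)
    # oracle: the extracted events reproduce the read from the reference,
    # and the net length change matches the planting script
    expect_identical(apply_events(amp, ev), read)
    expect_identical(net_indel(ev), net_indel(cs$key))
    expect_identical(nrow(ev), 1L)
  }
})

test_that("indel placement is left-normalized", {
  site <- fixture_site()
  amp <- site$amplicon_seq
  chars <- strsplit(amp, "")[[1]]
  # force a homopolymer run inside the window, then delete its right end:
  # extraction must report the leftmost equivalent placement
  chars[60] <- "C"; chars[67] <- "G"  # bound the run on both sides
  chars[61:66] <- "A"
  amp2 <- paste(chars, collapse = "")
  site2 <- target_site("G", "a", amp2, substr(amp2, 55, 77), "TTTC", "+", 50)
  read <- apply_events(amp2, "D:64:2")  # deletes two of the A run
  ev <- align_read(read, site2)
  expect_identical(ev$kind, "deletion")
  start_of_run <- 60L
  expect_identical(ev$pos, start_of_run)
  expect_identical(apply_events(amp2, ev), read)
})

test_that("substitution noise rides along without breaking indel calls", {
  site <- fixture_site()
  amp <- site$amplicon_seq
  read <- apply_events(amp, "D:60:5+S:100:1:A")
  truth_read <- read
  ev <- align_read(read, site)
  expect_setequal(ev$kind, c("deletion", "substitution"))
  expect_identical(apply_events(amp, ev), truth_read)
})

test_that("reads are rejected for length and excess edits", {
  site <- fixture_site()
  r <- align_read("ACGTACGT", site)
  expect_s3_class(r, "read_rejection")
  expect_identical(r$reason, "read_too_short")

  garbage <- rand_dna(nchar(site$amplicon_seq), seed = 1)
  res <- align_reads(c(site$amplicon_seq, garbage), site)
  expect_identical(attr(res, "rejected"), c(NA_character_, "excess_edits"))
  expect_null(res[[2]])
})

test_that("collapse arithmetic matches direct fraction accounting", {
  site <- fixture_site()
  a <- parse_allele_key("D:60:6")
  b <- parse_allele_key("I:65:2:GG")
  events <- c(replicate(48, list(a)), replicate(47, list(b)),
              replicate(5, list(cas12mux:::empty_events())))
  res <- collapse_alleles(events, site)
  expect_false(res$no_call)
  expect_identical(res$calls$key, c("D:60:6", "I:65:2:GG"))
  expect_equal(res$calls$fraction, c(0.48, 0.47))
  expect_equal(res$wt_fraction, 0.05)
  expect_identical(res$n_retained, 100L)
  expect_identical(classify_zygosity(res$calls$fraction, res$wt_fraction),
                   "Bi")
})

test_that("noise-floor alleles leave the denominator entirely", {
  site <- fixture_site()
  a <- parse_allele_key("D:60:6")
  noise <- parse_allele_key("S:62:1:A+D:60:6")
  events <- c(replicate(98, list(a)), replicate(2, list(noise)))
  res <- collapse_alleles(events, site)
  expect_identical(res$calls$key, "D:60:6")
  expect_identical(res$n_retained, 98L)
  expect_equal(res$calls$fraction, 1)
  # an allele clearing either floor survives
  events2 <- c(replicate(88, list(a)), replicate(12, list(noise)))
  res2 <- collapse_alleles(events2, site)
  expect_identical(nrow(res2$calls), 2L)
  expect_identical(res2$n_retained, 100L)
})

test_that("substitution-only reads count as wild type unless switched", {
  site <- fixture_site()
  sub_only <- parse_allele_key("S:62:1:A")
  events <- c(replicate(50, list(sub_only)),
              replicate(50, list(cas12mux:::empty_events())))
  res <- collapse_alleles(events, site)
  expect_identical(nrow(res$calls), 0L)
  expect_equal(res$wt_fraction, 1)
  res2 <- collapse_alleles(events, site, count_substitutions_as_mutant = TRUE)
  expect_identical(res2$calls$key, "S:62:1:A")
  expect_equal(res2$calls$fraction, 0.5)
})

test_that("collapsing is idempotent and fractions always sum to one", {
  site <- fixture_site()
  withr::with_seed(21, {
    for (rep in 1:15) {
      n_alleles <- sample(0:4, 1)
      keys <- unique(replicate(n_alleles, sprintf(
        "D:%d:%d", sample(55:75, 1), sample(1:10, 1))))
      counts <- if (length(keys)) sample(1:60, length(keys), replace = TRUE)
        else integer(0)
      wt <- sample(0:40, 1)
      events <- c(
        unlist(lapply(seq_along(keys), function(i)
          replicate(counts[i], list(parse_allele_key(keys[i])))),
          recursive = FALSE),
        replicate(wt, list(cas12mux:::empty_events()))
      )
      if (!length(events)) next
      res <- collapse_alleles(events, site)
      if (res$no_call) next
      expect_equal(sum(res$calls$fraction) + res$wt_fraction, 1,
                   tolerance = 1e-9)
      # idempotence: re-collapsing the collapsed evidence changes nothing
      events2 <- c(
        unlist(lapply(seq_len(nrow(res$calls)), function(i)
          replicate(res$calls$reads[i],
                    list(parse_allele_key(res$calls$key[i])))),
          recursive = FALSE),
        replicate(res$wt_reads, list(cas12mux:::empty_events()))
      )
      res2 <- collapse_alleles(events2, site)
      expect_identical(res2$calls$key, res$calls$key)
      expect_identical(res2$calls$reads, res$calls$reads)
      expect_identical(res2$wt_reads, res$wt_reads)
    }
  })
})

test_that("zero retained reads yield a no-call distinct from WT", {
  site <- fixture_site()
  res <- collapse_alleles(list(NULL, NULL), site)
  expect_true(res$no_call)
  expect_true(is.na(res$wt_fraction))
  expect_identical(res$n_retained, 0L)
})

test_that("pooled wild-type scan reflects pool composition and order", {
  site <- fixture_site()
  amp <- site$amplicon_seq
  mut <- apply_events(amp, "D:60:6")
  ho_pools <- replicate(19, rep(mut, 30), simplify = FALSE)
  wt_pool <- list(rep(amp, 30))

  expect_equal(pooled_wt_fraction(ho_pools, site), 0)
  expect_equal(pooled_wt_fraction(c(ho_pools, wt_pool), site), 0.05)
  expect_equal(pooled_wt_fraction(wt_pool, site), 1)
  # pooling then scanning equals scanning the concatenated pool, in any order
  shuffled <- withr::with_seed(3, sample(c(ho_pools, wt_pool)))
  expect_equal(pooled_wt_fraction(shuffled, site),
               pooled_wt_fraction(list(unlist(c(ho_pools, wt_pool)))[1], site))
  expect_true(is.na(pooled_wt_fraction(list(), site)))
})

test_that("pool homozygosity inference applies the noise ceiling", {
  expect_identical(infer_pool_homozygosity(0), "all-mutant-consistent")
  expect_identical(infer_pool_homozygosity(0.5), "wt-detected")
  expect_identical(infer_pool_homozygosity(0.004), "all-mutant-consistent")
  expect_identical(infer_pool_homozygosity(0.006), "wt-detected")
})
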