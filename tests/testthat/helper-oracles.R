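# Shared fixtures and independent oracles used by unit and acceptance tests.
# Oracles are deliberately written with different machinery than the package
# (regex scans, substr loops, direct arithmetic) so agreement is meaningful.

# A 200-nt amplicon with a TTTC PAM at 0-based offset 50 and 23-nt spacer.
fixture_amplicon <- function(seed = 42) {
  withr::with_seed(seed, {
    amp <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
    amp[51:54] <- c("T", "T", "T", "C")
    paste(amp, collapse = "")
  })
}

fixture_site <- function(seed = 42) {
  amp <- fixture_amplicon(seed)
  target_site(
    gene_id = "GENE", amplicon_id = "amp1", amplicon_seq = amp,
    spacer_seq = substr(amp, 55, 77), pam_seq = "TTTC",
    strand = "+", offset = 50
  )
}

# Decision-table oracle for zygosity classes, written as one vectorised
# lookup over (top fraction, mutant total, allele count).
oracle_zygosity <- function(top, total_mut, n_mut,
                            ho_bi = 0.95, he = 0.45) {
  ifelse(top >= ho_bi, "Ho",
         ifelse(total_mut >= ho_bi & n_mut >= 2, "Bi",
                ifelse(n_mut == 0, "WT",
                       ifelse(top >= he, "He", "Chi"))))
}

# Regex-based brute-force PAM scan of the plus strand of one sequence.
# Returns 0-based PAM starts with room for the spacer.
oracle_scan_plus <- function(seq, pam_regex = "TTT[ACG]", spacer_len = 23) {
  hits <- integer(0)
  n <- nchar(seq)
  off <- 0L
  rest <- seq
  repeat {
    m <- regexpr(pam_regex, rest)
    if (m < 0) break
    hits <- c(hits, off + as.integer(m) - 1L)
    off <- off + as.integer(m)
    rest <- substr(seq, off + 1L, n)
  }
  hits[hits + 4L + spacer_len <= n]
}

# Brute-force Hamming off-target scan of one strand using utf8ToInt.
oracle_offtargets_strand <- function(spacer, subj, max_mm, require_pam) {
  L <- nchar(spacer)
  sp <- utf8ToInt(spacer)
  sj <- utf8ToInt(subj)
  n <- length(sj)
  out <- list()
  for (i in seq_len(n - L + 1L)) {
    mm <- sum(sj[i:(i + L - 1L)] != sp)
    if (mm > max_mm) next
    if (require_pam) {
      if (i < 5L) next
      pam <- intToUtf8(sj[(i - 4L):(i - 1L)], multiple = TRUE)
      if (!(all(pam[1:3] == "T") && pam[4] %in% c("A", "C", "G"))) next
    }
    out[[length(out) + 1L]] <- c(start1 = as.numeric(i), mm = as.numeric(mm))
  }
  out
}

# Deterministic random DNA for tests.
rand_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Build a plant_genotype from bare per-gene specs:
# list(gene = list(class=, keys=, reads=, wt_reads=)).
fixture_plant <- function(id, spec) {
  gene_calls <- lapply(names(spec), function(g) {
    s <- spec[[g]]
    calls <- tibble::tibble(key = s$keys %||% character(0),
                            reads = s$reads %||% integer(0))
    gene_zygosity_from_counts(
      gene_id = g, class = s$class, calls = calls,
      wt_reads = s$wt_reads %||% 0L,
      n_retained = sum(calls$reads) + (s$wt_reads %||% 0L)
    )
  })
  names(gene_calls) <- names(spec)
  call_multiplex(gene_calls, names(spec), plant_id = id)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
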