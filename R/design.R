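# crRNA design: TTTV PAM scanning, homolog dual-targeting with PAM-distal
# mismatches, off-target enumeration, tandem array assembly across two U6
# promoters, and Golden Gate oligo rendering with in-silico ligation.

#' Default sequence parts for Cas12a crRNA cassettes
#'
#' Editable parts list: the canonical LbCas12a direct repeat, a tRNA(Gly)
#' 5' leader and an HDV ribozyme 3' tag (the flanking elements that release
#' precise crRNA ends from a Pol III transcript), and the two U6 promoter
#' identifiers used to drive split arrays. Exact plasmid parts vary between
#' vector systems, so every element can be overridden.
#'
#' @return Named list: `direct_repeat`, `tgly`, `hdv`, `promoters`.
#' @export
default_parts <- function() {
  list(
    direct_repeat = "AATTTCTACTAAGTGTAGAT",
    tgly = paste0("AACAAAGCACCAGTGGTCTAGTGGTAGAATAGTACCCTGCCACGGTACAGAC",
                  "CCGGGTTCGATTCCCGGCTGGTGCA"),
    hdv = paste0("GGCCGGCATGGTCCCAGCCTCCTCGCTGGCGCCGGCTGGGCAACATTCCGAG",
                 "GGGACCGTCCCCTCGGTAATGGCGAATGGGAC"),
    promoters = c("U6-26", "U6-29")
  )
}

#' Scan a sequence for Cas12a protospacer sites
#'
#' Finds every occurrence of the PAM pattern (default TTTV) with room for an
#' `spacer_len`-nt spacer immediately 3' of it on the protospacer strand, on
#' one or both strands. Coordinates are 0-based half-open on the input plus
#' strand.
#'
#' @param seq DNA sequence (single string, ACGT).
#' @param pam_pattern IUPAC PAM pattern (default `"TTTV"`).
#' @param spacer_len Spacer length (default 23).
#' @param both_strands Scan the minus strand too (default `TRUE`).
#' @return Tibble sorted by plus-strand spacer start then strand: `strand`,
#'   `pam_start` (protospacer-strand 0-based PAM offset), `pam_seq`,
#'   `spacer_seq` (protospacer strand), `spacer_start`, `spacer_end`
#'   (plus-strand 0-based half-open).
#' @export
scan_pam_sites <- function(seq, pam_pattern = "TTTV", spacer_len = 23L,
                           both_strands = TRUE) {
  seq <- toupper(seq)
  assert_acgt(stats::setNames(seq, "input"), "scan subject")
  pam_len <- nchar(pam_pattern)
  n <- nchar(seq)
  scan_one <- function(s, strand) {
    chars <- strsplit(s, "")[[1]]
    hits <- iupac_hits(chars, pam_pattern)
    hits <- hits[hits + pam_len - 1L + spacer_len <= n]
    if (!length(hits)) return(NULL)
    off <- hits - 1L  # 0-based PAM start on this strand
    ps <- off + pam_len
    pe <- ps + spacer_len
    spacer_start <- if (strand == "+") ps else n - pe
    spacer_end <- if (strand == "+") pe else n - ps
    tibble::tibble(
      strand = strand,
      pam_start = off,
      pam_seq = substr(rep(s, length(off)), off + 1L, off + pam_len),
      spacer_seq = substr(rep(s, length(off)), ps + 1L, pe),
      spacer_start = spacer_start,
      spacer_end = spacer_end
    )
  }
  out <- scan_one(seq, "+")
  if (both_strands) out <- rbind(out, scan_one(revcomp(seq), "-"))
  if (is.null(out)) {
    out <- tibble::tibble(strand = character(0), pam_start = integer(0),
                          pam_seq = character(0), spacer_seq = character(0),
                          spacer_start = integer(0), spacer_end = integer(0))
  }
  out[order(out$spacer_start, out$strand), ]
}

# 1-based spacer positions (1 = PAM-proximal) where two spacers differ.
spacer_mismatch_positions <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  which(ca != cb)
}

#' Find dual-target spacer pairs across two homologous genes
#'
#' A single crRNA can cut two homologs when its spacer matches one gene
#' perfectly and differs from the other only at PAM-distal positions, which
#' Cas12a tolerates. For every PAM site in the anchor gene, reports the PAM
#' sites in the partner gene whose spacer differs at no more than `max_mm`
#' positions, all of them at spacer position `distal_zone_start` or beyond
#' (position 1 = PAM-proximal base).
#'
#' @param seq_a,seq_b The two gene sequences.
#' @param max_mm Maximum tolerated mismatches (default 2).
#' @param distal_zone_start First spacer position counted as PAM-distal
#'   (default 19 of a 23-nt spacer, i.e. the final 5 nt).
#' @param pam_pattern,spacer_len,both_strands Passed to [scan_pam_sites()].
#' @param symmetric Also anchor on `seq_b` (default `FALSE`); anchored gene
#'   recorded in the `anchor` column.
#' @return Tibble: `anchor`, site coordinates in both genes
#'   (`*_a` = anchor gene, `*_b` = partner), `spacer_a`, `spacer_b`,
#'   `n_mismatch`, `mismatch_positions` (list column).
#' @export
find_dual_targets <- function(seq_a, seq_b, max_mm = 2L,
                              distal_zone_start = 19L,
                              pam_pattern = "TTTV", spacer_len = 23L,
                              both_strands = TRUE, symmetric = FALSE) {
  if (distal_zone_start > spacer_len) {
    stop("distal_zone_start exceeds spacer length", call. = FALSE)
  }
  pair_up <- function(sa, sb, anchor) {
    rows <- list()
    for (i in seq_len(nrow(sa))) {
      for (j in seq_len(nrow(sb))) {
        mm <- spacer_mismatch_positions(sa$spacer_seq[i], sb$spacer_seq[j])
        if (length(mm) <= max_mm && all(mm >= distal_zone_start)) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            anchor = anchor,
            strand_a = sa$strand[i], spacer_start_a = sa$spacer_start[i],
            strand_b = sb$strand[j], spacer_start_b = sb$spacer_start[j],
            spacer_a = sa$spacer_seq[i], spacer_b = sb$spacer_seq[j],
            n_mismatch = length(mm),
            mismatch_positions = list(as.integer(mm))
          )
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  sites_a <- scan_pam_sites(seq_a, pam_pattern, spacer_len, both_strands)
  sites_b <- scan_pam_sites(seq_b, pam_pattern, spacer_len, both_strands)
  out <- pair_up(sites_a, sites_b, "a")
  if (symmetric) out <- rbind(out, pair_up(sites_b, sites_a, "b"))
  if (is.null(out)) {
    out <- tibble::tibble(anchor = character(0), strand_a = character(0),
                          spacer_start_a = integer(0), strand_b = character(0),
                          spacer_start_b = integer(0), spacer_a = character(0),
                          spacer_b = character(0), n_mismatch = integer(0),
                          mismatch_positions = list())
  }
  out
}

#' Enumerate putative off-target sites by Hamming distance
#'
#' Slides the spacer over every window of each subject sequence (both
#' strands) and reports windows within `max_mm` mismatches, optionally
#' requiring a canonical PAM immediately 5' of the window on the matching
#' strand. Bulged (indel) off-targets are not considered.
#'
#' @param spacer Spacer sequence (protospacer strand).
#' @param subjects Named character vector of subject sequences.
#' @param max_mm Maximum mismatches (default 3).
#' @param require_pam Require the PAM at the off-target locus (default
#'   `TRUE`).
#' @param pam_pattern IUPAC PAM (default `"TTTV"`).
#' @return Tibble sorted by mismatch count then subject/coordinate:
#'   `subject_id`, `position` (0-based plus-strand start of the protospacer
#'   window), `strand`, `mismatches`, `site_seq`.
#' @export
enumerate_offtargets <- function(spacer, subjects, max_mm = 3L,
                                 require_pam = TRUE, pam_pattern = "TTTV") {
  spacer <- toupper(spacer)
  L <- nchar(spacer)
  pam_len <- nchar(pam_pattern)
  spc <- strsplit(spacer, "")[[1]]
  if (is.null(names(subjects))) {
    names(subjects) <- sprintf("subject%d", seq_along(subjects))
  }
  rows <- list()
  for (id in names(subjects)) {
    s <- toupper(subjects[[id]])
    n <- nchar(s)
    if (n < L + pam_len) {
      warning(sprintf("subject '%s' shorter than spacer+PAM; skipped", id))
      next
    }
    for (strand in c("+", "-")) {
      sc <- strsplit(if (strand == "+") s else revcomp(s), "")[[1]]
      starts <- seq_len(n - L + 1L)  # 1-based window starts on this strand
      mm <- integer(length(starts))
      for (j in seq_len(L)) {
        mm <- mm + (sc[starts + j - 1L] != spc[j])
      }
      keep <- mm <= max_mm
      if (require_pam) {
        pam_ok <- logical(length(starts))
        ok_idx <- iupac_hits(sc, pam_pattern)          # PAM starts (1-based)
        want <- starts - pam_len                        # PAM must sit here
        pam_ok <- want %in% ok_idx
        keep <- keep & pam_ok
      }
      idx <- which(keep)
      if (!length(idx)) next
      # plus-strand 0-based start of the window
      pos <- if (strand == "+") starts[idx] - 1L else n - (starts[idx] - 1L) - L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = id, position = as.integer(pos), strand = strand,
        mismatches = as.integer(mm[idx]),
        site_seq = substr(rep(paste(sc, collapse = ""), length(idx)),
                          starts[idx], starts[idx] + L - 1L)
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(subject_id = character(0), position = integer(0),
                          strand = character(0), mismatches = integer(0),
                          site_seq = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$mismatches, out$subject_id, out$position, out$strand), ]
}

#' Build a crRNA array under one promoter
#'
#' @param promoter_id Promoter label (e.g. `"U6-26"`).
#' @param spacers Character vector of spacer sequences (ACGT only).
#' @param parts Sequence parts from [default_parts()].
#' @return A `"crrna_array"` list: `promoter_id`, `spacers`, `parts`.
#' @export
crrna_array <- function(promoter_id, spacers, parts = default_parts()) {
  assert_acgt(stats::setNames(spacers, spacers), "spacer")
  if (length(spacers) < 1) stop("array needs at least one spacer", call. = FALSE)
  structure(list(promoter_id = promoter_id, spacers = spacers, parts = parts),
            class = "crrna_array")
}

#' Split six spacers across the two U6 promoters
#'
#' The six-crRNA layout drives two tandem arrays of three crRNAs each from
#' separate U6 promoters. Input order is preserved: the first three spacers
#' go to the first promoter, the last three to the second. Any permutation
#' of spacers is a valid design (array position has negligible effect on
#' editing efficiency).
#'
#' @param spacers Exactly six spacer sequences.
#' @param parts Sequence parts ([default_parts()]).
#' @return Named list of two `"crrna_array"` objects keyed by promoter.
#' @export
split_six <- function(spacers, parts = default_parts()) {
  if (length(spacers) != 6) {
    stop(sprintf("split_six needs exactly 6 spacers, got %d", length(spacers)),
         call. = FALSE)
  }
  proms <- parts$promoters
  stats::setNames(list(
    crrna_array(proms[1], spacers[1:3], parts),
    crrna_array(proms[2], spacers[4:6], parts)
  ), proms)
}

# Core of an array: seamlessly fused DR+spacer units.
array_core <- function(array) {
  dr <- array$parts$direct_repeat
  paste0(paste0(dr, array$spacers, collapse = ""), collapse = "")
}

#' Render a crRNA array to its cassette sequence
#'
#' `tRNA(Gly) + (DR + spacer)*n + HDV`. Refuses to assemble if the direct
#' repeat occurs inside any spacer, which would make the cassette ambiguous
#' to parse (and to process in vivo).
#'
#' @param array A `"crrna_array"`.
#' @return Cassette DNA string.
#' @export
assemble_array <- function(array) {
  stopifnot(inherits(array, "crrna_array"))
  dr <- array$parts$direct_repeat
  hit <- vapply(array$spacers, function(s) grepl(dr, s, fixed = TRUE),
                logical(1))
  if (any(hit)) {
    stop(sprintf("spacer %d contains the direct repeat; the array would be ambiguous",
                 which(hit)[1]), call. = FALSE)
  }
  paste0(array$parts$tgly, array_core(array), array$parts$hdv)
}

#' Parse a crRNA cassette back into spacers
#'
#' Splits the cassette (or its bare DR+spacer core) on exact occurrences of
#' the direct repeat; the inverse of [assemble_array()].
#'
#' @param seq Cassette or core sequence.
#' @param parts Sequence parts; `direct_repeat` is the separator, and the
#'   tRNA(Gly)/HDV flanks are stripped when present.
#' @return Character vector of spacers.
#' @export
parse_array <- function(seq, parts = default_parts()) {
  if (startsWith(seq, parts$tgly)) seq <- substr(seq, nchar(parts$tgly) + 1L,
                                                 nchar(seq))
  if (endsWith(seq, parts$hdv)) seq <- substr(seq, 1L,
                                              nchar(seq) - nchar(parts$hdv))
  dr <- parts$direct_repeat
  if (!startsWith(seq, dr)) {
    stop("array core does not start with the direct repeat", call. = FALSE)
  }
  spacers <- strsplit(substr(seq, nchar(dr) + 1L, nchar(seq)), dr,
                      fixed = TRUE)[[1]]
  if (any(spacers == "")) stop("empty spacer in array", call. = FALSE)
  spacers
}

#' Design annealed oligo pairs for Golden Gate cloning
#'
#' Renders each insert as a top/bottom oligo pair whose annealed duplex
#' carries 4-nt 5' overhangs: terminal overhangs come from
#' `overhang_config`, junction overhangs inside a multi-insert assembly are
#' taken from the insert sequence itself at the fragment boundary, so
#' ligation is seamless. All overhangs in one assembly must be distinct, or
#' the one-pot ligation order would be ambiguous; when a boundary 4-mer
#' duplicates an existing overhang the cut slides up to 8 nt into the core
#' to find a unique one, and the design is refused only if no placement
#' works.
#'
#' @param cores Character vector of insert core sequences in assembly order
#'   (a single spacer, or DR+spacer units of an array).
#' @param overhang_config List with 4-nt `left` and `right` terminal
#'   overhangs. Defaults: `left` = last 4 nt of the canonical direct repeat
#'   (the upstream vector DR supplies it), `right = "CTTG"`. Override to
#'   match the destination vector.
#' @param enzyme Type IIS context, `"BsaI"` or `"BbsI"` (annotation only;
#'   oligo inserts replace the excised stuffer).
#' @return List of `"oligo_pair"` lists: `top`, `bottom`, `overhang_5`,
#'   `overhang_3`, `enzyme`.
#' @export
design_oligos <- function(cores, overhang_config = NULL,
                          enzyme = c("BsaI", "BbsI")) {
  enzyme <- match.arg(enzyme)
  cfg <- overhang_config %||%
    list(left = substr(default_parts()$direct_repeat, 17, 20), right = "CTTG")
  stopifnot(nchar(cfg$left) == 4, nchar(cfg$right) == 4)
  if (cfg$left == cfg$right) {
    stop(sprintf("overhang collision ('%s'): Golden Gate order would be ambiguous",
                 cfg$left), call. = FALSE)
  }
  full <- paste0(cfg$left, paste(cores, collapse = ""), cfg$right)
  bounds <- cumsum(nchar(cores)) + 4L  # core ends within `full`
  # place each junction cut at the core boundary, sliding a few nt into the
  # core when the 4-nt overhang it would produce duplicates one already in
  # the assembly (a duplicated overhang makes the one-pot ligation order
  # ambiguous, so the cut site is moved instead)
  taken <- c(cfg$left, cfg$right)
  cuts <- integer(0)
  for (b in utils::head(bounds, -1)) {
    placed <- FALSE
    for (delta in 0:8) {
      oh <- substr(full, b - delta - 3L, b - delta)
      if (!oh %in% taken) {
        taken <- c(taken, oh)
        cuts <- c(cuts, b - delta)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("overhang collision ('%s'): Golden Gate order would be ambiguous",
                   substr(full, b - 3L, b)), call. = FALSE)
    }
  }
  starts <- c(1L, cuts - 3L)
  ends_frag <- c(cuts, nchar(full))
  lapply(seq_along(cores), function(i) {
    sense <- substr(full, starts[i], ends_frag[i])
    structure(list(
      top = substr(sense, 1L, nchar(sense) - 4L),
      bottom = revcomp(substr(sense, 5L, nchar(sense))),
      overhang_5 = substr(sense, 1L, 4L),
      overhang_3 = substr(sense, nchar(sense) - 3L, nchar(sense)),
      enzyme = enzyme
    ), class = "oligo_pair")
  })
}

#' Simulate a Golden Gate ligation of annealed oligo pairs
#'
#' Re-anneals each pair into a duplex, chains fragments by matching 5'/3'
#' overhangs starting from the fragment whose 5' overhang no other fragment
#' terminates in, and returns the ligated sense strand with the terminal
#' vector overhangs stripped -- i.e. the insert core the assembly encodes.
#' Order of the input pairs does not matter.
#'
#' @param pairs List of `"oligo_pair"` objects from [design_oligos()].
#' @return Ligated core sequence.
#' @export
ligate_oligos <- function(pairs) {
  senses <- vapply(pairs, function(p) paste0(p$top, p$overhang_3), "")
  oh5 <- vapply(pairs, `[[`, "", "overhang_5")
  oh3 <- vapply(pairs, `[[`, "", "overhang_3")
  if (anyDuplicated(oh5) || anyDuplicated(oh3)) {
    stop("ambiguous ligation: duplicated overhangs", call. = FALSE)
  }
  start <- which(!oh5 %in% oh3)
  if (length(start) != 1) {
    stop("ligation does not form a single linear product", call. = FALSE)
  }
  ordered <- start
  while (length(ordered) < length(pairs)) {
    nxt <- which(oh5 == oh3[ordered[length(ordered)]])
    if (length(nxt) != 1) stop("broken overhang chain", call. = FALSE)
    ordered <- c(ordered, nxt)
  }
  product <- senses[ordered[1]]
  for (i in ordered[-1]) {
    product <- paste0(product, substr(senses[i], 5L, nchar(senses[i])))
  }
  # strip terminal vector overhangs
  substr(product, 5L, nchar(product) - 4L)
}

#' Two-level Golden Gate design for a six-crRNA construct
#'
#' Mirrors the standard two-step route: each spacer is first cloned as an
#' annealed oligo pair into a spacer-cloning vector (BbsI level), and the
#' resulting DR+spacer units are then assembled into the two three-unit
#' arrays of the binary vector (BsaI level), one per U6 promoter.
#'
#' @param spacers Exactly six spacers (order defines array layout via
#'   [split_six()]).
#' @param parts Sequence parts ([default_parts()]).
#' @param overhang_config Terminal overhangs per level (see
#'   [design_oligos()]).
#' @return List with `level1` (six BbsI spacer oligo pairs) and `level2`
#'   (named list per promoter of BsaI unit oligo pairs).
#' @export
design_six_crrna_oligos <- function(spacers, parts = default_parts(),
                                    overhang_config = NULL) {
  arrays <- split_six(spacers, parts)
  level1 <- lapply(spacers, function(s)
    design_oligos(s, overhang_config, enzyme = "BbsI")[[1]])
  level2 <- lapply(arrays, function(a)
    design_oligos(paste0(a$parts$direct_repeat, a$spacers),
                  overhang_config, enzyme = "BsaI"))
  list(level1 = level1, level2 = level2)
}
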