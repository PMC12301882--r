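# Semi-global alignment of amplicon reads against their reference and
# extraction of mutation events in reference coordinates.
#
# The aligner is Biostrings::pairwiseAlignment with type = "global-local":
# the read aligns end-to-end while reference end-gaps are free. Event
# extraction uses the range accessors (indel(), mismatchTable()) rather than
# the gapped alignment strings, which are far too slow at population scale.
# Accessor coordinate conventions (verified empirically, and guarded by the
# reconstruction tests): gaps in the *pattern* (deletions from the read) are
# reported in read coordinates; gaps in the *subject* (insertions) and
# mismatches are reported in reference coordinates.

#' Alignment scoring and filtering parameters
#'
#' @param match,mismatch Per-base substitution scores (default +2/-2).
#' @param gap_open,gap_extend Gap penalties as negative scores (default
#'   -6/-1); a k-nt gap costs `|gap_open| + k * |gap_extend|`.
#' @param min_read_len Reads shorter than this are rejected before alignment
#'   (default 30).
#' @param max_read_mismatch_frac Reads whose edited bases (mismatches plus
#'   gap columns) exceed this fraction of read length are rejected as noise
#'   (default 0.2).
#' @return An `"alignment_params"` list.
#' @export
alignment_params <- function(match = 2L, mismatch = -2L, gap_open = -6L,
                             gap_extend = -1L, min_read_len = 30L,
                             max_read_mismatch_frac = 0.2) {
  stopifnot(gap_open <= gap_extend, gap_extend <= 0, match >= 0,
            mismatch <= 0, max_read_mismatch_frac > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_read_len = as.integer(min_read_len),
                 max_read_mismatch_frac = max_read_mismatch_frac),
            class = "alignment_params")
}

# Cache of the substitution matrix keyed by match/mismatch.
.submat_cache <- new.env(parent = emptyenv())
submat_for <- function(params) {
  key <- paste(params$match, params$mismatch)
  if (is.null(.submat_cache[[key]])) {
    .submat_cache[[key]] <- Biostrings::nucleotideSubstitutionMatrix(
      match = params$match, mismatch = params$mismatch)
  }
  .submat_cache[[key]]
}

#' Align reads to an amplicon and extract mutation events
#'
#' Aligns each (unique) read semi-globally to the amplicon of `site` and
#' returns, per read, the ordered list of mutation events in 0-based
#' reference coordinates. Adjacent mismatched bases are merged into one
#' substitution run; gap runs become single insertion/deletion events.
#'
#' Exact reference matches and same-length reads within Hamming distance 3
#' bypass the dynamic program (at these scoring parameters a substitution-only
#' explanation is provably optimal below 4 mismatches, since one
#' insertion-deletion pair costs more than 3 substitutions).
#'
#' @param reads Character vector of read sequences.
#' @param site A [target_site()].
#' @param params [alignment_params()].
#' @return A list with one element per read: either an event data.frame
#'   (zero rows = wild-type read) or `NULL` for rejected reads; the
#'   `"rejected"` attribute carries a character vector of rejection reasons
#'   (`NA` for retained reads).
#' @export
align_reads <- function(reads, site, params = alignment_params()) {
  stopifnot(inherits(site, "target_site"))
  ref <- site$amplicon_seq
  n_reads <- length(reads)
  reads <- toupper(reads)
  out <- vector("list", n_reads)
  reason <- rep(NA_character_, n_reads)

  short <- nchar(reads) < params$min_read_len
  reason[short] <- "read_too_short"

  todo <- which(!short)
  if (!length(todo)) return(structure(out, rejected = reason))

  # work on unique sequences only
  uniq <- unique(reads[todo])
  map <- match(reads[todo], uniq)
  uevents <- vector("list", length(uniq))
  ureason <- rep(NA_character_, length(uniq))

  ref_chars <- strsplit(ref, "")[[1]]
  need_dp <- logical(length(uniq))
  for (i in seq_along(uniq)) {
    u <- uniq[i]
    if (u == ref) {
      uevents[[i]] <- empty_events()
    } else if (nchar(u) == nchar(ref)) {
      uc <- strsplit(u, "")[[1]]
      mm <- which(uc != ref_chars)
      if (length(mm) <= 3L) {
        uevents[[i]] <- runs_to_subs(mm, uc)
      } else need_dp[i] <- TRUE
    } else need_dp[i] <- TRUE
  }

  if (any(need_dp)) {
    dp <- align_events_dp(uniq[need_dp], ref, params)
    uevents[need_dp] <- dp$events
    ureason[need_dp] <- dp$reason
  }

  # edit-fraction rejection (also applies to the fast path)
  for (i in seq_along(uniq)) {
    ev <- uevents[[i]]
    if (is.null(ev)) next
    edits <- if (nrow(ev)) sum(ev$len) else 0L
    if (edits > params$max_read_mismatch_frac * nchar(uniq[i])) {
      uevents[i] <- list(NULL)
      ureason[i] <- "excess_edits"
    }
  }

  out[todo] <- uevents[map]
  reason[todo] <- ureason[map]
  structure(out, rejected = reason)
}

# Merge sorted mismatch positions (1-based) into substitution run events.
runs_to_subs <- function(mm_pos, read_chars) {
  if (!length(mm_pos)) return(empty_events())
  grp <- cumsum(c(1L, diff(mm_pos) != 1L))
  lens <- tabulate(grp)
  fast_events(rep.int("substitution", length(lens)),
              mm_pos[!duplicated(grp)] - 1L, lens,
              unname(vapply(split(read_chars[mm_pos], grp), paste, "",
                            collapse = "")))
}

# Full dynamic-programming path through Biostrings for a set of unique reads.
align_events_dp <- function(useqs, ref, params) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(useqs), Biostrings::DNAString(ref),
    type = "global-local",
    substitutionMatrix = submat_for(params),
    gapOpening = abs(params$gap_open), gapExtension = abs(params$gap_extend))

  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  # deletions = gaps in pattern (read coords); insertions = gaps in subject
  # (reference coords). Flatten both compressed range lists once: per-element
  # S4 extraction is two orders of magnitude slower than unlist + split.
  del_l <- Biostrings::indel(pat)
  ins_l <- Biostrings::indel(sub)
  sub_start <- BiocGenerics::start(sub)
  split_flat <- function(rl) {
    ns <- S4Vectors::elementNROWS(rl)
    flat <- BiocGenerics::unlist(rl)
    grp <- factor(rep.int(seq_along(ns), ns), levels = seq_along(ns))
    list(start = split(BiocGenerics::start(flat), grp),
         width = split(BiocGenerics::width(flat), grp))
  }
  dels <- split_flat(del_l)
  inss <- split_flat(ins_l)

  ref_chars <- strsplit(ref, "")[[1]]
  events <- vector("list", length(useqs))
  reason <- rep(NA_character_, length(useqs))
  for (i in seq_along(useqs)) {
    ev <- walk_alignment_events(
      read = useqs[i], ref_chars = ref_chars,
      del_start = dels$start[[i]], del_w = dels$width[[i]],
      ins_start = inss$start[[i]], ins_w = inss$width[[i]],
      ref_offset = sub_start[i] - 1L
    )
    events[[i]] <- left_normalize_indels(ev, ref_chars)
  }
  list(events = events, reason = reason)
}

# Shift each indel to its leftmost equivalent placement (the standard
# normalization for ambiguous gap positions in repeat context), without
# crossing the previous event. A deletion of ref[p..p+l) may move to p-1
# when ref[p-1] == ref[p+l-1]; an insertion may move left when its last
# inserted base equals the reference base it would hop over (rotating the
# inserted sequence accordingly).
left_normalize_indels <- function(ev, ref_chars) {
  kind <- ev$kind; pos <- ev$pos; len <- ev$len; sq <- ev$seq
  if (!length(kind)) return(ev)
  ord <- order(pos, kind)
  kind <- kind[ord]; pos <- pos[ord]; len <- len[ord]; sq <- sq[ord]
  bound <- 0L
  for (i in seq_along(kind)) {
    p <- pos[i]
    l <- len[i]
    if (kind[i] == "deletion") {
      while (p > bound && ref_chars[p] == ref_chars[p + l]) p <- p - 1L
      pos[i] <- p
      bound <- p + l
    } else if (kind[i] == "insertion") {
      s <- sq[i]
      while (p > bound && ref_chars[p] == substr(s, l, l)) {
        s <- paste0(ref_chars[p], substr(s, 1L, l - 1L))
        p <- p - 1L
      }
      pos[i] <- p
      sq[i] <- s
      bound <- p
    } else {
      bound <- p + l
    }
  }
  ord <- order(pos, kind)
  fast_events(kind[ord], pos[ord], len[ord], sq[ord])
}

# Convert Biostrings gap ranges into insertion/deletion events in reference
# coordinates by walking both coordinate systems in alignment order, and
# collect mismatch positions by comparing the matched blocks between gaps.
walk_alignment_events <- function(read, ref_chars, del_start, del_w,
                                  ins_start, ins_w, ref_offset) {
  read_chars <- strsplit(read, "")[[1]]
  n_ev <- length(del_start) + length(ins_start)
  kind <- character(n_ev); pos <- integer(n_ev)
  len <- integer(n_ev); sq <- character(n_ev)
  mm_pos <- integer(0)      # 0-based reference positions of mismatches
  k <- 0L; di <- 1L; ii <- 1L
  cur_read <- 0L            # read chars consumed
  cur_ref <- ref_offset     # reference chars consumed (0-based)
  compare_block <- function(m) {
    if (m > 0L) {
      rc <- read_chars[cur_read + seq_len(m)]
      fc <- ref_chars[cur_ref + seq_len(m)]
      hit <- which(rc != fc)
      if (length(hit)) mm_pos <<- c(mm_pos, cur_ref + hit - 1L)
    }
  }
  repeat {
    # deletion gap starts are in read coordinates; insertion gap starts are
    # relative to the aligned (clipped) subject region
    d_gap <- if (di <= length(del_start)) del_start[di] - 1L - cur_read else Inf
    i_gap <- if (ii <= length(ins_start))
      ins_start[ii] - 1L - (cur_ref - ref_offset) else Inf
    if (is.infinite(d_gap) && is.infinite(i_gap)) break
    k <- k + 1L
    if (d_gap <= i_gap) {
      compare_block(d_gap)
      cur_read <- cur_read + d_gap
      cur_ref <- cur_ref + d_gap
      kind[k] <- "deletion"; pos[k] <- cur_ref; len[k] <- del_w[di]; sq[k] <- ""
      cur_ref <- cur_ref + del_w[di]
      di <- di + 1L
    } else {
      compare_block(i_gap)
      cur_read <- cur_read + i_gap
      cur_ref <- cur_ref + i_gap
      kind[k] <- "insertion"; pos[k] <- cur_ref; len[k] <- ins_w[ii]
      sq[k] <- substr(read, cur_read + 1L, cur_read + ins_w[ii])
      cur_read <- cur_read + ins_w[ii]
      ii <- ii + 1L
    }
  }
  compare_block(length(read_chars) - cur_read)
  indels <- fast_events(kind, pos, len, sq)
  if (!length(mm_pos)) return(indels)
  # merge adjacent mismatches into substitution runs
  mm_read <- read_ref_char_at(mm_pos, indels, ref_offset, read_chars)
  grp <- cumsum(c(1L, diff(mm_pos) != 1L))
  slen <- tabulate(grp)
  fast_events(
    c(kind, rep.int("substitution", length(slen))),
    c(pos, mm_pos[!duplicated(grp)]),
    c(len, slen),
    c(sq, unname(vapply(split(mm_read, grp), paste, "", collapse = "")))
  )
}

# Read characters aligned to given 0-based reference positions, given the
# indel events between the two coordinate systems.
read_ref_char_at <- function(ref_pos, indels, ref_offset, read_chars) {
  shift <- rep.int(-ref_offset, length(ref_pos))
  if (nrow(indels)) {
    for (j in seq_len(nrow(indels))) {
      if (indels$kind[j] == "insertion") {
        shift <- shift + ifelse(ref_pos >= indels$pos[j], indels$len[j], 0L)
      } else if (indels$kind[j] == "deletion") {
        shift <- shift - ifelse(ref_pos >= indels$pos[j] + indels$len[j],
                                indels$len[j], 0L)
      }
    }
  }
  read_chars[ref_pos + shift + 1L]
}

#' Align a single read
#'
#' Convenience wrapper around [align_reads()] for one read.
#'
#' @inheritParams align_reads
#' @param read Single read sequence.
#' @return Event data.frame, or `NULL` with attribute `"reason"` if the read
#'   was rejected.
#' @export
align_read <- function(read, site, params = alignment_params()) {
  res <- align_reads(read, site, params)
  ev <- res[[1]]
  if (is.null(ev)) {
    return(structure(list(reason = attr(res, "rejected")[1]),
                     class = "read_rejection"))
  }
  ev
}
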