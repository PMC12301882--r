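# Alleles: a collapsed set of mutation events with a canonical serialization.
#
# Events live in a data.frame with columns
#   kind: "insertion" | "deletion" | "substitution"
#   pos:  0-based position on the amplicon (for insertions, the reference
#         position the bases are inserted before)
#   len:  event length in nt (positive)
#   seq:  inserted/substituted bases ("" for deletions)
# Allele identity is the canonical serialization of the full event list, so
# two alleles are equal iff their event lists are identical.

# Fast data.frame constructor for the alignment hot path: no checking, no
# name mangling (columns are always well-formed atomic vectors here).
fast_events <- function(kind, pos, len, seq) {
  structure(list(kind = kind, pos = pos, len = len, seq = seq),
            class = "data.frame", row.names = seq_along(kind))
}

empty_events <- function() {
  fast_events(character(0), integer(0), integer(0), character(0))
}

mutation_event <- function(kind, pos, len, seq = "") {
  kind <- match.arg(kind, c("insertion", "deletion", "substitution"))
  stopifnot(len >= 1, pos >= 0)
  if (kind != "deletion" && nchar(seq) != len) {
    stop("inserted/substituted sequence length must equal event length",
         call. = FALSE)
  }
  data.frame(kind = kind, pos = as.integer(pos), len = as.integer(len),
             seq = seq, stringsAsFactors = FALSE)
}

#' Serialize an event list into a canonical allele key
#'
#' Keys look like `"D:54:12"` (deletion of 12 nt at 0-based position 54),
#' `"I:60:3:ACG"` (insertion) or `"S:70:2:AT"` (substitution run), joined with
#' `"+"` in position order. The wild-type (empty) event list serializes to
#' `"WT"`.
#'
#' @param events Event data.frame (see package internals).
#' @return Single string key.
#' @export
allele_key <- function(events) {
  if (is.null(events) || nrow(events) == 0) return("WT")
  ord <- order(events$pos, events$kind)
  kind <- events$kind[ord]
  code <- c(insertion = "I", deletion = "D", substitution = "S")[kind]
  parts <- paste(code, events$pos[ord], events$len[ord], sep = ":")
  del <- kind == "deletion"
  parts[!del] <- paste(parts[!del], events$seq[ord][!del], sep = ":")
  paste(parts, collapse = "+")
}

#' Parse an allele key back into an event list
#'
#' @param key Allele key produced by [allele_key()].
#' @return Event data.frame; `"WT"` gives zero rows.
#' @export
parse_allele_key <- function(key) {
  stopifnot(length(key) == 1)
  if (key == "WT") return(empty_events())
  parts <- strsplit(key, "+", fixed = TRUE)[[1]]
  rows <- lapply(parts, function(p) {
    f <- strsplit(p, ":", fixed = TRUE)[[1]]
    kind <- c(I = "insertion", D = "deletion", S = "substitution")[[f[1]]]
    mutation_event(kind, as.integer(f[2]), as.integer(f[3]),
                   if (kind == "deletion") "" else f[4])
  })
  do.call(rbind, rows)
}

#' Net indel length of an event list
#'
#' Signed sum: insertion lengths minus deletion lengths. Substitutions do not
#' change length.
#'
#' @param events Event data.frame or allele key string.
#' @return Integer net indel in nt.
#' @export
net_indel <- function(events) {
  if (is.character(events)) events <- parse_allele_key(events)
  if (nrow(events) == 0) return(0L)
  sum(events$len[events$kind == "insertion"]) -
    sum(events$len[events$kind == "deletion"])
}

#' Classify the reading-frame consequence of an allele
#'
#' A mutant allele whose net indel length is a multiple of 3 keeps the
#' reading frame and may retain partial protein function; any other net
#' length shifts the frame and is a loss-of-function candidate.
#'
#' @param events Event data.frame or allele key string; `"WT"`/empty means no
#'   mutation.
#' @return One of `"wt"`, `"in-frame-3x-candidate"`,
#'   `"frameshift-LOF-candidate"`.
#' @export
annotate_frame <- function(events) {
  if (is.character(events) && length(events) == 1 && events == "WT") return("wt")
  if (is.character(events)) events <- parse_allele_key(events)
  if (nrow(events) == 0) return("wt")
  if (net_indel(events) %% 3L == 0L) "in-frame-3x-candidate"
  else "frameshift-LOF-candidate"
}

# TRUE if a mutant allele (by key) is an in-frame 3x candidate.
is_in_frame_3x <- function(key) {
  key != "WT" & vapply(key, function(k) net_indel(k) %% 3L == 0L, logical(1))
}

# Does the allele carry any indel (as opposed to substitutions only)?
has_indel <- function(events) {
  if (is.character(events)) events <- parse_allele_key(events)
  any(events$kind %in% c("insertion", "deletion"))
}

#' Apply an allele's events to a reference sequence
#'
#' Reconstructs the mutant sequence implied by an event list; used both by
#' the read simulator and as an internal consistency oracle for alignment
#' event extraction.
#'
#' @param ref Reference sequence (single string).
#' @param events Event data.frame or allele key.
#' @return Mutant sequence string.
#' @export
apply_events <- function(ref, events) {
  if (is.character(events)) events <- parse_allele_key(events)
  if (nrow(events) == 0) return(ref)
  chars <- strsplit(ref, "")[[1]]
  # apply right-to-left so earlier positions stay valid
  events <- events[order(events$pos, decreasing = TRUE), , drop = FALSE]
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$kind == "deletion") {
      stopifnot(e$pos + e$len <= length(chars))
      chars <- chars[-((e$pos + 1L):(e$pos + e$len))]
    } else if (e$kind == "insertion") {
      chars <- append(chars, strsplit(e$seq, "")[[1]], after = e$pos)
    } else {
      stopifnot(e$pos + e$len <= length(chars))
      chars[(e$pos + 1L):(e$pos + e$len)] <- strsplit(e$seq, "")[[1]]
    }
  }
  paste(chars, collapse = "")
}
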