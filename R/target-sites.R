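# Target sites: one gene's amplicon, spacer and PAM, with 0-based half-open
# coordinates on the amplicon plus strand. The PAM sits immediately 5' of the
# spacer on the protospacer strand (Cas12a convention).

#' Construct and validate a target site
#'
#' A target site ties a gene to its amplicon reference, the crRNA spacer, the
#' PAM, and the strand the protospacer lies on. All intervals are 0-based
#' half-open on the amplicon plus strand. `offset` is the 0-based start of the
#' PAM on the *protospacer strand* (the plus strand when `strand == "+"`, the
#' reverse complement of the amplicon when `strand == "-"`).
#'
#' The indel calling window (`cleavage_start`/`cleavage_end`) defaults to the
#' spacer interval widened by `window_pad` nucleotides on each side and clipped
#' to the amplicon: Cas12a cleaves PAM-distal of the spacer and repair
#' outcomes spread around the cut, so a fixed pad around the protospacer is
#' used rather than a cut-site point.
#'
#' @param gene_id,amplicon_id Identifiers (single strings).
#' @param amplicon_seq Amplicon reference sequence (plain ACGT; IUPAC
#'   ambiguity codes are rejected).
#' @param spacer_seq Spacer sequence on the protospacer strand.
#' @param pam_seq Observed PAM sequence (4 nt) on the protospacer strand.
#' @param strand `"+"` or `"-"`, protospacer strand relative to the amplicon.
#' @param offset 0-based PAM start on the protospacer strand.
#' @param pam_pattern IUPAC pattern the PAM must match (default `"TTTV"`).
#' @param window_pad Nucleotides added on each side of the spacer interval to
#'   form the cleavage window (default 10).
#' @return An object of class `"target_site"`: a list with the fields above
#'   plus `spacer_start`, `spacer_end`, `cleavage_start`, `cleavage_end`
#'   (0-based half-open, plus-strand coordinates) and `spacer_len`.
#' @export
target_site <- function(gene_id, amplicon_id, amplicon_seq, spacer_seq,
                        pam_seq, strand = "+", offset,
                        pam_pattern = "TTTV", window_pad = 10L) {
  stopifnot(length(gene_id) == 1, length(amplicon_seq) == 1,
            strand %in% c("+", "-"))
  amplicon_seq <- toupper(amplicon_seq)
  spacer_seq <- toupper(spacer_seq)
  pam_seq <- toupper(pam_seq)
  if (!is_dna_acgt(amplicon_seq)) {
    stop(sprintf("amplicon for gene '%s' contains non-ACGT characters %s",
                 gene_id, "(IUPAC ambiguity is allowed only in PAM patterns)"),
         call. = FALSE)
  }
  if (nchar(pam_seq) != 4L) {
    stop(sprintf("gene '%s': PAM must be 4 nt, got '%s'", gene_id, pam_seq),
         call. = FALSE)
  }
  if (!iupac_match(pam_pattern, pam_seq)) {
    stop(sprintf("gene '%s': PAM '%s' does not match pattern '%s'",
                 gene_id, pam_seq, pam_pattern), call. = FALSE)
  }
  L <- nchar(spacer_seq)
  n <- nchar(amplicon_seq)
  offset <- as.integer(offset)
  if (offset < 0L || offset + 4L + L > n) {
    stop(sprintf("gene '%s': PAM offset %d with %d-nt spacer exceeds %d-nt amplicon",
                 gene_id, offset, L, n), call. = FALSE)
  }
  proto <- if (strand == "+") amplicon_seq else revcomp(amplicon_seq)
  pam_obs <- substr(proto, offset + 1L, offset + 4L)
  spacer_obs <- substr(proto, offset + 5L, offset + 4L + L)
  if (pam_obs != pam_seq) {
    stop(sprintf("gene '%s': declared PAM '%s' not found at offset %d (found '%s')",
                 gene_id, pam_seq, offset, pam_obs), call. = FALSE)
  }
  if (spacer_obs != spacer_seq) {
    stop(sprintf("gene '%s': declared spacer does not match amplicon slice at offset %d",
                 gene_id, offset), call. = FALSE)
  }
  # protospacer-strand interval of the spacer, then map to plus strand
  ps <- offset + 4L
  pe <- offset + 4L + L
  if (strand == "+") {
    spacer_start <- ps; spacer_end <- pe
  } else {
    spacer_start <- n - pe; spacer_end <- n - ps
  }
  structure(list(
    gene_id = gene_id,
    amplicon_id = amplicon_id,
    amplicon_seq = amplicon_seq,
    pam_seq = pam_seq,
    spacer_seq = spacer_seq,
    strand = strand,
    offset = offset,
    spacer_len = L,
    spacer_start = spacer_start,
    spacer_end = spacer_end,
    cleavage_start = max(0L, spacer_start - as.integer(window_pad)),
    cleavage_end = min(n, spacer_end + as.integer(window_pad))
  ), class = "target_site")
}

#' @export
print.target_site <- function(x, ...) {
  cat(sprintf("<target_site> %s (%s) %s strand\n", x$gene_id, x$amplicon_id,
              x$strand))
  cat(sprintf("  PAM %s + %d-nt spacer; spacer [%d,%d), window [%d,%d) on %d-nt amplicon\n",
              x$pam_seq, x$spacer_len, x$spacer_start, x$spacer_end,
              x$cleavage_start, x$cleavage_end, nchar(x$amplicon_seq)))
  invisible(x)
}

#' Parse a target manifest (TSV or JSON)
#'
#' The manifest declares one targeted gene per row/record with fields
#' `gene_id`, `amplicon_id`, `spacer`, `pam`, `strand` and `offset` (0-based
#' PAM start on the protospacer strand). Amplicon sequences are supplied
#' separately as a named character vector or a FASTA file whose names match
#' `amplicon_id`. Every site is validated against its amplicon: the declared
#' PAM and spacer must be found verbatim at the declared coordinates.
#'
#' @param path Path to a `.tsv`/`.txt` (tab-separated, with header) or
#'   `.json` manifest.
#' @param amplicons Named character vector of amplicon sequences, or the path
#'   to a FASTA file.
#' @param pam_pattern,window_pad Passed to [target_site()].
#' @return A named list of [target_site()] objects (one per gene, manifest
#'   order preserved).
#' @export
parse_target_manifest <- function(path, amplicons, pam_pattern = "TTTV",
                                  window_pad = 10L) {
  if (is.character(amplicons) && length(amplicons) == 1 && file.exists(amplicons)) {
    fa <- read_sequences(amplicons, format = "fasta")
    amplicons <- stats::setNames(fa$seq, fa$id)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    rows <- utils::read.delim(path, stringsAsFactors = FALSE,
                              colClasses = "character")
  }
  required <- c("gene_id", "amplicon_id", "spacer", "pam", "strand", "offset")
  missing <- setdiff(required, names(rows))
  if (length(missing)) {
    stop("manifest is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rows$gene_id)) {
    stop("duplicate gene_id in manifest: ",
         paste(unique(rows$gene_id[duplicated(rows$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  sites <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    amp_id <- rows$amplicon_id[i]
    if (!amp_id %in% names(amplicons)) {
      stop(sprintf("manifest row %d (gene '%s'): amplicon '%s' not supplied",
                   i, rows$gene_id[i], amp_id), call. = FALSE)
    }
    sites[[i]] <- target_site(
      gene_id = rows$gene_id[i],
      amplicon_id = amp_id,
      amplicon_seq = amplicons[[amp_id]],
      spacer_seq = rows$spacer[i],
      pam_seq = rows$pam[i],
      strand = rows$strand[i],
      offset = as.integer(rows$offset[i]),
      pam_pattern = pam_pattern,
      window_pad = window_pad
    )
  }
  stats::setNames(sites, rows$gene_id)
}

#' Write a target manifest
#'
#' Inverse of [parse_target_manifest()]; writes the TSV form.
#'
#' @param sites List of [target_site()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_target_manifest <- function(sites, path) {
  df <- data.frame(
    gene_id = vapply(sites, `[[`, "", "gene_id"),
    amplicon_id = vapply(sites, `[[`, "", "amplicon_id"),
    spacer = vapply(sites, `[[`, "", "spacer_seq"),
    pam = vapply(sites, `[[`, "", "pam_seq"),
    strand = vapply(sites, `[[`, "", "strand"),
    offset = vapply(sites, function(s) s$offset, integer(1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
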