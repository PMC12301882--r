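# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code -> allowed bases, used for PAM patterns only (amplicon bodies
# must be plain ACGT).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse-complement a DNA string
#'
#' Thin character wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (ACGT + IUPAC codes).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Round half away from zero at a fixed number of decimals
#'
#' Published efficiency percentages use conventional half-up rounding
#' (45/61 -> 73.8, 124/138 -> 89.9), not the banker's rounding of [round()].
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

is_dna_acgt <- function(x) {
  grepl("^[ACGT]+$", x)
}

assert_acgt <- function(x, what = "sequence") {
  bad <- !vapply(x, is_dna_acgt, logical(1))
  if (any(bad)) {
    stop(sprintf("%s must contain only A/C/G/T (offending entry: %s)",
                 what, names(x)[bad][1] %||% which(bad)[1]), call. = FALSE)
  }
  invisible(x)
}

# Match an IUPAC pattern (e.g. "TTTV") against equal-length DNA strings.
iupac_match <- function(pattern, x) {
  pat <- strsplit(toupper(pattern), "")[[1]]
  if (!all(pat %in% names(IUPAC_SETS))) {
    stop("invalid IUPAC pattern: ", pattern, call. = FALSE)
  }
  ok <- rep(TRUE, length(x))
  chars <- strsplit(toupper(x), "")
  for (i in seq_along(x)) {
    xi <- chars[[i]]
    ok[i] <- length(xi) == length(pat) &&
      all(mapply(function(b, p) b %in% IUPAC_SETS[[p]], xi, pat))
  }
  ok
}

# Positions (1-based) in `chars` where an IUPAC pattern matches, vectorised
# over all windows of a character vector of single bases.
iupac_hits <- function(chars, pattern) {
  pat <- strsplit(toupper(pattern), "")[[1]]
  if (!all(pat %in% names(IUPAC_SETS))) {
    stop("invalid IUPAC pattern: ", pattern, call. = FALSE)
  }
  n <- length(chars)
  k <- length(pat)
  if (n < k) return(integer(0))
  idx <- seq_len(n - k + 1L)
  ok <- rep(TRUE, length(idx))
  for (j in seq_len(k)) {
    ok <- ok & chars[idx + j - 1L] %in% IUPAC_SETS[[pat[j]]]
  }
  idx[ok]
}
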