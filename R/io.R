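# Sequence and table I/O. FASTA/FASTQ go through Biostrings (gzip-aware);
# genotype tables are plain TSV that round-trip losslessly because allele
# evidence is stored as integer read counts, not floating fractions.

#' Read sequences from FASTA or FASTQ
#'
#' @param path File path (plain or gzip).
#' @param format `"fasta"` or `"fastq"`; guessed from the extension when
#'   omitted.
#' @return A tibble with columns `id`, `seq` (uppercase) and, for FASTQ,
#'   `qual`. Record order is preserved.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq" else "fasta"
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "fasta") {
    set <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) diagnose_parse_error(path, "fasta", conditionMessage(e))
    )
    tibble::tibble(
      id = sub("\\s.*$", "", names(set)),
      seq = unname(toupper(as.character(set)))
    )
  } else {
    # quality extraction is inside the tryCatch: a record whose quality line
    # length disagrees with its sequence corrupts the parsed qualities
    res <- tryCatch({
      set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                          with.qualities = TRUE)
      qual <- unname(as.character(S4Vectors::mcols(set)$qualities))
      bad <- which(nchar(qual) != BiocGenerics::width(set))
      if (length(bad)) {
        stop(sprintf("quality length differs from sequence length (record %d)",
                     bad[1]))
      }
      list(set = set, qual = qual)
    }, error = function(e) diagnose_parse_error(path, "fastq",
                                                conditionMessage(e)))
    tibble::tibble(
      id = sub("\\s.*$", "", names(res$set)),
      seq = unname(toupper(as.character(res$set))),
      qual = res$qual
    )
  }
}

# Re-scan a file line-wise to attach a record index to a parse failure.
diagnose_parse_error <- function(path, format, msg) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character(0))
  idx <- NA_integer_
  if (format == "fastq" && length(lines)) {
    nrec <- length(lines) %/% 4L
    for (i in seq_len(nrec + 1L)) {
      block <- lines[((i - 1L) * 4L + 1L):min(length(lines), i * 4L)]
      if (length(block) < 4L || !startsWith(block[1], "@") || block[3] != "+" &&
          !startsWith(block[3], "+")) { idx <- i; break }
      if (nchar(block[2]) != nchar(block[4])) { idx <- i; break }
    }
  } else if (format == "fasta" && length(lines) && !startsWith(lines[1], ">")) {
    idx <- 1L
  }
  stop(sprintf("malformed %s record%s in %s: %s", format,
               if (is.na(idx)) "" else paste0(" ", idx), path, msg),
       call. = FALSE)
}

#' Write a read pool to FASTQ
#'
#' Flat quality (Q40, `"I"`) is written for every base; the simulator does
#' not model quality scores.
#'
#' @param reads Character vector of read sequences.
#' @param path Output path; `.gz` suffix triggers compression.
#' @param ids Optional read names (defaults to `read1..readN`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  ids <- ids %||% sprintf("read%d", seq_along(reads))
  set <- Biostrings::DNAStringSet(reads)
  names(set) <- ids
  quals <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("I", n), character(1)))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write per-gene zygosity calls to a TSV genotype table
#'
#' One row per plant x gene. Allele evidence is serialized as
#' `key=read_count` pairs joined with `";"`, plus the retained wild-type read
#' count, so that [read_genotype_table()] reconstructs calls losslessly
#' (fractions are recomputed from the integer counts).
#'
#' @param plants List of plant genotypes as returned by [call_multiplex()]
#'   (or a list of per-gene call lists).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(plants, path) {
  rows <- list()
  for (p in plants) {
    for (g in p$gene_calls) {
      alleles <- if (nrow(g$calls)) {
        paste(sprintf("%s=%d", g$calls$key, g$calls$reads), collapse = ";")
      } else ""
      rows[[length(rows) + 1L]] <- data.frame(
        plant_id = p$plant_id, gene_id = g$gene_id,
        class = g$class, alleles = alleles,
        wt_reads = g$wt_reads, n_retained = g$n_retained,
        stringsAsFactors = FALSE
      )
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(plant_id = character(0), gene_id = character(0),
               class = character(0), alleles = character(0),
               wt_reads = integer(0), n_retained = integer(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype table written by [write_genotype_table()]
#'
#' @param path TSV path.
#' @param targeted_genes Optional character vector of genes each plant must
#'   have a call for (passed to [call_multiplex()]).
#' @return Named list of plant genotypes (see [call_multiplex()]).
#' @export
read_genotype_table <- function(path, targeted_genes = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(plant_id = "character",
                                         gene_id = "character",
                                         class = "character",
                                         alleles = "character"))
  if (nrow(df) == 0) return(list())
  plants <- list()
  for (pid in unique(df$plant_id)) {
    sub <- df[df$plant_id == pid, , drop = FALSE]
    gene_calls <- list()
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      if (is.na(r$alleles) || r$alleles == "") {
        calls <- tibble::tibble(key = character(0), reads = integer(0))
      } else {
        pairs <- strsplit(strsplit(r$alleles, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
        calls <- tibble::tibble(
          key = vapply(pairs, `[`, "", 1),
          reads = as.integer(vapply(pairs, `[`, "", 2))
        )
      }
      gene_calls[[r$gene_id]] <- gene_zygosity_from_counts(
        gene_id = r$gene_id, class = r$class, calls = calls,
        wt_reads = r$wt_reads, n_retained = r$n_retained
      )
    }
    genes <- targeted_genes %||% names(gene_calls)
    plants[[pid]] <- call_multiplex(gene_calls, genes, plant_id = pid)
  }
  plants
}
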