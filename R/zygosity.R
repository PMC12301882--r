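# Per-gene zygosity classification, cross-gene multiplex aggregation,
# germination typing and T1 -> T2 heritability.

ZYGOSITY_CLASSES <- c("WT", "Ho", "Bi", "He", "Chi")
GERMINATION_TYPES <- c("Type-0", "Type-1", "Type-2", "Type-3")

#' Classify zygosity from allele read fractions
#'
#' Threshold rules on retained-read fractions at one gene:
#' * **Ho** -- the top mutant allele carries at least `ho_bi_min` of reads;
#' * **Bi** -- at least two mutant alleles jointly carry `ho_bi_min`;
#' * **WT** -- no mutant allele remains;
#' * **He** -- the top mutant allele carries at least `he_min`;
#' * **Chi** -- anything else (no single mutation type dominates).
#'
#' Wild-type reads are never counted as a "type of mutation": the He
#' threshold applies to the top mutant allele only.
#'
#' @param mutant_fractions Numeric vector of mutant allele fractions (may be
#'   empty), over retained reads.
#' @param wt_fraction Wild-type read fraction.
#' @param thresholds [zygosity_thresholds()].
#' @return One of `"WT"`, `"Ho"`, `"Bi"`, `"He"`, `"Chi"`.
#' @export
classify_zygosity <- function(mutant_fractions, wt_fraction,
                              thresholds = zygosity_thresholds()) {
  total <- sum(mutant_fractions) + wt_fraction
  if (is.na(total) || abs(total - 1) > 1e-6) {
    stop(sprintf("allele fractions must sum to 1 (got %.8f)", total),
         call. = FALSE)
  }
  if (any(mutant_fractions < 0) || wt_fraction < 0) {
    stop("fractions must be non-negative", call. = FALSE)
  }
  n_mut <- length(mutant_fractions)
  top <- if (n_mut) max(mutant_fractions) else 0
  if (top >= thresholds$ho_bi_min) return("Ho")
  if (n_mut >= 2 && sum(mutant_fractions) >= thresholds$ho_bi_min) return("Bi")
  if (n_mut == 0) return("WT")
  if (top >= thresholds$he_min) return("He")
  "Chi"
}

#' Rebuild a gene-zygosity call from integer read counts
#'
#' Reconstructs the gene-call structure produced by [call_pool()] from
#' stored allele read counts (e.g. a genotype table row): fractions,
#' net indel lengths and frame flags are recomputed from the counts and
#' keys.
#'
#' @param gene_id Gene identifier.
#' @param class Stored zygosity class.
#' @param calls Tibble with `key` and `reads` columns (mutant alleles).
#' @param wt_reads Retained wild-type read count.
#' @param n_retained Total retained reads.
#' @param thresholds [zygosity_thresholds()] (reserved; class is taken as
#'   stored).
#' @return A gene-call list (see [call_pool()]).
#' @export
gene_zygosity_from_counts <- function(gene_id, class, calls, wt_reads,
                                      n_retained,
                                      thresholds = zygosity_thresholds()) {
  n_retained <- as.integer(n_retained)
  if (n_retained == 0) {
    res <- no_call_result()
    res$gene_id <- gene_id
    res$class <- "no_call"
    return(res)
  }
  calls <- calls[order(calls$reads, calls$key, decreasing = TRUE), ]
  calls$net_indel <- vapply(calls$key, net_indel, integer(1), USE.NAMES = FALSE)
  calls$in_frame <- is_in_frame_3x(calls$key)
  calls$fraction <- calls$reads / n_retained
  list(calls = calls, gene_id = gene_id, class = class,
       wt_reads = as.integer(wt_reads), wt_fraction = wt_reads / n_retained,
       n_retained = n_retained, no_call = FALSE)
}

#' Aggregate per-gene calls into a multiplex plant genotype
#'
#' A plant is a *sextuple (no-WT) mutant* when every targeted gene is Ho or
#' Bi; it is *full loss-of-function* when, additionally, none of its retained
#' mutant alleles is an in-frame (3x) indel. Full-LOF plants are predicted
#' never to germinate (Type-3). Plants with any no-call gene are marked
#' unresolved and excluded from sextuple logic.
#'
#' The Type-3 prediction is a labeled heuristic: rare mutants can germinate
#' without any in-frame allele, plausibly because some edits arose after
#' germination commitment, so the flag is a genotype-based expectation rather
#' than a phenotype fact.
#'
#' @param gene_calls Named list of gene-zygosity lists (from [call_pool()] or
#'   [gene_zygosity_from_counts()]).
#' @param targeted_genes Character vector of genes the construct targets.
#' @param plant_id Plant identifier.
#' @return A `"plant_genotype"` list: `plant_id`, `gene_calls`,
#'   `unresolved`, `is_sextuple_no_wt`, `is_full_lof`, `predicted_type3`.
#' @export
call_multiplex <- function(gene_calls, targeted_genes,
                           plant_id = "plant") {
  absent <- setdiff(targeted_genes, names(gene_calls))
  if (length(absent)) {
    stop(sprintf("plant '%s': no call record for targeted gene(s) %s",
                 plant_id, paste(absent, collapse = ", ")), call. = FALSE)
  }
  gc <- gene_calls[targeted_genes]
  classes <- vapply(gc, `[[`, "", "class")
  unresolved <- any(classes == "no_call")
  sextuple <- !unresolved && all(classes %in% c("Ho", "Bi"))
  any_in_frame <- any(vapply(gc, function(g) any(g$calls$in_frame), logical(1)))
  full_lof <- sextuple && !any_in_frame
  structure(list(
    plant_id = plant_id,
    gene_calls = gc,
    unresolved = unresolved,
    is_sextuple_no_wt = sextuple,
    is_full_lof = full_lof,
    predicted_type3 = full_lof
  ), class = "plant_genotype")
}

#' @export
print.plant_genotype <- function(x, ...) {
  cls <- vapply(x$gene_calls, `[[`, "", "class")
  cat(sprintf("<plant_genotype> %s: %s\n", x$plant_id,
              paste(sprintf("%s=%s", names(cls), cls), collapse = " ")))
  cat(sprintf("  sextuple(no WT)=%s full-LOF=%s predicted Type-3=%s%s\n",
              x$is_sextuple_no_wt, x$is_full_lof, x$predicted_type3,
              if (x$unresolved) " [unresolved]" else ""))
  invisible(x)
}

#' Classify a germination record into Type-0..Type-3
#'
#' * **Type-3** -- no germination (or no seedling) within the observation
#'   horizon (70 d by default);
#' * **Type-2** -- germinated but stunted (long roots, weak shoot);
#' * **Type-0** -- germinated within 7 d;
#' * **Type-1** -- delayed germination (day 14/21/28).
#'
#' @param germinated Logical.
#' @param day_of_germination Day the seed germinated (`NA` if it never did).
#' @param stunted Logical; stunted seedling morphology.
#' @return One of `"Type-0"` .. `"Type-3"`. Vectorised.
#' @export
classify_germination <- function(germinated, day_of_germination = NA,
                                 stunted = FALSE) {
  n <- max(length(germinated), length(day_of_germination), length(stunted))
  germinated <- rep_len(germinated, n)
  day <- rep_len(day_of_germination, n)
  stunted <- rep_len(stunted, n)
  if (any(germinated & is.na(day))) {
    stop("germinated record lacks day_of_germination", call. = FALSE)
  }
  ifelse(!germinated, "Type-3",
         ifelse(stunted, "Type-2",
                ifelse(day <= 7, "Type-0", "Type-1")))
}

#' Compare T1 and T2 genotypes for heritability
#'
#' Per gene: *heritable* when the T2 mutant allele set is a nonempty subset
#' of the T1 set (selfing of a biallelic plant may fix either allele);
#' *novel-allele* when T2 shows an allele absent from T1; *inconsistent* when
#' T2 is wild type at a gene where T1 was Ho/Bi. The overall verdict is
#' `TRUE` only when every gene is heritable.
#'
#' @param t1,t2 `"plant_genotype"` objects over the same targeted gene set.
#' @return A `"heritability_verdict"` list: `plant_pair`, `per_gene` (named
#'   character vector), `overall` (logical).
#' @export
compare_generations <- function(t1, t2) {
  g1 <- names(t1$gene_calls)
  g2 <- names(t2$gene_calls)
  if (!setequal(g1, g2)) {
    stop("T1 and T2 genotypes cover different gene sets", call. = FALSE)
  }
  per_gene <- vapply(g1, function(g) {
    a1 <- t1$gene_calls[[g]]$calls$key
    a2 <- t2$gene_calls[[g]]$calls$key
    if (length(setdiff(a2, a1)) > 0) return("novel-allele")
    if (length(a2) == 0 &&
        t1$gene_calls[[g]]$class %in% c("Ho", "Bi")) return("inconsistent")
    "heritable"
  }, character(1))
  structure(list(
    plant_pair = c(t1 = t1$plant_id, t2 = t2$plant_id),
    per_gene = per_gene,
    overall = all(per_gene == "heritable")
  ), class = "heritability_verdict")
}

#' @export
print.heritability_verdict <- function(x, ...) {
  cat(sprintf("<heritability> %s -> %s: overall %s\n", x$plant_pair[["t1"]],
              x$plant_pair[["t2"]], if (x$overall) "heritable" else "NOT heritable"))
  bad <- x$per_gene[x$per_gene != "heritable"]
  if (length(bad)) {
    cat(paste(sprintf("  %s: %s", names(bad), bad), collapse = "\n"), "\n")
  }
  invisible(x)
}
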