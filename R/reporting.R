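# Population tallies and efficiency reporting: mutant / total counts per
# germination type and the percentage arithmetic used in published
# multiplex-editing efficiency tables.

#' Tally sextuple-mutant status by germination type
#'
#' Joins plant genotypes with germination records and counts, per
#' germination type, how many plants are homozygous/biallelic sextuple
#' mutants out of the total seeds in that category. Seeds present in the
#' germination table but never genotyped are kept in the totals: Type-3
#' seeds (never germinated, so never genotyped) count as mutant only under
#' `presume_type3_mutant`; germinated seeds without a genotype (e.g. died
#' before sampling) count as nonmutant ("not recovered").
#'
#' @param plants List of `"plant_genotype"` objects (may omit ungenotyped
#'   seeds).
#' @param germination Tibble with `plant_id` and either `germination_type`
#'   or the raw `germinated`/`day_of_germination`/`stunted` columns.
#' @param presume_type3_mutant Count never-germinating seeds as sextuple
#'   mutants (default `FALSE`). The presumption is justified when germinated
#'   siblings show near-complete editing and wild-type-free pools.
#' @param label Tally label.
#' @return A `"population_tally"` list: `label`, `presume_type3_mutant` and
#'   `counts` (tibble: `germination_type`, `mutant`, `total`).
#' @export
tally_population <- function(plants, germination,
                             presume_type3_mutant = FALSE,
                             label = "population") {
  if (anyDuplicated(germination$plant_id)) {
    stop("duplicate plant_id in germination table", call. = FALSE)
  }
  ids <- vapply(plants, `[[`, "", "plant_id")
  if (anyDuplicated(ids)) stop("duplicate plant_id in genotypes", call. = FALSE)
  if (!"germination_type" %in% names(germination)) {
    germination$germination_type <- classify_germination(
      germination$germinated, germination$day_of_germination,
      germination$stunted)
  }
  mutant_by_id <- stats::setNames(
    vapply(plants, `[[`, TRUE, "is_sextuple_no_wt"), ids)
  not_recovered <- 0L
  counts <- lapply(GERMINATION_TYPES, function(tp) {
    sel <- germination$plant_id[germination$germination_type == tp]
    total <- length(sel)
    genotyped <- sel[sel %in% ids]
    mutant <- sum(mutant_by_id[genotyped])
    if (tp == "Type-3" && presume_type3_mutant) {
      mutant <- mutant + sum(!sel %in% ids)
    }
    if (tp != "Type-3") {
      not_recovered <<- not_recovered + sum(!sel %in% ids)
    }
    tibble::tibble(germination_type = tp, mutant = as.integer(mutant),
                   total = as.integer(total))
  })
  structure(list(label = label, presume_type3_mutant = presume_type3_mutant,
                 counts = do.call(rbind, counts),
                 not_recovered = not_recovered),
            class = "population_tally")
}

#' Build a population tally from explicit counts
#'
#' For transcribed published count tables (or any externally tallied data):
#' supply mutant/total per germination type directly.
#'
#' @param counts Tibble or data.frame with `germination_type`, `mutant`,
#'   `total`.
#' @param label Tally label.
#' @param presume_type3_mutant Whether Type-3 counts already presume
#'   mutancy (documentation flag only).
#' @param not_recovered Number of germinated seedlings that died before
#'   genotyping. They sit in their germination type's totals as nonmutants;
#'   under the presumption they are added to the overall mutant estimate
#'   (see [efficiency_summary()]).
#' @return A `"population_tally"` object.
#' @export
population_tally <- function(counts, label = "population",
                             presume_type3_mutant = TRUE,
                             not_recovered = 0L) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("germination_type", "mutant", "total") %in% names(counts)))
  if (any(counts$mutant > counts$total) || any(counts$mutant < 0)) {
    stop("mutant counts must lie in [0, total]", call. = FALSE)
  }
  structure(list(label = label, presume_type3_mutant = presume_type3_mutant,
                 counts = counts, not_recovered = as.integer(not_recovered)),
            class = "population_tally")
}

#' Efficiency percentages from a population tally
#'
#' Computes, per germination type and for the standard aggregates, the
#' percentage of sextuple mutants at one decimal with half-up rounding (the
#' convention behind printed ratios such as 45/61 -> 73.8). Aggregates:
#' `"Type-0+1"` (genotyped seedlings with normal or delayed germination),
#' `"germinated"` (Types 0-2) and `"all"` (Types 0-3, meaningful when
#' Type-3 seeds are presumed mutant). Under that presumption, seedlings
#' that germinated but died before genotyping (`not_recovered`) are also
#' added to the overall (`"all"`) mutant numerator -- they are scored
#' nonmutant within their own germination type, but the overall efficiency
#' estimate treats unobservable genotypes the same way it treats
#' never-germinating seeds. Zero-total cells report `NA`, never 0%.
#'
#' @param tally A `"population_tally"`.
#' @return An `"efficiency_report"` list with `label` and `table` (tibble:
#'   `category`, `mutant`, `total`, `percent`).
#' @export
efficiency_summary <- function(tally) {
  stopifnot(inherits(tally, "population_tally"))
  ct <- tally$counts
  if (any(ct$mutant < 0 | ct$total < 0)) stop("negative counts", call. = FALSE)
  one <- function(category, mutant, total) {
    tibble::tibble(category = category, mutant = as.integer(mutant),
                   total = as.integer(total),
                   percent = if (total > 0)
                     round_half_up(100 * mutant / total, 1) else NA_real_)
  }
  get <- function(tp) ct[ct$germination_type == tp, ]
  rows <- lapply(GERMINATION_TYPES, function(tp) {
    r <- get(tp)
    if (nrow(r) == 0) one(tp, 0L, 0L) else one(tp, r$mutant, r$total)
  })
  agg <- function(types, name, extra_mutant = 0L) {
    r <- ct[ct$germination_type %in% types, ]
    one(name, sum(r$mutant) + extra_mutant, sum(r$total))
  }
  presumed_dead <- if (isTRUE(tally$presume_type3_mutant))
    tally$not_recovered %||% 0L else 0L
  tab <- rbind(do.call(rbind, rows),
               agg(c("Type-0", "Type-1"), "Type-0+1"),
               agg(c("Type-0", "Type-1", "Type-2"), "germinated"),
               agg(GERMINATION_TYPES, "all", presumed_dead))
  structure(list(label = tally$label, table = tab),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("<efficiency_report> %s\n", x$label))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    pc <- if (is.na(tab$percent[i])) "   n/a" else
      sprintf("%5.1f%%", tab$percent[i])
    cat(sprintf("  %-10s %s (%d/%d)\n", tab$category[i], pc,
                tab$mutant[i], tab$total[i]))
  }
  invisible(x)
}

#' Published T1 sextuple-mutant counts for the six-gene PP2C constructs
#'
#' Transcribed mutant/total counts per germination type for the two
#' six-crRNA vectors (identical spacers, swapped array order) from the
#' published T1 screen: Type-0/1 counts are HTS-genotyped seedlings, Type-2
#' counts rest on pooled wild-type-free HTS, and Type-3 seeds are presumed
#' mutant. Two p6xV1 and eight p6xV2 seedlings died after transplanting
#' before genotyping; they are scored nonmutant within their germination
#' types and presumed mutant only in the overall estimate, which is the
#' arithmetic that yields the published overall ratios (124/138 and
#' 171/214). These are fixed observed counts -- they cannot be recomputed
#' without the plants -- and serve as the reference input for
#' [efficiency_summary()].
#'
#' @return Named list of two `"population_tally"` objects (`p6xV1`,
#'   `p6xV2`).
#' @export
sextuple_screen_counts <- function() {
  list(
    p6xV1 = population_tally(tibble::tibble(
      germination_type = GERMINATION_TYPES,
      mutant = c(11L, 14L, 20L, 77L),
      total = c(21L, 20L, 20L, 77L)
    ), label = "p6xV1", not_recovered = 2L),
    p6xV2 = population_tally(tibble::tibble(
      germination_type = GERMINATION_TYPES,
      mutant = c(16L, 15L, 21L, 111L),
      total = c(37L, 45L, 21L, 111L)
    ), label = "p6xV2", not_recovered = 8L)
  )
}
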