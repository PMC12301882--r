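# Collapse per-read mutation events into allele calls with fractions, and
# the pooled-sample wild-type scan used for Type-2 seedling pools.

#' Zygosity-calling thresholds
#'
#' Read-fraction thresholds for scoring a line at one gene: a line is
#' homozygous (Ho) when one mutant allele carries at least `ho_bi_min` of the
#' retained reads, biallelic (Bi) when two or more mutant alleles jointly do,
#' heterozygous (He) when the top mutant allele carries at least `he_min`,
#' and chimeric (Chi) otherwise. Low-evidence alleles (below
#' `allele_floor_fraction` of reads *and* below `allele_floor_reads` reads)
#' are treated as noise and dropped from the denominator. A pooled sample is
#' consistent with all-mutant plants when its wild-type read fraction does
#' not exceed `wt_noise_max`.
#'
#' @param ho_bi_min Ho/Bi threshold on read fraction (default 0.95).
#' @param he_min He threshold on the top mutant allele fraction (default
#'   0.45).
#' @param allele_floor_fraction,allele_floor_reads Noise floor for retaining
#'   an allele (defaults 0.05 and 10; both must be undercut to drop it).
#' @param wt_noise_max Maximum wild-type read fraction still consistent with
#'   an all-mutant pool (default 0.005).
#' @return A `"zygosity_thresholds"` list.
#' @export
zygosity_thresholds <- function(ho_bi_min = 0.95, he_min = 0.45,
                                allele_floor_fraction = 0.05,
                                allele_floor_reads = 10L,
                                wt_noise_max = 0.005) {
  stopifnot(0 < he_min, he_min < ho_bi_min, ho_bi_min <= 1,
            allele_floor_fraction >= 0, allele_floor_reads >= 0,
            wt_noise_max >= 0)
  structure(list(ho_bi_min = ho_bi_min, he_min = he_min,
                 allele_floor_fraction = allele_floor_fraction,
                 allele_floor_reads = as.integer(allele_floor_reads),
                 wt_noise_max = wt_noise_max),
            class = "zygosity_thresholds")
}

# Keep only events that touch the cleavage window (an event counts if any
# base lies inside; insertions count by their insertion point).
clip_events_to_window <- function(events, site) {
  if (nrow(events) == 0) return(events)
  ws <- site$cleavage_start
  we <- site$cleavage_end
  ins <- events$kind == "insertion"
  span_end <- ifelse(ins, events$pos, events$pos + events$len)
  keep <- (events$pos < we & span_end > ws) |
    (ins & events$pos >= ws & events$pos <= we)
  if (all(keep)) return(events)
  fast_events(events$kind[keep], events$pos[keep], events$len[keep],
              events$seq[keep])
}

#' Collapse per-read events into allele calls
#'
#' Events are restricted to the cleavage window of `site`; reads with no
#' in-window events (and, by default, reads whose in-window events are
#' substitutions only) count as wild type. Identical event lists pool into
#' one allele. Alleles under the noise floor are discarded together with
#' their reads, and fractions are recomputed over the retained reads so they
#' sum to 1.
#'
#' @param events_per_read List of event data.frames as returned by
#'   [align_reads()] (`NULL` entries = rejected reads).
#' @param site A [target_site()].
#' @param thresholds [zygosity_thresholds()].
#' @param count_substitutions_as_mutant Count substitution-only reads as
#'   mutant alleles rather than wild type (default `FALSE`; the downstream
#'   loss-of-function logic is indel-driven).
#' @return A list: `calls` (tibble with `key`, `net_indel`, `in_frame`,
#'   `reads`, `fraction`, mutant alleles only, descending fraction),
#'   `wt_reads`, `wt_fraction`, `n_retained`, and `no_call` (`TRUE` when no
#'   reads survive filtering -- distinct from a wild-type call).
#' @export
collapse_alleles <- function(events_per_read, site,
                             thresholds = zygosity_thresholds(),
                             count_substitutions_as_mutant = FALSE) {
  keys <- window_allele_keys(events_per_read, site,
                             count_substitutions_as_mutant)
  collapse_from_keys(keys, thresholds)
}

# Per-read in-window allele keys; NA marks rejected reads.
window_allele_keys <- function(events_per_read, site,
                               count_substitutions_as_mutant = FALSE) {
  vapply(events_per_read, function(ev) {
    if (is.null(ev)) return(NA_character_)
    ev <- clip_events_to_window(ev, site)
    if (nrow(ev) == 0) return("WT")
    if (!count_substitutions_as_mutant && !has_indel(ev)) return("WT")
    allele_key(ev)
  }, character(1))
}

# The collapsing/floor arithmetic on a vector of per-read allele keys.
collapse_from_keys <- function(keys, thresholds = zygosity_thresholds()) {
  keys <- keys[!is.na(keys)]
  n <- length(keys)
  if (n == 0) return(no_call_result())

  tab <- table(keys)
  wt_reads <- if ("WT" %in% names(tab)) as.integer(tab[["WT"]]) else 0L
  mut <- tab[setdiff(names(tab), "WT")]
  counts <- as.integer(mut)
  mkeys <- names(mut)

  # noise floor: drop alleles that undercut both the fraction and the read
  # floor; their reads leave the denominator entirely
  if (length(counts)) {
    frac0 <- counts / n
    drop <- frac0 < thresholds$allele_floor_fraction &
      counts < thresholds$allele_floor_reads
    mkeys <- mkeys[!drop]
    counts <- counts[!drop]
  }
  n_retained <- wt_reads + sum(counts)
  if (n_retained == 0) return(no_call_result())

  ord <- order(counts, mkeys, decreasing = TRUE)
  mkeys <- mkeys[ord]; counts <- counts[ord]
  calls <- tibble::tibble(
    key = mkeys,
    net_indel = vapply(mkeys, net_indel, integer(1), USE.NAMES = FALSE),
    in_frame = is_in_frame_3x(mkeys),
    reads = counts,
    fraction = counts / n_retained
  )
  list(calls = calls, wt_reads = wt_reads,
       wt_fraction = wt_reads / n_retained,
       n_retained = as.integer(n_retained), no_call = FALSE)
}

no_call_result <- function() {
  list(calls = tibble::tibble(key = character(0), net_indel = integer(0),
                              in_frame = logical(0), reads = integer(0),
                              fraction = numeric(0)),
       wt_reads = 0L, wt_fraction = NA_real_, n_retained = 0L, no_call = TRUE)
}

#' Call alleles and zygosity for one read pool
#'
#' Runs [align_reads()], [collapse_alleles()] and [classify_zygosity()] for
#' a single line x gene read pool.
#'
#' @param reads Character vector of reads.
#' @param site A [target_site()].
#' @param params [alignment_params()].
#' @param thresholds [zygosity_thresholds()].
#' @param count_substitutions_as_mutant See [collapse_alleles()].
#' @return A gene-zygosity list: fields of [collapse_alleles()]'s result plus
#'   `gene_id` and `class` (one of WT/Ho/Bi/He/Chi, or `"no_call"`).
#' @export
call_pool <- function(reads, site, params = alignment_params(),
                      thresholds = zygosity_thresholds(),
                      count_substitutions_as_mutant = FALSE) {
  ev <- align_reads(reads, site, params)
  res <- collapse_alleles(ev, site, thresholds, count_substitutions_as_mutant)
  res$gene_id <- site$gene_id
  res$class <- if (res$no_call) "no_call" else
    classify_zygosity(res$calls$fraction, res$wt_fraction, thresholds)
  res
}

#' Combined wild-type read fraction of pooled samples
#'
#' Applies the same alignment, window clipping and noise filtering as
#' [call_pool()] to the concatenation of several plants' read pools and
#' returns the retained wild-type read fraction. Used for pooled Type-2
#' seedling samples, where any detectable wild-type reads would contradict an
#' all-mutant pool.
#'
#' @param pools List of character vectors of reads (one per plant); a single
#'   character vector is treated as one pool.
#' @inheritParams call_pool
#' @return Wild-type fraction in `[0, 1]`, or `NA` (no-call) when no reads
#'   survive.
#' @export
pooled_wt_fraction <- function(pools, site, params = alignment_params(),
                               thresholds = zygosity_thresholds(),
                               count_substitutions_as_mutant = FALSE) {
  if (is.character(pools)) pools <- list(pools)
  reads <- unlist(pools, use.names = FALSE)
  if (!length(reads)) return(NA_real_)
  ev <- align_reads(reads, site, params)
  res <- collapse_alleles(ev, site, thresholds, count_substitutions_as_mutant)
  res$wt_fraction
}

#' Is a pooled sample consistent with all-mutant plants?
#'
#' Advisory inference, not a per-plant genotype: a pooled wild-type fraction
#' at or below the noise ceiling is read as "every plant in the pool carries
#' only mutant alleles".
#'
#' @param wt_fraction Pooled wild-type fraction in `[0, 1]`.
#' @param thresholds [zygosity_thresholds()] (uses `wt_noise_max`).
#' @return `"all-mutant-consistent"` or `"wt-detected"`.
#' @export
infer_pool_homozygosity <- function(wt_fraction,
                                    thresholds = zygosity_thresholds()) {
  stopifnot(is.na(wt_fraction) || (wt_fraction >= 0 && wt_fraction <= 1))
  if (is.na(wt_fraction)) return(NA_character_)
  if (wt_fraction <= thresholds$wt_noise_max) "all-mutant-consistent"
  else "wt-detected"
}
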