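# Synthetic T1-like populations with known per-gene editing outcomes.
# Every downstream stage is testable against the emitted truth table; no
# sequencing data are required anywhere in the package.

#' Synthetic six-gene target panel
#'
#' Builds a reproducible six-gene panel (HAI1/HAI2/HAI3/AHG1/AHG3/HAB2 --
#' the clade A PP2C genes whose joint knockout blocks seed germination) with
#' random amplicons carrying a planted TTTV PAM + spacer. The sequences are
#' synthetic stand-ins: real amplicon and spacer sequences are
#' experiment-specific and arrive via [parse_target_manifest()].
#'
#' @param seed RNG seed for the panel sequences (default 101).
#' @param amplicon_len Amplicon length in nt (default 180).
#' @param spacer_len Spacer length in nt (default 23).
#' @param pam_offset 0-based PAM start within each amplicon (default 60).
#' @return Named list of six [target_site()] objects.
#' @export
synthetic_pp2c_sites <- function(seed = 101L, amplicon_len = 180L,
                                 spacer_len = 23L, pam_offset = 60L) {
  genes <- c("HAI1", "HAI2", "HAI3", "AHG1", "AHG3", "HAB2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sites <- lapply(genes, function(g) {
    amp <- strsplit(random_dna(amplicon_len), "")[[1]]
    pam <- c("T", "T", "T", sample(c("A", "C", "G"), 1))
    amp[(pam_offset + 1L):(pam_offset + 4L)] <- pam
    amp_seq <- paste(amp, collapse = "")
    target_site(
      gene_id = g, amplicon_id = paste0(g, "_amp"), amplicon_seq = amp_seq,
      spacer_seq = substr(amp_seq, pam_offset + 5L, pam_offset + 4L + spacer_len),
      pam_seq = paste(pam, collapse = ""), strand = "+", offset = pam_offset
    )
  })
  stats::setNames(sites, genes)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates. Class probabilities
#' default to an efficient multiplex editor: mostly homozygous/biallelic
#' outcomes with smaller heterozygous, chimeric and unedited fractions.
#' Indel sizes follow truncated geometric distributions (deletions 1-30 nt,
#' insertions 1-10 nt, deletions more likely), with an optional extra weight
#' on multiples of 3.
#'
#' @param n_plants Number of T1 plants.
#' @param genes Named list of [target_site()] objects (default
#'   [synthetic_pp2c_sites()]).
#' @param class_probs Named probabilities over `WT/Ho/Bi/He/Chi`; must sum
#'   to 1.
#' @param p_deletion Probability an indel is a deletion (default 0.7).
#' @param del_geom_p,ins_geom_p Geometric decay parameters for deletion and
#'   insertion sizes (defaults 0.15 and 0.3).
#' @param three_x_weight Multiplicative weight on sizes divisible by 3
#'   (default 1 = natural mass).
#' @param substitution_error_rate Per-base substitution error rate applied
#'   to every read (default 0.001).
#' @param depth Reads per plant x gene (default 100).
#' @param chimera_allele_count Mutant alleles in a chimeric plant (default
#'   4).
#' @param seed RNG seed; every simulation output is reproducible from it.
#' @return A `"simulation_config"` list.
#' @export
simulation_config <- function(n_plants = 200L,
                              genes = synthetic_pp2c_sites(),
                              class_probs = c(WT = 0.05, Ho = 0.35, Bi = 0.35,
                                              He = 0.15, Chi = 0.10),
                              p_deletion = 0.7,
                              del_geom_p = 0.15, ins_geom_p = 0.3,
                              three_x_weight = 1,
                              substitution_error_rate = 0.001,
                              depth = 100L,
                              chimera_allele_count = 4L,
                              seed = 1L) {
  stopifnot(n_plants >= 1, depth >= 1, chimera_allele_count >= 1)
  if (!setequal(names(class_probs), c("WT", "Ho", "Bi", "He", "Chi"))) {
    stop("class_probs must be named WT/Ho/Bi/He/Chi", call. = FALSE)
  }
  if (abs(sum(class_probs) - 1) > 1e-9) {
    stop(sprintf("class_probs must sum to 1 (got %.12f)", sum(class_probs)),
         call. = FALSE)
  }
  structure(list(
    n_plants = as.integer(n_plants), genes = genes,
    class_probs = class_probs[c("WT", "Ho", "Bi", "He", "Chi")],
    p_deletion = p_deletion, del_geom_p = del_geom_p, ins_geom_p = ins_geom_p,
    three_x_weight = three_x_weight,
    substitution_error_rate = substitution_error_rate,
    depth = as.integer(depth),
    chimera_allele_count = as.integer(chimera_allele_count),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Signed indel size distribution (negative = deletion).
indel_size_probs <- function(config) {
  del_sizes <- 1:30
  ins_sizes <- 1:10
  dw <- (1 - config$del_geom_p)^(del_sizes - 1) * config$del_geom_p
  iw <- (1 - config$ins_geom_p)^(ins_sizes - 1) * config$ins_geom_p
  dw[del_sizes %% 3 == 0] <- dw[del_sizes %% 3 == 0] * config$three_x_weight
  iw[ins_sizes %% 3 == 0] <- iw[ins_sizes %% 3 == 0] * config$three_x_weight
  sizes <- c(-del_sizes, ins_sizes)
  probs <- c(config$p_deletion * dw / sum(dw),
             (1 - config$p_deletion) * iw / sum(iw))
  list(sizes = sizes, probs = probs / sum(probs))
}

# Draw one random mutant allele: a single indel overlapping the protospacer
# (repair outcomes concentrate around the cut site within the spacer; the
# caller's padded cleavage window absorbs placement ambiguity at the edges).
draw_allele <- function(site, sizedist) {
  size <- sample(sizedist$sizes, 1, prob = sizedist$probs)
  ss <- site$spacer_start
  se <- site$spacer_end
  n <- nchar(site$amplicon_seq)
  if (size < 0) {
    len <- -size
    # deletion start uniform such that the event overlaps the spacer
    lo <- max(0L, ss - len + 1L)
    hi <- min(se - 1L, n - len)
    pos <- if (hi <= lo) lo else sample(lo:hi, 1)
    ev <- mutation_event("deletion", pos, len)
  } else {
    pos <- sample(ss:se, 1)
    ev <- mutation_event("insertion", pos, size, random_dna(size))
  }
  ev
}

# Largest-remainder allocation of `depth` reads over `fracs` (sums to depth).
quantize_depth <- function(fracs, depth) {
  raw <- fracs * depth
  base <- floor(raw)
  left <- depth - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Draw the allele composition for one plant x gene of a given class.
draw_composition <- function(class, site, config, sizedist,
                             thresholds = zygosity_thresholds()) {
  # distinct by mutant *sequence*, not just event list: two different event
  # lists can collapse to one read sequence in repeat context, which would
  # silently merge a biallelic plant into a homozygous one downstream
  draw_distinct <- function(k) {
    seqs <- character(0); evs <- list()
    while (length(evs) < k) {
      ev <- draw_allele(site, sizedist)
      s <- apply_events(site$amplicon_seq, ev)
      if (!s %in% seqs) { seqs <- c(seqs, s); evs <- c(evs, list(ev)) }
    }
    evs
  }
  if (class == "WT") {
    return(list(key = "WT", fraction = 1))
  }
  if (class == "Ho") {
    ev <- draw_distinct(1)
    return(list(key = allele_key(ev[[1]]), fraction = 1))
  }
  if (class == "Bi") {
    evs <- draw_distinct(2)
    return(list(key = vapply(evs, allele_key, ""), fraction = c(0.5, 0.5)))
  }
  if (class == "He") {
    ev <- draw_distinct(1)
    return(list(key = c(allele_key(ev[[1]]), "WT"), fraction = c(0.5, 0.5)))
  }
  # Chi: flat simplex over k mutant alleles + WT, rejected until every
  # mutant fraction is below the He threshold and the mutant total below the
  # Ho/Bi threshold (the class is defined only by those thresholds). Each
  # mutant fraction must also clear the caller's allele detection floor:
  # a sub-floor allele is indistinguishable from sequencing noise at finite
  # depth, so compositions containing one would not have a well-defined
  # truth class.
  # The same constraints must hold for the depth-quantized read counts,
  # otherwise rounding at finite depth could carry a boundary composition
  # across a threshold and the pool's class would not be well-defined. The
  # quantized check is only meaningful (and only feasible) once the depth
  # can represent the allele floor and leave headroom under the He bound;
  # at shallower depths the generator guarantees the true fractions only.
  k <- config$chimera_allele_count
  check_quantized <- config$depth * thresholds$allele_floor_fraction >= 1
  repeat {
    w <- -log(stats::runif(k + 1))
    fr <- w / sum(w)
    if (!(all(fr[seq_len(k)] < thresholds$he_min) &&
          all(fr[seq_len(k)] >= thresholds$allele_floor_fraction) &&
          sum(fr[seq_len(k)]) < thresholds$ho_bi_min)) next
    if (!check_quantized) break
    q <- quantize_depth(fr, config$depth) / config$depth
    if (all(q[seq_len(k)] < thresholds$he_min) &&
        all(q[seq_len(k)] >= thresholds$allele_floor_fraction) &&
        sum(q[seq_len(k)]) < thresholds$ho_bi_min) break
  }
  evs <- draw_distinct(k)
  list(key = c(vapply(evs, allele_key, ""), "WT"), fraction = fr)
}

#' Simulate a T1-like population with known editing outcomes
#'
#' For each plant and targeted gene, a zygosity class is drawn from
#' `class_probs` and an allele composition from the class archetype:
#' homozygous = one mutant allele at fraction 1; biallelic = two distinct
#' mutant alleles at 0.5/0.5; heterozygous = one mutant allele + wild type at
#' 0.5/0.5; chimeric = several low-fraction alleles plus wild type. Reads are
#' amplicon copies with the allele's events applied; read counts per allele
#' are the largest-remainder quantization of `fraction * depth`, so the truth
#' stays analytically known and sampling jitter enters only through the
#' finite depth. Per-base substitution noise is then applied independently to
#' every read.
#'
#' @param config A [simulation_config()].
#' @param outdir Optional directory; when given, per-plant x gene FASTQ
#'   files (`<plant>__<gene>.fastq`), `truth.tsv` and the resolved config
#'   JSON are written there.
#' @return A list with `truth` (tibble: `plant_id`, `gene_id`, `true_class`,
#'   `key`, `net_indel`, `in_frame`, `fraction`, `reads` -- one row per true
#'   allele) and `reads` (nested list `reads[[plant_id]][[gene_id]]` of read
#'   character vectors). Byte-identical across runs with the same config.
#' @export
simulate_population <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  sizedist <- indel_size_probs(config)
  genes <- config$genes
  classes <- names(config$class_probs)

  plant_ids <- sprintf("plant%03d", seq_len(config$n_plants))
  n_pools <- config$n_plants * length(genes)
  t_pid <- character(n_pools); t_gid <- character(n_pools)
  t_cls <- character(n_pools)
  t_key <- vector("list", n_pools); t_frac <- vector("list", n_pools)
  t_reads <- vector("list", n_pools)
  reads_out <- stats::setNames(vector("list", length(plant_ids)), plant_ids)
  row_i <- 0L

  for (p in seq_along(plant_ids)) {
    pid <- plant_ids[p]
    reads_out[[pid]] <- stats::setNames(vector("list", length(genes)),
                                        names(genes))
    for (g in names(genes)) {
      site <- genes[[g]]
      cls <- sample(classes, 1, prob = config$class_probs)
      comp <- draw_composition(cls, site, config, sizedist)
      nreads <- quantize_depth(comp$fraction, config$depth)
      # materialize reads
      pool <- unlist(lapply(seq_along(comp$key), function(i) {
        if (nreads[i] == 0) return(character(0))
        seq <- if (comp$key[i] == "WT") site$amplicon_seq else
          apply_events(site$amplicon_seq, comp$key[i])
        rep(seq, nreads[i])
      }), use.names = FALSE)
      pool <- add_substitution_noise(pool, config$substitution_error_rate)
      reads_out[[pid]][[g]] <- pool
      row_i <- row_i + 1L
      t_pid[row_i] <- pid; t_gid[row_i] <- g; t_cls[row_i] <- cls
      t_key[[row_i]] <- comp$key
      t_frac[[row_i]] <- comp$fraction
      t_reads[[row_i]] <- nreads
    }
  }
  n_alleles <- lengths(t_key)
  all_keys <- unlist(t_key, use.names = FALSE)
  ukey <- unique(all_keys)
  uni <- vapply(ukey, net_indel, integer(1), USE.NAMES = FALSE)
  ki <- match(all_keys, ukey)
  truth <- tibble::tibble(
    plant_id = rep.int(t_pid, n_alleles),
    gene_id = rep.int(t_gid, n_alleles),
    true_class = rep.int(t_cls, n_alleles),
    key = all_keys,
    net_indel = uni[ki],
    in_frame = all_keys != "WT" & uni[ki] %% 3L == 0L,
    fraction = unlist(t_frac, use.names = FALSE),
    reads = unlist(t_reads, use.names = FALSE)
  )
  result <- list(truth = truth, reads = reads_out, config = config)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (pid in plant_ids) {
      for (g in names(genes)) {
        write_fastq(reads_out[[pid]][[g]],
                    file.path(outdir, sprintf("%s__%s.fastq", pid, g)),
                    ids = sprintf("%s_%s_r%03d", pid, g,
                                  seq_along(reads_out[[pid]][[g]])))
      }
    }
    utils::write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg <- config
    cfg$genes <- lapply(cfg$genes, function(s) s[c("gene_id", "amplicon_id",
                                                   "spacer_seq", "pam_seq",
                                                   "strand", "offset")])
    jsonlite::write_json(unclass(cfg), file.path(outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

# Apply iid per-base substitution noise to a vector of reads. Reads with a
# single error (the vast majority at realistic rates) are handled
# vectorised; multi-error reads fall back to a per-read loop.
add_substitution_noise <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  lens <- nchar(reads)
  nerr <- stats::rbinom(length(reads), lens, rate)

  one <- which(nerr == 1L)
  if (length(one)) {
    p <- 1L + floor(stats::runif(length(one)) * lens[one])
    old <- substr(reads[one], p, p)
    # shift each base by 1-3 within the alphabet to guarantee a change
    idx <- match(old, DNA_BASES)
    new_idx <- 1L + (idx - 1L + sample.int(3L, length(one), replace = TRUE)) %% 4L
    reads[one] <- paste0(substr(reads[one], 1L, p - 1L),
                         DNA_BASES[new_idx],
                         substr(reads[one], p + 1L, lens[one]))
  }
  multi <- which(nerr > 1L)
  for (i in multi) {
    chars <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

# Truth tibble -> per-plant summary of sextuple/LOF status.
truth_plant_flags <- function(truth) {
  out <- list()
  for (pid in unique(truth$plant_id)) {
    sub <- truth[truth$plant_id == pid, ]
    per_gene <- split(sub, sub$gene_id)
    classes <- vapply(per_gene, function(x) x$true_class[1], "")
    sextuple <- all(classes %in% c("Ho", "Bi"))
    any_if <- any(sub$in_frame & sub$key != "WT")
    out[[pid]] <- tibble::tibble(
      plant_id = pid, is_sextuple_no_wt = sextuple,
      is_full_lof = sextuple && !any_if,
      predicted_type3 = sextuple && !any_if
    )
  }
  do.call(rbind, out)
}

#' Simulate seed germination from a truth table
#'
#' Applies the genotype-to-germination rule deterministically: full
#' loss-of-function sextuple plants never germinate within the horizon
#' (Type-3); sextuple plants rescued by at least one in-frame (3x) allele
#' germinate late (day 14/21/28) or stunted (Type-1/Type-2); all other
#' plants germinate normally at day 7 (Type-0). `in_frame_rescue_prob`
#' optionally lets an in-frame sextuple plant fail to germinate anyway.
#'
#' @param truth Truth tibble from [simulate_population()].
#' @param in_frame_rescue_prob Probability an in-frame sextuple plant
#'   germinates at all (default 1).
#' @param delay_probs Named probabilities over delayed outcomes `"14"`,
#'   `"21"`, `"28"` and `"stunted"` for rescued plants.
#' @param observation_horizon Days observed (default 70).
#' @param seed RNG seed (default: derived from nothing -- pass one for
#'   reproducibility).
#' @return Tibble of germination records: `plant_id`, `germinated`,
#'   `day_of_germination`, `stunted`, `observation_horizon`,
#'   `germination_type`.
#' @export
simulate_germination <- function(truth, in_frame_rescue_prob = 1,
                                 delay_probs = c(`14` = 0.25, `21` = 0.25,
                                                 `28` = 0.25, stunted = 0.25),
                                 observation_horizon = 70L, seed = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  if (!is.null(seed)) set.seed(seed)
  flags <- truth_plant_flags(truth)
  n <- nrow(flags)
  germinated <- rep(TRUE, n)
  day <- rep(7L, n)
  stunted <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (flags$is_full_lof[i]) {
      germinated[i] <- FALSE; day[i] <- NA_integer_
    } else if (flags$is_sextuple_no_wt[i]) {
      rescued <- stats::runif(1) <= in_frame_rescue_prob
      if (!rescued) {
        germinated[i] <- FALSE; day[i] <- NA_integer_
      } else {
        pick <- sample(names(delay_probs), 1, prob = delay_probs)
        if (pick == "stunted") { stunted[i] <- TRUE; day[i] <- 21L }
        else day[i] <- as.integer(pick)
      }
    }
  }
  tibble::tibble(
    plant_id = flags$plant_id, germinated = germinated,
    day_of_germination = day, stunted = stunted,
    observation_horizon = as.integer(observation_horizon),
    germination_type = classify_germination(germinated, day, stunted)
  )
}

#' Write germination records to TSV
#'
#' @param germination Tibble from [simulate_germination()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_germination_table <- function(germination, path) {
  utils::write.table(germination, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a germination TSV
#'
#' @param path TSV with columns `plant_id`, `germinated`,
#'   `day_of_germination`, `stunted`, `observation_horizon`.
#' @return Tibble with `germination_type` recomputed.
#' @export
read_germination_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$germinated <- as.logical(df$germinated)
  df$stunted <- as.logical(df$stunted)
  df$germination_type <- classify_germination(df$germinated,
                                              df$day_of_germination,
                                              df$stunted)
  tibble::as_tibble(df)
}
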