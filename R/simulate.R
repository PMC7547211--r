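#' Forward simulation of a diploid mutation-accumulation lineage
#'
#' Simulates one MA line through `n_passages` single-cell bottleneck
#' passages. Per passage, new SNVs and InDels arrive as Poisson processes
#' over the diploid genome (`mu * 2 * genome_length * generations_per_passage`
#' expected events), placed uniformly and assigned to a random homolog. LOH
#' events arrive at `loh_rate` per passage: terminal tracts are anchored at a
#' chromosome end (BIR-like), interstitial tracts (gene-conversion-like) are
#' placed uniformly with lengths drawn from the configured distributions.
#' Each pre-existing heterozygous variant overlapped by a new LOH tract is
#' fixed (made homozygous) when it sits on the retained homolog and
#' eliminated otherwise -- a fair Bernoulli by symmetric chromatid
#' segregation. Whole-chromosome aneuploidies and structural deletions
#' update copy number and likewise fix/eliminate overlapped heterozygous
#' variants. Every event is recorded in a ground-truth event log.
#'
#' @param config A [sim_config()] object.
#' @param lineage_id Integer lineage index; the RNG stream is seeded
#'   `config$seed + lineage_id - 1`, so lineages are independent and
#'   reproducible.
#' @param keep_states Keep a per-passage snapshot (needed for trajectory
#'   analysis)? If `FALSE` only the final state is retained.
#' @param marker_map Optional precomputed marker map (tibble `chrom`, `pos`,
#'   `p1_allele`, `p2_allele`); computed from the config when `NULL`.
#' @return An object of class `"ma_lineage"`: a list with elements
#'   `states` (per-passage snapshots; each has `passage`, `variants`,
#'   `tracts`, `chrom_cn`, `hap_cn`, `genome`, `marker_map`),
#'   `events` (the ground-truth event log tibble), `config`, `lineage_id`.
#' @export
#' @examples
#' cfg <- sim_config(n_passages = 5, n_markers = 500, loh_rate = 1, seed = 7)
#' lin <- simulate_lineage(cfg)
#' lin$events
simulate_lineage <- function(config, lineage_id = 1L, keep_states = FALSE,
                             marker_map = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(marker_map)) marker_map <- sim_marker_map(config)

  genome <- config$genome
  chroms <- genome$chrom
  chrlen <- as.numeric(genome$length)
  names(chrlen) <- chroms
  total_len <- sum(chrlen)
  gpp <- config$generations_per_passage
  lambda_snv <- config$mu_snv * 2 * total_len * gpp
  lambda_indel <- config$mu_indel * 2 * total_len * gpp

  ref <- config$reference
  hp_runs <- if (!is.null(ref)) homopolymer_runs(ref) else NULL

  set.seed(config$seed + lineage_id - 1L)

  variants <- empty_variants()
  tracts <- empty_tracts()
  chrom_cn <- stats::setNames(rep(2L, length(chroms)), chroms)
  # haplotype gained (CN 3) or retained (CN 1) per chromosome, NA when CN 2
  hap_cn <- stats::setNames(rep(NA_integer_, length(chroms)), chroms)
  events <- list()
  n_event <- 0L
  n_var <- 0L

  snapshot <- function(p) {
    list(passage = p, variants = variants, tracts = tracts,
         chrom_cn = chrom_cn, hap_cn = hap_cn,
         genome = genome, marker_map = marker_map)
  }
  states <- if (keep_states) list(snapshot(0L)) else NULL

  add_event <- function(passage, kind, chrom, start, end, haplotype, outcome,
                        variant_id = NA_character_, ref_id = NA_character_,
                        detail = NA_character_) {
    n_event <<- n_event + 1L
    id <- sprintf("E%05d", n_event)
    events[[n_event]] <<- list(
      event_id = id, passage = passage, kind = kind, chrom = chrom,
      start = start, end = end, haplotype = haplotype, outcome = outcome,
      variant_id = variant_id, ref_id = ref_id, detail = detail
    )
    id
  }

  sample_chrom <- function() sample(chroms, 1L, prob = chrlen)

  local_cn_at <- function(ch, pos) {
    cn <- chrom_cn[[ch]]
    if (cn == 2L && nrow(tracts) > 0L) {
      hit <- tracts$kind == "sv_deletion" & tracts$chrom == ch &
        tracts$start <= pos & tracts$end >= pos
      if (any(hit)) cn <- 1L
    }
    cn
  }

  # fix/eliminate het variants overlapped by a homogenizing interval that
  # retains haplotype `kept`; returns variant table updated
  segregate <- function(p, ch, s, e, kept, kind_label, ref_id) {
    idx <- which(variants$status == "het" & variants$chrom == ch &
                   variants$pos >= s & variants$pos <= e)
    for (i in idx) {
      if (variants$haplotype[i] == kept) {
        variants$status[i] <<- "hom"
        variants$fate_passage[i] <<- p
        add_event(p, variants$type[i], ch, variants$pos[i], variants$pos[i],
                  variants$haplotype[i], "fixed",
                  variant_id = variants$variant_id[i], ref_id = ref_id)
      } else {
        variants$status[i] <<- "eliminated"
        variants$fate_passage[i] <<- p
        add_event(p, variants$type[i], ch, variants$pos[i], variants$pos[i],
                  variants$haplotype[i], "eliminated",
                  variant_id = variants$variant_id[i], ref_id = ref_id)
      }
    }
    invisible(NULL)
  }

  add_tract <- function(p, ch, s, e, kept, kind) {
    tracts[nrow(tracts) + 1L, ] <<- list(
      sprintf("T%04d", nrow(tracts) + 1L), p, ch, as.integer(s), as.integer(e),
      as.integer(kept), kind
    )
  }

  new_variant <- function(p, type, ch, pos, refa, alta, hp) {
    cn <- local_cn_at(ch, pos)
    hap <- if (cn == 1L) hap_cn[[ch]] else sample(1:2, 1L)
    if (is.na(hap)) hap <- sample(1:2, 1L) # CN1 via sv deletion: either label
    status <- if (cn == 1L) "hom" else "het"
    n_var <<- n_var + 1L
    vid <- sprintf("L%03d.V%04d", lineage_id, n_var)
    variants[nrow(variants) + 1L, ] <<- list(
      vid, ch, as.integer(pos), refa, alta, type, as.integer(hap),
      status, p, NA_integer_, hp
    )
    add_event(p, type, ch, pos, pos, hap,
              if (status == "het") "heterozygous" else "na",
              variant_id = vid)
    invisible(vid)
  }

  draw_snv_alleles <- function(ch, pos) {
    bases <- c("A", "C", "G", "T")
    if (!is.null(ref)) {
      r <- substr(as.character(Biostrings::subseq(ref[[ch]], pos, pos)), 1, 1)
      if (!r %in% bases) r <- sample(bases, 1L)
    } else {
      r <- sample(bases, 1L)
    }
    list(ref = r, alt = sample(setdiff(bases, r), 1L))
  }

  for (p in seq_len(config$n_passages)) {
    ## --- new SNVs ---
    for (k in seq_len(stats::rpois(1L, lambda_snv))) {
      ch <- sample_chrom()
      pos <- sample.int(chrlen[[ch]], 1L)
      al <- draw_snv_alleles(ch, pos)
      new_variant(p, "snv", ch, pos, al$ref, al$alt, hp = FALSE)
    }

    ## --- new InDels ---
    for (k in seq_len(stats::rpois(1L, lambda_indel))) {
      in_hp <- stats::runif(1) < config$homopolymer_fraction
      if (in_hp && !is.null(hp_runs) && nrow(hp_runs) > 0L) {
        run <- hp_runs[sample.int(nrow(hp_runs), 1L), ]
        ch <- run$chrom; pos <- run$start; unit <- run$unit
      } else {
        ch <- sample_chrom()
        pos <- sample.int(max(chrlen[[ch]] - 2L, 1L), 1L)
        unit <- if (!is.null(ref)) {
          substr(as.character(Biostrings::subseq(ref[[ch]], pos, pos)), 1, 1)
        } else sample(c("A", "C", "G", "T"), 1L)
      }
      if (in_hp) {
        if (stats::runif(1) < 0.5) {
          refa <- unit; alta <- paste0(unit, unit)          # +1 slippage
        } else {
          refa <- paste0(unit, unit); alta <- unit          # -1 slippage
        }
      } else {
        len <- 1L + min(stats::rgeom(1L, 0.35), 43L)
        ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
        if (stats::runif(1) < 0.5) {
          refa <- unit; alta <- paste0(unit, ins)
        } else {
          refa <- paste0(unit, ins); alta <- unit
        }
      }
      new_variant(p, "indel", ch, pos, refa, alta, hp = in_hp)
    }

    ## --- LOH events ---
    for (k in seq_len(stats::rpois(1L, config$loh_rate))) {
      ch <- sample_chrom()
      if (chrom_cn[[ch]] == 1L) next  # monosomic: nothing left to lose
      len <- chrlen[[ch]]
      terminal <- stats::runif(1) < config$p_terminal
      if (terminal) {
        L <- min(draw_length(config$terminal_length_dist), len)
        if (stats::runif(1) < 0.5) { s <- 1L; e <- L } else { s <- len - L + 1L; e <- len }
        kind <- "terminal"
      } else {
        L <- min(draw_length(config$interstitial_length_dist), len)
        s <- sample.int(len - L + 1L, 1L)
        e <- s + L - 1L
        kind <- "interstitial"
      }
      kept <- sample(1:2, 1L)
      id <- add_event(p, "loh", ch, s, e, kept, "na", detail = kind)
      add_tract(p, ch, s, e, kept, kind)
      segregate(p, ch, s, e, kept, kind, id)
    }

    ## --- aneuploidies ---
    for (k in seq_len(stats::rpois(1L, config$aneuploidy_rate))) {
      ch <- sample(chroms, 1L)
      if (chrom_cn[[ch]] != 2L) next
      if (stats::runif(1) < 0.5) {                       # gain -> trisomy
        dup <- sample(1:2, 1L)
        chrom_cn[[ch]] <- 3L
        hap_cn[[ch]] <- dup
        add_event(p, "aneuploidy", ch, 1L, chrlen[[ch]], dup, "na",
                  detail = "gain")
      } else {                                           # loss -> monosomy
        lost <- sample(1:2, 1L)
        kept <- 3L - lost
        chrom_cn[[ch]] <- 1L
        hap_cn[[ch]] <- kept
        id <- add_event(p, "aneuploidy", ch, 1L, chrlen[[ch]], lost, "na",
                        detail = "loss")
        add_tract(p, ch, 1L, as.integer(chrlen[[ch]]), kept, "chrom_loss")
        segregate(p, ch, 1L, chrlen[[ch]], kept, "chrom_loss", id)
      }
    }

    ## --- structural deletions (one homolog, local) ---
    for (k in seq_len(stats::rpois(1L, config$sv_rate))) {
      ch <- sample_chrom()
      if (chrom_cn[[ch]] != 2L) next
      len <- chrlen[[ch]]
      L <- min(draw_length(config$sv_length_dist), len - 1L)
      s <- sample.int(len - L + 1L, 1L)
      e <- s + L - 1L
      lost <- sample(1:2, 1L)
      kept <- 3L - lost
      id <- add_event(p, "sv_deletion", ch, s, e, lost, "na")
      add_tract(p, ch, s, e, kept, "sv_deletion")
      segregate(p, ch, s, e, kept, "sv_deletion", id)
    }

    if (keep_states) states[[p + 1L]] <- snapshot(p)
  }

  if (!keep_states) states <- list(snapshot(config$n_passages))

  ev <- if (length(events) > 0L) {
    dplyr::bind_rows(lapply(events, tibble::as_tibble))
  } else {
    tibble::tibble(
      event_id = character(), passage = integer(), kind = character(),
      chrom = character(), start = numeric(), end = numeric(),
      haplotype = integer(), outcome = character(), variant_id = character(),
      ref_id = character(), detail = character()
    )
  }

  structure(list(states = states, events = ev, config = config,
                 lineage_id = lineage_id, marker_map = marker_map),
            class = "ma_lineage")
}

empty_variants <- function() {
  data.frame(
    variant_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), type = character(),
    haplotype = integer(), status = character(), born = integer(),
    fate_passage = integer(), in_homopolymer = logical(),
    stringsAsFactors = FALSE
  )
}

empty_tracts <- function() {
  data.frame(
    tract_id = character(), passage = integer(), chrom = character(),
    start = integer(), end = integer(), haplotype = integer(),
    kind = character(), stringsAsFactors = FALSE
  )
}

# marker map with constitutive parental alleles; deterministic per config
sim_marker_map <- function(config) {
  set.seed((config$seed + 999983L) %% .Machine$integer.max)
  map <- make_marker_map(config$genome, config$n_markers)
  if (nrow(map) == 0L) {
    return(dplyr::mutate(map, p1_allele = character(0), p2_allele = character(0)))
  }
  bases <- c("A", "C", "G", "T")
  p1 <- sample(bases, nrow(map), replace = TRUE)
  shift <- sample.int(3L, nrow(map), replace = TRUE)
  p2 <- bases[(match(p1, bases) - 1L + shift) %% 4L + 1L]
  dplyr::mutate(map, p1_allele = p1, p2_allele = p2)
}

#' Simulate several independent MA lineages
#'
#' @inheritParams simulate_lineage
#' @param n_lineages Number of parallel clones to simulate.
#' @return A list of [simulate_lineage()] results, one per clone.
#' @export
simulate_lineages <- function(config, n_lineages, keep_states = FALSE) {
  stopifnot(n_lineages >= 1)
  marker_map <- sim_marker_map(config)
  lapply(seq_len(n_lineages), function(i) {
    simulate_lineage(config, lineage_id = i, keep_states = keep_states,
                     marker_map = marker_map)
  })
}

#' @export
print.ma_lineage <- function(x, ...) {
  st <- x$states[[length(x$states)]]
  present <- sum(st$variants$status %in% c("het", "hom"))
  cat(sprintf(
    "<ma_lineage %d> %d passages | %d variants present (%d ever) | %d LOH tracts\n",
    x$lineage_id, st$passage, present, nrow(st$variants),
    sum(st$tracts$kind %in% c("interstitial", "terminal"))
  ))
  invisible(x)
}
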