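#' Classify the molecular origin of homozygous de novo mutations
#'
#' Assigns each apparently homozygous mutation to one origin by a decision
#' list over copy number, LOH overlap and co-located variants:
#'
#' 1. whole chromosome at copy number 1 -> `chromosome_loss`;
#' 2. a local copy-number < 2 segment covering the locus -> `deletion_overlap`;
#' 3. copy number 2 and inside an LOH region -> `rec` (mitotic
#'    recombination / BIR: a heterozygous mutation passively fixed by a
#'    subsequent overlapping LOH event);
#' 4. copy number 2 and a second, distinct InDel in the same homopolymer
#'    tract with both at heterozygous allele fractions -> `double_slippage`
#'    (independent slippage on the two homologs, leaving no wild-type
#'    allele in the tract);
#' 5. otherwise -> `not_in_loh_unexplained`.
#'
#' Copy-number evidence is tested before LOH overlap so that a deletion
#' inside a larger LOH region is attributed to the deletion, the more
#' direct signal. Rule 4 is the one case where the input variant itself has
#' a heterozygous allele fraction: the tract, not the locus, is homozygous.
#' Any other heterozygous variant is rejected.
#'
#' @param variants Tibble of candidate homozygous variants with `chrom`,
#'   `pos`, `ref`, `alt`, `zygosity`, `copy_number` (from
#'   [classify_zygosity()]) and, for slippage detection, `hp_unit`,
#'   `hp_start` (from [annotate_homopolymer()]).
#' @param loh_regions Tibble from [segment_loh()] (may be empty for
#'   isogenic lines).
#' @param cn_segments Tibble with `chrom`, `start`, `end`, `copy_number`.
#' @param aneuploidies Tibble from [call_aneuploidies()].
#' @param all_variants Full variant table of the clone (searched for
#'   slippage partners); defaults to `variants`.
#' @param het_window Allelic-fraction window treated as heterozygous for
#'   the tract-level slippage test (default `c(0.3, 0.7)`).
#' @return `variants` with columns `origin`, `loh_region` (id of the
#'   overlapping region or `NA`) and `partner` (row id of the slippage
#'   partner or `NA`) added.
#' @export
classify_homozygous_origin <- function(variants, loh_regions, cn_segments,
                                       aneuploidies, all_variants = variants,
                                       het_window = c(0.3, 0.7)) {
  n <- nrow(variants)
  origin <- rep(NA_character_, n)
  loh_id <- rep(NA_character_, n)
  partner <- rep(NA_character_, n)

  has_hp <- all(c("hp_unit", "hp_start") %in% names(all_variants))
  av_class <- classify_variant_class(all_variants$ref, all_variants$alt)
  av_key <- if (has_hp) {
    ifelse(is.na(all_variants$hp_start), NA_character_,
           paste(all_variants$chrom, all_variants$hp_start,
                 all_variants$hp_unit))
  } else rep(NA_character_, nrow(all_variants))

  for (i in seq_len(n)) {
    v <- variants[i, ]
    slip_partner <- NA_character_
    if (has_hp && !is.na(v$hp_start)) {
      key <- paste(v$chrom, v$hp_start, v$hp_unit)
      j <- which(av_key == key & av_class == "indel" &
                   !(all_variants$chrom == v$chrom &
                       all_variants$pos == v$pos &
                       all_variants$ref == v$ref &
                       all_variants$alt == v$alt))
      het_j <- j[all_variants$allele_fraction[j] >= het_window[1] &
                   all_variants$allele_fraction[j] <= het_window[2]]
      if (length(het_j) > 0L) slip_partner <- as.character(het_j[1])
    }
    if (v$zygosity != "homozygous") {
      af_het <- !is.na(v$allele_fraction) &&
        v$allele_fraction >= het_window[1] && v$allele_fraction <= het_window[2]
      if (!(af_het && !is.na(slip_partner))) {
        stop("variant ", i, " is not homozygous (zygosity = ", v$zygosity,
             ") and has no homopolymer-tract partner")
      }
    }
    chrom_lost <- v$chrom %in% aneuploidies$chrom[aneuploidies$copy_number == 1L]
    local_cn <- lookup_cn(v$chrom, v$pos, cn_segments)
    in_loh <- which(loh_regions$chrom == v$chrom &
                      loh_regions$start <= v$pos & loh_regions$end >= v$pos)
    if (chrom_lost) {
      origin[i] <- "chromosome_loss"
    } else if (!is.na(local_cn) && local_cn < 2L) {
      origin[i] <- "deletion_overlap"
    } else if (length(in_loh) > 0L) {
      origin[i] <- "rec"
      loh_id[i] <- as.character(in_loh[1])
    } else if (!is.na(slip_partner)) {
      origin[i] <- "double_slippage"
      partner[i] <- slip_partner
    } else {
      origin[i] <- "not_in_loh_unexplained"
    }
  }
  dplyr::mutate(variants, origin = origin, loh_region = loh_id,
                partner = partner)
}

#' Tabulate homozygous-mutation origins
#'
#' @param origin_calls Tibble from [classify_homozygous_origin()],
#'   optionally with a `strain` column.
#' @return Tibble of counts per origin (x strain when present), including
#'   zero rows for unobserved origins; counts sum to `nrow(origin_calls)`.
#' @export
summarize_origins <- function(origin_calls) {
  levels <- c("rec", "chromosome_loss", "deletion_overlap",
              "double_slippage", "not_in_loh_unexplained")
  groups <- if ("strain" %in% names(origin_calls)) c("strain", "origin") else "origin"
  base <- if ("strain" %in% names(origin_calls)) {
    tidyr::expand_grid(strain = unique(origin_calls$strain), origin = levels)
  } else {
    tibble::tibble(origin = levels)
  }
  counts <- origin_calls |>
    dplyr::count(dplyr::across(dplyr::all_of(groups)), name = "n")
  dplyr::left_join(base, counts, by = groups) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L))
}
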