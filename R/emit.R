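#' Ground-truth marker genotypes of a simulated state
#'
#' Derives the true genotype of every constitutive marker from the
#' accumulated homogenizing intervals (LOH tracts, chromosome losses,
#' structural deletions) of a lineage state. A marker is heterozygous unless
#' covered by such an interval; the first covering interval decides the
#' retained haplotype (a region made homozygous once cannot lose
#' heterozygosity again).
#'
#' @param state One element of a [simulate_lineage()] `states` list.
#' @return Tibble with columns `chrom`, `pos`, `genotype`
#'   (`het`/`hom_p1`/`hom_p2`), `copy_number`, `p1_frac` (true parent-1
#'   allele fraction).
#' @export
marker_truth <- function(state) {
  map <- state$marker_map
  if (nrow(map) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          genotype = character(), copy_number = integer(),
                          p1_frac = numeric()))
  }
  gt_hap <- rep(NA_integer_, nrow(map))
  tr <- state$tracts
  if (nrow(tr) > 0L) {
    for (i in seq_len(nrow(tr))) {
      hit <- is.na(gt_hap) & map$chrom == tr$chrom[i] &
        map$pos >= tr$start[i] & map$pos <= tr$end[i]
      gt_hap[hit] <- tr$haplotype[i]
    }
  }
  cn <- state$chrom_cn[map$chrom]
  sv <- tr[tr$kind == "sv_deletion", , drop = FALSE]
  if (nrow(sv) > 0L) {
    for (i in seq_len(nrow(sv))) {
      hit <- map$chrom == sv$chrom[i] & map$pos >= sv$start[i] & map$pos <= sv$end[i]
      cn[hit] <- 1L
    }
  }
  genotype <- ifelse(is.na(gt_hap), "het",
                     ifelse(gt_hap == 1L, "hom_p1", "hom_p2"))
  dup <- state$hap_cn[map$chrom]
  p1_frac <- ifelse(genotype == "hom_p1", 1,
                    ifelse(genotype == "hom_p2", 0, 0.5))
  tris <- genotype == "het" & cn == 3L & !is.na(dup)
  p1_frac[tris] <- ifelse(dup[tris] == 1L, 2 / 3, 1 / 3)
  tibble::tibble(chrom = map$chrom, pos = map$pos, genotype = genotype,
                 copy_number = as.integer(unname(cn)), p1_frac = p1_frac)
}

#' Ground-truth copy-number segments of a simulated state
#'
#' @param state One element of a [simulate_lineage()] `states` list.
#' @return Tibble with `chrom`, `start`, `end`, `copy_number`
#'   (non-overlapping, covering each chromosome).
#' @export
cn_truth <- function(state) {
  genome <- state$genome
  sv <- state$tracts[state$tracts$kind == "sv_deletion", , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    ch <- genome$chrom[i]
    len <- genome$length[i]
    base <- state$chrom_cn[[ch]]
    cuts <- sv[sv$chrom == ch, , drop = FALSE]
    if (nrow(cuts) == 0L || base != 2L) {
      return(tibble::tibble(chrom = ch, start = 1L, end = as.integer(len),
                            copy_number = as.integer(base)))
    }
    iv <- merge_intervals(cuts$start, cuts$end)
    bounds <- sort(unique(c(1L, iv$start, iv$end + 1L, len + 1L)))
    bounds <- bounds[bounds <= len + 1L]
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L] - 1L
    in_del <- vapply(starts, function(s) any(iv$start <= s & iv$end >= s), logical(1))
    tibble::tibble(chrom = ch, start = as.integer(starts), end = as.integer(ends),
                   copy_number = ifelse(in_del, 1L, 2L))
  })
}

merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1L) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

local_copy_number <- function(state, chrom, pos) {
  cn <- unname(state$chrom_cn[chrom])
  sv <- state$tracts[state$tracts$kind == "sv_deletion", , drop = FALSE]
  if (nrow(sv) > 0L) {
    for (i in seq_len(nrow(sv))) {
      hit <- chrom == sv$chrom[i] & pos >= sv$start[i] & pos <= sv$end[i]
      cn[hit] <- 1L
    }
  }
  as.integer(cn)
}

#' Emit sequencing-like observables from a simulated state
#'
#' Converts the ground truth of one lineage state into the three tables the
#' analysis modules consume, adding depth sampling noise: per-variant total
#' depth ~ Poisson(`read_depth_mean` x local copy number / 2) and alt depth
#' ~ Binomial(depth, true allele fraction); marker allele depths likewise;
#' copy-number segments are reported exactly.
#'
#' @param state One element of a [simulate_lineage()] `states` list.
#' @param read_depth_mean Expected depth at a diploid locus (> 0).
#' @param seed Optional integer seed for the depth sampling.
#' @return List with tibbles `variants` (chrom, pos, ref, alt, ad_alt, dp,
#'   allele_fraction), `markers` (chrom, pos, p1_allele, p2_allele,
#'   depth_p1, depth_p2) and `cn` (chrom, start, end, copy_number).
#' @export
emit_observables <- function(state, read_depth_mean = 50, seed = NULL) {
  if (read_depth_mean <= 0) stop("read_depth_mean must be > 0")
  if (!is.null(seed)) set.seed(seed)

  v <- state$variants[state$variants$status %in% c("het", "hom"), , drop = FALSE]
  if (nrow(v) > 0L) {
    cn <- local_copy_number(state, v$chrom, v$pos)
    dup <- unname(state$hap_cn[v$chrom])
    af <- ifelse(v$status == "hom", 1, 0.5)
    tris <- v$status == "het" & cn == 3L & !is.na(dup)
    af[tris] <- ifelse(v$haplotype[tris] == dup[tris], 2 / 3, 1 / 3)
    dp <- stats::rpois(nrow(v), read_depth_mean * cn / 2)
    ad <- stats::rbinom(nrow(v), dp, af)
    vtab <- tibble::tibble(
      chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      ad_alt = ad, dp = dp,
      allele_fraction = ifelse(dp > 0, ad / dp, NA_real_)
    )
  } else {
    vtab <- tibble::tibble(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           ad_alt = integer(), dp = integer(),
                           allele_fraction = numeric())
  }

  mt <- marker_truth(state)
  if (nrow(mt) > 0L) {
    tot <- stats::rpois(nrow(mt), read_depth_mean * mt$copy_number / 2)
    d1 <- stats::rbinom(nrow(mt), tot, mt$p1_frac)
    mtab <- tibble::tibble(
      chrom = mt$chrom, pos = mt$pos,
      p1_allele = state$marker_map$p1_allele,
      p2_allele = state$marker_map$p2_allele,
      depth_p1 = d1, depth_p2 = tot - d1
    )
  } else {
    mtab <- tibble::tibble(chrom = character(), pos = integer(),
                           p1_allele = character(), p2_allele = character(),
                           depth_p1 = integer(), depth_p2 = integer())
  }

  list(variants = vtab, markers = mtab, cn = cn_truth(state))
}

#' Write observables to disk (minimal VCF + TSVs)
#'
#' Writes the variant table as a minimal VCF (`AD:DP:GT` FORMAT fields), the
#' marker allele-depth table and the copy-number segment table as TSV, and
#' optionally the ground-truth event log.
#'
#' @param obs Result of [emit_observables()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, e.g. `"clone01_p25"`.
#' @param events Optional event-log tibble to write alongside.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_observables <- function(obs, dir, prefix, events = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, paste0(prefix, ".vcf")),
    markers = file.path(dir, paste0(prefix, ".markers.tsv")),
    cn = file.path(dir, paste0(prefix, ".cn.tsv"))
  )
  write_minimal_vcf(obs$variants, paths[["vcf"]])
  readr::write_tsv(obs$markers, paths[["markers"]])
  readr::write_tsv(obs$cn, paths[["cn"]])
  if (!is.null(events)) {
    paths <- c(paths, events = file.path(dir, paste0(prefix, ".events.tsv")))
    readr::write_tsv(events, paths[["events"]])
  }
  invisible(paths)
}

write_minimal_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=mutaccum",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample"
  ), con)
  if (nrow(variants) > 0L) {
    af <- variants$allele_fraction
    gt <- ifelse(!is.na(af) & af >= 0.9, "1/1", "0/1")
    writeLines(sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD:DP:GT\t%d,%d:%d:%s",
      variants$chrom, variants$pos, variants$ref, variants$alt,
      variants$dp - variants$ad_alt, variants$ad_alt, variants$dp, gt
    ), con)
  }
  invisible(path)
}
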