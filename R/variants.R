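#' Read per-clone variant calls from a VCF
#'
#' Parses a VCF with per-sample `AD` and `DP` FORMAT fields into a tidy
#' variant table, one row per ALT allele, with the alt allele fraction
#' computed from the allelic depths.
#'
#' @param path Path to a VCF file (uncompressed or bgzipped).
#' @param sample Sample column to use (default: the first).
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `ad_alt`, `dp`,
#'   `allele_fraction`.
#' @export
read_variants <- function(path, sample = 1L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          ad_alt = integer(), dp = integer(),
                          allele_fraction = numeric()))
  }
  fmt <- unname(v@gt[, 1L])
  has_ad <- grepl("(^|:)AD(:|$)", fmt)
  has_dp <- grepl("(^|:)DP(:|$)", fmt)
  if (any(!has_ad) || any(!has_dp)) {
    bad <- which(!(has_ad & has_dp))[1]
    stop(sprintf("record %d (%s:%s) lacks AD/DP FORMAT fields",
                 bad, fix[bad, "CHROM"], fix[bad, "POS"]))
  }
  ad <- unname(vcfR::extract.gt(v, element = "AD")[, sample])
  dp <- as.integer(unname(vcfR::extract.gt(v, element = "DP")[, sample]))
  rows <- purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[[i, "ALT"]], ",", fixed = TRUE)[[1]]
    depths <- suppressWarnings(as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]]))
    if (anyNA(depths)) {
      stop(sprintf("malformed AD field at record %d (%s:%s)",
                   i, fix[[i, "CHROM"]], fix[[i, "POS"]]))
    }
    tibble::tibble(
      chrom = unname(fix[[i, "CHROM"]]), pos = as.integer(fix[[i, "POS"]]),
      ref = unname(fix[[i, "REF"]]), alt = unname(alts),
      ad_alt = depths[seq_along(alts) + 1L], dp = dp[i]
    )
  })
  dplyr::mutate(rows, allele_fraction = ifelse(dp > 0, ad_alt / dp, NA_real_))
}

#' Classify a variant by allele structure
#'
#' Assigns each ref/alt pair to one of `snp` (1-bp substitution), `mnp`
#' (equal-length multi-bp substitution), `indel` (pure length change below
#' the SV threshold; the anchored shorter allele is a prefix of the longer),
#' `complex` (combined substitution and length change) or `sv` (length
#' change of at least `sv_threshold` bp). The classification is total and
#' deterministic over all pairs with `ref != alt`.
#'
#' @param ref,alt Character vectors of reference and alternate alleles.
#' @param sv_threshold Minimum length change (bp) for class `sv`
#'   (default 50; small InDels observed in MA lines span 1-44 bp while the
#'   shortest structural deletions start at 62 bp, so 50 separates them).
#' @return Character vector of classes.
#' @export
#' @examples
#' classify_variant_class(c("C", "AT", "A"), c("T", "GC", "AAG"))
classify_variant_class <- function(ref, alt, sv_threshold = 50L) {
  stopifnot(length(ref) == length(alt))
  if (any(nchar(ref) == 0L | nchar(alt) == 0L)) stop("alleles must be nonempty")
  if (any(ref == alt)) stop("ref == alt is not a variant")
  nr <- nchar(ref); na <- nchar(alt)
  span <- abs(nr - na)
  shorter <- ifelse(nr <= na, ref, alt)
  longer <- ifelse(nr <= na, alt, ref)
  pure_len <- nr != na & substr(longer, 1L, nchar(shorter)) == shorter
  dplyr::case_when(
    nr == na & nr == 1L ~ "snp",
    nr == na ~ "mnp",
    pure_len & span >= sv_threshold ~ "sv",
    pure_len ~ "indel",
    span >= sv_threshold ~ "sv",
    TRUE ~ "complex"
  )
}

#' Call zygosity from allelic ratio and local copy number
#'
#' Classifies each variant as `heterozygous` (allelic ratio ~0.5 at copy
#' number 2), `homozygous` (allelic ratio ~1.0; also hemizygous calls at
#' copy number 1), `het_trisomic` (ratio near 1/3 or 2/3 at copy number 3)
#' or `unresolved` (insufficient depth or ambiguous ratio).
#'
#' @param variants Tibble with `chrom`, `pos`, `allele_fraction`, `dp`.
#' @param cn_segments Tibble with `chrom`, `start`, `end`, `copy_number`;
#'   every variant position must be covered by exactly one segment.
#' @param het_window Allelic-ratio window called heterozygous at copy
#'   number 2 (default `c(0.3, 0.7)`).
#' @param hom_threshold Minimum allelic ratio called homozygous
#'   (default 0.9).
#' @param min_depth Minimum total depth for a call (default 10); lower
#'   depth yields `unresolved`.
#' @param trisomic_tol Allelic-ratio tolerance around 1/3 and 2/3 at copy
#'   number 3 (default 0.12).
#' @return The input tibble with `copy_number` and `zygosity` columns added.
#' @export
classify_zygosity <- function(variants, cn_segments,
                              het_window = c(0.3, 0.7), hom_threshold = 0.9,
                              min_depth = 10L, trisomic_tol = 0.12) {
  if (nrow(variants) == 0L) {
    return(dplyr::mutate(variants, copy_number = integer(0), zygosity = character(0)))
  }
  cn <- lookup_cn(variants$chrom, variants$pos, cn_segments)
  if (anyNA(cn)) {
    i <- which(is.na(cn))[1]
    stop(sprintf("no covering copy-number segment for %s:%d",
                 variants$chrom[i], variants$pos[i]))
  }
  af <- variants$allele_fraction
  dp <- variants$dp
  zyg <- dplyr::case_when(
    is.na(af) | dp < min_depth ~ "unresolved",
    cn == 2L & af >= het_window[1] & af <= het_window[2] ~ "heterozygous",
    cn == 2L & af >= hom_threshold ~ "homozygous",
    cn == 3L & (abs(af - 1 / 3) <= trisomic_tol | abs(af - 2 / 3) <= trisomic_tol) ~ "het_trisomic",
    cn == 3L & af >= hom_threshold ~ "homozygous",
    cn == 1L & af >= hom_threshold ~ "homozygous",
    TRUE ~ "unresolved"
  )
  dplyr::mutate(variants, copy_number = cn, zygosity = zyg)
}

lookup_cn <- function(chrom, pos, cn_segments) {
  out <- rep(NA_integer_, length(chrom))
  for (ch in unique(chrom)) {
    seg <- cn_segments[cn_segments$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    if (nrow(seg) == 0L) next
    seg <- seg[order(seg$start), , drop = FALSE]
    j <- findInterval(pos[idx], seg$start)
    ok <- j >= 1L & pos[idx] <= seg$end[pmax(j, 1L)]
    out[idx[ok]] <- as.integer(seg$copy_number[j[ok]])
  }
  out
}

#' Annotate variants with the homopolymer tract they disturb
#'
#' For each variant, finds the maximal single-base run of the reference
#' containing or immediately adjacent to the variant span. Runs of at least
#' `min_tract` bp are reported (slippage-prone tracts); shorter or absent
#' runs yield `NA`.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param reference A [Biostrings::DNAStringSet] covering all loci.
#' @param min_tract Minimum tract length reported (default 4 bp).
#' @return The input tibble with `hp_unit`, `hp_start`, `hp_length` added.
#' @export
annotate_homopolymer <- function(variants, reference, min_tract = 4L) {
  n <- nrow(variants)
  unit <- rep(NA_character_, n)
  hstart <- rep(NA_integer_, n)
  hlen <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ch <- variants$chrom[i]
    if (!ch %in% names(reference)) stop("locus outside reference: ", ch)
    chlen <- Biostrings::width(reference[ch])
    lo <- variants$pos[i] - 1L
    hi <- variants$pos[i] + nchar(variants$ref[i])
    if (variants$pos[i] < 1L || variants$pos[i] > chlen) {
      stop(sprintf("locus outside reference: %s:%d", ch, variants$pos[i]))
    }
    w <- 64L
    repeat {
      ws <- max(1L, lo - w)
      we <- min(chlen, hi + w)
      s <- strsplit(as.character(Biostrings::subseq(reference[[ch]], ws, we)), "")[[1]]
      r <- rle(s)
      ends <- cumsum(r$lengths) + ws - 1L
      starts <- ends - r$lengths + 1L
      cand <- which(starts <= hi & ends >= lo & r$lengths >= min_tract)
      # re-scan wider if the best candidate might be clipped by the window
      clipped <- length(cand) > 0L &&
        any((starts[cand] == ws & ws > 1L) | (ends[cand] == we & we < chlen))
      if (!clipped || (ws == 1L && we == chlen)) {
        if (length(cand) > 0L) {
          best <- cand[which.max(r$lengths[cand])]
          unit[i] <- r$values[best]
          hstart[i] <- starts[best]
          hlen[i] <- r$lengths[best]
        }
        break
      }
      w <- w * 4L
    }
  }
  dplyr::mutate(variants, hp_unit = unit, hp_start = hstart, hp_length = hlen)
}

#' Annotate variants with coding status and premature stop codons
#'
#' Marks each variant as coding when its position falls inside a CDS
#' interval of the gene model, and flags substitutions (SNP/MNP) whose
#' codon change creates a stop codon upstream of the annotated stop.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param gene_model Tibble with `chrom`, `start`, `end`, `strand`
#'   (`+`/`-`), `frame` (0-2), e.g. from [make_gene_model()]. Each interval
#'   is a CDS whose in-frame length must be a multiple of 3.
#' @param reference A [Biostrings::DNAStringSet].
#' @return The input tibble with logical `coding` and `premature_stop`
#'   columns added.
#' @export
annotate_coding <- function(variants, gene_model, reference) {
  bad <- (gene_model$end - gene_model$start + 1L - gene_model$frame) %% 3L != 0L
  if (any(bad)) {
    stop("frame inconsistency in gene model: interval length minus frame not a multiple of 3 (row ",
         which(bad)[1], ")")
  }
  n <- nrow(variants)
  coding <- logical(n)
  pstop <- logical(n)
  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(n)) {
    pos <- variants$pos[i]
    g <- gene_model[gene_model$chrom == variants$chrom[i] &
                      gene_model$start <= pos & gene_model$end >= pos, , drop = FALSE]
    if (nrow(g) == 0L) next
    coding[i] <- TRUE
    vclass <- classify_variant_class(variants$ref[i], variants$alt[i])
    if (!vclass %in% c("snp", "mnp")) next
    g <- g[1L, ]
    chrseq <- reference[[variants$chrom[i]]]
    span <- nchar(variants$ref[i])
    alt_chars <- strsplit(variants$alt[i], "")[[1]]
    if (g$strand == "+") {
      cds_start <- g$start + g$frame
      n_codons <- (g$end - cds_start + 1L) %/% 3L
      off0 <- pos - cds_start
      off1 <- pos + span - 1L - cds_start
    } else {
      cds_end <- g$end - g$frame
      n_codons <- (cds_end - g$start + 1L) %/% 3L
      off0 <- cds_end - (pos + span - 1L)
      off1 <- cds_end - pos
    }
    for (ci in max(0L, off0 %/% 3L):min(n_codons - 1L, off1 %/% 3L)) {
      if (g$strand == "+") {
        c_start <- cds_start + 3L * ci
        c_end <- c_start + 2L
      } else {
        c_end <- cds_end - 3L * ci
        c_start <- c_end - 2L
      }
      fwd <- strsplit(as.character(Biostrings::subseq(chrseq, c_start, c_end)), "")[[1]]
      rel <- (c_start - pos + 1L):(c_start - pos + 3L) # indices into ref/alt span
      mut <- fwd
      keep <- rel >= 1L & rel <= span
      mut[keep] <- alt_chars[rel[keep]]
      fwd_str <- paste(fwd, collapse = "")
      mut_str <- paste(mut, collapse = "")
      if (g$strand == "-") {
        fwd_str <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd_str)))
        mut_str <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mut_str)))
      }
      if (!is.na(code[mut_str]) && code[mut_str] == "*" && code[fwd_str] != "*" &&
          ci < n_codons - 1L) {
        pstop[i] <- TRUE
      }
    }
  }
  dplyr::mutate(variants, coding = coding, premature_stop = pstop)
}

#' Call whole-chromosome aneuploidies from copy-number segments
#'
#' Reports a chromosome as aneuploid when at least `whole_chrom_fraction`
#' of its length carries a uniform copy number different from 2. Local
#' changes (e.g. a deletion inside an otherwise disomic chromosome) are not
#' reported.
#'
#' @param cn_segments Tibble with `chrom`, `start`, `end`, `copy_number`.
#' @param genome Tibble with `chrom`, `length`.
#' @param whole_chrom_fraction Minimum fraction at the aberrant copy number
#'   (default 0.9).
#' @param max_gap_fraction Maximum fraction of a chromosome allowed to be
#'   uncovered by segments (default 0.1); larger gaps are an error.
#' @return Tibble with `chrom` and `copy_number` for each aneuploid
#'   chromosome.
#' @export
call_aneuploidies <- function(cn_segments, genome, whole_chrom_fraction = 0.9,
                              max_gap_fraction = 0.1) {
  check_genome(genome)
  out <- list()
  for (i in seq_len(nrow(genome))) {
    ch <- genome$chrom[i]
    len <- as.numeric(genome$length[i])
    seg <- cn_segments[cn_segments$chrom == ch, , drop = FALSE]
    covered <- sum(as.numeric(seg$end) - as.numeric(seg$start) + 1)
    if (covered < (1 - max_gap_fraction) * len) {
      stop(sprintf("copy-number coverage gap on %s exceeds %.0f%% of its length",
                   ch, 100 * max_gap_fraction))
    }
    by_cn <- tapply(as.numeric(seg$end) - as.numeric(seg$start) + 1,
                    seg$copy_number, sum)
    aberrant <- by_cn[names(by_cn) != "2"]
    if (length(aberrant) > 0L && max(aberrant) >= whole_chrom_fraction * len) {
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = ch,
        copy_number = as.integer(names(aberrant)[which.max(aberrant)])
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(chrom = character(), copy_number = integer()))
  }
  dplyr::bind_rows(out)
}
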