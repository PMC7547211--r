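#' Nuclear chromosome lengths of the S. cerevisiae reference genome
#'
#' Returns the 16 nuclear chromosomes of the R64 reference assembly with
#' their lengths (total 12,071,326 bp, i.e. ~12.07 Mb haploid). This is the
#' default genome model for simulation and rate normalization; any
#' two-column `chrom`/`length` tibble can be used in its place.
#'
#' @return A tibble with columns `chrom` (character) and `length` (integer bp).
#' @export
#' @examples
#' yeast_genome()
yeast_genome <- function() {
  tibble::tibble(
    chrom = paste0("chr", c(
      "I", "II", "III", "IV", "V", "VI", "VII", "VIII",
      "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI"
    )),
    length = c(
      230218L, 813184L, 316620L, 1531933L, 576874L, 270161L, 1090940L,
      562643L, 439888L, 745751L, 666816L, 1078177L, 924431L, 784333L,
      1091291L, 948066L
    )
  )
}

check_genome <- function(genome) {
  stopifnot(is.data.frame(genome), all(c("chrom", "length") %in% names(genome)))
  if (nrow(genome) == 0L) stop("genome must contain at least one chromosome")
  if (any(genome$length <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(genome$chrom)) stop("duplicate chromosome ids in genome")
  genome
}

#' Build a constitutive marker map over a genome
#'
#' Places `n_markers` polymorphic marker positions across the genome,
#' allocated to chromosomes proportionally to their length (largest-remainder
#' rounding so the total is exact) and drawn uniformly without replacement
#' within each chromosome. With the default yeast genome and 53,523 markers
#' the mean spacing is ~218 bp, the density of the SK1-vs-BY polymorphism
#' map used to genotype hybrid diploids.
#'
#' @param genome Tibble with `chrom` and `length` columns.
#' @param n_markers Total number of markers to place (>= 0).
#' @param seed Optional integer seed for reproducible placement.
#' @return A tibble with columns `chrom` and `pos` (1-based bp), positions
#'   strictly increasing within each chromosome.
#' @export
#' @examples
#' make_marker_map(yeast_genome(), 1000, seed = 1)
make_marker_map <- function(genome, n_markers, seed = NULL) {
  check_genome(genome)
  stopifnot(length(n_markers) == 1L, n_markers >= 0)
  n_markers <- as.integer(n_markers)
  total <- sum(as.numeric(genome$length))
  if (n_markers > total) {
    stop("n_markers exceeds total genome length; cannot place distinct positions")
  }
  if (n_markers == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer()))
  }
  if (!is.null(seed)) set.seed(seed)

  # largest-remainder apportionment, capped at chromosome length
  quota <- n_markers * as.numeric(genome$length) / total
  alloc <- floor(quota)
  rem <- n_markers - sum(alloc)
  if (rem > 0) {
    order_frac <- order(quota - alloc, decreasing = TRUE)
    alloc[order_frac[seq_len(rem)]] <- alloc[order_frac[seq_len(rem)]] + 1
  }
  over <- alloc > genome$length
  if (any(over)) {
    excess <- sum(alloc[over] - genome$length[over])
    alloc[over] <- genome$length[over]
    room <- which(alloc < genome$length)
    for (i in room) {
      if (excess <= 0) break
      add <- min(excess, genome$length[i] - alloc[i])
      alloc[i] <- alloc[i] + add
      excess <- excess - add
    }
  }

  purrr::map2_dfr(seq_len(nrow(genome)), alloc, function(i, k) {
    tibble::tibble(
      chrom = genome$chrom[i],
      pos = sort(sample.int(genome$length[i], size = k))
    )
  })
}

#' Generate a random reference sequence for a genome
#'
#' Synthesizes an i.i.d. random nucleotide sequence per chromosome,
#' providing trinucleotide context and homopolymer structure for simulated
#' variants.
#'
#' @param genome Tibble with `chrom` and `length` columns.
#' @param seed Optional integer seed.
#' @param gc GC content in \[0, 1\] (default 0.38, yeast-like).
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
simulate_reference <- function(genome, seed = NULL, gc = 0.38) {
  check_genome(genome)
  stopifnot(gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(genome$length, function(len) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  names(seqs) <- genome$chrom
  Biostrings::DNAStringSet(seqs)
}

#' Annotate homopolymer runs of a reference sequence
#'
#' Finds all maximal single-base runs of at least `min_tract` bp. Used to
#' place slippage-prone simulated InDels and as the tract universe for
#' homopolymer annotation of observed variants.
#'
#' @param reference A [Biostrings::DNAStringSet].
#' @param min_tract Minimum run length in bp (default 4).
#' @return Tibble with columns `chrom`, `start`, `end`, `unit`, `tract_length`.
#' @export
homopolymer_runs <- function(reference, min_tract = 4L) {
  purrr::map_dfr(names(reference), function(ch) {
    r <- rle(strsplit(as.character(reference[[ch]]), "")[[1]])
    ends <- cumsum(r$lengths)
    keep <- r$lengths >= min_tract
    tibble::tibble(
      chrom = ch,
      start = (ends - r$lengths + 1L)[keep],
      end = ends[keep],
      unit = r$values[keep],
      tract_length = r$lengths[keep]
    )
  })
}

#' Generate a synthetic gene model covering a target coding fraction
#'
#' Lays down non-overlapping CDS intervals (lengths a multiple of 3,
#' alternating strand, frame 0) until approximately `cds_fraction` of the
#' genome is covered. A deliberately simple stand-in for a real annotation,
#' sufficient for coding-fraction accounting and premature-stop calling.
#'
#' @param genome Tibble with `chrom` and `length`.
#' @param cds_fraction Target fraction of the genome covered by CDS
#'   (default 0.765, the random expectation for the yeast genome).
#' @param mean_cds_length Mean CDS length in bp (default 1500).
#' @param seed Optional integer seed.
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`, `frame`,
#'   `gene_id` (1-based closed intervals).
#' @export
make_gene_model <- function(genome, cds_fraction = 0.765,
                            mean_cds_length = 1500, seed = NULL) {
  check_genome(genome)
  stopifnot(cds_fraction >= 0, cds_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  gid <- 0L
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    target <- cds_fraction * len
    covered <- 0
    pos <- 1L
    rows <- list()
    while (covered < target && pos < len - 30L) {
      gap_scale <- mean_cds_length * (1 - cds_fraction) / max(cds_fraction, 1e-9)
      gap <- 1L + stats::rpois(1, gap_scale)
      cds <- 3L * max(10L, stats::rpois(1, mean_cds_length / 3))
      start <- pos + gap
      end <- min(start + cds - 1L, len)
      end <- start + ((end - start + 1L) %/% 3L) * 3L - 1L
      if (end <= start) break
      gid <<- gid + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = genome$chrom[i], start = start, end = end,
        strand = if (gid %% 2L == 0L) "-" else "+", frame = 0L,
        gene_id = sprintf("gene%05d", gid)
      )
      covered <- covered + (end - start + 1L)
      pos <- end + 1L
    }
    dplyr::bind_rows(rows)
  })
}
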