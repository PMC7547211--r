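# Shared fixtures and independent brute-force oracles used across tests.

tiny_genome <- function(n = 3, len = 1e5) {
  tibble::tibble(chrom = paste0("chr", seq_len(n)), length = as.integer(len))
}

# random genotyped marker track (one chromosome)
random_track <- function(n, chrom = "chr1",
                         probs = c(het = 0.5, hom_p1 = 0.2, hom_p2 = 0.2,
                                   missing = 0.1)) {
  tibble::tibble(
    chrom = chrom,
    pos = sort(sample.int(n * 50L, n)),
    genotype = sample(names(probs), n, replace = TRUE, prob = probs)
  )
}

# exhaustive run-length scan over a genotype sequence; the reference
# implementation for LOH segmentation, written independently of segment_loh
oracle_segment_loh <- function(track, min_markers = 3L) {
  out <- list()
  for (ch in unique(track$chrom)) {
    d <- track[track$chrom == ch, ]
    g <- d$genotype[d$genotype != "missing"]
    p <- d$pos[d$genotype != "missing"]
    i <- 1L
    while (i <= length(g)) {
      if (g[i] %in% c("hom_p1", "hom_p2")) {
        j <- i
        while (j < length(g) && g[j + 1L] == g[i]) j <- j + 1L
        if (j - i + 1L >= min_markers) {
          out[[length(out) + 1L]] <- tibble::tibble(
            chrom = ch, start = p[i], end = p[j], n_markers = j - i + 1L,
            haplotype = sub("hom_", "", g[i]),
            length = as.numeric(p[j]) - p[i] + 1
          )
        }
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_markers = integer(),
                          haplotype = character(), length = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

# exact two-sided Mann-Whitney p-value by exhaustive enumeration of all
# C(m+n, m) group assignments of the pooled ranks (no ties assumed)
oracle_mann_whitney <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  u_all <- apply(combos, 2, function(idx) sum(ranks[idx]) - m * (m + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# brute-force character scan for the maximal homopolymer run touching a
# variant span (independent of annotate_homopolymer's windowed rle)
oracle_homopolymer <- function(seq_chars, pos, ref_len, min_tract = 4L) {
  lo <- pos - 1L
  hi <- pos + ref_len
  best <- NULL
  i <- 1L
  n <- length(seq_chars)
  while (i <= n) {
    j <- i
    while (j < n && seq_chars[j + 1L] == seq_chars[i]) j <- j + 1L
    run_len <- j - i + 1L
    if (run_len >= min_tract && i <= hi && j >= lo) {
      if (is.null(best) || run_len > best$len) {
        best <- list(unit = seq_chars[i], start = i, len = run_len)
      }
    }
    i <- j + 1L
  }
  best
}

# simple interval-overlap scan used to cross-check diff_loh and
# annotate_breakpoints
overlaps <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2
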