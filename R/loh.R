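#' Genotype constitutive markers from parental allele depths
#'
#' Calls each SK1/BY-style constitutive marker as heterozygous, homozygous
#' parent 1, homozygous parent 2 or missing from the parental allele depths:
#' parent-1 fraction at or above `hom_threshold` is `hom_p1`, at or below
#' `1 - hom_threshold` is `hom_p2`, within `het_window` is `het`; low total
#' depth or an intermediate fraction is `missing`.
#'
#' @param markers Tibble with `chrom`, `pos`, `depth_p1`, `depth_p2`,
#'   positions sorted increasing within each chromosome.
#' @param hom_threshold Homozygous parent-fraction threshold (default 0.9).
#' @param het_window Parent-1 fraction window called het (default
#'   `c(0.3, 0.7)`).
#' @param min_depth Minimum total depth for a call (default 10).
#' @return The input tibble with a `genotype` column
#'   (`het`/`hom_p1`/`hom_p2`/`missing`) added.
#' @export
call_marker_genotypes <- function(markers, hom_threshold = 0.9,
                                  het_window = c(0.3, 0.7), min_depth = 10L) {
  if (any(markers$depth_p1 < 0 | markers$depth_p2 < 0)) {
    stop("marker depths must be nonnegative")
  }
  unsorted <- markers |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = !is.unsorted(.data$pos, strictly = TRUE)) |>
    dplyr::filter(!.data$ok)
  if (nrow(unsorted) > 0L) {
    stop("marker positions not strictly increasing on ", unsorted$chrom[1])
  }
  tot <- markers$depth_p1 + markers$depth_p2
  f1 <- ifelse(tot > 0, markers$depth_p1 / tot, NA_real_)
  gt <- dplyr::case_when(
    tot < min_depth ~ "missing",
    f1 >= hom_threshold ~ "hom_p1",
    f1 <= 1 - hom_threshold ~ "hom_p2",
    f1 >= het_window[1] & f1 <= het_window[2] ~ "het",
    TRUE ~ "missing"
  )
  dplyr::mutate(markers, genotype = gt)
}

#' Segment a genotyped marker track into LOH regions
#'
#' Finds all maximal runs of at least `min_markers` consecutive homozygous
#' markers of the same parental haplotype. Missing markers are skipped and
#' do not interrupt a run (depth dropouts must not fragment a true tract);
#' a heterozygous marker, or a homozygous marker of the opposite haplotype,
#' breaks the run. Region coordinates span the first to the last marker of
#' the run.
#'
#' @param track Tibble from [call_marker_genotypes()] (columns `chrom`,
#'   `pos`, `genotype`).
#' @param min_markers Minimum markers per region (default 3, the
#'   three-consecutive-marker rule).
#' @return Tibble with columns `chrom`, `start`, `end`, `n_markers`,
#'   `haplotype` (`p1`/`p2`), `length` (`end - start + 1`), in coordinate
#'   order.
#' @export
#' @examples
#' track <- tibble::tibble(
#'   chrom = "chrI", pos = 1:6 * 100,
#'   genotype = c("het", "het", "hom_p2", "hom_p2", "hom_p2", "het")
#' )
#' segment_loh(track)
segment_loh <- function(track, min_markers = 3L) {
  out <- track |>
    dplyr::filter(.data$genotype != "missing") |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(function(d, key) {
      r <- rle(d$genotype)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values %in% c("hom_p1", "hom_p2") & r$lengths >= min_markers
      if (!any(keep)) return(NULL)
      tibble::tibble(
        chrom = key$chrom,
        start = d$pos[starts[keep]],
        end = d$pos[ends[keep]],
        n_markers = r$lengths[keep],
        haplotype = sub("hom_", "", r$values[keep])
      )
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_markers = integer(),
                          haplotype = character(), length = numeric()))
  }
  out |>
    dplyr::mutate(length = as.numeric(.data$end) - .data$start + 1) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Classify LOH regions as interstitial or terminal
#'
#' A region is terminal when its run includes the first or last informative
#' (non-missing) marker of its chromosome -- the hallmark of BIR or a single
#' cross-over extending to the chromosome end. All other regions are
#' interstitial (gene-conversion-like). "Terminal" is judged against
#' informative markers rather than sequence ends because subtelomeres are
#' marker-poor.
#'
#' @param regions Tibble from [segment_loh()].
#' @param track The genotyped track the regions were segmented from.
#' @return `regions` with a `kind` column (`interstitial`/`terminal`) added.
#' @export
classify_tract <- function(regions, track) {
  informative <- track[track$genotype != "missing", , drop = FALSE]
  bounds <- informative |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(first = min(.data$pos), last = max(.data$pos))
  out <- dplyr::left_join(regions, bounds, by = "chrom")
  if (anyNA(out$first)) {
    stop("region chromosome not found in track: ",
         out$chrom[which(is.na(out$first))[1]])
  }
  miss <- !(out$start %in% informative$pos) | !(out$end %in% informative$pos)
  if (any(miss)) stop("region boundaries do not match track markers")
  out |>
    dplyr::mutate(kind = ifelse(.data$start <= .data$first | .data$end >= .data$last,
                                "terminal", "interstitial")) |>
    dplyr::select(-"first", -"last")
}

#' Genome homozygosity fraction of a set of LOH regions
#'
#' @param regions Tibble with `chrom`, `start`, `end`, `haplotype`
#'   (non-overlapping within a chromosome).
#' @param genome Tibble with `chrom`, `length`.
#' @return One-row tibble: `fraction` (total LOH length / genome length)
#'   and the per-parental-haplotype split `fraction_p1`, `fraction_p2`.
#' @export
homozygosity_fraction <- function(regions, genome) {
  check_genome(genome)
  total <- sum(as.numeric(genome$length))
  if (nrow(regions) > 0L) {
    ov <- regions |>
      dplyr::group_by(.data$chrom) |>
      dplyr::arrange(.data$start, .by_group = TRUE) |>
      dplyr::summarise(bad = any(.data$start[-1] <= .data$end[-dplyr::n()]))
    if (any(ov$bad)) stop("overlapping LOH regions")
  }
  len <- as.numeric(regions$end) - regions$start + 1
  tibble::tibble(
    fraction = sum(len) / total,
    fraction_p1 = sum(len[regions$haplotype == "p1"]) / total,
    fraction_p2 = sum(len[regions$haplotype == "p2"]) / total
  )
}

#' LOH occurrence rate per clone per passage
#'
#' @param n_regions Total number of LOH regions observed (or a regions
#'   tibble, in which case its row count is used).
#' @param n_clones,n_passages Number of clones and passages per clone.
#' @return Events per clone per passage.
#' @export
loh_rate <- function(n_regions, n_clones, n_passages) {
  if (is.data.frame(n_regions)) n_regions <- nrow(n_regions)
  stopifnot(n_regions >= 0)
  if (n_clones * n_passages <= 0) stop("n_clones * n_passages must be > 0")
  n_regions / (n_clones * n_passages)
}

#' Annotate LOH breakpoints with nearby genomic features
#'
#' For each region edge (start and end), reports every feature interval
#' overlapping a window of +/- `window` bp around the breakpoint, or
#' `"none"`.
#'
#' @param regions Tibble with `chrom`, `start`, `end`.
#' @param features Tibble with `chrom`, `start`, `end`, `name`, sorted by
#'   position within chromosome.
#' @param window Half-width of the breakpoint window in bp (default 1000).
#' @return Long tibble: `region` (row index), `chrom`, `edge`
#'   (`start`/`end`), `breakpoint`, `feature`.
#' @export
annotate_breakpoints <- function(regions, features, window = 1000L) {
  if (nrow(regions) == 0L) {
    return(tibble::tibble(region = integer(), chrom = character(),
                          edge = character(), breakpoint = integer(),
                          feature = character()))
  }
  edges <- dplyr::bind_rows(
    tibble::tibble(region = seq_len(nrow(regions)), chrom = regions$chrom,
                   edge = "start", breakpoint = regions$start),
    tibble::tibble(region = seq_len(nrow(regions)), chrom = regions$chrom,
                   edge = "end", breakpoint = regions$end)
  )
  purrr::map_dfr(seq_len(nrow(edges)), function(i) {
    e <- edges[i, ]
    hit <- features$chrom == e$chrom &
      features$start <= e$breakpoint + window &
      features$end >= e$breakpoint - window
    tibble::tibble(
      region = e$region, chrom = e$chrom, edge = e$edge,
      breakpoint = e$breakpoint,
      feature = if (any(hit)) features$name[hit] else "none"
    )
  }) |>
    dplyr::arrange(.data$region, dplyr::desc(.data$edge))
}

#' Write LOH regions as BED6
#'
#' BED uses 0-based half-open coordinates; `name` carries the haplotype
#' and `score` the marker count (capped at 1000, the BED maximum).
#'
#' @param regions Tibble from [segment_loh()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_loh_bed <- function(regions, path) {
  bed <- data.frame(
    chrom = regions$chrom,
    start = regions$start - 1L,
    end = regions$end,
    name = regions$haplotype,
    score = pmin(regions$n_markers, 1000L),
    strand = "."
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
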