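#' Configuration for the MA-line forward simulator
#'
#' Bundles and validates all parameters of the diploid mutation-accumulation
#' simulation. Defaults reproduce a wild-type hybrid line: SNVs arrive as a
#' Poisson process at 1.8e-10 per nucleotide per generation over the diploid
#' genome with ~25 generations per single-cell bottleneck passage (~0.11 new
#' SNVs per clone per passage on the default genome), rare LOH events
#' (0.09 per clone per passage), and no structural variants or aneuploidies.
#'
#' @param genome Tibble with `chrom` and `length` columns
#'   (default [yeast_genome()]).
#' @param n_markers Number of constitutive het markers (default 53523).
#' @param generations_per_passage Mitotic generations per bottleneck passage
#'   (default 25).
#' @param n_passages Number of passages to simulate (default 25).
#' @param mu_snv SNV rate per nucleotide per generation (default 1.8e-10).
#' @param mu_indel InDel rate per nucleotide per generation (default 1e-11).
#' @param homopolymer_fraction Probability an InDel falls in a homopolymer
#'   tract (default 0.9).
#' @param sv_rate Structural-variant (deletion) events per clone per passage
#'   (default 0).
#' @param aneuploidy_rate Whole-chromosome gain/loss events per clone per
#'   passage (default 0).
#' @param loh_rate LOH events per clone per passage (default 0.09).
#' @param p_terminal Probability an LOH event is terminal (BIR-like,
#'   anchored at a chromosome end; default 0.2).
#' @param interstitial_length_dist,terminal_length_dist LOH tract length
#'   distributions, each `list(family, ...)` with family `"loguniform"`
#'   (`min`, `max` in bp) or `"fixed"` (`length` in bp). Defaults span the
#'   observed tract-length ranges: interstitial 17 bp to 846 kb, terminal
#'   55 bp to 1,079 kb.
#' @param sv_length_dist Deletion length distribution, same format
#'   (default log-uniform 62 bp to 59,200 bp).
#' @param read_depth_mean Expected sequencing depth for emitted observables
#'   (default 50).
#' @param reference Optional [Biostrings::DNAStringSet] matching `genome`;
#'   when supplied, simulated alleles are consistent with its sequence
#'   (needed for spectra and homopolymer-aware placement).
#' @param seed Integer base seed; lineage `i` uses stream `seed + i - 1`.
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_passages = 10, seed = 1)
sim_config <- function(genome = yeast_genome(),
                       n_markers = 53523L,
                       generations_per_passage = 25L,
                       n_passages = 25L,
                       mu_snv = 1.8e-10,
                       mu_indel = 1e-11,
                       homopolymer_fraction = 0.9,
                       sv_rate = 0,
                       aneuploidy_rate = 0,
                       loh_rate = 0.09,
                       p_terminal = 0.2,
                       interstitial_length_dist = list(family = "loguniform", min = 17, max = 846000),
                       terminal_length_dist = list(family = "loguniform", min = 55, max = 1079000),
                       sv_length_dist = list(family = "loguniform", min = 62, max = 59200),
                       read_depth_mean = 50,
                       reference = NULL,
                       seed = 1L) {
  check_genome(genome)
  rates <- c(mu_snv = mu_snv, mu_indel = mu_indel, sv_rate = sv_rate,
             aneuploidy_rate = aneuploidy_rate, loh_rate = loh_rate)
  if (any(rates < 0)) stop("all rates must be >= 0")
  probs <- c(homopolymer_fraction = homopolymer_fraction, p_terminal = p_terminal)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (generations_per_passage < 1) stop("generations_per_passage must be >= 1")
  if (n_passages < 1) stop("n_passages must be >= 1")
  if (n_markers < 0) stop("n_markers must be >= 0")
  if (read_depth_mean <= 0) stop("read_depth_mean must be > 0")
  for (d in list(interstitial_length_dist, terminal_length_dist, sv_length_dist)) {
    check_length_dist(d)
  }
  if (!is.null(reference)) {
    if (!all(genome$chrom %in% names(reference))) {
      stop("reference must contain every chromosome in the genome")
    }
  }
  structure(list(
    genome = genome, n_markers = as.integer(n_markers),
    generations_per_passage = as.integer(generations_per_passage),
    n_passages = as.integer(n_passages),
    mu_snv = mu_snv, mu_indel = mu_indel,
    homopolymer_fraction = homopolymer_fraction,
    sv_rate = sv_rate, aneuploidy_rate = aneuploidy_rate, loh_rate = loh_rate,
    p_terminal = p_terminal,
    interstitial_length_dist = interstitial_length_dist,
    terminal_length_dist = terminal_length_dist,
    sv_length_dist = sv_length_dist,
    read_depth_mean = read_depth_mean,
    reference = reference,
    seed = as.integer(seed)
  ), class = "sim_config")
}

check_length_dist <- function(d) {
  if (!is.list(d) || is.null(d$family)) stop("length distribution must be list(family, ...)")
  switch(d$family,
    loguniform = {
      if (is.null(d$min) || is.null(d$max) || d$min < 1 || d$max < d$min) {
        stop("loguniform length distribution needs 1 <= min <= max")
      }
    },
    fixed = {
      if (is.null(d$length) || d$length < 1) stop("fixed length distribution needs length >= 1")
    },
    stop("unknown length distribution family: ", d$family)
  )
  invisible(d)
}

draw_length <- function(d, n = 1L) {
  switch(d$family,
    loguniform = pmax(1L, as.integer(round(exp(stats::runif(n, log(d$min), log(d$max)))))),
    fixed = rep(as.integer(d$length), n)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosomes, %s bp haploid\n",
              nrow(x$genome), format(sum(as.numeric(x$genome$length)), big.mark = ",")))
  cat(sprintf("  markers: %d | passages: %d x %d generations\n",
              x$n_markers, x$n_passages, x$generations_per_passage))
  cat(sprintf("  mu_snv: %.3g /nt/gen | mu_indel: %.3g /nt/gen\n", x$mu_snv, x$mu_indel))
  cat(sprintf("  loh_rate: %.3g /clone/passage (p_terminal %.2f) | sv: %.3g | aneuploidy: %.3g\n",
              x$loh_rate, x$p_terminal, x$sv_rate, x$aneuploidy_rate))
  cat(sprintf("  read depth: %.1fx | seed: %d\n", x$read_depth_mean, x$seed))
  invisible(x)
}
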