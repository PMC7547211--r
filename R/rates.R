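#' Mean mutations per clone per passage
#'
#' Normalizes per-clone mutation counts by each clone's number of passages
#' and averages across clones; the standard error is the sample SD of the
#' per-clone normalized rates over `sqrt(n_clones)`.
#'
#' @param counts Integer vector, one mutation count per clone.
#' @param passages Number of passages per clone (length 1 or same length
#'   as `counts`; all > 0).
#' @return One-row tibble: `mean`, `se` (`NA` for a single clone),
#'   `n_clones`.
#' @export
#' @examples
#' per_clone_per_passage(c(10, 12), 100)
per_clone_per_passage <- function(counts, passages) {
  if (length(passages) == 1L) passages <- rep(passages, length(counts))
  stopifnot(length(passages) == length(counts))
  if (any(passages <= 0)) stop("passages must be > 0")
  r <- counts / passages
  tibble::tibble(
    mean = mean(r),
    se = if (length(r) > 1L) stats::sd(r) / sqrt(length(r)) else NA_real_,
    n_clones = length(r)
  )
}

#' Convert a per-clone-per-passage rate to per nucleotide per generation
#'
#' `rate_pcp / (diploid_genome_length * generations_per_passage)`: e.g.
#' 0.11 mutations per clone per passage on a 2 x 12.07 Mb diploid genome at
#' 25 generations per passage is 1.8e-10 per nucleotide per generation.
#'
#' @param rate_pcp Mutations per clone per passage.
#' @param diploid_genome_length Diploid callable genome length in
#'   nucleotides (default `2 * 12071326`).
#' @param generations_per_passage Generations per bottleneck passage
#'   (default 25).
#' @return Rate per nucleotide per generation.
#' @export
#' @examples
#' per_nt_per_generation(0.11)
per_nt_per_generation <- function(rate_pcp,
                                  diploid_genome_length = 2 * 12071326,
                                  generations_per_passage = 25) {
  if (diploid_genome_length <= 0 || generations_per_passage <= 0) {
    stop("genome length and generations per passage must be > 0")
  }
  rate_pcp / (diploid_genome_length * generations_per_passage)
}

#' @rdname per_nt_per_generation
#' @param rate_nt Rate per nucleotide per generation.
#' @export
per_clone_per_passage_rate <- function(rate_nt,
                                       diploid_genome_length = 2 * 12071326,
                                       generations_per_passage = 25) {
  if (diploid_genome_length <= 0 || generations_per_passage <= 0) {
    stop("genome length and generations per passage must be > 0")
  }
  rate_nt * diploid_genome_length * generations_per_passage
}

#' Mutational fold change of a strain versus a reference
#'
#' @param strain_rate,wt_rate Nonnegative rates; `wt_rate` must be > 0.
#' @return `strain_rate / wt_rate`.
#' @export
fold_change <- function(strain_rate, wt_rate) {
  if (any(wt_rate <= 0)) stop("wt_rate must be > 0")
  strain_rate / wt_rate
}

#' Compare per-clone mutation rates of two strains
#'
#' Two-sided Mann-Whitney-Wilcoxon rank-sum test: exact when both groups
#' have at most 20 untied observations, normal approximation with
#' continuity and tie correction otherwise.
#'
#' @param rates_a,rates_b Numeric vectors of per-clone normalized rates
#'   (at least one observation each; >= 3 recommended).
#' @return The two-sided p-value.
#' @export
compare_strains <- function(rates_a, rates_b) {
  if (length(rates_a) == 0L || length(rates_b) == 0L) {
    stop("both groups must be nonempty")
  }
  has_ties <- anyDuplicated(c(rates_a, rates_b)) > 0L
  use_exact <- length(rates_a) <= 20L && length(rates_b) <= 20L && !has_ties
  stats::wilcox.test(rates_a, rates_b, alternative = "two.sided",
                     exact = use_exact, correct = TRUE)$p.value
}

#' Ma-Sandri-Sarkar mutant-count distribution
#'
#' Probability mass `P(k; m)` of observing `k` mutant colonies in a
#' Luria-Delbruck fluctuation culture with `m` expected mutations per
#' culture, by the Ma-Sandri-Sarkar recursion:
#' `P(0) = exp(-m)`; `P(k) = (m / k) * sum_{j=0}^{k-1} P(j) / (k - j + 1)`.
#'
#' @param k_max Largest count to evaluate.
#' @param m Expected mutations per culture (>= 0).
#' @return Numeric vector of `P(0..k_max; m)`.
#' @export
mss_prob <- function(k_max, m) {
  stopifnot(m >= 0, k_max >= 0)
  p <- numeric(k_max + 1L)
  p[1] <- exp(-m)
  if (k_max >= 1L) {
    for (k in seq_len(k_max)) {
      j <- 0:(k - 1L)
      p[k + 1L] <- (m / k) * sum(p[j + 1L] / (k - j + 1L))
    }
  }
  p
}

#' Sample mutant counts from the Luria-Delbruck (MSS) distribution
#'
#' @param n Number of cultures.
#' @param m Expected mutations per culture.
#' @param k_max Truncation point for the inverse-CDF sampling (default
#'   chosen so the truncated tail is negligible for moderate `m`).
#' @return Integer vector of mutant counts.
#' @export
rmss <- function(n, m, k_max = max(200L, ceiling(50 * max(m, 1)))) {
  p <- mss_prob(k_max, m)
  p <- p / sum(p)
  sample(0:k_max, n, replace = TRUE, prob = p)
}

#' Estimate a mutation rate from a fluctuation test
#'
#' Maximum-likelihood estimation of `m`, the expected number of mutations
#' per culture, under the Luria-Delbruck mutant-count distribution computed
#' by the Ma-Sandri-Sarkar recursion, with a profile-likelihood 95%
#' confidence interval. The per-generation per-cell mutation rate is
#' `m / N_t`. When only a fraction of each culture is plated, `m` is
#' corrected by Stewart's efficiency factor
#' `(e - 1) / (e * log(e))` (an approximation; exact plating-fraction
#' likelihoods differ slightly).
#'
#' @param counts Integer vector of mutant colony counts, one per culture
#'   (>= 2 cultures).
#' @param N_t Final population size per culture (> 0).
#' @param plating_fraction Fraction of each culture plated (default 1).
#' @param conf_level Confidence level for the profile interval
#'   (default 0.95).
#' @return Object of class `"fluctuation_fit"`: list with `m`, `m_ci`,
#'   `rate`, `rate_ci`, `N_t`, `counts`, `plating_fraction`, `logLik`.
#' @export
estimate_fluctuation_rate <- function(counts, N_t, plating_fraction = 1,
                                      conf_level = 0.95) {
  if (length(counts) < 2L) stop("at least 2 cultures are required")
  if (any(counts < 0)) stop("mutant counts must be nonnegative")
  if (N_t <= 0) stop("N_t must be > 0")
  if (plating_fraction <= 0 || plating_fraction > 1) {
    stop("plating_fraction must be in (0, 1]")
  }
  kmax <- max(counts)
  ll <- function(m) {
    if (m <= 0) return(if (all(counts == 0)) 0 else -Inf)
    p <- mss_prob(kmax, m)
    p <- pmax(p, 1e-300)
    sum(log(p[counts + 1L]))
  }
  crit <- stats::qchisq(conf_level, df = 1) / 2

  if (all(counts == 0)) {
    # boundary: likelihood maximized at m = 0; one-sided upper limit from
    # P(all zero) = exp(-n m)
    upper <- -log(1 - conf_level) / length(counts)
    m_hat <- 0
    m_ci <- c(0, upper)
    ll_max <- 0
  } else {
    opt <- stats::optimize(function(lm) ll(exp(lm)),
                           interval = c(log(1e-4), log(kmax + 10)),
                           maximum = TRUE, tol = 1e-9)
    m_hat <- exp(opt$maximum)
    ll_max <- opt$objective
    f <- function(m) ll(m) - (ll_max - crit)
    lo <- if (f(1e-6) < 0) {
      stats::uniroot(f, c(1e-6, m_hat), tol = 1e-8)$root
    } else 0
    hi_bound <- m_hat
    while (f(hi_bound) > 0 && hi_bound < 1e4) hi_bound <- hi_bound * 2
    hi <- stats::uniroot(f, c(m_hat, hi_bound), tol = 1e-8)$root
    m_ci <- c(lo, hi)
  }
  if (plating_fraction < 1) {
    e <- plating_fraction
    corr <- (e - 1) / (e * log(e))
    m_hat <- m_hat * corr
    m_ci <- m_ci * corr
  }
  structure(list(
    m = m_hat, m_ci = m_ci,
    rate = m_hat / N_t, rate_ci = m_ci / N_t,
    N_t = N_t, counts = counts, plating_fraction = plating_fraction,
    logLik = ll_max
  ), class = "fluctuation_fit")
}

#' @export
print.fluctuation_fit <- function(x, ...) {
  cat(sprintf("<fluctuation_fit> m = %.3f [%.3f, %.3f] | rate = %.3g [%.3g, %.3g] per cell per generation (%d cultures)\n",
              x$m, x$m_ci[1], x$m_ci[2], x$rate, x$rate_ci[1], x$rate_ci[2],
              length(x$counts)))
  invisible(x)
}

#' @rdname estimate_fluctuation_rate
#' @param x A `fluctuation_fit` object.
#' @param ... Unused.
#' @export
tidy.fluctuation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("m", "rate"),
    estimate = c(x$m, x$rate),
    conf.low = c(x$m_ci[1], x$rate_ci[1]),
    conf.high = c(x$m_ci[2], x$rate_ci[2])
  )
}

#' @rdname estimate_fluctuation_rate
#' @export
glance.fluctuation_fit <- function(x, ...) {
  tibble::tibble(
    n_cultures = length(x$counts),
    n_zero = sum(x$counts == 0),
    median_count = stats::median(x$counts),
    N_t = x$N_t,
    logLik = x$logLik
  )
}

#' Aggregate mutation rates across fluctuation tests
#'
#' @param rates Numeric vector of per-test rate estimates (>= 1).
#' @return One-row tibble: `mean`, `sd` (`NA` for a single test),
#'   `n_tests`.
#' @export
aggregate_rate_tests <- function(rates) {
  if (length(rates) < 1L) stop("at least one test is required")
  tibble::tibble(
    mean = mean(rates),
    sd = if (length(rates) > 1L) stats::sd(rates) else NA_real_,
    n_tests = length(rates)
  )
}

#' Strain-level rate summary table
#'
#' Builds a per-strain summary of mutation burden from a per-clone table:
#' per-class counts, the mean mutations per clone per passage with its SE,
#' the fold change versus a reference strain, and a Mann-Whitney p-value
#' for the comparison.
#'
#' @param clone_table Tibble with one row per clone: `strain`, `clone`,
#'   `n_passages`, `n_mutations` (total count for the clone).
#' @param reference Strain label used as the comparison baseline
#'   (default `"WT"`).
#' @return Tibble with one row per strain: `strain`, `n_clones`,
#'   `n_mutations`, `mean_per_clone_passage`, `se`, `fold_change`,
#'   `p_value` (`NA` for the reference itself).
#' @export
strain_rate_summary <- function(clone_table, reference = "WT") {
  stopifnot(all(c("strain", "n_passages", "n_mutations") %in% names(clone_table)))
  if (!reference %in% clone_table$strain) {
    stop("reference strain not present: ", reference)
  }
  clone_table <- dplyr::mutate(clone_table,
                               rate = .data$n_mutations / .data$n_passages)
  per_strain <- clone_table |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(
      n_clones = dplyr::n(),
      mean_per_clone_passage = mean(.data$rate),
      se = if (dplyr::n() > 1L) {
        stats::sd(.data$rate) / sqrt(dplyr::n())
      } else NA_real_,
      n_mutations = sum(.data$n_mutations)
    )
  wt <- dplyr::filter(clone_table, .data$strain == reference)
  wt_mean <- mean(wt$rate)
  per_strain |>
    dplyr::rowwise() |>
    dplyr::mutate(
      fold_change = if (wt_mean > 0) .data$mean_per_clone_passage / wt_mean else NA_real_,
      p_value = if (.data$strain == reference) NA_real_ else {
        this <- clone_table$n_mutations[clone_table$strain == .data$strain] /
          clone_table$n_passages[clone_table$strain == .data$strain]
        compare_strains(this, wt$rate)
      }
    ) |>
    dplyr::ungroup()
}
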