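#' The 96 pyrimidine-strand trinucleotide substitution contexts
#'
#' Fixed index order for all spectra in the package: lexicographic by
#' substitution (`C>A`, `C>G`, `C>T`, `T>A`, `T>C`, `T>G`), then 5' base
#' (`A`, `C`, `G`, `T`), then 3' base, in `"A[C>A]A"` notation.
#'
#' @return Character vector of length 96.
#' @export
contexts_96 <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) for (b5 in bases) for (b3 in bases) {
    out <- c(out, sprintf("%s[%s]%s", b5, s, b3))
  }
  out
}

#' Build a 96-context base-substitution spectrum
#'
#' Counts SNVs over the 96 trinucleotide contexts. Substitutions with a
#' purine reference base (A or G) are reverse-complemented together with
#' their context onto the pyrimidine strand, the standard collapse used for
#' mutational-signature analysis. SNVs at a contig edge (no flanking base)
#' are excluded; their number is attached as attribute `n_excluded` and
#' reported with a warning.
#'
#' @param snvs Tibble with `chrom`, `pos`, `ref`, `alt` (class `snp` only:
#'   single-base ref and alt).
#' @param reference A [Biostrings::DNAStringSet] covering the loci.
#' @return Tibble of class `"spectrum_96"` with columns `context` (the
#'   fixed 96 contexts, in order) and `count`.
#' @export
build_96_spectrum <- function(snvs, reference) {
  stopifnot(all(nchar(snvs$ref) == 1L), all(nchar(snvs$alt) == 1L))
  ctx <- contexts_96()
  counts <- stats::setNames(rep(0L, 96L), ctx)
  n_excluded <- 0L
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (ch in unique(snvs$chrom)) {
    if (!ch %in% names(reference)) stop("chromosome absent from reference: ", ch)
    seq_ch <- as.character(reference[[ch]])
    chlen <- nchar(seq_ch)
    d <- snvs[snvs$chrom == ch, , drop = FALSE]
    edge <- d$pos <= 1L | d$pos >= chlen
    n_excluded <- n_excluded + sum(edge)
    d <- d[!edge, , drop = FALSE]
    if (nrow(d) == 0L) next
    tri <- substring(seq_ch, d$pos - 1L, d$pos + 1L)
    refb <- d$ref
    altb <- d$alt
    pur <- refb %in% c("A", "G")
    if (any(pur)) {
      rc <- function(s) {
        vapply(strsplit(s, ""), function(x) paste(rev(unname(comp[x])), collapse = ""),
               character(1))
      }
      tri[pur] <- rc(tri[pur])
      refb[pur] <- comp[refb[pur]]
      altb[pur] <- comp[altb[pur]]
    }
    lab <- sprintf("%s[%s>%s]%s", substr(tri, 1, 1), refb, altb, substr(tri, 3, 3))
    tab <- table(lab)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  if (n_excluded > 0L) {
    warning(n_excluded, " SNV(s) at contig edges excluded from the spectrum")
  }
  out <- tibble::tibble(context = ctx, count = as.integer(unname(counts)))
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("spectrum_96", class(out))
  out
}

spectrum_counts <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("context", "count") %in% names(x)))
    x <- x[match(contexts_96(), x$context), ]
    as.numeric(x$count)
  } else {
    as.numeric(x)
  }
}

#' Cosine similarity between two spectra
#'
#' @param a,b Spectra as `spectrum_96` tibbles or plain nonnegative numeric
#'   vectors of equal length; neither may be all zero.
#' @return `dot(a, b) / (|a| |b|)`, in \[0, 1\] for nonnegative input.
#' @export
cosine_similarity <- function(a, b) {
  va <- spectrum_counts(a)
  vb <- spectrum_counts(b)
  stopifnot(length(va) == length(vb))
  na <- sqrt(sum(va^2))
  nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero spectrum")
  sum(va * vb) / (na * nb)
}

#' Non-negative least squares by Lawson-Hanson active set
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0`. The solution satisfies
#' the KKT conditions: the gradient `A'(b - A x)` is `<= 0` on coordinates
#' at zero and zero on positive coordinates (up to numerical tolerance).
#'
#' @param A Numeric matrix (m x n).
#' @param b Numeric vector of length m.
#' @param tol Dual-feasibility tolerance (default based on machine
#'   precision and problem scale).
#' @return List with `x` (the solution), `residual_norm` and `iterations`.
#' @export
nnls <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * max(m, n)
  x <- rep(0, n)
  passive <- rep(FALSE, n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  max_iter <- 30L * n
  while (any(!passive) && max(w[!passive]) > tol && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- rep(0, n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  list(x = x, residual_norm = sqrt(sum((b - A %*% x)^2)), iterations = iter)
}

#' Refit a spectrum as a non-negative combination of signatures
#'
#' Estimates the contribution of each signature to an observed 96-context
#' spectrum by non-negative least squares: contributions minimize
#' `||M x - spectrum||_2` subject to `x >= 0`, where `M` is the
#' column-normalized signature matrix. Deterministic for a given input; no
#' sparsity penalty or signature preselection is applied.
#'
#' @param spectrum A `spectrum_96` tibble or numeric vector of 96 counts
#'   (must not be all zero).
#' @param signature_matrix Numeric 96 x S matrix of signature
#'   probabilities, columns summing to 1 (within 1e-6), with column names;
#'   e.g. from [read_signature_matrix()] or
#'   [synthetic_signature_matrix()].
#' @return Object of class `"signature_fit"`: list with `contribution`
#'   (named, absolute mutation counts attributed), `relative`
#'   (`contribution / sum`), `fitted` (reconstructed spectrum),
#'   `residual_norm`, `cosine` (reconstruction vs input), `spectrum`.
#' @export
fit_signatures <- function(spectrum, signature_matrix) {
  y <- spectrum_counts(spectrum)
  M <- as.matrix(signature_matrix)
  stopifnot(nrow(M) == length(y))
  if (sum(y) == 0) stop("empty spectrum")
  colsum <- colSums(M)
  if (any(abs(colsum - 1) > 1e-6)) {
    stop("signature matrix columns must each sum to 1 (+/- 1e-6)")
  }
  sol <- nnls(M, y)
  contribution <- stats::setNames(sol$x, colnames(M))
  fitted <- drop(M %*% sol$x)
  structure(list(
    contribution = contribution,
    relative = if (sum(sol$x) > 0) contribution / sum(sol$x) else contribution,
    fitted = fitted,
    residual_norm = sol$residual_norm,
    cosine = if (sum(fitted) > 0) cosine_similarity(y, fitted) else NA_real_,
    spectrum = y
  ), class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat(sprintf("<signature_fit> %d signatures | cosine %.4f | residual %.3f\n",
              length(x$contribution), x$cosine, x$residual_norm))
  top <- sort(x$relative[x$relative > 0.005], decreasing = TRUE)
  if (length(top) > 0) {
    cat("  ", paste(sprintf("%s: %.1f%%", names(top), 100 * top),
                    collapse = " | "), "\n")
  }
  invisible(x)
}

#' @rdname fit_signatures
#' @param x A `signature_fit` object.
#' @param ... Unused.
#' @export
tidy.signature_fit <- function(x, ...) {
  tibble::tibble(
    signature = names(x$contribution),
    contribution = unname(x$contribution),
    relative = unname(x$relative)
  )
}

#' @rdname fit_signatures
#' @export
glance.signature_fit <- function(x, ...) {
  tibble::tibble(
    n_mutations = sum(x$spectrum),
    n_signatures = length(x$contribution),
    n_active = sum(x$contribution > 0),
    residual_norm = x$residual_norm,
    cosine = x$cosine
  )
}

#' Read a signature matrix from TSV
#'
#' Expects a first column of 96 context labels in `"A[C>A]A"` notation and
#' one column per signature; rows are reordered to the package's fixed
#' context order and columns are checked to sum to 1.
#'
#' @param path TSV file path.
#' @return Numeric 96 x S matrix with context rownames.
#' @export
read_signature_matrix <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  ctx <- contexts_96()
  lab <- d[[1]]
  if (!setequal(lab, ctx)) stop("first column must contain the 96 context labels")
  M <- as.matrix(d[match(ctx, lab), -1, drop = FALSE])
  rownames(M) <- ctx
  colsum <- colSums(M)
  if (any(abs(colsum - 1) > 1e-6)) {
    stop("signature columns must each sum to 1 (+/- 1e-6)")
  }
  M
}

#' Generate a synthetic signature matrix
#'
#' Produces a column-normalized 96 x `n_signatures` matrix of synthetic
#' signature profiles (sparse Dirichlet-like columns concentrated on a few
#' contexts, so the columns are well separated). Intended for simulation
#' and testing; for real analyses supply a published signature catalog via
#' [read_signature_matrix()].
#'
#' @param n_signatures Number of signature columns (default 8).
#' @param seed Optional integer seed.
#' @param concentration Gamma shape controlling sparsity (default 0.1;
#'   smaller is sparser).
#' @return Numeric 96 x S matrix, columns `sig1` ... `sigS` summing to 1.
#' @export
synthetic_signature_matrix <- function(n_signatures = 8L, seed = NULL,
                                       concentration = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(stats::rgamma(96L * n_signatures, shape = concentration, rate = 1),
              nrow = 96L)
  M <- sweep(M, 2, colSums(M), "/")
  rownames(M) <- contexts_96()
  colnames(M) <- paste0("sig", seq_len(n_signatures))
  M
}

#' Bar plot of a 96-context spectrum
#'
#' Standard mutational-profile layout: one bar per trinucleotide context,
#' faceted and coloured by the six pyrimidine substitutions.
#'
#' @param spectrum A `spectrum_96` tibble (or tibble with `context`,
#'   `count`).
#' @param relative Plot fractions instead of counts (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum, relative = FALSE) {
  d <- tibble::as_tibble(spectrum) |>
    dplyr::mutate(
      substitution = sub(".*\\[(.*)\\].*", "\\1", .data$context),
      context = factor(.data$context, levels = contexts_96()),
      y = if (relative) .data$count / max(sum(.data$count), 1) else .data$count
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$context, y = .data$y,
                                  fill = .data$substitution)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(. ~ substitution, scales = "free_x") +
    ggplot2::labs(x = NULL, y = if (relative) "fraction" else "count") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 4))
}

#' @rdname fit_signatures
#' @param object A `signature_fit` object.
#' @export
autoplot.signature_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$signature, y = .data$relative)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "relative contribution") +
    ggplot2::theme_minimal()
}
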