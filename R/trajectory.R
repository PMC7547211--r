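#' Build per-variant trajectories across consecutive passages
#'
#' Tracks every distinct variant (keyed by chromosome, position, ref, alt)
#' across the passages of one lineage and derives its per-passage status
#' (`absent`, `heterozygous`, `homozygous`, `het_trisomic`) together with
#' fixation and elimination events. A variant missing at up to
#' `dropout_tolerance` consecutive intermediate passages but present before
#' and after is imputed present with its previous status (single-passage
#' sequencing dropouts must not look like elimination followed by
#' re-mutation).
#'
#' Events: a *fixation* at passage `p` is a het (or het_trisomic) status at
#' `p - 1` turning homozygous at `p`; an *elimination* at passage `p` is a
#' present variant at `p - 1` that is absent from `p` onward.
#'
#' @param calls Tibble of per-passage variant calls with columns `passage`,
#'   `chrom`, `pos`, `ref`, `alt`, `zygosity` (from [classify_zygosity()];
#'   values `heterozygous`, `homozygous`, `het_trisomic`). Passages must be
#'   consecutive integers.
#' @param dropout_tolerance Maximum imputed consecutive missing passages
#'   (default 1).
#' @param passages Integer vector of all surveyed passages (consecutive).
#'   Defaults to the range present in `calls`; supply it explicitly when
#'   trailing passages carry no variant calls at all, otherwise an
#'   elimination in the last surveyed passages cannot be seen.
#' @return List of class `"ma_trajectories"` with elements `status` (long
#'   tibble: `variant`, `passage`, `status`), `events` (tibble: `variant`,
#'   `chrom`, `pos`, `ref`, `alt`, `kind`, `passage`) and `passages` (the
#'   passage range).
#' @export
build_trajectories <- function(calls, dropout_tolerance = 1L,
                               passages = NULL) {
  if (is.null(passages)) passages <- sort(unique(calls$passage))
  passages <- as.integer(passages)
  if (length(passages) == 0L) stop("no calls supplied")
  if (!identical(passages, seq(min(passages), max(passages)))) {
    stop("passages must be consecutive")
  }
  if (!all(calls$passage %in% passages)) {
    stop("calls contain passages outside the surveyed range")
  }
  zmap <- c(heterozygous = "heterozygous", homozygous = "homozygous",
            het_trisomic = "het_trisomic")
  calls <- calls |>
    dplyr::filter(.data$zygosity %in% names(zmap)) |>
    dplyr::mutate(variant = paste(.data$chrom, .data$pos, .data$ref,
                                  .data$alt, sep = ":"))

  keys <- dplyr::distinct(calls, .data$variant, .data$chrom, .data$pos,
                          .data$ref, .data$alt)
  grid <- tidyr::expand_grid(variant = keys$variant, passage = passages) |>
    dplyr::left_join(dplyr::select(calls, "variant", "passage", "zygosity"),
                     by = c("variant", "passage")) |>
    dplyr::mutate(status = unname(dplyr::coalesce(zmap[.data$zygosity], "absent"))) |>
    dplyr::select(-"zygosity")

  status <- grid |>
    dplyr::group_by(.data$variant) |>
    dplyr::arrange(.data$passage, .by_group = TRUE) |>
    dplyr::group_modify(~ impute_dropouts(.x, dropout_tolerance)) |>
    dplyr::ungroup()

  events <- status |>
    dplyr::group_by(.data$variant) |>
    dplyr::arrange(.data$passage, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      s <- d$status
      present <- s != "absent"
      if (!any(present)) return(tibble::tibble())
      born <- which(present)[1]
      out <- list()
      fix <- which(s[-1] == "homozygous" &
                     s[-length(s)] %in% c("heterozygous", "het_trisomic")) + 1L
      if (length(fix) > 0L) {
        out[[1]] <- tibble::tibble(kind = "fixation", passage = d$passage[fix[1]])
      }
      last_present <- max(which(present))
      if (last_present < length(s) && last_present >= born) {
        out[[length(out) + 1L]] <- tibble::tibble(
          kind = "elimination", passage = d$passage[last_present + 1L]
        )
      }
      dplyr::bind_rows(out)
    }) |>
    dplyr::ungroup()
  if (!"kind" %in% names(events)) {
    events <- tibble::tibble(variant = character(), kind = character(),
                             passage = integer())
  }
  events <- events |>
    dplyr::left_join(keys, by = "variant") |>
    dplyr::select("variant", "chrom", "pos", "ref", "alt", "kind", "passage")

  structure(list(status = status, events = events, passages = passages),
            class = "ma_trajectories")
}

impute_dropouts <- function(d, tol) {
  s <- d$status
  if (tol > 0L) {
    r <- rle(s == "absent")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] && r$lengths[k] <= tol &&
          starts[k] > 1L && ends[k] < length(s)) {
        s[starts[k]:ends[k]] <- s[starts[k] - 1L]
      }
    }
  }
  d$status <- s
  d
}

#' @export
print.ma_trajectories <- function(x, ...) {
  cat(sprintf("<ma_trajectories> %d variants over passages %d..%d | %d events\n",
              dplyr::n_distinct(x$status$variant),
              min(x$passages), max(x$passages), nrow(x$events)))
  invisible(x)
}

#' Compare LOH region sets of two consecutive passages
#'
#' A region of the later passage is `new` when it overlaps no
#' same-haplotype region of the earlier passage, `extended` when it
#' overlaps one and is strictly longer, and `stable` otherwise.
#'
#' @param regions_p,regions_p1 [segment_loh()] results for passages `p` and
#'   `p + 1` on the same marker map.
#' @return `regions_p1` with columns `change` (`new`/`extended`/`stable`)
#'   and, for extensions, `old_start`, `old_end` of the longest overlapped
#'   earlier region.
#' @export
diff_loh <- function(regions_p, regions_p1) {
  n <- nrow(regions_p1)
  change <- character(n)
  old_start <- rep(NA_integer_, n)
  old_end <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    r <- regions_p1[i, ]
    ov <- which(regions_p$chrom == r$chrom &
                  regions_p$haplotype == r$haplotype &
                  regions_p$start <= r$end & regions_p$end >= r$start)
    if (length(ov) == 0L) {
      change[i] <- "new"
    } else {
      j <- ov[which.max(regions_p$end[ov] - regions_p$start[ov])]
      len_old <- regions_p$end[j] - regions_p$start[j] + 1
      len_new <- r$end - r$start + 1
      change[i] <- if (len_new > len_old) "extended" else "stable"
      old_start[i] <- regions_p$start[j]
      old_end[i] <- regions_p$end[j]
    }
  }
  dplyr::mutate(regions_p1, change = change, old_start = old_start,
                old_end = old_end)
}

#' Link fixation/elimination events to LOH changes
#'
#' For each trajectory event at passage `p`, searches the LOH difference
#' between passages `p - 1` and `p` for a new or extended region overlapping
#' the variant position. A fixation is caused by an LOH that retains the
#' mutation-carrying homolog, an elimination by one retaining the wild-type
#' homolog; when a ground-truth `carrier` column (`"p1"`/`"p2"`) is present
#' in `events` this direction is enforced, otherwise the linked region's
#' haplotype is reported as the inferred carrier (fixation) or wild-type
#' haplotype (elimination).
#'
#' @param events Events tibble from [build_trajectories()], optionally with
#'   a `carrier` column.
#' @param loh_diffs Tibble concatenating [diff_loh()] results with a
#'   `passage` column (the later passage of each pair).
#' @return `events` with `linked` (logical), `loh_haplotype`, `loh_change`,
#'   `loh_start`, `loh_end` columns added; unlinked events carry `NA`s.
#' @export
link_events_to_loh <- function(events, loh_diffs) {
  n <- nrow(events)
  linked <- logical(n)
  hap <- rep(NA_character_, n)
  chg <- rep(NA_character_, n)
  ls <- rep(NA_integer_, n)
  le <- rep(NA_integer_, n)
  has_carrier <- "carrier" %in% names(events)
  for (i in seq_len(n)) {
    e <- events[i, ]
    cand <- loh_diffs[loh_diffs$passage == e$passage &
                        loh_diffs$chrom == e$chrom &
                        loh_diffs$start <= e$pos & loh_diffs$end >= e$pos &
                        loh_diffs$change %in% c("new", "extended"), , drop = FALSE]
    if (has_carrier && !is.na(e$carrier)) {
      want <- if (e$kind == "fixation") e$carrier else setdiff(c("p1", "p2"), e$carrier)
      cand <- cand[cand$haplotype == want, , drop = FALSE]
    }
    if (nrow(cand) > 0L) {
      linked[i] <- TRUE
      hap[i] <- cand$haplotype[1]
      chg[i] <- cand$change[1]
      ls[i] <- cand$start[1]
      le[i] <- cand$end[1]
    }
  }
  dplyr::mutate(events, linked = linked, loh_haplotype = hap,
                loh_change = chg, loh_start = ls, loh_end = le)
}

#' Per-passage event summary for one lineage
#'
#' Summarizes a lineage into a per-passage table: new heterozygous
#' mutations, fixations, eliminations, new/extended LOH regions and
#' cumulative genome homozygosity.
#'
#' @param trajectories [build_trajectories()] result.
#' @param regions_by_passage Named list of [segment_loh()] results, one per
#'   passage in order (names or positions correspond to
#'   `trajectories$passages`).
#' @param genome Tibble with `chrom`, `length` (for the homozygosity
#'   fraction); `NULL` omits that column.
#' @return Tibble with one row per passage: `passage`, `n_new_mutations`,
#'   `n_fixations`, `n_eliminations`, `n_new_loh`, `n_extended_loh`,
#'   `homozygosity`.
#' @export
lineage_report <- function(trajectories, regions_by_passage = NULL,
                           genome = NULL) {
  passages <- trajectories$passages
  present <- dplyr::filter(trajectories$status, .data$status != "absent")
  births <- if (nrow(present) > 0L) {
    present |>
      dplyr::group_by(.data$variant) |>
      dplyr::summarise(born = min(.data$passage))
  } else {
    tibble::tibble(variant = character(), born = integer())
  }
  out <- tibble::tibble(passage = passages) |>
    dplyr::left_join(dplyr::count(births, .data$born, name = "n_new_mutations"),
                     by = c(passage = "born")) |>
    dplyr::left_join(
      trajectories$events |>
        dplyr::count(.data$passage, .data$kind) |>
        tidyr::pivot_wider(names_from = "kind", values_from = "n"),
      by = "passage"
    )
  for (col in c("n_new_mutations", "fixation", "elimination")) {
    if (!col %in% names(out)) out[[col]] <- NA_integer_
  }
  out <- out |>
    dplyr::rename(n_fixations = "fixation", n_eliminations = "elimination") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("n_"),
                                ~ tidyr::replace_na(.x, 0L)))
  n_new_loh <- rep(0L, length(passages))
  n_ext_loh <- rep(0L, length(passages))
  homoz <- rep(NA_real_, length(passages))
  if (!is.null(regions_by_passage)) {
    for (k in seq_along(passages)) {
      cur <- regions_by_passage[[k]]
      if (k > 1L) {
        d <- diff_loh(regions_by_passage[[k - 1L]], cur)
        n_new_loh[k] <- sum(d$change == "new")
        n_ext_loh[k] <- sum(d$change == "extended")
      } else {
        n_new_loh[k] <- nrow(cur)
      }
      if (!is.null(genome)) {
        homoz[k] <- homozygosity_fraction(cur, genome)$fraction
      }
    }
  }
  dplyr::mutate(out, n_new_loh = n_new_loh, n_extended_loh = n_ext_loh,
                homozygosity = homoz)
}
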