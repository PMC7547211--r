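#' Run the simulate-and-analyze pipeline end to end
#'
#' Simulates a set of MA clones, emits sequencing-like observables for each,
#' runs the analysis modules (variant classification and zygosity, marker
#' genotyping, LOH segmentation and classification, homozygous-origin
#' classification, rate summary) and writes per-clone tables, a strain
#' summary and a machine-readable run manifest. In hybrid mode
#' (`n_markers > 0`) the full LOH analysis runs; with `n_markers = 0`
#' (isogenic mode) LOH-dependent stages are skipped.
#'
#' @param config A [sim_config()] object, a list of [sim_config()]
#'   arguments, or a path to a YAML file of them.
#' @param out_dir Output directory for the artifact tree.
#' @param n_clones Number of parallel clones (default 4).
#' @param seed Optional integer overriding the config seed.
#' @param strain Strain label recorded in outputs (default `"sim"`).
#' @return Invisibly, a list with `clone_summary`, `rates`, `manifest` and
#'   the output directory.
#' @export
run_pipeline <- function(config, out_dir, n_clones = 4L, seed = NULL,
                         strain = "sim") {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, config)
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  lineages <- simulate_lineages(config, n_clones)
  hybrid <- config$n_markers > 0L

  clone_rows <- list()
  all_regions <- list()
  for (i in seq_along(lineages)) {
    lin <- lineages[[i]]
    state <- lin$states[[length(lin$states)]]
    obs <- emit_observables(state, config$read_depth_mean,
                            seed = config$seed + 5000L + i)
    prefix <- sprintf("%s_clone%02d", strain, i)
    write_observables(obs, out_dir, prefix, events = lin$events)

    v <- obs$variants
    if (nrow(v) > 0L) {
      v <- v |>
        dplyr::mutate(variant_class = classify_variant_class(.data$ref, .data$alt)) |>
        classify_zygosity(obs$cn)
      if (!is.null(config$reference)) {
        v <- annotate_homopolymer(v, config$reference)
      }
    } else {
      v <- dplyr::mutate(v, variant_class = character(0),
                         copy_number = integer(0), zygosity = character(0))
    }
    readr::write_tsv(v, file.path(out_dir, paste0(prefix, ".annotated.tsv")))

    regions <- tibble::tibble()
    hom_frac <- NA_real_
    if (hybrid) {
      track <- call_marker_genotypes(obs$markers)
      regions <- segment_loh(track)
      if (nrow(regions) > 0L) regions <- classify_tract(regions, track)
      hom_frac <- homozygosity_fraction(regions, config$genome)$fraction
      readr::write_tsv(regions, file.path(out_dir, paste0(prefix, ".loh.tsv")))
      hom <- v[!is.na(v$zygosity) & v$zygosity == "homozygous", , drop = FALSE]
      if (nrow(hom) > 0L) {
        an <- call_aneuploidies(obs$cn, config$genome)
        origins <- classify_homozygous_origin(hom, regions, obs$cn, an,
                                              all_variants = v)
        readr::write_tsv(origins,
                         file.path(out_dir, paste0(prefix, ".origins.tsv")))
      }
    }
    all_regions[[i]] <- regions
    clone_rows[[i]] <- tibble::tibble(
      strain = strain, clone = i, n_passages = config$n_passages,
      n_mutations = nrow(v),
      n_het = sum(v$zygosity == "heterozygous", na.rm = TRUE),
      n_hom = sum(v$zygosity == "homozygous", na.rm = TRUE),
      n_loh = nrow(regions),
      homozygosity = hom_frac
    )
  }
  clone_summary <- dplyr::bind_rows(clone_rows)
  readr::write_tsv(clone_summary, file.path(out_dir, "clone_summary.tsv"))

  rate <- per_clone_per_passage(clone_summary$n_mutations, config$n_passages)
  rates <- dplyr::mutate(
    rate,
    per_nt_per_generation = per_nt_per_generation(
      rate$mean, 2 * sum(as.numeric(config$genome$length)),
      config$generations_per_passage
    ),
    loh_per_clone_passage = if (hybrid) {
      loh_rate(sum(clone_summary$n_loh), n_clones, config$n_passages)
    } else NA_real_
  )
  readr::write_tsv(rates, file.path(out_dir, "rates.tsv"))

  manifest <- list(
    package = "mutaccum",
    version = as.character(utils::packageVersion("mutaccum")),
    seed = config$seed, n_clones = n_clones,
    n_passages = config$n_passages, n_markers = config$n_markers,
    generations_per_passage = config$generations_per_passage,
    mu_snv = config$mu_snv, mu_indel = config$mu_indel,
    loh_rate = config$loh_rate, p_terminal = config$p_terminal,
    sv_rate = config$sv_rate, aneuploidy_rate = config$aneuploidy_rate,
    mode = if (hybrid) "hybrid" else "isogenic",
    n_mutations_total = sum(clone_summary$n_mutations),
    n_loh_total = sum(clone_summary$n_loh)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(clone_summary = clone_summary, rates = rates,
                 manifest = manifest, out_dir = out_dir))
}
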