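test_that("VCF round trip preserves positions, alleles and allele fractions", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  tab <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"), pos = c(100L, 250L, 7L),
    ref = c("C", "A", "AT"), alt = c("T", "AAG", "A"),
    ad_alt = c(24L, 50L, 10L), dp = c(49L, 50L, 40L),
    allele_fraction = c(24 / 49, 1, 0.25)
  )
  write_observables(list(variants = tab,
                         markers = tibble::tibble(chrom = character(),
                                                  pos = integer(),
                                                  p1_allele = character(),
                                                  p2_allele = character(),
                                                  depth_p1 = integer(),
                                                  depth_p2 = integer()),
                         cn = tibble::tibble(chrom = character(),
                                             start = integer(),
                                             end = integer(),
                                             copy_number = integer())),
                    dirname(tmp), sub("\\.vcf$", "", basename(tmp)))
  got <- read_variants(tmp)
  expect_equal(got$chrom, tab$chrom)
  expect_equal(got$pos, tab$pos)
  expect_equal(got$ref, tab$ref)
  expect_equal(got$alt, tab$alt)
  expect_equal(got$allele_fraction, tab$allele_fraction, tolerance = 1e-12)
  expect_equal(got$allele_fraction[1], 0.49, tolerance = 0.01)
  expect_equal(got$allele_fraction[2], 1.0)
})

test_that("VCF records missing AD/DP raise a named error", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t100\t.\tC\tT\t.\tPASS\t.\tGT\t0/1"
  ), tmp)
  expect_error(read_variants(tmp), "AD/DP")
})

test_that("variant classes cover the substitution/indel/complex/sv taxonomy", {
  expect_equal(classify_variant_class("C", "T"), "snp")
  expect_equal(classify_variant_class("AT", "GC"), "mnp")
  expect_equal(classify_variant_class("A", "AAG"), "indel")   # +2 bp insertion
  expect_equal(classify_variant_class("ACTT", "A"), "indel")  # -3 bp deletion
  expect_equal(classify_variant_class("AC", "TTT"), "complex")
  expect_equal(
    classify_variant_class("A", paste0("A", strrep("T", 44))), "indel")
  expect_equal(
    classify_variant_class("A", paste0("A", strrep("T", 50))), "sv")
  expect_error(classify_variant_class("A", "A"), "not a variant")
  expect_error(classify_variant_class("A", ""), "nonempty")
})

test_that("variant classification is total and deterministic on random pairs", {
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  rand_allele <- function(n) {
    paste(sample(bases, n, replace = TRUE), collapse = "")
  }
  for (i in 1:500) {
    ref <- rand_allele(sample(1:60, 1))
    alt <- rand_allele(sample(1:60, 1))
    if (ref == alt) next
    cls <- classify_variant_class(ref, alt)
    expect_true(cls %in% c("snp", "mnp", "indel", "complex", "sv"))
    expect_identical(cls, classify_variant_class(ref, alt))
  }
})

test_that("zygosity follows allelic ratio and copy number", {
  cn <- tibble::tibble(chrom = "chr1", start = 1L, end = 1e6,
                       copy_number = c(2L))
  v <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
    allele_fraction = c(0.50, 1.00, 0.80, 0.55), dp = c(50L, 50L, 50L, 5L)
  )
  z <- classify_zygosity(v, cn)
  expect_equal(z$zygosity, c("heterozygous", "homozygous", "unresolved",
                             "unresolved"))
  cn3 <- tibble::tibble(chrom = "chr1", start = 1L, end = 1e6,
                        copy_number = 3L)
  z3 <- classify_zygosity(
    tibble::tibble(chrom = "chr1", pos = c(1L, 2L),
                   allele_fraction = c(0.33, 0.66), dp = 60L), cn3)
  expect_equal(z3$zygosity, c("het_trisomic", "het_trisomic"))
  cn1 <- tibble::tibble(chrom = "chr1", start = 1L, end = 1e6,
                        copy_number = 1L)
  z1 <- classify_zygosity(
    tibble::tibble(chrom = "chr1", pos = 1L, allele_fraction = 1, dp = 30L),
    cn1)
  expect_equal(z1$zygosity, "homozygous")
  expect_error(
    classify_zygosity(
      tibble::tibble(chrom = "chr9", pos = 5L, allele_fraction = 0.5, dp = 30L),
      cn),
    "no covering copy-number segment")
})

test_that("zygosity calls on clean simulated data match ground truth", {
  cfg <- sim_config(genome = tiny_genome(4, 2e5), n_markers = 0,
                    n_passages = 20, mu_snv = 2e-6, mu_indel = 0,
                    loh_rate = 1, read_depth_mean = 60,
                    interstitial_length_dist = list(family = "loguniform",
                                                    min = 1e4, max = 1e5),
                    seed = 17)
  lin <- simulate_lineage(cfg)
  st <- lin$states[[length(lin$states)]]
  obs <- emit_observables(st, 60, seed = 2)
  z <- classify_zygosity(obs$variants, obs$cn)
  truth <- st$variants[st$variants$status %in% c("het", "hom"), ]
  keep <- z$dp >= 30
  expect_gt(sum(keep), 100)
  got <- z$zygosity[keep]
  want <- ifelse(truth$status == "hom", "homozygous", "heterozygous")[keep]
  # binomial depth sampling leaves a small tail outside the het window even
  # without genotyping noise; agreement must be near-perfect, never wrong
  expect_gt(mean(got == want), 0.995)
  expect_true(all(got[got != want] == "unresolved"))
})

test_that("homopolymer annotation equals a brute-force run scan", {
  g <- tiny_genome(2, 5000)
  ref <- simulate_reference(g, seed = 8)
  set.seed(9)
  n <- 300
  v <- tibble::tibble(
    chrom = sample(g$chrom, n, replace = TRUE),
    pos = sample.int(4900, n) + 2L
  ) |>
    dplyr::mutate(
      ref = vapply(seq_len(n), function(i) {
        as.character(Biostrings::subseq(ref[[chrom[i]]], pos[i],
                                        pos[i] + sample(0:1, 1)))
      }, character(1)),
      alt = substr(ref, 1, 1)
    )
  v$alt[nchar(v$ref) == 1] <- paste0(v$ref[nchar(v$ref) == 1], "A")
  ann <- annotate_homopolymer(v, ref)
  chars <- lapply(as.character(ref), function(s) strsplit(s, "")[[1]])
  for (i in seq_len(n)) {
    want <- oracle_homopolymer(chars[[v$chrom[i]]], v$pos[i], nchar(v$ref[i]))
    if (is.null(want)) {
      expect_true(is.na(ann$hp_unit[i]))
    } else {
      expect_equal(ann$hp_unit[i], want$unit)
      expect_equal(ann$hp_start[i], want$start)
      expect_equal(ann$hp_length[i], want$len)
    }
  }
  # construction: insertion of A inside an AAAAA run reports (A, 5)
  ref2 <- Biostrings::DNAStringSet(c(chrA = "GGCAAAAACGT"))
  a <- annotate_homopolymer(
    tibble::tibble(chrom = "chrA", pos = 5L, ref = "A", alt = "AA"), ref2)
  expect_equal(a$hp_unit, "A")
  expect_equal(a$hp_start, 4L)
  expect_equal(a$hp_length, 5L)
  # a SNP in a non-repetitive context has no tract
  b <- annotate_homopolymer(
    tibble::tibble(chrom = "chrA", pos = 2L, ref = "G", alt = "T"), ref2)
  expect_true(is.na(b$hp_unit))
  expect_error(
    annotate_homopolymer(
      tibble::tibble(chrom = "chrZ", pos = 1L, ref = "A", alt = "T"), ref2),
    "outside reference")
})

test_that("coding and premature-stop annotation follow the genetic code", {
  #           123456789012345678
  # CDS +:    ...ATGCAACGTTAA... (codons ATG CAA CGT TAA)
  ref <- Biostrings::DNAStringSet(c(chr1 = "GGGATGCAACGTTAAGGGCCC"))
  gm <- tibble::tibble(chrom = "chr1", start = 4L, end = 15L, strand = "+",
                       frame = 0L, gene_id = "g1")
  # C>T at pos 7 turns CAA -> TAA: premature stop
  v <- tibble::tibble(chrom = "chr1", pos = c(7L, 11L, 18L),
                      ref = c("C", "C", "G"), alt = c("T", "A", "T"))
  a <- annotate_coding(v, gm, ref)
  expect_equal(a$coding, c(TRUE, TRUE, FALSE))
  expect_equal(a$premature_stop, c(TRUE, FALSE, FALSE))
  # same gene encoded on the minus strand: reverse-complement layout
  # gene on -: genomic TTACGTTGCAT (revcomp = ATGCAACGTAA)
  ref2 <- Biostrings::DNAStringSet(c(chr1 = "GGTTAACGTTGCATGGG"))
  gm2 <- tibble::tibble(chrom = "chr1", start = 3L, end = 14L, strand = "-",
                        frame = 0L, gene_id = "g2")
  # G>A at genomic pos 11 is C>T on the coding strand: CAA -> TAA
  v2 <- tibble::tibble(chrom = "chr1", pos = 11L, ref = "G", alt = "A")
  a2 <- annotate_coding(v2, gm2, ref2)
  expect_true(a2$coding)
  expect_true(a2$premature_stop)
  expect_error(
    annotate_coding(v, dplyr::mutate(gm, end = 14L), ref),
    "frame inconsistency")
})

test_that("coding fraction of uniform SNVs converges to the CDS coverage", {
  g <- tiny_genome(2, 3e5)
  gm <- make_gene_model(g, cds_fraction = 0.765, seed = 3)
  cds_cov <- sum(gm$end - gm$start + 1) / sum(g$length)
  expect_equal(cds_cov, 0.765, tolerance = 0.02)
  set.seed(4)
  n <- 20000
  pos <- tibble::tibble(
    chrom = sample(g$chrom, n, replace = TRUE),
    pos = sample.int(3e5, n, replace = TRUE)
  )
  hit <- logical(n)
  for (ch in g$chrom) {
    gmc <- gm[gm$chrom == ch, ]
    idx <- pos$chrom == ch
    hit[idx] <- vapply(pos$pos[idx], function(p) {
      any(gmc$start <= p & gmc$end >= p)
    }, logical(1))
  }
  expect_equal(mean(hit), cds_cov, tolerance = 0.015)
})

test_that("aneuploidy calls report whole-chromosome events only", {
  g <- tiny_genome(2, 1e5)
  cn <- tibble::tibble(
    chrom = c("chr1", "chr2", "chr2", "chr2"),
    start = c(1L, 1L, 50001L, 60001L),
    end = c(1e5, 5e4, 6e4, 1e5),
    copy_number = c(3L, 2L, 1L, 2L)
  )
  an <- call_aneuploidies(cn, g)
  expect_equal(an$chrom, "chr1")
  expect_equal(an$copy_number, 3L)
  expect_error(
    call_aneuploidies(cn[cn$chrom == "chr1", ][0, ], g),
    "coverage gap")
  # simulated aneuploidies are recovered exactly
  cfg <- sim_config(genome = tiny_genome(6, 2e5), n_markers = 0,
                    n_passages = 15, mu_snv = 0, mu_indel = 0, loh_rate = 0,
                    aneuploidy_rate = 0.2, seed = 23)
  lins <- simulate_lineages(cfg, 10)
  for (l in lins) {
    st <- l$states[[length(l$states)]]
    got <- call_aneuploidies(cn_truth(st), cfg$genome)
    want <- tibble::tibble(
      chrom = names(st$chrom_cn)[st$chrom_cn != 2L],
      copy_number = unname(st$chrom_cn[st$chrom_cn != 2L])
    )
    expect_equal(dplyr::arrange(got, chrom), dplyr::arrange(want, chrom))
  }
})
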