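test_that("gene association follows overlap-else-nearest-within-distance", {
  genes <- data.frame(chrom = "chr1",
                      start = c(10000, 50000), end = c(20000, 60000),
                      symbol = c("GA", "GB"), stringsAsFactors = FALSE)
  # inside GA
  s1 <- make_set("chr1", 12000, 13000)
  a1 <- associate_genes(s1, genes)
  expect_equal(a1$gene, "GA")
  expect_equal(a1$relation, "overlapping")
  expect_equal(a1$distance_bp, 0)
  # 3 kb downstream of GA, within the 10 kb default
  s2 <- make_set("chr1", 23000, 24000)
  a2 <- associate_genes(s2, genes)
  expect_equal(a2$gene, "GA")
  expect_equal(a2$relation, "within_distance")
  expect_equal(a2$distance_bp, 3000)
  # beyond the maximum distance: unassociated
  s3 <- make_set("chr1", 35000, 36000)
  expect_equal(nrow(associate_genes(s3, genes, max_distance_bp = 10000)), 0)
  # spanning two genes reports both
  s4 <- make_set("chr1", 15000, 55000)
  a4 <- associate_genes(s4, genes)
  expect_equal(sort(a4$gene), c("GA", "GB"))
})

test_that("gene association matches an exhaustive nearest-gene scan", {
  set.seed(55)
  asm <- tiny_assembly(2, 1e6)
  genes <- generate_gene_annotation(asm, 30, gene_width_bp = 10000, seed = 9)
  s <- random_set(60, asm, max_width = 3000)
  got <- associate_genes(s, genes, max_distance_bp = 15000)
  # oracle: plain double loop over (epimutation, gene)
  want <- list()
  for (i in seq_len(nrow(s))) {
    best <- NULL
    for (j in seq_len(nrow(genes))) {
      if (s$chrom[i] != genes$chrom[j]) next
      gap <- max(genes$start[j] - s$end[i], s$start[i] - genes$end[j])
      if (gap < 0) {
        want[[length(want) + 1L]] <- data.frame(
          id = s$id[i], gene = genes$symbol[j], relation = "overlapping",
          distance_bp = 0, stringsAsFactors = FALSE)
      } else if (gap <= 15000 &&
                 (is.null(best) || gap < best$distance_bp)) {
        best <- data.frame(id = s$id[i], gene = genes$symbol[j],
                           relation = "within_distance", distance_bp = gap,
                           stringsAsFactors = FALSE)
      }
    }
    overlapped <- length(want) && any(vapply(want, function(w) {
      w$id[1] == s$id[i]
    }, TRUE))
    if (!overlapped && !is.null(best)) want[[length(want) + 1L]] <- best
  }
  want <- do.call(rbind, want)
  want <- want[order(match(want$id, s$id), want$gene), ]
  rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("overlap matrix CSV round-trips without information loss", {
  sim <- generate_catalog(synthetic_config(
    seed = 41, n_chrom = 4, chrom_length_bp = 2e6,
    n_dmr = c(F1 = 30, F2 = 20, F3 = 30),
    n_ncrna = c(F1 = 20, F2 = 20, F3 = 20), n_dhr = 20,
    n_near_miss = 10, n_background = 10, lineages = "DDT"))
  m <- extended_overlap_matrix(sim$catalog, "DDT")
  p <- withr::local_tempfile(fileext = ".csv")
  write_overlap_matrix(m, p)
  m2 <- read_overlap_matrix(p)
  expect_equal(m2$counts, m$counts)
  expect_equal(m2$percents, m$percents)
  expect_equal(m2$row_sizes, m$row_sizes)
  expect_equal(m2$flank_bp, m$flank_bp)
  expect_equal(m2$lineage, m$lineage)
})

test_that("export_report writes a complete, re-readable, idempotent report", {
  sim <- generate_catalog(synthetic_config(
    seed = 43, n_chrom = 4, chrom_length_bp = 2e6,
    n_dmr = c(F1 = 30, F2 = 20, F3 = 30),
    n_ncrna = c(F1 = 20, F2 = 20, F3 = 20), n_dhr = 20,
    n_near_miss = 10, n_background = 10, lineages = "DDT"))
  m <- extended_overlap_matrix(sim$catalog, "DDT")
  sel <- select_sets(sim$catalog, "DDT")
  v <- venn_partition(list(DMR = sel$stringent[["F3 DMR"]],
                           DHR = sel$stringent[["F3 DHR"]],
                           ncRNA = sel$stringent[["F3 ncRNA"]]))
  coloc <- colocalization_scan(sim$catalog, "DDT")
  pt <- multiway_colocalization_test(sim$catalog, "DDT",
                                     assembly = sim$assembly, n_perm = 19,
                                     seed = 2)
  res <- list(matrices = list(direct = m), venns = list(f3 = v),
              coloc = coloc, permutations = list(multiway = pt),
              config = list(note = "fixture"), seed = 2L)
  d1 <- withr::local_tempdir()
  files <- export_report(res, d1)
  expect_true(all(file.exists(files)))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  # JSON artefacts re-parse
  vj <- jsonlite::read_json(file.path(d1, "venn_f3.json"))
  expect_equal(vj$n_components, v$n_components)
  pj <- jsonlite::read_json(file.path(d1, "permutation_multiway.json"))
  expect_equal(pj$observed, pt$observed)
  expect_equal(pj$p_value, pt$p_value)
  # empty results still yield a manifest
  d2 <- withr::local_tempdir()
  export_report(list(seed = 1L), d2)
  expect_true(file.exists(file.path(d2, "manifest.json")))
  # idempotent overwrite: re-export is byte-identical
  before <- tools::md5sum(list.files(d1, full.names = TRUE))
  export_report(res, d1)
  after <- tools::md5sum(list.files(d1, full.names = TRUE))
  expect_identical(before, after)
})

test_that("colocalized sites export to TSV/BED and a plot table", {
  sim <- generate_catalog(synthetic_config(
    seed = 47, n_chrom = 4, chrom_length_bp = 2e6,
    n_dmr = c(F1 = 30, F2 = 20, F3 = 30),
    n_ncrna = c(F1 = 20, F2 = 20, F3 = 20), n_dhr = 20,
    n_near_miss = 10, n_background = 10, lineages = "DDT"))
  coloc <- colocalization_scan(sim$catalog, "DDT")
  expect_gt(nrow(coloc), 0)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_colocalized_sites(coloc, tsv, bed)
  back <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(coloc))
  expect_equal(back$anchor_id, coloc$anchor_id)
  bed_lines <- readLines(bed)
  expect_equal(length(bed_lines), nrow(coloc))
  expect_true(all(grepl("^\\S+\t\\d+\t\\d+\t", bed_lines)))
  pt <- chromosome_plot_table(coloc)
  expect_equal(nrow(pt), nrow(coloc))
  expect_true(all(pt$color %in% c("red", "blue", "green")))
})
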