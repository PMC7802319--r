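test_that("p-value tiers respect the threshold contract", {
  cfg <- synthetic_config(seed = 13, n_chrom = 5, chrom_length_bp = 2e6,
                          n_dmr = c(F1 = 50, F2 = 30, F3 = 50),
                          n_ncrna = c(F1 = 40, F2 = 40, F3 = 40), n_dhr = 40,
                          n_near_miss = 30, n_background = 30,
                          lineages = "vinclozolin")
  sim <- generate_catalog(cfg)
  scheme <- threshold_scheme()
  feat <- sim$ground_truth$features
  for (key in names(sim$catalog)) {
    s <- sim$catalog[[key]]
    if (!nrow(s)) next
    tier <- feat$tier[match(s$id, feat$id)]
    cut <- scheme$stringent[[attr(s, "mark")]]
    # planted features pass their mark's stringent cutoff
    expect_true(all(s$p_value[tier == "planted"] < cut))
    # near-misses pass relaxed but not stringent
    expect_true(all(s$p_value[tier == "near_miss"] >= cut))
    expect_true(all(s$p_value[tier == "near_miss"] < scheme$relaxed))
    # background features pass neither
    expect_true(all(s$p_value[tier == "background"] >= scheme$relaxed))
  }
})

test_that("full retention with zero jitter gives 100% planted F1-F3 DMR overlap", {
  cfg <- synthetic_config(seed = 17, n_chrom = 5, chrom_length_bp = 5e6,
                          n_dmr = c(F1 = 80, F2 = 0, F3 = 0),
                          n_ncrna = c(F1 = 0, F2 = 0, F3 = 0), n_dhr = 0,
                          dmr_retention = 1, coloc_ncrna_dmr = 0,
                          coloc_trimark = 0, jitter_bp = 0,
                          n_near_miss = 0, n_background = 0,
                          lineages = "vinclozolin")
  sim <- generate_catalog(cfg)
  f1 <- catalog_get(sim$catalog, "vinclozolin", "F1", "DMR")
  f3 <- catalog_get(sim$catalog, "vinclozolin", "F3", "DMR")
  expect_equal(nrow(f3), 80)
  expect_equal(overlap_count_percent(f1, f3)$percent, 100)
})

test_that("DHRs appear only in the configured generations", {
  sim <- generate_catalog(synthetic_config(
    seed = 19, n_chrom = 4, chrom_length_bp = 2e6,
    n_dmr = c(F1 = 30, F2 = 20, F3 = 30),
    n_ncrna = c(F1 = 20, F2 = 20, F3 = 20), n_dhr = 25,
    n_near_miss = 10, n_background = 10, lineages = "DDT"))
  scheme <- threshold_scheme()
  for (g in c("F1", "F2")) {
    s <- catalog_get(sim$catalog, "DDT", g, "DHR")
    expect_equal(nrow(apply_threshold(s, scheme$stringent[["DHR"]])), 0)
  }
  f3 <- catalog_get(sim$catalog, "DDT", "F3", "DHR")
  expect_gt(nrow(apply_threshold(f3, scheme$stringent[["DHR"]])), 0)
})

test_that("planted fractions are recovered within sampling tolerance", {
  cfg <- synthetic_config(seed = 23)  # study-condition defaults
  sim <- generate_catalog(cfg)
  gt <- sim$ground_truth$loci
  for (lin in cfg$lineages) {
    f1 <- gt[gt$lineage == lin & gt$role == "dmr_F1", ]
    # retention: binomial around 0.35 on n = 400 loci (sd ~ 2.4%)
    expect_lt(abs(mean(f1$retained) - cfg$dmr_retention), 0.08)
    expect_lt(abs(mean(f1$ncrna_coloc) - cfg$coloc_ncrna_dmr), 0.08)
  }
  # planted structure drives the measured overlap matrix
  m <- extended_overlap_matrix(sim$catalog, "vinclozolin")
  expect_lt(abs(m$percents["F1 DMR", "F3 DMR"] - 35), 8)
  expect_lt(abs(m$percents["F1 DMR", "F1 ncRNA"] - 30), 8)
})

test_that("same configuration writes byte-identical catalogs", {
  cfg <- synthetic_config(seed = 29, n_chrom = 4, chrom_length_bp = 2e6,
                          n_dmr = c(F1 = 30, F2 = 20, F3 = 30),
                          n_ncrna = c(F1 = 20, F2 = 20, F3 = 20), n_dhr = 20,
                          n_near_miss = 10, n_background = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_catalog_dir(generate_catalog(cfg), d1)
  write_catalog_dir(generate_catalog(cfg), d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # and the directory round-trips through the reader
  back <- read_catalog_dir(d1)
  sim <- generate_catalog(cfg)
  expect_equal(back$assembly, sim$assembly)
  expect_identical(sort(names(back$catalog)), sort(names(sim$catalog)))
  for (k in names(sim$catalog)) {
    expect_equal(back$catalog[[k]]$id, sim$catalog[[k]]$id)
    expect_equal(back$catalog[[k]]$start, sim$catalog[[k]]$start)
    expect_equal(back$catalog[[k]]$p_value, sim$catalog[[k]]$p_value,
                 tolerance = 1e-12)
  }
})

test_that("zero colocalization and retention leaves only chance overlap", {
  cfg <- synthetic_config(seed = 37, n_chrom = 10, chrom_length_bp = 1e7,
                          dmr_retention = 0, coloc_ncrna_dmr = 0,
                          coloc_trimark = 0)
  sim <- generate_catalog(cfg)
  m <- extended_overlap_matrix(sim$catalog, "vinclozolin")
  off <- m$percents
  diag(off) <- NA
  # expected chance rate: ~900 x 1 kb column features on a 100 Mb genome
  expect_lt(max(off, na.rm = TRUE), 5)
})

test_that("synthetic gene annotation is disjoint and supports recovery", {
  asm <- genome_assembly(c("chr1", "chr2"), c(1e7, 5e6))
  g0 <- generate_gene_annotation(asm, 0)
  expect_equal(nrow(g0), 0)
  genes <- generate_gene_annotation(asm, 100, gene_width_bp = 20000,
                                    seed = 2)
  expect_equal(nrow(genes), 100)
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  expect_identical(genes, generate_gene_annotation(asm, 100,
                                                   gene_width_bp = 20000,
                                                   seed = 2))
  expect_error(generate_gene_annotation(asm, 5000, gene_width_bp = 20000),
               "infeasible")
  # an epimutation planted inside a gene is associated with it
  s <- make_set(genes$chrom[7], genes$start[7] + 100, genes$start[7] + 600)
  ga <- associate_genes(s, genes)
  expect_equal(ga$gene, genes$symbol[7])
  expect_equal(ga$relation, "overlapping")
})
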