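test_that("epimutation tables read from TSV and BED with validation", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tp_value",
               "chr2\t100\t600\t1e-07",
               "chr1\t500\t1500\t0.01",
               "chr1\t10\t40\t0.9"), p)
  s <- read_epimutation_table(p, "tsv", mark = "DMR", generation = "F1",
                              lineage = "vinclozolin")
  expect_equal(nrow(s), 3)
  # sorted by (chrom, start)
  expect_equal(s$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(s$start, c(10, 500, 100))

  writeLines(c("chrom\tstart\tend\tp_value", "chr1\t1\t2\t0"), p)
  expect_error(read_epimutation_table(p, "tsv", mark = "DMR",
                                      generation = "F1", lineage = "x"),
               "row 1")
  writeLines(c("chrom\tstart\tend\tp_value", "chr1\t1\t2\tabc"), p)
  expect_error(read_epimutation_table(p, "tsv", mark = "DMR",
                                      generation = "F1", lineage = "x"),
               "unparseable")
  writeLines(c("chrom\tbegin\tend\tp_value", "chr1\t1\t2\t0.5"), p)
  expect_error(read_epimutation_table(p, "tsv", mark = "DMR",
                                      generation = "F1", lineage = "x"),
               "not found")

  # 1-based input converted at the reader boundary
  writeLines(c("chrom\tstart\tend\tp_value", "chr1\t1\t100\t0.5"), p)
  s1 <- read_epimutation_table(p, "tsv", mark = "DMR", generation = "F1",
                               lineage = "x", zero_based = FALSE)
  expect_equal(s1$start, 0)
  expect_equal(s1$end, 100)

  b <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t1000\tfeat1\t1e-07", b)
  sb <- read_epimutation_table(b, "bed", mark = "DHR", generation = "F3",
                               lineage = "DDT")
  expect_equal(sb$id, "feat1")
  expect_equal(sb$p_value, 1e-07)
})

test_that("catalog writers round-trip through the readers", {
  set.seed(101)
  asm <- tiny_assembly()
  s <- random_set(50, asm, mark = "ncRNA", generation = "F2",
                  lineage = "DDT")
  for (fmt in c("tsv", "bed")) {
    p <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_epimutation_table(s, p, fmt)
    s2 <- read_epimutation_table(p, fmt, mark = "ncRNA", generation = "F2",
                                 lineage = "DDT")
    expect_equal(s2$id, s$id)
    expect_equal(s2$chrom, s$chrom)
    expect_equal(s2$start, s$start)
    expect_equal(s2$end, s$end)
    expect_equal(s2$p_value, s$p_value, tolerance = 1e-12)
  }
})

test_that("apply_threshold is strict, monotone and idempotent", {
  s <- make_set(c("chr1", "chr1"), c(0, 2000), c(1000, 3000),
                p = c(1e-07, 1e-05))
  kept <- apply_threshold(s, 1e-06)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$p_value, 1e-07)
  expect_equal(attr(kept, "threshold_applied"), 1e-06)
  # strictness: a member at exactly the cutoff is excluded
  s_at <- make_set("chr1", 0, 10, p = 1e-06)
  expect_equal(nrow(apply_threshold(s_at, 1e-06)), 0)
  # p_max = 1 keeps everything except p == 1
  s_mix <- make_set(rep("chr1", 3), c(0, 100, 200), c(50, 150, 250),
                    p = c(0.2, 1, 1e-9))
  expect_equal(nrow(apply_threshold(s_mix, 1)), 2)

  set.seed(7)
  asm <- tiny_assembly()
  for (rep in 1:10) {
    s <- random_set(80, asm)
    # linear-scan oracle at the relaxed cutoff
    expect_equal(nrow(apply_threshold(s, 0.05)), sum(s$p_value < 0.05))
    cuts <- sort(runif(3))
    res <- lapply(cuts, function(cc) apply_threshold(s, cc)$id)
    expect_true(all(res[[1]] %in% res[[2]]))
    expect_true(all(res[[2]] %in% res[[3]]))
    twice <- apply_threshold(apply_threshold(s, cuts[2]), cuts[2])
    expect_equal(twice$id, res[[2]])
  }
})

test_that("select_sets pairs stringent and relaxed sets per label", {
  sim <- generate_catalog(synthetic_config(
    seed = 3, n_chrom = 4, chrom_length_bp = 2e6,
    n_dmr = c(F1 = 40, F2 = 20, F3 = 40),
    n_ncrna = c(F1 = 30, F2 = 30, F3 = 30), n_dhr = 30,
    n_near_miss = 20, n_background = 20, lineages = "vinclozolin"))
  sel <- select_sets(sim$catalog, "vinclozolin")
  expect_length(sel$stringent, 9)
  expect_length(sel$relaxed, 9)
  expect_identical(names(sel$stringent), names(sel$relaxed))
  # every stringent set is a subset of its relaxed counterpart
  for (lab in names(sel$stringent)) {
    expect_true(all(sel$stringent[[lab]]$id %in% sel$relaxed[[lab]]$id))
  }
  # dropping one set yields 8 + 8 with a warning
  cat8 <- build_catalog(unname(sim$catalog[
    names(sim$catalog) != "vinclozolin|F1|DHR"]))
  expect_warning(sel8 <- select_sets(cat8, "vinclozolin"), "F1 DHR")
  expect_length(sel8$stringent, 8)
  expect_error(select_sets(build_catalog(list()), "vinclozolin"), "empty")
  expect_error(select_sets(sim$catalog, "nope"), "not present")
})

test_that("set constructor rejects invalid members and records identity", {
  expect_error(epimutation_set(data.frame(chrom = "chr1", start = 5, end = 5,
                                          p_value = 0.5),
                               "DMR", "F1", "x"), "start")
  expect_error(epimutation_set(data.frame(chrom = "chr1", start = 0, end = 5,
                                          p_value = 1.5),
                               "DMR", "F1", "x"), "p_value")
  expect_error(epimutation_set(data.frame(chrom = "chr1", start = 0, end = 5,
                                          p_value = 0.5),
                               "XXX", "F1", "x"))
  s <- make_set("chr1", 0, 10, mark = "DHR", generation = "F3",
                lineage = "DDT")
  expect_equal(set_label(s), "F3 DHR")
})
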