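# Synthetic epimutation catalogs with planted structure.
#
# The generator emulates the processed multi-generation sperm epimutation
# catalogs the analysis consumes: 2 exposure lineages x 3 generations x 3
# mark types, kilobase-scale features with per-feature p-values, planted
# cross-mark colocalization (F1 ncRNA on F1 DMRs; a tri-mark DMR/DHR/ncRNA
# fraction in F3), cross-generation DMR retention, and DHRs present only in
# the transgenerational F3 generation. p-values come in three explicit
# tiers so that the stringent-vs-relaxed contrast is testable:
#   planted   p = 10^-U(6,12) for DMR/DHR, 10^-U(4,10) for ncRNA
#             (always below the stringent cutoffs)
#   near-miss p ~ U(stringent cutoff of the mark, 0.05)
#             (passes relaxed, fails stringent)
#   background p ~ U(0.05, 1) (passes neither; thresholds are strict)

#' Configuration of the synthetic catalog generator
#'
#' Defaults describe the study conditions the package is validated under:
#' a 20-chromosome 200 Mb genome, ~1 kb features, 35% F1-to-F2/F3 DMR
#' retention, 30% of F1 DMR loci carrying a colocalized F1 ncRNA, 25% of F3
#' DMR loci carrying all three marks, and DHRs confined to F3.
#'
#' @param seed Integer RNG seed; the whole catalog is deterministic in it.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_bp Chromosome length(s) in bp (recycled).
#' @param mark_widths Named bp widths per mark (DMR/DHR 1000, ncRNA 500).
#' @param n_dmr Named counts of freshly planted DMR loci per generation
#'   (retained F1 loci are added to F2/F3 on top of these).
#' @param n_ncrna Named counts of freshly planted ncRNA loci per generation.
#' @param n_dhr Freshly planted DHR loci per DHR-carrying generation.
#' @param dhr_generations Generations that carry DHRs (default `"F3"`).
#' @param dmr_retention Fraction of F1 DMR loci re-emitted in F2 and F3.
#' @param coloc_ncrna_dmr Fraction of F1 DMR loci also carrying an F1 ncRNA.
#' @param coloc_trimark Fraction of F3 DMR loci also carrying an F3 DHR and
#'   an F3 ncRNA.
#' @param jitter_bp Positional noise: each feature's centre is displaced
#'   uniformly within +/- `jitter_bp` of its latent locus. 0 gives exact
#'   colocalization; a few kb probes the direct-vs-10 kb-window contrast.
#' @param n_near_miss Near-miss features per active set.
#' @param n_background Background features per set.
#' @param stringent_cutoffs Per-mark stringent cutoffs the p-value tiers are
#'   anchored to (must match the analysis [threshold_scheme()]).
#' @param relaxed_cutoff Relaxed cutoff anchoring the tiers.
#' @param lineages Lineage labels to emit; loci are independent between
#'   lineages.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chrom = 20L,
                             chrom_length_bp = 1e7,
                             mark_widths = c(DMR = 1000, DHR = 1000,
                                             ncRNA = 500),
                             n_dmr = c(F1 = 400, F2 = 200, F3 = 400),
                             n_ncrna = c(F1 = 300, F2 = 300, F3 = 300),
                             n_dhr = 300,
                             dhr_generations = "F3",
                             dmr_retention = 0.35,
                             coloc_ncrna_dmr = 0.30,
                             coloc_trimark = 0.25,
                             jitter_bp = 0,
                             n_near_miss = 100,
                             n_background = 150,
                             stringent_cutoffs = c(DMR = 1e-06, DHR = 1e-06,
                                                   ncRNA = 1e-04),
                             relaxed_cutoff = 0.05,
                             lineages = c("vinclozolin", "DDT")) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length_bp = chrom_length_bp,
              mark_widths = mark_widths[EPI_MARKS],
              n_dmr = n_dmr, n_ncrna = n_ncrna, n_dhr = n_dhr,
              dhr_generations = dhr_generations,
              dmr_retention = dmr_retention,
              coloc_ncrna_dmr = coloc_ncrna_dmr,
              coloc_trimark = coloc_trimark,
              jitter_bp = jitter_bp,
              n_near_miss = n_near_miss, n_background = n_background,
              stringent_cutoffs = stringent_cutoffs[EPI_MARKS],
              relaxed_cutoff = relaxed_cutoff,
              lineages = lineages)
  fr <- c(cfg$dmr_retention, cfg$coloc_ncrna_dmr, cfg$coloc_trimark)
  if (any(fr < 0) || any(fr > 1)) {
    stop("retention/colocalization fractions must lie in [0, 1]",
         call. = FALSE)
  }
  if (any(cfg$mark_widths < 1) || cfg$jitter_bp < 0) {
    stop("mark widths must be >= 1 bp and jitter >= 0", call. = FALSE)
  }
  miss <- setdiff(cfg$dhr_generations, EPI_GENERATIONS)
  if (length(miss)) stop("unknown DHR generation(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

# Draw n latent locus positions, chromosome-weighted by length, keeping a
# margin so jittered/extended features never fall off a chromosome end.
draw_loci <- function(n, assembly, margin) {
  if (any(assembly$length <= 2 * margin)) {
    stop("chromosomes too short for the configured feature widths/jitter",
         call. = FALSE)
  }
  if (n == 0) {
    return(data.frame(chrom = character(0), pos = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ci <- sample.int(nrow(assembly), n, replace = TRUE, prob = assembly$length)
  pos <- floor(margin + stats::runif(n) * (assembly$length[ci] - 2 * margin))
  data.frame(chrom = assembly$chrom[ci], pos = pos, stringsAsFactors = FALSE)
}

#' Generate a synthetic epimutation catalog
#'
#' Deterministic in `cfg$seed`. Ground truth records every planted locus
#' and feature (with its p-value tier), enabling exact recovery checks of
#' the downstream analysis.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `assembly` (a [genome_assembly()]), `catalog` (an
#'   epimutation catalog of `length(lineages) * 9` sets) and `ground_truth`
#'   (list of data frames `loci` -- locus_id, lineage, chrom, pos, role,
#'   retained, trimark, ncrna_coloc -- and `features` -- feature id, locus
#'   id, lineage, generation, mark, tier).
#' @export
generate_catalog <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    lens <- rep_len(cfg$chrom_length_bp, cfg$n_chrom)
    assembly <- genome_assembly(paste0("chr", seq_len(cfg$n_chrom)), lens)
    margin <- max(cfg$mark_widths) + cfg$jitter_bp + 1000
    locus_counter <- 0L
    gt_loci <- list()
    gt_feat <- list()
    sets <- list()

    new_loci <- function(n, lineage, role) {
      df <- draw_loci(n, assembly, margin)
      df$locus_id <- sprintf("L%06d", locus_counter + seq_len(n))
      locus_counter <<- locus_counter + n
      df$lineage <- rep(lineage, n)
      df$role <- rep(role, n)
      df$retained <- logical(n)
      df$trimark <- logical(n)
      df$ncrna_coloc <- logical(n)
      df
    }

    planted_p <- function(mark, n) {
      rng <- if (mark == "ncRNA") c(4, 10) else c(6, 12)
      10^-stats::runif(n, rng[1], rng[2])
    }

    for (lin in cfg$lineages) {
      # Latent loci. F1 DMR loci drive retention and ncRNA colocalization;
      # F3 DMR loci (retained + fresh) drive the tri-mark fraction.
      f1_dmr <- new_loci(cfg$n_dmr[["F1"]], lin, "dmr_F1")
      f1_dmr$retained <- stats::runif(nrow(f1_dmr)) < cfg$dmr_retention
      f1_dmr$ncrna_coloc <- stats::runif(nrow(f1_dmr)) < cfg$coloc_ncrna_dmr
      f2_fresh <- new_loci(cfg$n_dmr[["F2"]], lin, "dmr_F2")
      f3_fresh <- new_loci(cfg$n_dmr[["F3"]], lin, "dmr_F3")
      dmr_loci <- list(F1 = f1_dmr,
                       F2 = rbind(f1_dmr[f1_dmr$retained, ], f2_fresh),
                       F3 = rbind(f1_dmr[f1_dmr$retained, ], f3_fresh))
      tri <- stats::runif(nrow(dmr_loci$F3)) < cfg$coloc_trimark
      dmr_loci$F3$trimark <- tri
      tri_loci <- dmr_loci$F3[tri, ]

      ncrna_loci <- list()
      for (g in EPI_GENERATIONS) {
        fresh <- new_loci(cfg$n_ncrna[[g]], lin, paste0("ncrna_", g))
        extra <- NULL
        if (g == "F1") extra <- f1_dmr[f1_dmr$ncrna_coloc, ]
        if (g == "F3" && nrow(tri_loci)) extra <- tri_loci
        ncrna_loci[[g]] <- if (is.null(extra)) fresh else rbind(extra, fresh)
      }

      dhr_loci <- list()
      for (g in intersect(EPI_GENERATIONS, cfg$dhr_generations)) {
        fresh <- new_loci(cfg$n_dhr, lin, paste0("dhr_", g))
        extra <- if (g == "F3" && nrow(tri_loci)) tri_loci else NULL
        dhr_loci[[g]] <- if (is.null(extra)) fresh else rbind(extra, fresh)
      }

      gt_loci[[lin]] <- rbind(f1_dmr, f2_fresh, f3_fresh,
                              do.call(rbind, lapply(EPI_GENERATIONS, function(g) {
                                l <- ncrna_loci[[g]]
                                l[!l$locus_id %in% f1_dmr$locus_id &
                                  !l$locus_id %in% dmr_loci$F3$locus_id, ]
                              })),
                              do.call(rbind, lapply(names(dhr_loci), function(g) {
                                l <- dhr_loci[[g]]
                                l[!l$locus_id %in% dmr_loci$F3$locus_id, ]
                              })))
      # trimark flags live on the F3 DMR locus rows
      gt_loci[[lin]]$trimark[match(dmr_loci$F3$locus_id,
                                   gt_loci[[lin]]$locus_id)] <- dmr_loci$F3$trimark

      emit <- function(loci, mark, gen, tier) {
        n <- nrow(loci)
        w <- cfg$mark_widths[[mark]]
        centre <- loci$pos
        if (cfg$jitter_bp > 0 && n) {
          centre <- centre + round(stats::runif(n, -cfg$jitter_bp,
                                                cfg$jitter_bp))
        }
        start <- centre - floor(w / 2)
        p <- switch(tier,
                    planted = planted_p(mark, n),
                    near_miss = stats::runif(n, cfg$stringent_cutoffs[[mark]],
                                             cfg$relaxed_cutoff),
                    background = stats::runif(n, cfg$relaxed_cutoff, 1))
        data.frame(locus_id = loci$locus_id, chrom = loci$chrom,
                   start = start, end = start + w, p_value = p,
                   tier = tier, stringsAsFactors = FALSE)
      }

      for (g in EPI_GENERATIONS) {
        for (m in EPI_MARKS) {
          planted <- switch(m,
                            DMR = dmr_loci[[g]],
                            ncRNA = ncrna_loci[[g]],
                            DHR = dhr_loci[[g]])
          active <- !is.null(planted) && nrow(planted) > 0
          parts <- list()
          if (active) parts$planted <- emit(planted, m, g, "planted")
          if (active && cfg$n_near_miss > 0) {
            parts$near <- emit(new_loci(cfg$n_near_miss, lin,
                                        paste0("nearmiss_", g, "_", m)),
                               m, g, "near_miss")
          }
          if (cfg$n_background > 0) {
            parts$bg <- emit(new_loci(cfg$n_background, lin,
                                      paste0("background_", g, "_", m)),
                             m, g, "background")
          }
          feat <- if (length(parts)) do.call(rbind, parts) else
            data.frame(locus_id = character(0), chrom = character(0),
                       start = numeric(0), end = numeric(0),
                       p_value = numeric(0), tier = character(0),
                       stringsAsFactors = FALSE)
          feat$id <- if (nrow(feat)) {
            sprintf("%s_%s_%s_%05d", lin, g, m, seq_len(nrow(feat)))
          } else character(0)
          sets[[length(sets) + 1L]] <- epimutation_set(
            feat[, c("id", "chrom", "start", "end", "p_value")],
            mark = m, generation = g, lineage = lin)
          gt_feat[[length(gt_feat) + 1L]] <- data.frame(
            id = feat$id, locus_id = feat$locus_id,
            lineage = rep(lin, nrow(feat)), generation = rep(g, nrow(feat)),
            mark = rep(m, nrow(feat)), tier = feat$tier,
            stringsAsFactors = FALSE)
        }
      }
    }

    loci <- do.call(rbind, gt_loci)
    rownames(loci) <- NULL
    features <- do.call(rbind, gt_feat)
    rownames(features) <- NULL
    list(assembly = assembly, catalog = build_catalog(sets),
         ground_truth = list(loci = loci[, c("locus_id", "lineage", "chrom",
                                             "pos", "role", "retained",
                                             "trimark", "ncrna_coloc")],
                             features = features))
  })
}

#' Generate a non-overlapping synthetic gene annotation
#'
#' Genes are spread uniformly over the genome on a per-chromosome grid of
#' slots with a random offset inside each slot, which guarantees disjoint
#' intervals while keeping placement random. Deterministic in `seed`.
#'
#' @param assembly A [genome_assembly()].
#' @param n_genes Number of genes (>= 0), apportioned to chromosomes in
#'   proportion to length.
#' @param gene_width_bp Gene width in bp (constant).
#' @param seed Integer seed.
#' @return Data frame with columns `chrom`, `start`, `end`, `symbol`
#'   (synthetic symbols `G000001`, ...), sorted by position.
#' @export
generate_gene_annotation <- function(assembly, n_genes, gene_width_bp = 20000,
                                     seed = 1L) {
  stopifnot(n_genes >= 0, gene_width_bp >= 1)
  if (n_genes == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), symbol = character(0),
                      stringsAsFactors = FALSE))
  }
  with_seed(as.integer(seed), {
    share <- assembly$length / sum(assembly$length)
    n_per <- diff(c(0, round(cumsum(share * n_genes))))
    out <- list()
    for (k in seq_len(nrow(assembly))) {
      nk <- n_per[k]
      if (nk == 0) next
      slot <- floor(assembly$length[k] / nk)
      if (slot <= gene_width_bp) {
        stop("gene density infeasible on ", assembly$chrom[k],
             ": slot ", slot, " bp <= gene width", call. = FALSE)
      }
      offset <- floor(stats::runif(nk) * (slot - gene_width_bp))
      start <- (seq_len(nk) - 1) * slot + offset
      out[[k]] <- data.frame(chrom = assembly$chrom[k], start = start,
                             end = start + gene_width_bp,
                             stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, out)
    genes$symbol <- sprintf("G%06d", seq_len(nrow(genes)))
    rownames(genes) <- NULL
    genes
  })
}

#' Write a simulated catalog to a directory
#'
#' Emits `chrom.sizes`, one TSV per set named
#' `<lineage>_<generation>_<mark>.tsv`, and `ground_truth.json`. The layout
#' round-trips through [read_catalog_dir()], and identical configurations
#' produce byte-identical files.
#'
#' @param sim A [generate_catalog()] result (or a list with `assembly` and
#'   `catalog`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_catalog_dir <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_chrom_sizes(sim$assembly, file.path(dir, "chrom.sizes"))
  for (s in sim$catalog) {
    fn <- sprintf("%s_%s_%s.tsv", set_lineage(s), set_generation(s),
                  set_mark(s))
    write_epimutation_table(s, file.path(dir, fn), format = "tsv")
  }
  if (!is.null(sim$ground_truth)) {
    jsonlite::write_json(sim$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         dataframe = "columns", digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a catalog directory written by [write_catalog_dir()]
#'
#' @param dir Directory containing `chrom.sizes` and
#'   `<lineage>_<generation>_<mark>.tsv` files.
#' @return List with `assembly` and `catalog`.
#' @export
read_catalog_dir <- function(dir) {
  assembly <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  files <- list.files(dir, pattern = "\\.tsv$", full.names = FALSE)
  sets <- list()
  for (fn in files) {
    parts <- strsplit(sub("\\.tsv$", "", fn), "_")[[1]]
    if (length(parts) < 3L) next
    mark <- parts[length(parts)]
    gen <- parts[length(parts) - 1L]
    lin <- paste(parts[seq_len(length(parts) - 2L)], collapse = "_")
    if (!mark %in% EPI_MARKS || !gen %in% EPI_GENERATIONS) next
    sets[[length(sets) + 1L]] <- read_epimutation_table(
      file.path(dir, fn), format = "tsv", mark = mark, generation = gen,
      lineage = lin)
  }
  if (!length(sets)) stop("no catalog TSV files found in ", dir, call. = FALSE)
  list(assembly = assembly, catalog = build_catalog(sets))
}
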