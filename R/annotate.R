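# Gene association and tabular exports.

#' Associate epimutations with genes
#'
#' Each epimutation is linked to every gene it shares at least one base pair
#' with (relation `"overlapping"`, distance 0). An epimutation overlapping
#' no gene is linked to the single nearest gene on its chromosome if the gap
#' is at most `max_distance_bp` (relation `"within_distance"`); ties are
#' broken by gene symbol. Epimutations with no association are omitted.
#' An abutting gene counts as `within_distance` at distance 0.
#'
#' @param s An [epimutation_set()] (or interval table with an `id` column).
#' @param genes Gene table with columns `chrom`, `start`, `end`, `symbol`
#'   (e.g. from [generate_gene_annotation()]).
#' @param max_distance_bp Maximum gap for nearest-gene association
#'   (default 10000, the window scale of the analysis).
#' @return Data frame with columns `id`, `gene`, `relation`, `distance_bp`,
#'   in the order of `s`.
#' @export
associate_genes <- function(s, genes, max_distance_bp = 10000) {
  validate_intervals(genes, "gene table")
  out <- list()
  for (ch in unique(s$chrom)) {
    ei <- which(s$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    # gap matrix: negative where the epimutation and gene share bases
    gap <- pmax(outer(-s$end[ei], g$start, `+`),
                outer(s$start[ei], -g$end, `+`))
    for (r in seq_along(ei)) {
      ov <- which(gap[r, ] < 0)
      if (length(ov)) {
        ov <- ov[order(g$symbol[ov])]
        out[[length(out) + 1L]] <- data.frame(
          id = s$id[ei[r]], gene = g$symbol[ov], relation = "overlapping",
          distance_bp = 0, stringsAsFactors = FALSE)
      } else {
        d <- gap[r, ]
        j <- which(d == min(d))
        j <- j[order(g$symbol[j])][1]
        if (d[j] <= max_distance_bp) {
          out[[length(out) + 1L]] <- data.frame(
            id = s$id[ei[r]], gene = g$symbol[j],
            relation = "within_distance", distance_bp = d[j],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(id = character(0), gene = character(0),
                      relation = character(0), distance_bp = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$id, s$id), res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write an overlap matrix as long-format CSV
#'
#' One row per cell: `flank_bp`, `lineage`, `row_label`, `col_label`,
#' `row_size`, `count`, `percent`. Reads back with
#' [read_overlap_matrix()] without information loss.
#'
#' @param m An `overlap_matrix` from [extended_overlap_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_overlap_matrix <- function(m, path) {
  labs_r <- rownames(m$counts)
  labs_c <- colnames(m$counts)
  df <- data.frame(
    flank_bp = m$flank_bp, lineage = m$lineage,
    row_label = rep(labs_r, times = length(labs_c)),
    col_label = rep(labs_c, each = length(labs_r)),
    row_size = rep(unname(m$row_sizes), times = length(labs_c)),
    count = as.vector(m$counts),
    percent = as.vector(m$percents),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an overlap matrix written by [write_overlap_matrix()]
#'
#' @param path CSV path.
#' @return An `overlap_matrix` (without the threshold scheme, which is not
#'   serialized).
#' @export
read_overlap_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  labs_r <- unique(df$row_label)
  labs_c <- unique(df$col_label)
  counts <- matrix(0L, length(labs_r), length(labs_c),
                   dimnames = list(labs_r, labs_c))
  percents <- matrix(NA_real_, length(labs_r), length(labs_c),
                     dimnames = list(labs_r, labs_c))
  counts[cbind(df$row_label, df$col_label)] <- df$count
  percents[cbind(df$row_label, df$col_label)] <- df$percent
  row_sizes <- df$row_size[match(labs_r, df$row_label)]
  names(row_sizes) <- labs_r
  structure(list(counts = counts, percents = percents,
                 row_sizes = row_sizes, col_sizes = NULL,
                 flank_bp = df$flank_bp[1], lineage = df$lineage[1],
                 scheme = NULL),
            class = "overlap_matrix")
}

#' Write a Venn partition as JSON
#' @param v A [venn_partition()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_venn <- function(v, path) {
  jsonlite::write_json(
    list(labels = v$labels, flank_bp = v$flank_bp, unit = v$unit,
         n_components = v$n_components, counts = as.list(v$counts)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a permutation test result as JSON
#'
#' Serializes the observed statistic, empirical p-value, settings and the
#' null summary (quantiles); optionally the full null distribution.
#'
#' @param x A `permutation_test`.
#' @param path Output path.
#' @param full_null Include the complete `null_counts` vector?
#' @return `path`, invisibly.
#' @export
write_permutation <- function(x, path, full_null = FALSE) {
  obj <- list(statistic = x$statistic, observed = x$observed,
              p_value = x$p_value, n_perm = x$n_perm,
              site_size_bp = x$site_size_bp, flank_bp = x$flank_bp,
              seed = x$seed,
              null_quantiles = as.list(stats::quantile(
                x$null_counts, c(0, 0.25, 0.5, 0.75, 0.95, 1))))
  if (full_null) obj$null_counts <- x$null_counts
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write colocalized sites as TSV and BED
#'
#' The TSV mirrors the supplementary-table layout (location, anchor mark and
#' p-value, partner marks and p-values, genes); the BED carries the anchor
#' intervals for genome browsers.
#'
#' @param sites A [colocalization_scan()] result.
#' @param tsv_path,bed_path Output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_colocalized_sites <- function(sites, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    out <- as.data.frame(sites)
    for (cn in c("start", "end", "midpoint")) {
      out[[cn]] <- format(out[[cn]], scientific = FALSE, trim = TRUE)
    }
    out$anchor_p <- format(out$anchor_p, digits = 6, trim = TRUE)
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  if (!is.null(bed_path)) {
    if (nrow(sites)) {
      lines <- sprintf("%s\t%s\t%s\t%s|%s>%s\t%s",
                       sites$chrom,
                       format(sites$start, scientific = FALSE, trim = TRUE),
                       format(sites$end, scientific = FALSE, trim = TRUE),
                       sites$anchor_id, sites$anchor_mark,
                       sites$partner_marks,
                       format(sites$anchor_p, digits = 6, trim = TRUE))
    } else lines <- character(0)
    writeLines(lines, bed_path)
  }
  invisible(c(tsv = tsv_path, bed = bed_path))
}

#' Chromosome-plot table for ideogram-style figures
#'
#' Emits a plot-ready long table (chromosome, position in Mb, mark, colour
#' code) from a colocalized-sites scan, suitable for external plotting of
#' per-chromosome epimutation maps.
#'
#' @param sites A [colocalization_scan()] result.
#' @return Data frame with columns `chrom`, `position_mb`, `mark`, `color`.
#' @export
chromosome_plot_table <- function(sites) {
  palette <- c(DMR = "red", ncRNA = "blue", DHR = "green")
  data.frame(chrom = sites$chrom,
             position_mb = sites$midpoint / 1e6,
             mark = sites$anchor_mark,
             color = unname(palette[sites$anchor_mark]),
             stringsAsFactors = FALSE)
}

#' Export a full analysis report
#'
#' Writes every computed result under `out_dir`: overlap-matrix CSVs, Venn
#' JSONs, colocalized-site TSV/BED, permutation JSONs, gene-association TSV
#' and a `manifest.json` recording the configuration, seed and package
#' version. Overwrites idempotently; identical inputs produce byte-identical
#' files.
#'
#' @param results Named list with any of: `matrices` (named list of
#'   `overlap_matrix`), `venns` (named list of `venn_partition`), `coloc`
#'   (colocalized sites), `permutations` (named list of
#'   `permutation_test`), `gene_associations` (data frame), `config`
#'   (serializable list), `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
export_report <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  add <- function(p) written <<- c(written, p)
  for (nm in names(results$matrices)) {
    p <- file.path(out_dir, sprintf("overlap_matrix_%s.csv", nm))
    write_overlap_matrix(results$matrices[[nm]], p); add(p)
  }
  for (nm in names(results$venns)) {
    p <- file.path(out_dir, sprintf("venn_%s.json", nm))
    write_venn(results$venns[[nm]], p); add(p)
  }
  if (!is.null(results$coloc)) {
    pt <- file.path(out_dir, "colocalized_sites.tsv")
    pb <- file.path(out_dir, "colocalized_sites.bed")
    write_colocalized_sites(results$coloc, pt, pb)
    add(pt); add(pb)
  }
  for (nm in names(results$permutations)) {
    p <- file.path(out_dir, sprintf("permutation_%s.json", nm))
    write_permutation(results$permutations[[nm]], p); add(p)
  }
  if (!is.null(results$gene_associations)) {
    p <- file.path(out_dir, "gene_associations.tsv")
    utils::write.table(results$gene_associations, p, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    add(p)
  }
  manifest <- list(
    package = "epioverlap",
    version = as.character(utils::packageVersion("epioverlap")),
    seed = results$seed,
    config = results$config,
    files = sort(basename(written)))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  add(mp)
  invisible(written)
}
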