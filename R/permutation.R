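# Permutation significance of observed overlaps against random placement.
#
# The null model re-places size-matched fixed-width sites (1 kb or 10 kb by
# default) uniformly over the genome: a chromosome is chosen with
# probability proportional to the number of valid start positions
# (length - site_size + 1), then the start is uniform over that range.
# Empirical p-values use the add-one estimator (1 + #{null >= obs}) /
# (1 + n_perm), which is conservative and never zero.

#' Place random fixed-width sites uniformly on a genome
#'
#' @param n Number of sites (>= 0).
#' @param site_size_bp Site width in bp (>= 1). Chromosomes shorter than the
#'   site are excluded with a warning.
#' @param assembly A [genome_assembly()].
#' @param lineage,generation,mark Identity stamped on the returned set
#'   (placement is what matters; defaults mark the set as randomized).
#' @return An [epimutation_set()] of `n` sites of exactly `site_size_bp` bp.
#'   Sites may overlap one another. Placement uses the current RNG state;
#'   seed via [set.seed()] or the calling test function.
#' @export
randomize_sites <- function(n, site_size_bp, assembly,
                            lineage = "random", generation = "F1",
                            mark = "DMR") {
  stopifnot(n >= 0, site_size_bp >= 1)
  ok <- assembly$length >= site_size_bp
  if (!any(ok)) {
    stop("no chromosome can host a site of ",
         format(site_size_bp, scientific = FALSE), " bp", call. = FALSE)
  }
  if (!all(ok)) {
    warning(sum(!ok), " chromosome(s) shorter than the site size excluded",
            call. = FALSE)
  }
  chroms <- assembly$chrom[ok]
  lens <- assembly$length[ok]
  nvalid <- lens - site_size_bp + 1
  if (n == 0) {
    return(epimutation_set(
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 p_value = numeric(0), stringsAsFactors = FALSE),
      mark = mark, generation = generation, lineage = lineage))
  }
  ci <- sample.int(length(chroms), n, replace = TRUE, prob = nvalid)
  start <- floor(stats::runif(n) * nvalid[ci])
  epimutation_set(
    data.frame(chrom = chroms[ci], start = start,
               end = start + site_size_bp, p_value = rep(1, n),
               stringsAsFactors = FALSE),
    mark = mark, generation = generation, lineage = lineage)
}

new_permutation_test <- function(observed, null_counts, n_perm, site_size_bp,
                                 flank_bp, seed, statistic) {
  p <- (1 + sum(null_counts >= observed)) / (1 + n_perm)
  structure(list(observed = observed, null_counts = null_counts,
                 p_value = p, n_perm = n_perm,
                 site_size_bp = site_size_bp, flank_bp = flank_bp,
                 seed = seed, statistic = statistic),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation overlap test (%s)\n", x$statistic))
  cat(sprintf("  observed = %d, null mean = %.2f (sd %.2f), n_perm = %d\n",
              x$observed, mean(x$null_counts), stats::sd(x$null_counts),
              x$n_perm))
  cat(sprintf("  site size = %s bp, flank = %s bp, seed = %d\n",
              format(x$site_size_bp, scientific = FALSE),
              format(x$flank_bp, scientific = FALSE), x$seed))
  cat(sprintf("  empirical p = %.6g\n", x$p_value))
  invisible(x)
}

#' Permutation test of overlap between two feature sets
#'
#' The observed statistic is the number of `test` features overlapping at
#' least one `fixed` feature (after optional symmetric flank extension of
#' both sets). Each permutation replaces `test` with size-matched random
#' fixed-width sites placed uniformly on the genome and recomputes the
#' statistic; `fixed` conditions the test and is never randomized.
#'
#' @param fixed The anchor set, held fixed.
#' @param test The set whose placement is randomized.
#' @param assembly A [genome_assembly()].
#' @param site_size_bp Width of the random replacement sites (1000 or 10000
#'   in the standard analysis).
#' @param n_perm Number of permutations (>= 1; default 999).
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   results. The caller's RNG state is restored afterwards.
#' @param flank_bp Optional symmetric extension applied to both sets (and to
#'   each randomized replacement) before counting.
#' @return A `permutation_test` with `observed`, `null_counts`, `p_value`
#'   (add-one estimator), `n_perm`, `site_size_bp`, `flank_bp`, `seed`.
#' @export
permutation_overlap_test <- function(fixed, test, assembly,
                                     site_size_bp = 1000, n_perm = 999,
                                     seed = 1, flank_bp = 0) {
  stopifnot(n_perm >= 1)
  seed <- as.integer(seed)
  fixed_e <- if (flank_bp > 0) extend_window(fixed, flank_bp, assembly) else fixed
  test_e <- if (flank_bp > 0) extend_window(test, flank_bp, assembly) else test
  prep <- prepare_subject(fixed_e)
  observed <- sum(overlaps_any_prepared(test_e, prep))
  n_sites <- nrow(test)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      r <- randomize_sites(n_sites, site_size_bp, assembly)
      if (flank_bp > 0) r <- extend_window(r, flank_bp, assembly)
      sum(overlaps_any_prepared(r, prep))
    }, 0L)
  })
  new_permutation_test(observed, null_counts, n_perm, site_size_bp, flank_bp,
                       seed, statistic = "test features overlapping fixed set")
}

#' Permutation test of three-mark colocalization
#'
#' The statistic is the number of overlap regions (connected components of
#' the pooled stringent F3 DMR, DHR and ncRNA features, see
#' [venn_partition()]) containing all three marks. The DMR set anchors the
#' test; the null randomizes the DHR and ncRNA sets as size-matched
#' fixed-width sites.
#'
#' @param catalog An epimutation catalog containing the three stringent F3
#'   sets for `lineage`.
#' @param lineage Lineage label.
#' @param scheme A [threshold_scheme()].
#' @param assembly A [genome_assembly()].
#' @param site_size_bp,n_perm,seed,flank_bp As in
#'   [permutation_overlap_test()].
#' @param generation Generation to test (default `"F3"`, where all three
#'   mark types are present).
#' @return A `permutation_test`.
#' @export
multiway_colocalization_test <- function(catalog, lineage,
                                         scheme = threshold_scheme(),
                                         assembly, site_size_bp = 1000,
                                         n_perm = 999, seed = 1,
                                         flank_bp = 0, generation = "F3") {
  stopifnot(n_perm >= 1)
  seed <- as.integer(seed)
  sel <- suppressWarnings(select_sets(catalog, lineage, scheme))
  sets <- list(DMR = sel$stringent[[paste(generation, "DMR")]],
               DHR = sel$stringent[[paste(generation, "DHR")]],
               ncRNA = sel$stringent[[paste(generation, "ncRNA")]])
  miss <- names(sets)[vapply(sets, is.null, TRUE)]
  if (length(miss)) {
    stop("catalog lacks stringent ", generation, " set(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  triple_sig <- paste(c("DMR", "DHR", "ncRNA"), collapse = "&")
  stat <- function(dmr, dhr, ncrna) {
    vp <- venn_partition(list(DMR = dmr, DHR = dhr, ncRNA = ncrna),
                         flank_bp = flank_bp, assembly = assembly)
    cnt <- vp$counts[triple_sig]
    if (is.na(cnt)) 0L else as.integer(cnt)
  }
  observed <- stat(sets$DMR, sets$DHR, sets$ncRNA)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      dhr_r <- randomize_sites(nrow(sets$DHR), site_size_bp, assembly,
                               mark = "DHR", generation = generation)
      nc_r <- randomize_sites(nrow(sets$ncRNA), site_size_bp, assembly,
                              mark = "ncRNA", generation = generation)
      stat(sets$DMR, dhr_r, nc_r)
    }, 0L)
  })
  new_permutation_test(observed, null_counts, n_perm, site_size_bp, flank_bp,
                       seed,
                       statistic = "overlap regions containing DMR, DHR and ncRNA")
}
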