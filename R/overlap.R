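# Interval overlap engine: pairwise sweep-line enumeration, fast membership
# queries, window extension, the stringent-vs-relaxed extended overlap
# matrix, Venn partitioning into overlap components, and colocalization
# scans.
#
# Overlap is defined as >= 1 shared base pair under half-open arithmetic:
# a overlaps b iff a$start < b$end && b$start < a$end on the same
# chromosome. Abutting intervals ([0,10) vs [10,20)) do not overlap.

# Sweep-line pair enumeration on one chromosome. Returns a 2-column matrix
# of (index into a, index into b). End events are processed before start
# events at the same coordinate, which realises the half-open convention.
sweep_chrom_pairs <- function(sa, ea, sb, eb) {
  n <- length(sa); m <- length(sb)
  pos <- c(sa, sb, ea, eb)
  typ <- rep.int(c(1L, 2L, 3L, 4L), c(n, m, n, m))
  idx <- c(seq_len(n), seq_len(m), seq_len(n), seq_len(m))
  o <- order(pos, typ >= 3L, method = "radix", decreasing = c(FALSE, TRUE))
  active_a <- logical(n); active_b <- logical(m)
  acc_i <- vector("list", n + m); acc_j <- vector("list", n + m); k <- 0L
  for (e in o) {
    t <- typ[e]; i <- idx[e]
    if (t == 1L) {
      js <- which(active_b)
      if (length(js)) {
        k <- k + 1L
        acc_i[[k]] <- rep.int(i, length(js)); acc_j[[k]] <- js
      }
      active_a[i] <- TRUE
    } else if (t == 2L) {
      is <- which(active_a)
      if (length(is)) {
        k <- k + 1L
        acc_i[[k]] <- is; acc_j[[k]] <- rep.int(i, length(is))
      }
      active_b[i] <- TRUE
    } else if (t == 3L) {
      active_a[i] <- FALSE
    } else {
      active_b[i] <- FALSE
    }
  }
  if (!k) return(cbind(integer(0), integer(0)))
  cbind(unlist(acc_i[seq_len(k)], use.names = FALSE),
        unlist(acc_j[seq_len(k)], use.names = FALSE))
}

#' Enumerate all overlapping feature pairs between two sets
#'
#' Sweep-line enumeration, O((n+m) log(n+m) + k) in the number of events and
#' reported pairs k. A pair is reported iff the two features share at least
#' one base pair.
#'
#' @param a,b Interval tables with columns `chrom`, `start`, `end` and `id`
#'   (e.g. [epimutation_set()] objects).
#' @return Data frame with columns `row_id` (member of `a`), `col_id`
#'   (member of `b`) and `shared_bp`, sorted by position of the `a` member.
#' @export
find_overlaps <- function(a, b) {
  empty <- data.frame(row_id = character(0), col_id = character(0),
                      shared_bp = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(a) || !nrow(b)) return(empty)
  out <- vector("list", 0L)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    pr <- sweep_chrom_pairs(a$start[ai], a$end[ai], b$start[bi], b$end[bi])
    if (nrow(pr)) {
      i <- ai[pr[, 1]]; j <- bi[pr[, 2]]
      out[[length(out) + 1L]] <- data.frame(
        row_id = a$id[i], col_id = b$id[j],
        shared_bp = pmin(a$end[i], b$end[j]) - pmax(a$start[i], b$start[j]),
        .i = i, .j = j, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$.i, res$.j), c("row_id", "col_id", "shared_bp")]
  rownames(res) <- NULL
  res
}

# Merge intervals (already on one chromosome) into a disjoint sorted union.
merge_intervals <- function(start, end) {
  o <- order(start, end, method = "radix")
  s <- start[o]; e <- cummax(end[o])
  new_grp <- c(TRUE, s[-1] > e[-length(e)])
  grp <- cumsum(new_grp)
  list(start = s[new_grp], end = as.numeric(tapply(e, grp, max)))
}

# Precompute the per-chromosome merged union of a subject set, for repeated
# membership queries (used heavily by the permutation engine).
prepare_subject <- function(s) {
  if (!nrow(s)) return(list())
  sp <- split(seq_len(nrow(s)), s$chrom)
  lapply(sp, function(i) merge_intervals(s$start[i], s$end[i]))
}

# Logical vector: does each query interval overlap >= 1 subject feature?
# `prep` is a prepare_subject() result.
overlaps_any_prepared <- function(q, prep) {
  out <- logical(nrow(q))
  if (!nrow(q) || !length(prep)) return(out)
  for (ch in intersect(unique(q$chrom), names(prep))) {
    m <- prep[[ch]]
    qi <- which(q$chrom == ch)
    qs <- q$start[qi]; qe <- q$end[qi]
    idx <- findInterval(qs, m$start)
    hit <- idx >= 1L & m$end[pmax(idx, 1L)] > qs
    nxt <- idx + 1L
    ok <- nxt <= length(m$start)
    hit[ok] <- hit[ok] | m$start[nxt[ok]] < qe[ok]
    out[qi] <- hit
  }
  out
}

overlaps_any <- function(q, s) overlaps_any_prepared(q, prepare_subject(s))

#' Count members of one set overlapping another
#'
#' @param a,b Interval tables (`a` provides the denominator).
#' @return List with `count` (distinct members of `a` overlapping at least
#'   one member of `b`), `percent` (`100 * count / nrow(a)`, `NA` when `a`
#'   is empty) and `n` (`nrow(a)`).
#' @details Overlap is symmetric as a relation, but `count`/`percent` are
#'   not: the denominator is always the first argument's size.
#' @export
overlap_count_percent <- function(a, b) {
  count <- sum(overlaps_any(a, b))
  list(count = count,
       percent = if (nrow(a)) 100 * count / nrow(a) else NA_real_,
       n = nrow(a))
}

#' Extend features symmetrically and clip to the chromosome
#'
#' Each interval `[start, end)` becomes `[start - flank_bp, end + flank_bp)`
#' clipped to its chromosome, so an interior feature's span grows by exactly
#' `2 * flank_bp`. With the default 5 kb flank a 1 kb-scale feature is
#' assessed over a ~10 kb window, capturing near-but-not-touching
#' colocalization.
#'
#' @param s An [epimutation_set()] (or plain interval table).
#' @param flank_bp Non-negative extension in bp per side.
#' @param assembly [genome_assembly()] used for clipping.
#' @return The extended set (ids, p-values and set identity preserved;
#'   re-sorted).
#' @export
extend_window <- function(s, flank_bp, assembly) {
  stopifnot(is.numeric(flank_bp), length(flank_bp) == 1L, flank_bp >= 0)
  if (flank_bp == 0 || !nrow(s)) return(s)
  df <- as.data.frame(s)
  df$start <- df$start - flank_bp
  df$end <- df$end + flank_bp
  df <- clip_intervals(df, assembly)
  if (inherits(s, "epimutation_set")) {
    epimutation_set(df, mark = set_mark(s), generation = set_generation(s),
                    lineage = set_lineage(s),
                    threshold_applied = attr(s, "threshold_applied"))
  } else {
    df[order(df$chrom, df$start, df$end), , drop = FALSE]
  }
}

#' Extended overlap matrix (stringent rows vs relaxed columns)
#'
#' For one lineage, every (generation, mark) set at its stringent cutoff is
#' compared against every (generation, mark) set at the relaxed cutoff. Cell
#' (i, j) counts the distinct stringent-row features overlapping at least
#' one relaxed-column feature; the percentage divides by the row set size.
#' A set compared with its own relaxed superset therefore always reads 100%.
#' With `flank_bp > 0` both row and column features are extended by
#' `flank_bp` before comparison (both-sides extension; see the vignette).
#'
#' @param catalog An epimutation catalog.
#' @param lineage Lineage label.
#' @param scheme A [threshold_scheme()].
#' @param flank_bp Flank in bp (0 = direct overlap; 5000 = 10 kb windows).
#' @param assembly [genome_assembly()]; required when `flank_bp > 0`.
#' @return An `overlap_matrix`: list with integer `counts`, real `percents`
#'   (`NA` rows for empty stringent sets), `row_sizes`, `col_sizes`,
#'   `flank_bp` and `lineage`.
#' @export
extended_overlap_matrix <- function(catalog, lineage,
                                    scheme = threshold_scheme(),
                                    flank_bp = 0, assembly = NULL) {
  sel <- select_sets(catalog, lineage, scheme)
  rows <- sel$stringent
  cols <- sel$relaxed
  if (flank_bp > 0) {
    if (is.null(assembly)) {
      stop("an assembly is required when flank_bp > 0", call. = FALSE)
    }
    rows <- lapply(rows, extend_window, flank_bp = flank_bp,
                   assembly = assembly)
    cols <- lapply(cols, extend_window, flank_bp = flank_bp,
                   assembly = assembly)
  }
  labs_r <- names(rows)
  labs_c <- names(cols)
  counts <- matrix(0L, length(labs_r), length(labs_c),
                   dimnames = list(labs_r, labs_c))
  percents <- matrix(NA_real_, length(labs_r), length(labs_c),
                     dimnames = list(labs_r, labs_c))
  preps <- lapply(cols, prepare_subject)
  for (i in seq_along(rows)) {
    ri <- rows[[i]]
    for (j in seq_along(cols)) {
      cnt <- sum(overlaps_any_prepared(ri, preps[[j]]))
      counts[i, j] <- cnt
      if (nrow(ri)) percents[i, j] <- 100 * cnt / nrow(ri)
    }
  }
  structure(list(counts = counts, percents = percents,
                 row_sizes = vapply(rows, nrow, 0L),
                 col_sizes = vapply(cols, nrow, 0L),
                 flank_bp = flank_bp, lineage = lineage,
                 scheme = scheme),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf(
    "Extended overlap matrix, lineage %s, flank %s bp (rows stringent, columns p < %g)\n",
    x$lineage, format(x$flank_bp, scientific = FALSE), x$scheme$relaxed))
  disp <- matrix(sprintf("%d (%s%%)", x$counts,
                         ifelse(is.na(x$percents), "-",
                                formatC(x$percents, format = "f", digits = 1))),
                 nrow(x$counts), dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  invisible(x)
}

# Single-linkage overlap components over a combined interval table.
# Returns an integer component id per row. Features in a component chain
# overlap pairwise-transitively; abutting intervals start a new component.
overlap_components <- function(df) {
  comp <- integer(nrow(df))
  offset <- 0L
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    o <- order(df$start[i], df$end[i], method = "radix")
    io <- i[o]
    s <- df$start[io]; e <- df$end[io]
    maxe <- cummax(e)
    new_comp <- c(TRUE, s[-1] >= maxe[-length(maxe)])
    comp[io] <- offset + cumsum(new_comp)
    offset <- offset + sum(new_comp)
  }
  comp
}

#' Venn partition of 2-3 epimutation sets
#'
#' Pools the (optionally window-extended) features of the input sets,
#' clusters them into connected components under single-linkage overlap, and
#' counts components by membership signature (which input sets contribute at
#' least one feature). Counting regions rather than features keeps the
#' partition well defined when sets differ in feature width; per-feature
#' counting is available via `unit = "feature"`.
#'
#' @param sets Named list of 2 or 3 interval tables; names are the Venn
#'   labels (defaults to `set_label()` for epimutation sets).
#' @param flank_bp Extension per side before clustering (0 = direct).
#' @param assembly Required when `flank_bp > 0`.
#' @param unit `"region"` (default; count components) or `"feature"` (count
#'   features by their component's signature).
#' @return A `venn_partition`: list with `labels`, named integer `counts`
#'   per signature (labels joined by `"&"`), `n_components` and `flank_bp`.
#'   Signature counts always sum to `n_components` (region unit) or to the
#'   total feature count (feature unit).
#' @export
venn_partition <- function(sets, flank_bp = 0, assembly = NULL,
                           unit = c("region", "feature")) {
  unit <- match.arg(unit)
  if (length(sets) < 2L || length(sets) > 3L) {
    stop("venn_partition supports 2 or 3 sets, got ", length(sets),
         call. = FALSE)
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- vapply(sets, function(s) {
      if (inherits(s, "epimutation_set")) set_label(s) else ""
    }, "")
    if (any(!nzchar(names(sets))) || anyDuplicated(names(sets))) {
      names(sets) <- paste0("set", seq_along(sets))
    }
  }
  if (flank_bp > 0) {
    if (is.null(assembly)) {
      stop("an assembly is required when flank_bp > 0", call. = FALSE)
    }
    sets <- lapply(sets, extend_window, flank_bp = flank_bp,
                   assembly = assembly)
  }
  labels <- names(sets)
  df <- do.call(rbind, lapply(seq_along(sets), function(k) {
    s <- sets[[k]]
    if (!nrow(s)) return(NULL)
    data.frame(chrom = s$chrom, start = s$start, end = s$end,
               label = labels[k], stringsAsFactors = FALSE)
  }))
  if (is.null(df) || !nrow(df)) {
    return(structure(list(labels = labels, counts = integer(0),
                          n_components = 0L, flank_bp = flank_bp,
                          unit = unit),
                     class = "venn_partition"))
  }
  comp <- overlap_components(df)
  sig_of <- vapply(split(df$label, comp), function(ls) {
    paste(labels[labels %in% ls], collapse = "&")
  }, "")
  if (unit == "region") {
    counts <- table(sig_of)
  } else {
    counts <- table(sig_of[as.character(comp)])
  }
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(labels = labels, counts = counts,
                 n_components = max(comp), flank_bp = flank_bp, unit = unit),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("Venn partition of {%s}: %d overlap region(s), flank %s bp, unit = %s\n",
              paste(x$labels, collapse = ", "), x$n_components,
              format(x$flank_bp, scientific = FALSE), x$unit))
  for (sig in names(x$counts)) cat(sprintf("  %-30s %d\n", sig, x$counts[[sig]]))
  invisible(x)
}

#' Scan for multi-mark colocalized sites
#'
#' Within each generation of a lineage, every stringent-threshold feature is
#' taken as an anchor and relaxed-threshold features of the *other* marks
#' overlapping it (directly, or within the window when `flank_bp > 0`;
#' both sides are extended) are collected as partners. Only anchors with at
#' least one partner are reported.
#'
#' @param catalog An epimutation catalog.
#' @param lineage Lineage label.
#' @param scheme A [threshold_scheme()].
#' @param flank_bp Window flank per side (0 = direct overlap).
#' @param assembly Required when `flank_bp > 0`.
#' @param generations Generations to scan (default all three).
#' @return A data frame (class `colocalized_sites`), one row per anchor with
#'   partners, sorted by (generation, chrom, midpoint): columns `lineage`,
#'   `generation`, `anchor_id`, `anchor_mark`, `anchor_p`, `chrom`, `start`,
#'   `end`, `midpoint`, `n_partners`, `partner_marks`, `partner_ids`,
#'   `partner_p`, `genes` (comma-joined partner lists).
#' @export
colocalization_scan <- function(catalog, lineage, scheme = threshold_scheme(),
                                flank_bp = 0, assembly = NULL,
                                generations = EPI_GENERATIONS) {
  sel <- select_sets(catalog, lineage, scheme)
  ext <- function(s) {
    if (flank_bp > 0) {
      if (is.null(assembly)) {
        stop("an assembly is required when flank_bp > 0", call. = FALSE)
      }
      extend_window(s, flank_bp, assembly)
    } else s
  }
  rows <- list()
  for (g in generations) {
    for (m in EPI_MARKS) {
      lab <- paste(g, m)
      anchors <- sel$stringent[[lab]]
      if (is.null(anchors) || !nrow(anchors)) next
      anchors_e <- ext(anchors)
      partner_tabs <- list()
      for (m2 in setdiff(EPI_MARKS, m)) {
        p <- sel$relaxed[[paste(g, m2)]]
        if (is.null(p) || !nrow(p)) next
        pe <- ext(p)
        hits <- find_overlaps(anchors_e, pe)
        if (nrow(hits)) {
          pm <- match(hits$col_id, p$id)
          partner_tabs[[m2]] <- data.frame(
            anchor_id = hits$row_id, partner_id = hits$col_id,
            partner_mark = m2, partner_p = p$p_value[pm],
            partner_gene = p$gene[pm], stringsAsFactors = FALSE)
        }
      }
      if (!length(partner_tabs)) next
      partners <- do.call(rbind, partner_tabs)
      by_anchor <- split(partners, partners$anchor_id)
      am <- match(names(by_anchor), anchors$id)
      rows[[length(rows) + 1L]] <- data.frame(
        lineage = lineage, generation = g,
        anchor_id = names(by_anchor), anchor_mark = m,
        anchor_p = anchors$p_value[am],
        chrom = anchors$chrom[am],
        start = anchors$start[am], end = anchors$end[am],
        midpoint = floor((anchors$start[am] + anchors$end[am]) / 2),
        n_partners = vapply(by_anchor, nrow, 0L),
        partner_marks = vapply(by_anchor, function(d) {
          paste(sort(unique(d$partner_mark)), collapse = ",")
        }, ""),
        partner_ids = vapply(by_anchor, function(d) {
          paste(d$partner_id, collapse = ",")
        }, ""),
        partner_p = vapply(by_anchor, function(d) {
          paste(format(d$partner_p, digits = 6, trim = TRUE), collapse = ",")
        }, ""),
        genes = vapply(by_anchor, function(d) {
          gs <- unique(d$partner_gene[!is.na(d$partner_gene)])
          paste(gs, collapse = ",")
        }, ""),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(lineage = character(0), generation = character(0),
                      anchor_id = character(0), anchor_mark = character(0),
                      anchor_p = numeric(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      midpoint = numeric(0), n_partners = integer(0),
                      partner_marks = character(0), partner_ids = character(0),
                      partner_p = character(0), genes = character(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(match(out$generation, EPI_GENERATIONS), out$chrom,
                     out$midpoint, out$anchor_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("colocalized_sites", "data.frame")
  out
}
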