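# Epimutation records, sets and the dual-threshold scheme.
#
# An epimutation is one candidate feature -- a differential DNA methylation
# region (DMR), a differential histone retention site (DHR), or a
# differentially expressed non-coding RNA locus (ncRNA) -- with a genomic
# interval and a raw p-value. Sets are homogeneous in (lineage, generation,
# mark). The analysis contrasts each set at a stringent per-mark cutoff
# (DMR/DHR p < 1e-06, ncRNA p < 1e-04) against sets at a relaxed p < 0.05
# cutoff; all comparisons are strict ("p < cutoff").

#' Recognised epigenetic mark types, in display order
#' @export
EPI_MARKS <- c("DMR", "ncRNA", "DHR")

#' Recognised generations, in display order
#' @export
EPI_GENERATIONS <- c("F1", "F2", "F3")

#' Construct an epimutation set
#'
#' @param x Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `p_value`; optional `id`, `gene`, `subtype`. Missing ids
#'   are synthesised from lineage/generation/mark and row number.
#' @param mark One of `r paste(EPI_MARKS, collapse = ", ")`.
#' @param generation One of `r paste(EPI_GENERATIONS, collapse = ", ")`.
#' @param lineage Exposure-lineage label (e.g. `"vinclozolin"`, `"DDT"`).
#' @param threshold_applied Optional p-value cutoff already applied to the
#'   members (every member must then satisfy `p_value < threshold_applied`).
#' @return An `epimutation_set`: a data frame sorted by
#'   (chrom, start, end, id) with attributes `mark`, `generation`,
#'   `lineage` and `threshold_applied`.
#' @details Duplicate or mutually overlapping members are kept as-is: counts
#'   downstream are per feature, and merging would silently change the
#'   denominators of overlap percentages.
#' @export
epimutation_set <- function(x, mark, generation, lineage,
                            threshold_applied = NULL) {
  mark <- match.arg(mark, EPI_MARKS)
  generation <- match.arg(generation, EPI_GENERATIONS)
  stopifnot(is.character(lineage), length(lineage) == 1L, nzchar(lineage))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  validate_intervals(x, what = sprintf("%s %s %s set", lineage, generation, mark))
  if (!"p_value" %in% names(x)) {
    stop("epimutation table lacks a 'p_value' column", call. = FALSE)
  }
  if (nrow(x)) {
    bad <- which(is.na(x$p_value) | x$p_value <= 0 | x$p_value > 1)
    if (length(bad)) {
      stop(sprintf("row %d: p_value must lie in (0, 1] (got %s)",
                   bad[1], format(x$p_value[bad[1]])), call. = FALSE)
    }
  }
  if (!"id" %in% names(x)) {
    x$id <- if (nrow(x)) {
      sprintf("%s_%s_%s_%05d", lineage, generation, mark, seq_len(nrow(x)))
    } else character(0)
  }
  x$id <- as.character(x$id)
  if (!"gene" %in% names(x)) x$gene <- rep(NA_character_, nrow(x))
  if (!"subtype" %in% names(x)) x$subtype <- rep(NA_character_, nrow(x))
  if (!is.null(threshold_applied)) {
    stopifnot(threshold_applied > 0, threshold_applied <= 1)
    if (nrow(x) && any(x$p_value >= threshold_applied)) {
      stop("members violate the declared threshold_applied", call. = FALSE)
    }
  }
  x <- x[, c("id", "chrom", "start", "end", "p_value", "gene", "subtype")]
  o <- order(x$chrom, x$start, x$end, x$id, method = "radix")
  x <- x[o, , drop = FALSE]
  rownames(x) <- NULL
  structure(x,
            mark = mark, generation = generation, lineage = lineage,
            threshold_applied = threshold_applied,
            class = c("epimutation_set", "data.frame"))
}

#' @export
print.epimutation_set <- function(x, ...) {
  thr <- attr(x, "threshold_applied")
  cat(sprintf("Epimutation set: %s / %s / %s, %d feature(s)%s\n",
              attr(x, "lineage"), attr(x, "generation"), attr(x, "mark"),
              nrow(x),
              if (is.null(thr)) "" else sprintf(" (p < %g applied)", thr)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more\n", nrow(x) - 6))
  invisible(x)
}

#' @export
`[.epimutation_set` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && identical(names(out), names(x))) {
    attr(out, "mark") <- attr(x, "mark")
    attr(out, "generation") <- attr(x, "generation")
    attr(out, "lineage") <- attr(x, "lineage")
    attr(out, "threshold_applied") <- attr(x, "threshold_applied")
    class(out) <- class(x)
  }
  out
}

set_mark <- function(s) attr(s, "mark")
set_generation <- function(s) attr(s, "generation")
set_lineage <- function(s) attr(s, "lineage")

#' Label of an epimutation set ("generation mark")
#' @param s An [epimutation_set()].
#' @return Character scalar, e.g. `"F1 DMR"`.
#' @export
set_label <- function(s) paste(set_generation(s), set_mark(s))

#' Dual-threshold scheme
#'
#' The per-mark stringent cutoffs used to define each candidate set, and the
#' single relaxed cutoff the stringent sets are compared against. Both are
#' applied strictly (`p < cutoff`).
#'
#' @param stringent Named numeric vector of per-mark cutoffs. Defaults:
#'   DMR `1e-06`, DHR `1e-06`, ncRNA `1e-04`.
#' @param relaxed Single relaxed cutoff, default `0.05`.
#' @return A `threshold_scheme` list.
#' @export
threshold_scheme <- function(stringent = c(DMR = 1e-06, DHR = 1e-06,
                                           ncRNA = 1e-04),
                             relaxed = 0.05) {
  miss <- setdiff(EPI_MARKS, names(stringent))
  if (length(miss)) {
    stop("stringent cutoffs missing for mark(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  stringent <- stringent[EPI_MARKS]
  if (any(stringent <= 0) || any(stringent > relaxed) ||
      relaxed > 1 || relaxed <= 0) {
    stop("need 0 < stringent cutoff <= relaxed <= 1 for every mark",
         call. = FALSE)
  }
  structure(list(stringent = stringent, relaxed = relaxed),
            class = "threshold_scheme")
}

#' @export
print.threshold_scheme <- function(x, ...) {
  cat("Threshold scheme (strict p < cutoff):\n")
  for (m in names(x$stringent)) {
    cat(sprintf("  %-6s stringent p < %g\n", m, x$stringent[[m]]))
  }
  cat(sprintf("  relaxed  p < %g\n", x$relaxed))
  invisible(x)
}

#' Filter an epimutation set at a p-value cutoff
#'
#' Keeps members with `p_value < p_max` (strict). Monotone in `p_max` and
#' idempotent at a fixed cutoff; the input is not modified.
#'
#' @param s An [epimutation_set()].
#' @param p_max Cutoff in (0, 1].
#' @return A new `epimutation_set` with `threshold_applied = p_max`.
#' @export
apply_threshold <- function(s, p_max) {
  stopifnot(inherits(s, "epimutation_set"),
            is.numeric(p_max), length(p_max) == 1L, p_max > 0, p_max <= 1)
  keep <- s$p_value < p_max
  epimutation_set(as.data.frame(s)[keep, , drop = FALSE],
                  mark = set_mark(s), generation = set_generation(s),
                  lineage = set_lineage(s), threshold_applied = p_max)
}

#' Read an epimutation table from TSV or BED
#'
#' @param path Input file.
#' @param format `"tsv"` (tab-delimited with header) or `"bed"`
#'   (headerless; columns chrom, start, end, name, p-value-as-score).
#' @param mark,generation,lineage Set identity (see [epimutation_set()]).
#' @param columns For TSV: named list mapping the required fields
#'   (`chrom`, `start`, `end`, `p_value`; optionally `id`, `gene`,
#'   `subtype`) to column names in the file. Defaults to identical names.
#' @param zero_based Are input coordinates 0-based half-open (`TRUE`,
#'   default, the BED convention)? If `FALSE`, 1-based inclusive starts are
#'   converted at this boundary.
#' @return An [epimutation_set()].
#' @export
read_epimutation_table <- function(path, format = c("tsv", "bed"),
                                   mark, generation, lineage,
                                   columns = NULL, zero_based = TRUE) {
  format <- match.arg(format)
  if (format == "bed") {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end",
                                           "id", "p_value")[1:5],
                             fill = TRUE)
    df <- raw
  } else {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    map <- list(chrom = "chrom", start = "start", end = "end",
                p_value = "p_value", id = "id", gene = "gene",
                subtype = "subtype")
    if (!is.null(columns)) map[names(columns)] <- columns
    need <- c("chrom", "start", "end", "p_value")
    miss <- need[!vapply(map[need], function(cn) cn %in% names(raw), TRUE)]
    if (length(miss)) {
      stop("column(s) not found in ", path, ": ",
           paste(unlist(map[miss]), collapse = ", "), call. = FALSE)
    }
    df <- data.frame(chrom = as.character(raw[[map$chrom]]),
                     start = raw[[map$start]],
                     end = raw[[map$end]],
                     p_value = raw[[map$p_value]],
                     stringsAsFactors = FALSE)
    for (opt in c("id", "gene", "subtype")) {
      if (map[[opt]] %in% names(raw)) df[[opt]] <- raw[[map[[opt]]]]
    }
  }
  for (cn in c("start", "end", "p_value")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad)) {
      stop(sprintf("%s row %d: unparseable %s '%s'", path, bad[1], cn,
                   df[[cn]][bad[1]]), call. = FALSE)
    }
    df[[cn]] <- v
  }
  if (!zero_based) df$start <- df$start - 1
  bad <- which(is.na(df$p_value) | df$p_value <= 0 | df$p_value > 1)
  if (length(bad)) {
    stop(sprintf("%s row %d: p_value outside (0, 1]", path, bad[1]),
         call. = FALSE)
  }
  epimutation_set(df, mark = mark, generation = generation, lineage = lineage)
}

#' Write an epimutation set to TSV or BED
#'
#' The TSV writer emits a header and the full record
#' (id, chrom, start, end, p_value, gene, subtype); the BED writer emits
#' chrom, start, end, id and the p-value in the score column. Both round-trip
#' through [read_epimutation_table()].
#'
#' @param s An [epimutation_set()].
#' @param path Output file.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_epimutation_table <- function(s, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  df <- as.data.frame(s)
  fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)
  if (format == "bed") {
    lines <- sprintf("%s\t%s\t%s\t%s\t%s", df$chrom, fmt_num(df$start),
                     fmt_num(df$end), df$id,
                     format(df$p_value, digits = 15, trim = TRUE))
    writeLines(lines, path)
  } else {
    out <- df
    out$start <- fmt_num(out$start)
    out$end <- fmt_num(out$end)
    out$p_value <- format(out$p_value, digits = 15, trim = TRUE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

catalog_key <- function(lineage, generation, mark) {
  paste(lineage, generation, mark, sep = "|")
}

#' Assemble an epimutation catalog
#'
#' A catalog is the full collection of sets for an analysis, keyed by
#' `lineage|generation|mark`.
#'
#' @param sets List of [epimutation_set()] objects.
#' @return An `epimutation_catalog` (named list).
#' @export
build_catalog <- function(sets) {
  stopifnot(is.list(sets), all(vapply(sets, inherits, TRUE, "epimutation_set")))
  keys <- vapply(sets, function(s) {
    catalog_key(set_lineage(s), set_generation(s), set_mark(s))
  }, "")
  if (anyDuplicated(keys)) {
    stop("duplicate lineage/generation/mark set(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  names(sets) <- keys
  structure(sets, class = "epimutation_catalog")
}

#' @export
print.epimutation_catalog <- function(x, ...) {
  cat(sprintf("Epimutation catalog: %d set(s)\n", length(x)))
  for (k in names(x)) cat(sprintf("  %-30s %5d feature(s)\n", k, nrow(x[[k]])))
  invisible(x)
}

#' Retrieve one set from a catalog
#'
#' @param catalog An [build_catalog()] result.
#' @param lineage,generation,mark Set identity.
#' @return The [epimutation_set()], or `NULL` if absent.
#' @export
catalog_get <- function(catalog, lineage, generation, mark) {
  catalog[[catalog_key(lineage, generation, mark)]]
}

#' Lineages present in a catalog
#' @param catalog An epimutation catalog.
#' @return Character vector of lineage labels.
#' @export
catalog_lineages <- function(catalog) {
  unique(vapply(catalog, set_lineage, ""))
}

#' Select the stringent and relaxed sets for one lineage
#'
#' For each of the 9 (generation, mark) combinations, applies the per-mark
#' stringent cutoff and the relaxed cutoff to the same underlying set. Each
#' stringent set is by construction a subset of its relaxed counterpart.
#' Missing combinations are dropped with a warning.
#'
#' @param catalog An epimutation catalog.
#' @param lineage Lineage label to select.
#' @param scheme A [threshold_scheme()].
#' @return List with elements `stringent` and `relaxed`: parallel named
#'   lists of filtered sets keyed `"generation mark"` (e.g. `"F1 DMR"`).
#' @export
select_sets <- function(catalog, lineage, scheme = threshold_scheme()) {
  stopifnot(inherits(scheme, "threshold_scheme"))
  if (!length(catalog)) stop("empty catalog", call. = FALSE)
  if (!lineage %in% catalog_lineages(catalog)) {
    stop("lineage '", lineage, "' not present in catalog", call. = FALSE)
  }
  stringent <- list()
  relaxed <- list()
  for (g in EPI_GENERATIONS) {
    for (m in EPI_MARKS) {
      s <- catalog_get(catalog, lineage, g, m)
      lab <- paste(g, m)
      if (is.null(s)) {
        warning(sprintf("catalog lacks %s %s %s; label dropped",
                        lineage, g, m), call. = FALSE)
        next
      }
      stringent[[lab]] <- apply_threshold(s, scheme$stringent[[m]])
      relaxed[[lab]] <- apply_threshold(s, scheme$relaxed)
    }
  }
  list(stringent = stringent, relaxed = relaxed)
}
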