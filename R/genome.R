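# Genome assembly and interval primitives.
#
# All coordinates are 0-based, half-open [start, end): interval length is
# end - start and two intervals overlap iff a$start < b$end && b$start < a$end.
# Chromosome names are matched by exact string equality; no "chr" prefix
# normalisation is applied.

#' Construct a genome assembly
#'
#' An assembly is the coordinate universe for every interval in an analysis:
#' an ordered table of chromosome names and lengths.
#'
#' @param chrom Character vector of chromosome names (unique, non-empty).
#' @param length Numeric vector of chromosome lengths in base pairs (> 0).
#' @return A `genome_assembly` object (a data frame with columns `chrom`,
#'   `length`, in the order given).
#' @examples
#' genome_assembly(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_assembly <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (base::length(chrom) != base::length(length)) {
    stop("'chrom' and 'length' must have equal length", call. = FALSE)
  }
  if (anyNA(chrom) || any(!nzchar(chrom))) {
    stop("chromosome names must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(chrom)) {
    dup <- unique(chrom[duplicated(chrom)])
    stop("duplicate chromosome name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(length) || any(length <= 0)) {
    stop("every chromosome length must be > 0", call. = FALSE)
  }
  structure(
    data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
    class = c("genome_assembly", "data.frame")
  )
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("Genome assembly: %d chromosome(s), %.3f Mb total\n",
              nrow(x), sum(x$length) / 1e6))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Look up chromosome lengths
#'
#' @param assembly A [genome_assembly()].
#' @param chrom Character vector of chromosome names; every name must exist
#'   in the assembly.
#' @return Numeric vector of lengths, one per element of `chrom`.
#' @export
chrom_length <- function(assembly, chrom) {
  stopifnot(inherits(assembly, "genome_assembly"))
  i <- match(chrom, assembly$chrom)
  if (anyNA(i)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  assembly$length[i]
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two whitespace-delimited columns: chromosome name and length in bp.
#' File order is preserved.
#'
#' @param path Path to the file.
#' @return A [genome_assembly()].
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!base::length(lines)) stop("empty chrom.sizes file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(fields, base::length, 0L) != 2L)
  if (base::length(bad)) {
    stop(sprintf("malformed chrom.sizes line %d: '%s'", bad[1], lines[bad[1]]),
         call. = FALSE)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  bad <- which(is.na(len))
  if (base::length(bad)) {
    stop(sprintf("non-numeric length at chrom.sizes line %d: '%s'",
                 bad[1], lines[bad[1]]), call. = FALSE)
  }
  bad <- which(len <= 0)
  if (base::length(bad)) {
    stop(sprintf("non-positive length at chrom.sizes line %d: '%s'",
                 bad[1], lines[bad[1]]), call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  genome_assembly(nm, len)
}

#' Write a UCSC-style chrom.sizes file
#'
#' @param assembly A [genome_assembly()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(assembly, path) {
  stopifnot(inherits(assembly, "genome_assembly"))
  writeLines(sprintf("%s\t%s", assembly$chrom,
                     format(assembly$length, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' Clip intervals to chromosome bounds
#'
#' Truncates each interval to `[0, chromosome length)`. Interior intervals
#' are returned unchanged; clipping is idempotent. An interval lying entirely
#' outside its chromosome is an error, as is an unknown chromosome.
#'
#' @param x Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), e.g. an [epimutation_set()].
#' @param assembly A [genome_assembly()] supplying chromosome lengths.
#' @return `x` with `start`/`end` clipped.
#' @export
clip_intervals <- function(x, assembly) {
  if (!nrow(x)) return(x)
  len <- chrom_length(assembly, x$chrom)
  ns <- pmax(x$start, 0)
  ne <- pmin(x$end, len)
  bad <- which(ns >= ne)
  if (base::length(bad)) {
    stop(sprintf(
      "interval [%s, %s) on %s lies entirely outside the chromosome (length %s)",
      format(x$start[bad[1]], scientific = FALSE),
      format(x$end[bad[1]], scientific = FALSE),
      x$chrom[bad[1]],
      format(len[bad[1]], scientific = FALSE)), call. = FALSE)
  }
  x$start <- ns
  x$end <- ne
  x
}

# Validate a bare interval data frame (chrom/start/end present, start < end,
# coordinates finite and non-negative start not required pre-clip).
validate_intervals <- function(x, what = "interval table") {
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(x))
  if (base::length(miss)) {
    stop(what, " lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x)) {
    if (anyNA(x$start) || anyNA(x$end)) {
      stop(what, " has missing coordinates", call. = FALSE)
    }
    bad <- which(!(x$start < x$end))
    if (base::length(bad)) {
      stop(sprintf("%s row %d: start (%s) must be < end (%s)",
                   what, bad[1],
                   format(x$start[bad[1]], scientific = FALSE),
                   format(x$end[bad[1]], scientific = FALSE)), call. = FALSE)
    }
    bad <- which(x$start < 0)
    if (base::length(bad)) {
      stop(sprintf("%s row %d: negative start", what, bad[1]), call. = FALSE)
    }
  }
  invisible(x)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
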