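# Fixture builders and independent brute-force oracles used across tests.

tiny_assembly <- function(n = 3, len = 1e6) {
  genome_assembly(paste0("chr", seq_len(n)), rep(len, n))
}

# Bare interval set with explicit coordinates.
make_set <- function(chrom, start, end, p = NULL, mark = "DMR",
                     generation = "F1", lineage = "test", id = NULL) {
  n <- length(start)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   p_value = if (is.null(p)) rep(1e-08, n) else p,
                   stringsAsFactors = FALSE)
  if (!is.null(id)) df$id <- id
  epimutation_set(df, mark = mark, generation = generation, lineage = lineage)
}

# Uniform random intervals for property tests.
random_set <- function(n, assembly, max_width = 5000, ...) {
  ci <- sample.int(nrow(assembly), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  start <- floor(runif(n) * (assembly$length[ci] - w))
  make_set(assembly$chrom[ci], start, start + w,
           p = runif(n, 1e-12, 1), ...)
}

# O(n*m) all-pairs overlap oracle: returns sorted "row_id|col_id" keys.
brute_force_pair_keys <- function(a, b) {
  keys <- character(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        keys <- c(keys, paste(a$id[i], b$id[j], sep = "|"))
      }
    }
  }
  sort(keys)
}

# Exhaustive connected-component labelling of the pooled features of 2-3
# sets under the pairwise-overlap relation (label propagation to a fixed
# point), returning signature counts comparable to venn_partition().
brute_force_venn_counts <- function(sets) {
  labels <- names(sets)
  df <- do.call(rbind, lapply(seq_along(sets), function(k) {
    s <- sets[[k]]
    if (!nrow(s)) return(NULL)
    data.frame(chrom = s$chrom, start = s$start, end = s$end,
               label = labels[k], stringsAsFactors = FALSE)
  }))
  if (is.null(df)) return(integer(0))
  n <- nrow(df)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (df$chrom[i] == df$chrom[j] &&
            df$start[i] < df$end[j] && df$start[j] < df$end[i] &&
            comp[j] != comp[i]) {
          tgt <- min(comp[i], comp[j])
          comp[comp == max(comp[i], comp[j])] <- tgt
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  sig <- vapply(split(df$label, comp), function(ls) {
    paste(labels[labels %in% ls], collapse = "&")
  }, "")
  counts <- table(sig)
  stats::setNames(as.integer(counts), names(counts))
}
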