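# Internal helpers shared across modules.

# Deterministic, platform-independent string hash in [0, 2^31).
# Used to derive per-sample RNG streams from the master seed so that adding
# or removing one sample never reshuffles the draws of another.
.stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 7
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

#' Derive a per-sample RNG seed from the master seed
#'
#' @param master_seed Integer master seed of the run.
#' @param sample_id Sample identifier (any string).
#' @return An integer seed in `[0, 2^31)`, a deterministic function of both
#'   arguments only.
#' @export
sample_stream_seed <- function(master_seed, sample_id) {
  .stable_hash(paste0(master_seed, "::", sample_id))
}

# Natural ordering for opaque chromosome labels: numeric labels first in
# numeric order, then the rest lexicographically.
.natural_chrom_order <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  order(is.na(num), num, chrom)
}

# data.frame with chrom/start_bp/end_bp (1-based inclusive) -> GRanges.
# A common seqlevels universe keeps cross-set operations well defined.
.as_granges <- function(df, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- unique(as.character(df$chrom))
  GenomicRanges::GRanges(
    seqnames = factor(as.character(df$chrom), levels = seqlevels),
    ranges = IRanges::IRanges(start = df$start_bp, end = df$end_bp)
  )
}

# Connected components by union-find. `edges` is a 2-column integer matrix of
# node indices in 1..n (may have zero rows). Returns component labels 1..k in
# first-appearance order.
.uf_components <- function(n, edges) {
  parent <- seq_len(n)
  findroot <- function(parent, i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (!is.null(edges) && nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      a <- findroot(parent, edges[r, 1L])
      b <- findroot(parent, edges[r, 2L])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), function(i) findroot(parent, i), integer(1))
  match(roots, unique(roots))
}

.assert_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", what), call. = FALSE)
  }
  invisible(x)
}

# Empty CNV call table with the canonical column set.
.empty_calls <- function() {
  data.frame(
    sample_id = character(0), chrom = character(0),
    start_bp = integer(0), end_bp = integer(0), n_markers = integer(0),
    copy_number = integer(0), class = character(0), caller_id = character(0),
    lbf = numeric(0), stringsAsFactors = FALSE
  )
}
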