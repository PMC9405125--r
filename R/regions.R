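# Three-stage CNVR consensus: per-group/per-caller merge of calls into
# potential regions, representativeness filtering, cross-caller
# intersection into candidate regions, and cross-group specificity
# classification, plus region-set summaries.
#
# Interval semantics are 1-based closed throughout. "Overlap" always means
# at least 1 shared bp: book-ended intervals never merge.

#' Merge CNV calls into potential CNV regions
#'
#' Merges all calls of one cattle type and one caller that overlap by at
#' least 1 bp across individuals (transitive closure of the overlap
#' relation); each merged region spans the min start / max end of its
#' members. Gains and losses are merged together; per-state counts are kept
#' in the output for reporting. Book-ended calls are not merged.
#'
#' @param calls Edited call data.frame (one cattle type, one caller; use
#'   `cattle_type`/`caller_id` to subset a mixed table).
#' @param metadata Sample metadata (`sample_id`, `population`,
#'   `cattle_type`).
#' @param cattle_type,caller_id Optional subset/validation labels; when
#'   omitted they must be unambiguous in the input.
#' @param chromosomes Optional chromosome universe; a call on a chromosome
#'   outside it is an error.
#' @return A data.frame of potential CNVRs: `region_id`, `chrom`,
#'   `start_bp`, `end_bp`, `cattle_type`, `caller_id`, `n_samples`,
#'   `n_populations`, `samples`, `populations` (comma-joined sorted sets),
#'   `n_gain`, `n_loss`.
#' @export
merge_calls_to_potential <- function(calls, metadata, cattle_type = NULL,
                                     caller_id = NULL, chromosomes = NULL) {
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (nrow(calls) > 0L) {
    pop <- metadata$population[match(calls$sample_id, metadata$sample_id)]
    typ <- metadata$cattle_type[match(calls$sample_id, metadata$sample_id)]
    if (anyNA(typ)) stop("calls contain samples missing from metadata")
    if (!is.null(cattle_type)) {
      keep <- typ == cattle_type
      calls <- calls[keep, , drop = FALSE]
      pop <- pop[keep]
    } else {
      cattle_type <- unique(typ)
      if (length(cattle_type) > 1L) {
        stop("calls span several cattle types; pass `cattle_type`")
      }
    }
    if (!is.null(caller_id)) {
      keep <- calls$caller_id == caller_id
      calls <- calls[keep, , drop = FALSE]
      pop <- pop[keep]
    } else {
      caller_id <- unique(calls$caller_id)
      if (length(caller_id) > 1L) {
        stop("calls span several callers; pass `caller_id`")
      }
    }
  }
  if (length(cattle_type) == 0L) cattle_type <- NA_character_
  if (length(caller_id) == 0L) caller_id <- NA_character_

  empty <- data.frame(
    region_id = character(0), chrom = character(0), start_bp = integer(0),
    end_bp = integer(0), cattle_type = character(0), caller_id = character(0),
    n_samples = integer(0), n_populations = integer(0), samples = character(0),
    populations = character(0), n_gain = integer(0), n_loss = integer(0),
    stringsAsFactors = FALSE
  )
  if (nrow(calls) == 0L) return(empty)

  if (is.null(chromosomes)) {
    chromosomes <- unique(calls$chrom)[.natural_chrom_order(unique(calls$chrom))]
  } else {
    bad <- setdiff(unique(calls$chrom), chromosomes)
    if (length(bad)) {
      stop("calls on unknown chromosome(s): ", paste(bad, collapse = ", "))
    }
  }

  gr <- .as_granges(calls, seqlevels = chromosomes)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(gr, red)
  member_of <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]

  pop <- metadata$population[match(calls$sample_id, metadata$sample_id)]
  n_reg <- length(red)
  rows <- lapply(seq_len(n_reg), function(i) {
    m <- which(member_of == i)
    smp <- sort(unique(calls$sample_id[m]))
    pp <- sort(unique(pop[m]))
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(red)[i]),
      start_bp = GenomicRanges::start(red)[i],
      end_bp = GenomicRanges::end(red)[i],
      cattle_type = cattle_type, caller_id = caller_id,
      n_samples = length(smp), n_populations = length(pp),
      samples = paste(smp, collapse = ","),
      populations = paste(pp, collapse = ","),
      n_gain = sum(calls$class[m] == "gain"),
      n_loss = sum(calls$class[m] == "loss"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$chrom, chromosomes), out$start_bp), , drop = FALSE]
  out <- cbind(
    region_id = sprintf("%s_%s_P%04d", cattle_type, caller_id,
                        seq_len(nrow(out))),
    out, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Representativeness filter for potential CNVRs
#'
#' Keeps regions supported by at least `min_individuals` samples OR at
#' least `min_populations` populations within the cattle type.
#'
#' @param regions Potential CNVRs from [merge_calls_to_potential()].
#' @param min_individuals,min_populations Thresholds (defaults 3 and 2).
#' @return The subset of representative regions.
#' @export
representativeness_filter <- function(regions, min_individuals = 3L,
                                      min_populations = 2L) {
  keep <- regions$n_samples >= min_individuals |
    regions$n_populations >= min_populations
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect representative CNVRs of two callers into candidate CNVRs
#'
#' With `bounds = "intersection"` (the default) candidates are the maximal
#' runs of bases covered by representative regions of both callers, i.e.
#' the upper and lower bounds of each overlap. With `bounds = "union"` each
#' connected component of cross-caller overlaps spans the min start / max
#' end of its members instead.
#'
#' @param repr_a,repr_b Representative region data.frames from the two
#'   callers, same cattle type.
#' @param bounds `"intersection"` or `"union"`.
#' @return A data.frame of candidate CNVRs: `candidate_id`, `chrom`,
#'   `start_bp`, `end_bp`, `cattle_type`, `provenance_a`, `provenance_b`
#'   (comma-joined parent region ids from each caller).
#' @export
intersect_callers <- function(repr_a, repr_b,
                              bounds = c("intersection", "union")) {
  bounds <- match.arg(bounds)
  type <- unique(c(repr_a$cattle_type, repr_b$cattle_type))
  type <- type[!is.na(type)]
  if (length(type) > 1L) stop("inputs must come from the same cattle type")
  if (length(type) == 0L) type <- NA_character_

  empty <- data.frame(
    candidate_id = character(0), chrom = character(0), start_bp = integer(0),
    end_bp = integer(0), cattle_type = character(0),
    provenance_a = character(0), provenance_b = character(0),
    stringsAsFactors = FALSE
  )
  if (nrow(repr_a) == 0L || nrow(repr_b) == 0L) return(empty)

  chroms <- unique(c(repr_a$chrom, repr_b$chrom))
  chroms <- chroms[.natural_chrom_order(chroms)]
  gr_a <- .as_granges(repr_a, seqlevels = chroms)
  gr_b <- .as_granges(repr_b, seqlevels = chroms)

  if (bounds == "intersection") {
    # pairwise intersection (bedtools-style): each overlapping (a, b) pair
    # contributes its shared interval; overlapping (not book-ended)
    # contributions are merged. This keeps every candidate inside one
    # parent region of each caller even when parents are book-ended.
    pairs <- GenomicRanges::findOverlaps(gr_a, gr_b)
    if (length(pairs) == 0L) return(empty)
    piece <- IRanges::pintersect(
      GenomicRanges::ranges(gr_a)[S4Vectors::queryHits(pairs)],
      GenomicRanges::ranges(gr_b)[S4Vectors::subjectHits(pairs)]
    )
    pieces_gr <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(gr_a)[S4Vectors::queryHits(pairs)],
      ranges = piece
    )
    ints <- GenomicRanges::reduce(pieces_gr, min.gapwidth = 0L)
    ha <- GenomicRanges::findOverlaps(ints, gr_a)
    hb <- GenomicRanges::findOverlaps(ints, gr_b)
    prov <- function(hits, ids) {
      vapply(seq_along(ints), function(i) {
        paste(sort(unique(ids[S4Vectors::subjectHits(hits)[
          S4Vectors::queryHits(hits) == i]])), collapse = ",")
      }, character(1))
    }
    out <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(ints)),
      start_bp = GenomicRanges::start(ints),
      end_bp = GenomicRanges::end(ints),
      cattle_type = type,
      provenance_a = prov(ha, repr_a$region_id),
      provenance_b = prov(hb, repr_b$region_id),
      stringsAsFactors = FALSE
    )
  } else {
    hits <- GenomicRanges::findOverlaps(gr_a, gr_b)
    if (length(hits) == 0L) return(empty)
    n_a <- nrow(repr_a)
    edges <- cbind(S4Vectors::queryHits(hits),
                   n_a + S4Vectors::subjectHits(hits))
    comp <- .uf_components(n_a + nrow(repr_b), edges)
    touched <- unique(comp[unique(as.vector(edges))])
    rows <- lapply(touched, function(cc) {
      ia <- which(comp[seq_len(n_a)] == cc)
      ib <- which(comp[n_a + seq_len(nrow(repr_b))] == cc)
      if (!length(ia) || !length(ib)) return(NULL)
      data.frame(
        chrom = repr_a$chrom[ia[1]],
        start_bp = min(repr_a$start_bp[ia], repr_b$start_bp[ib]),
        end_bp = max(repr_a$end_bp[ia], repr_b$end_bp[ib]),
        cattle_type = type,
        provenance_a = paste(sort(repr_a$region_id[ia]), collapse = ","),
        provenance_b = paste(sort(repr_b$region_id[ib]), collapse = ","),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
  }
  out <- out[order(match(out$chrom, chroms), out$start_bp), , drop = FALSE]
  out <- cbind(
    candidate_id = sprintf("%s_C%04d", type, seq_len(nrow(out))),
    out, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Classify cross-type specificity of candidate CNVRs
#'
#' Candidates with no >= 1 bp overlap across the two cattle types become
#' type-specific final regions with their own bounds. Each connected
#' component of cross-type overlaps becomes one shared final region spanning
#' the min start / max end of its members. The accounting table makes the
#' bookkeeping explicit: per type, total candidates, candidates absorbed
#' into shared regions, and type-specific count, plus the shared-region
#' count.
#'
#' @param cand_a,cand_b Candidate data.frames of the two types.
#' @param type_a,type_b Type labels (inferred from the inputs when
#'   possible).
#' @return A list with `final` (data.frame: `final_id`, `chrom`, `start_bp`,
#'   `end_bp`, `label` = `"<type>_specific"` or `"shared"`, `provenance`)
#'   and `accounting` (list with `per_type` data.frame, `shared`, `final`).
#' @export
classify_specificity <- function(cand_a, cand_b, type_a = NULL,
                                 type_b = NULL) {
  if (is.null(type_a)) type_a <- unique(cand_a$cattle_type)
  if (is.null(type_b)) type_b <- unique(cand_b$cattle_type)
  if (length(type_a) != 1L || length(type_b) != 1L) {
    stop("each candidate set must carry exactly one cattle type")
  }
  n_a <- nrow(cand_a)
  n_b <- nrow(cand_b)
  chroms <- unique(c(cand_a$chrom, cand_b$chrom))
  chroms <- chroms[.natural_chrom_order(chroms)]

  edges <- matrix(integer(0), ncol = 2)
  if (n_a > 0L && n_b > 0L) {
    hits <- GenomicRanges::findOverlaps(.as_granges(cand_a, chroms),
                                        .as_granges(cand_b, chroms))
    edges <- cbind(S4Vectors::queryHits(hits),
                   n_a + S4Vectors::subjectHits(hits))
  }
  comp <- .uf_components(n_a + n_b, edges)
  in_shared <- comp %in% unique(comp[unique(as.vector(edges))])

  all_cand <- rbind(
    if (n_a) data.frame(id = cand_a$candidate_id, chrom = cand_a$chrom,
                        start_bp = cand_a$start_bp, end_bp = cand_a$end_bp,
                        type = type_a, stringsAsFactors = FALSE),
    if (n_b) data.frame(id = cand_b$candidate_id, chrom = cand_b$chrom,
                        start_bp = cand_b$start_bp, end_bp = cand_b$end_bp,
                        type = type_b, stringsAsFactors = FALSE)
  )

  rows <- list()
  if (!is.null(all_cand) && nrow(all_cand) > 0L) {
    spec <- which(!in_shared)
    for (i in spec) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = all_cand$chrom[i], start_bp = all_cand$start_bp[i],
        end_bp = all_cand$end_bp[i],
        label = paste0(all_cand$type[i], "_specific"),
        provenance = all_cand$id[i], stringsAsFactors = FALSE
      )
    }
    for (cc in unique(comp[in_shared])) {
      m <- which(comp == cc)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = all_cand$chrom[m[1]],
        start_bp = min(all_cand$start_bp[m]),
        end_bp = max(all_cand$end_bp[m]),
        label = "shared",
        provenance = paste(sort(all_cand$id[m]), collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  final <- if (length(rows)) do.call(rbind, rows) else data.frame(
    chrom = character(0), start_bp = integer(0), end_bp = integer(0),
    label = character(0), provenance = character(0), stringsAsFactors = FALSE
  )
  final <- final[order(match(final$chrom, chroms), final$start_bp), ,
                 drop = FALSE]
  final <- cbind(final_id = sprintf("F%04d", seq_len(nrow(final))), final,
                 stringsAsFactors = FALSE)
  rownames(final) <- NULL

  absorbed_a <- sum(in_shared[seq_len(n_a)])
  absorbed_b <- sum(in_shared[n_a + seq_len(n_b)])
  accounting <- list(
    per_type = data.frame(
      cattle_type = c(type_a, type_b),
      candidates = c(n_a, n_b),
      absorbed = c(absorbed_a, absorbed_b),
      specific = c(n_a - absorbed_a, n_b - absorbed_b),
      stringsAsFactors = FALSE
    ),
    shared = sum(final$label == "shared"),
    final = nrow(final)
  )
  list(final = final, accounting = accounting)
}

#' Summarize a region set
#'
#' Counts, mean length, total genome coverage and per-length-class /
#' per-chromosome tallies for a set of non-overlapping regions. Lengths are
#' 1-based inclusive (`end - start + 1`). Default length classes:
#' `[0,50kb)`, `[50kb,100kb)`, `[100kb,500kb)`, `[500kb,1Mb)`, `[1Mb,Inf)`.
#'
#' @param regions Region data.frame (`chrom`, `start_bp`, `end_bp`).
#' @param length_bins Increasing numeric cut points in bp.
#' @return A list: `count`, `mean_length_bp` (`NA` for an empty set),
#'   `total_bp`, `length_class_counts` (named integer vector summing to
#'   `count`), `per_chromosome` (data.frame with counts and fractions).
#' @export
summarize_regions <- function(regions,
                              length_bins = c(5e4, 1e5, 5e5, 1e6)) {
  fmt <- function(b) {
    ifelse(b >= 1e6, paste0(b / 1e6, "Mb"), paste0(b / 1e3, "kb"))
  }
  labels <- c(
    paste0("[0,", fmt(length_bins[1]), ")"),
    paste0("[", fmt(length_bins[-length(length_bins)]), ",",
           fmt(length_bins[-1]), ")"),
    paste0("[", fmt(length_bins[length(length_bins)]), ",Inf)")
  )
  if (nrow(regions) == 0L) {
    return(list(
      count = 0L, mean_length_bp = NA_real_, total_bp = 0,
      length_class_counts = setNames(integer(length(labels)), labels),
      per_chromosome = data.frame(chrom = character(0), count = integer(0),
                                  fraction = numeric(0),
                                  stringsAsFactors = FALSE)
    ))
  }
  len <- regions$end_bp - regions$start_bp + 1
  cls <- cut(len, breaks = c(0, length_bins, Inf), right = FALSE,
             labels = labels)
  tab <- table(factor(regions$chrom,
                      levels = unique(regions$chrom)[
                        .natural_chrom_order(unique(regions$chrom))]))
  list(
    count = nrow(regions),
    mean_length_bp = mean(len),
    total_bp = sum(len),
    length_class_counts = setNames(as.integer(table(cls)), labels),
    per_chromosome = data.frame(
      chrom = names(tab), count = as.integer(tab),
      fraction = as.integer(tab) / nrow(regions),
      stringsAsFactors = FALSE
    )
  )
}
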