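# Readers and writers for the pipeline's tabular formats.
#
# Conventions (binding everywhere): TSV and report coordinates are 1-based
# inclusive; BED output is 0-based half-open. All writers are deterministic
# given identical inputs. Malformed numeric fields raise an error naming
# the file and 1-based line number (header = line 1).

# Read a TSV as character, check required columns, convert and validate
# numeric columns with line-accurate errors.
.read_tsv_checked <- function(file, required, numeric_cols = character(0)) {
  if (!file.exists(file)) stop("file not found: ", file)
  df <- data.table::fread(file, sep = "\t", header = TRUE,
                          colClasses = "character", fill = TRUE,
                          data.table = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", file,
                 paste(miss, collapse = ", ")))
  }
  for (col in numeric_cols) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !(raw %in% c("NA", "NaN")))
    if (length(bad)) {
      stop(sprintf("%s: line %d: malformed numeric value '%s' in column '%s'",
                   file, bad[1] + 1L, raw[bad[1]], col))
    }
    df[[col]] <- v
  }
  df
}

.fwrite_tsv <- function(df, file) {
  data.table::fwrite(df, file, sep = "\t", quote = FALSE, na = "NA")
  invisible(file)
}

#' @rdname io-formats
#' @export
write_marker_map <- function(map, file) {
  .fwrite_tsv(map[, c("chrom", "name", "pos")], file)
}

#' Tabular formats of the pipeline
#'
#' `write_*()`/`read_*()` pairs for the marker map, sample metadata,
#' intensity tables, CNV calls and region sets; every pair round-trips
#' (`read(write(x)) == x`). TSV coordinates are 1-based inclusive; the
#' `*_bed()` writers emit 0-based half-open BED.
#'
#' @param map,meta,calls,regions,truth Data.frames as produced by the
#'   package.
#' @param profiles Named list of `intensity_profile`s.
#' @param file Path.
#' @param name_col Column used for the BED name field.
#' @return Readers return the parsed data.frame (or, for
#'   [read_intensity()], a named list of `intensity_profile`s); writers
#'   return the path invisibly.
#' @name io-formats
#' @export
read_marker_map <- function(file) {
  df <- .read_tsv_checked(file, c("chrom", "name", "pos"), "pos")
  df$pos <- as.integer(df$pos)
  df
}

#' @rdname io-formats
#' @export
write_sample_meta <- function(meta, file) {
  .fwrite_tsv(meta[, c("sample_id", "population", "cattle_type")], file)
}

#' @rdname io-formats
#' @export
read_sample_meta <- function(file) {
  .read_tsv_checked(file, c("sample_id", "population", "cattle_type"))
}

#' @rdname io-formats
#' @export
write_intensity <- function(profiles, map, file) {
  tabs <- lapply(profiles, function(p) {
    data.frame(
      `Sample ID` = p$sample_id, `SNP Name` = map$name,
      `Log R Ratio` = p$lrr, `B Allele Freq` = p$baf,
      check.names = FALSE, stringsAsFactors = FALSE
    )
  })
  .fwrite_tsv(do.call(rbind, tabs), file)
}

#' @rdname io-formats
#' @export
read_intensity <- function(file, map) {
  df <- .read_tsv_checked(
    file, c("Sample ID", "SNP Name", "Log R Ratio", "B Allele Freq"),
    c("Log R Ratio", "B Allele Freq")
  )
  unknown <- setdiff(unique(df$`SNP Name`), map$name)
  if (length(unknown)) {
    stop(sprintf("%s: %d marker name(s) absent from the map (e.g. '%s')",
                 file, length(unknown), unknown[1]))
  }
  out <- lapply(split(df, df$`Sample ID`), function(d) {
    idx <- match(map$name, d$`SNP Name`)
    if (anyNA(idx)) {
      stop(sprintf("%s: sample '%s' is missing %d map marker(s)",
                   file, d$`Sample ID`[1], sum(is.na(idx))))
    }
    structure(
      list(sample_id = d$`Sample ID`[1],
           lrr = d$`Log R Ratio`[idx], baf = d$`B Allele Freq`[idx]),
      class = "intensity_profile"
    )
  })
  out[order(names(out))]
}

#' @rdname io-formats
#' @export
write_calls <- function(calls, file) {
  cols <- c("sample_id", "chrom", "start_bp", "end_bp", "n_markers",
            "copy_number", "class", "caller_id", "lbf")
  if ("tier" %in% names(calls)) cols <- c(cols, "tier")
  .fwrite_tsv(calls[, cols], file)
}

#' @rdname io-formats
#' @export
read_calls <- function(file) {
  df <- .read_tsv_checked(
    file, c("sample_id", "chrom", "start_bp", "end_bp", "n_markers",
            "copy_number", "class", "caller_id", "lbf"),
    c("start_bp", "end_bp", "n_markers", "copy_number", "lbf")
  )
  for (col in c("start_bp", "end_bp", "n_markers", "copy_number")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df
}

#' @rdname io-formats
#' @export
write_calls_bed <- function(calls, file) {
  bed <- data.frame(calls$chrom, calls$start_bp - 1L, calls$end_bp,
                    calls$sample_id, calls$copy_number)
  data.table::fwrite(bed, file, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname io-formats
#' @export
write_truth_bed <- function(truth, file) {
  bed <- data.frame(truth$chrom, truth$start_bp - 1L, truth$end_bp,
                    truth$sample_id, truth$copy_number)
  data.table::fwrite(bed, file, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname io-formats
#' @export
write_regions <- function(regions, file) {
  .fwrite_tsv(regions, file)
}

#' @rdname io-formats
#' @export
read_regions <- function(file) {
  df <- .read_tsv_checked(file, c("chrom", "start_bp", "end_bp"),
                          c("start_bp", "end_bp"))
  df$start_bp <- as.integer(df$start_bp)
  df$end_bp <- as.integer(df$end_bp)
  for (col in c("n_samples", "n_populations", "n_gain", "n_loss")) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  }
  df
}

#' @rdname io-formats
#' @export
write_regions_bed <- function(regions, file, name_col = NULL) {
  if (is.null(name_col)) {
    name_col <- intersect(c("final_id", "candidate_id", "region_id"),
                          names(regions))[1]
  }
  bed <- data.frame(regions$chrom, regions$start_bp - 1L, regions$end_bp,
                    regions[[name_col]])
  data.table::fwrite(bed, file, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read gene or QTL features from BED or TSV
#'
#' BED input is 0-based half-open with the id in the name (4th) column;
#' extra columns 7/8 of a QTL BED are read as `trait`/`category`. TSV input
#' is 1-based inclusive with explicit headers (`gene_id`/`qtl_id`, `chrom`,
#' `start_bp`, `end_bp`, and for QTL `trait`, `category`, `source`).
#'
#' @param file Path.
#' @param format `"auto"` (by extension), `"bed"` or `"tsv"`.
#' @return A feature data.frame with 1-based inclusive coordinates.
#' @export
read_genes <- function(file, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", file, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    df <- data.table::fread(file, sep = "\t", header = FALSE,
                            data.table = FALSE)
    out <- data.frame(gene_id = as.character(df$V4), chrom = as.character(df$V1),
                      start_bp = as.integer(df$V2) + 1L,
                      end_bp = as.integer(df$V3), stringsAsFactors = FALSE)
    if (ncol(df) >= 5L) out$symbol <- as.character(df$V5)
    out
  } else {
    df <- .read_tsv_checked(file, c("gene_id", "chrom", "start_bp", "end_bp"),
                            c("start_bp", "end_bp"))
    df$start_bp <- as.integer(df$start_bp)
    df$end_bp <- as.integer(df$end_bp)
    df
  }
}

#' @rdname read_genes
#' @export
read_qtls <- function(file, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", file, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    df <- data.table::fread(file, sep = "\t", header = FALSE,
                            data.table = FALSE)
    data.frame(
      qtl_id = as.character(df$V4), chrom = as.character(df$V1),
      start_bp = as.integer(df$V2) + 1L, end_bp = as.integer(df$V3),
      trait = if (ncol(df) >= 7L) as.character(df$V7) else NA_character_,
      category = if (ncol(df) >= 8L) as.character(df$V8) else NA_character_,
      source = if (ncol(df) >= 9L) as.character(df$V9) else NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    df <- .read_tsv_checked(
      file, c("qtl_id", "trait", "category", "source", "chrom", "start_bp",
              "end_bp"),
      c("start_bp", "end_bp")
    )
    df$start_bp <- as.integer(df$start_bp)
    df$end_bp <- as.integer(df$end_bp)
    df
  }
}

#' Read a gene-to-term map or a cluster definition
#'
#' @param file Path to a TSV. The term map has columns `gene_id`,
#'   `term_id`, optional `term_name`; the cluster file has `cluster_id`,
#'   `term_id`.
#' @return The parsed data.frame.
#' @export
read_term_map <- function(file) {
  .read_tsv_checked(file, c("gene_id", "term_id"))
}

#' @rdname read_term_map
#' @export
read_clusters <- function(file) {
  .read_tsv_checked(file, c("cluster_id", "term_id"))
}
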