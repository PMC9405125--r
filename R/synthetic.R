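# Synthetic cohort generator: marker maps, spiked copy-number events, and
# per-sample LRR/BAF intensity profiles with the statistical structure the
# downstream caller assumes.

#' Emission model parameters for LRR/BAF intensities
#'
#' One set of per-copy-number emission parameters is shared between the
#' generator and the HMM caller. LRR at a marker with copy number `cn` is
#' Normal(`lrr_mean[cn]`, `lrr_sd[cn]`). BAF is drawn from the genotype
#' clusters of the state: a marker with copy number `cn >= 1` carries
#' `g ~ Binomial(cn, p)` B alleles (Hardy-Weinberg at the marker's B-allele
#' frequency `p`) and BAF is Normal(`g/cn`, `baf_sd`) clipped to `[0, 1]`;
#' under homozygous deletion (CN0) BAF is Uniform(0, 1). With probability
#' `baf_drift_rate` a marker's BAF is replaced by a Uniform(0, 1) draw
#' (instrument drift / outliers).
#'
#' Default LRR means follow the conventions widely used for Illumina arrays:
#' CN0 -3.5, CN1 -0.66, CN2 0.0, CN3 0.40, CN4 0.68.
#'
#' @param lrr_mean Named numeric of length 5, LRR mean per state (log2-ratio
#'   units), names `"0"`..`"4"`.
#' @param lrr_sd LRR standard deviation per state; a scalar is recycled.
#' @param baf_sd Standard deviation of the BAF genotype clusters.
#' @param baf_drift_rate Probability that a marker's BAF is replaced by a
#'   uniform draw.
#' @return An object of class `emission_params`.
#' @export
emission_params <- function(lrr_mean = c("0" = -3.5, "1" = -0.66, "2" = 0.0,
                                         "3" = 0.40, "4" = 0.68),
                            lrr_sd = 0.2, baf_sd = 0.03,
                            baf_drift_rate = 0.001) {
  states <- 0:4
  if (length(lrr_mean) != 5L) stop("`lrr_mean` must have one value per state 0..4")
  lrr_mean <- setNames(as.numeric(lrr_mean), as.character(states))
  lrr_sd <- setNames(rep_len(as.numeric(lrr_sd), 5L), as.character(states))
  if (any(lrr_sd < 0) || baf_sd < 0) stop("standard deviations must be >= 0")
  if (baf_drift_rate < 0 || baf_drift_rate > 1) {
    stop("`baf_drift_rate` must be in [0, 1]")
  }
  structure(
    list(states = states, lrr_mean = lrr_mean, lrr_sd = lrr_sd,
         baf_sd = baf_sd, baf_drift_rate = baf_drift_rate),
    class = "emission_params"
  )
}

#' Generate an ordered autosomal marker map
#'
#' Positions are cumulative sums of inter-marker spacings drawn from an
#' exponential distribution with the configured mean (rounded, floored at
#' 1 bp), so positions are strictly increasing within a chromosome.
#'
#' @param n_chromosomes,markers_per_chromosome,mean_spacing_bp Positive
#'   integers/numbers describing map shape.
#' @param seed Integer seed; the map is a deterministic function of the
#'   arguments.
#' @return A data.frame with columns `chrom` (character label), `name`
#'   (unique marker name), `pos` (1-based bp).
#' @export
make_marker_map <- function(n_chromosomes, markers_per_chromosome,
                            mean_spacing_bp, seed) {
  .assert_positive(n_chromosomes, "n_chromosomes")
  .assert_positive(markers_per_chromosome, "markers_per_chromosome")
  .assert_positive(mean_spacing_bp, "mean_spacing_bp")
  set.seed(as.integer(seed))
  pieces <- lapply(seq_len(n_chromosomes), function(ch) {
    gaps <- pmax(1, round(rexp(markers_per_chromosome, rate = 1 / mean_spacing_bp)))
    data.frame(
      chrom = as.character(ch),
      name = sprintf("snp_%d_%06d", ch, seq_len(markers_per_chromosome)),
      pos = as.integer(cumsum(gaps)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Describe the event-frequency design of a synthetic cohort
#'
#' @param shared `NULL` or a data.frame with one row per designed recurrent
#'   region: `cattle_type` (one type label, or several comma-separated labels
#'   for a cross-type region), `n_carriers` (total carriers; split evenly
#'   across the listed types), `n_markers` (>= 3) and `copy_number`
#'   (0, 1, 3 or 4). Carriers of one region share the identical map interval,
#'   and within each type they are spread over at least two populations when
#'   possible.
#' @param private_rate Expected number (Poisson mean, in `[0, 1]`) of private
#'   events per sample.
#' @param private_markers Length-2 integer range of private event lengths in
#'   markers (uniform; minimum 3).
#' @param cn_mix Named probabilities over copy numbers `"0","1","3","4"` for
#'   private events.
#' @param min_separation_markers Minimum number of diploid markers kept
#'   between any two placed regions, so that distinct events never merge into
#'   one region downstream.
#' @return An object of class `event_design`.
#' @export
event_design <- function(shared = NULL, private_rate = 0,
                         private_markers = c(5L, 15L),
                         cn_mix = c("0" = 0.05, "1" = 0.40, "3" = 0.40, "4" = 0.15),
                         min_separation_markers = 30L) {
  if (!is.null(shared)) {
    shared <- as.data.frame(shared, stringsAsFactors = FALSE)
    need <- c("cattle_type", "n_carriers", "n_markers", "copy_number")
    if (!all(need %in% names(shared))) {
      stop("`shared` needs columns: ", paste(need, collapse = ", "))
    }
    if (any(shared$n_markers < 3)) stop("shared regions must span >= 3 markers")
    if (!all(shared$copy_number %in% c(0L, 1L, 3L, 4L))) {
      stop("copy_number must be one of 0, 1, 3, 4")
    }
  }
  if (private_rate < 0 || private_rate > 1) stop("`private_rate` must be in [0, 1]")
  private_markers <- as.integer(private_markers)
  if (length(private_markers) != 2L || private_markers[1] < 3L ||
      private_markers[2] < private_markers[1]) {
    stop("`private_markers` must be an increasing range with minimum >= 3")
  }
  cn_mix <- cn_mix / sum(cn_mix)
  if (!all(names(cn_mix) %in% c("0", "1", "3", "4"))) {
    stop("`cn_mix` names must be copy numbers 0, 1, 3, 4")
  }
  structure(
    list(shared = shared, private_rate = private_rate,
         private_markers = private_markers, cn_mix = cn_mix,
         min_separation_markers = as.integer(min_separation_markers)),
    class = "event_design"
  )
}

# Internal: map split into per-chromosome marker index tables.
.map_index <- function(map) {
  split(seq_len(nrow(map)), map$chrom)
}

# Internal: pick a free interval of n_markers consecutive markers, keeping
# `sep` markers clear of already used intervals. `used` is a list per chrom
# of 2-col matrices of marker offsets (within chromosome).
.place_interval <- function(chrom_sizes, used, n_markers, sep) {
  chroms <- names(chrom_sizes)
  for (attempt in seq_len(2000L)) {
    ch <- sample(chroms, 1L, prob = chrom_sizes)
    size <- chrom_sizes[[ch]]
    if (size < n_markers) next
    start <- sample.int(size - n_markers + 1L, 1L)
    end <- start + n_markers - 1L
    u <- used[[ch]]
    clash <- !is.null(u) && nrow(u) > 0L &&
      any(start <= u[, 2L] + sep & end >= u[, 1L] - sep)
    if (!clash) {
      return(list(chrom = ch, start_idx = start, end_idx = end))
    }
  }
  stop("could not place a region of ", n_markers,
       " markers; map too small for the requested design")
}

# Internal: choose carriers of a shared region within one type, spreading
# them over at least two populations when the type has more than one.
.pick_carriers <- function(cohort, type, k) {
  pool <- cohort[cohort$cattle_type == type, , drop = FALSE]
  if (nrow(pool) < k) {
    stop(sprintf("type '%s' has %d samples but %d carriers requested",
                 type, nrow(pool), k))
  }
  pops <- unique(pool$population)
  chosen <- character(0)
  if (length(pops) >= 2L && k >= 2L) {
    for (p in sample(pops, 2L)) {
      cand <- setdiff(pool$sample_id[pool$population == p], chosen)
      chosen <- c(chosen, sample(cand, 1L))
    }
  }
  rest <- setdiff(pool$sample_id, chosen)
  if (length(chosen) < k) {
    chosen <- c(chosen, sample(rest, k - length(chosen)))
  }
  chosen[seq_len(k)]
}

#' Spike ground-truth copy-number events into a cohort
#'
#' Places the designed shared (recurrent) regions at identical map intervals
#' across their carriers, then adds per-sample private events. All placed
#' regions are mutually non-overlapping (with a marker-separation buffer), so
#' events never overlap within a sample.
#'
#' @param map Marker map from [make_marker_map()].
#' @param cohort Sample metadata data.frame with columns `sample_id`,
#'   `population`, `cattle_type`.
#' @param design An [event_design()].
#' @param seed Integer seed.
#' @return A data.frame of truth events with columns `sample_id`, `chrom`,
#'   `start_bp`, `end_bp` (1-based, inclusive of first/last spanned marker),
#'   `copy_number`, `n_markers`, `origin` (shared region id or `"private"`).
#'   The designed recurrent regions are attached as
#'   `attr(x, "shared_regions")` (one row per region with its interval, copy
#'   number, types and carriers).
#' @export
spike_events <- function(map, cohort, design, seed) {
  if (!inherits(design, "event_design")) stop("`design` must be an event_design")
  cohort <- as.data.frame(cohort, stringsAsFactors = FALSE)
  if (nrow(cohort) == 0L) stop("`cohort` must contain at least one sample")
  set.seed(as.integer(seed))

  idx_by_chrom <- .map_index(map)
  chrom_sizes <- vapply(idx_by_chrom, length, integer(1))
  used <- setNames(vector("list", length(chrom_sizes)), names(chrom_sizes))
  sep <- design$min_separation_markers

  events <- list()
  regions <- list()
  add_event <- function(sample_id, ch, start_idx, end_idx, cn, origin) {
    rows <- idx_by_chrom[[ch]]
    data.frame(
      sample_id = sample_id, chrom = ch,
      start_bp = map$pos[rows[start_idx]], end_bp = map$pos[rows[end_idx]],
      copy_number = as.integer(cn), n_markers = end_idx - start_idx + 1L,
      origin = origin, stringsAsFactors = FALSE
    )
  }

  shared <- design$shared
  if (!is.null(shared) && nrow(shared) > 0L) {
    for (r in seq_len(nrow(shared))) {
      types <- trimws(strsplit(as.character(shared$cattle_type[r]), ",")[[1]])
      unknown <- setdiff(types, unique(cohort$cattle_type))
      if (length(unknown)) {
        stop("design references unknown cattle type(s): ",
             paste(unknown, collapse = ", "))
      }
      loc <- .place_interval(chrom_sizes, used, shared$n_markers[r], sep)
      used[[loc$chrom]] <- rbind(used[[loc$chrom]],
                                 c(loc$start_idx, loc$end_idx))
      k_total <- as.integer(shared$n_carriers[r])
      k_each <- diff(round(seq(0, k_total, length.out = length(types) + 1L)))
      carriers <- unlist(lapply(seq_along(types), function(i) {
        if (k_each[i] == 0L) character(0)
        else .pick_carriers(cohort, types[i], k_each[i])
      }))
      region_id <- sprintf("shared_%02d", r)
      rows <- idx_by_chrom[[loc$chrom]]
      regions[[r]] <- data.frame(
        region_id = region_id,
        cattle_type = paste(types, collapse = ","),
        chrom = loc$chrom,
        start_bp = map$pos[rows[loc$start_idx]],
        end_bp = map$pos[rows[loc$end_idx]],
        n_markers = shared$n_markers[r],
        copy_number = as.integer(shared$copy_number[r]),
        carriers = paste(sort(carriers), collapse = ","),
        stringsAsFactors = FALSE
      )
      for (s in carriers) {
        events[[length(events) + 1L]] <- add_event(
          s, loc$chrom, loc$start_idx, loc$end_idx,
          shared$copy_number[r], region_id
        )
      }
    }
  }

  # Private events avoid the shared regions and the sample's own events,
  # but may overlap private events of other samples (as in real cohorts).
  if (design$private_rate > 0) {
    cn_levels <- as.integer(names(design$cn_mix))
    for (s in cohort$sample_id) {
      own <- used
      k <- rpois(1L, design$private_rate)
      for (i in seq_len(k)) {
        n_mk <- sample(design$private_markers[1]:design$private_markers[2], 1L)
        cn <- sample(cn_levels, 1L, prob = design$cn_mix)
        loc <- .place_interval(chrom_sizes, own, n_mk, sep)
        own[[loc$chrom]] <- rbind(own[[loc$chrom]],
                                  c(loc$start_idx, loc$end_idx))
        events[[length(events) + 1L]] <- add_event(
          s, loc$chrom, loc$start_idx, loc$end_idx, cn, "private"
        )
      }
    }
  }

  out <- if (length(events)) do.call(rbind, events) else data.frame(
    sample_id = character(0), chrom = character(0), start_bp = integer(0),
    end_bp = integer(0), copy_number = integer(0), n_markers = integer(0),
    origin = character(0), stringsAsFactors = FALSE
  )
  ord <- order(out$sample_id, match(out$chrom, names(idx_by_chrom)), out$start_bp)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "shared_regions") <- if (length(regions)) {
    do.call(rbind, regions)
  } else {
    data.frame(region_id = character(0), cattle_type = character(0),
               chrom = character(0), start_bp = integer(0), end_bp = integer(0),
               n_markers = integer(0), copy_number = integer(0),
               carriers = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' Simulate one sample's LRR/BAF intensity profile
#'
#' Applies the emission model of [emission_params()] marker by marker, with
#' the copy-number state taken from the sample's truth events (CN2
#' elsewhere). Draws come from a per-sample RNG stream derived from
#' `(seed, sample_id)` by [sample_stream_seed()].
#'
#' @param map Marker map.
#' @param events Truth events of this sample (possibly zero rows); must be
#'   non-overlapping and inside the map.
#' @param emission An [emission_params()].
#' @param pfb Per-marker population B-allele frequency in `[0, 1]`; a scalar
#'   is recycled.
#' @param seed Master integer seed.
#' @param sample_id Sample identifier used to derive the RNG stream.
#' @return An object of class `intensity_profile`: a list with `sample_id`,
#'   `lrr` and `baf` numeric vectors aligned to the map.
#' @export
simulate_profile <- function(map, events, emission, pfb = 0.5, seed = 1L,
                             sample_id = "sample") {
  stopifnot(inherits(emission, "emission_params"))
  n <- nrow(map)
  pfb <- rep_len(pfb, n)
  if (any(pfb < 0 | pfb > 1)) stop("`pfb` must be in [0, 1]")

  cn <- rep(2L, n)
  if (!is.null(events) && nrow(events) > 0L) {
    for (r in seq_len(nrow(events))) {
      idx <- which(map$chrom == events$chrom[r] &
                     map$pos >= events$start_bp[r] &
                     map$pos <= events$end_bp[r])
      if (length(idx) == 0L) {
        stop(sprintf("event %s:%d-%d lies outside the marker map",
                     events$chrom[r], events$start_bp[r], events$end_bp[r]))
      }
      if (any(cn[idx] != 2L)) stop("events overlap within a sample")
      cn[idx] <- as.integer(events$copy_number[r])
    }
  }

  set.seed(sample_stream_seed(seed, sample_id))
  key <- as.character(cn)
  lrr <- rnorm(n, emission$lrr_mean[key], emission$lrr_sd[key])
  baf <- numeric(n)
  nz <- cn > 0L
  if (any(nz)) {
    g <- rbinom(sum(nz), cn[nz], pfb[nz])
    baf[nz] <- pmin(1, pmax(0, rnorm(sum(nz), g / cn[nz], emission$baf_sd)))
  }
  if (any(!nz)) baf[!nz] <- runif(sum(!nz))
  drift <- runif(n) < emission$baf_drift_rate
  if (any(drift)) baf[drift] <- runif(sum(drift))

  structure(list(sample_id = sample_id, lrr = lrr, baf = baf),
            class = "intensity_profile")
}

#' Simulate a full synthetic cohort
#'
#' Builds the marker map, sample metadata, truth events, per-marker B-allele
#' frequencies and one intensity profile per sample from a single config
#' list. Designated QC-failure samples get inflated `lrr_sd` and/or
#' `baf_drift_rate`, and their ids are recorded.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{seed}{integer master seed;}
#'     \item{map}{list(n_chromosomes, markers_per_chromosome, mean_spacing_bp);}
#'     \item{cohort}{named list of types, each
#'       `list(populations = <labels>, n_per_population = <int>)` (at least
#'       two types, two populations per type);}
#'     \item{emission}{optional overrides passed to [emission_params()];}
#'     \item{design}{optional overrides passed to [event_design()]; `shared`
#'       may be a data.frame or a list of rows;}
#'     \item{qc_failures}{optional data.frame/list of rows with `sample_id`
#'       and any of `lrr_sd`, `baf_drift_rate` to override for that sample.}
#'   }
#' @return A list with `map`, `samples`, `profiles` (named list of
#'   [simulate_profile()] outputs), `truth`, `shared_regions`, `pfb`,
#'   `emission`, and `qc_failures` (character vector of injected failure
#'   ids).
#' @export
simulate_cohort <- function(config) {
  if (is.null(config$seed)) stop("config must provide a `seed`")
  seed <- as.integer(config$seed)
  if (is.null(config$map) || is.null(config$cohort)) {
    stop("config must provide `map` and `cohort` blocks")
  }
  types <- names(config$cohort)
  if (length(types) < 2L) stop("config must name at least two cattle types")

  samples <- do.call(rbind, lapply(types, function(ty) {
    blk <- config$cohort[[ty]]
    pops <- as.character(blk$populations)
    if (length(pops) < 2L) {
      stop(sprintf("type '%s' must have at least two populations", ty))
    }
    n <- as.integer(blk$n_per_population)
    do.call(rbind, lapply(pops, function(p) {
      data.frame(
        sample_id = sprintf("%s_%s_%02d", ty, p, seq_len(n)),
        population = p, cattle_type = ty, stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(samples) <- NULL

  map <- do.call(make_marker_map, c(config$map, list(seed = seed)))

  em_args <- if (is.null(config$emission)) list() else config$emission
  emission <- do.call(emission_params, em_args)

  de_args <- if (is.null(config$design)) list() else config$design
  if (!is.null(de_args$shared) && !is.data.frame(de_args$shared)) {
    de_args$shared <- do.call(rbind, lapply(de_args$shared, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
  }
  design <- do.call(event_design, de_args)

  truth <- spike_events(map, samples, design, seed)

  set.seed(sample_stream_seed(seed, "__pfb__"))
  pfb <- runif(nrow(map), 0.05, 0.95)

  qc_fail <- config$qc_failures
  if (!is.null(qc_fail) && !is.data.frame(qc_fail)) {
    qc_fail <- do.call(rbind, lapply(qc_fail, function(r) {
      r <- as.list(r)
      data.frame(sample_id = r$sample_id,
                 lrr_sd = if (is.null(r$lrr_sd)) NA_real_ else r$lrr_sd,
                 baf_drift_rate = if (is.null(r$baf_drift_rate)) NA_real_
                                  else r$baf_drift_rate,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(qc_fail) && nrow(qc_fail) > 0L) {
    unknown <- setdiff(qc_fail$sample_id, samples$sample_id)
    if (length(unknown)) {
      stop("qc_failures references unknown sample(s): ",
           paste(unknown, collapse = ", "))
    }
  }

  profiles <- setNames(vector("list", nrow(samples)), samples$sample_id)
  for (s in samples$sample_id) {
    em_s <- emission
    if (!is.null(qc_fail) && s %in% qc_fail$sample_id) {
      row <- qc_fail[match(s, qc_fail$sample_id), ]
      if (!is.na(row$lrr_sd)) em_s$lrr_sd[] <- row$lrr_sd
      if (!is.na(row$baf_drift_rate)) em_s$baf_drift_rate <- row$baf_drift_rate
    }
    ev <- truth[truth$sample_id == s, , drop = FALSE]
    profiles[[s]] <- simulate_profile(map, ev, em_s, pfb, seed, s)
  }

  list(
    map = map, samples = samples, profiles = profiles, truth = truth,
    shared_regions = attr(truth, "shared_regions"), pfb = pfb,
    emission = emission,
    qc_failures = if (is.null(qc_fail)) character(0) else qc_fail$sample_id
  )
}
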