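# Copy-number HMM caller: emission likelihoods, Viterbi decoding, log Bayes
# factor scoring, and call editing.

#' HMM parameters for one caller profile
#'
#' Two caller profiles stand in for the two-program consensus design common
#' in array CNV studies; both consume the same LRR/BAF input:
#' \describe{
#'   \item{`"viterbi"`}{distance-decay transitions: between adjacent markers
#'     separated by `d` bp the stay probability is
#'     `1 - p_change * (1 - exp(-d / decay_bp))`, the remainder split equally
#'     among the other four states. No Bayes-factor scoring.}
#'   \item{`"bayes"`}{marker-count-penalized transitions: a constant per-step
#'     stay probability `1 - p_change` regardless of distance, plus log10
#'     Bayes factor scoring of every call (used by the 10/30 confidence
#'     tiers of [edit_calls()]).}
#' }
#'
#' @param profile `"viterbi"` or `"bayes"`.
#' @param emission An [emission_params()] describing the state emissions the
#'   caller assumes.
#' @param p_change Off-diagonal transition prior; defaults to 0.3 for the
#'   distance-decay profile and 0.003 per step for the constant-penalty
#'   profile.
#' @param decay_bp Transition decay length in bp (distance-decay profile
#'   only).
#' @param state_prior Initial-state probabilities over copy numbers 0..4
#'   (normalised internally); the default puts almost all mass on CN2.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(profile = c("viterbi", "bayes"),
                       emission = emission_params(),
                       p_change = NULL, decay_bp = 1e5,
                       state_prior = c(0.001, 0.004, 0.99, 0.004, 0.001)) {
  profile <- match.arg(profile)
  stopifnot(inherits(emission, "emission_params"))
  if (is.null(p_change)) p_change <- if (profile == "viterbi") 0.3 else 0.003
  if (p_change < 0 || p_change >= 1) stop("`p_change` must be in [0, 1)")
  .assert_positive(decay_bp, "decay_bp")
  if (length(state_prior) != 5L || any(state_prior <= 0)) {
    stop("`state_prior` must be 5 positive values")
  }
  if (any(emission$lrr_sd <= 0) || emission$baf_sd <= 0) {
    stop("caller emission standard deviations must be > 0")
  }
  structure(
    list(profile = profile, emission = emission, p_change = p_change,
         decay_bp = decay_bp, state_prior = state_prior / sum(state_prior)),
    class = "hmm_params"
  )
}

# Likelihood floor applied per marker before any ratio (numeric safety).
.LIK_FLOOR <- 1e-300

#' Per-marker emission log-likelihoods for all copy-number states
#'
#' Returns the natural-log likelihood of each marker's (LRR, BAF)
#' observation under each state 0..4. The LRR term is Normal. The BAF term
#' for states >= 1 is the Hardy-Weinberg genotype-cluster mixture at the
#' marker's B-allele frequency with Normal cluster noise, censored at the
#' rails: observations exactly 0 or 1 are scored with the corresponding tail
#' mass. A `baf_drift_rate` fraction of uniform outlier density is mixed in.
#' Under CN0 the BAF is modeled as state-independent uniform noise (density
#' 1 in the interior, no mass at the rails), so CN0 evidence comes from LRR.
#' Missing BAF (or LRR) contributes only the other term.
#'
#' @param lrr,baf Numeric vectors (may contain `NA`).
#' @param pfb Per-marker B-allele frequency (scalar recycled).
#' @param emission An [emission_params()].
#' @return An `n x 5` matrix of log-likelihoods (states 0..4 in columns).
#' @export
emission_loglik <- function(lrr, baf, pfb, emission) {
  n <- length(lrr)
  stopifnot(length(baf) == n)
  pfb <- rep_len(pfb, n)
  dr <- emission$baf_drift_rate
  bsd <- emission$baf_sd

  miss_b <- is.na(baf)
  miss_l <- is.na(lrr)
  at0 <- !miss_b & baf <= 0
  at1 <- !miss_b & baf >= 1
  interior <- !miss_b & !at0 & !at1

  ll <- matrix(0, n, 5L)
  for (j in 1:5) {
    s <- j - 1L
    l_lrr <- dnorm(lrr, emission$lrr_mean[j], emission$lrr_sd[j])
    l_lrr[miss_l] <- 1
    l_baf <- rep(1, n)
    if (s == 0L) {
      l_baf[interior] <- 1
      l_baf[at0 | at1] <- 0
    } else {
      mix <- numeric(n)
      mass0 <- numeric(n)
      mass1 <- numeric(n)
      for (g in 0:s) {
        w <- dbinom(g, s, pfb)
        m <- g / s
        mix <- mix + w * dnorm(baf, m, bsd)
        mass0 <- mass0 + w * pnorm(0, m, bsd)
        mass1 <- mass1 + w * pnorm(1, m, bsd, lower.tail = FALSE)
      }
      l_baf[interior] <- (1 - dr) * mix[interior] + dr
      l_baf[at0] <- (1 - dr) * mass0[at0]
      l_baf[at1] <- (1 - dr) * mass1[at1]
    }
    ll[, j] <- log(pmax(l_lrr * l_baf, .LIK_FLOOR))
  }
  ll
}

# Per-step symmetric transition log-probabilities for the marker gaps of one
# chromosome.
.transition_logprobs <- function(gaps_bp, params) {
  off <- if (params$profile == "viterbi") {
    params$p_change * (1 - exp(-gaps_bp / params$decay_bp))
  } else {
    rep(params$p_change, length(gaps_bp))
  }
  list(log_stay = log(1 - off), log_off = log(off / 4))
}

# State preference for tie-breaking: CN2 first, then smaller |cn - 2|
# (losses before gains at equal distance).
.STATE_PREF <- c(2L, 1L, 3L, 0L, 4L)

#' Call CNV segments from one intensity profile by Viterbi decoding
#'
#' Decodes the maximum-a-posteriori copy-number state path per chromosome
#' and reports every maximal run of a non-diploid state spanning at least
#' `min_markers` markers as a CNV call. Viterbi ties are broken toward CN2,
#' then toward the state closer to CN2. For the `"bayes"` caller profile
#' each call is scored with its log10 Bayes factor against CN2.
#'
#' @param profile An `intensity_profile`.
#' @param map Marker map the profile is aligned to.
#' @param params An [hmm_params()].
#' @param min_markers Minimum markers per reported call.
#' @param pfb Per-marker B-allele frequency (scalar recycled), as assumed by
#'   the caller.
#' @return A data.frame of calls: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp` (1-based inclusive), `n_markers`, `copy_number`, `class`
#'   (`"loss"`/`"gain"`), `caller_id`, `lbf` (`NA` for the `"viterbi"`
#'   profile). Calls are sorted and non-overlapping within the sample.
#' @export
viterbi_call <- function(profile, map, params, min_markers = 3L, pfb = 0.5) {
  stopifnot(inherits(params, "hmm_params"))
  n <- nrow(map)
  if (length(profile$lrr) != n || length(profile$baf) != n) {
    stop("profile length does not match the marker map")
  }
  pfb <- rep_len(pfb, n)
  log_prior <- log(params$state_prior)

  calls <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos[idx]
    ll <- emission_loglik(profile$lrr[idx], profile$baf[idx], pfb[idx],
                          params$emission)
    tr <- .transition_logprobs(diff(pos), params)
    path <- viterbi_path(ll, log_prior, tr$log_stay, tr$log_off, .STATE_PREF)
    runs <- rle(as.integer(path))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values != 2L & runs$lengths >= min_markers
    if (!any(keep)) next
    for (r in which(keep)) {
      cn <- runs$values[r]
      i0 <- starts[r]
      i1 <- ends[r]
      lbf <- if (params$profile == "bayes") {
        sum(ll[i0:i1, cn + 1L] - ll[i0:i1, 3L]) / log(10)
      } else {
        NA_real_
      }
      calls[[length(calls) + 1L]] <- data.frame(
        sample_id = profile$sample_id, chrom = ch,
        start_bp = pos[i0], end_bp = pos[i1], n_markers = i1 - i0 + 1L,
        copy_number = cn, class = if (cn < 2L) "loss" else "gain",
        caller_id = params$profile, lbf = lbf, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(calls)) return(.empty_calls())
  out <- do.call(rbind, calls)
  out <- out[order(match(out$chrom, unique(map$chrom)), out$start_bp), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Log10 Bayes factor of a CNV call against the diploid state
#'
#' Sums, over the call's markers, the log10 likelihood ratio of the called
#' copy-number state versus CN2 under the caller's emission model.
#'
#' @param call A one-row call data.frame (or list) with `chrom`, `start_bp`,
#'   `end_bp`, `copy_number`.
#' @param profile The sample's `intensity_profile`.
#' @param map Marker map.
#' @param params An [hmm_params()].
#' @param pfb Per-marker B-allele frequency (scalar recycled).
#' @return The log10 Bayes factor (numeric scalar).
#' @export
log_bayes_factor <- function(call, profile, map, params, pfb = 0.5) {
  idx <- which(map$chrom == call$chrom &
                 map$pos >= call$start_bp & map$pos <= call$end_bp)
  if (length(idx) == 0L) stop("call markers not resolvable on the map")
  pfb <- rep_len(pfb, nrow(map))
  ll <- emission_loglik(profile$lrr[idx], profile$baf[idx], pfb[idx],
                        params$emission)
  sum(ll[, as.integer(call$copy_number) + 1L] - ll[, 3L]) / log(10)
}

#' Edit CNV calls: QC gating, Bayes-factor filtering, confidence tiers
#'
#' Drops calls from QC-failed samples. Calls carrying a log10 Bayes factor
#' (the `"bayes"` caller profile) are additionally dropped when
#' `lbf < lbf_min` (default 10) and the kept ones are labeled
#' `"informative"` when `lbf > informative_lbf` (default 30) or
#' `"suggestive"` otherwise. Calls without a Bayes factor (the `"viterbi"`
#' profile) pass through with tier `"na"`.
#'
#' @param calls Call data.frame from [viterbi_call()].
#' @param qc QC report data.frame from [qc_cohort()] (needs `sample_id`,
#'   `passed`).
#' @param lbf_min Minimum log10 Bayes factor for a call to be kept.
#' @param informative_lbf Tier split between suggestive and informative.
#' @return The kept calls with an added `tier` column.
#' @export
edit_calls <- function(calls, qc, lbf_min = 10, informative_lbf = 30) {
  if (nrow(calls) == 0L) {
    out <- calls
    out$tier <- character(0)
    return(out)
  }
  failed <- qc$sample_id[!qc$passed]
  keep <- !(calls$sample_id %in% failed)
  scored <- !is.na(calls$lbf)
  keep <- keep & (!scored | calls$lbf >= lbf_min)
  out <- calls[keep, , drop = FALSE]
  out$tier <- ifelse(is.na(out$lbf), "na",
                     ifelse(out$lbf > informative_lbf, "informative",
                            "suggestive"))
  rownames(out) <- NULL
  out
}

#' Call CNVs for every passing sample of a cohort
#'
#' Convenience wrapper: runs [viterbi_call()] on each QC-passing sample and
#' binds the calls.
#'
#' @param profiles Named list of `intensity_profile`s.
#' @param map Marker map.
#' @param params An [hmm_params()].
#' @param qc QC report; when given, QC-failed samples are not decoded.
#' @inheritParams viterbi_call
#' @return A call data.frame.
#' @export
call_cohort <- function(profiles, map, params, qc = NULL, min_markers = 3L,
                        pfb = 0.5) {
  ids <- names(profiles)
  if (!is.null(qc)) ids <- intersect(ids, qc$sample_id[qc$passed])
  out <- lapply(ids, function(s) {
    viterbi_call(profiles[[s]], map, params, min_markers = min_markers,
                 pfb = pfb)
  })
  out <- do.call(rbind, c(list(.empty_calls()), out))
  rownames(out) <- NULL
  out
}
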