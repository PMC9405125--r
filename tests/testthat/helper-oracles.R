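# Independent oracles and fixture builders used across the test files.
# Every oracle recomputes the checked quantity by brute force (path
# enumeration, per-base set algebra, explicit graph construction, explicit
# hypergeometric summation) without calling the code path under test.

# ---- brute-force MAP path score -------------------------------------------

.path_cache <- new.env(parent = emptyenv())

# Enumerates all S^n state paths and returns the maximum joint
# log-likelihood (prior + emissions + per-step symmetric transitions).
oracle_map_score <- function(emis_ll, log_prior, log_stay, log_off) {
  n <- nrow(emis_ll)
  S <- ncol(emis_ll)
  stopifnot(n <= 8)  # 5^8 = 390,625 paths
  key <- paste(n, S, sep = "x")
  P <- get0(key, envir = .path_cache)
  if (is.null(P)) {
    P <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
    assign(key, P, envir = .path_cache)
  }
  sc <- log_prior[P[, 1]]
  for (t in seq_len(n)) sc <- sc + emis_ll[(P[, t] - 1L) * n + t]
  if (n > 1) {
    for (t in seq_len(n - 1)) {
      sc <- sc + ifelse(P[, t] == P[, t + 1], log_stay[t], log_off[t])
    }
  }
  list(score = max(sc), n_argmax = sum(sc > max(sc) - 1e-9),
       path = P[which.max(sc), ] - 1L)
}

# Random HMM instance in the same parameterisation viterbi_path() consumes.
random_hmm_instance <- function(n_markers) {
  list(
    emis_ll = matrix(rnorm(n_markers * 5, sd = 2), n_markers, 5),
    log_prior = log(local({ p <- runif(5, 0.05, 1); p / sum(p) })),
    log_stay = log(runif(n_markers - 1, 0.6, 0.999)),
    log_off = log(runif(n_markers - 1, 1e-4, 0.1))
  )
}

# ---- per-base / graph interval oracles ------------------------------------

# Components of the >= 1 bp overlap graph (explicit adjacency + igraph),
# returning each component's span. 1-based closed intervals on one
# chromosome.
oracle_overlap_components <- function(start, end) {
  m <- length(start)
  adj <- outer(seq_len(m), seq_len(m),
               function(i, j) start[i] <= end[j] & end[i] >= start[j])
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  spans <- t(vapply(sort(unique(memb)), function(cc) {
    c(min(start[memb == cc]), max(end[memb == cc]))
  }, numeric(2)))
  spans[order(spans[, 1]), , drop = FALSE]
}

# Maximal runs of bases covered by both interval sets (per-base AND).
oracle_perbase_intersect <- function(sa, ea, sb, eb, L) {
  cov_a <- logical(L)
  cov_b <- logical(L)
  for (i in seq_along(sa)) cov_a[sa[i]:ea[i]] <- TRUE
  for (i in seq_along(sb)) cov_b[sb[i]:eb[i]] <- TRUE
  r <- rle(cov_a & cov_b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

# Bipartite-plus-isolated overlap graph between two interval sets:
# component membership over c(set A, set B) nodes, edges only across sets.
oracle_bipartite_components <- function(sa, ea, sb, eb) {
  n_a <- length(sa)
  n_b <- length(sb)
  edges <- integer(0)
  for (i in seq_len(n_a)) {
    for (j in seq_len(n_b)) {
      if (sa[i] <= eb[j] && ea[i] >= sb[j]) {
        edges <- c(edges, i, n_a + j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n_a + n_b, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

# Random already-merged region set: overlap-component spans with no
# book-ended neighbours (gap of at least 2 bp between spans), so per-base
# and pairwise interval semantics coincide on them.
draw_merged_spans <- function(n, max_pos, max_len) {
  repeat {
    s <- sample.int(max_pos, n)
    e <- s + sample.int(max_len, n)
    sp <- oracle_overlap_components(s, e)
    if (nrow(sp) < 2 || all(sp[-1, 1] > sp[-nrow(sp), 2] + 1)) return(sp)
  }
}

# Explicit hypergeometric upper tail: P(X >= k) for X ~ Hyper(N, K, n).
oracle_hyper_tail <- function(k, n, K, N) {
  sum(stats::dhyper(k:min(n, K), K, N - K, n))
}

# ---- fixture builders ------------------------------------------------------

make_profile <- function(lrr, baf, sample_id = "s1") {
  structure(list(sample_id = sample_id, lrr = lrr, baf = baf),
            class = "intensity_profile")
}

make_call <- function(sample_id, chrom, start_bp, end_bp, copy_number,
                      caller_id = "viterbi", lbf = NA_real_,
                      n_markers = 3L) {
  data.frame(
    sample_id = sample_id, chrom = as.character(chrom),
    start_bp = start_bp, end_bp = end_bp, n_markers = n_markers,
    copy_number = copy_number,
    class = ifelse(copy_number < 2, "loss", "gain"),
    caller_id = caller_id, lbf = lbf, stringsAsFactors = FALSE
  )
}

make_region_df <- function(chrom, start_bp, end_bp, cattle_type = "taurine",
                           caller_id = "viterbi", prefix = "R") {
  data.frame(
    region_id = sprintf("%s%03d", prefix, seq_along(start_bp)),
    chrom = as.character(chrom), start_bp = start_bp, end_bp = end_bp,
    cattle_type = cattle_type, caller_id = caller_id,
    stringsAsFactors = FALSE
  )
}

# Two-population-per-type metadata for region tests.
toy_metadata <- function() {
  data.frame(
    sample_id = sprintf("s%02d", 1:12),
    population = rep(c("popA", "popB", "popC", "popD"), each = 3),
    cattle_type = rep(c("taurine", "zebu"), each = 6),
    stringsAsFactors = FALSE
  )
}

# Small cohort config exercising the whole pipeline quickly.
demo_config <- function(seed = 1L, n_per_population = 3L,
                        markers_per_chromosome = 500L,
                        private_rate = 0.2, qc_failures = NULL) {
  list(
    seed = seed,
    simulate = list(
      map = list(n_chromosomes = 2, markers_per_chromosome = markers_per_chromosome,
                 mean_spacing_bp = 1000),
      cohort = list(
        taurine = list(populations = c("Lagunaire", "NDamaBF", "NDamaCo"),
                       n_per_population = n_per_population),
        zebu = list(populations = c("Bororo", "ZebuPeulBe", "ZebuPeulBF"),
                    n_per_population = n_per_population)
      ),
      design = list(
        shared = data.frame(
          cattle_type = c("taurine", "taurine", "zebu", "taurine,zebu"),
          n_carriers = c(5, 4, 5, 6),
          n_markers = c(40, 30, 35, 30),
          copy_number = c(3, 1, 3, 1),
          stringsAsFactors = FALSE
        ),
        private_rate = private_rate
      ),
      qc_failures = qc_failures
    )
  )
}

# Study-scale cohort config: 2 types x 3 populations x 10 samples,
# 5 chromosomes x 2000 markers, default emissions with lrr_sd 0.2.
recovery_config <- function(seed) {
  list(
    seed = seed,
    simulate = list(
      map = list(n_chromosomes = 5, markers_per_chromosome = 2000,
                 mean_spacing_bp = 1000),
      cohort = list(
        taurine = list(populations = c("Lagunaire", "NDamaBF", "NDamaCo"),
                       n_per_population = 10),
        zebu = list(populations = c("Bororo", "ZebuPeulBe", "ZebuPeulBF"),
                    n_per_population = 10)
      ),
      emission = list(lrr_sd = 0.2),
      design = list(
        shared = data.frame(
          cattle_type = c("taurine", "taurine", "taurine", "taurine",
                          "zebu", "zebu", "zebu", "zebu",
                          "taurine,zebu", "taurine,zebu"),
          n_carriers = c(5, 4, 6, 3, 5, 4, 3, 6, 6, 6),
          n_markers = c(40, 30, 25, 20, 35, 45, 20, 30, 30, 40),
          copy_number = c(3, 1, 4, 0, 3, 1, 3, 4, 3, 1),
          stringsAsFactors = FALSE
        ),
        private_rate = 0.2
      )
    )
  )
}
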