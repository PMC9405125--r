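# End-to-end orchestration: configuration defaulting, stage sequencing,
# output writing and a reproducibility manifest.

#' Default pipeline configuration
#'
#' Every stage threshold defaults to the conventional value of the
#' dual-caller CNVR workflow: sample QC at LRR sd 0.3 / BAF drift 0.01,
#' Bayes-factor filtering at 10 with the informative tier above 30, minimum
#' 3 markers per call, representativeness at 3 individuals or 2
#' populations, length classes at 50 kb / 100 kb / 500 kb / 1 Mb, and a
#' cluster enrichment-score threshold of 1.3. All are overridable.
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = NULL,   # a simulate_cohort() config block, or NULL
    inputs = NULL,     # list(map=, intensity=, metadata=) of file paths
    qc = list(lrr_sd_max = 0.3, baf_drift_max = 0.01),
    calling = list(min_markers = 3L, lbf_min = 10, informative_lbf = 30,
                   pfb = 0.5),
    regions = list(min_individuals = 3L, min_populations = 2L,
                   candidate_bounds = "intersection",
                   length_bins = c(5e4, 1e5, 5e5, 1e6)),
    annotation = list(genes = NULL, qtls = NULL, term_map = NULL,
                      clusters = NULL, score_threshold = 1.3)
  )
}

# Recursive config merge: user values override defaults, unknown keys kept.
.merge_config <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(defaults[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read a pipeline configuration from YAML
#'
#' @param file Path to a YAML file; its values override [default_config()].
#' @return The merged configuration list.
#' @export
read_config <- function(file) {
  .merge_config(default_config(), yaml::read_yaml(file))
}

#' Run the full dual-caller CNVR pipeline
#'
#' Sequences the stages: data (simulation, or reading the map/intensity/
#' metadata inputs), per-sample QC, CNV calling with both caller profiles,
#' call editing, per-type/per-caller merge into potential CNVRs,
#' representativeness filtering, cross-caller intersection into candidate
#' CNVRs, cross-type specificity classification, region summaries and —
#' when feature files are configured — gene/QTL annotation with term
#' enrichment. All stage outputs are written under `out_dir` together with
#' a `manifest.json` recording the config hash, seed, per-stage record
#' counts and timings. Rerunning with an identical config reproduces
#' identical outputs.
#'
#' @param config Configuration list (merged over [default_config()]) or a
#'   YAML path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  config <- .merge_config(default_config(), config)

  # -- validation before any stage runs
  if (is.null(config$simulate) && is.null(config$inputs)) {
    stop("config must provide either a `simulate` block or `inputs` paths")
  }
  if (!is.null(config$inputs)) {
    need <- c("map", "intensity", "metadata")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss)) stop("`inputs` must name: ", paste(miss, collapse = ", "))
    absent <- !vapply(unlist(config$inputs[need]), file.exists, logical(1))
    if (any(absent)) {
      stop("missing input file(s): ",
           paste(unlist(config$inputs[need])[absent], collapse = ", "))
    }
  }
  for (f in Filter(Negate(is.null),
                   config$annotation[c("genes", "qtls", "term_map",
                                       "clusters")])) {
    if (!file.exists(f)) stop("missing annotation file: ", f)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  timings <- list()
  counts <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # -- stage 1: data
  dat <- clock("data", {
    if (!is.null(config$simulate)) {
      sim <- simulate_cohort(c(config$simulate, list(seed = config$seed)))
      write_marker_map(sim$map, file.path(out_dir, "marker_map.tsv"))
      write_sample_meta(sim$samples, file.path(out_dir, "samples.tsv"))
      if (nrow(sim$truth)) {
        write_truth_bed(sim$truth, file.path(out_dir, "truth_events.bed"))
      }
      sim
    } else {
      map <- read_marker_map(config$inputs$map)
      samples <- read_sample_meta(config$inputs$metadata)
      profiles <- read_intensity(config$inputs$intensity, map)
      list(map = map, samples = samples, profiles = profiles, truth = NULL,
           shared_regions = NULL, pfb = config$calling$pfb)
    }
  })
  counts$samples <- nrow(dat$samples)
  counts$markers <- nrow(dat$map)

  # -- stage 2: QC
  qc <- clock("qc", qc_cohort(dat$profiles,
                              lrr_sd_max = config$qc$lrr_sd_max,
                              baf_drift_max = config$qc$baf_drift_max))
  .fwrite_tsv(qc, file.path(out_dir, "sample_qc.tsv"))
  counts$qc_failed <- sum(!qc$passed)

  # -- stage 3: calling, both profiles
  emission <- if (!is.null(dat$emission)) dat$emission else emission_params()
  edited <- clock("calling", {
    out <- list()
    for (prof in c("viterbi", "bayes")) {
      params <- hmm_params(prof, emission = emission)
      calls <- call_cohort(dat$profiles, dat$map, params, qc = qc,
                           min_markers = config$calling$min_markers,
                           pfb = dat$pfb)
      out[[prof]] <- edit_calls(calls, qc,
                                lbf_min = config$calling$lbf_min,
                                informative_lbf = config$calling$informative_lbf)
      write_calls(out[[prof]],
                  file.path(out_dir, sprintf("calls_%s.tsv", prof)))
      write_calls_bed(out[[prof]],
                      file.path(out_dir, sprintf("calls_%s.bed", prof)))
    }
    out
  })
  counts$calls_viterbi <- nrow(edited$viterbi)
  counts$calls_bayes <- nrow(edited$bayes)

  # -- stage 4: regions
  types <- sort(unique(dat$samples$cattle_type))
  if (length(types) != 2L) stop("region stages need exactly two cattle types")
  chroms <- unique(dat$map$chrom)

  reg <- clock("regions", {
    potential <- list()
    representative <- list()
    candidates <- list()
    for (ty in types) {
      for (prof in c("viterbi", "bayes")) {
        pot <- merge_calls_to_potential(edited[[prof]], dat$samples,
                                        cattle_type = ty, caller_id = prof,
                                        chromosomes = chroms)
        potential[[paste(ty, prof, sep = ".")]] <- pot
        representative[[paste(ty, prof, sep = ".")]] <-
          representativeness_filter(pot,
                                    config$regions$min_individuals,
                                    config$regions$min_populations)
      }
      candidates[[ty]] <- intersect_callers(
        representative[[paste(ty, "viterbi", sep = ".")]],
        representative[[paste(ty, "bayes", sep = ".")]],
        bounds = config$regions$candidate_bounds
      )
    }
    cls <- classify_specificity(candidates[[types[1]]], candidates[[types[2]]],
                                type_a = types[1], type_b = types[2])
    list(potential = potential, representative = representative,
         candidates = candidates, final = cls$final,
         accounting = cls$accounting)
  })
  for (nm in names(reg$potential)) {
    write_regions(reg$potential[[nm]],
                  file.path(out_dir, sprintf("potential_%s.tsv", nm)))
  }
  for (ty in types) {
    write_regions(reg$candidates[[ty]],
                  file.path(out_dir, sprintf("candidates_%s.tsv", ty)))
    write_regions_bed(reg$candidates[[ty]],
                      file.path(out_dir, sprintf("candidates_%s.bed", ty)))
  }
  write_regions(reg$final, file.path(out_dir, "final_cnvrs.tsv"))
  write_regions_bed(reg$final, file.path(out_dir, "final_cnvrs.bed"))
  .fwrite_tsv(reg$accounting$per_type, file.path(out_dir, "accounting.tsv"))
  counts$candidates <- vapply(reg$candidates, nrow, integer(1))
  counts$final_regions <- nrow(reg$final)
  counts$shared_regions <- reg$accounting$shared

  summaries <- lapply(
    split(reg$final, reg$final$label),
    summarize_regions, length_bins = config$regions$length_bins
  )
  summary_tab <- do.call(rbind, lapply(names(summaries), function(lb) {
    s <- summaries[[lb]]
    data.frame(label = lb, count = s$count,
               mean_length_bp = s$mean_length_bp, total_bp = s$total_bp,
               t(s$length_class_counts), check.names = FALSE,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(summary_tab)) {
    .fwrite_tsv(summary_tab, file.path(out_dir, "region_summary.tsv"))
  }

  # -- stage 5: annotation (optional)
  annotation <- NULL
  if (!is.null(config$annotation$genes)) {
    annotation <- clock("annotation", {
      genes <- read_genes(config$annotation$genes)
      out <- list()
      for (ty in types) {
        lab <- paste0(ty, "_specific")
        regs <- reg$final[reg$final$label == lab, , drop = FALSE]
        rg <- genes_in_regions(regs, genes, chromosomes = chroms)
        out[[ty]] <- list(region_genes = rg)
        .fwrite_tsv(rg$assignments,
                    file.path(out_dir, sprintf("genes_%s.tsv", lab)))
        if (!is.null(config$annotation$qtls)) {
          qtls <- read_qtls(config$annotation$qtls)
          rep_q <- qtl_overlap_report(rg, genes, qtls)
          out[[ty]]$qtl <- rep_q
          .fwrite_tsv(rep_q$overlaps,
                      file.path(out_dir, sprintf("qtl_overlap_%s.tsv", lab)))
        }
        if (!is.null(config$annotation$term_map) &&
            rg$n_genes > 0L) {
          tm <- read_term_map(config$annotation$term_map)
          enr <- fisher_enrichment(unique(rg$assignments$gene_id),
                                   unique(genes$gene_id), tm)
          out[[ty]]$enrichment <- enr
          .fwrite_tsv(enr, file.path(out_dir,
                                     sprintf("enrichment_%s.tsv", lab)))
          if (!is.null(config$annotation$clusters)) {
            cl <- score_clusters(enr, read_clusters(config$annotation$clusters),
                                 config$annotation$score_threshold)
            out[[ty]]$clusters <- cl
            .fwrite_tsv(cl, file.path(out_dir,
                                      sprintf("clusters_%s.tsv", lab)))
          }
        }
      }
      out
    })
  }

  manifest <- list(
    config_hash = .stable_hash(paste(deparse(config), collapse = "\n")),
    seed = config$seed,
    counts = counts,
    timings = timings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    config = config, data = dat, qc = qc, calls = edited,
    potential = reg$potential, representative = reg$representative,
    candidates = reg$candidates, final = reg$final,
    accounting = reg$accounting, summaries = summaries,
    annotation = annotation, manifest = manifest
  ))
}
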