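# Orchestration: a single configuration object holding every tunable with
# its default, and the end-to-end demo workflow
# simulate -> call-insertions -> annotate -> quantify-pirna -> associate
# with truth-vs-called comparison.

#' Pipeline configuration with defaults
#'
#' Collects every tunable of the pipeline in one list. Defaults are the
#' procedure's standard values: 20.0 percent dual-strand threshold, top-15
#' active clusters, 24-35 nt piRNA size class, GD < 10 percent phenotype
#' criterion, 300-600 bp size selection, 250-bp paired junction reads,
#' 40-individual pools. Round-trips losslessly through YAML.
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @param ... Overrides for any field.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # synthetic genome
    n_chromosomes = 4L, chrom_length = 300000L, n_clusters = 20L,
    paper_emulation = FALSE,
    # strains and planted insertions
    n_strains = 5L, insertions_per_strain = 8L,
    # junction library
    enzymes = c("GCGC", "TCGA"), read_length = 250L, pool_size = 40L,
    mean_depth_per_individual = 2, size_range = c(300L, 600L),
    primer_offset = 100L, error_rate = 0,
    # calling
    min_element_match = 20L, map_k = 31L, map_max_mismatch = 2L,
    merge_window = 10L,
    # cluster annotation
    strandness_threshold = 20, n_active = 15L,
    # small RNA
    smallrna_min_len = 24L, smallrna_max_len = 35L,
    n_mirna_reads = 50000L, n_junk_reads = 1000L,
    smallrna_max_mismatch = 0L,
    # panel / association
    beta_pirna = -3, beta_kp = -1, noise_sd = 0.5,
    gd_criterion = 10
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) stop("unknown config field(s): ",
                                paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Write / read a pipeline configuration as YAML
#' @param config A \code{pipeline_config}.
#' @param path YAML path.
#' @return Invisibly the path; the reader returns the config.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, c(list(seed = vals$seed), vals[names(vals) != "seed"]))
}

#' Run the end-to-end demo workflow on synthetic data
#'
#' Builds an element model and genome, then for each simulated strain:
#' plants insertions (a mix of in-cluster, active-, silent-region and
#' uniform targets), simulates and calls the junction library, annotates
#' cluster membership, simulates and quantifies small RNAs. A strain panel
#' built from the per-strain measurements (GD scores generated from the
#' configured logistic model on the measured piRNA and KP levels) is then
#' passed through the association layer. Each stage logs record counts to
#' stderr when \code{verbose}.
#'
#' @param config A \code{pipeline_config}.
#' @param out_dir Optional directory for report files (sites TSV/BED,
#'   profiles, panel TSV, newick dendrogram, JSON summary).
#' @param verbose Log stage progress to stderr (default FALSE).
#' @return List of class \code{demo_report}: element_model, genome
#'   (annotated clusters), per-strain list (insertions, truth, sites,
#'   profile, comparison), panel, association, summary.
#' @export
run_demo <- function(config = pipeline_config(), out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) if (verbose) message(sprintf(...))
  seed0 <- config$seed

  em <- make_element_model(seed = seed0)
  genome <- make_genome(n_chromosomes = config$n_chromosomes,
                        chrom_length = config$chrom_length,
                        n_clusters = config$n_clusters,
                        paper_emulation = config$paper_emulation,
                        seed = seed0 + 1L)
  genome$clusters <- annotate_clusters(genome$clusters,
                                       threshold = config$strandness_threshold,
                                       n_active = config$n_active)
  log_msg("genome: %d chromosomes, %d clusters", length(genome$chromosomes),
          nrow(genome$clusters))

  strains <- sprintf("S%02d", seq_len(config$n_strains))
  per_strain <- vector("list", config$n_strains)
  names(per_strain) <- strains

  for (s in seq_len(config$n_strains)) {
    sseed <- seed0 + 100L * s
    n_ins <- config$insertions_per_strain
    classes <- rep(c("in-cluster", "active-region", "silent-region", "uniform"),
                   length.out = n_ins)
    ins_spec <- data.frame(
      target_class = classes,
      variant = rep(c("FP", "KP"), length.out = n_ins),
      occupancy = rep(c(1, 0.5, 0.25, 1), length.out = n_ins),
      stringsAsFactors = FALSE
    )
    insertions <- plant_insertions(genome, ins_spec, seed = sseed)
    lib <- simulate_junction_library(genome, insertions, em,
                                     enzymes = config$enzymes,
                                     read_length = config$read_length,
                                     pool_size = config$pool_size,
                                     mean_depth_per_individual = config$mean_depth_per_individual,
                                     size_range = config$size_range,
                                     primer_offset = config$primer_offset,
                                     error_rate = config$error_rate,
                                     seed = sseed + 1L)
    sites <- call_insertions(lib, genome, em,
                             min_element_match = config$min_element_match,
                             k = config$map_k,
                             max_mismatch = config$map_max_mismatch,
                             merge_window = config$merge_window)
    sites <- assign_membership(sites, genome$clusters)

    srl <- simulate_small_rnas(genome, insertions, em,
                               n_mirna_reads = config$n_mirna_reads,
                               n_junk_reads = config$n_junk_reads,
                               seed = sseed + 2L)
    profile <- tryCatch(
      quantify_pirnas(srl, em, max_mismatch = config$smallrna_max_mismatch,
                      sample = strains[s]),
      error = function(e) {
        log_msg("strain %s: piRNA quantification failed: %s", strains[s],
                conditionMessage(e))
        structure(list(sense = integer(0), antisense = integer(0), total = 0L,
                       n_input = length(srl$reads), mirna_count = 0L,
                       rpm = NA_real_, sample = strains[s],
                       error = conditionMessage(e)),
                  class = "smallrna_profile")
      })

    comparison <- compare_to_truth(sites, lib$truth$insertions, config$merge_window)
    log_msg("strain %s: %d/%d detectable insertions recovered, %d sites, %.1f RPM",
            strains[s], comparison$n_recovered, comparison$n_detectable,
            nrow(sites), profile$rpm)

    per_strain[[s]] <- list(
      insertions = insertions, truth = lib$truth, sites = sites,
      cluster_read_pct = if (nrow(sites) > 0) cluster_read_fraction(sites) else NA_real_,
      region_fractions = if (nrow(sites) > 0) region_state_fractions(sites) else NULL,
      profile = profile, comparison = comparison
    )
  }

  # panel: measured piRNA RPM and cluster fractions; P/KP mRNA and GD from
  # the generative logistic model on the measured quantities
  rpms <- vapply(per_strain, function(x) x$profile$rpm %||% NA_real_, numeric(1))
  cl_pct <- vapply(per_strain, function(x) x$cluster_read_pct, numeric(1))
  panel <- with_seed(seed0 + 9999L, {
    kp <- stats::rlnorm(config$n_strains, log(2), 0.8)
    p_mrna <- stats::rlnorm(config$n_strains, log(1), 0.6)
    z <- function(v) {
      v[!is.finite(v)] <- 0  # strains without a measurement carry no signal
      s <- stats::sd(v)
      if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
    lin <- config$beta_pirna * z(rpms) + config$beta_kp * z(kp)
    gd_f1 <- 100 * stats::plogis(lin + stats::rnorm(config$n_strains, 0, config$noise_sd))
    gd_f2 <- 100 * stats::plogis(0.5 * lin + stats::rnorm(config$n_strains, 0, config$noise_sd))
    gd_astar <- 100 * stats::plogis(config$beta_pirna * z(rpms) +
                                      stats::rnorm(config$n_strains, 0, config$noise_sd))
    data.frame(strain = strains, pirna_rpm = rpms, p_mrna = p_mrna,
               kp_mrna = kp, cluster_read_pct = cl_pct,
               gd_f1 = gd_f1, gd_f2 = gd_f2, gd_astar = gd_astar,
               stringsAsFactors = FALSE)
  })
  panel$inducibility <- as.character(label_phenotype(panel$gd_f1, "A",
                                                     config$gd_criterion))
  panel$susceptibility <- as.character(label_phenotype(panel$gd_astar, "A*",
                                                       config$gd_criterion))

  association <- tryCatch(associate_panel(panel), error = function(e) {
    log_msg("association stage failed: %s", conditionMessage(e))
    structure(list(error = conditionMessage(e)), class = "association_error")
  })

  summary <- list(
    n_strains = config$n_strains,
    total_sites = sum(vapply(per_strain, function(x) nrow(x$sites), integer(1))),
    mean_recall = mean(vapply(per_strain, function(x)
      x$comparison$recall, numeric(1)), na.rm = TRUE),
    mean_precision = mean(vapply(per_strain, function(x)
      x$comparison$precision, numeric(1)), na.rm = TRUE),
    rpm_range = suppressWarnings(range(rpms, na.rm = TRUE)),
    regression_signs = if (inherits(association, "association_error")) NULL else
      sign(association$regression$coefficients$coef_zx)
  )

  report <- structure(list(element_model = em, genome = genome,
                           per_strain = per_strain, panel = panel,
                           association = association, summary = summary,
                           config = config),
                      class = "demo_report")
  if (!is.null(out_dir) && !inherits(association, "association_error")) {
    write_demo_report(report, out_dir)
  }
  report
}

#' Compare called insertion sites against simulation truth
#'
#' Detectable insertions are those whose truth records at least one
#' mappable read pair (the junction assay cannot see an insertion whose
#' restriction fragments all fall outside the size-selection window or
#' expose too little flank). A detectable insertion counts as recovered
#' when a called site with the right element orientation lies within
#' \code{merge_window} of its planted position.
#'
#' @param sites Called site table.
#' @param truth Truth insertion table from
#'   \code{\link{simulate_junction_library}}.
#' @param merge_window Positional tolerance (bp).
#' @return List: n_detectable, n_recovered, recall, precision,
#'   max_position_error.
#' @export
compare_to_truth <- function(sites, truth, merge_window = 10L) {
  detectable <- truth[truth$n_mappable > 0, , drop = FALSE]
  recovered <- logical(nrow(detectable))
  matched_sites <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(detectable))) {
    hit <- which(sites$chrom == detectable$chrom[i] &
                   sites$element_strand == detectable$strand[i] &
                   abs(sites$position - detectable$position[i]) <= merge_window)
    if (length(hit) > 0) {
      recovered[i] <- TRUE
      matched_sites[hit] <- TRUE
    }
  }
  pos_err <- vapply(which(recovered), function(i) {
    min(abs(sites$position[sites$chrom == detectable$chrom[i]] -
              detectable$position[i]))
  }, numeric(1))
  list(n_detectable = nrow(detectable),
       n_recovered = sum(recovered),
       recall = if (nrow(detectable) > 0) mean(recovered) else NA_real_,
       precision = if (nrow(sites) > 0) mean(matched_sites) else NA_real_,
       max_position_error = if (length(pos_err) > 0) max(pos_err) else NA_real_)
}

#' Write the demo report files
#'
#' @param report A \code{demo_report}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_demo_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_clusters_bed(report$genome$clusters, file.path(out_dir, "clusters.bed"))
  write_track_bed(report$genome$track, file.path(out_dir, "track.bed"))
  for (s in names(report$per_strain)) {
    ps <- report$per_strain[[s]]
    write_sites(ps$sites,
                bed_path = file.path(out_dir, paste0(s, "_sites.bed")),
                tsv_path = file.path(out_dir, paste0(s, "_sites.tsv")))
    utils::write.table(profile_table(ps$profile),
                       file.path(out_dir, paste0(s, "_profile.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_panel_tsv(report$panel, file.path(out_dir, "panel.tsv"))
  writeLines(report$association$newick, file.path(out_dir, "dendrogram.nwk"))
  jsonlite::write_json(
    list(summary = report$summary,
         correlations = report$association$correlations,
         regression = report$association$regression$coefficients),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.demo_report <- function(x, ...) {
  cat(sprintf("demo_report: %d strains, %d called sites, mean recall %.3f, mean precision %.3f\n",
              x$summary$n_strains, x$summary$total_sites,
              x$summary$mean_recall, x$summary$mean_precision))
  cat(sprintf("piRNA RPM range: %.1f - %.1f\n",
              x$summary$rpm_range[1], x$summary$rpm_range[2]))
  if (inherits(x$association, "association_error")) {
    cat("association stage failed:", x$association$error, "\n")
  } else {
    print(x$association$regression)
  }
  invisible(x)
}
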