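#' Write a run manifest
#'
#' Every pipeline output directory gets one manifest recording the command,
#' a snapshot of the configuration, md5 checksums of the input files, the
#' package version, the seed and a timestamp — enough to reproduce the run.
#'
#' @param out_dir Output directory.
#' @param command Command or stage list executed.
#' @param config Configuration list snapshot.
#' @param inputs Character vector of input file paths to checksum.
#' @param seed Seed used for the run (or `NA`).
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(out_dir, command, config, inputs = character(),
                           seed = NA_integer_) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    command = command,
    config = config,
    input_checksums = as.list(tools::md5sum(inputs)),
    tool = "mipmeter",
    version = as.character(packageVersion("mipmeter")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.stage_deps <- c(design = "", simulate = "", count = "",
                 qc = "count|simulate", freq = "qc",
                 traits = "freq")

.validate_pipeline_config <- function(config) {
  known <- c("stages", "seed", "out_dir", "design", "simulate", "count",
             "qc", "freq", "traits")
  bad <- setdiff(names(config), known)
  if (length(bad) > 0L) {
    stop("config error: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stages <- config$stages
  if (is.null(stages) || !all(stages %in% names(.stage_deps))) {
    stop("config error: `stages` must be a subset of ",
         paste(names(.stage_deps), collapse = ", "), call. = FALSE)
  }
  for (st in stages) {
    dep <- .stage_deps[[st]]
    if (!nzchar(dep)) next
    alts <- strsplit(dep, "|", fixed = TRUE)[[1]]
    if (!any(alts %in% stages)) {
      stop("dependency error: stage '", st, "' requires stage '",
           alts[1L], "' (missing from `stages`)", call. = FALSE)
    }
  }
  stages
}

#' Run the MIP-seq pipeline from a configuration
#'
#' Executes the requested stages in dependency order with per-stage
#' summaries, writing every intermediate as a plain TSV so it stays
#' inspectable, plus a run manifest. Stages: `design` (VCF + FASTA ->
#' panel), `simulate` (simulator -> counts + sample map + truth), `count`
#' (FASTQ -> counts), `qc` (pilot counts -> probe QC), `freq` (counts + QC
#' -> strain frequencies), `traits` (frequencies + sample map -> Slope/PC1
#' trait table). Configuration errors and missing dependencies fail fast
#' with stage-attributed messages.
#'
#' @param config Path to a YAML configuration or an equivalent list. Keys:
#'   `stages` (character vector), `out_dir`, `seed`, and one block per
#'   stage.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a list of stage outputs.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  stages <- .validate_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("config error: no out_dir",
                                                   call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  inputs <- character(0)
  res <- list()

  if ("design" %in% stages) {
    dc <- config$design
    inputs <- c(inputs, dc$vcf, dc$fasta)
    snvs <- find_unique_snvs(dc$vcf, dc$strains)
    panel <- build_panel(snvs, dc$fasta,
                         probes_per_strain = dc$probes_per_strain %||% 4L)
    write_panel(panel, file.path(out_dir, "panel.tsv"),
                file.path(out_dir, "panel.fasta"))
    message("design: ", length(panel$probes), " probes for ",
            length(panel$strains), " strains")
    res$panel <- panel
  }

  if ("simulate" %in% stages) {
    sc <- do.call(sim_config, c(config$simulate %||% list(),
                                list(seed = as.integer(seed))))
    refpan <- sim_reference_panel(sc)
    truth <- simulate_trajectories(sc)
    sim <- simulate_reads(truth, refpan$panel)
    write_panel(refpan$panel, file.path(out_dir, "panel.tsv"))
    write_counts(sim$counts, file.path(out_dir, "counts.tsv"))
    write.table(sim$sample_map, file.path(out_dir, "samples.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    truth_df <- as.data.frame.table(truth$true_frequency,
                                    stringsAsFactors = FALSE)
    names(truth_df) <- c("replicate", "strain_id", "day", "true_frequency")
    write.table(truth_df, file.path(out_dir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    message("simulate: ", sc$n_strains, " strains, ", sc$replicates,
            " replicates")
    res$panel <- refpan$panel
    res$counts <- sim$counts
    res$sample_map <- sim$sample_map
    res$truth <- truth
  }

  if ("count" %in% stages) {
    cc <- config$count
    panel <- res$panel %||% read_panel(cc$panel)
    inputs <- c(inputs, cc$fastq, cc$panel)
    cnt <- count_alleles(unlist(cc$fastq), panel,
                         sample_ids = unlist(cc$sample_ids %||% NULL),
                         dedup_umi = isTRUE(cc$dedup_umi))
    write_counts(cnt$counts, file.path(out_dir, "counts.tsv"))
    write.table(cnt$summary, file.path(out_dir, "count_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    message("count: ", sum(cnt$summary$n_reads), " reads, ",
            round(100 * mean(cnt$summary$frac_key_match), 1),
            "% matched the assignment key")
    res$counts <- cnt$counts
  }

  if ("qc" %in% stages) {
    qcfg <- config$qc %||% list()
    counts <- res$counts %||% (if (!is.null(qcfg$counts))
      read_counts(qcfg$counts) else
        stop("dependency error: qc needs counts (stage 'count' or ",
             "'simulate', or qc$counts)", call. = FALSE))
    pilot_id <- qcfg$pilot_sample %||% counts$sample_id[1L]
    pilot <- counts[counts$sample_id == pilot_id, , drop = FALSE]
    thr <- qc_thresholds(
      n_strains = qcfg$n_strains %||% length(unique(res$panel$strains)),
      depth_scale = qcfg$depth_scale %||% 1
    )
    exempt <- character(0)
    if (!is.null(qcfg$exempt_strains) && !is.null(res$panel)) {
      tab <- panel_table(res$panel)
      exempt <- tab$probe_id[tab$strain_id %in% qcfg$exempt_strains]
    }
    qc <- qc_probes(pilot, thr, exempt = exempt)
    write.table(qc, file.path(out_dir, "qc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    message("qc: ", sum(qc$pass), "/", nrow(qc), " probes passing")
    res$qc <- qc
  }

  if ("freq" %in% stages) {
    freqs <- strain_frequencies(res$counts, res$qc, res$panel)
    write.table(freqs, file.path(out_dir, "frequencies.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    message("freq: ", length(unique(freqs$strain_id)), " strains retained",
            if (length(attr(freqs, "dropouts")))
              paste0(" (dropouts: ",
                     paste(attr(freqs, "dropouts"), collapse = ", "), ")")
            else "")
    res$frequencies <- freqs
  }

  if ("traits" %in% stages) {
    tc <- config$traits %||% list()
    smap <- res$sample_map %||% (if (!is.null(tc$samples))
      read.delim(tc$samples, stringsAsFactors = FALSE) else
        stop("dependency error: traits needs a sample map (stage ",
             "'simulate' or traits$samples)", call. = FALSE))
    traj <- normalize_to_baseline(res$frequencies, smap)
    sl <- slope_trait(traj, fit_days = tc$slope_days %||% c(1, 9, 13))
    pc <- pc1_trait(traj, days = tc$pc_days %||% c(1, 9, 13, 17))
    traits <- trait_table(sl, pc)
    export_traits(traits, file.path(out_dir, "traits.tsv"))
    message("traits: ", sum(!is.na(traits$slope)), " strains with Slope, ",
            sum(!is.na(traits$pc1)), " with PC1")
    res$traits <- traits
  }

  write_manifest(out_dir, command = paste(stages, collapse = " -> "),
                 config = config, inputs = unlist(inputs), seed = seed)
  invisible(res)
}
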