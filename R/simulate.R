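#' Configuration for a simulated pooled-competition experiment
#'
#' Defines the conditions of a synthetic starvation-competition experiment:
#' a pool of `n_strains` strains at near-equal baseline composition
#' (perturbed per replicate with Dirichlet dispersion controlled by
#' `baseline_concentration`), strain-specific logistic survival with
#' per-strain half-lives acting across the starvation days, an optional
#' per-strain recovery/fecundity multiplier, per-probe capture bias, and
#' sequencing substitution error feeding the "other" allele classes.
#' Default conditions mirror the study design: 103 strains, 5 biological
#' replicates, sampling days 1/9/13/17 with a day-1 baseline, 4 probes per
#' strain. Read depth defaults to ~10^4 reads per probe so simulations run
#' in seconds; `published_depth = TRUE` rescales to the published per-probe
#' depth.
#'
#' @param n_strains Number of strains (default 103).
#' @param replicates Biological replicates (default 5).
#' @param timepoints Starvation days sampled (default `c(1, 9, 13, 17)`).
#' @param baseline_day Day of the baseline aliquot (default 1).
#' @param strain_half_life Per-strain survival half-life in days; default a
#'   grade from 8 to 16 days across strains (order-of-magnitude choice
#'   matching wild-strain L1 survival curves).
#' @param survival_rate Logistic mortality steepness, per day (default 0.5).
#' @param recovery_gain Per-strain log-scale recovery/fecundity advantage
#'   per day of starvation (default 0: fitness differences are
#'   survival-driven).
#' @param baseline_concentration Dirichlet concentration per strain for the
#'   baseline composition (default 200: ~7% CV around equal proportions).
#' @param recovery_saturation Strength of late-starvation compression of
#'   frequency differences (default 0 = off); see
#'   [simulate_trajectories()].
#' @param probes_per_strain Probes per strain (default 4).
#' @param probe_depth_mean Mean reads per probe per sample (default 1e4).
#' @param probe_bias_sd Log-scale SD of mean-one log-normal per-probe
#'   capture bias (default 0.25).
#' @param error_rate Per-base substitution probability at the SNV slot
#'   (default 0.001).
#' @param read_length,umi_length Read architecture (defaults 50 and 10).
#' @param published_depth Emulate the published sequencing depth (~1.25e5 reads
#'   per probe) instead of the fast default.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_strains = 103L, replicates = 5L,
                       timepoints = c(1, 9, 13, 17), baseline_day = 1,
                       strain_half_life = NULL, survival_rate = 0.5,
                       recovery_gain = 0, baseline_concentration = 200,
                       recovery_saturation = 0, probes_per_strain = 4L,
                       probe_depth_mean = 1e4, probe_bias_sd = 0.25,
                       error_rate = 0.001, read_length = 50L,
                       umi_length = 10L, published_depth = FALSE, seed = 1L) {
  n_strains <- as.integer(n_strains)
  if (is.null(strain_half_life)) {
    strain_half_life <- seq(8, 16, length.out = n_strains)
  }
  strain_half_life <- rep_len(strain_half_life, n_strains)
  recovery_gain <- rep_len(recovery_gain, n_strains)
  if (published_depth) probe_depth_mean <- 1.25e5
  cfg <- list(
    n_strains = n_strains,
    replicates = as.integer(replicates),
    timepoints = sort(unique(timepoints)),
    baseline_day = baseline_day,
    strain_half_life = strain_half_life,
    survival_rate = survival_rate,
    recovery_gain = recovery_gain,
    baseline_concentration = baseline_concentration,
    recovery_saturation = recovery_saturation,
    probes_per_strain = as.integer(probes_per_strain),
    probe_depth_mean = probe_depth_mean,
    probe_bias_sd = probe_bias_sd,
    error_rate = error_rate,
    read_length = as.integer(read_length),
    umi_length = as.integer(umi_length),
    seed = as.integer(seed),
    strain_ids = sprintf("S%03d", seq_len(n_strains))
  )
  stopifnot(cfg$n_strains >= 2L, cfg$replicates >= 1L,
            all(cfg$strain_half_life > 0),
            cfg$error_rate >= 0, cfg$error_rate <= 0.1,
            cfg$probe_depth_mean > 0, cfg$baseline_concentration > 0,
            cfg$survival_rate > 0)
  structure(cfg, class = "sim_config")
}

#' Load a simulator configuration from a YAML file
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

.logistic_survival <- function(t, half_life, rate) {
  1 / (1 + exp(rate * (t - half_life)))
}

#' Simulate true strain trajectories of a pooled competition
#'
#' Baseline composition per replicate is Dirichlet around equal proportions.
#' At starvation day `t`, strain weight is
#' `baseline * S(t)^phi(t) * exp(recovery_gain * (t - baseline_day))`, where
#' `S(t)` is the same logistic survival form used by [fit_survival()] and
#' `phi(t) = Sbar / (Sbar + recovery_saturation * (1 - Sbar))` (with `Sbar`
#' the across-strain mean survival) is a saturation exponent: recovery
#' cultures grow to saturation from however many larvae survive, so when
#' late mortality is heavy the effective resolution of strain differences
#' scales with the surviving fraction and between-strain frequency
#' differences compress, mirroring the observed shrinkage of differences at
#' the last sampling day. Weights are renormalized to frequencies at each
#' (replicate, day).
#'
#' @param config A [sim_config()].
#' @return A `sim_truth`: list with `true_frequency` (replicate x strain x
#'   day array), `true_baseline` (replicate x strain matrix) and the config.
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  S <- config$n_strains
  R <- config$replicates
  days <- config$timepoints
  base <- matrix(rgamma(R * S, shape = config$baseline_concentration,
                        rate = 1), nrow = R)
  base <- base / rowSums(base)
  dimnames(base) <- list(paste0("r", seq_len(R)), config$strain_ids)

  freq <- array(NA_real_, dim = c(R, S, length(days)),
                dimnames = list(paste0("r", seq_len(R)), config$strain_ids,
                                as.character(days)))
  for (di in seq_along(days)) {
    t <- days[di]
    surv <- .logistic_survival(t, config$strain_half_life,
                               config$survival_rate)
    sbar <- mean(surv)
    phi <- sbar / (sbar + config$recovery_saturation * (1 - sbar))
    gain <- exp(config$recovery_gain * (t - config$baseline_day))
    w <- sweep(base, 2L, surv^phi * gain, `*`)
    freq[, , di] <- w / rowSums(w)
  }
  structure(list(true_frequency = freq, true_baseline = base,
                 config = config), class = "sim_truth")
}

# Per-probe mean-one log-normal capture bias (deterministic given seed).
.draw_probe_bias <- function(panel, config) {
  tab <- panel_table(panel)
  set.seed(config$seed + 1L)
  sdl <- config$probe_bias_sd
  setNames(exp(rnorm(nrow(tab), mean = -sdl^2 / 2, sd = sdl)), tab$probe_id)
}

# Allele-class probabilities for one probe given target-strain frequency f,
# capture bias b, substitution error e. The bias renormalizes the alt
# capture probability; substitution error reallocates reads uniformly to
# the three non-source nucleotides.
.class_probs <- function(f, b, e) {
  p_alt0 <- f * b / (f * b + (1 - f))
  p_ref0 <- 1 - p_alt0
  c(ref     = p_ref0 * (1 - e) + p_alt0 * e / 3,
    alt     = p_alt0 * (1 - e) + p_ref0 * e / 3,
    other_a = e / 3,
    other_b = e / 3)
}

# Simulate counts for one sample at the given strain frequencies.
.simulate_sample_counts <- function(freqs, panel, config, bias, sample_id) {
  tab <- panel_table(panel)
  n <- nrow(tab)
  depth <- rpois(n, config$probe_depth_mean)
  out <- data.frame(
    probe_id = tab$probe_id, sample_id = sample_id,
    n_ref = 0L, n_alt = 0L, n_other_a = 0L, n_other_b = 0L,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    f <- freqs[[tab$strain_id[i]]]
    pr <- .class_probs(f, bias[[tab$probe_id[i]]], config$error_rate)
    cts <- rmultinom(1L, size = depth[i], prob = pr)[, 1L]
    out$n_ref[i] <- cts[1L]; out$n_alt[i] <- cts[2L]
    out$n_other_a[i] <- cts[3L]; out$n_other_b[i] <- cts[4L]
  }
  out$n_assigned <- out$n_ref + out$n_alt + out$n_other_a + out$n_other_b
  out
}

# Materialize FASTQ reads for one sample's count table.
.counts_to_reads <- function(counts, panel, config) {
  keys <- .panel_key_table(panel, read_layout(config$umi_length,
                                              read_length = config$read_length))
  ki <- match(counts$probe_id, keys$probe_id)
  reads <- character(0)
  for (i in seq_len(nrow(counts))) {
    k <- keys[ki[i], ]
    idx <- k$snv_pos - config$umi_length - nchar(k$key_seq)
    per_base <- c(REF = k$ref, ALT = k$alt,
                  OTHER_A = k$other_a, OTHER_B = k$other_b)
    ns <- c(counts$n_ref[i], counts$n_alt[i],
            counts$n_other_a[i], counts$n_other_b[i])
    for (j in seq_along(ns)) {
      if (ns[j] == 0L) next
      body <- k$scan_prefix
      substr(body, idx, idx) <- per_base[[j]]
      umis <- vapply(seq_len(ns[j]), function(z) {
        paste(sample(c("A", "C", "G", "T"), config$umi_length,
                     replace = TRUE), collapse = "")
      }, "")
      reads <- c(reads, paste0(umis, k$key_seq, body))
    }
  }
  reads
}

#' Simulate probe-level reads for a pooled competition
#'
#' Draws per-probe read depth around `probe_depth_mean`, alternative reads
#' with probability `true_frequency x probe bias` (renormalized), and
#' reallocates reads to the two "other" allele classes at the substitution
#' error rate. Samples comprise one baseline per replicate plus every
#' (replicate, day). In `"fastq"` mode the same count draws are
#' materialized as reads laid out per [read_layout()] (UMI, assignment key,
#' scan prefix with the allele base) with random UMIs, so piping the FASTQ
#' back through [count_alleles()] reproduces the count tables exactly.
#'
#' @param truth A `sim_truth` from [simulate_trajectories()].
#' @param panel A `panel_spec` whose strains match the simulated strains.
#' @param emit `"counts"` (default) or `"fastq"`.
#' @param fastq_dir Output directory for FASTQ files (fastq mode).
#' @return List with `counts`, `sample_map` (`sample_id`, `replicate`,
#'   `day`, `is_baseline`), `probe_bias`, and in fastq mode `fastq_paths`.
#' @export
simulate_reads <- function(truth, panel, emit = c("counts", "fastq"),
                           fastq_dir = tempdir()) {
  stopifnot(inherits(truth, "sim_truth"), inherits(panel, "panel_spec"))
  emit <- match.arg(emit)
  config <- truth$config
  panel_strains <- unique(panel_table(panel)$strain_id)
  if (!all(panel_strains %in% config$strain_ids)) {
    stop("panel strains not covered by the simulation: ",
         paste(setdiff(panel_strains, config$strain_ids), collapse = ", "),
         call. = FALSE)
  }
  bias <- .draw_probe_bias(panel, config)
  set.seed(config$seed + 2L)
  R <- config$replicates
  days <- config$timepoints
  counts <- list()
  sample_map <- list()
  for (r in seq_len(R)) {
    rep_id <- paste0("r", r)
    sid <- paste0(rep_id, "_base")
    counts[[sid]] <- .simulate_sample_counts(
      as.list(truth$true_baseline[r, ]), panel, config, bias, sid)
    sample_map[[sid]] <- data.frame(
      sample_id = sid, replicate = rep_id, day = config$baseline_day,
      is_baseline = TRUE, stringsAsFactors = FALSE)
    for (di in seq_along(days)) {
      sid <- paste0(rep_id, "_d", days[di])
      counts[[sid]] <- .simulate_sample_counts(
        as.list(truth$true_frequency[r, , di]), panel, config, bias, sid)
      sample_map[[sid]] <- data.frame(
        sample_id = sid, replicate = rep_id, day = days[di],
        is_baseline = FALSE, stringsAsFactors = FALSE)
    }
  }
  counts_df <- do.call(rbind, counts)
  rownames(counts_df) <- NULL
  map_df <- do.call(rbind, sample_map)
  rownames(map_df) <- NULL
  out <- list(counts = counts_df, sample_map = map_df, probe_bias = bias)
  if (emit == "fastq") {
    set.seed(config$seed + 3L)
    dir.create(fastq_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    for (sid in map_df$sample_id) {
      reads <- .counts_to_reads(
        counts_df[counts_df$sample_id == sid, , drop = FALSE], panel, config)
      path <- file.path(fastq_dir, paste0(sid, ".fastq.gz"))
      seqs <- Biostrings::DNAStringSet(reads)
      names(seqs) <- paste0(sid, ":", seq_along(reads))
      Biostrings::writeXStringSet(
        seqs, path, format = "fastq", compress = TRUE,
        qualities = Biostrings::BStringSet(
          rep(strrep("I", config$read_length), length(reads))))
      paths[sid] <- path
    }
    out$fastq_paths <- paths
  }
  out
}

#' Simulate an equimolar pilot sample
#'
#' One sample at exactly equal strain proportions (1/S), used to exercise
#' the probe QC filters.
#'
#' @param panel A `panel_spec`.
#' @param config A [sim_config()].
#' @param sample_id Sample label (default `"pilot"`).
#' @return List with `counts` and `probe_bias`.
#' @export
simulate_pilot <- function(panel, config, sample_id = "pilot") {
  stopifnot(inherits(config, "sim_config"))
  bias <- .draw_probe_bias(panel, config)
  set.seed(config$seed + 4L)
  freqs <- setNames(as.list(rep(1 / config$n_strains, config$n_strains)),
                    config$strain_ids)
  list(counts = .simulate_sample_counts(freqs, panel, config, bias,
                                        sample_id),
       probe_bias = bias)
}

#' Simulate a standard-curve sample at known mixing proportions
#'
#' Single-sample read simulation at the given composition, e.g. seven
#' strains spanning three orders of magnitude of concentration.
#'
#' @param proportions Named numeric vector (strain id -> proportion) summing
#'   to 1; strains absent from the names get proportion 0.
#' @param panel A `panel_spec`.
#' @param config A [sim_config()].
#' @return List with `counts`, `expected` (data frame `strain_id`,
#'   `known_proportion`) and `probe_bias`.
#' @export
simulate_standard_curve <- function(proportions, panel, config) {
  stopifnot(inherits(config, "sim_config"), !is.null(names(proportions)))
  if (abs(sum(proportions) - 1) > 1e-8) {
    stop("`proportions` must sum to 1", call. = FALSE)
  }
  freqs <- setNames(as.list(rep(0, config$n_strains)), config$strain_ids)
  freqs[names(proportions)] <- as.list(unname(proportions))
  bias <- .draw_probe_bias(panel, config)
  set.seed(config$seed + 5L)
  list(
    counts = .simulate_sample_counts(freqs, panel, config, bias, "stdcurve"),
    expected = data.frame(strain_id = names(proportions),
                          known_proportion = unname(proportions),
                          stringsAsFactors = FALSE),
    probe_bias = bias
  )
}

#' Generate a synthetic reference genome, unique SNVs and probe panel
#'
#' Builds a random reference contig with strain-unique SNV sites spaced
#' along it (each strain receiving `probes_per_strain` sites) and runs the
#' real panel-design machinery over them, so simulated experiments exercise
#' the same probe objects as real data. Labelled synthetic: sequences are
#' random, not *C. elegans*.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (`DNAStringSet`), `snvs` (candidate table as
#'   from [find_unique_snvs()]) and `panel` (`panel_spec`).
#' @export
sim_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 6L)
  spacing <- 250L
  n_sites <- config$n_strains * config$probes_per_strain
  contig_len <- (n_sites + 1L) * spacing
  contig <- paste(sample(c("A", "C", "G", "T"), contig_len, replace = TRUE),
                  collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(contig, "chrS"))
  pos <- spacing * seq_len(n_sites)
  ref <- substring(contig, pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                        1L), "", USE.NAMES = FALSE)
  snvs <- data.frame(
    strain_id = rep(config$strain_ids, each = config$probes_per_strain),
    chrom = "chrS",
    pos = pos,
    ref_allele = ref,
    alt_allele = alt,
    stringsAsFactors = FALSE
  )
  panel <- build_panel(snvs, genome,
                       probes_per_strain = config$probes_per_strain,
                       read_length = config$read_length,
                       umi_length = config$umi_length)
  list(genome = genome, snvs = snvs, panel = panel)
}
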