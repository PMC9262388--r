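#' Per-probe strain frequency
#'
#' Frequency of the probe's target strain: alternative reads divided by the
#' total of alternative and reference reads. "Other" allele counts are
#' excluded from the denominator. Records with no REF or ALT reads have no
#' defined frequency and yield `NA` with a warning.
#'
#' @param n_alt Alternative-allele read counts (vector).
#' @param n_ref Reference-allele read counts (vector).
#' @return Numeric vector of proportions in `[0, 1]` (NA where undefined).
#' @export
mip_frequency <- function(n_alt, n_ref) {
  denom <- n_alt + n_ref
  if (any(denom == 0, na.rm = TRUE)) {
    warning("record(s) with no REF or ALT reads: frequency undefined, ",
            "returning NA", call. = FALSE)
  }
  ifelse(denom > 0, n_alt / denom, NA_real_)
}

#' QC thresholds for the equimolar pilot
#'
#' The three published probe filters: observed frequency within `fold_band`
#' of the expected `1/n_strains` (band closed on both sides), combined
#' "other" allele reads below `other_max`, and REF+ALT totals inside
#' `[total_min, total_max]`. The count thresholds are tied to the published
#' sequencing depth; `depth_scale` rescales all three proportionally for
#' shallower runs.
#'
#' @param n_strains Number of strains in the equimolar pool (S).
#' @param fold_band Allowed fold deviation from 1/S (default 3.5).
#' @param other_max Maximum combined OTHER reads (default 20000).
#' @param total_min,total_max Allowed REF+ALT total read range (defaults
#'   20000 and 2000000).
#' @param depth_scale Proportional rescaling of the three count thresholds
#'   (default 1).
#' @return A `qc_thresholds` object.
#' @export
qc_thresholds <- function(n_strains, fold_band = 3.5, other_max = 20000,
                          total_min = 20000, total_max = 2e6,
                          depth_scale = 1) {
  stopifnot(n_strains >= 2, fold_band > 1, total_min < total_max,
            depth_scale > 0)
  structure(list(
    n_strains = as.integer(n_strains),
    fold_band = fold_band,
    other_max = other_max * depth_scale,
    total_min = total_min * depth_scale,
    total_max = total_max * depth_scale
  ), class = "qc_thresholds")
}

#' QC probes against the equimolar pilot
#'
#' Evaluates every record against all three criteria and reports every
#' violated criterion, not just the first. Probes named in `exempt` bypass
#' the filters but stay flagged (mirroring the reference-derived strain
#' whose probes were kept despite failing).
#'
#' @param counts Pilot allele-count records (data frame with `probe_id`,
#'   `n_ref`, `n_alt`, `n_other_a`, `n_other_b`).
#' @param thresholds A [qc_thresholds()] object.
#' @param exempt Character vector of probe ids exempted from filtering.
#' @return Data frame with `probe_id`, `observed_freq`, `pass`,
#'   `fail_reasons` (comma-joined subset of `band`, `other`, `total`) and
#'   `exempt`.
#' @export
qc_probes <- function(counts, thresholds, exempt = character()) {
  stopifnot(inherits(thresholds, "qc_thresholds"), is.data.frame(counts))
  expected <- 1 / thresholds$n_strains
  freq <- suppressWarnings(mip_frequency(counts$n_alt, counts$n_ref))
  total <- counts$n_alt + counts$n_ref
  other <- counts$n_other_a + counts$n_other_b

  band_ok  <- !is.na(freq) &
    freq >= expected / thresholds$fold_band &
    freq <= expected * thresholds$fold_band          # closed band
  other_ok <- other < thresholds$other_max
  total_ok <- total >= thresholds$total_min & total <= thresholds$total_max

  reasons <- mapply(function(b, o, t) {
    paste(c(if (!b) "band", if (!o) "other", if (!t) "total"),
          collapse = ",")
  }, band_ok, other_ok, total_ok)
  is_exempt <- counts$probe_id %in% exempt
  data.frame(
    probe_id      = counts$probe_id,
    observed_freq = freq,
    pass          = reasons == "" | is_exempt,
    fail_reasons  = reasons,
    exempt        = is_exempt,
    stringsAsFactors = FALSE
  )
}

.panel_strain_map <- function(panel) {
  if (inherits(panel, "panel_spec")) {
    tab <- panel_table(panel)
  } else {
    tab <- as.data.frame(panel, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("probe_id", "strain_id") %in% names(tab)))
  tab[, c("probe_id", "strain_id")]
}

#' Estimate per-strain frequencies from probe counts
#'
#' Per sample, a strain's frequency is the unweighted mean of the
#' [mip_frequency()] values of its probes that passed QC (or are exempt).
#' Strains with no usable probe are omitted from the table and listed in
#' the dropout attribute, never imputed.
#'
#' @param counts Allele-count records for one or more samples.
#' @param qc QC table from [qc_probes()]; pass `NULL` to use every probe.
#' @param panel A `panel_spec` (or probe table) mapping probes to strains.
#' @return Data frame `(sample_id, strain_id, frequency, n_probes_used)`
#'   with attribute `dropouts` (character vector of omitted strains).
#' @export
strain_frequencies <- function(counts, qc, panel) {
  if (!is.data.frame(counts) || nrow(counts) == 0L) {
    stop("`counts` must be a nonempty data frame", call. = FALSE)
  }
  map <- .panel_strain_map(panel)
  usable_probes <- if (is.null(qc)) map$probe_id else qc$probe_id[qc$pass]
  df <- merge(counts, map, by = "probe_id")
  df <- df[df$probe_id %in% usable_probes, , drop = FALSE]
  df$frequency <- suppressWarnings(mip_frequency(df$n_alt, df$n_ref))
  df <- df[!is.na(df$frequency), , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("no usable probe records after QC", call. = FALSE)
  }
  agg <- aggregate(frequency ~ sample_id + strain_id, data = df, FUN = mean)
  n <- aggregate(cbind(n_probes_used = frequency) ~ sample_id + strain_id,
                 data = df, FUN = length)
  out <- merge(agg, n, by = c("sample_id", "strain_id"))
  out <- out[order(out$sample_id, out$strain_id), , drop = FALSE]
  rownames(out) <- NULL
  dropouts <- setdiff(unique(map$strain_id), unique(out$strain_id))
  attr(out, "dropouts") <- dropouts
  out
}

#' Evaluate a standard curve of observed vs known proportions
#'
#' Least-squares line of `log10(observed)` on `log10(expected)` across
#' strains mixed at known proportions. Because the curve spans orders of
#' magnitude, the regression is on the log10-log10 scale; zero observed
#' frequencies are floored at half the smallest nonzero observed frequency
#' (with a warning) before logging.
#'
#' @param observed Strain-frequency table for the standard-curve sample
#'   (columns `strain_id`, `frequency`).
#' @param expected Data frame `(strain_id, known_proportion)` with strictly
#'   positive proportions for at least 3 strains.
#' @return List with `r_squared`, `slope`, `intercept` and a `residuals`
#'   data frame (per-strain expected, observed, residual on log10 scale).
#' @export
standard_curve_eval <- function(observed, expected) {
  stopifnot(is.data.frame(observed), is.data.frame(expected),
            all(c("strain_id", "frequency") %in% names(observed)),
            all(c("strain_id", "known_proportion") %in% names(expected)))
  df <- merge(observed[, c("strain_id", "frequency")], expected,
              by = "strain_id")
  df <- df[df$known_proportion > 0, , drop = FALSE]
  if (nrow(df) < 3L) {
    stop("need at least 3 strains with positive expected proportions",
         call. = FALSE)
  }
  if (any(df$frequency == 0)) {
    floor_val <- min(df$frequency[df$frequency > 0]) / 2
    warning("zero observed frequencies floored at ", signif(floor_val, 3),
            call. = FALSE)
    df$frequency[df$frequency == 0] <- floor_val
  }
  fit <- lm(log10(frequency) ~ log10(known_proportion), data = df)
  list(
    r_squared = summary(fit)$r.squared,
    slope     = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    residuals = data.frame(
      strain_id = df$strain_id,
      known_proportion = df$known_proportion,
      observed = df$frequency,
      residual = unname(resid(fit)),
      stringsAsFactors = FALSE
    )
  )
}
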