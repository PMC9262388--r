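#' Normalize time-course frequencies to the replicate baseline
#'
#' Converts strain frequencies into log2 ratios against each replicate's
#' baseline sample: `y = log2(f(day) / f(baseline))`. The baseline is an
#' aliquot taken on day 1 of starvation before recovery, so every replicate
#' must map exactly one sample with `is_baseline = TRUE`. Strain-replicates
#' with a zero or missing baseline frequency, or a zero frequency at a
#' timepoint, are masked with a recorded reason rather than propagated as
#' infinities.
#'
#' @param freq Strain-frequency table (`sample_id`, `strain_id`,
#'   `frequency`) from [strain_frequencies()].
#' @param sample_map Data frame `(sample_id, replicate, day, is_baseline)`.
#' @return A `trajectory_set`: list with `y` (data frame `replicate`,
#'   `strain_id`, `day`, `y`), `masked` (with `reason`), `baseline_day`
#'   and `timepoints`.
#' @export
normalize_to_baseline <- function(freq, sample_map) {
  stopifnot(is.data.frame(freq), is.data.frame(sample_map),
            all(c("sample_id", "strain_id", "frequency") %in% names(freq)),
            all(c("sample_id", "replicate", "day", "is_baseline") %in%
                  names(sample_map)))
  base_map <- sample_map[as.logical(sample_map$is_baseline), , drop = FALSE]
  per_rep <- table(base_map$replicate)
  reps <- unique(sample_map$replicate)
  if (!setequal(names(per_rep), as.character(reps)) || any(per_rep != 1L)) {
    stop("each replicate must have exactly one baseline sample", call. = FALSE)
  }
  df <- merge(freq, sample_map, by = "sample_id")
  base <- merge(
    base_map[, c("sample_id", "replicate")],
    freq[, c("sample_id", "strain_id", "frequency")],
    by = "sample_id"
  )
  names(base)[names(base) == "frequency"] <- "baseline_frequency"
  day_df <- df[!as.logical(df$is_baseline), , drop = FALSE]
  day_df <- merge(day_df, base[, c("replicate", "strain_id",
                                   "baseline_frequency")],
                  by = c("replicate", "strain_id"), all.x = TRUE)

  reason <- rep(NA_character_, nrow(day_df))
  reason[is.na(day_df$baseline_frequency)] <- "missing_baseline"
  reason[!is.na(day_df$baseline_frequency) &
           day_df$baseline_frequency == 0] <- "zero_baseline"
  reason[is.na(reason) & day_df$frequency == 0] <- "zero_frequency"
  ok <- is.na(reason)

  y <- day_df[ok, c("replicate", "strain_id", "day"), drop = FALSE]
  y$y <- log2(day_df$frequency[ok] / day_df$baseline_frequency[ok])
  y <- y[order(y$replicate, y$strain_id, y$day), , drop = FALSE]
  rownames(y) <- NULL
  masked <- day_df[!ok, c("replicate", "strain_id", "day"), drop = FALSE]
  masked$reason <- reason[!ok]
  rownames(masked) <- NULL
  structure(list(
    y = y,
    masked = masked,
    baseline_day = unique(base_map$day)[1L],
    timepoints = sort(unique(day_df$day))
  ), class = "trajectory_set")
}

.replicate_means <- function(traj, days) {
  df <- traj$y[traj$y$day %in% days, , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(strain_id = character(), day = numeric(),
                      y = numeric(), n_reps = integer()))
  }
  m <- aggregate(y ~ strain_id + day, data = df, FUN = mean)
  n <- aggregate(cbind(n_reps = y) ~ strain_id + day, data = df,
                 FUN = length)
  merge(m, n, by = c("strain_id", "day"))
}

#' Slope starvation-resistance trait
#'
#' Replicate-averaged log2 baseline-normalized frequencies over the fitted
#' days are regressed on day with the intercept fixed at zero, so
#' `slope = sum(t * ybar(t)) / sum(t^2)`. The zero intercept reflects the
#' baseline normalization: a trajectory starts at a log2 ratio of ~0. A
#' positive slope means the strain gains frequency during starvation
#' (starvation-resistant). Strains with fewer than two usable days get a
#' missing trait value.
#'
#' @param traj A `trajectory_set` from [normalize_to_baseline()].
#' @param fit_days Days entering the fit (default `c(1, 9, 13)`).
#' @param per_replicate If `TRUE`, fit each replicate separately and average
#'   the per-replicate slopes (sensitivity mode); default is to average
#'   replicates before fitting.
#' @return Data frame `(strain_id, slope, n_days_used, n_replicates_used)`.
#' @export
slope_trait <- function(traj, fit_days = c(1, 9, 13),
                        per_replicate = FALSE) {
  stopifnot(inherits(traj, "trajectory_set"))
  zero_slope <- function(t, y) sum(t * y) / sum(t^2)
  df <- traj$y[traj$y$day %in% fit_days, , drop = FALSE]
  strains <- sort(unique(traj$y$strain_id))
  out <- lapply(strains, function(s) {
    d <- df[df$strain_id == s, , drop = FALSE]
    n_reps <- length(unique(d$replicate))
    if (per_replicate) {
      sl <- vapply(split(d, d$replicate), function(r) {
        if (length(unique(r$day)) < 2L) return(NA_real_)
        zero_slope(r$day, r$y)
      }, 0)
      sl <- sl[!is.na(sl)]
      slope <- if (length(sl)) mean(sl) else NA_real_
      n_days <- length(unique(d$day))
    } else {
      m <- aggregate(y ~ day, data = d, FUN = mean)
      n_days <- nrow(m)
      slope <- if (n_days >= 2L) zero_slope(m$day, m$y) else NA_real_
    }
    data.frame(strain_id = s, slope = slope, n_days_used = n_days,
               n_replicates_used = n_reps, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (any(is.na(res$slope))) {
    attr(res, "missing") <- res$strain_id[is.na(res$slope)]
  }
  res
}

.strain_day_matrix <- function(traj, days) {
  m <- .replicate_means(traj, days)
  if (nrow(m) == 0L) stop("no trajectory data for the requested days",
                          call. = FALSE)
  mat <- matrix(NA_real_, nrow = length(unique(m$strain_id)),
                ncol = length(days),
                dimnames = list(sort(unique(m$strain_id)), days))
  mat[cbind(m$strain_id, as.character(m$day))] <- m$y
  mat
}

#' PC1 starvation-resistance trait
#'
#' Strain-level PCA: replicates are averaged to a strain x day matrix of
#' log2 baseline-normalized frequencies, columns are mean-centered (no
#' variance scaling by default), and each strain's score on the first
#' principal component is the trait. The component sign is arbitrary from
#' the decomposition and is oriented so that PC1 correlates positively with
#' the Slope trait, making resistant strains score consistently. Strains
#' with any missing fitted day are dropped from the PCA (complete-case) and
#' reported. Replicate-level scores (samples as rows, strains as variables)
#' are returned for diagnostics: their first component tracks duration of
#' starvation.
#'
#' @param traj A `trajectory_set`.
#' @param days Days entering the PCA (default `c(1, 9, 13, 17)`).
#' @param center,scale. Column centering/scaling passed to [stats::prcomp()]
#'   (defaults `TRUE` / `FALSE`).
#' @return List with `traits` (`strain_id`, `pc1`), `replicate_scores`
#'   (`replicate`, `day`, `score`), `dropped_strains` and `var_explained`.
#' @export
pc1_trait <- function(traj, days = c(1, 9, 13, 17), center = TRUE,
                      scale. = FALSE) {
  stopifnot(inherits(traj, "trajectory_set"))
  mat <- .strain_day_matrix(traj, days)
  complete <- rowSums(is.na(mat)) == 0L
  dropped <- rownames(mat)[!complete]
  mat <- mat[complete, , drop = FALSE]
  if (nrow(mat) < 2L) {
    stop("fewer than 2 strains with complete trajectories; PCA is degenerate",
         call. = FALSE)
  }
  pca <- prcomp(mat, center = center, scale. = scale.)
  pc1 <- pca$x[, 1L]

  # orient: resistant strains (positive Slope) score positive
  sl <- slope_trait(traj)
  sl <- setNames(sl$slope, sl$strain_id)[names(pc1)]
  if (sum(!is.na(sl)) >= 3L && sd(sl, na.rm = TRUE) > 0 && sd(pc1) > 0) {
    r <- cor(pc1, sl, use = "complete.obs")
    if (!is.na(r) && r < 0) pc1 <- -pc1
  }

  # replicate-level diagnostics: samples x strains
  yy <- traj$y[traj$y$day %in% days &
                 traj$y$strain_id %in% rownames(mat), , drop = FALSE]
  yy$sample <- paste(yy$replicate, yy$day, sep = "\r")
  smat <- matrix(NA_real_, nrow = length(unique(yy$sample)),
                 ncol = nrow(mat),
                 dimnames = list(sort(unique(yy$sample)), rownames(mat)))
  smat[cbind(yy$sample, yy$strain_id)] <- yy$y
  keep_col <- colSums(is.na(smat)) == 0L
  rep_scores <- NULL
  if (sum(keep_col) >= 2L && nrow(smat) >= 2L) {
    rpca <- prcomp(smat[, keep_col, drop = FALSE], center = center,
                   scale. = scale.)
    parts <- strsplit(rownames(smat), "\r", fixed = TRUE)
    rep_scores <- data.frame(
      replicate = vapply(parts, `[`, "", 1L),
      day = as.numeric(vapply(parts, `[`, "", 2L)),
      score = unname(rpca$x[, 1L]),
      stringsAsFactors = FALSE
    )
  }
  list(
    traits = data.frame(strain_id = names(pc1), pc1 = unname(pc1),
                        stringsAsFactors = FALSE),
    replicate_scores = rep_scores,
    dropped_strains = dropped,
    var_explained = unname(pca$sdev^2 / sum(pca$sdev^2))[1L]
  )
}

#' Combine Slope and PC1 into a mapping-ready trait table
#'
#' @param slope Data frame from [slope_trait()].
#' @param pc1 Result of [pc1_trait()] (or its `traits` data frame).
#' @return Data frame `(strain_id, slope, pc1, n_replicates_used)`, one row
#'   per strain; missing traits are `NA`.
#' @export
trait_table <- function(slope, pc1) {
  if (is.list(pc1) && !is.data.frame(pc1)) pc1 <- pc1$traits
  out <- merge(slope[, c("strain_id", "slope", "n_replicates_used")],
               pc1, by = "strain_id", all = TRUE)
  out <- out[order(out$strain_id),
             c("strain_id", "slope", "pc1", "n_replicates_used")]
  rownames(out) <- NULL
  out
}

#' Export trait values for external association mapping
#'
#' Writes a TSV with strain identifiers and one column per trait; missing
#' trait values become empty cells (not zeros).
#'
#' @param traits Trait table from [trait_table()] (nonempty).
#' @param path Output TSV path.
#' @return Invisibly, the table written.
#' @export
export_traits <- function(traits, path) {
  if (!is.data.frame(traits) || nrow(traits) == 0L) {
    stop("`traits` must be a nonempty data frame", call. = FALSE)
  }
  ok <- tryCatch({
    write.table(traits, path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    TRUE
  }, error = function(e) {
    stop("failed to write traits to '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(traits)
}
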