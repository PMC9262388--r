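#' Fit a logistic curve to starvation survival data
#'
#' Nonlinear least squares of `p(t) = A / (1 + exp(rate * (t - t50)))` to
#' the fraction of worms alive over days of L1 arrest. By default the upper
#' asymptote `A` is fixed at 1 (survival starts at ~100%); set
#' `fix_asymptote = FALSE` for degraded day-1 viability. The half-life
#' `t50` is the day at which the fitted curve equals `A / 2`. Series that
#' never cross 0.5 are still fitted but flagged as extrapolated so that
#' replicate-level t-tests keep a value.
#'
#' @param series Data frame with `day` and `alive_fraction` (or `alive` and
#'   `plated`, from which the fraction is computed).
#' @param fix_asymptote Fix `A = 1` (default `TRUE`).
#' @return A `survival_fit`: list with `t50`, `rate`, `asymptote`, `rss`,
#'   `extrapolated` and the underlying `nls` fit.
#' @export
fit_survival <- function(series, fix_asymptote = TRUE) {
  stopifnot(is.data.frame(series), "day" %in% names(series))
  if (!"alive_fraction" %in% names(series)) {
    stopifnot(all(c("alive", "plated") %in% names(series)))
    series$alive_fraction <- series$alive / series$plated
  }
  series <- series[order(series$day), , drop = FALSE]
  if (nrow(series) < 3L) stop("need at least 3 survival points", call. = FALSE)
  if (any(series$alive_fraction < 0 | series$alive_fraction > 1)) {
    stop("alive_fraction must be in [0, 1]", call. = FALSE)
  }
  crosses <- any(series$alive_fraction >= 0.5) &&
    any(series$alive_fraction <= 0.5)
  if (!crosses) {
    warning("survival series never crosses 0.5; t50 is extrapolated",
            call. = FALSE)
  }
  # starting values: t50 where the series straddles 0.5, moderate rate
  t50_0 <- tryCatch(
    stats::approx(series$alive_fraction, series$day, xout = 0.5,
                  ties = mean)$y,
    error = function(e) NA_real_
  )
  if (is.na(t50_0)) t50_0 <- mean(range(series$day))
  start <- if (fix_asymptote) list(rate = 0.5, t50 = t50_0)
           else list(A = max(series$alive_fraction), rate = 0.5, t50 = t50_0)
  form <- if (fix_asymptote) {
    alive_fraction ~ 1 / (1 + exp(rate * (day - t50)))
  } else {
    alive_fraction ~ A / (1 + exp(rate * (day - t50)))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = series, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("logistic survival fit failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  cf <- coef(fit)
  structure(list(
    t50 = unname(cf[["t50"]]),
    rate = unname(cf[["rate"]]),
    asymptote = if (fix_asymptote) 1 else unname(cf[["A"]]),
    rss = sum(resid(fit)^2),
    extrapolated = !crosses,
    fit = fit
  ), class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("logistic survival fit: t50 = %.2f d, rate = %.3f /d%s\n",
              x$t50, x$rate,
              if (x$extrapolated) " (extrapolated)" else ""))
  invisible(x)
}

#' Compare starvation half-lives between two strains
#'
#' Welch two-sample t-test on per-replicate half-lives.
#'
#' @param fits_a,fits_b Lists of `survival_fit` objects (or numeric vectors
#'   of t50 values), one element per biological replicate.
#' @return List with `t`, `df`, `p`, and per-group means. With fewer than 2
#'   replicates in either group a degenerate-test warning is raised and the
#'   statistics are `NA`.
#' @export
compare_half_lives <- function(fits_a, fits_b) {
  get_t50 <- function(f) {
    if (is.numeric(f)) return(f)
    vapply(f, function(x) {
      if (inherits(x, "survival_fit")) x$t50 else as.numeric(x)
    }, 0)
  }
  a <- get_t50(fits_a)
  b <- get_t50(fits_b)
  if (length(a) < 2L || length(b) < 2L) {
    warning("fewer than 2 replicate half-lives per group; test degenerate",
            call. = FALSE)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_a = mean(a), mean_b = mean(b))
}

# Power of the two-sided two-sample t-test at standardized effect d,
# n per group: noncentral-t tail probabilities.
.t_power <- function(d, n, sig_level) {
  df <- 2 * (n - 1)
  ncp <- d * sqrt(n / 2)
  tcrit <- qt(1 - sig_level / 2, df)
  pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    pt(-tcrit, df, ncp = ncp, lower.tail = TRUE)
}

#' Smallest detectable difference from a power specification
#'
#' Inverts the two-sample t-test power relation: finds the standardized
#' effect size `d` at which a two-sided test with `n_per_group` per group
#' and level `sig_level` reaches the requested power (numerical root of the
#' noncentral-t power function), then scales it by the control-group
#' standard deviation to an outcome-scale difference. With the published
#' parameters (n = 5, sig.level = 0.05, power = 0.5, two-sample) `d` is
#' about 1.46, so the detectable difference is about 1.5 control SDs.
#'
#' @param n_per_group Replicates per group (>= 2).
#' @param sig_level Two-sided significance level (default 0.05).
#' @param power Target power (default 0.5).
#' @param sd_control Standard deviation of the control outcome (same units
#'   as the outcome; default 1 returns `d` itself).
#' @return List with `d` (standardized) and `difference`
#'   (`d * sd_control`, outcome units).
#' @export
detectable_effect <- function(n_per_group, sig_level = 0.05, power = 0.5,
                              sd_control = 1) {
  stopifnot(n_per_group >= 2, sig_level > 0, sig_level < 1,
            power > 0, power < 1, sd_control > 0)
  if (power <= sig_level) {
    stop("requested power must exceed the significance level", call. = FALSE)
  }
  f <- function(d) .t_power(d, n_per_group, sig_level) - power
  if (f(10) < 0) stop("no solution for d in (0, 10]", call. = FALSE)
  d <- uniroot(f, interval = c(1e-8, 10), tol = 1e-10)$root
  list(d = d, difference = d * sd_control)
}

#' Difference-in-differences of worm length across starvation durations
#'
#' The interaction effect size between strain and duration of starvation:
#' `dd = [mean(A, late) - mean(A, early)] - [mean(B, late) - mean(B, early)]`
#' where A is the first strain. Positive values mean strain A is less
#' affected by extended starvation than strain B. Invariant to adding a
#' constant to all lengths; swapping the strain labels flips the sign.
#'
#' @param lengths Data frame `(strain, day, worm_length)` with exactly two
#'   strains and two days.
#' @param strain_order Optional length-2 character vector fixing which
#'   strain is A; defaults to order of first appearance.
#' @return The interaction effect size in the units of `worm_length`.
#' @export
delta_delta <- function(lengths, strain_order = NULL) {
  stopifnot(is.data.frame(lengths),
            all(c("strain", "day", "worm_length") %in% names(lengths)))
  strains <- strain_order %||% unique(as.character(lengths$strain))
  days <- sort(unique(lengths$day))
  if (length(strains) != 2L || length(days) != 2L) {
    stop("`lengths` must contain exactly two strains and two days",
         call. = FALSE)
  }
  cell_mean <- function(s, d) {
    v <- lengths$worm_length[lengths$strain == s & lengths$day == d]
    if (length(v) == 0L) {
      stop("missing cell: strain ", s, ", day ", d, call. = FALSE)
    }
    mean(v)
  }
  early <- days[1L]; late <- days[2L]
  (cell_mean(strains[1L], late) - cell_mean(strains[1L], early)) -
    (cell_mean(strains[2L], late) - cell_mean(strains[2L], early))
}
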