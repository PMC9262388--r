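make_freq_fixture <- function() {
  # one replicate, baseline + two days, two strains with known ratios
  freq <- rbind(
    data.frame(sample_id = "b1", strain_id = c("sA", "sB"),
               frequency = c(0.10, 0.20)),
    data.frame(sample_id = "d1", strain_id = c("sA", "sB"),
               frequency = c(0.10, 0.40)),
    data.frame(sample_id = "d9", strain_id = c("sA", "sB"),
               frequency = c(0.05, 0.20))
  )
  smap <- data.frame(
    sample_id = c("b1", "d1", "d9"),
    replicate = "r1",
    day = c(1, 1, 9),
    is_baseline = c(TRUE, FALSE, FALSE)
  )
  list(freq = freq, smap = smap)
}

test_that("normalize_to_baseline computes log2 ratios against the baseline", {
  fx <- make_freq_fixture()
  traj <- normalize_to_baseline(fx$freq, fx$smap)
  y <- traj$y
  expect_equal(y$y[y$strain_id == "sA" & y$day == 1], 0)      # f = f_base
  expect_equal(y$y[y$strain_id == "sB" & y$day == 1], 1)      # f = 2 f_base
  expect_equal(y$y[y$strain_id == "sA" & y$day == 9], -1)
  expect_equal(y$y[y$strain_id == "sB" & y$day == 9], 0)
})

test_that("zero baselines and zero frequencies are masked with reasons", {
  fx <- make_freq_fixture()
  fx$freq$frequency[fx$freq$sample_id == "b1" &
                      fx$freq$strain_id == "sA"] <- 0
  fx$freq$frequency[fx$freq$sample_id == "d9" &
                      fx$freq$strain_id == "sB"] <- 0
  traj <- normalize_to_baseline(fx$freq, fx$smap)
  expect_equal(nrow(traj$y), 1L)                      # only sB day 1 usable
  expect_setequal(traj$masked$reason[traj$masked$strain_id == "sA"],
                  "zero_baseline")
  expect_equal(traj$masked$reason[traj$masked$strain_id == "sB"],
               "zero_frequency")
  expect_true(all(is.finite(traj$y$y)))
})

test_that("a replicate without exactly one baseline is a configuration error", {
  fx <- make_freq_fixture()
  bad <- fx$smap
  bad$is_baseline <- FALSE
  expect_error(normalize_to_baseline(fx$freq, bad), "baseline")
  two <- rbind(fx$smap, data.frame(sample_id = "b2", replicate = "r1",
                                   day = 1, is_baseline = TRUE))
  expect_error(normalize_to_baseline(fx$freq, two), "baseline")
})

test_that("replicates with different baselines but shared fitness agree", {
  cfg <- sim_config(n_strains = 12, replicates = 3,
                    baseline_concentration = 30,  # strong baseline scatter
                    probe_depth_mean = 2e4, seed = 9)
  panel <- sim_reference_panel(cfg)$panel
  truth <- simulate_trajectories(cfg)
  sim <- simulate_reads(truth, panel)
  freqs <- strain_frequencies(sim$counts, NULL, panel)
  traj <- normalize_to_baseline(freqs, sim$sample_map)
  # normalization removes the replicate-specific composition: per-strain
  # trajectories from different replicates agree closely at late days
  y13 <- traj$y[traj$y$day == 13, ]
  spread <- tapply(y13$y, y13$strain_id, function(v) diff(range(v)))
  signal <- diff(range(tapply(y13$y, y13$strain_id, mean)))
  expect_lt(max(spread), signal / 2)
})

test_that("slope_trait implements the zero-intercept least-squares line", {
  mk_traj <- function(days, y_by_strain) {
    y <- do.call(rbind, lapply(names(y_by_strain), function(s) {
      data.frame(replicate = "r1", strain_id = s, day = days,
                 y = y_by_strain[[s]], stringsAsFactors = FALSE)
    }))
    structure(list(y = y, masked = y[0, ], baseline_day = 1,
                   timepoints = days), class = "trajectory_set")
  }
  days <- c(1, 9, 13)
  traj <- mk_traj(days, list(null = c(0, 0, 0),
                             prop = 0.1 * days,
                             gen = c(0.2, 0.7, 1.5)))
  sl <- slope_trait(traj)
  expect_equal(sl$slope[sl$strain_id == "null"], 0)
  expect_equal(sl$slope[sl$strain_id == "prop"], 0.1)
  expect_equal(sl$slope[sl$strain_id == "gen"], 26.0 / 251)
  # independent oracle: lm with suppressed intercept
  fit <- lm(c(0.2, 0.7, 1.5) ~ 0 + days)
  expect_equal(sl$slope[sl$strain_id == "gen"], unname(coef(fit)[1]))
  # linearity: slope(a*y) = a*slope(y)
  traj3 <- mk_traj(days, list(gen = 3 * c(0.2, 0.7, 1.5)))
  expect_equal(slope_trait(traj3)$slope, 3 * 26.0 / 251)
  # fewer than two usable days: missing trait, reported
  traj1 <- mk_traj(1, list(gen = 0.5))
  s1 <- slope_trait(traj1)
  expect_true(is.na(s1$slope))
  expect_equal(attr(s1, "missing"), "gen")
})

test_that("pc1_trait matches a direct eigendecomposition oracle", {
  set.seed(5)
  strains <- paste0("s", 1:4)
  days <- c(1, 9, 13, 17)
  vals <- matrix(rnorm(16), 4, 4, dimnames = list(strains, days))
  y <- expand.grid(strain_id = strains, day = days,
                   stringsAsFactors = FALSE)
  y$replicate <- "r1"
  y$y <- vals[cbind(y$strain_id, as.character(y$day))]
  traj <- structure(list(y = y, masked = y[0, ], baseline_day = 1,
                         timepoints = days), class = "trajectory_set")
  res <- pc1_trait(traj)
  # oracle: eigenvector of the centered covariance, scores by projection
  xc <- scale(vals, center = TRUE, scale = FALSE)
  ev <- eigen(t(xc) %*% xc)$vectors[, 1]
  scores <- unname(drop(xc %*% ev))
  got <- res$traits$pc1[match(strains, res$traits$strain_id)]
  expect_equal(abs(got), abs(scores), tolerance = 1e-8)
  expect_equal(abs(cor(got, scores)), 1)
})

test_that("pc1 of a rank-1 trajectory matrix is proportional to the strain factor", {
  strains <- paste0("s", 1:5)
  days <- c(1, 9, 13, 17)
  a <- c(2, 1, 0, -1, -2)
  b <- c(0.1, 0.9, 1.3, 1.1)
  y <- expand.grid(strain_id = strains, day = days,
                   stringsAsFactors = FALSE)
  y$replicate <- "r1"
  y$y <- a[match(y$strain_id, strains)] * b[match(y$day, days)]
  traj <- structure(list(y = y, masked = y[0, ], baseline_day = 1,
                         timepoints = days), class = "trajectory_set")
  res <- pc1_trait(traj)
  got <- res$traits$pc1[match(strains, res$traits$strain_id)]
  expect_equal(abs(cor(got, a)), 1, tolerance = 1e-10)
  expect_equal(res$var_explained, 1, tolerance = 1e-10)
})

test_that("pc1 is oriented to correlate positively with Slope", {
  cfg <- sim_config(n_strains = 15, replicates = 3, probe_depth_mean = 5000,
                    seed = 33)
  panel <- sim_reference_panel(cfg)$panel
  sim <- simulate_reads(simulate_trajectories(cfg), panel)
  freqs <- strain_frequencies(sim$counts, NULL, panel)
  traj <- normalize_to_baseline(freqs, sim$sample_map)
  tt <- trait_table(slope_trait(traj), pc1_trait(traj))
  expect_gt(cor(tt$slope, tt$pc1, use = "complete.obs"), 0)
})

test_that("replicate-level first component tracks duration of starvation", {
  cfg <- sim_config(n_strains = 30, replicates = 5, probe_depth_mean = 5000,
                    seed = 14)
  panel <- sim_reference_panel(cfg)$panel
  sim <- simulate_reads(simulate_trajectories(cfg), panel)
  freqs <- strain_frequencies(sim$counts, NULL, panel)
  traj <- normalize_to_baseline(freqs, sim$sample_map)
  res <- pc1_trait(traj)
  expect_gt(abs(cor(res$replicate_scores$score, res$replicate_scores$day)),
            0.8)
})

test_that("strains with incomplete trajectories are dropped from PC1 only", {
  fx <- make_freq_fixture()
  # sB has no day-9 value
  fx$freq <- fx$freq[!(fx$freq$sample_id == "d9" &
                         fx$freq$strain_id == "sB"), ]
  traj <- normalize_to_baseline(fx$freq, fx$smap)
  expect_error(pc1_trait(traj, days = c(1, 9)), "degenerate")
  sl <- slope_trait(traj, fit_days = c(1, 9))
  expect_false(is.na(sl$slope[sl$strain_id == "sA"]))
})

test_that("export_traits writes missing values as empty cells and round-trips", {
  traits <- data.frame(strain_id = c("s1", "s2", "s3"),
                       slope = c(0.1, NA, -0.2),
                       pc1 = c(1.5, 0.3, NA),
                       n_replicates_used = c(5L, 5L, 4L),
                       stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  export_traits(traits, path)
  lines <- readLines(path)
  expect_equal(length(lines), 4L)                    # header + 3 rows
  expect_match(lines[3], "^s2\t\t0\\.3\t5$")         # NA -> empty cell
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back, traits)
  expect_error(export_traits(traits[0, ], tempfile()), "nonempty")
})
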