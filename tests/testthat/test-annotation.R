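# Exhaustive hypergeometric oracle: enumerate all C(N, n) draws.
enum_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2L, function(d) sum(d <= K) >= k))
}

make_universe <- function(N, K, n, k) {
  genes <- paste0("g", seq_len(N))
  bg <- rbind(
    data.frame(gene_id = genes[seq_len(K)], category = "dom",
               stringsAsFactors = FALSE),
    data.frame(gene_id = genes, category = "all",
               stringsAsFactors = FALSE)   # keeps every gene in the universe
  )
  hits <- c(genes[seq_len(k)],
            if (n > k) genes[(K + 1):(K + n - k)])
  list(background = bg, hits = hits)
}

test_that("hypergeometric p equals exhaustive enumeration for all N <= 12", {
  grid <- expand.grid(N = c(6L, 9L, 12L), K = c(2L, 4L), n = c(3L, 5L),
                      k = 1:3)
  grid <- grid[grid$k <= grid$K & grid$k <= grid$n &
                 grid$n - grid$k <= grid$N - grid$K, ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    u <- make_universe(g$N, g$K, g$n, g$k)
    res <- hypergeom_enrichment(u$background, u$hits, min_hit_count = 1L)
    expect_equal(res$p[res$category == "dom"],
                 enum_hyper_p(g$N, g$K, g$n, g$k),
                 tolerance = 1e-12,
                 info = paste("N,K,n,k =", g$N, g$K, g$n, g$k))
  }
})

test_that("worked hypergeometric example: N=10, K=5, n=4, k=4", {
  u <- make_universe(10L, 5L, 4L, 4L)
  res <- hypergeom_enrichment(u$background, u$hits, min_hit_count = 1L)
  expect_equal(res$p[res$category == "dom"], 5 / 210)
  expect_equal(res$k_hit[res$category == "dom"], 4L)
  expect_equal(res$fold[res$category == "dom"], (4 / 4) / (5 / 10))
})

test_that("Bonferroni threshold divides alpha by categories in the hit set", {
  genes <- paste0("g", 1:300)
  set.seed(8)
  bg <- data.frame(
    gene_id = rep(genes, each = 2),
    category = c(rbind(sample(paste0("dom", 1:102), 300, replace = TRUE),
                       "shared")),
    stringsAsFactors = FALSE
  )
  hits <- unique(bg$gene_id[bg$category != "shared"])
  res <- hypergeom_enrichment(bg, hits, alpha = 0.05)
  n_cats <- length(unique(res$category))
  expect_equal(res$alpha_bonferroni[1] * n_cats, 0.05)
  if (n_cats == 103) {  # 102 domains + "shared"
    expect_equal(signif(0.05 / 103, 2), attr(res, "threshold_2sf"))
  }
  # the published count: 102 categories at alpha 0.05
  expect_equal(signif(0.05 / 102, 2), 0.00049)
})

test_that("saturated draws and monotonicity behave as required", {
  # hits = entire background: every category has fold 1 and p = 1
  bg <- data.frame(gene_id = paste0("g", 1:8),
                   category = rep(c("c1", "c2"), 4),
                   stringsAsFactors = FALSE)
  res <- hypergeom_enrichment(bg, paste0("g", 1:8), min_hit_count = 1L)
  expect_true(all(res$fold == 1))
  expect_true(all(res$p == 1))
  # p non-increasing in k for fixed (N, K, n)
  p_at <- vapply(1:4, function(k) {
    u <- make_universe(12L, 6L, 4L, k)
    r <- hypergeom_enrichment(u$background, u$hits, min_hit_count = 1L)
    r$p[r$category == "dom"]
  }, 0)
  expect_true(all(diff(p_at) < 0))
})

test_that("low-count categories are flagged and stray hits intersected", {
  bg <- data.frame(gene_id = paste0("g", 1:40),
                   category = rep(c("rare", "common"), c(4, 36)),
                   stringsAsFactors = FALSE)
  expect_warning(
    res <- hypergeom_enrichment(bg, c(paste0("g", 1:10), "absent_gene"),
                                min_hit_count = 5L),
    "absent"
  )
  expect_true(res$filtered_low_count[res$category == "rare"])
  expect_false(res$significant[res$category == "rare"])
  expect_equal(res$n_hit[1], 10L)   # stray hit removed
})

test_that("hyper-divergent calls use half-open >= 1 base overlap", {
  regions <- data.frame(
    strain_id = c("inside", "touch_left", "one_base", "far", "multi",
                  "multi"),
    chrom = "V",
    start = c(90L, 50L, 199L, 500L, 700L, 120L),
    end   = c(210L, 100L, 300L, 600L, 800L, 121L),
    stringsAsFactors = FALSE
  )
  locus <- list(chrom = "V", start = 100L, end = 200L)
  calls <- classify_hyperdivergent(regions, locus)
  got <- setNames(calls$hyperdivergent, calls$strain_id)
  expect_true(got[["inside"]])       # locus fully inside the region
  expect_false(got[["touch_left"]])  # ends exactly where locus begins
  expect_true(got[["one_base"]])     # single-base overlap counts
  expect_false(got[["far"]])
  expect_true(got[["multi"]])        # any region suffices
  # brute-force base-set oracle, row by row
  for (i in seq_len(nrow(regions))) {
    bases_region <- seq(regions$start[i], regions$end[i] - 1L)
    bases_locus <- seq(locus$start, locus$end - 1L)
    single <- regions[i, ]
    single$strain_id <- "only"
    expect_equal(
      classify_hyperdivergent(single, locus)$hyperdivergent,
      length(intersect(bases_region, bases_locus)) > 0
    )
  }
  expect_error(
    classify_hyperdivergent(data.frame(strain_id = "x", chrom = "V",
                                       start = 10L, end = 10L), locus),
    "malformed"
  )
})

test_that("region/locus roles are symmetric for overlap", {
  set.seed(12)
  for (i in 1:20) {
    a <- sort(sample(1:50, 2)); b <- sort(sample(1:50, 2))
    if (a[1] == a[2]) a[2] <- a[2] + 1L
    if (b[1] == b[2]) b[2] <- b[2] + 1L
    as_region <- classify_hyperdivergent(
      data.frame(strain_id = "s", chrom = "c", start = a[1], end = a[2]),
      list(chrom = "c", start = b[1], end = b[2]))$hyperdivergent
    swapped <- classify_hyperdivergent(
      data.frame(strain_id = "s", chrom = "c", start = b[1], end = b[2]),
      list(chrom = "c", start = a[1], end = a[2]))$hyperdivergent
    expect_equal(as_region, swapped)
  }
})

test_that("split_trait_by_group computes a Welch t-test", {
  # identical groups: t = 0, p = 1
  traits <- data.frame(strain_id = paste0("s", 1:6),
                       slope = c(1, 2, 3, 1, 2, 3))
  groups <- data.frame(strain_id = paste0("s", 1:6),
                       group = rep(c("div", "nondiv"), each = 3))
  res <- split_trait_by_group(traits, groups)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # hand-computed Welch statistic on a fixture
  x <- c(0.12, 0.35, -0.1, 0.4); y <- c(-0.3, -0.05, -0.42)
  traits2 <- data.frame(strain_id = paste0("s", 1:7), slope = c(x, y))
  groups2 <- data.frame(strain_id = paste0("s", 1:7),
                        group = rep(c("a", "b"), c(4, 3)))
  res2 <- split_trait_by_group(traits2, groups2)
  se2 <- var(x) / 4 + var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(res2$t, t_hand, tolerance = 1e-6)
  expect_equal(res2$p, p_hand, tolerance = 1e-6)
  # clearly separated groups
  traits3 <- data.frame(strain_id = paste0("s", 1:6),
                        slope = c(0, 0.001, -0.001, 1, 1.001, 0.999))
  res3 <- split_trait_by_group(traits3, groups)
  expect_lt(res3$p, 1e-4)
  expect_equal(abs(diff(res3$summary$mean)), 1, tolerance = 0.01)
  # degenerate group
  expect_warning(
    res4 <- split_trait_by_group(traits2[c(1, 5, 6), ],
                                 groups2[c(1, 5, 6), ]),
    "degenerate")
  expect_true(is.na(res4$p))
})
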