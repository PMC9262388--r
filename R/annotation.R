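#' Hypergeometric enrichment of annotation categories among candidate genes
#'
#' For each category present among the hit genes, the upper-tail probability
#' `P(X >= k)` under the hypergeometric law with population `N_bg` (unique
#' background genes), `K_bg` category members in the background, and `n_hit`
#' draws. A gene counts at most once per category even if it carries the
#' domain several times. The Bonferroni threshold divides `alpha` by the
#' number of categories observed in the hit set (for the published 102
#' domains at alpha 0.05 this is 0.00049 to two significant figures).
#' Categories occurring fewer than `min_hit_count` times among hit genes are
#' flagged and excluded from significance calls.
#'
#' @param background Data frame `(gene_id, category)`: the genome-wide
#'   category assignments.
#' @param hits Character vector of candidate gene ids. Hits absent from the
#'   background are reported with a warning and intersected away.
#' @param alpha Family-wise error rate (default 0.05).
#' @param min_hit_count Minimum category occurrences among hits (default 5).
#' @return Data frame with `category`, `k_hit`, `n_hit`, `K_bg`, `N_bg`,
#'   `fold`, `p`, `alpha_bonferroni`, `significant`, `filtered_low_count`;
#'   attribute `threshold_2sf` carries the reporting-precision threshold.
#' @export
hypergeom_enrichment <- function(background, hits, alpha = 0.05,
                                 min_hit_count = 5L) {
  stopifnot(is.data.frame(background),
            all(c("gene_id", "category") %in% names(background)),
            length(hits) >= 1L)
  background <- unique(background[, c("gene_id", "category")])
  bg_genes <- unique(background$gene_id)
  stray <- setdiff(hits, bg_genes)
  if (length(stray) > 0L) {
    warning(length(stray), " hit gene(s) absent from background removed: ",
            paste(head(stray, 5L), collapse = ", "),
            if (length(stray) > 5L) ", ...", call. = FALSE)
    hits <- intersect(hits, bg_genes)
  }
  if (length(hits) == 0L) stop("no hit genes left in the background universe",
                               call. = FALSE)
  N <- length(bg_genes)
  n <- length(hits)
  hit_cats <- background[background$gene_id %in% hits, , drop = FALSE]
  cats <- sort(unique(hit_cats$category))
  if (length(cats) == 0L) stop("hit genes carry no categories", call. = FALSE)
  k <- table(factor(hit_cats$category, levels = cats))
  K <- table(factor(background$category[background$category %in% cats],
                    levels = cats))
  alpha_bonf <- alpha / length(cats)
  p <- phyper(as.integer(k) - 1L, as.integer(K), N - as.integer(K), n,
              lower.tail = FALSE)
  res <- data.frame(
    category = cats,
    k_hit = as.integer(k),
    n_hit = n,
    K_bg = as.integer(K),
    N_bg = N,
    fold = (as.integer(k) / n) / (as.integer(K) / N),
    p = p,
    alpha_bonferroni = alpha_bonf,
    filtered_low_count = as.integer(k) < min_hit_count,
    stringsAsFactors = FALSE
  )
  res$significant <- res$p < alpha_bonf & !res$filtered_low_count
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "threshold_2sf") <- signif(alpha_bonf, 2L)
  res
}

#' Classify strains as hyper-divergent at a locus
#'
#' A strain is hyper-divergent at the locus if any of its hyper-divergent
#' regions overlaps the locus by at least one base. Intervals are 0-based
#' half-open (BED convention): a region ending exactly where the locus
#' begins does not overlap.
#'
#' @param region_table Data frame `(strain_id, chrom, start, end)` of
#'   hyper-divergent regions, 0-based half-open.
#' @param locus List or one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return Data frame `(strain_id, hyperdivergent)` covering every strain in
#'   `region_table`.
#' @export
classify_hyperdivergent <- function(region_table, locus) {
  stopifnot(is.data.frame(region_table),
            all(c("strain_id", "chrom", "start", "end") %in%
                  names(region_table)))
  locus <- as.list(locus)
  bad <- region_table$start >= region_table$end
  if (any(bad) || locus$start >= locus$end) {
    stop("malformed interval: start must be < end (0-based half-open)",
         call. = FALSE)
  }
  same_chrom <- region_table$chrom == locus$chrom
  hit <- rep(FALSE, nrow(region_table))
  if (any(same_chrom)) {
    # convert half-open [start, end) to 1-based closed for IRanges
    regions <- IRanges::IRanges(start = region_table$start[same_chrom] + 1L,
                                end = region_table$end[same_chrom])
    loc <- IRanges::IRanges(start = locus$start + 1L, end = locus$end)
    hit[same_chrom] <- IRanges::overlapsAny(regions, loc)
  }
  agg <- aggregate(hit ~ strain_id,
                   data = data.frame(strain_id = region_table$strain_id,
                                     hit = hit),
                   FUN = any)
  names(agg)[2L] <- "hyperdivergent"
  agg[order(agg$strain_id), , drop = FALSE]
}

#' Compare trait values between two strain groups
#'
#' Group means plus a Welch (unequal-variance) two-sample t-test, e.g.
#' hyper-divergent versus non-divergent strains.
#'
#' @param traits Trait table with `strain_id` and the trait column.
#' @param groups Data frame `(strain_id, group)` or a named vector of group
#'   labels; exactly two groups after intersecting with `traits`.
#' @param trait Name of the trait column to test (default `"slope"`).
#' @return List with `summary` (per-group n, mean, sd), `t`, `df`, `p`.
#'   If either group has fewer than 2 strains the test is degenerate: a
#'   warning is raised and `t`/`p` are `NA`.
#' @export
split_trait_by_group <- function(traits, groups, trait = "slope") {
  stopifnot(is.data.frame(traits), trait %in% names(traits))
  if (!is.data.frame(groups)) {
    groups <- data.frame(strain_id = names(groups),
                         group = unname(groups),
                         stringsAsFactors = FALSE)
  }
  df <- merge(traits[, c("strain_id", trait)], groups, by = "strain_id")
  df <- df[!is.na(df[[trait]]), , drop = FALSE]
  lv <- sort(unique(as.character(df$group)))
  if (length(lv) != 2L) stop("need exactly two nonempty groups", call. = FALSE)
  x <- df[[trait]][df$group == lv[1L]]
  y <- df[[trait]][df$group == lv[2L]]
  summ <- data.frame(
    group = lv,
    n = c(length(x), length(y)),
    mean = c(mean(x), mean(y)),
    sd = c(sd(x), sd(y)),
    stringsAsFactors = FALSE
  )
  if (length(x) < 2L || length(y) < 2L) {
    warning("a group has fewer than 2 strains; t-test is degenerate",
            call. = FALSE)
    return(list(summary = summ, t = NA_real_, df = NA_real_, p = NA_real_))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(summary = summ, t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}
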