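#' Read layout for single-end MIP sequencing
#'
#' Describes how a read decomposes into UMI, assignment key (the 20-nt
#' ligation-arm target site), and captured scan sequence. The SNV of the
#' probe matched by a read sits at read position
#' `umi_length + snv_offset` (1-based).
#'
#' @param umi_length UMI length in nt (default 10).
#' @param key_length Assignment-key length in nt (default 20).
#' @param read_length Nominal read length in nt (default 50).
#' @return A `read_layout` object.
#' @export
read_layout <- function(umi_length = 10L, key_length = 20L,
                        read_length = 50L) {
  stopifnot(umi_length >= 0L, key_length > 0L,
            read_length > umi_length + key_length)
  structure(list(umi_length = as.integer(umi_length),
                 key_length = as.integer(key_length),
                 read_length = as.integer(read_length)),
            class = "read_layout")
}

.other_alleles <- function(ref, alt) {
  # two non-REF/ALT nucleotides in lexicographic order
  t(mapply(function(r, a) sort(setdiff(c("A", "C", "G", "T"), c(r, a))),
           ref, alt, USE.NAMES = FALSE))
}

.panel_key_table <- function(panel, layout) {
  tab <- panel_table(panel)
  others <- .other_alleles(tab$ref_allele, tab$alt_allele)
  scan_len <- layout$read_length - layout$umi_length - layout$key_length
  data.frame(
    probe_id    = tab$probe_id,
    strain_id   = tab$strain_id,
    key_seq     = tab$key_seq,
    ref         = tab$ref_allele,
    alt         = tab$alt_allele,
    other_a     = others[, 1L],
    other_b     = others[, 2L],
    snv_pos     = layout$umi_length + tab$snv_offset,  # 1-based in read
    scan_prefix = substr(tab$scan_seq, 1L, scan_len),
    stringsAsFactors = FALSE
  )
}

# Vectorized probe/allele assignment. Returns a data frame aligned with
# `reads`: probe_id (NA if key unmatched), allele (REF/ALT/OTHER_A/OTHER_B,
# NA if unassigned), umi, key_match, scan_match.
.assign_reads <- function(reads, panel, layout = read_layout()) {
  keys <- .panel_key_table(panel, layout)
  if (anyDuplicated(keys$key_seq)) {
    stop("panel assignment keys are not unique; probes ",
         paste(keys$probe_id[duplicated(keys$key_seq)], collapse = ", "),
         call. = FALSE)
  }
  u <- layout$umi_length
  k <- layout$key_length
  key_of_read <- substr(reads, u + 1L, u + k)
  m <- match(key_of_read, keys$key_seq)
  snv_pos <- keys$snv_pos[m]
  base <- substr(reads, snv_pos, snv_pos)
  allele <- rep(NA_character_, length(reads))
  hit <- !is.na(m)
  allele[hit & base == keys$ref[m]]     <- "REF"
  allele[hit & base == keys$alt[m]]     <- "ALT"
  allele[hit & base == keys$other_a[m]] <- "OTHER_A"
  allele[hit & base == keys$other_b[m]] <- "OTHER_B"

  # scan-tier match: read past the key equals the reference scan prefix at
  # every position except the SNV slot (any called allele base is accepted)
  scan_match <- rep(FALSE, length(reads))
  if (any(hit)) {
    prefix <- keys$scan_prefix[m]
    plen <- nchar(prefix)
    got <- substr(reads, u + k + 1L, u + k + plen)
    idx <- snv_pos - u - k               # SNV index within the scan prefix
    expected <- prefix
    ok <- hit & nchar(got) == plen & !is.na(allele)
    if (any(ok)) {
      substr(expected[ok], idx[ok], idx[ok]) <- base[ok]
      scan_match[ok] <- got[ok] == expected[ok]
    }
  }
  data.frame(
    probe_id   = keys$probe_id[m],
    allele     = allele,
    umi        = substr(reads, 1L, u),
    key_match  = hit,
    scan_match = scan_match,
    stringsAsFactors = FALSE
  )
}

#' Assign one read to a probe and allele class
#'
#' The probe is determined by exact match of its assignment key (the 20-nt
#' ligation-arm target site on the reference strand) at the post-UMI read
#' positions; the allele class by the single base at the probe's SNV slot.
#' The two nucleotides that are neither REF nor ALT map to `OTHER_A` and
#' `OTHER_B` in lexicographic order. Reads with any mismatch inside the key,
#' reads too short to cover the SNV slot, and non-ACGT bases at the slot are
#' unassigned.
#'
#' @param read_seq A single read sequence (character).
#' @param panel A `panel_spec`.
#' @param layout A [read_layout()].
#' @return A list with `probe_id` and `allele`, or `NULL` if unassigned.
#' @export
assign_read <- function(read_seq, panel, layout = read_layout()) {
  stopifnot(is.character(read_seq), length(read_seq) == 1L)
  a <- .assign_reads(read_seq, panel, layout)
  if (is.na(a$allele[1L])) return(NULL)
  list(probe_id = a$probe_id[1L], allele = a$allele[1L])
}

.empty_counts <- function(panel, sample_id) {
  tab <- panel_table(panel)
  data.frame(
    probe_id = tab$probe_id, sample_id = sample_id,
    n_ref = 0L, n_alt = 0L, n_other_a = 0L, n_other_b = 0L,
    n_assigned = 0L, stringsAsFactors = FALSE
  )
}

#' Count alleles from in-memory reads
#'
#' Workhorse behind [count_alleles()], also usable directly on simulated
#' reads. When `dedup_umi` is `TRUE`, reads sharing (probe, UMI, allele
#' class) collapse to a single observation; the published analysis leaves
#' deduplication off.
#'
#' @param reads Character vector of read sequences.
#' @param panel A `panel_spec`.
#' @param layout A [read_layout()].
#' @param sample_id Sample label for the output records.
#' @param dedup_umi Collapse duplicate (probe, UMI, allele) reads.
#' @return List with `counts` (one `AlleleCountRecord` row per panel probe)
#'   and `summary` (reads, key-tier and key+scan-tier match fractions).
#' @export
count_reads <- function(reads, panel, layout = read_layout(),
                        sample_id = "sample", dedup_umi = FALSE) {
  stopifnot(inherits(panel, "panel_spec"))
  counts <- .empty_counts(panel, sample_id)
  n_total <- length(reads)
  if (n_total > 0L) {
    a <- .assign_reads(reads, panel, layout)
    assigned <- !is.na(a$allele)
    aa <- a[assigned, , drop = FALSE]
    if (dedup_umi && nrow(aa) > 0L) {
      aa <- aa[!duplicated(paste(aa$probe_id, aa$umi, aa$allele, sep = "\r")),
               , drop = FALSE]
    }
    if (nrow(aa) > 0L) {
      tb <- table(factor(aa$probe_id, levels = counts$probe_id),
                  factor(aa$allele,
                         levels = c("REF", "ALT", "OTHER_A", "OTHER_B")))
      counts$n_ref     <- as.integer(tb[, "REF"])
      counts$n_alt     <- as.integer(tb[, "ALT"])
      counts$n_other_a <- as.integer(tb[, "OTHER_A"])
      counts$n_other_b <- as.integer(tb[, "OTHER_B"])
      counts$n_assigned <- counts$n_ref + counts$n_alt +
        counts$n_other_a + counts$n_other_b
    }
    summary <- data.frame(
      sample_id = sample_id,
      n_reads = n_total,
      frac_key_match = mean(a$key_match),
      frac_key_scan_match = mean(a$key_match & a$scan_match),
      stringsAsFactors = FALSE
    )
  } else {
    summary <- data.frame(sample_id = sample_id, n_reads = 0L,
                          frac_key_match = NA_real_,
                          frac_key_scan_match = NA_real_,
                          stringsAsFactors = FALSE)
  }
  list(counts = counts, summary = summary)
}

#' Count alleles per probe from FASTQ files
#'
#' Classifies every read in each FASTQ (plain or gzipped) against the panel
#' and tallies reference, alternative and the two "other" allele counts per
#' probe. Base qualities are ignored and reads are used untrimmed.
#'
#' @param fastq Character vector of FASTQ paths, one per sample. Names (or
#'   `sample_ids`) give the sample labels; defaults to file basenames.
#' @param panel A `panel_spec`.
#' @param layout A [read_layout()].
#' @param sample_ids Optional sample labels parallel to `fastq`.
#' @param dedup_umi Collapse duplicate (probe, UMI, allele) reads
#'   (default `FALSE`, matching the published analysis).
#' @return List with `counts` (rows of probe x sample allele counts) and
#'   `summary` (per-sample read totals and match fractions).
#' @export
count_alleles <- function(fastq, panel, layout = read_layout(),
                          sample_ids = NULL, dedup_umi = FALSE) {
  stopifnot(is.character(fastq), length(fastq) >= 1L)
  if (is.null(sample_ids)) {
    sample_ids <- names(fastq) %||% sub("\\.(fastq|fq)(\\.gz)?$", "",
                                        basename(fastq))
  }
  stopifnot(length(sample_ids) == length(fastq))
  res <- lapply(seq_along(fastq), function(i) {
    reads <- tryCatch(
      as.character(Biostrings::readDNAStringSet(fastq[i], format = "fastq")),
      error = function(e) stop("malformed FASTQ '", fastq[i], "': ",
                               conditionMessage(e), call. = FALSE)
    )
    count_reads(reads, panel, layout, sample_id = sample_ids[i],
                dedup_umi = dedup_umi)
  })
  list(counts  = do.call(rbind, lapply(res, `[[`, "counts")),
       summary = do.call(rbind, lapply(res, `[[`, "summary")))
}

#' Write an allele-count table to TSV
#' @param counts Count data frame from [count_alleles()].
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts)
}

#' Read an allele-count TSV
#' @param path Counts TSV path.
#' @return Count data frame.
#' @export
read_counts <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
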