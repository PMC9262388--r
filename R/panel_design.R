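#' Default molecular inversion probe backbone
#'
#' The fixed 30-nt linker joining the extension arm to the UMI and ligation
#' arm in the assembled 80-nt oligo. It carries the landing sites used for
#' amplification of captured circles. The sequence is a documented default:
#' real panels substitute the linker of their ordered probe design via the
#' `backbone` argument of [design_probe()].
#'
#' @return A 30-character nucleotide string.
#' @export
mip_default_backbone <- function() {
  "CTTCAGCTTCCCGATATCCGACGGTAGTGT"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_genome <- function(genome) {
  if (is.character(genome)) {
    if (!file.exists(genome)) {
      stop("reference FASTA not found: ", genome, call. = FALSE)
    }
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (!methods::is(genome, "DNAStringSet")) {
    stop("`genome` must be a FASTA path or a DNAStringSet", call. = FALSE)
  }
  # FASTA headers often carry descriptions after the first word
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Find strain-unique homozygous SNVs in a multi-sample VCF
#'
#' Scans biallelic SNV sites and keeps those where exactly one panel strain
#' carries the homozygous alternative genotype while every other panel strain
#' is homozygous reference. Sites with any missing (`./.`) or heterozygous
#' genotype among the panel strains are excluded, as are multi-allelic sites
#' and non-SNV records: only sites with an unambiguous frequency
#' interpretation downstream are retained. A strain derived from the
#' reference genome (such as N2) can legitimately yield no unique SNVs.
#'
#' @param vcf_path Path to a VCF file (plain or bgzipped) with genotypes for
#'   all panel strains.
#' @param panel_strains Character vector of strain identifiers to design for;
#'   must all be present as sample columns in the VCF.
#' @return A data frame with columns `strain_id`, `chrom`, `pos` (1-based, as
#'   in the VCF), `ref_allele`, `alt_allele`, ordered by strain then position.
#' @export
find_unique_snvs <- function(vcf_path, panel_strains) {
  stopifnot(is.character(vcf_path), length(vcf_path) == 1L)
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path, call. = FALSE)
  vcf <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", vcf_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  samples <- colnames(vcf@gt)[-1L]
  missing <- setdiff(panel_strains, samples)
  if (length(missing) > 0L) {
    stop("strain(s) absent from VCF header: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(strain_id = character(), chrom = character(),
                      pos = integer(), ref_allele = character(),
                      alt_allele = character(), stringsAsFactors = FALSE))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[, panel_strains, drop = FALSE]

  nt <- c("A", "C", "G", "T")
  snv <- fix$REF %in% nt & fix$ALT %in% nt  # multi-allelic ALT contains ','
  hom_ref <- gt %in% c("0/0", "0|0")
  hom_alt <- gt %in% c("1/1", "1|1")
  dim(hom_ref) <- dim(gt); dim(hom_alt) <- dim(gt)
  n_ref <- rowSums(hom_ref)
  n_alt <- rowSums(hom_alt)
  S <- length(panel_strains)
  keep <- snv & n_alt == 1L & n_ref == S - 1L
  if (!any(keep)) {
    return(data.frame(strain_id = character(), chrom = character(),
                      pos = integer(), ref_allele = character(),
                      alt_allele = character(), stringsAsFactors = FALSE))
  }
  which_alt <- apply(hom_alt[keep, , drop = FALSE], 1L, which.max)
  out <- data.frame(
    strain_id  = panel_strains[which_alt],
    chrom      = fix$CHROM[keep],
    pos        = as.integer(fix$POS[keep]),
    ref_allele = fix$REF[keep],
    alt_allele = fix$ALT[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$strain_id, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.rejection <- function(snv, reason, detail = "") {
  structure(list(target = snv, reason = reason, detail = detail),
            class = "mip_rejection")
}

#' Test whether a probe design attempt was rejected
#' @param x Object returned by [design_probe()].
#' @return `TRUE` for rejection objects.
#' @export
is_rejection <- function(x) inherits(x, "mip_rejection")

.validate_probe <- function(p) {
  stopifnot(
    nchar(p$extension_arm) == p$arm_length,
    nchar(p$ligation_arm) == p$arm_length,
    nchar(p$oligo_seq) == 2L * p$arm_length + nchar(p$backbone) + p$umi_length,
    nchar(p$scan_seq) == p$capture_size,
    p$snv_offset <= p$read_length - p$umi_length,
    substr(p$scan_seq, p$snv_offset - p$arm_length,
           p$snv_offset - p$arm_length) == p$ref_allele
  )
  invisible(p)
}

#' Design a molecular inversion probe for one strain-unique SNV
#'
#' Places a `capture_size`-nt capture window (the scan sequence) over the SNV
#' so that the SNV falls within the first `read_length - umi_length` bases of
#' the sequencing read, then extracts 20-nt arms complementary to the
#' reference flanks of the window and assembles the 80-nt oligo as
#' extension arm + backbone + UMI (as `N`s) + ligation arm (5'->3'). The
#' window search slides left-to-right over all placements satisfying the
#' offset constraint and accepts the first placement whose arms fit inside
#' the contig and contain no ambiguous bases.
#'
#' The read architecture assumed throughout the package is: UMI
#' (`umi_length` nt), then the 20-nt ligation-arm target site on the
#' reference strand, then the scan sequence. `snv_offset` is the 1-based
#' distance of the SNV from the end of the UMI, so the SNV sits at read
#' position `umi_length + snv_offset`.
#'
#' @param genome Reference FASTA path or a `DNAStringSet`.
#' @param snv One-row data frame (or list) with `strain_id`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele` as produced by [find_unique_snvs()].
#' @param read_length Single-end read length in nt (default 50).
#' @param umi_length UMI length in nt (default 10).
#' @param arm_length Arm length in nt (default 20).
#' @param capture_size Capture (scan) window size in nt (default 100).
#' @param backbone Linker sequence; see [mip_default_backbone()].
#' @return A `mip_probe` object, or a `mip_rejection` (see [is_rejection()])
#'   with a `reason` in `"offset"`, `"contig_end"`, `"ambiguous_base"`,
#'   `"missing_contig"`, `"ref_mismatch"`.
#' @export
design_probe <- function(genome, snv, read_length = 50L, umi_length = 10L,
                         arm_length = 20L, capture_size = 100L,
                         backbone = mip_default_backbone()) {
  genome <- .load_genome(genome)
  snv <- as.list(snv)
  if (!snv$chrom %in% names(genome)) {
    return(.rejection(snv, "missing_contig",
                      paste0("contig '", snv$chrom, "' not in reference")))
  }
  chrom_seq <- genome[[snv$chrom]]
  len <- length(chrom_seq)
  p0 <- as.integer(snv$pos) - 1L  # 0-based SNV coordinate
  max_i <- read_length - umi_length - arm_length - 1L
  if (max_i < 0L) return(.rejection(snv, "offset", "read too short for layout"))

  obs <- as.character(Biostrings::subseq(chrom_seq, p0 + 1L, p0 + 1L))
  if (obs != snv$ref_allele) {
    return(.rejection(snv, "ref_mismatch",
                      paste0("reference has ", obs, ", VCF REF is ",
                             snv$ref_allele)))
  }

  saw_ambiguous <- FALSE
  in_bounds <- FALSE
  for (w in (p0 - max_i):p0) {          # left-to-right window starts (0-based)
    if (w - arm_length < 0L || w + capture_size + arm_length > len) next
    in_bounds <- TRUE
    lig_site <- as.character(Biostrings::subseq(chrom_seq, w - arm_length + 1L, w))
    ext_site <- as.character(Biostrings::subseq(chrom_seq, w + capture_size + 1L,
                                                w + capture_size + arm_length))
    if (grepl("[^ACGT]", lig_site) || grepl("[^ACGT]", ext_site)) {
      saw_ambiguous <- TRUE
      next
    }
    scan_seq <- as.character(Biostrings::subseq(chrom_seq, w + 1L,
                                                w + capture_size))
    i <- p0 - w                          # SNV index within scan, 0-based
    probe <- structure(list(
      probe_id      = paste(snv$strain_id, snv$chrom, snv$pos, sep = "_"),
      strain_id     = snv$strain_id,
      chrom         = snv$chrom,
      pos           = as.integer(snv$pos),
      ref_allele    = snv$ref_allele,
      alt_allele    = snv$alt_allele,
      extension_arm = as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(ext_site))),
      ligation_arm  = as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(lig_site))),
      umi_length    = as.integer(umi_length),
      arm_length    = as.integer(arm_length),
      read_length   = as.integer(read_length),
      backbone      = backbone,
      scan_seq      = scan_seq,
      snv_offset    = arm_length + i + 1L,
      capture_size  = as.integer(capture_size),
      key_seq       = lig_site,          # reference-strand assignment key
      oligo_seq     = paste0(
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(ext_site))),
        backbone, strrep("N", umi_length),
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(lig_site))))
    ), class = "mip_probe")
    return(.validate_probe(probe))
  }
  if (saw_ambiguous) {
    return(.rejection(snv, "ambiguous_base", "N in arm region"))
  }
  if (!in_bounds) {
    return(.rejection(snv, "contig_end", "SNV too close to contig end"))
  }
  .rejection(snv, "offset", "no placement satisfies the offset constraint")
}

.arm_gc <- function(probe) {
  arms <- paste0(probe$extension_arm, probe$ligation_arm)
  mean(strsplit(arms, "")[[1]] %in% c("G", "C"))
}

#' Build a probe panel from candidate strain-unique SNVs
#'
#' Designs probes for every candidate SNV and retains up to
#' `probes_per_strain` accepted designs per strain. Accepted candidates are
#' ranked by arm GC content closest to 50%, ties broken by genomic
#' coordinate, so the selection is deterministic and invariant to the input
#' ordering of candidates. Strains with fewer accepted designs than
#' requested are listed in the shortfall table rather than raising an error.
#'
#' @param snvs Data frame of candidates as from [find_unique_snvs()].
#' @param genome Reference FASTA path or `DNAStringSet`.
#' @param probes_per_strain Maximum probes per strain (default 4).
#' @param ... Passed to [design_probe()] (read length, backbone, ...).
#' @return A `panel_spec` object: list with `probes` (list of `mip_probe`),
#'   `strains`, `probes_per_strain`, `shortfall` (data frame) and
#'   `rejections` (data frame of rejected candidates with reasons).
#' @export
build_panel <- function(snvs, genome, probes_per_strain = 4L, ...) {
  stopifnot(is.data.frame(snvs))
  genome <- .load_genome(genome)
  strains <- sort(unique(snvs$strain_id))
  probes <- list()
  shortfall <- list()
  rejections <- list()
  for (s in strains) {
    cand <- snvs[snvs$strain_id == s, , drop = FALSE]
    designed <- lapply(seq_len(nrow(cand)), function(i) {
      design_probe(genome, cand[i, ], ...)
    })
    ok <- Filter(Negate(is_rejection), designed)
    bad <- Filter(is_rejection, designed)
    if (length(bad) > 0L) {
      rejections[[s]] <- data.frame(
        strain_id = s,
        chrom  = vapply(bad, function(r) r$target$chrom, ""),
        pos    = vapply(bad, function(r) as.integer(r$target$pos), 0L),
        reason = vapply(bad, function(r) r$reason, ""),
        stringsAsFactors = FALSE
      )
    }
    if (length(ok) > 0L) {
      gc_dist <- vapply(ok, function(p) abs(.arm_gc(p) - 0.5), 0)
      ord <- order(gc_dist,
                   vapply(ok, function(p) p$chrom, ""),
                   vapply(ok, function(p) p$pos, 0L))
      ok <- ok[ord]
      probes <- c(probes, ok[seq_len(min(probes_per_strain, length(ok)))])
    }
    if (length(ok) < probes_per_strain) {
      shortfall[[s]] <- data.frame(
        strain_id = s, n_requested = probes_per_strain,
        n_accepted = length(ok), stringsAsFactors = FALSE
      )
    }
  }
  ids <- vapply(probes, function(p) p$probe_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate probe ids in panel: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(
    probes            = probes,
    strains           = strains,
    probes_per_strain = as.integer(probes_per_strain),
    shortfall         = if (length(shortfall)) do.call(rbind, shortfall)
                        else data.frame(strain_id = character(),
                                        n_requested = integer(),
                                        n_accepted = integer()),
    rejections        = if (length(rejections)) do.call(rbind, rejections)
                        else data.frame(strain_id = character(),
                                        chrom = character(), pos = integer(),
                                        reason = character())
  ), class = "panel_spec")
}

#' @export
print.panel_spec <- function(x, ...) {
  cat("MIP panel:", length(x$probes), "probes for", length(x$strains),
      "strains (requested", x$probes_per_strain, "per strain)\n")
  if (nrow(x$shortfall) > 0L) {
    cat("Shortfall strains:", paste(x$shortfall$strain_id, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Flatten a panel to a data frame
#'
#' @param panel A `panel_spec`.
#' @return Data frame with one row per probe and all probe fields.
#' @export
panel_table <- function(panel) {
  stopifnot(inherits(panel, "panel_spec"))
  cols <- c("probe_id", "strain_id", "chrom", "pos", "ref_allele",
            "alt_allele", "extension_arm", "ligation_arm", "umi_length",
            "arm_length", "read_length", "backbone", "scan_seq",
            "snv_offset", "capture_size", "key_seq", "oligo_seq")
  do.call(rbind, lapply(panel$probes, function(p) {
    as.data.frame(p[cols], stringsAsFactors = FALSE)
  }))
}

#' Reconstruct a panel from its table representation
#'
#' @param df Data frame as written by [write_panel()] / [panel_table()].
#' @param probes_per_strain Declared panel redundancy (default: max probes
#'   per strain observed in the table).
#' @return A `panel_spec`.
#' @export
panel_from_table <- function(df, probes_per_strain = NULL) {
  stopifnot(is.data.frame(df), nrow(df) > 0L)
  probes <- lapply(seq_len(nrow(df)), function(i) {
    p <- as.list(df[i, , drop = FALSE])
    p <- lapply(p, function(v) if (is.factor(v)) as.character(v) else v)
    structure(p, class = "mip_probe")
  })
  per_strain <- table(df$strain_id)
  structure(list(
    probes            = probes,
    strains           = sort(unique(df$strain_id)),
    probes_per_strain = as.integer(probes_per_strain %||% max(per_strain)),
    shortfall         = data.frame(strain_id = character(),
                                   n_requested = integer(),
                                   n_accepted = integer()),
    rejections        = data.frame(strain_id = character(),
                                   chrom = character(), pos = integer(),
                                   reason = character())
  ), class = "panel_spec")
}

#' Write a panel TSV (and optionally a probe FASTA)
#'
#' @param panel A `panel_spec`.
#' @param tsv_path Output TSV path.
#' @param fasta_path Optional path for a FASTA of assembled oligos.
#' @return Invisibly, the panel table.
#' @export
write_panel <- function(panel, tsv_path, fasta_path = NULL) {
  tab <- panel_table(panel)
  write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta_path)) {
    oligos <- Biostrings::DNAStringSet(setNames(tab$oligo_seq, tab$probe_id))
    Biostrings::writeXStringSet(oligos, fasta_path)
  }
  invisible(tab)
}

#' Read a panel TSV written by [write_panel()]
#' @param tsv_path Panel TSV path.
#' @return A `panel_spec`.
#' @export
read_panel <- function(tsv_path) {
  panel_from_table(read.delim(tsv_path, stringsAsFactors = FALSE))
}

#' Probe pool needed for hybridization
#'
#' Total picomoles of the phosphorylated probe pool added to one capture
#' reaction: `panel_size * per_probe_amount`. With the published per-probe
#' amount of 0.0083 pmol and a 412-probe panel this is 3.42 pmol.
#'
#' @param panel_size Number of probes in the pool.
#' @param per_probe_amount Picomoles of each individual probe (default
#'   0.0083).
#' @return Picomoles of pooled probe (unrounded).
#' @export
hybridization_input <- function(panel_size, per_probe_amount = 0.0083) {
  if (!is.numeric(panel_size) || length(panel_size) != 1L ||
      is.na(panel_size) || panel_size < 1) {
    stop("`panel_size` must be a positive count", call. = FALSE)
  }
  panel_size * per_probe_amount
}
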