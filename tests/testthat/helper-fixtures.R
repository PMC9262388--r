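# Fixtures are built in code at test time.

# Toy multi-sample VCF: six hand-enumerable sites for strains A, B, C.
# Expected unique SNVs: A at chr1:600 (G>C), B at chr1:100 (A>G).
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A", "B", "C", sep = "\t"),
    paste("chr1", 100, ".", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "1/1", "0/0", sep = "\t"),   # unique to B
    paste("chr1", 200, ".", "C", "T", ".", "PASS", ".", "GT",
          "1/1", "1/1", "0/0", sep = "\t"),   # shared alt: excluded
    paste("chr1", 300, ".", "G", "A", ".", "PASS", ".", "GT",
          "0/0", "0/1", "0/0", sep = "\t"),   # heterozygous: excluded
    paste("chr1", 400, ".", "T", "C", ".", "PASS", ".", "GT",
          "./.", "0/0", "1/1", sep = "\t"),   # missing genotype: excluded
    paste("chr1", 500, ".", "A", "C,T", ".", "PASS", ".", "GT",
          "0/0", "0/0", "1/1", sep = "\t"),   # multi-allelic: excluded
    paste("chr1", 600, ".", "G", "C", ".", "PASS", ".", "GT",
          "1/1", "0/0", "0/0", sep = "\t")    # unique to A
  )
  writeLines(lines, path)
  path
}

# Deterministic 300-nt contig with an SNV at position 150 (1-based).
toy_genome <- function(seed = 42L) {
  set.seed(seed)
  contig <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                  collapse = "")
  Biostrings::DNAStringSet(stats::setNames(contig, "ctg"))
}

toy_snv <- function(genome, pos = 150L, strain = "ST1") {
  contig <- as.character(genome[[1]])
  ref <- substring(contig, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  data.frame(strain_id = strain, chrom = "ctg", pos = pos,
             ref_allele = ref, alt_allele = alt, stringsAsFactors = FALSE)
}

# Independent reverse complement (no Biostrings) for arm-alignment oracles.
revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Build a read for a probe: UMI + assignment key + scan prefix carrying
# `base` at the SNV slot.
probe_read <- function(probe, base = probe$ref_allele, umi = NULL,
                       read_length = 50L, umi_length = 10L) {
  if (is.null(umi)) umi <- strrep("A", umi_length)
  scan_len <- read_length - umi_length - nchar(probe$key_seq)
  body <- substr(probe$scan_seq, 1L, scan_len)
  idx <- probe$snv_offset - nchar(probe$key_seq)
  substr(body, idx, idx) <- base
  paste0(umi, probe$key_seq, body)
}

# Small synthetic panel for read/count tests.
small_panel <- function(n_strains = 4L, probes_per_strain = 2L, seed = 11L) {
  cfg <- mipmeter::sim_config(n_strains = n_strains,
                              probes_per_strain = probes_per_strain,
                              seed = seed)
  mipmeter::sim_reference_panel(cfg)$panel
}
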