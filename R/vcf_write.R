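# VCF v4.2 export of simulated populations: the fixture generator that
# closes the loop between the attack simulator and the allele store.

#' Write beacon members of a simulated population to a VCF file
#'
#' Emits one line per SNP segregating among the selected members (sites
#' where no member carries the alt allele are omitted), with per-member
#' `GT` columns and `INFO` `AC`/`AN` consistent with the genotypes. An
#' empty membership produces a valid header-only VCF.
#'
#' @param population A [simulate_population()].
#' @param member_ids Integer indices of the individuals to export.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(population, member_ids, path) {
  stopifnot(inherits(population, "synthetic_population"))
  n <- length(member_ids)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=beaconr-synthetic-population",
    sprintf("##contig=<ID=%s>", unique(population$sites$chrom)),
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alt allele count in called genotypes\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total called alleles\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (n > 0L) {
    cols <- c(cols, "FORMAT", sprintf("S%04d", member_ids))
  }
  lines <- c(header, paste(cols, collapse = "\t"))

  if (n > 0L) {
    G <- population$genotypes[member_ids, , drop = FALSE]
    ac <- colSums(G)
    seg <- which(ac > 0L)
    if (length(seg) > 0L) {
      gt_code <- c("0/0", "0/1", "1/1")
      body <- vapply(seg, function(j) {
        gts <- gt_code[G[, j] + 1L]
        paste(c(population$sites$chrom[j], population$sites$pos[j], ".",
                population$sites$ref[j], population$sites$alt[j], ".",
                "PASS", sprintf("AC=%d;AN=%d", ac[j], 2L * n), "GT", gts),
              collapse = "\t")
      }, "")
      lines <- c(lines, body)
    }
  }
  writeLines(lines, path)
  invisible(path)
}
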