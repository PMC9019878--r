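#' Read SNV/indel alterations from a VCF
#'
#' Optional ingestion path mapping annotated VCF v4.2 records to
#' [alteration()] objects. Gene symbol and protein change are taken from
#' a SnpEff/VEP-style `ANN` INFO field (subfields `Gene_Name` and
#' `HGVS.p`, the `p.` prefix stripped); the population frequency from a
#' numeric INFO field (default `AF`), left unknown when absent. REF/ALT
#' of equal length 1 map to `kind = "snv"`, anything else to `"indel"`.
#' Fusions and expression flags do not travel in VCF and enter via the
#' TSV path only.
#'
#' Requires the suggested \pkg{vcfR} package.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param freq_field INFO key holding the population allele frequency.
#' @return A list of [alteration()] objects, one per record.
#' @export
read_alterations_vcf <- function(path, freq_field = "AF") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_alterations_vcf() needs the 'vcfR' package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  info <- vcfR::extract.info(v, element = "ANN")
  freq <- suppressWarnings(as.numeric(
    vcfR::extract.info(v, element = freq_field)))
  lapply(seq_len(nrow(fix)), function(i) {
    ref <- fix[i, "REF"]; alt <- fix[i, "ALT"]
    kind <- if (nchar(ref) == 1L && nchar(alt) == 1L) "snv" else "indel"
    ann <- info[i]
    if (is.na(ann))
      stop("VCF record ", i, " (", fix[i, "CHROM"], ":", fix[i, "POS"],
           ") has no ANN annotation", call. = FALSE)
    parts <- strsplit(strsplit(ann, ",", fixed = TRUE)[[1]][1],
                      "|", fixed = TRUE)[[1]]
    gene <- if (length(parts) >= 4L) parts[4] else ""
    if (!nzchar(gene))
      stop("VCF record ", i, ": ANN field has no gene name", call. = FALSE)
    detail <- if (length(parts) >= 11L) sub("^p\\.", "", parts[11]) else ""
    alteration(gene, kind, detail,
               population_frequency = if (length(freq) >= i) freq[i]
                                      else NA_real_)
  })
}
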