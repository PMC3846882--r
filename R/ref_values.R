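#' Published REF values for the human multi-tRNA synthetase complex
#'
#' Relative enrichment factors reported for an AP-MS survey of the human
#' multi-tRNA synthetase complex (MSC) in HEK 293T cells, with AIMP1, AIMP2
#' and KARS as baits: one row per protein scoring above 0.3, one REF column
#' per bait. The eleven known MSC components (the three AIMP scaffolds and
#' eight synthetases) plus TARSL2, the candidate member nominated by the
#' analysis, are included. Because REF is scale-normalized, these columns
#' can be fed back to [compute_ref()] as quotients (up to any positive
#' factor) to reproduce themselves — useful as a worked example and as a
#' regression fixture.
#'
#' @param path Optional override of the packaged TSV.
#' @return A `data.frame` with columns `ipi`, `uniprot`, `gene_symbol`,
#'   `ref_AIMP1`, `ref_AIMP2`, `ref_KARS`.
#' @examples
#' tab <- msc_ref_values()
#' q <- setNames(tab$ref_AIMP1 * 7.3, tab$gene_symbol)
#' ref <- compute_ref(q, setdiff(tab$gene_symbol, "TARSL2"), "AIMP1")
#' round(ref$ref[ref$protein_id == "TARSL2"], 2)  # 0.57
#' @export
msc_ref_values <- function(path = system.file("extdata",
                                              "msc_ref_values.tsv",
                                              package = "apmsref")) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' The MSC core-complex reference set
#'
#' Gene symbols of the eleven known components of the human multi-tRNA
#' synthetase complex: the AIMP1/AIMP2/EEF1E1 (AIMP3) scaffolds and the
#' eight complex-forming synthetases.
#'
#' @return Character vector of 11 gene symbols.
#' @export
msc_reference_set <- function() {
  c("AIMP1", "AIMP2", "DARS", "EEF1E1", "EPRS", "IARS", "KARS", "LARS",
    "MARS", "QARS", "RARS")
}
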