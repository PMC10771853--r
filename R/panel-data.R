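#' Published 27-CpG adalimumab-response predictor panel
#'
#' The reported whole-blood predictor panel for adalimumab response in
#' rheumatoid arthritis: probe id, hg19 location, beta-scale group difference
#' (responders minus non-responders), nominal p-value, annotated gene
#' (semicolon-separated when multiple), gene feature and effect direction.
#' Bundled as a plain-text fixture for annotation and reporting tests; the
#' underlying patient-level data are controlled-access and not included.
#'
#' @return data.frame with 27 rows.
#' @export
published_panel <- function() {
  path <- system.file("extdata", "ada_response_panel27.tsv",
                      package = "methresp", mustWork = TRUE)
  data.table::fread(path, sep = "\t", data.table = FALSE,
                    na.strings = "NA")
}
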