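# Packaged worked-example data.

#' CASP12 T0912 quality-assessment scores (top 15 decoys)
#'
#' True GDT_TS and the predicted scores of five CASP12 QA groups for the
#' 15 best decoy models (by GDT_TS) of target T0912 from the best-150
#' evaluation set, as published by the CASP12 assessment. The `fdubio`
#' column is the learning-to-rank + quasi-clustering pipeline this
#' package implements (CASP12 group FDUBio); `mufoldqa_c`,
#' `davis_consensus`, `modfold6_cor` and `mufoldqa_s` are leading
#' clustering, reference-consensus, quasi-single and single methods.
#'
#' @return data.frame with 15 rows and columns `decoy_id`, `gdt_ts`,
#'   `fdubio`, `mufoldqa_c`, `davis_consensus`, `modfold6_cor`,
#'   `mufoldqa_s`.
#' @export
load_t0912_scores <- function() {
  path <- system.file("extdata", "casp12_t0912_qa_scores.csv",
                      package = "decoyrank", mustWork = TRUE)
  read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}
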