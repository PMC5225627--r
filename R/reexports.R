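## Re-exported accessors so that the containers this package returns can
## be inspected with only poolDiv attached.

#' @importFrom SummarizedExperiment assay
#' @export
SummarizedExperiment::assay

#' @importFrom SummarizedExperiment assays
#' @export
SummarizedExperiment::assays

#' @importFrom SummarizedExperiment rowData
#' @export
SummarizedExperiment::rowData

#' @importFrom SummarizedExperiment colData
#' @export
SummarizedExperiment::colData

#' @importFrom SummarizedExperiment rowRanges
#' @export
SummarizedExperiment::rowRanges

#' @importFrom S4Vectors metadata
#' @export
S4Vectors::metadata
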