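#' @useDynLib SubMatBench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames runif cor sd splinefun
#' @importFrom utils read.table write.table combn
"_PACKAGE"
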