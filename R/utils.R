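#' @importFrom rlang %||% .data :=
#' @importFrom stats pnorm pwilcox rnbinom rgamma rnorm rpois runif setNames
#' @keywords internal
"_PACKAGE"

# derive a reproducible child seed from a base seed and a stage label;
# kept below 2^31 so it is a valid R integer seed
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1021L + h) %% .Machine$integer.max)
}
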