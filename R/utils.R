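#' @importFrom rlang .data %||%
#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm qnorm dnorm rnorm runif rgeom optimize optim
#'   coef lm model.matrix quantile sd var setNames
NULL

# consistent z-quantile for two-sided (1 - alpha) intervals
z_level <- function(level) stats::qnorm((1 + level) / 2)
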