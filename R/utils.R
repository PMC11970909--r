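# Half-up rounding for report percentages (base round() is half-even).
round_half_up <- function(x) floor(x + 0.5)

#' @importFrom grDevices rgb
#' @importFrom graphics plot text
#' @importFrom stats kmeans median rbeta rbinom rgeom rpois runif setNames
#' @importFrom utils read.table write.table
NULL
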