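#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats pchisq pnorm qnorm optim nlminb model.matrix terms var
#'   setNames complete.cases delete.response ptukey runif rnorm quantile
#'   as.formula sd
#' @importFrom utils head modifyList combn
NULL

# Replace Unicode minus (U+2212) with ASCII hyphen-minus in character columns.
normalise_minus <- function(x) {
  if (is.character(x)) gsub("−", "-", x, fixed = TRUE) else x
}

# Stop with a telometa-classed condition so callers can test error types.
tm_abort <- function(message, class, ...) {
  abort(message, class = c(class, "telometa_error"), ...)
}

tm_warn <- function(message, class = "telometa_warning") {
  warn(message, class = class)
}

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x == round(x))
}

# Symmetrise a numeric matrix (guards against floating-point asymmetry).
symmetrise <- function(m) (m + t(m)) / 2
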