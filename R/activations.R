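#' Swish (SiLU) activation
#'
#' `swish(x) = x * sigmoid(x)`, the smooth self-gated activation used in
#' every convolution block of the baseline detector.
#'
#' @param x numeric vector or array.
#' @return numeric object of the same shape.
#' @examples
#' swish(0)   # 0
#' swish(1)   # 0.7310586
#' @export
swish <- function(x) x / (1 + exp(-x))

#' Hard sigmoid
#'
#' Piecewise-linear approximation of the logistic sigmoid: 0 below -3,
#' 1 above 3, and `x/6 + 1/2` in between. Cheaper than the exponential form
#' on embedded hardware.
#'
#' @param x numeric vector or array.
#' @return numeric object of the same shape, values in `[0, 1]`.
#' @export
hardsigmoid <- function(x) pmin(pmax(x / 6 + 0.5, 0), 1)

#' HardSwish activation
#'
#' `hardswish(x) = x * hardsigmoid(x)`, implemented through the ReLU6 form
#' `x * clamp(x + 3, 0, 6) / 6` so all three branches collapse into one
#' expression. Equals `x` for `x >= 3` and 0 for `x <= -3`.
#'
#' @param x numeric vector or array.
#' @return numeric object of the same shape.
#' @export
hardswish <- function(x) x * pmin(pmax(x + 3, 0), 6) / 6

#' Derivative of HardSwish
#'
#' Piecewise: 1 for `x >= 3`, `x/3 + 1/2` on `(-3, 3)`, 0 for `x <= -3`.
#' At the two kinks the closed-interval (one-sided) value is returned.
#'
#' @param x numeric vector or array.
#' @return numeric object of the same shape.
#' @export
hardswish_derivative <- function(x) {
  ifelse(x >= 3, 1, ifelse(x <= -3, 0, x / 3 + 0.5))
}
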