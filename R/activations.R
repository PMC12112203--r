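#' Activation functions
#'
#' Elementwise nonlinearities shared by the graph encoder and the Tucker
#' decoder, together with their derivatives (needed for back-propagation).
#' Supported names: `"identity"`, `"relu"`, `"tanh"`, `"elu"`, `"prelu"`,
#' `"leakyrelu"`. `prelu` and `leakyrelu` take a fixed negative slope
#' (defaults 0.25 and 0.01); `elu` uses alpha = 1.
#'
#' @param name Activation name (case-insensitive).
#' @param prelu_slope Negative slope used when `name = "prelu"`.
#' @return A list with elements `fn` and `grad`, each a vectorised function.
#' @examples
#' act <- activation("leakyrelu")
#' act$fn(c(-1, 0, 2))
#' @export
activation <- function(name, prelu_slope = 0.25) {
  name <- tolower(name)
  slope <- switch(name, prelu = prelu_slope, leakyrelu = 0.01, 0)
  switch(name,
    identity = list(
      fn = function(x) x,
      grad = function(x) array(1, dim = dim(x) %||% length(x))
    ),
    relu = list(
      fn = function(x) pmax(x, 0),
      grad = function(x) (x > 0) * 1
    ),
    tanh = list(
      fn = tanh,
      grad = function(x) 1 - tanh(x)^2
    ),
    elu = list(
      fn = function(x) ifelse(x > 0, x, expm1(x)),
      grad = function(x) ifelse(x > 0, 1, exp(x))
    ),
    prelu = ,
    leakyrelu = list(
      fn = function(x) ifelse(x > 0, x, slope * x),
      grad = function(x) ifelse(x > 0, 1, slope)
    ),
    stop("unknown activation: '", name, "'", call. = FALSE)
  )
}

activation_names <- function() {
  c("identity", "relu", "tanh", "elu", "prelu", "leakyrelu")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

logistic <- function(x) 1 / (1 + exp(-x))
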