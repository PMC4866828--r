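#' Read and write anticipation parameters as JSON
#'
#' Serializes an [anticipation_params()] as a flat JSON object
#' `{R, nu, gamma, eta0, sigma, boost: {kind, c, c1, c2}}`.
#'
#' @param params An [anticipation_params()].
#' @param file Path to a JSON file.
#' @return `write_params()` invisibly returns `file`; `read_params()`
#'   returns an [anticipation_params()].
#' @export
write_params <- function(params, file) {
  stopifnot(inherits(params, "anticipation_params"))
  jsonlite::write_json(
    list(R = params$R, nu = params$nu, gamma = params$gamma,
         eta0 = params$eta0, sigma = params$sigma,
         boost = unclass(params$boost)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_params
#' @export
read_params <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  anticipation_params(
    R = x$R, nu = x$nu, gamma = x$gamma, eta0 = x$eta0,
    boost = boost_spec(x$boost$kind, c = x$boost$c, c1 = x$boost$c1,
                       c2 = x$boost$c2),
    sigma = x$sigma)
}
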