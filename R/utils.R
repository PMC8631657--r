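# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed <- function(seed, code) withr::with_seed(seed, code)

abort_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

abort_format <- function(file, msg) {
  stop(sprintf("format error in '%s': %s", file, msg), call. = FALSE)
}

# sample standard-deviation based coefficient of variation, in percent
#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean, expressed in percent.
#' Used to summarise replicate-to-replicate variability of molecular-feature
#' counts and intensities.
#'
#' @param values numeric vector of at least two values with non-zero mean.
#' @return CV in percent.
#' @export
#' @examples
#' coefficient_of_variation(c(2, 4))   # 47.14
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("coefficient_of_variation() needs at least two values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("coefficient_of_variation() undefined for zero mean",
                   call. = FALSE)
  stats::sd(values) / m * 100
}
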