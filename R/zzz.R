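#' @useDynLib seamapr, .registration = TRUE
#' @importFrom generics tidy glance augment
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

.onLoad <- function(libname, pkgname) {
  register_default_organisms()
}
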