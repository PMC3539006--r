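#' Convert isotope ratios to delta notation
#'
#' Stable isotope abundances are conventionally reported in delta notation,
#' the per-mil deviation of the sample's heavy-to-light isotope ratio from an
#' international standard (AIR for nitrogen, V-PDB for carbon):
#' \deqn{\delta = (R_{sample}/R_{standard} - 1) \times 1000}
#'
#' @param r_sample Isotope ratio(s) of the sample (heavy/light). Must be > 0.
#' @param r_standard Isotope ratio(s) of the standard. Must be > 0.
#' @return Numeric vector of delta values in per mil.
#' @examples
#' delta_from_ratios(0.0036765, 0.0036765)  # 0
#' delta_from_ratios(1.001 * 0.0036765, 0.0036765)  # 1
#' @export
delta_from_ratios <- function(r_sample, r_standard) {
  if (!is.numeric(r_sample) || !is.numeric(r_standard)) {
    stop("isotope ratios must be numeric", call. = FALSE)
  }
  if (any(!is.finite(r_sample)) || any(!is.finite(r_standard)) ||
      any(r_sample <= 0) || any(r_standard <= 0)) {
    stop("isotope ratios must be finite and strictly positive", call. = FALSE)
  }
  (r_sample / r_standard - 1) * 1000
}
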