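#' Bell parameters for the coiled-coil constructs
#'
#' Preset force-free dissociation rates and potential widths for the three
#' heterodimeric coiled-coil constructs studied by dynamic SMFS in the
#' shear geometry (means over three cantilever replicates):
#'
#' | construct   | koff (1/s) | deltaX (nm) |
#' |-------------|-----------:|------------:|
#' | CC-A4B4     | 3.2e-4     | 1.29        |
#' | CC-A4B3.5   | 1.1e-1     | 0.89        |
#' | CC-A4B3     | 6.5e-3     | 1.03        |
#'
#' The 4-heptad construct is the most stable (slowest off-rate, widest
#' potential); truncating the B helix shortens the potential width, and
#' the half-heptad construct is mechanically the weakest.
#'
#' @param name construct name; one of `"A4B4"`, `"A4B3.5"`, `"A4B3"`
#'   (optionally prefixed with `"CC-"`).
#' @param kBT thermal energy (pN nm).
#' @return A [BellParameters-class].
#' @examples
#' ccConstruct("A4B4")
#' @export
ccConstruct <- function(name, kBT = 4.114) {
  key <- toupper(sub("^CC-", "", name))
  params <- switch(key,
    "A4B4"   = c(koff = 3.2e-4, deltaX = 1.29),
    "A4B3.5" = c(koff = 1.1e-1, deltaX = 0.89),
    "A4B3"   = c(koff = 6.5e-3, deltaX = 1.03),
    stop(sprintf("unknown construct '%s' (use A4B4, A4B3.5 or A4B3)", name)))
  BellParameters(koff = unname(params["koff"]),
                 deltaX = unname(params["deltaX"]), kBT = kBT)
}

#' Names of the available construct presets
#' @return Character vector of construct names.
#' @export
ccConstructNames <- function() c("A4B4", "A4B3.5", "A4B3")

#' Default retract-speed panel
#'
#' Eight speeds spanning the experimentally used 50-5000 nm/s range in
#' roughly logarithmic steps.
#'
#' @return Numeric vector of retract speeds (nm/s).
#' @export
defaultSpeedPanel <- function() c(50, 100, 200, 400, 800, 1600, 3200, 5000)
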