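#' Prefrontal 27-channel probe layout
#'
#' MNI coordinates and anatomical labels of the 27 measurement channels of the
#' 9-source / 9-detector prefrontal probe (3 cm source-detector separation,
#' middle channel of the most inferior row at Fpz).
#'
#' @return A data frame with columns `channel`, `mni_x`, `mni_y`, `mni_z`,
#'   `region`, `overlap` (fraction of the channel's projection inside the
#'   labeled region) and `brodmann`.
#' @export
#' @examples
#' head(probe_layout())
probe_layout <- function() {
  path <- system.file("extdata", "probe_layout_27ch.csv", package = "fnirsnet")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Default rostral/caudal channel partition
#'
#' Splits the probe's channels into a rostral (frontopolar, Brodmann area 10)
#' and a caudal (dorsal prefrontal, areas 8/9/46) block, the two-compartment
#' structure the synthetic generator uses for its block-correlated signals.
#'
#' @param n_channels Number of channels. For the packaged 27-channel probe the
#'   partition is derived from the Brodmann labels; for other channel counts
#'   the first half is labeled rostral.
#' @return A character vector of length `n_channels` with values `"rostral"`
#'   or `"caudal"`.
#' @export
default_block_assignment <- function(n_channels = 27L) {
  if (n_channels == 27L) {
    layout <- probe_layout()
    ifelse(layout$brodmann == 10, "rostral", "caudal")
  } else {
    rep(c("rostral", "caudal"),
        c(ceiling(n_channels / 2), floor(n_channels / 2)))
  }
}
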