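#' TMT 10-plex channel names
#'
#' The ten reporter channels of a TMT 10-plex kit, in mass order. The last
#' channel (131) conventionally carries the pooled "master mix" reference
#' sample.
#'
#' @return Character vector of length 10.
#' @export
tmt10_channels <- function() {
  c("126", "127N", "127C", "128N", "128C",
    "129N", "129C", "130N", "130C", "131")
}

# Column names of the reporter columns in a PSM table.
reporter_cols <- function(channels = tmt10_channels()) {
  paste0("channel_", channels)
}

#' PSM table column schema
#'
#' Fixed column order of a PSM-level table as read and written by this
#' package: identification columns followed by the ten reporter-intensity
#' columns. A missing reporter intensity is an empty field on disk and `NA`
#' in memory.
#'
#' @return Character vector of column names.
#' @export
psm_schema <- function() {
  c("spectrum_id", "peptide", "protein", "gene", "is_unique",
    "peptide_probability", "precursor_purity",
    "ms1_intensity", "ms2_summed_intensity",
    reporter_cols())
}

# Derive a stage-specific seed from a global seed in a documented,
# deterministic way. Stage indices are small integers; results stay
# within 32-bit integer range.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(stage) * 7919) %% 2147483647)
}
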