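#' Electrode montage specification
#'
#' A montage is the ordered set of channel labels of a recording, split into
#' brain (EEG) channels and non-brain auxiliary channels (ocular and cardiac
#' leads), plus the subset of labels that form the standard 32-channel
#' international 10/20 layout used for the low-density comparison.
#'
#' @param channel_names ordered character vector of all channel labels.
#' @param auxiliary_names labels treated as non-brain auxiliaries; must be a
#'   subset of `channel_names`.
#' @param standard32_names labels of the 10/20 standard subset; must be a
#'   subset of the EEG (non-auxiliary) channels.
#' @return An object of class `montage_spec`.
#' @seealso [default_montage()]
#' @export
montage_spec <- function(channel_names, auxiliary_names = character(),
                         standard32_names = character()) {
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names))
    stop_hfd("montage has duplicate channel labels: ",
             paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  if (!all(auxiliary_names %in% channel_names))
    stop_hfd("auxiliary_names must be a subset of channel_names")
  eeg <- setdiff(channel_names, auxiliary_names)
  if (!all(standard32_names %in% eeg))
    stop_hfd("standard32_names must be a subset of the non-auxiliary channels")
  structure(
    list(channel_names = channel_names,
         auxiliary_names = as.character(auxiliary_names),
         standard32_names = as.character(standard32_names)),
    class = "montage_spec")
}

#' @export
print.montage_spec <- function(x, ...) {
  cat(sprintf("<montage_spec> %d channels (%d EEG, %d auxiliary, %d in 10/20 subset)\n",
              length(x$channel_names), length(eeg_channels(x)),
              length(x$auxiliary_names), length(x$standard32_names)))
  invisible(x)
}

#' EEG (non-auxiliary) channels of a montage
#'
#' @param montage a [montage_spec()].
#' @return Character vector of brain-channel labels, in montage order.
#' @export
eeg_channels <- function(montage) {
  setdiff(montage$channel_names, montage$auxiliary_names)
}

# 32-channel extended 10/20 layout used as the low-density standard montage.
STANDARD32 <- c(
  "Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
  "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
  "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
  "PO3", "PO4", "O1", "Oz", "O2")

# Non-brain auxiliary leads recorded alongside the EEG: vertical/horizontal
# electro-oculogram and the cardiac channel.
AUXILIARY5 <- c("VEOGL", "HEOGL", "HEOGR", "VEOGU", "HEART")

#' Default 129-channel high-density montage
#'
#' 124 EEG channels (the 32 standard 10/20 labels plus 92 high-density filler
#' sites labelled `E1`..`E92`) and 5 auxiliary channels (`VEOGL`, `HEOGL`,
#' `HEOGR`, `VEOGU`, `HEART`). The exact vendor label set of a high-density
#' cap is not standardised, so labels are fully configurable through
#' [montage_spec()]; this default only fixes the counts and the 10/20 subset.
#'
#' @return A `montage_spec` with 129 channels.
#' @export
default_montage <- function() {
  fillers <- sprintf("E%d", seq_len(124 - length(STANDARD32)))
  montage_spec(channel_names = c(STANDARD32, fillers, AUXILIARY5),
               auxiliary_names = AUXILIARY5,
               standard32_names = STANDARD32)
}
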