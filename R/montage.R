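#' Canonical 16-lead 10-20 montage
#'
#' Channel order used throughout the package. Every reader reorders incoming
#' channels to this order, and the channel axis of every feature tensor and
#' importance report follows it.
#'
#' @format Character vector of 16 electrode names.
#' @export
EEG_MONTAGE <- c("FP1", "FP2", "F3", "F4", "F7", "T3", "T5", "C3",
                 "C4", "P3", "P4", "F8", "T4", "T6", "O1", "O2")

#' Brain region of each montage lead
#'
#' Frontal (FP1, FP2, F3, F4), left temporal (F7, T3, T5), parietal
#' (C3, C4, P3, P4), right temporal (F8, T4, T6), occipital (O1, O2).
#'
#' @format Named character vector keyed by electrode name.
#' @export
EEG_REGIONS <- c(
  FP1 = "frontal", FP2 = "frontal", F3 = "frontal", F4 = "frontal",
  F7 = "left temporal", T3 = "left temporal", T5 = "left temporal",
  C3 = "parietal", C4 = "parietal", P3 = "parietal", P4 = "parietal",
  F8 = "right temporal", T4 = "right temporal", T6 = "right temporal",
  O1 = "occipital", O2 = "occipital"
)

N_CHANNELS <- 16L

# Strip reference suffixes such as "FP1-A1", "EEG Fp1-REF" and case-fold,
# returning the canonical montage name or NA.
canonical_channel <- function(label) {
  x <- toupper(trimws(label))
  x <- sub("^EEG[ _]*", "", x)
  x <- sub("[-_ ](A1|A2|REF|LE|AVG|M1|M2|CZ)$", "", x)
  ifelse(x %in% EEG_MONTAGE, x, NA_character_)
}

# Map arbitrary labels to an index permutation into EEG_MONTAGE order.
# Errors name any missing montage lead.
montage_permutation <- function(labels) {
  canon <- canonical_channel(labels)
  idx <- match(EEG_MONTAGE, canon)
  if (anyNA(idx)) {
    missing <- EEG_MONTAGE[is.na(idx)]
    stop("missing montage channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  idx
}
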