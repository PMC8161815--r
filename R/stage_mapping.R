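#' Device type
#'
#' Consumer sleep trackers report one of two stage alphabets. "Type I"
#' devices distinguish REM (Wake-REM-Light-Deep, alphabet `DEV4`); "type II"
#' devices fold REM into deep sleep (Wake-Light-Deep, alphabet `DEV3`).
#'
#' @param kind `"I"` or `"II"`.
#' @return An object of class `"device_type"` with fields `kind` and
#'   `alphabet`.
#' @export
device_type <- function(kind = c("II", "I")) {
  kind <- match.arg(as.character(kind), c("II", "I"))
  structure(list(kind = kind,
                 alphabet = if (kind == "I") "DEV4" else "DEV3"),
            class = "device_type")
}

#' Categorize PSG stages to a device alphabet
#'
#' Relabels the five AASM stages onto the coarser alphabet a wearable
#' reports, so that PSG and device hypnograms become comparable epoch by
#' epoch. N1 and N2 are light sleep for both device types. N3 is deep sleep;
#' for type II devices (no REM channel) REM is counted as deep sleep too,
#' while type I devices keep REM distinct.
#'
#' @param psg a [hypnogram] with alphabet `PSG5`.
#' @param dev_type a [device_type] (or `"I"`/`"II"`).
#' @return A [hypnogram] in the device alphabet, same length, grid and
#'   source as `psg`.
#' @examples
#' h <- hypnogram(c("Wake", "N1", "N2", "N3", "REM"), source = "PSG",
#'                alphabet = "PSG5")
#' categorize_psg(h, "II")$stages  # REM becomes Deep
#' @export
categorize_psg <- function(psg, dev_type) {
  stopifnot(inherits(psg, "hypnogram"))
  if (!inherits(dev_type, "device_type")) dev_type <- device_type(dev_type)
  if (psg$alphabet != "PSG5")
    stop("categorize_psg expects a PSG5 hypnogram, got ", psg$alphabet)
  map <- if (dev_type$kind == "I")
    c(Wake = "Wake", N1 = "Light", N2 = "Light", N3 = "Deep", REM = "REM")
  else
    c(Wake = "Wake", N1 = "Light", N2 = "Light", N3 = "Deep", REM = "Deep")
  hypnogram(unname(map[psg$stages]), psg$epoch_duration, psg$start_time,
            psg$source, dev_type$alphabet)
}

#' Stage encoding for the mismatch-index algebra
#'
#' Assigns each stage of a device alphabet an integer code: Wake 1, Light 2,
#' Deep 4, and (four-stage alphabets only) a configurable REM code, 8 by
#' default. The defaults make the magnitudes of all stage-transition first
#' differences pairwise distinct, so a transition's stages can be recovered
#' from its delta. Wake always takes the smallest code.
#'
#' @param alphabet `"DEV3"` or `"DEV4"` (or a [device_type]).
#' @param rem_code integer code for REM in four-stage mode.
#' @return An object of class `"stage_encoding"`: a named integer vector of
#'   codes with attribute `alphabet`.
#' @export
stage_encoding <- function(alphabet = "DEV3", rem_code = 8L) {
  if (inherits(alphabet, "device_type")) alphabet <- alphabet$alphabet
  alphabet <- match.arg(alphabet, c("DEV3", "DEV4"))
  codes <- c(Wake = 1L, Light = 2L, Deep = 4L)
  if (alphabet == "DEV4") {
    rem_code <- as.integer(rem_code)
    if (is.na(rem_code) || rem_code <= 0)
      stop("rem_code must be a positive integer")
    codes <- c(codes, REM = rem_code)
  }
  if (anyDuplicated(codes)) stop("stage codes must be pairwise distinct")
  if (codes[["Wake"]] != min(codes)) stop("Wake must carry the smallest code")
  structure(codes, alphabet = alphabet, class = "stage_encoding")
}

#' Encode a hypnogram as an integer sequence
#'
#' @param h a [hypnogram] whose alphabet is covered by `enc`.
#' @param enc a [stage_encoding].
#' @return Integer vector, one code per epoch.
#' @export
encode_stages <- function(h, enc) {
  stopifnot(inherits(h, "hypnogram"), inherits(enc, "stage_encoding"))
  missing_codes <- setdiff(unique(h$stages), names(enc))
  if (length(missing_codes))
    stop("no integer code for stage(s): ", paste(missing_codes, collapse = ", "))
  unname(unclass(enc)[h$stages])
}
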