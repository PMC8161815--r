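#' Stage alphabets
#'
#' The three stage alphabets handled by the package:
#' * `PSG5`: the five AASM stages scored from polysomnography
#'   (Wake, N1, N2, N3, REM).
#' * `DEV4`: the four-stage alphabet of "type I" wearables that report REM
#'   distinctly (Wake, Light, Deep, REM).
#' * `DEV3`: the three-stage alphabet of "type II" wearables
#'   (Wake, Light, Deep).
#'
#' @format A named list of character vectors.
#' @export
stage_alphabets <- list(
  PSG5 = c("Wake", "N1", "N2", "N3", "REM"),
  DEV4 = c("Wake", "Light", "Deep", "REM"),
  DEV3 = c("Wake", "Light", "Deep")
)

#' Parse a clock time to seconds since midnight
#'
#' @param x character `"hh:mm:ss"` (or `"hh:mm"`), or a numeric already in
#'   seconds (returned unchanged).
#' @return numeric seconds since midnight, in `[0, 86400)`.
#' @keywords internal
parse_clock <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.numeric(x)) {
    if (any(x < 0 | x >= 86400)) stop("clock time in seconds must be in [0, 86400)")
    return(as.numeric(x))
  }
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (!length(p) %in% c(2L, 3L) || anyNA(suppressWarnings(as.numeric(p))))
      stop("cannot parse clock time: expected hh:mm:ss, got '",
           paste(p, collapse = ":"), "'")
    p <- as.numeric(p)
    if (length(p) == 2L) p <- c(p, 0)
    if (p[1] < 0 || p[1] > 23 || p[2] < 0 || p[2] > 59 || p[3] < 0 || p[3] >= 60)
      stop("clock time out of range: ", paste(p, collapse = ":"))
    p[1] * 3600 + p[2] * 60 + p[3]
  }, numeric(1))
}

#' Format seconds since midnight as hh:mm:ss
#'
#' @param sec numeric seconds (wrapped modulo 24 h).
#' @return character `"hh:mm:ss"`.
#' @export
format_clock <- function(sec) {
  sec <- round(sec) %% 86400
  sprintf("%02d:%02d:%02d", sec %/% 3600, (sec %% 3600) %/% 60, sec %% 60)
}

#' Construct a hypnogram
#'
#' A hypnogram is an epoch-indexed sequence of sleep-stage labels, together
#' with the epoch duration, the clock time of epoch 0, the scoring source and
#' the stage alphabet. Epochs are indexed from 0; epoch `i` spans the
#' half-open clock interval
#' `[start_time + i * epoch_duration, start_time + (i + 1) * epoch_duration)`.
#'
#' @param stages character vector of stage labels, one per epoch (length >= 1).
#' @param epoch_duration epoch length in seconds (default 30).
#' @param start_time clock time of epoch 0 as `"hh:mm:ss"` or seconds since
#'   midnight; `NULL` if unknown (synchronization then refuses the input).
#' @param source `"PSG"` or `"device"`.
#' @param alphabet one of `"PSG5"`, `"DEV4"`, `"DEV3"` (see [stage_alphabets]).
#' @return An object of class `"hypnogram"`.
#' @examples
#' h <- hypnogram(c("Wake", "N1", "N2"), start_time = "23:00:00",
#'                source = "PSG", alphabet = "PSG5")
#' length(h$stages)
#' @export
hypnogram <- function(stages, epoch_duration = 30, start_time = NULL,
                      source = c("PSG", "device"),
                      alphabet = c("PSG5", "DEV4", "DEV3")) {
  source <- match.arg(source)
  alphabet <- match.arg(alphabet)
  stages <- as.character(stages)
  if (length(stages) < 1L) stop("a hypnogram needs at least one epoch")
  if (anyNA(stages)) stop("stage labels must not be NA")
  legal <- stage_alphabets[[alphabet]]
  bad <- setdiff(unique(stages), legal)
  if (length(bad))
    stop("stage label(s) outside alphabet ", alphabet, ": ",
         paste(bad, collapse = ", "))
  if (!is.numeric(epoch_duration) || length(epoch_duration) != 1L ||
      epoch_duration <= 0)
    stop("epoch_duration must be a positive number of seconds")
  structure(
    list(stages = stages,
         epoch_duration = as.numeric(epoch_duration),
         start_time = parse_clock(start_time),
         source = source,
         alphabet = alphabet),
    class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %gs, source=%s, alphabet=%s%s\n",
              length(x$stages), x$epoch_duration, x$source, x$alphabet,
              if (!is.null(x$start_time))
                paste0(", start=", format_clock(x$start_time)) else ""))
  tab <- table(factor(x$stages, levels = stage_alphabets[[x$alphabet]]))
  print(tab)
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' Extract a contiguous window of a hypnogram
#'
#' @param h a [hypnogram].
#' @param from,to 0-based epoch indices, inclusive on both ends.
#' @return A [hypnogram] covering epochs `from..to`, with `start_time`
#'   advanced accordingly.
#' @export
hypnogram_window <- function(h, from, to) {
  stopifnot(inherits(h, "hypnogram"))
  n <- length(h$stages)
  if (from < 0 || to > n - 1 || from > to)
    stop("window [", from, ", ", to, "] outside hypnogram of ", n, " epochs")
  st <- if (is.null(h$start_time)) NULL else
    (h$start_time + from * h$epoch_duration) %% 86400
  hypnogram(h$stages[(from + 1):(to + 1)], h$epoch_duration, st,
            h$source, h$alphabet)
}

#' Read a hypnogram from a file
#'
#' Two plain-text formats are supported:
#'
#' * `"csv"` — header `epoch,stage` or `time,stage`. With a `time` column
#'   (hh:mm:ss), timestamps must advance by positive whole multiples of
#'   `epoch_duration`; a record whose successor is `k` epochs later is
#'   expanded to `k` epochs of its stage, and the final record contributes
#'   one epoch. Metadata comment lines (`#key=value` for `epoch_duration`,
#'   `start_time`, `source`, `alphabet`), as written by [write_hypnogram()],
#'   are honoured; explicit arguments override them.
#' * `"annotations"` — header `onset,duration,stage` with onset/duration in
#'   seconds from `start_time` (the layout of an EDF+ annotation track
#'   exported to text). Annotations are rasterized onto the epoch grid; an
#'   epoch takes the stage annotated at its start.
#'
#' @param path file to read.
#' @param format `"csv"` or `"annotations"`.
#' @param alphabet target stage alphabet; `NULL` to take it from file
#'   metadata.
#' @param label_map optional named character vector mapping vendor stage
#'   strings to alphabet labels (e.g. `c(W = "Wake", LS = "Light")`). Labels
#'   already in the alphabet pass through; anything else is an error.
#' @param epoch_duration epoch length in seconds; `NULL` for metadata/default.
#' @param source `"PSG"` or `"device"`; `NULL` for metadata/default.
#' @param start_time clock time of epoch 0; `NULL` takes the first `time`
#'   value or file metadata.
#' @return A validated [hypnogram].
#' @export
read_hypnogram <- function(path, format = c("csv", "annotations"),
                           alphabet = NULL, label_map = NULL,
                           epoch_duration = NULL, source = NULL,
                           start_time = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_meta_comments(path)
  epoch_duration <- epoch_duration %||%
    (if (!is.null(meta$epoch_duration)) as.numeric(meta$epoch_duration)) %||% 30
  source <- source %||% meta$source %||% "device"
  alphabet <- alphabet %||% meta$alphabet %||%
    stop("alphabet neither given nor recorded in ", path)
  start_time <- start_time %||% meta$start_time

  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                        stringsAsFactors = FALSE)
  if (format == "csv") {
    if (!("stage" %in% names(df)) ||
        !any(c("epoch", "time") %in% names(df)))
      stop("CSV must have columns epoch,stage or time,stage")
    stages <- map_labels(as.character(df$stage), label_map, alphabet)
    if ("time" %in% names(df)) {
      tsec <- parse_clock(df$time)
      # unwrap past-midnight times into a monotone axis
      tlin <- tsec + 86400 * cumsum(c(0, diff(tsec) < 0))
      steps <- diff(tlin)
      # a backward clock step reads as a forward step across midnight; only
      # accept that reading for steps under 12 h, else the file is disordered
      if (any(steps <= 0) || any(steps >= 43200))
        stop("non-monotonic timestamps in ", path)
      k <- steps / epoch_duration
      if (any(abs(k - round(k)) > 1e-9))
        stop("timestamp steps are not whole multiples of epoch_duration")
      reps <- c(round(k), 1)
      stages <- rep(stages, times = reps)
      start_time <- start_time %||% tsec[1]
    }
  } else {
    need <- c("onset", "duration", "stage")
    if (!all(need %in% names(df)))
      stop("annotation file must have columns onset,duration,stage")
    if (is.unsorted(df$onset, strictly = FALSE))
      stop("non-monotonic annotation onsets in ", path)
    labels <- map_labels(as.character(df$stage), label_map, alphabet)
    total <- max(df$onset + df$duration)
    n <- floor(total / epoch_duration)          # partial final epoch dropped
    if (n < 1) stop("annotations cover less than one epoch")
    at <- (seq_len(n) - 1) * epoch_duration
    idx <- findInterval(at, df$onset)
    if (any(idx == 0)) stop("annotation track does not start at onset 0")
    covered <- at < (df$onset + df$duration)[idx]
    if (!all(covered)) stop("annotation gaps at epoch(s) ",
                            paste(which(!covered) - 1, collapse = ", "))
    stages <- labels[idx]
  }
  hypnogram(stages, epoch_duration, start_time, source, alphabet)
}

map_labels <- function(x, label_map, alphabet) {
  if (!is.null(label_map)) {
    hit <- x %in% names(label_map)
    x[hit] <- unname(label_map[x[hit]])
  }
  legal <- stage_alphabets[[alphabet]]
  bad <- setdiff(unique(x), legal)
  if (length(bad))
    stop("unmapped stage label(s) for alphabet ", alphabet, ": ",
         paste(bad, collapse = ", "),
         " (supply a label_map entry for each)")
  x
}

read_meta_comments <- function(path) {
  head_lines <- readLines(path, n = 10L, warn = FALSE)
  meta_lines <- grep("^#\\s*\\w+\\s*=", head_lines, value = TRUE)
  out <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub("=.*", "", kv))
    out[[key]] <- trimws(sub("^[^=]*=", "", kv))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a hypnogram to CSV
#'
#' Writes metadata comment lines (`#epoch_duration=`, `#start_time=`,
#' `#source=`, `#alphabet=`) followed by `epoch,stage` rows, so that
#' [read_hypnogram()] reproduces the object exactly.
#'
#' @param h a [hypnogram].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#epoch_duration=%g", h$epoch_duration), con)
  if (!is.null(h$start_time))
    writeLines(paste0("#start_time=", format_clock(h$start_time)), con)
  writeLines(paste0("#source=", h$source), con)
  writeLines(paste0("#alphabet=", h$alphabet), con)
  writeLines("epoch,stage", con)
  writeLines(sprintf("%d,%s", seq_along(h$stages) - 1L, h$stages), con)
  invisible(path)
}

#' Resample a hypnogram to a different epoch duration
#'
#' Coarsening (new duration a whole multiple of the old) takes the majority
#' label in each block, ties going to the earlier epoch; refining (old a
#' whole multiple of new) repeats labels. Used to put two hypnograms on a
#' common grid before alignment without inventing stages.
#'
#' @param h a [hypnogram].
#' @param new_duration target epoch duration in seconds.
#' @return A [hypnogram] with `epoch_duration = new_duration`.
#' @export
resample_hypnogram <- function(h, new_duration) {
  stopifnot(inherits(h, "hypnogram"))
  old <- h$epoch_duration
  if (new_duration == old) return(h)
  if (new_duration > old) {
    k <- new_duration / old
    if (abs(k - round(k)) > 1e-9)
      stop("target duration must be a whole multiple of the current one")
    k <- round(k)
    n_new <- length(h$stages) %/% k            # partial final block dropped
    if (n_new < 1) stop("hypnogram shorter than one coarse epoch")
    stages <- vapply(seq_len(n_new), function(j) {
      block <- h$stages[((j - 1) * k + 1):(j * k)]
      counts <- table(block)
      winners <- names(counts)[counts == max(counts)]
      block[block %in% winners][1]             # earliest of the tied labels
    }, character(1))
  } else {
    k <- old / new_duration
    if (abs(k - round(k)) > 1e-9)
      stop("current duration must be a whole multiple of the target one")
    stages <- rep(h$stages, each = round(k))
  }
  hypnogram(stages, new_duration, h$start_time, h$source, h$alphabet)
}

#' Synchronize a PSG and a device hypnogram by clock time
#'
#' Aligns the device recording onto the PSG epoch grid using the two start
#' clock times, truncates both sequences to the overlapping interval and
#' returns them as an aligned pair. Offsets that are not a whole number of
#' epochs are rounded to the nearest epoch. Hypnograms with different epoch
#' durations are first resampled to the coarser duration (see
#' [resample_hypnogram()]). Start times less than 12 h apart on the clock
#' are taken to be the same night (recordings may cross midnight).
#'
#' @param psg,device [hypnogram] objects carrying `start_time`.
#' @return An object of class `"aligned_pair"`: list with elements `psg`,
#'   `device` (equal-length hypnograms on the PSG grid) and `n_epochs`.
#' @export
synchronize <- function(psg, device) {
  stopifnot(inherits(psg, "hypnogram"), inherits(device, "hypnogram"))
  if (is.null(psg$start_time) || is.null(device$start_time))
    stop("both hypnograms must carry a start_time for synchronization")
  dur <- max(psg$epoch_duration, device$epoch_duration)
  if (psg$epoch_duration != dur) psg <- resample_hypnogram(psg, dur)
  if (device$epoch_duration != dur) device <- resample_hypnogram(device, dur)

  off_sec <- (device$start_time - psg$start_time) %% 86400
  if (off_sec > 43200) off_sec <- off_sec - 86400   # same-night convention
  off <- round(off_sec / dur)                        # nearest-epoch rounding

  n_p <- length(psg$stages)
  n_d <- length(device$stages)
  lo <- max(0L, off)                 # first PSG epoch covered by both
  hi <- min(n_p - 1L, off + n_d - 1L)
  if (lo > hi) stop("no temporal overlap between the two hypnograms")

  psg_cut <- hypnogram_window(psg, lo, hi)
  dev_cut <- hypnogram(device$stages[(lo - off + 1):(hi - off + 1)], dur,
                       psg_cut$start_time, device$source, device$alphabet)
  aligned_pair(psg_cut, dev_cut)
}

#' Construct an aligned pair
#'
#' @param psg,device equal-length [hypnogram]s on a common epoch grid.
#' @return An object of class `"aligned_pair"`.
#' @export
aligned_pair <- function(psg, device) {
  stopifnot(inherits(psg, "hypnogram"), inherits(device, "hypnogram"))
  if (length(psg$stages) != length(device$stages))
    stop("aligned hypnograms must have identical length")
  if (psg$epoch_duration != device$epoch_duration)
    stop("aligned hypnograms must share an epoch duration")
  if (!is.null(psg$start_time) && !is.null(device$start_time) &&
      psg$start_time != device$start_time)
    stop("aligned hypnograms must share a start time")
  structure(list(psg = psg, device = device,
                 n_epochs = length(psg$stages)),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("<aligned_pair> %d epochs x %gs (PSG %s vs device %s)\n",
              x$n_epochs, x$psg$epoch_duration, x$psg$alphabet,
              x$device$alphabet))
  invisible(x)
}
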