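# Wake-sleep and sleep-architecture features of a single hypnogram.
# All wake/sleep distinctions depend only on stage == "Wake", so these
# features are invariant under PSG5 -> device-alphabet categorization.

is_sleep <- function(stages) stages != "Wake"

light_stages <- c("N1", "N2", "Light")
deep_stages  <- c("N3", "Deep")

no_sleep_error <- function() {
  stop(structure(class = c("no_sleep_error", "error", "condition"),
                 list(message = "hypnogram contains no sleep epochs",
                      call = sys.call(-1))))
}

#' Sleep onset
#'
#' The first epoch scored as any sleep stage (N1/N2/N3/REM, or
#' Light/Deep/REM in device alphabets).
#'
#' @param h a [hypnogram].
#' @return List with `epoch` (0-based index) and `clock` (`"hh:mm:ss"`, or
#'   `NA` when the hypnogram has no start time).
#' @seealso [extract_features()]
#' @export
sleep_onset <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  idx <- which(is_sleep(h$stages))
  if (!length(idx)) no_sleep_error()
  i0 <- idx[1] - 1L                                  # 0-based
  clock <- if (is.null(h$start_time)) NA_character_ else
    format_clock(h$start_time + i0 * h$epoch_duration)
  list(epoch = i0, clock = clock)
}

last_sleep_epoch <- function(h) {
  idx <- which(is_sleep(h$stages))
  if (!length(idx)) no_sleep_error()
  idx[length(idx)] - 1L                              # 0-based
}

#' Sleep period time (SPT)
#'
#' Minutes from sleep onset to the last sleep epoch, inclusive of the last
#' sleep epoch's own duration (so a single sleep epoch gives 0.5 min at the
#' standard 30-s epoch).
#'
#' @param h a [hypnogram] with at least one sleep epoch.
#' @return Minutes (numeric).
#' @export
sleep_period_time <- function(h) {
  so <- sleep_onset(h)$epoch
  lsp <- last_sleep_epoch(h)
  (lsp - so + 1) * h$epoch_duration / 60
}

#' Total sleep time (TST) and its stage components
#'
#' Minutes actually asleep within the sleep period, split into light
#' (N1/N2 or Light), deep (N3 or Deep) and REM components:
#' `TST = TLST + TDST + TRST`. `TRST` is 0 for alphabets without REM.
#'
#' @param h a [hypnogram] with at least one sleep epoch.
#' @return List with `TST`, `TLST`, `TDST`, `TRST` in minutes.
#' @export
total_sleep_time <- function(h) {
  so <- sleep_onset(h)$epoch
  lsp <- last_sleep_epoch(h)
  inside <- h$stages[(so + 1):(lsp + 1)]
  mins <- h$epoch_duration / 60
  tlst <- sum(inside %in% light_stages) * mins
  tdst <- sum(inside %in% deep_stages) * mins
  trst <- sum(inside == "REM") * mins
  list(TST = tlst + tdst + trst, TLST = tlst, TDST = tdst, TRST = trst)
}

#' Sleep efficiency (SE)
#'
#' @param h a [hypnogram] with at least one sleep epoch.
#' @return Percent of the sleep period actually spent asleep,
#'   `100 * TST / SPT`.
#' @export
sleep_efficiency <- function(h) {
  spt <- sleep_period_time(h)
  if (spt <= 0) stop("sleep period time is zero")
  100 * total_sleep_time(h)$TST / spt
}

#' Wakefulness after sleep onset (WASO)
#'
#' `WASO = SPT - TST + WAS`, where WAS is wake time between the last sleep
#' epoch and lights-on. Hypnogram-only input does not record lights-on, so
#' WAS defaults to 0; supply `lights_on` to include wake scored between the
#' last sleep epoch and that clock time.
#'
#' @param h a [hypnogram] with at least one sleep epoch.
#' @param lights_on optional clock time (`"hh:mm:ss"` or seconds); must not
#'   precede the end of the last sleep epoch.
#' @return Minutes (numeric).
#' @export
waso <- function(h, lights_on = NULL) {
  spt <- sleep_period_time(h)
  tst <- total_sleep_time(h)$TST
  was <- 0
  if (!is.null(lights_on)) {
    if (is.null(h$start_time))
      stop("lights_on given but the hypnogram has no start_time")
    lo <- parse_clock(lights_on)
    lsp_end <- h$start_time + (last_sleep_epoch(h) + 1) * h$epoch_duration
    lo_lin <- h$start_time + ((lo - h$start_time) %% 86400)  # same-night clock
    if (lo_lin < lsp_end) stop("lights_on precedes the last sleep epoch")
    after <- h$stages[seq_along(h$stages) - 1L >= last_sleep_epoch(h) + 1L]
    n_after <- min(length(after), floor((lo_lin - lsp_end) / h$epoch_duration))
    if (n_after > 0)
      was <- sum(after[seq_len(n_after)] == "Wake") * h$epoch_duration / 60
  }
  spt - tst + was
}

#' Stage percentages of total sleep time
#'
#' @param h a [hypnogram] with at least one sleep epoch.
#' @return List with `PLS`, `PDS`, `PRS`: percent of TST spent in light,
#'   deep and REM sleep. `PRS` is `NA` for three-stage alphabets, where REM
#'   is not observable.
#' @export
stage_percentages <- function(h) {
  tt <- total_sleep_time(h)
  if (tt$TST <= 0) stop("total sleep time is zero")
  list(PLS = 100 * tt$TLST / tt$TST,
       PDS = 100 * tt$TDST / tt$TST,
       PRS = if ("REM" %in% stage_alphabets[[h$alphabet]])
         100 * tt$TRST / tt$TST else NA_real_)
}

#' Extract the full wake-sleep feature set of a night
#'
#' Computes sleep onset (SO), sleep period time (SPT), total sleep time
#' (TST) with its light/deep/REM components, sleep efficiency (SE),
#' wakefulness after sleep onset (WASO) and the stage percentages
#' (PLS/PDS/PRS) from one hypnogram.
#'
#' @param h a [hypnogram].
#' @param lights_on optional lights-on clock time, passed to [waso()].
#' @return An object of class `"sleep_features"`: a list with fields
#'   `SO_epoch`, `SO_clock`, `SO_min` (onset in minutes from recording
#'   start), `LSP_clock`, `SPT`, `TST`, `TLST`, `TDST`, `TRST`, `SE`,
#'   `WASO`, `PLS`, `PDS`, `PRS`.
#' @examples
#' h <- hypnogram(c("Wake", "Light", "Light", "Deep", "Wake"),
#'                start_time = "23:00:00", alphabet = "DEV3")
#' extract_features(h)$SE
#' @export
extract_features <- function(h, lights_on = NULL) {
  stopifnot(inherits(h, "hypnogram"))
  so <- sleep_onset(h)
  lsp <- last_sleep_epoch(h)
  tt <- total_sleep_time(h)
  pct <- stage_percentages(h)
  structure(
    list(SO_epoch = so$epoch,
         SO_clock = so$clock,
         SO_min = so$epoch * h$epoch_duration / 60,
         LSP_clock = if (is.null(h$start_time)) NA_character_ else
           format_clock(h$start_time + lsp * h$epoch_duration),
         SPT = sleep_period_time(h),
         TST = tt$TST, TLST = tt$TLST, TDST = tt$TDST, TRST = tt$TRST,
         SE = sleep_efficiency(h),
         WASO = waso(h, lights_on),
         PLS = pct$PLS, PDS = pct$PDS, PRS = pct$PRS),
    class = "sleep_features")
}

#' @export
print.sleep_features <- function(x, ...) {
  cat("<sleep_features>\n")
  cat(sprintf("  SO %s (epoch %d, %.1f min)  SPT %.1f min  TST %.1f min\n",
              x$SO_clock, x$SO_epoch, x$SO_min, x$SPT, x$TST))
  cat(sprintf("  SE %.1f%%  WASO %.1f min  PLS %.1f%%  PDS %.1f%%  PRS %s\n",
              x$SE, x$WASO, x$PLS, x$PDS,
              if (is.na(x$PRS)) "-" else sprintf("%.1f%%", x$PRS)))
  invisible(x)
}

#' Flatten a feature set to a one-row data frame
#'
#' @param x a `"sleep_features"` object.
#' @param ... unused.
#' @return A one-row `data.frame` suitable for rbinding into a per-night
#'   report table.
#' @export
as.data.frame.sleep_features <- function(x, ...) {
  data.frame(SO_epoch = x$SO_epoch, SO_clock = x$SO_clock, SO_min = x$SO_min,
             LSP_clock = x$LSP_clock, SPT = x$SPT, TST = x$TST,
             TLST = x$TLST, TDST = x$TDST, TRST = x$TRST, SE = x$SE,
             WASO = x$WASO, PLS = x$PLS, PDS = x$PDS, PRS = x$PRS,
             stringsAsFactors = FALSE)
}
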