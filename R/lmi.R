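# Localized mismatch index (LMI): chronological, epoch-by-epoch scoring of
# sleep-stage-transition agreement between a device and PSG hypnogram.
#
# With stages encoded Wake=1, Light=2, Deep=4, the first differences of the
# encoded sequence identify each stage transition uniquely by magnitude and
# direction (W-L 1, W-D 3, L-D 2 and their negatives), and the product of the
# PSG and device deltas at an epoch boundary is the localized mismatch index:
# positive perfect squares (1, 4, 9) mean both scorers saw the same
# transition; every other value is a specific kind of disagreement.

lmi_classes <- c("correct_wake", "correct_sleep",
                 "incorrect_wake", "incorrect_sleep")

#' First differences of an encoded hypnogram
#'
#' Delta `i` (0-based, `i` from 0 to n-2) is the stage-code change across the
#' boundary between epochs `i` and `i+1`.
#'
#' @param codes integer stage codes, length >= 2.
#' @return Integer vector of length `length(codes) - 1`.
#' @export
transition_deltas <- function(codes) {
  if (length(codes) < 2L)
    stop("need at least two epochs to form transition deltas")
  diff(as.integer(codes))
}

# Deltas whose transition has Wake as an endpoint, derived from the encoding.
# With distinct positive codes and Wake minimal these are +/- (code - wake);
# the constructor guarantees they cannot collide with sleep-sleep deltas for
# the default codes, and we refuse encodings where they do.
wake_deltas <- function(enc) {
  codes <- unclass(enc)
  w <- codes[["Wake"]]
  others <- codes[setdiff(names(codes), "Wake")]
  wd <- unique(abs(others - w))
  sd_ <- if (length(others) > 1)
    unique(abs(as.vector(outer(others, others, "-")))) else integer(0)
  sd_ <- setdiff(sd_, 0L)
  if (length(intersect(wd, sd_)))
    stop("encoding makes a wake transition indistinguishable from a ",
         "sleep-sleep transition; choose different codes")
  wd
}

#' Classify one transition-epoch delta pair
#'
#' Assigns the four-way agreement class to the pair of first differences at
#' one epoch boundary:
#'
#' * both deltas equal (and nonzero): the device reproduced the PSG
#'   transition — `correct_wake` if the transition has Wake as an endpoint,
#'   else `correct_sleep`;
#' * exactly one delta zero (a missed or spurious transition): incorrect;
#'   the wake/sleep subclass follows the transition that did occur;
#' * both nonzero but different: incorrect; the subclass is
#'   `incorrect_sleep` when the two scorers agree about Wake involvement
#'   and direction but differ in sleep depth (e.g. Wake-to-Light vs
#'   Wake-to-Deep) or when neither transition touches Wake, and
#'   `incorrect_wake` otherwise.
#'
#' For the three-stage encoding this rule reproduces exactly the grouping of
#' the delta product: correct wake \{1, 9\}, correct sleep \{4\}, incorrect
#' sleep \{3, -4\}, incorrect wake \{2, 6, -1, -2, -3, -6, -9\}. It extends
#' unchanged to four-stage (REM-reporting) devices, where products of a
#' single REM code would collide and the delta pair, not the product, is
#' authoritative.
#'
#' @param delta_psg,delta_device integer first differences (not both zero).
#' @param enc the [stage_encoding] both sequences were encoded with.
#' @return One of `"correct_wake"`, `"correct_sleep"`, `"incorrect_wake"`,
#'   `"incorrect_sleep"`.
#' @export
classify_lmi <- function(delta_psg, delta_device, enc) {
  if (delta_psg == 0 && delta_device == 0)
    stop("both deltas zero: not a transition epoch (restrict to the set A)")
  wd <- wake_deltas(enc)
  wake_p <- abs(delta_psg) %in% wd
  wake_w <- abs(delta_device) %in% wd
  if (delta_psg == delta_device)
    return(if (wake_p) "correct_wake" else "correct_sleep")
  if (delta_psg == 0 || delta_device == 0) {
    nz_wake <- if (delta_psg == 0) wake_w else wake_p
    return(if (nz_wake) "incorrect_wake" else "incorrect_sleep")
  }
  if (!wake_p && !wake_w) return("incorrect_sleep")
  if (wake_p && wake_w && sign(delta_psg) == sign(delta_device))
    return("incorrect_sleep")        # same wake<->sleep move, depth wrong
  "incorrect_wake"
}

#' Localized mismatch index over an aligned night
#'
#' Encodes both hypnograms, forms their first differences, finds the
#' transition-epoch set `A` (boundaries where at least one scorer changes
#' stage), computes the index `LMI_i = delta_device_i * delta_psg_i` on `A`,
#' classifies every member of `A`, and summarizes the class rates.
#'
#' @param pair an [aligned_pair]; the PSG member must already be categorized
#'   to the device alphabet (see [categorize_psg()]).
#' @param enc a [stage_encoding] covering the common alphabet; defaults to
#'   the standard encoding of the device alphabet.
#' @return An object of class `"lmi_result"`: list with
#'   `deltas_psg`, `deltas_device` (length n-1), `transition_set` (sorted
#'   0-based boundary indices), `lmi_values`, `classes` (parallel to
#'   `transition_set`), and `rates` (see [summarize_rates()]).
#' @examples
#' psg <- hypnogram(c("Wake", "Deep"), alphabet = "DEV3", source = "PSG")
#' dev <- hypnogram(c("Wake", "Deep"), alphabet = "DEV3", source = "device")
#' lmi_sequence(aligned_pair(psg, dev))$lmi_values  # 9: correct W-D
#' @export
lmi_sequence <- function(pair, enc = NULL) {
  stopifnot(inherits(pair, "aligned_pair"))
  if (pair$psg$alphabet != pair$device$alphabet)
    stop("categorize the PSG hypnogram to the device alphabet first ",
         "(alphabets: ", pair$psg$alphabet, " vs ", pair$device$alphabet, ")")
  enc <- enc %||% stage_encoding(pair$psg$alphabet)
  if (attr(enc, "alphabet") != pair$psg$alphabet)
    stop("encoding is for alphabet ", attr(enc, "alphabet"),
         ", pair uses ", pair$psg$alphabet)
  yp <- encode_stages(pair$psg, enc)
  yw <- encode_stages(pair$device, enc)
  dp <- transition_deltas(yp)
  dw <- transition_deltas(yw)
  A <- which(dp != 0L | dw != 0L)                 # 1-based positions
  classes <- vapply(A, function(i) classify_lmi(dp[i], dw[i], enc),
                    character(1))
  res <- structure(
    list(deltas_psg = dp,
         deltas_device = dw,
         transition_set = A - 1L,                 # 0-based boundary indices
         lmi_values = dw[A] * dp[A],
         classes = classes,
         encoding = enc,
         n_epochs = pair$n_epochs,
         rates = NULL),
    class = "lmi_result")
  res$rates <- tryCatch(summarize_rates(res), empty_transition_set = function(e) NULL)
  res
}

#' Correct/incorrect transition rates
#'
#' Percent of transition epochs in each agreement class, over the transition
#' set `A` (epoch boundaries where at least one scorer changes stage).
#' The four class percentages sum to 100, as do overall correct + incorrect.
#'
#' @param result an `"lmi_result"` from [lmi_sequence()].
#' @return Named list: `n_transitions`, the four class percentages, and
#'   `correct` / `incorrect` overall percentages.
#' @export
summarize_rates <- function(result) {
  stopifnot(inherits(result, "lmi_result"))
  nA <- length(result$transition_set)
  if (nA == 0L)
    stop(structure(class = c("empty_transition_set", "error", "condition"),
                   list(message = "no transition epochs: rates undefined",
                        call = sys.call(-1))))
  counts <- table(factor(result$classes, levels = lmi_classes))
  pct <- as.list(100 * as.numeric(counts) / nA)
  names(pct) <- lmi_classes
  c(list(n_transitions = nA), pct,
    list(correct = pct$correct_wake + pct$correct_sleep,
         incorrect = pct$incorrect_wake + pct$incorrect_sleep))
}

#' @export
print.lmi_result <- function(x, ...) {
  cat(sprintf("<lmi_result> %d epochs, |A| = %d transition epochs\n",
              x$n_epochs, length(x$transition_set)))
  if (!is.null(x$rates))
    cat(sprintf("  correct %.1f%% (wake %.1f%%, sleep %.1f%%)  incorrect %.1f%%\n",
                x$rates$correct, x$rates$correct_wake, x$rates$correct_sleep,
                x$rates$incorrect))
  invisible(x)
}

#' Flatten an LMI result to a per-transition data frame
#'
#' @param x an `"lmi_result"`.
#' @param ... unused.
#' @return `data.frame` with one row per transition epoch: `epoch` (0-based
#'   boundary index), `delta_psg`, `delta_device`, `lmi`, `class`.
#' @export
as.data.frame.lmi_result <- function(x, ...) {
  A <- x$transition_set
  data.frame(epoch = A,
             delta_psg = x$deltas_psg[A + 1L],
             delta_device = x$deltas_device[A + 1L],
             lmi = x$lmi_values,
             class = x$classes,
             stringsAsFactors = FALSE)
}

#' Table of all localized mismatch index values
#'
#' Evaluates the index for every ordered pair of legal single-step stage
#' transitions of an alphabet: entry (r, c) is the delta product when PSG
#' scores transition r and the device scores transition c. For the
#' three-stage alphabet this is the full 6 x 6 value table, symmetric with
#' diagonal \{1, 4, 9\}.
#'
#' @param enc a [stage_encoding].
#' @return Numeric matrix with transition names (`"W-L"`, `"W-D"`, ...) as
#'   dimnames and attribute `deltas` (the per-transition first differences).
#' @export
lmi_table <- function(enc = stage_encoding("DEV3")) {
  codes <- unclass(enc)
  short <- c(Wake = "W", Light = "L", Deep = "D", REM = "R")
  st <- names(codes)
  prs <- expand.grid(from = st, to = st, stringsAsFactors = FALSE)
  prs <- prs[prs$from != prs$to, ]
  # canonical order: ascending-code pairs first (W-L, W-D, L-D, ...), then
  # their reversals, matching the conventional listing
  up <- prs[codes[prs$from] < codes[prs$to], ]
  up <- up[order(codes[up$from], codes[up$to]), ]
  down <- data.frame(from = up$to, to = up$from)
  down <- down[order(codes[down$from] - codes[down$to]), ]  # -1, -2, -3, ...
  prs <- rbind(up, down)
  deltas <- codes[prs$to] - codes[prs$from]
  nm <- paste(short[prs$from], short[prs$to], sep = "-")
  tab <- outer(deltas, deltas)
  dimnames(tab) <- list(PSG = nm, device = nm)
  attr(tab, "deltas") <- stats::setNames(as.integer(deltas), nm)
  tab
}
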