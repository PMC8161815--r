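# Interrater gating, epoch-by-epoch confusion metrics, and the paired
# feature-comparison suite.

#' Fleiss' kappa for multi-rater stage agreement
#'
#' Chance-corrected agreement among m >= 2 raters assigning each epoch one
#' category: `kappa = (Pbar - Pbar_e) / (1 - Pbar_e)`, where `Pbar` is the
#' mean over epochs of the pairwise rater agreement and `Pbar_e` the chance
#' agreement implied by the marginal category frequencies. Used to gate PSG
#' hypnograms scored by several physicians before device comparison.
#'
#' @param ratings an epochs x raters matrix (or data frame) of stage labels.
#' @return `kappa` (numeric scalar). Total agreement gives 1. When every
#'   rating falls in a single category, chance agreement is 1 and the
#'   statistic is undefined except in the total-agreement case; that
#'   degenerate disagreeing case raises an error of class
#'   `"degenerate_kappa"`.
#' @examples
#' m <- cbind(r1 = c("Wake", "N2", "N2"), r2 = c("Wake", "N2", "N3"),
#'            r3 = c("Wake", "N2", "N2"))
#' fleiss_kappa(m)
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2L) stop("Fleiss' kappa needs at least two raters")
  if (nrow(ratings) < 1L) stop("Fleiss' kappa needs at least one epoch")
  if (anyNA(ratings)) stop("ratings must not contain NA")
  m <- ncol(ratings)
  cats <- sort(unique(as.vector(ratings)))
  # n_ij: number of raters assigning epoch i to category j
  nij <- vapply(cats, function(cc) rowSums(ratings == cc),
                numeric(nrow(ratings)))
  nij <- matrix(nij, nrow = nrow(ratings))
  Pi <- (rowSums(nij^2) - m) / (m * (m - 1))
  Pbar <- mean(Pi)
  pj <- colSums(nij) / (nrow(ratings) * m)
  Pe <- sum(pj^2)
  if (abs(1 - Pe) < .Machine$double.eps^0.5) {
    if (Pbar >= 1 - 1e-12) return(1)
    stop(structure(class = c("degenerate_kappa", "error", "condition"),
                   list(message = "chance agreement is 1 but raters disagree: kappa undefined",
                        call = sys.call(-1))))
  }
  (Pbar - Pe) / (1 - Pe)
}

#' Interrater reliability gate
#'
#' PSG hypnograms scored by multiple raters proceed to device comparison
#' only when Fleiss' kappa reaches the threshold (0.8 by default); below it
#' the hypnogram must be revised jointly by the raters. The boundary value
#' passes.
#'
#' @param kappa Fleiss' kappa, e.g. from [fleiss_kappa()].
#' @param threshold minimum acceptable kappa (default 0.8).
#' @return List with `kappa`, `threshold`, `pass` (logical) and `decision`
#'   (`"pass"` or `"revise"`).
#' @export
interrater_gate <- function(kappa, threshold = 0.8) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, !is.na(kappa))
  pass <- kappa >= threshold
  list(kappa = kappa, threshold = threshold, pass = pass,
       decision = if (pass) "pass" else "revise")
}

#' Epoch-by-epoch confusion summary
#'
#' Cross-tabulates device against PSG stage over an aligned pair and derives
#' per-stage sensitivity (percent of PSG epochs of a stage that the device
#' scored as that stage), per-stage specificity (percent of PSG epochs *not*
#' of the stage that the device scored as something else) and overall
#' accuracy (percent of epochs with equal labels).
#'
#' @param pair an [aligned_pair] on a common alphabet.
#' @return An object of class `"confusion_summary"`: list with `counts`
#'   (device stage x PSG stage matrix), `sensitivity`, `specificity`
#'   (named percent vectors; `NA` with a flag in `undefined` when the PSG
#'   never, or always, shows a stage), `accuracy`, `n_epochs`.
#' @export
confusion <- function(pair) {
  stopifnot(inherits(pair, "aligned_pair"))
  if (pair$psg$alphabet != pair$device$alphabet)
    stop("confusion requires a common alphabet; categorize the PSG first")
  stages <- stage_alphabets[[pair$psg$alphabet]]
  dev <- factor(pair$device$stages, levels = stages)
  psg <- factor(pair$psg$stages, levels = stages)
  counts <- table(device = dev, PSG = psg)
  n <- sum(counts)
  sens <- spec <- stats::setNames(rep(NA_real_, length(stages)), stages)
  for (s in stages) {
    pos <- sum(counts[, s])
    if (pos > 0) sens[s] <- 100 * counts[s, s] / pos
    neg <- n - pos
    if (neg > 0) spec[s] <- 100 * (neg - (sum(counts[s, ]) - counts[s, s])) / neg
  }
  structure(list(counts = unclass(counts),
                 sensitivity = sens,
                 specificity = spec,
                 undefined = stages[colSums(counts) == 0],
                 accuracy = 100 * sum(diag(counts)) / n,
                 n_epochs = n),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> %d epochs, accuracy %.2f%%\n",
              x$n_epochs, x$accuracy))
  tab <- rbind(sensitivity = x$sensitivity, specificity = x$specificity)
  print(round(tab, 2))
  invisible(x)
}

#' Paired comparison of a sleep feature between device and PSG
#'
#' Tests, across nights, whether a feature scored by the device differs from
#' the same feature scored from PSG. The nightly paired differences
#' (device minus PSG) are checked for normality with a Shapiro-Wilk test at
#' alpha = 0.05; normal differences get a paired t-test, non-normal ones a
#' Wilcoxon signed-rank test. The signed paired effect size
#' `mean(diff) / sd(diff)` (paired Cohen's d) is reported alongside.
#'
#' @param psg_values,dev_values numeric vectors of per-night feature values,
#'   paired by night, length >= 3.
#' @param feature optional feature name carried into the result.
#' @param alpha significance level (default 0.05).
#' @return An object of class `"feature_test"`: list with `feature`, `n`,
#'   `test` (`"paired_t"`, `"wilcoxon"` or `"degenerate"`), `p_value`,
#'   `effect`, `significant`, `mean_diff`, `shapiro_p`.
#' @export
paired_feature_test <- function(psg_values, dev_values, feature = "",
                                alpha = 0.05) {
  if (length(psg_values) != length(dev_values))
    stop("paired samples must have equal length")
  if (length(psg_values) < 3L)
    stop("need at least 3 paired nights for a feature test")
  if (anyNA(psg_values) || anyNA(dev_values)) stop("feature values contain NA")
  d <- dev_values - psg_values
  if (all(d == 0)) {
    res <- list(feature = feature, n = length(d), test = "degenerate",
                p_value = 1, effect = 0, significant = FALSE,
                mean_diff = 0, shapiro_p = NA_real_)
    return(structure(res, class = "feature_test"))
  }
  sw <- if (stats::sd(d) > 0) stats::shapiro.test(d)$p.value else 0
  if (sw > 0.05) {
    test <- "paired_t"
    p <- stats::t.test(dev_values, psg_values, paired = TRUE)$p.value
  } else {
    test <- "wilcoxon"
    p <- stats::wilcox.test(dev_values, psg_values, paired = TRUE,
                            exact = FALSE)$p.value
  }
  effect <- if (stats::sd(d) > 0) mean(d) / stats::sd(d) else Inf * sign(mean(d))
  structure(list(feature = feature, n = length(d), test = test,
                 p_value = p, effect = effect,
                 significant = p < alpha,
                 mean_diff = mean(d), shapiro_p = sw),
            class = "feature_test")
}

#' @export
print.feature_test <- function(x, ...) {
  cat(sprintf("<feature_test> %s: %s, n=%d, p=%.4g, effect=%.3f %s\n",
              if (nzchar(x$feature)) x$feature else "(unnamed)",
              x$test, x$n, x$p_value, x$effect,
              if (x$significant) "(*)" else "(**)"))
  invisible(x)
}
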