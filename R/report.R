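# Pipeline orchestration: single-night comparison, cohort summaries with
# paired tests and device ranking, and report serialization. The bundled
# command-line script (inst/cli/hypnomatch) is a thin wrapper over these
# functions; no logic lives only in the CLI.

#' Validated run configuration
#'
#' @param dev_type `"I"` or `"II"` (or a [device_type]).
#' @param epoch_duration epoch length in seconds.
#' @param rem_code integer REM code for four-stage encodings.
#' @param kappa_threshold interrater gate threshold.
#' @param alpha significance level for feature tests.
#' @param lights_on optional lights-on clock time for WASO.
#' @param label_map optional named vector mapping vendor stage strings.
#' @param seed integer seed recorded in reports.
#' @return An object of class `"run_config"`; echoed verbatim into every
#'   report for provenance.
#' @export
run_config <- function(dev_type = "II", epoch_duration = 30, rem_code = 8L,
                       kappa_threshold = 0.8, alpha = 0.05,
                       lights_on = NULL, label_map = NULL, seed = 1L) {
  if (!inherits(dev_type, "device_type")) dev_type <- device_type(dev_type)
  stopifnot(epoch_duration > 0, kappa_threshold >= 0, kappa_threshold <= 1,
            alpha > 0, alpha < 1)
  if (!is.null(lights_on)) parse_clock(lights_on)   # validate early
  structure(list(dev_type = dev_type, epoch_duration = epoch_duration,
                 rem_code = as.integer(rem_code),
                 kappa_threshold = kappa_threshold, alpha = alpha,
                 lights_on = lights_on, label_map = label_map,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_provenance <- function(config) {
  list(device_type = config$dev_type$kind,
       epoch_duration = config$epoch_duration,
       rem_code = config$rem_code,
       kappa_threshold = config$kappa_threshold,
       alpha = config$alpha,
       lights_on = config$lights_on,
       seed = config$seed,
       package_version = as.character(utils::packageVersion("hypnomatch")))
}

load_night <- function(x, config, source, alphabet) {
  if (inherits(x, "hypnogram")) return(x)
  read_hypnogram(x, format = "csv", alphabet = alphabet,
                 label_map = config$label_map, source = source)
}

#' Compare one device night with its PSG ground truth
#'
#' Runs the full single-night pipeline: clock-time synchronization, AASM
#' categorization of the PSG to the device alphabet, feature extraction for
#' both scorers, the localized mismatch index with its transition rates,
#' and the epoch-by-epoch confusion summary.
#'
#' @param psg a `PSG5` [hypnogram] or path to a PSG hypnogram CSV.
#' @param device a device-alphabet [hypnogram] or path to a CSV.
#' @param config a [run_config].
#' @return An object of class `"night_report"`: list with `config`
#'   (provenance echo), `n_epochs`, `features_psg`, `features_device`
#'   ([extract_features()] results), `lmi` (an `"lmi_result"`),
#'   `confusion` (a `"confusion_summary"`).
#' @export
compare_night <- function(psg, device, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  psg <- load_night(psg, config, "PSG", "PSG5")
  device <- load_night(device, config, "device", config$dev_type$alphabet)
  if (device$alphabet != config$dev_type$alphabet)
    stop("device hypnogram alphabet ", device$alphabet,
         " does not match device type ", config$dev_type$kind)
  pair <- if (!is.null(psg$start_time) && !is.null(device$start_time))
    synchronize(psg, device)
  else {
    if (length(psg$stages) != length(device$stages))
      stop("without start times, hypnograms must already be equal length")
    aligned_pair(psg, device)
  }
  pair_cat <- aligned_pair(categorize_psg(pair$psg, config$dev_type),
                           pair$device)
  enc <- stage_encoding(config$dev_type, rem_code = config$rem_code)
  structure(
    list(config = config_provenance(config),
         n_epochs = pair$n_epochs,
         features_psg = extract_features(pair_cat$psg, config$lights_on),
         features_device = extract_features(pair_cat$device, config$lights_on),
         lmi = lmi_sequence(pair_cat, enc),
         confusion = confusion(pair_cat)),
    class = "night_report")
}

#' @export
print.night_report <- function(x, ...) {
  cat(sprintf("<night_report> %d epochs, accuracy %.2f%%, correct transitions %s\n",
              x$n_epochs, x$confusion$accuracy,
              if (is.null(x$lmi$rates)) "n/a"
              else sprintf("%.2f%%", x$lmi$rates$correct)))
  invisible(x)
}

#' Write a single-night report to disk
#'
#' @param report a `"night_report"` from [compare_night()].
#' @param out_dir output directory (created if needed).
#' @param stem file-name stem (default `"night"`).
#' @return Character vector of the files written (`<stem>_summary.json` and
#'   `<stem>_lmi.csv`), invisibly.
#' @export
write_night_report <- function(report, out_dir, stem = "night") {
  stopifnot(inherits(report, "night_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jf <- file.path(out_dir, paste0(stem, "_summary.json"))
  cf <- file.path(out_dir, paste0(stem, "_lmi.csv"))
  summ <- list(
    config = report$config,
    n_epochs = report$n_epochs,
    features = list(psg = unclass(report$features_psg),
                    device = unclass(report$features_device)),
    transition_rates = report$lmi$rates,
    confusion = list(counts = report$confusion$counts,
                     sensitivity = as.list(report$confusion$sensitivity),
                     specificity = as.list(report$confusion$specificity),
                     accuracy = report$confusion$accuracy))
  jsonlite::write_json(summ, jf, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", matrix = "rowmajor")
  utils::write.csv(as.data.frame(report$lmi), cf, row.names = FALSE,
                   quote = FALSE)
  invisible(c(jf, cf))
}

cohort_features <- c("SPT", "SE", "WASO", "SO_min", "TST",
                     "PLS", "PDS", "PRS")

#' Compare a cohort of nights, per device
#'
#' Reads a manifest (columns `night`, `device`, `device_type`, `psg_file`,
#' `device_file`; paths relative to the manifest), runs [compare_night()]
#' on every row, and per device computes the paired feature-comparison
#' suite across nights, pooled transition rates and a pooled confusion
#' summary. When several devices are present, each feature also gets a
#' ranking by descending p-value (a larger p means the device is harder to
#' distinguish from PSG), ties broken by smaller absolute effect size.
#'
#' @param manifest path to a manifest CSV, or a data frame with a `dir`
#'   attribute/column resolving the files.
#' @param config a [run_config]; its `dev_type` is overridden per manifest
#'   row when the manifest carries a `device_type` column.
#' @param min_nights_for_tests nights a device needs before feature tests
#'   run (3 by default); devices below it still get rates and confusion.
#' @return An object of class `"cohort_report"`: list with `config`,
#'   `nights` (per-night feature rows), `devices` (per-device list:
#'   `tests`, `mean_rates`, `confusion`), and `ranking` (per-feature
#'   device order), plus `n_nights`.
#' @export
cohort_report <- function(manifest, config = run_config(),
                          min_nights_for_tests = 3L) {
  if (is.character(manifest)) {
    mdir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  } else {
    mdir <- attr(manifest, "dir") %||% manifest$dir[1] %||% "."
  }
  need <- c("night", "device", "psg_file", "device_file")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns ", paste(need, collapse = ", "))

  night_rows <- list()
  per_device <- list()
  for (dv in unique(manifest$device)) {
    rows <- manifest[manifest$device == dv, ]
    cfg <- config
    if ("device_type" %in% names(rows))
      cfg$dev_type <- device_type(rows$device_type[1])
    resolve <- function(f) ifelse(grepl("^(/|[A-Za-z]:)", f), f,
                                  file.path(mdir, f))
    reports <- lapply(seq_len(nrow(rows)), function(r) {
      compare_night(resolve(rows$psg_file[r]),
                    resolve(rows$device_file[r]), cfg)
    })
    feat <- do.call(rbind, lapply(seq_along(reports), function(r) {
      cbind(data.frame(night = rows$night[r], device = dv, scorer = "PSG"),
            as.data.frame(reports[[r]]$features_psg))
    }))
    featd <- do.call(rbind, lapply(seq_along(reports), function(r) {
      cbind(data.frame(night = rows$night[r], device = dv, scorer = "device"),
            as.data.frame(reports[[r]]$features_device))
    }))
    night_rows[[dv]] <- rbind(feat, featd)

    tests <- NULL
    if (nrow(rows) >= min_nights_for_tests) {
      tests <- lapply(cohort_features, function(f) {
        pv <- feat[[f]]; dvv <- featd[[f]]
        if (anyNA(pv) || anyNA(dvv)) return(NULL)   # e.g. PRS for type II
        paired_feature_test(pv, dvv, feature = f, alpha = config$alpha)
      })
      tests <- Filter(Negate(is.null), tests)
      names(tests) <- vapply(tests, `[[`, character(1), "feature")
    }
    rates <- lapply(reports, function(r) r$lmi$rates)
    rates <- Filter(Negate(is.null), rates)
    mean_rates <- if (length(rates))
      sapply(c("correct_wake", "correct_sleep", "incorrect_wake",
               "incorrect_sleep", "correct", "incorrect"),
             function(k) mean(vapply(rates, `[[`, numeric(1), k)),
             simplify = FALSE) else NULL
    counts <- Reduce(`+`, lapply(reports, function(r) r$confusion$counts))
    pooled <- pooled_confusion(counts)
    per_device[[dv]] <- list(device = dv, n_nights = nrow(rows),
                             tests = tests, mean_rates = mean_rates,
                             confusion = pooled)
  }

  ranking <- rank_devices(per_device)
  structure(list(config = config_provenance(config),
                 n_nights = nrow(manifest),
                 nights = do.call(rbind, night_rows),
                 devices = per_device,
                 ranking = ranking),
            class = "cohort_report")
}

pooled_confusion <- function(counts) {
  n <- sum(counts)
  stages <- rownames(counts)
  sens <- spec <- stats::setNames(rep(NA_real_, length(stages)), stages)
  for (s in stages) {
    pos <- sum(counts[, s])
    if (pos > 0) sens[s] <- 100 * counts[s, s] / pos
    neg <- n - pos
    if (neg > 0) spec[s] <- 100 * (neg - (sum(counts[s, ]) - counts[s, s])) / neg
  }
  structure(list(counts = counts, sensitivity = sens, specificity = spec,
                 undefined = stages[colSums(counts) == 0],
                 accuracy = 100 * sum(diag(counts)) / n, n_epochs = n),
            class = "confusion_summary")
}

# Per-feature device order: descending p (less distinguishable from PSG
# first), ties by smaller |effect|.
rank_devices <- function(per_device) {
  tested <- Filter(function(d) !is.null(d$tests), per_device)
  if (length(tested) < 2) return(NULL)
  feats <- Reduce(intersect, lapply(tested, function(d) names(d$tests)))
  out <- lapply(feats, function(f) {
    p <- vapply(tested, function(d) d$tests[[f]]$p_value, numeric(1))
    e <- abs(vapply(tested, function(d) d$tests[[f]]$effect, numeric(1)))
    names(p) <- vapply(tested, `[[`, character(1), "device")
    names(p)[order(-p, e)]
  })
  names(out) <- feats
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d night(s), %d device(s)\n",
              x$n_nights, length(x$devices)))
  for (d in x$devices) {
    cat(sprintf("  %s: %d nights, accuracy %.2f%%, correct transitions %s\n",
                d$device, d$n_nights, d$confusion$accuracy,
                if (is.null(d$mean_rates)) "n/a"
                else sprintf("%.2f%%", d$mean_rates$correct)))
    if (!is.null(d$tests))
      for (t in d$tests)
        cat(sprintf("    %-6s %-9s p=%.4g effect=%.3f %s\n", t$feature,
                    t$test, t$p_value, t$effect,
                    if (t$significant) "(*)" else "(**)"))
  }
  invisible(x)
}

#' Write a cohort report to disk
#'
#' @param report a `"cohort_report"`.
#' @param out_dir output directory.
#' @return Files written (`cohort_summary.json`, `cohort_features.csv`),
#'   invisibly.
#' @export
write_cohort_report <- function(report, out_dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jf <- file.path(out_dir, "cohort_summary.json")
  cf <- file.path(out_dir, "cohort_features.csv")
  devices <- lapply(report$devices, function(d) {
    list(device = d$device, n_nights = d$n_nights,
         tests = if (!is.null(d$tests)) lapply(d$tests, unclass),
         mean_rates = d$mean_rates,
         confusion = list(counts = d$confusion$counts,
                          sensitivity = as.list(d$confusion$sensitivity),
                          specificity = as.list(d$confusion$specificity),
                          accuracy = d$confusion$accuracy))
  })
  jsonlite::write_json(list(config = report$config,
                            n_nights = report$n_nights,
                            devices = devices,
                            ranking = report$ranking),
                       jf, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", matrix = "rowmajor")
  utils::write.csv(report$nights, cf, row.names = FALSE, quote = FALSE)
  invisible(c(jf, cf))
}
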