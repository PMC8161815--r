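# Markov-chain hypnogram simulator with a controllable device-error channel.
# Gives every agreement metric a closed loop: the generated pair carries the
# exact per-epoch ground truth, so planted error rates can be recovered.

#' Default overnight PSG stage-transition matrix
#'
#' First-order Markov transition probabilities per 30-s epoch over the five
#' AASM stages, chosen to give plausible adult overnight architecture:
#' sticky sleep stages (self-transition 0.88-0.95, i.e. mean dwell of a few
#' minutes), sleep entered through N1/N2, REM mostly exited to N1/N2 or
#' brief wake. The stationary stage mix is roughly 5-8% Wake, ~50% light
#' (N1+N2), ~20% N3 and ~20% REM.
#'
#' @return A 5 x 5 row-stochastic matrix with PSG5 dimnames.
#' @export
default_psg_transitions <- function() {
  st <- stage_alphabets$PSG5
  P <- matrix(c(
    # to:  Wake   N1     N2     N3     REM
          0.80,  0.15,  0.05,  0.00,  0.00,   # from Wake
          0.05,  0.70,  0.23,  0.01,  0.01,   # from N1
          0.02,  0.03,  0.88,  0.05,  0.02,   # from N2
          0.01,  0.01,  0.06,  0.90,  0.02,   # from N3
          0.02,  0.03,  0.05,  0.00,  0.90),  # from REM
    nrow = 5, byrow = TRUE, dimnames = list(from = st, to = st))
  P
}

check_stochastic <- function(M, what) {
  if (any(M < 0) || any(abs(rowSums(M) - 1) > 1e-8))
    stop(what, " must be row-stochastic (non-negative rows summing to 1)")
  invisible(M)
}

#' Define a simulation scenario
#'
#' Bundles everything needed to generate one synthetic night: the PSG
#' Markov model, the device type, and the device-error channel (uniform
#' mislabeling, a constant scoring lag, and epoch dropout refilled by
#' holding the previous stage, as consumer firmware does).
#'
#' @param n_epochs epochs per night (default 960 = 8 h of 30-s epochs).
#' @param epoch_duration seconds per epoch (default 30).
#' @param start_time clock time of epoch 0 (default `"22:30:00"`).
#' @param init initial-stage probability vector over PSG5 (default: start
#'   awake).
#' @param transitions 5 x 5 row-stochastic PSG5 transition matrix.
#' @param dev_type a [device_type] or `"I"`/`"II"` (default `"II"`).
#' @param mislabel either a single probability (each epoch is replaced,
#'   independently with this probability, by a stage drawn uniformly from
#'   the *other* stages of the device alphabet) or a full row-stochastic
#'   confusion matrix over the device alphabet (rows = true stage).
#' @param lag_epochs integer scoring lag: the device reports each stage
#'   `lag_epochs` epochs late (edge-padded). 0 disables.
#' @param missing_prob probability an epoch is missing from the device
#'   stream; missing epochs are refilled with the previous reported stage.
#' @param seed integer master seed; fixes all randomness.
#' @return An object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(n_epochs = 960, epoch_duration = 30,
                         start_time = "22:30:00",
                         init = c(Wake = 1, N1 = 0, N2 = 0, N3 = 0, REM = 0),
                         transitions = default_psg_transitions(),
                         dev_type = "II",
                         mislabel = 0, lag_epochs = 0L, missing_prob = 0,
                         seed = 1L) {
  if (!inherits(dev_type, "device_type")) dev_type <- device_type(dev_type)
  stopifnot(n_epochs >= 1, epoch_duration > 0,
            missing_prob >= 0, missing_prob < 1)
  transitions <- as.matrix(transitions)
  if (!identical(dim(transitions), c(5L, 5L)))
    stop("transitions must be a 5 x 5 matrix over the PSG5 stages")
  check_stochastic(transitions, "transition matrix")
  init <- init / sum(init)
  if (length(init) != 5) stop("init must have one probability per PSG5 stage")
  if (is.matrix(mislabel)) {
    dev_stages <- stage_alphabets[[dev_type$alphabet]]
    if (!identical(sort(rownames(mislabel)), sort(dev_stages)))
      stop("mislabel matrix must be over the device alphabet stages")
    check_stochastic(mislabel, "mislabel matrix")
  } else {
    stopifnot(length(mislabel) == 1, mislabel >= 0, mislabel <= 1)
  }
  structure(list(n_epochs = as.integer(n_epochs),
                 epoch_duration = epoch_duration,
                 start_time = start_time,
                 init = init, transitions = transitions,
                 dev_type = dev_type,
                 mislabel = mislabel,
                 lag_epochs = as.integer(lag_epochs),
                 missing_prob = missing_prob,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Read a simulation scenario from a YAML file
#'
#' Accepts the fields of [sim_scenario()]; `transitions` and matrix
#' `mislabel` are given as lists of named rows. Missing fields take the
#' defaults.
#'
#' @param path YAML file.
#' @return A `"sim_scenario"`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  rowlist_to_matrix <- function(rl) {
    rows <- names(rl)
    cols <- names(rl[[1]])
    m <- do.call(rbind, lapply(rl, function(r) unlist(r)[cols]))
    dimnames(m) <- list(rows, cols)
    m
  }
  args <- y
  if (!is.null(y$transitions)) args$transitions <- rowlist_to_matrix(y$transitions)
  if (!is.null(y$mislabel) && is.list(y$mislabel))
    args$mislabel <- rowlist_to_matrix(y$mislabel)
  if (!is.null(y$init)) args$init <- unlist(y$init)
  do.call(sim_scenario, args)
}

# Run expr under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a PSG-scored night
#'
#' Draws a first-order Markov stage sequence from the scenario's transition
#' matrix. Bit-reproducible for a given scenario seed.
#'
#' @param s a [sim_scenario].
#' @return A [hypnogram] with alphabet `PSG5` and source `"PSG"`.
#' @export
simulate_psg <- function(s) {
  stopifnot(inherits(s, "sim_scenario"))
  st <- stage_alphabets$PSG5
  with_seed(s$seed, {
    seq_idx <- integer(s$n_epochs)
    seq_idx[1] <- sample.int(5L, 1L, prob = s$init)
    if (s$n_epochs > 1)
      for (i in 2:s$n_epochs)
        seq_idx[i] <- sample.int(5L, 1L, prob = s$transitions[seq_idx[i - 1], ])
    hypnogram(st[seq_idx], s$epoch_duration, s$start_time, "PSG", "PSG5")
  })
}

#' Simulate a device-scored night from a PSG night
#'
#' Categorizes the PSG hypnogram to the device alphabet (the error-free
#' device reading), then passes it through the error channel: a constant
#' scoring lag, per-epoch mislabeling, and epoch dropout refilled by
#' holding the previous stage. Returns the device hypnogram together with
#' the per-epoch ground truth needed for exact expected agreement values.
#'
#' @param psg a `PSG5` [hypnogram].
#' @param s the [sim_scenario] (device randomness uses `seed + 1`, keeping
#'   the PSG and device draws independent but jointly reproducible).
#' @return List with `hypnogram` (device-alphabet [hypnogram], source
#'   `"device"`) and `truth`: data frame with `epoch` (0-based),
#'   `true_stage` (categorized PSG), `device_stage`, `mislabeled`,
#'   `missing` flags.
#' @export
simulate_device <- function(psg, s) {
  stopifnot(inherits(psg, "hypnogram"), inherits(s, "sim_scenario"))
  truth0 <- categorize_psg(psg, s$dev_type)
  dev_stages <- stage_alphabets[[s$dev_type$alphabet]]
  n <- length(truth0$stages)
  with_seed(s$seed + 1L, {
    x <- truth0$stages
    if (s$lag_epochs != 0L) {
      k <- s$lag_epochs
      x <- if (k > 0) c(rep(x[1], min(k, n)), x[seq_len(max(n - k, 0))])
           else c(x[(-k + 1):n], rep(x[n], min(-k, n)))
    }
    mislabeled <- rep(FALSE, n)
    if (is.matrix(s$mislabel)) {
      for (i in seq_len(n)) {
        drawn <- sample(colnames(s$mislabel), 1L, prob = s$mislabel[x[i], ])
        mislabeled[i] <- drawn != x[i]
        x[i] <- drawn
      }
    } else if (s$mislabel > 0) {
      flip <- stats::runif(n) < s$mislabel
      if (any(flip)) {
        x[flip] <- vapply(x[flip], function(stg)
          sample(setdiff(dev_stages, stg), 1L), character(1))
        mislabeled <- flip
      }
    }
    missing <- if (s$missing_prob > 0) stats::runif(n) < s$missing_prob
               else rep(FALSE, n)
    if (missing[1]) missing[1] <- FALSE        # nothing earlier to hold
    if (any(missing)) {
      for (i in which(missing)) x[i] <- x[i - 1]   # hold previous stage
    }
    dev <- hypnogram(x, truth0$epoch_duration, truth0$start_time,
                     "device", truth0$alphabet)
    list(hypnogram = dev,
         truth = data.frame(epoch = seq_len(n) - 1L,
                            true_stage = truth0$stages,
                            device_stage = x,
                            mislabeled = mislabeled,
                            missing = missing,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a paired night
#'
#' Convenience wrapper: PSG night, device night, and the aligned pair with
#' the PSG categorized to the device alphabet.
#'
#' @param s a [sim_scenario].
#' @return List with `psg` (PSG5 hypnogram), `device`, `pair` (an
#'   [aligned_pair] on the device alphabet) and `truth`.
#' @export
simulate_pair <- function(s) {
  psg <- simulate_psg(s)
  dev <- simulate_device(psg, s)
  list(psg = psg, device = dev$hypnogram,
       pair = aligned_pair(categorize_psg(psg, s$dev_type), dev$hypnogram),
       truth = dev$truth)
}

#' Simulate a cohort of paired nights
#'
#' Writes `n_nights` independent PSG/device CSV pairs plus a manifest.
#' Night `k` uses seed `master_seed + k`, so the whole cohort is
#' reproducible from the scenario alone.
#'
#' @param n_nights number of nights (>= 1).
#' @param s a [sim_scenario]; its `seed` is the master seed.
#' @param out_dir output directory (created if needed).
#' @param device name recorded in the manifest (default `"simdev"`).
#' @return The manifest `data.frame` (columns `night`, `device`,
#'   `device_type`, `seed`, `psg_file`, `device_file`), invisibly; also
#'   written to `manifest.csv` in `out_dir`.
#' @export
simulate_cohort <- function(n_nights, s, out_dir, device = "simdev") {
  stopifnot(n_nights >= 1, inherits(s, "sim_scenario"))
  if (s$seed + n_nights >= 2^31) stop("master seed too large for per-night seeds")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(n_nights), function(k) {
    sk <- s
    sk$seed <- s$seed + k
    night <- simulate_pair(sk)
    pf <- file.path(out_dir, sprintf("psg_%03d.csv", k))
    df <- file.path(out_dir, sprintf("device_%03d.csv", k))
    write_hypnogram(night$psg, pf)
    write_hypnogram(night$device, df)
    data.frame(night = k, device = device, device_type = s$dev_type$kind,
               seed = sk$seed, psg_file = basename(pf),
               device_file = basename(df), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
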