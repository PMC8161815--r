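# The six legal three-stage transitions in conventional order, with their
# first differences under Wake=1, Light=2, Deep=4.
trans3 <- list("W-L" = c("Wake", "Light"), "W-D" = c("Wake", "Deep"),
               "L-D" = c("Light", "Deep"), "L-W" = c("Light", "Wake"),
               "D-L" = c("Deep", "Light"), "D-W" = c("Deep", "Wake"))
trans3_deltas <- c(1L, 3L, 2L, -1L, -2L, -3L)

two_epoch_pair <- function(psg_tr, dev_tr)
  aligned_pair(dev3_hyp(psg_tr, source = "PSG"), dev3_hyp(dev_tr))

test_that("transition deltas are first differences of the encoded sequence", {
  enc <- stage_encoding("DEV3")
  expect_identical(transition_deltas(encode_stages(dev3_hyp(c("Deep", "Wake")),
                                                   enc)), -3L)
  expect_identical(transition_deltas(rep(2L, 6)), rep(0L, 5))
  expect_identical(transition_deltas(c(1L, 2L, 4L, 2L, 1L)),
                   c(1L, 2L, -2L, -1L))
  expect_error(transition_deltas(1L), "two epochs")
  got <- vapply(trans3, function(tr)
    transition_deltas(encode_stages(dev3_hyp(tr), enc)), integer(1))
  expect_identical(unname(got), trans3_deltas)
})

test_that("the LMI product reproduces the full 6 x 6 transition table", {
  # oracle: outer product of the six deltas, written out by hand
  expected <- outer(trans3_deltas, trans3_deltas)
  got <- matrix(NA_real_, 6, 6)
  for (r in 1:6) for (c in 1:6)
    got[r, c] <- lmi_sequence(two_epoch_pair(trans3[[r]], trans3[[c]]))$lmi_values
  expect_equal(got, expected)
  expect_equal(got, t(got))                        # symmetric about the diagonal
  expect_equal(diag(got), c(1, 9, 4, 1, 4, 9))     # perfect squares on agreement
  # and the package's own table helper agrees cell by cell
  tab <- lmi_table(stage_encoding("DEV3"))
  expect_equal(matrix(as.vector(tab), 6, 6), expected)
  expect_identical(unname(attr(tab, "deltas")), trans3_deltas)
})

test_that("specific index values match the published examples", {
  expect_equal(lmi_sequence(two_epoch_pair(c("Wake", "Deep"),
                                           c("Wake", "Deep")))$lmi_values, 9)
  r <- lmi_sequence(two_epoch_pair(c("Wake", "Deep"), c("Light", "Deep")))
  expect_equal(r$lmi_values, 6)
  expect_equal(r$classes, "incorrect_wake")
})

test_that("delta-pair classes reproduce the product grouping exhaustively", {
  enc <- stage_encoding("DEV3")
  legal <- c(0L, trans3_deltas)
  for (dp in legal) for (dw in legal) {
    if (dp == 0 && dw == 0) {
      expect_error(classify_lmi(dp, dw, enc), "not a transition")
      next
    }
    cls <- classify_lmi(dp, dw, enc)
    prod <- dp * dw
    expected <- if (dp == dw) {
      if (prod %in% c(1, 9)) "correct_wake" else "correct_sleep"
    } else if (prod %in% c(3, -4)) {
      "incorrect_sleep"
    } else if (prod != 0) {
      "incorrect_wake"
    } else {                          # one-sided: class follows the mover
      if (abs(dp + dw) == 2) "incorrect_sleep" else "incorrect_wake"
    }
    expect_equal(cls, expected, info = sprintf("dp=%d dw=%d", dp, dw))
    # correct classes arise only from equal deltas: a square product of a
    # legal delta implies equality
    if (prod %in% c(1, 4, 9))
      expect_equal(startsWith(cls, "correct"), dp == dw)
    # symmetry under swapping the scorer roles
    expect_equal(classify_lmi(dw, dp, enc), cls)
  }
})

test_that("four-stage classification is pair-based and REM-code invariant", {
  for (rem in c(8L, 10L, 16L)) {
    enc <- stage_encoding("DEV4", rem_code = rem)
    codes <- unclass(enc)
    d <- function(a, b) codes[[b]] - codes[[a]]
    expect_equal(classify_lmi(d("Light", "REM"), d("Light", "REM"), enc),
                 "correct_sleep")
    expect_equal(classify_lmi(d("Wake", "REM"), d("Wake", "REM"), enc),
                 "correct_wake")
    expect_equal(classify_lmi(d("Light", "REM"), d("Light", "Deep"), enc),
                 "incorrect_sleep")
    expect_equal(classify_lmi(d("Wake", "REM"), d("Wake", "Deep"), enc),
                 "incorrect_sleep")
    expect_equal(classify_lmi(d("Wake", "REM"), d("REM", "Wake"), enc),
                 "incorrect_wake")
    expect_equal(classify_lmi(d("REM", "Wake"), d("Light", "Deep"), enc),
                 "incorrect_wake")
  }
  # REM code 3 makes a wake delta collide with a sleep-sleep delta (|3-1| =
  # |4-2| = 2): classification must refuse rather than misclassify
  expect_error(classify_lmi(1L, 2L, stage_encoding("DEV4", rem_code = 3L)),
               "indistinguishable")
})

test_that("the transition set and index sequence follow the definition", {
  psg <- dev3_hyp(c("Wake", "Wake", "Light", "Light", "Deep", "Deep"),
                  source = "PSG")
  dev <- dev3_hyp(c("Wake", "Light", "Light", "Light", "Light", "Deep"))
  r <- lmi_sequence(aligned_pair(psg, dev))
  expect_identical(r$deltas_psg, c(0L, 1L, 0L, 2L, 0L))
  expect_identical(r$deltas_device, c(1L, 0L, 0L, 0L, 2L))
  expect_identical(r$transition_set, c(0L, 1L, 3L, 4L))   # 0-based, sorted
  expect_equal(r$lmi_values, r$deltas_device[r$transition_set + 1L] *
                             r$deltas_psg[r$transition_set + 1L])
  df <- as.data.frame(r)
  expect_equal(nrow(df), 4)
  expect_equal(df$lmi, r$lmi_values)
})

test_that("transition rates are percentages over the transition set", {
  # identical hypnograms: all transitions correct
  h <- dev3_hyp(c("Wake", "Light", "Deep", "Light", "Wake"))
  r <- lmi_sequence(aligned_pair(
    hypnogram(h$stages, 30, h$start_time, "PSG", "DEV3"), h))
  expect_true(all(r$lmi_values %in% c(1, 4, 9)))
  expect_equal(r$rates$correct, 100)
  expect_equal(r$rates$incorrect, 0)

  # constant device while the PSG transitions k times: all one-sided, 0%
  psg <- dev3_hyp(c("Wake", "Light", "Wake", "Light"), source = "PSG")
  dev <- dev3_hyp(rep("Light", 4))
  r2 <- lmi_sequence(aligned_pair(psg, dev))
  expect_equal(length(r2$transition_set), 3)
  expect_true(all(r2$lmi_values == 0))
  expect_equal(r2$rates$correct, 0)
  expect_equal(r2$rates$incorrect, 100)

  # class rates always sum to 100 over |A|
  sums <- r2$rates$correct_wake + r2$rates$correct_sleep +
          r2$rates$incorrect_wake + r2$rates$incorrect_sleep
  expect_equal(sums, 100)

  flat <- dev3_hyp(rep("Light", 5))
  r3 <- lmi_sequence(aligned_pair(
    hypnogram(rep("Light", 5), 30, flat$start_time, "PSG", "DEV3"), flat))
  expect_length(r3$transition_set, 0)
  expect_null(r3$rates)
  expect_error(summarize_rates(r3), class = "empty_transition_set")
})

test_that("measured rates equal an independent bookkeeping of the truth record", {
  # the simulator's truth table allows an exact from-scratch recount of the
  # correct-transition rate without going through the lmi_result path
  night <- simulate_pair(sim_scenario(n_epochs = 960, seed = 19, mislabel = 0.2))
  r <- lmi_sequence(night$pair)
  codes <- c(Wake = 1L, Light = 2L, Deep = 4L)
  dp <- diff(codes[night$truth$true_stage])
  dw <- diff(codes[night$truth$device_stage])
  in_A <- dp != 0 | dw != 0
  expect_equal(r$rates$n_transitions, sum(in_A))
  expect_equal(r$rates$correct,
               100 * sum(dp == dw & in_A) / sum(in_A))
  expect_equal(sort(r$lmi_values), sort(unname((dp * dw)[in_A])))
})
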