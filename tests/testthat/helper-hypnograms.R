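# Shared fixtures, built in code.

dev3_hyp <- function(stages, start = "23:00:00", source = "device")
  hypnogram(stages, 30, start, source, "DEV3")

psg5_hyp <- function(stages, start = "23:00:00")
  hypnogram(stages, 30, start, "PSG", "PSG5")

# A deterministic 6-epoch night used across the feature tests.
six_epoch_night <- function() psg5_hyp(c("Wake", "N1", "N2", "Wake", "N2", "Wake"))

write_lines_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
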