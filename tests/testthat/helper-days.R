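# Pool the meal-aligned normalized-power curves of several simulated days,
# the multi-day averaging design used for gastric meal-response curves.
pooled_meal_response <- function(n_days, base_seed, ...) {
  alignments <- lapply(seq_len(n_days), function(d) {
    day <- simulate_ambulatory_day(seed = base_seed + d, ...)
    rep <- suppressMessages(suppressWarnings(
      run_ambulatory_pipeline(day$recording, day$events, value = observed)
    ))
    rep$meal_aligned
  })
  combine_alignments(Filter(Negate(is.null), alignments))
}

meal_response_stats <- function(alignment) {
  s <- alignment$summary
  base <- mean(s$mean[s$rel_time < 0])
  list(
    baseline = base,
    rise = mean(s$mean[s$rel_time > 0 & s$rel_time <= 1.5 * 3600]) - base,
    late_dev = mean(s$mean[s$rel_time >= 3 * 3600 &
                             s$rel_time <= 4 * 3600]) - base
  )
}
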