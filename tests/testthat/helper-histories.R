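# build a long capture-history table from compact per-individual state
# strings, e.g. "a a d" = alive, alive, dead; "a c" = alive then censored.
# Intervals run Winter 2000, Spring 2000, ... in order.
make_histories <- function(..., start_year = 2000L,
                           stage = "subadult1", sex = "unknown") {
  specs <- list(...)
  rows <- lapply(seq_along(specs), function(i) {
    states <- strsplit(specs[[i]], "\\s+")[[1]]
    codes <- c(a = "alive-detected", n = "not-detected", d = "dead",
               c = "censored")[states]
    at <- interval_at(seq_along(codes) - 1L, start_year)
    data.frame(individual_id = sprintf("B%03d", i), sex = sex,
               stage_at_entry = stage, entry_year = start_year,
               entry_season = "Winter", year = at$year,
               season = at$season, state = codes,
               cause = ifelse(codes == "dead", "Undiagnosed fatality",
                              NA_character_),
               stringsAsFactors = FALSE)
  })
  capture_histories(do.call(rbind, rows))
}

# replicate a state-string spec n times
rep_histories <- function(spec, n, ...) {
  do.call(make_histories, c(as.list(rep(spec, n)), list(...)))
}
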