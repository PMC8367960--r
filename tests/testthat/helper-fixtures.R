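# build a small quadrat survey in code: `counts` is a list mapping species to
# a named vector of quadrat counts
make_observations <- function(counts, zone = "Z1") {
  rows <- lapply(names(counts), function(sp) {
    q <- counts[[sp]]
    data.frame(zone = zone, plot = "P1", quadrat = names(q),
               species = sp, count = as.integer(q),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

reference_cfs <- function() {
  list(correction_factor("rain", 369, 909),
       correction_factor("snow", 51, 186))
}
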