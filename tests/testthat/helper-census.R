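# random census with contiguous lifespans (the shape real individual-tracked
# plot data has after gap filling); sizes default to the small regime used
# by the oracle and algebra property tests
randomCensus <- function(T = sample(2:6, 1),
                         nInd = sample(1:30, 1),
                         nSpecies = sample(1:6, 1)) {
  birth <- sample.int(T, nInd, replace = TRUE)
  last <- birth + floor(stats::runif(nInd) * (T - birth + 1))
  Z <- outer(birth, seq_len(T), "<=") & outer(last, seq_len(T), ">=")
  storage.mode(Z) <- "integer"
  rownames(Z) <- paste0("i", seq_len(nInd))
  colnames(Z) <- paste0("t", seq_len(T))
  census(Z, species = sample(paste0("s", seq_len(nSpecies)), nInd,
                             replace = TRUE))
}

# the worked 5-individual, 2-census example used across the tests
fiveIndividualCensus <- function() {
  z <- rbind(i1 = c(1, 1), i2 = c(1, 0), i3 = c(1, 0),
             i4 = c(0, 1), i5 = c(0, 1))
  colnames(z) <- c("t1", "t2")
  census(z, species = c("sp1", "sp1", "sp2", "sp1", "sp3"))
}

writeTempLong <- function(lines) {
  tf <- tempfile(fileext = ".csv")
  writeLines(lines, tf)
  tf
}
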