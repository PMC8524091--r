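# In-code fixtures shared across test files.

# A small 4-marker panel.
tiny_panel <- function() {
  validate_marker_panel(data.frame(
    marker_id = c("m1", "m2", "m3", "m4"),
    chromosome = c(1L, 1L, 2L, 3L),
    pos_start = c(100, 500, 100, 100),
    pos_end = c(200, 600, 200, 200),
    allele1 = c("T", "A", "C", "T"),
    allele2 = c("C", "G", "G", "G"),
    stringsAsFactors = FALSE
  ))
}

# Build a geno_matrix from a named list of state-string vectors.
# States: "1" = HOM1, "2" = HOM2, "H" = HET, "." = missing.
gm_from_codes <- function(codes, panel = tiny_panel()) {
  decode <- c("1" = "HOM1", "2" = "HOM2", "H" = "HET")
  calls <- t(vapply(codes, function(s) {
    ch <- strsplit(s, "")[[1]]
    out <- unname(decode[ch])
    out[ch == "."] <- NA_character_
    out
  }, character(nrow(panel))))
  colnames(calls) <- panel$marker_id
  geno_matrix(calls, panel)
}

# Panel of arbitrary size for wider fixtures.
wide_panel <- function(m) {
  validate_marker_panel(data.frame(
    marker_id = sprintf("w%02d", seq_len(m)),
    chromosome = rep_len(1:11, m),
    pos_start = seq_len(m) * 1000,
    pos_end = seq_len(m) * 1000 + 100,
    allele1 = rep_len(c("T", "A", "C"), m),
    allele2 = rep_len(c("C", "G", "G"), m),
    stringsAsFactors = FALSE
  ))
}

# Minimal cross design.
tiny_design <- function(crosses, f1_lists) {
  cross_design(crosses, f1_lists)
}

# Brute-force allele recount oracle: tally allele copies one call at a time.
brute_allele_freq <- function(states) {
  copies <- c()
  for (s in states) {
    if (is.na(s)) next
    copies <- c(copies, switch(s, HOM1 = c(1, 1), HOM2 = c(2, 2), HET = c(1, 2)))
  }
  if (length(copies) == 0) return(c(NA_real_, NA_real_))
  c(mean(copies == 1), mean(copies == 2))
}
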