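# Small in-code fixtures shared across test files.

# 3 proteins x 4 samples (2 lineages x 2 replicates of one cell line each).
tiny_quant_table <- function() {
  meta <- data.frame(
    sample_id = c("H1", "H2", "F1", "F2"),
    lineage = c("HGSOC", "HGSOC", "FT", "FT"),
    source = "cell_line",
    unit_id = c("OV1", "OV1", "FT1", "FT1"),
    replicate = c(1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE
  )
  m <- rbind(
    P1 = c(100, 120, 50, 60),
    P2 = c(0, 10, 30, 35),
    P3 = c(0, 0, 0, 0)
  )
  colnames(m) <- meta$sample_id
  protein_quant_table(m, meta)
}

# Brute-force Mann-Whitney AUC with ties counted 1/2 (independent oracle).
brute_force_auc <- function(controls, cases) {
  s <- 0
  for (a in cases) for (b in controls) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(cases) * length(controls))
}
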