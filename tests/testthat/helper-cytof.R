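# CyTOF-style template: DNA-DNA singlets, CD3/CD8, four maturational
# quadrants, nine functional markers reference-gated off the unstimulated
# sample (99th percentile), per maturational parent
write_cytof_template <- function(path = tempfile(fileext = ".csv")) {
  functionals <- c("TNFa", "IFNg", "MIP1b", "MIP1a", "IL2", "GMCSF",
                   "CD107", "GzB", "Perforin")
  quads <- c("CD45RA+CCR7+", "CD45RA-CCR7+", "CD45RA-CCR7-", "CD45RA+CCR7-")
  rows <- c(
    "dna,+,root,\"DNA1,DNA2\",dnaGate,,FALSE,",
    "cd3,+,dna,CD3,mindensity,,FALSE,",
    "cd8,+,cd3,CD8,mindensity,,FALSE,",
    "mat,cd45ra+/-ccr7+/-,cd8,\"CD45RA,CCR7\",mindensity,,FALSE,")
  ref_args <- "\"ref_key=STIM,ref_value=unstim,method=quantileGate,probs=0.99\""
  for (qi in seq_along(quads))
    for (m in functionals)
      rows <- c(rows, sprintf("%s_%d,%s+,%s,%s,refGate,%s,FALSE,",
                              m, qi, m, quads[qi], m, ref_args))
  writeLines(c(
    "alias,pop,parent,dims,gating_method,gating_args,collapseDataForGating,groupBy",
    rows), path)
  path
}

CYTOF_QUAD_PATHS <- file.path("/dna/cd3/cd8",
                              c("CD45RA+CCR7+", "CD45RA-CCR7+",
                                "CD45RA-CCR7-", "CD45RA+CCR7-"))

cytof_marker_paths <- function(quad_index) {
  functionals <- c("TNFa", "IFNg", "MIP1b", "MIP1a", "IL2", "GMCSF",
                   "CD107", "GzB", "Perforin")
  file.path(CYTOF_QUAD_PATHS[quad_index],
            paste0(functionals, "_", quad_index))
}
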