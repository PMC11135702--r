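# shared constructors for rule-boundary presence matrices
# presence matrix with given green/non-green counts per orthogroup
boundary_matrix <- function(cases, n_green = 10L, n_nongreen = 10L) {
  gs <- sprintf("g%03d", seq_len(n_green))
  ns <- sprintf("n%03d", seq_len(n_nongreen))
  m <- matrix(0L, nrow(cases), n_green + n_nongreen,
              dimnames = list(cases$og, c(gs, ns)))
  for (i in seq_len(nrow(cases))) {
    if (cases$green[i] > 0) m[i, gs[seq_len(cases$green[i])]] <- 1L
    if (cases$nongreen[i] > 0) m[i, ns[seq_len(cases$nongreen[i])]] <- 1L
  }
  m
}

boundary_lineages <- function(n_green = 10L, n_nongreen = 10L) {
  lineage_map(c(sprintf("g%03d", seq_len(n_green)),
                sprintf("n%03d", seq_len(n_nongreen))),
              c(rep("embryophyte", n_green), rep("rhodophyte", n_nongreen)))
}
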