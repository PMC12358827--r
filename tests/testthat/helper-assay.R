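# Small assay configurations used across tests (desk-sized rasters).

smallConfig <- function(...) {
  defaults <- list(n_rows = 12, n_cols = 12, n_cells = 20, seed = 42)
  do.call(assayConfig, utils::modifyList(defaults, list(...)))
}

# A phenotype mix concentrated on one class.
pureMix <- function(class) {
  mix <- c(psma_pos_secretor = 0, psma_neg_secretor = 0,
           psma_pos_nonsecretor = 0, psma_neg_nonsecretor = 0,
           leukocyte = 0)
  mix[class] <- 1
  mix
}
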