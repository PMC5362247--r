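# Programmatic fixtures: a minimal one-plate bundle written to temp files.

toy_bundle_files <- function(dir = NULL,
                             signals = c(A1 = 10, A2 = 20, A3 = 30, A4 = 40),
                             scrambled_signal = 12) {
  if (is.null(dir)) {
    dir <- tempfile("bundle")
    dir.create(dir)
  }
  wells <- names(signals)
  layout <- data.frame(
    plate_id = "P1", replicate_id = "R1",
    well = c(wells, "B1"),
    role = c(rep("sample", length(wells)), "scrambled_control"),
    content_id = c(paste0("POOL", seq_along(wells)), "SCRAMBLED_01"))
  meas <- data.frame(
    plate_id = "P1", replicate_id = "R1",
    well = c(wells, "B1"),
    signal = c(unname(signals), scrambled_signal))
  lib <- data.frame(
    pool_id = rep(paste0("POOL", seq_along(wells)), each = 2),
    gene = rep(paste0("GENE", seq_along(wells)), each = 2),
    sirna_id = paste0("si", seq_len(2 * length(wells))),
    isoform_note = NA)
  paths <- file.path(dir, c("layout.tsv", "measurements.tsv", "library.tsv"))
  write_tsv(layout, paths[1]); write_tsv(meas, paths[2]); write_tsv(lib, paths[3])
  list(layout = paths[1], measurements = paths[2], library = paths[3], dir = dir)
}

# tiny deterministic screen bundle built in memory (no files)
toy_screen <- function(seed = 1, n_genes = 50, ...) {
  simulate_screen(sim_config(n_genes = n_genes, seed = seed, ...))
}
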