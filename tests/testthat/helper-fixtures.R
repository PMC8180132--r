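# Shared fixture builders; everything is generated in code under fixed seeds.

# Write a small FASTA from named sequences and return its path.
write_fasta_fixture <- function(seqs, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(names(seqs), function(id) {
    c(paste0(">", id), seqs[[id]])
  }))
  writeLines(lines, path)
  path
}

# Hand-built catalog without sequences.
make_catalog <- function(ids, lengths, gc) {
  cat <- data.frame(transcript_id = ids, gene_id = ids,
                    length = as.integer(lengths), gc = gc,
                    stringsAsFactors = FALSE)
  class(cat) <- c("transcript_catalog", "data.frame")
  cat
}

# Random catalog with independent uniform length and gc.
random_catalog <- function(n, seed = 1) {
  set.seed(seed)
  make_catalog(sprintf("t%04d", seq_len(n)),
               sample(200:5000, n, replace = TRUE),
               stats::runif(n, 0.2, 0.8))
}

# Small expression matrix with live/fixed annotations from explicit counts.
make_em <- function(counts, lengths, treatment = NULL, cell_type = NULL) {
  n_cells <- ncol(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("c%02d", seq_len(n_cells))
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("f%03d", seq_len(nrow(counts)))
  }
  cd <- data.frame(cell_id = colnames(counts), stringsAsFactors = FALSE)
  if (!is.null(treatment)) cd$treatment <- treatment
  if (!is.null(cell_type)) cd$cell_type <- cell_type
  normalize_log_tpm(counts, lengths = lengths, cell_data = cd)
}

# Desk-scale simulated experiment used across modules.
small_experiment <- function(seed = 42, n_transcripts = 400, n_cells = 25,
                             n_cell_types = 1, model = fixation_model(),
                             molecules_per_cell = 5000,
                             keep_molecules = TRUE, ...) {
  cfg <- sim_config(n_transcripts = n_transcripts, n_cells = n_cells,
                    n_cell_types = n_cell_types,
                    molecules_per_cell = molecules_per_cell,
                    seed = seed, ...)
  catalog <- simulate_catalog(cfg, sequences = FALSE)
  sim <- simulate_experiment(catalog, cfg, model,
                             keep_molecules = keep_molecules)
  em <- normalize_log_tpm(sim$counts, catalog, cell_data = sim$cell_data)
  list(catalog = catalog, config = cfg, model = model, sim = sim, em = em)
}
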