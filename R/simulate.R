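#' Parametric fixation model
#'
#' Formalizes the hypothesized mechanism behind the live-vs-fixed discrepancy:
#' reverse transcription of a fixed cell's molecule proceeds from the 3' end
#' and fails with a constant per-base hazard once it has travelled beyond a
#' grace distance `d0`; the hazard grows linearly with the transcript's GC
#' content (a proxy for secondary structure). Fixation additionally lowers the
#' per-molecule capture probability.
#'
#' The survival function of the truncation point (distance `x` from the 3'
#' end) for transcript `t` is `S_t(x) = exp(-lambda_t * max(0, x - d0))` with
#' `lambda_t = lambda0 * (1 + gamma * (gc_t - 0.5))`, clipped at 0.
#'
#' @param d0 Grace distance in bases from the 3' end (default 1500, matching
#'   the observed coverage break in fixed full-length libraries).
#' @param lambda0 Baseline per-base truncation hazard (default 2e-4).
#' @param gamma GC sensitivity multiplier, >= 0 (default 4).
#' @param pi_live,pi_fixed Per-molecule capture probabilities in (0, 1]
#'   (defaults 0.15 and 0.10).
#' @param full_length_required When `TRUE` (full-length protocol emulation) a
#'   molecule enters the count matrix only if reverse transcription survives
#'   to its 5' end; when `FALSE` (3'-tag emulation) a truncated molecule still
#'   contributes its 3'-end count.
#' @return An object of class `fixation_model`.
#' @export
fixation_model <- function(d0 = 1500, lambda0 = 2e-4, gamma = 4,
                           pi_live = 0.15, pi_fixed = 0.10,
                           full_length_required = TRUE) {
  stopifnot(d0 >= 0, lambda0 >= 0, gamma >= 0,
            pi_live > 0, pi_live <= 1, pi_fixed > 0, pi_fixed <= 1)
  structure(
    list(d0 = d0, lambda0 = lambda0, gamma = gamma,
         pi_live = pi_live, pi_fixed = pi_fixed,
         full_length_required = full_length_required),
    class = "fixation_model"
  )
}

#' Null fixation model
#'
#' Convenience constructor: zero truncation hazard and equal capture
#' efficiency, under which fixed cells are draws from exactly the live
#' generative process.
#' @param pi Common capture probability (default 0.15).
#' @return A `fixation_model`.
#' @export
null_fixation_model <- function(pi = 0.15) {
  fixation_model(lambda0 = 0, pi_live = pi, pi_fixed = pi)
}

#' Per-transcript truncation hazard
#'
#' @param model A [fixation_model()].
#' @param gc Vector of GC fractions.
#' @return `lambda0 * (1 + gamma * (gc - 0.5))`, clipped at 0.
#' @export
hazard_rate <- function(model, gc) {
  pmax(0, model$lambda0 * (1 + model$gamma * (gc - 0.5)))
}

#' Truncation survival function
#'
#' Probability that reverse transcription of a transcript with hazard
#' `lambda` reaches at least `x` bases from the 3' end.
#'
#' @param model A [fixation_model()].
#' @param x Distance from the 3' end, in bases.
#' @param gc GC fraction(s) determining the hazard.
#' @return `exp(-lambda * max(0, x - d0))`, in (0, 1].
#' @export
survival_prob <- function(model, x, gc) {
  exp(-hazard_rate(model, gc) * pmax(0, x - model$d0))
}

#' Simulation configuration
#'
#' Collects every parameter of the synthetic world: a toy transcriptome, two
#' cell types with a continuous cell-cycle covariate, log-normal expression
#' means, and library sizes. Defaults describe a desk-scale version of a
#' two-cell-line full-length scRNA-seq experiment: median transcript length
#' 1200 bases clipped to \[200, 12000\], GC ~ Beta with mean 0.5 and sd 0.1,
#' log-normal expression means with sd 1.5 on the log scale, an 8-fold
#' cell-type effect on a random 10% of transcripts, and a cell-cycle gene set
#' (10% of transcripts) multiplied by `2^(cycle_amp * (phase - 0.5))`.
#'
#' @param n_transcripts Number of transcripts (default 2000).
#' @param n_cells Cells per treatment per cell type (default 50).
#' @param n_cell_types Number of cell types (default 2).
#' @param length_meanlog,length_sdlog Log-normal length parameters
#'   (defaults `log(1200)` and 1.0).
#' @param length_range Lengths are clipped to this range (default
#'   `c(200, 12000)`).
#' @param gc_mean,gc_sd Beta-distributed GC content moments (0.5, 0.1).
#' @param mean_sdlog Sd of log-normal relative expression means (1.5).
#' @param celltype_frac Fraction of transcripts carrying a cell-type effect
#'   (0.10).
#' @param celltype_fc Fold change of the cell-type effect (default 8, large
#'   enough that cell identity outranks cycle and fixation in the PCA, as
#'   distinct cell lines do).
#' @param cycle_frac Fraction of transcripts in the cycle gene set (0.10).
#' @param cycle_amp Amplitude of the cycle effect: cycle genes are multiplied
#'   by `2^(cycle_amp * (phase - 0.5))` (default 5, a ~32-fold swing across
#'   the cycle, making cycle the dominant within-cell-type variance as in
#'   full-length single-cell data of proliferating lines).
#' @param molecules_per_cell Expected mRNA molecules sampled per cell before
#'   capture (default 50000; scaled down from a real cell's 1e5-1e6 mRNA
#'   molecules for tractability).
#' @param read_length Read length in bases for depth simulation (100).
#' @param reads_per_cell Reads per cell for depth simulation (20000; pooled
#'   per treatment group downstream).
#' @param seed Integer seed; every random draw flows from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 2000, n_cells = 50, n_cell_types = 2,
                       length_meanlog = log(1200), length_sdlog = 1.0,
                       length_range = c(200, 12000),
                       gc_mean = 0.5, gc_sd = 0.1,
                       mean_sdlog = 1.5,
                       celltype_frac = 0.10, celltype_fc = 8,
                       cycle_frac = 0.10, cycle_amp = 5,
                       molecules_per_cell = 50000,
                       read_length = 100, reads_per_cell = 20000,
                       seed = 1L) {
  stopifnot(n_transcripts >= 1, n_cells >= 1, n_cell_types >= 1,
            length_sdlog >= 0, gc_sd >= 0, mean_sdlog >= 0,
            molecules_per_cell > 0, read_length >= 1, reads_per_cell >= 0)
  structure(
    list(n_transcripts = as.integer(n_transcripts),
         n_cells = as.integer(n_cells),
         n_cell_types = as.integer(n_cell_types),
         length_meanlog = length_meanlog, length_sdlog = length_sdlog,
         length_range = length_range,
         gc_mean = gc_mean, gc_sd = gc_sd,
         mean_sdlog = mean_sdlog,
         celltype_frac = celltype_frac, celltype_fc = celltype_fc,
         cycle_frac = cycle_frac, cycle_amp = cycle_amp,
         molecules_per_cell = molecules_per_cell,
         read_length = as.integer(read_length),
         reads_per_cell = as.integer(reads_per_cell),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a toy transcript catalog
#'
#' Draws transcript lengths (log-normal, clipped) and GC fractions (beta) and
#' materializes sequences with the target base composition, so running
#' [load_catalog()] on the emitted FASTA reproduces the catalog exactly. The
#' catalog's `gc` column is the realized composition of the generated
#' sequence (within `1/length` of the drawn target).
#'
#' @param config A [sim_config()].
#' @param sequences Materialize sequences (default `TRUE`); with `FALSE` the
#'   drawn GC target is used directly, which is cheaper for replicate studies
#'   that never touch sequence.
#' @return A `transcript_catalog` with a `sequence` column when materialized.
#' @export
simulate_catalog <- function(config, sequences = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_transcripts
  len <- round(stats::rlnorm(n, config$length_meanlog, config$length_sdlog))
  len <- pmin(pmax(len, config$length_range[1]), config$length_range[2])
  if (config$gc_sd == 0) {
    gc <- rep(config$gc_mean, n)
  } else {
    v <- config$gc_sd^2
    m <- config$gc_mean
    if (v >= m * (1 - m)) stop("gc_sd too large for a beta distribution")
    shape <- m * (1 - m) / v - 1
    gc <- stats::rbeta(n, m * shape, (1 - m) * shape)
  }
  ids <- sprintf("tx%04d", seq_len(n))
  if (!sequences) {
    cat <- data.frame(transcript_id = ids, gene_id = ids,
                      length = as.integer(len), gc = gc,
                      stringsAsFactors = FALSE)
    class(cat) <- c("transcript_catalog", "data.frame")
    return(cat)
  }
  # composition is forced: exactly round(gc * len) strong bases per sequence
  seqs <- vapply(seq_len(n), function(i) {
    n_gc <- round(gc[i] * len[i])
    bases <- c(sample(c("G", "C"), n_gc, replace = TRUE),
               sample(c("A", "T"), len[i] - n_gc, replace = TRUE))
    paste(sample(bases), collapse = "")
  }, character(1))
  catalog_from_sequences(ids, seqs, keep_sequence = TRUE)
}

#' Write a catalog's sequences as FASTA
#'
#' @param catalog A catalog with a `sequence` column.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_catalog_fasta <- function(catalog, path) {
  if (is.null(catalog$sequence)) stop("catalog carries no sequences")
  x <- Biostrings::DNAStringSet(catalog$sequence)
  names(x) <- catalog$transcript_id
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

# Baseline relative expression means and per-transcript effect assignments;
# drawn once per seed so live and fixed share the same underlying world.
simulate_world <- function(catalog, config) {
  set.seed(config$seed + 1L)
  n <- nrow(catalog)
  mu <- stats::rlnorm(n, 0, config$mean_sdlog)
  ct_idx <- sample(n, round(config$celltype_frac * n))
  cyc_idx <- sample(setdiff(seq_len(n), ct_idx),
                    max(1L, round(config$cycle_frac * n)))
  list(mu = mu, celltype_transcripts = ct_idx, cycle_transcripts = cyc_idx)
}

#' Simulate live or fixed single-cell expression
#'
#' Per cell, molecule counts per transcript are Poisson with mean
#' `relative mean * molecules_per_cell`; each molecule is captured with the
#' treatment's capture probability. In fixed cells each captured molecule is
#' truncated at a 3'-distance drawn from the fixation model's survival
#' function; under `full_length_required` only molecules surviving to the 5'
#' end enter the count matrix, otherwise every captured molecule contributes
#' its 3'-end count. Molecule records (the covered span from the 3' end) are
#' retained for coverage and window quantification.
#'
#' @param catalog A transcript catalog.
#' @param config A [sim_config()]; cell-type and cycle structure comes from
#'   here.
#' @param model A [fixation_model()].
#' @param treatment `"live"` or `"fixed"`.
#' @param keep_molecules Retain per-molecule spans (default `TRUE`).
#' @return A list with `counts` (transcripts x cells), `cell_data`
#'   (`cell_id`, `treatment`, `cell_type`, `cycle_phase`), `molecules`
#'   (`transcript_id`, `cell`, `span` — bases covered from the 3' end), and
#'   `world` (ground-truth means and effect sets).
#' @export
simulate_cells <- function(catalog, config, model,
                           treatment = c("live", "fixed"),
                           keep_molecules = TRUE) {
  treatment <- match.arg(treatment)
  stopifnot(nrow(catalog) >= 1, inherits(model, "fixation_model"))
  world <- simulate_world(catalog, config)
  n_tx <- nrow(catalog)
  n_cells <- config$n_cells * config$n_cell_types
  set.seed(config$seed + ifelse(treatment == "live", 2L, 3L))

  cell_type <- rep(paste0("type", seq_len(config$n_cell_types)),
                   each = config$n_cells)
  phase <- stats::runif(n_cells)
  cell_id <- sprintf("%s_%s_c%03d", treatment, cell_type, seq_len(n_cells))

  # Per-cell expected molecule counts.
  base <- world$mu
  lam <- matrix(base, n_tx, n_cells)
  if (config$n_cell_types > 1) {
    fc <- rep(1, n_tx)
    fc[world$celltype_transcripts] <- config$celltype_fc
    alt <- cell_type != "type1"
    lam[, alt] <- lam[, alt] * fc
  }
  cyc_mult <- 2^(config$cycle_amp * (phase - 0.5))
  lam[world$cycle_transcripts, ] <-
    lam[world$cycle_transcripts, , drop = FALSE] *
    rep(cyc_mult, each = length(world$cycle_transcripts))
  lam <- sweep(lam, 2, colSums(lam), "/") * config$molecules_per_cell

  pi_cap <- if (treatment == "live") model$pi_live else model$pi_fixed
  mol <- matrix(stats::rpois(n_tx * n_cells, lam), n_tx, n_cells)
  captured <- matrix(stats::rbinom(n_tx * n_cells, mol, pi_cap),
                     n_tx, n_cells)

  lambda_t <- hazard_rate(model, catalog$gc)
  len <- catalog$length
  if (treatment == "fixed") {
    # Full-length survival is a closed-form thinning of the captured counts.
    surv_full <- survival_prob(model, len, catalog$gc)
    if (any(surv_full <= 0 | surv_full > 1)) {
      stop("fixation model yields survival outside (0, 1]")
    }
    counts <- if (model$full_length_required) {
      matrix(stats::rbinom(n_tx * n_cells, captured, surv_full),
             n_tx, n_cells)
    } else {
      captured
    }
  } else {
    counts <- captured
  }
  dimnames(counts) <- list(catalog$transcript_id, cell_id)

  molecules <- NULL
  if (keep_molecules) {
    per_tx <- rowSums(captured)
    tx_idx <- rep.int(seq_len(n_tx), per_tx)
    cell_of <- unlist(lapply(seq_len(n_tx), function(i) {
      rep.int(seq_len(n_cells), captured[i, ])
    }), use.names = FALSE)
    if (treatment == "fixed") {
      # Truncation distance X = d0 + Exp(lambda_t); lambda 0 => never truncates.
      lam_m <- lambda_t[tx_idx]
      x <- rep(Inf, length(tx_idx))
      pos <- lam_m > 0
      x[pos] <- model$d0 + stats::rexp(sum(pos), lam_m[pos])
      span <- pmin(x, len[tx_idx])
    } else {
      span <- as.numeric(len[tx_idx])
    }
    molecules <- data.frame(
      transcript_id = catalog$transcript_id[tx_idx],
      cell = cell_id[cell_of],
      span = floor(span),
      stringsAsFactors = FALSE
    )
  }

  cell_data <- data.frame(
    cell_id = cell_id, treatment = treatment, cell_type = cell_type,
    cycle_phase = phase, stringsAsFactors = FALSE
  )
  list(counts = counts, cell_data = cell_data, molecules = molecules,
       world = world)
}

#' Simulate a live + fixed experiment
#'
#' Runs [simulate_cells()] for both treatments with a shared world and
#' returns the combined count matrix, annotations and molecule records.
#'
#' @inheritParams simulate_cells
#' @return A list with `counts`, `cell_data`, `molecules` (named list with
#'   `live` and `fixed` records) and `world`.
#' @export
simulate_experiment <- function(catalog, config, model,
                                keep_molecules = TRUE) {
  live <- simulate_cells(catalog, config, model, "live", keep_molecules)
  fixed <- simulate_cells(catalog, config, model, "fixed", keep_molecules)
  list(
    counts = cbind(live$counts, fixed$counts),
    cell_data = rbind(live$cell_data, fixed$cell_data),
    molecules = list(live = live$molecules, fixed = fixed$molecules),
    world = live$world
  )
}

#' Simulate per-base depth from molecule records
#'
#' Places reads uniformly within each molecule's covered interval (the `span`
#' bases abutting the 3' end) and accumulates per-base depth per transcript,
#' pooled over the treatment group. A read whose length exceeds the covered
#' span yields a single full-span read. Output follows the three-column
#' `samtools depth` dialect: transcript id, 1-based position (5'->3'), depth.
#'
#' @param molecules Molecule records from [simulate_cells()].
#' @param catalog The transcript catalog (for lengths).
#' @param config A [sim_config()]; `read_length` and `reads_per_cell` scale
#'   the read budget (total reads = `reads_per_cell` x number of cells
#'   contributing molecules).
#' @param n_reads Optional explicit total read count overriding the budget.
#' @param seed Seed for read placement (default `config$seed + 4`).
#' @return A data frame `(transcript_id, pos, depth)`; zero-depth positions
#'   are omitted.
#' @export
simulate_depth <- function(molecules, catalog, config, n_reads = NULL,
                           seed = config$seed + 4L) {
  if (is.null(molecules) || nrow(molecules) == 0L) {
    return(data.frame(transcript_id = character(), pos = integer(),
                      depth = integer(), stringsAsFactors = FALSE))
  }
  set.seed(seed)
  if (is.null(n_reads)) {
    n_reads <- config$reads_per_cell * length(unique(molecules$cell))
  }
  rl <- config$read_length
  tx_idx <- match(molecules$transcript_id, catalog$transcript_id)
  if (anyNA(tx_idx)) stop("molecule records name transcripts absent from catalog")
  len <- catalog$length[tx_idx]
  span <- pmin(molecules$span, len)
  span <- pmax(span, 1L)

  pick <- sample.int(nrow(molecules), n_reads, replace = TRUE)
  m_len <- len[pick]
  m_span <- span[pick]
  int_start <- m_len - m_span + 1L       # covered interval [int_start, m_len]
  r_len <- pmin(rl, m_span)              # short spans give one full-span read
  max_start <- m_len - r_len + 1L
  start <- int_start +
    floor(stats::runif(n_reads) * (max_start - int_start + 1L))
  end <- start + r_len - 1L

  # diff/cumsum accumulation over concatenated transcript coordinates
  offs <- c(0L, cumsum(as.numeric(catalog$length)))
  g_start <- offs[tx_idx[pick]] + start
  g_end <- offs[tx_idx[pick]] + end
  total <- offs[length(offs)]
  delta <- numeric(total + 1L)
  ts <- tabulate(g_start, nbins = total)
  te <- tabulate(g_end + 1L, nbins = total + 1L)
  delta[seq_len(total)] <- ts
  delta <- delta - te
  depth_all <- cumsum(delta[seq_len(total)])

  nz <- which(depth_all > 0)
  tx_of <- findInterval(nz - 0.5, offs)
  data.frame(
    transcript_id = catalog$transcript_id[tx_of],
    pos = as.integer(nz - offs[tx_of]),
    depth = as.integer(depth_all[nz]),
    stringsAsFactors = FALSE
  )
}
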