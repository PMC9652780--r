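# On-disk formats: behavioural trial tables as TSV, epoched EEG as a
# float32 binary array with a JSON sidecar, similarity functions as TSV,
# and a minimal EDF export hook for interoperability.

trial_table_columns <- c(
  "subject", "experiment", "block", "condition", "trial_type", "load",
  "cue_side", "probe_domain", "is_match", "target_deg", "nontarget1_deg",
  "nontarget2_deg", "probed_location", "response", "response_deg", "rt_s",
  "truth_component")

#' Write a behavioural trial table as TSV
#'
#' Emits the package's common TSV dialect (a fixed column set shared by
#' recognition and recall tables); columns absent from `trials` are written
#' as NA.
#'
#' @param trials data.frame of trials.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials_tsv <- function(trials, path) {
  out <- trials
  for (cl in setdiff(trial_table_columns, names(out))) out[[cl]] <- NA
  out <- out[trial_table_columns]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a behavioural trial table from TSV
#' @param path file path.
#' @return data.frame of trials.
#' @export
read_trials_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a similarity function as TSV
#' @param sim a [similarity_function()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sim, path) {
  utils::write.table(data.frame(offset = sim$offsets, f = sim$f), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity function from TSV
#' @param path file path.
#' @param domain domain label for the reconstructed function.
#' @return A [similarity_function()].
#' @export
read_similarity_tsv <- function(path, domain = "orientation") {
  d <- utils::read.delim(path)
  similarity_function(d$offset, d$f, domain = domain)
}

#' Write an epoch_set to disk
#'
#' Stores the voltage array as little-endian float32 (trials x channels x
#' samples, fastest-varying index first, muV) in `epochs.dat`, and all
#' structure (sampling rate, channel names and cluster sides, t0, per-trial
#' metadata, artifact annotations) in a JSON sidecar `epochs.json`.
#'
#' @param epochs an [epoch_set()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "epochs.dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 4, endian = "little")
  sidecar <- list(
    format = "cdawm-epochs-v1",
    dims = dim(epochs$data),
    sfreq_hz = epochs$sfreq,
    t0_s = epochs$t0,
    ch_names = epochs$ch_names,
    ch_cluster = epochs$ch_side,
    cluster_mask = epochs$cluster_mask,
    heog_ch = epochs$heog_ch,
    meta = epochs$meta,
    annotations = epochs$annotations)
  jsonlite::write_json(sidecar, file.path(dir, "epochs.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read an epoch_set from disk
#' @param dir directory written by [write_epochs()].
#' @return An [epoch_set()]. Voltages round-trip at float32 precision.
#' @export
read_epochs <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "epochs.json"), simplifyVector = TRUE)
  dims <- as.integer(sc$dims)
  con <- file(file.path(dir, "epochs.dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = prod(dims), size = 4, endian = "little")
  meta <- if (!is.null(sc$meta)) as.data.frame(sc$meta) else NULL
  ann <- if (!is.null(sc$annotations)) as.data.frame(sc$annotations) else NULL
  epoch_set(array(x, dim = dims), sfreq = sc$sfreq_hz, t0 = sc$t0_s,
            ch_names = sc$ch_names, ch_side = sc$ch_cluster,
            cluster_mask = sc$cluster_mask,
            heog_ch = if (is.null(sc$heog_ch)) NA_character_ else sc$heog_ch,
            meta = meta, annotations = ann)
}

#' Export an epoch_set to EDF (interoperability hook)
#'
#' Minimal 16-bit EDF writer: one data record per epoch, all channels at the
#' epoch sampling rate, physical range taken from the data. Intended only so
#' external EEG tools can open the synthetic epochs; metadata beyond channel
#' labels is not carried.
#'
#' @param epochs an [epoch_set()].
#' @param path output `.edf` file path.
#' @return `path`, invisibly.
#' @export
export_edf <- function(epochs, path) {
  d <- epochs$data
  n_tr <- dim(d)[1]; n_ch <- dim(d)[2]; n_samp <- dim(d)[3]
  phys_min <- floor(min(d)); phys_max <- ceiling(max(d))
  if (phys_min == phys_max) phys_max <- phys_min + 1
  dig_min <- -32768L; dig_max <- 32767L
  pad <- function(x, n) formatC(as.character(x), width = n, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("synthetic epochs", 80), pad("cdawm export", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 + 256 * n_ch, 8), pad("", 44),
    pad(n_tr, 8), pad(format(n_samp / epochs$sfreq, nsmall = 3), 8), pad(n_ch, 4)),
    con, eos = NULL)
  field <- function(vals, width) writeChar(paste(pad(vals, width), collapse = ""),
                                           con, eos = NULL)
  field(epochs$ch_names, 16)
  field(rep("synthetic EEG", n_ch), 80)
  field(rep("uV", n_ch), 8)
  field(rep(phys_min, n_ch), 8)
  field(rep(phys_max, n_ch), 8)
  field(rep(dig_min, n_ch), 8)
  field(rep(dig_max, n_ch), 8)
  field(rep("none", n_ch), 80)
  field(rep(n_samp, n_ch), 8)
  field(rep("", n_ch), 32)
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (i in seq_len(n_tr)) {
    rec <- t(d[i, , , drop = TRUE])          # samples x channels
    if (is.null(dim(rec))) rec <- matrix(rec, ncol = n_ch)
    dig <- as.integer(round((rec - phys_min) * scale + dig_min))
    writeBin(as.vector(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}
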