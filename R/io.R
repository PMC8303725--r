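# Readers/writers for the pipeline's plain-text formats.

#' Read gradient-decay experiments from CSV
#'
#' Columns `resonance_id, gradient_G_per_cm, intensity`; one experiment
#' per resonance id. Acquisition metadata (delta, Delta, gamma) comes from
#' the caller or a config block, not from the CSV.
#'
#' @param path CSV path.
#' @param delta,Delta,gamma acquisition parameters (s, s, rad s^-1 T^-1).
#' @return named list of [decay_experiment()] objects.
#' @export
read_decay_csv <- function(path, delta = 2e-3, Delta = 0.2,
                           gamma = GAMMA_1H) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("resonance_id", "gradient_G_per_cm", "intensity")
  if (!all(need %in% names(df)))
    stop("decay CSV must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$resonance_id), function(d) {
    d <- d[order(d$gradient_G_per_cm), ]
    decay_experiment(d$resonance_id[1], d$gradient_G_per_cm, d$intensity,
                     delta, Delta, gamma, gradient_unit = "G/cm")
  })
  out[unique(df$resonance_id)]
}

#' Write gradient-decay experiments to CSV
#'
#' @param exps list of [decay_experiment()] objects (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_decay_csv <- function(exps, path) {
  if (inherits(exps, "decay_experiment")) exps <- list(exps)
  df <- do.call(rbind, lapply(exps, function(e)
    data.frame(resonance_id = e$resonance_id,
               gradient_G_per_cm = e$gradients / 0.01,
               intensity = e$intensities)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binding-systems table
#'
#' Tab-separated columns `sample, C_host_mM, C_ligand_mM, D_ligand_free,
#' D_host_free, D_obs_ligand, D_obs_host`, diffusion coefficients in units
#' of `D_scale` m^2 s^-1 (default 1e-10, the conventional DOSY scale).
#'
#' @param path TSV path.
#' @param D_scale multiplier converting table D values to m^2 s^-1.
#' @return data frame with D columns converted to m^2 s^-1.
#' @export
read_binding_table <- function(path, D_scale = 1e-10) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "C_host_mM", "C_ligand_mM", "D_ligand_free",
            "D_host_free", "D_obs_ligand", "D_obs_host")
  if (!all(need %in% names(df)))
    stop("binding table must have columns ", paste(need, collapse = ", "))
  for (col in c("D_ligand_free", "D_host_free", "D_obs_ligand",
                "D_obs_host"))
    df[[col]] <- df[[col]] * D_scale
  df
}

#' Estimate binding constants for every row of a binding table
#'
#' @param df data frame from [read_binding_table()].
#' @return data frame with `sample`, `MF_ligand`, `complex_conc_mM`,
#'   `Ka_mM`, `warnings` (";"-joined).
#' @export
binding_table_constants <- function(df) {
  rows <- lapply(seq_len(nrow(df)), function(i) {
    sys <- binding_system(df$C_host_mM[i], df$C_ligand_mM[i],
                          df$D_ligand_free[i], df$D_host_free[i],
                          df$D_obs_ligand[i], df$D_obs_host[i])
    res <- binding_constant(sys)
    data.frame(sample = df$sample[i], MF_ligand = res$MF_ligand,
               complex_conc_mM = res$complex_conc, Ka_mM = res$Ka,
               warnings = paste(res$warnings, collapse = ";"))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read a peak list from CSV
#'
#' @param path CSV with columns `mz` and optionally `intensity`.
#' @return data frame.
#' @export
read_peaklist_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"mz" %in% names(df)) stop("peak CSV must have an mz column")
  if (any(df$mz <= 0)) stop("peak m/z must be positive")
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
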