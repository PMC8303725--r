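# Seeded synthetic-data generators emulating the statistical structure of
# the DOSY, NOE-ensemble and MS inputs, so the whole pipeline is testable
# without external data.

#' Default DOSY gradient schedule
#'
#' 16 gradient strengths from 6 to 50 G/cm in a geometric progression,
#' returned in T/m.
#'
#' @param n number of gradient values.
#' @param g_min,g_max first and last gradient strength in G/cm.
#' @return numeric vector of gradient strengths (T/m).
#' @export
gradient_schedule <- function(n = 16, g_min = 6, g_max = 50) {
  if (n < 2) stop("schedule needs at least 2 gradients")
  g_gcm <- g_min * (g_max / g_min)^(seq(0, n - 1) / (n - 1))
  g_gcm * 0.01
}

#' Generate a synthetic pulsed-field-gradient decay
#'
#' Stejskal-Tanner intensities with multiplicative Gaussian noise:
#' I_k = I(g_k) * (1 + noise_frac * e_k), e_k ~ N(0, 1).
#'
#' @param D diffusion coefficient (m^2 s^-1).
#' @param I0 zero-gradient intensity.
#' @param gradients gradient strengths (T/m); default [gradient_schedule()].
#' @param delta,Delta pulse duration and diffusion time (s); defaults 2 ms
#'   and 200 ms.
#' @param gamma gyromagnetic ratio.
#' @param noise_frac multiplicative noise fraction (0 = noiseless).
#' @param seed integer seed.
#' @param resonance_id label.
#' @return a [decay_experiment()].
#' @export
gen_decay_dataset <- function(D, I0 = 1, gradients = gradient_schedule(),
                              delta = 2e-3, Delta = 0.2,
                              gamma = GAMMA_1H, noise_frac = 0, seed = 1,
                              resonance_id = "sim") {
  ideal <- stejskal_tanner_intensity(D, I0, gradients, delta, Delta, gamma)
  if (noise_frac > 0) {
    set.seed(seed)
    ideal <- ideal * (1 + noise_frac * stats::rnorm(length(ideal)))
    ideal[ideal < 0] <- 0
  }
  decay_experiment(resonance_id, gradients, ideal, delta, Delta, gamma)
}

#' Generate a fast-exchange titration series
#'
#' For each host:ligand ratio the 1:1 equilibrium is solved forward for the
#' complex concentration, observed diffusion coefficients follow from the
#' population-weighted average law, and optional Gaussian noise is applied
#' to the observed values.
#'
#' @param Ka association constant (mM^-1).
#' @param C_host host concentration (mM).
#' @param ligand_ratios ligand:host molar ratios.
#' @param D_free,D_complex free-ligand and complex diffusion coefficients
#'   (m^2 s^-1).
#' @param D_host_free free-host diffusion coefficient; defaults to
#'   `D_complex` (large-host approximation).
#' @param noise_frac relative Gaussian noise on observed D values.
#' @param seed integer seed.
#' @return data frame, one row per ratio, with the [binding_system()]
#'   fields plus `ratio` and the true `complex_conc`.
#' @export
gen_titration_dataset <- function(Ka, C_host, ligand_ratios = c(1, 2, 3),
                                  D_free, D_complex,
                                  D_host_free = D_complex,
                                  noise_frac = 0, seed = 1) {
  if (Ka < 0) stop("Ka must be non-negative")
  set.seed(seed)
  rows <- lapply(ligand_ratios, function(r) {
    C_ligand <- r * C_host
    x <- solve_equilibrium(Ka, C_host, C_ligand)
    MF_L <- 1 - x / C_ligand
    D_obs_L <- MF_L * D_free + (1 - MF_L) * D_complex
    D_obs_H <- D_complex
    if (noise_frac > 0) {
      D_obs_L <- D_obs_L * (1 + noise_frac * stats::rnorm(1))
      D_obs_H <- D_obs_H * (1 + noise_frac * stats::rnorm(1))
    }
    data.frame(ratio = r, C_host_mM = C_host, C_ligand_mM = C_ligand,
               D_ligand_free = D_free, D_host_free = D_host_free,
               D_obs_ligand = D_obs_L, D_obs_host = D_obs_H,
               complex_conc = x)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Generate a toy conformer ensemble with prescribed distance statistics
#'
#' Builds placeholder ligand/duplex proton pairs whose per-model distances
#' are Gaussian around the prescribed means, plus (optionally) a
#' donor/hydrogen/acceptor triple realising a target hydrogen-bond
#' geometry in a prescribed fraction of models. Geometry is intentionally
#' schematic: atoms are placeholders compatible with the
#' `chain:resid:atomname` selector grammar, not chemically valid
#' structures.
#'
#' @param n_models number of models.
#' @param distance_spec data frame with columns `mean_A` and `sd_A`, one
#'   row per proton pair; pair i is generated as atoms `L:i:HA` (chain L)
#'   and `D:i:HB` (chain D) separated along x by N(mean, sd).
#' @param hbond_spec optional list with elements `DA_distance`, `DHA_angle`
#'   (degrees) and `occupancy_fraction`; generates a triple `L:90:DON`,
#'   `L:90:HDN`, `D:90:ACC` satisfying the geometry in that fraction of
#'   models (remaining models get the acceptor displaced beyond reach).
#' @param seed integer seed.
#' @return a `conformer_ensemble`.
#' @export
gen_toy_ensemble <- function(n_models, distance_spec,
                             hbond_spec = NULL, seed = 1) {
  stopifnot(all(c("mean_A", "sd_A") %in% names(distance_spec)))
  if (any(distance_spec$mean_A <= 0))
    stop("infeasible geometry: distance means must be positive")
  set.seed(seed)
  npair <- nrow(distance_spec)
  atoms <- do.call(rbind, lapply(seq_len(npair), function(i) {
    data.frame(chain = c("L", "D"), resno = i, resid = "TOY",
               elety = c("HA", "HB"))
  }))
  if (!is.null(hbond_spec)) {
    atoms <- rbind(atoms,
                   data.frame(chain = c("L", "L", "D"), resno = 90,
                              resid = "TOY",
                              elety = c("DON", "HDN", "ACC")))
  }
  xyz <- matrix(0, nrow = n_models, ncol = 3L * nrow(atoms))
  for (i in seq_len(npair)) {
    d <- stats::rnorm(n_models, distance_spec$mean_A[i],
                      distance_spec$sd_A[i])
    d[d < 0.1] <- 0.1
    base <- c(0, 10 * i, 0)  # pairs well separated from each other
    a_col <- 3L * (2L * i - 2L)
    b_col <- 3L * (2L * i - 1L)
    xyz[, a_col + 1:3] <- matrix(base, n_models, 3, byrow = TRUE)
    xyz[, b_col + 1:3] <- cbind(d, rep(base[2], n_models),
                                rep(base[3], n_models))
  }
  if (!is.null(hbond_spec)) {
    dDA <- hbond_spec$DA_distance
    ang <- hbond_spec$DHA_angle * pi / 180
    occ <- hbond_spec$occupancy_fraction
    # D at origin-ish, H 1.0 A along x; A placed so the D-H...A angle and
    # D...A distance meet the spec. Solve A position in the xz plane.
    off <- 3L * (nrow(atoms) - 3L)
    base <- c(0, 10 * (npair + 2), 0)
    Dpos <- base
    Hpos <- base + c(1, 0, 0)
    # angle at H between H->D (-x) and H->A; put A at angle theta from -x
    # with |DA| = dDA: find t >= 0 with |D - (H + t*u)| = dDA
    u <- c(-cos(ang), 0, sin(ang))
    hd <- Hpos - Dpos
    bq <- 2 * sum(u * hd)
    cq <- sum(hd^2) - dDA^2
    t <- (-bq + sqrt(bq^2 - 4 * cq)) / 2
    Apos_ok <- Hpos + t * u
    Apos_bad <- Hpos + c(8, 0, 0)  # far beyond any DA cutoff
    ok <- stats::runif(n_models) < occ
    xyz[, off + 1:3] <- matrix(Dpos, n_models, 3, byrow = TRUE)
    xyz[, off + 4:6] <- matrix(Hpos, n_models, 3, byrow = TRUE)
    xyz[, off + 7:9] <- t(vapply(ok, function(o)
      if (o) Apos_ok else Apos_bad, numeric(3)))
  }
  conformer_ensemble(atoms, xyz)
}

#' Generate an ensemble of jittered copies of planted conformations
#'
#' Useful for cluster-recovery tests: each group is an isotropic Gaussian
#' cloud (in coordinate space) around its template conformation.
#'
#' @param templates list of n_atoms x 3 coordinate matrices (identical
#'   dimensions).
#' @param n_per_group models per template (recycled).
#' @param jitter_sd isotropic Gaussian jitter (Angstrom).
#' @param seed integer seed.
#' @return list with `ensemble` (a `conformer_ensemble`) and
#'   `group` (true group index per model).
#' @export
gen_planted_ensemble <- function(templates, n_per_group, jitter_sd = 0.1,
                                 seed = 1) {
  set.seed(seed)
  na <- nrow(templates[[1]])
  n_per_group <- rep_len(n_per_group, length(templates))
  atoms <- data.frame(chain = "L", resno = seq_len(na), resid = "TOY",
                      elety = "CA")
  rows <- list(); group <- integer(0)
  for (gi in seq_along(templates)) {
    for (r in seq_len(n_per_group[gi])) {
      x <- templates[[gi]] +
        matrix(stats::rnorm(3 * na, 0, jitter_sd), na, 3)
      rows[[length(rows) + 1L]] <- as.numeric(t(x))
      group <- c(group, gi)
    }
  }
  list(ensemble = conformer_ensemble(atoms, do.call(rbind, rows)),
       group = group)
}

#' Generate a synthetic peak list
#'
#' Expected m/z values jittered by additive Gaussian noise, plus uniform
#' decoy peaks.
#'
#' @param expected_mz numeric vector of true species m/z.
#' @param jitter_Da additive Gaussian SD in Da.
#' @param n_noise_peaks number of uniform decoy peaks.
#' @param mz_range range for decoy peaks; default spans the expected m/z
#'   +/- 50 Da.
#' @param seed integer seed.
#' @return data frame with `mz`, `intensity` and `is_decoy`.
#' @export
gen_peaklist <- function(expected_mz, jitter_Da = 0, n_noise_peaks = 0,
                         mz_range = NULL, seed = 1) {
  if (jitter_Da < 0) stop("jitter must be non-negative")
  set.seed(seed)
  mz <- expected_mz + stats::rnorm(length(expected_mz), 0, jitter_Da)
  inten <- stats::runif(length(expected_mz), 50, 100)
  decoy <- logical(length(mz))
  if (n_noise_peaks > 0) {
    if (is.null(mz_range))
      mz_range <- range(expected_mz) + c(-50, 50)
    mz <- c(mz, stats::runif(n_noise_peaks, mz_range[1], mz_range[2]))
    inten <- c(inten, stats::runif(n_noise_peaks, 1, 20))
    decoy <- c(decoy, rep(TRUE, n_noise_peaks))
  }
  ord <- order(mz)
  data.frame(mz = mz[ord], intensity = inten[ord], is_decoy = decoy[ord])
}
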