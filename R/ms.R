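# Formula arithmetic, transformation rules (hydrolysis / retro-Mannich /
# quinone-methide alkylation) and peak assignment for ESI and MALDI spectra.

# Embedded element mass table, version 2021 IUPAC standard atomic weights
# (average) and most-abundant-isotope masses (monoisotopic); nominal masses
# are the integer mass numbers of the most abundant isotope.
.element_masses <- local({
  tab <- rbind(
    #            nominal  monoisotopic     average
    H  = c( 1,  1.00782503207,  1.008),
    C  = c(12, 12.0000000000,  12.011),
    N  = c(14, 14.0030740048,  14.007),
    O  = c(16, 15.9949146196,  15.999),
    P  = c(31, 30.97376163,    30.974),
    S  = c(32, 31.97207100,    32.06),
    Na = c(23, 22.9897692809,  22.990),
    K  = c(39, 38.96370668,    39.098),
    Cl = c(35, 34.96885268,    35.45),
    F  = c(19, 18.99840322,    18.998),
    Br = c(79, 78.9183371,     79.904),
    I  = c(127, 126.904473,   126.904),
    Si = c(28, 27.9769265325,  28.085),
    B  = c(11, 11.0093054,     10.81)
  )
  colnames(tab) <- c("nominal", "monoisotopic", "average")
  tab
})

# proton mass added/subtracted on (de)protonation, per mass mode
.proton_mass <- c(nominal = 1, monoisotopic = 1.007276, average = 1.008)

#' Parse a molecular formula in Hill-like notation
#'
#' @param text formula string, e.g. `"C22H20N2O5"` or `"H2O"`. Element
#'   symbols are one capital optionally followed by one lowercase letter;
#'   counts default to 1. Repeated symbols accumulate.
#' @return named integer vector of class `formula_counts` (element -> count).
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("formula must be a single non-empty string")
  pos <- 1L
  n <- nchar(text)
  counts <- integer(0)
  while (pos <= n) {
    m <- regmatches(substr(text, pos, n),
                    regexpr("^[A-Z][a-z]?[0-9]*", substr(text, pos, n)))
    if (length(m) == 0L || !nzchar(m))
      stop(sprintf("formula parse error at position %d in '%s'", pos, text))
    sym <- regmatches(m, regexpr("^[A-Z][a-z]?", m))
    cnt_s <- sub("^[A-Z][a-z]?", "", m)
    cnt <- if (nzchar(cnt_s)) as.integer(cnt_s) else 1L
    if (!sym %in% rownames(.element_masses))
      stop(sprintf("unknown element '%s' at position %d in '%s'",
                   sym, pos, text))
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + cnt
    pos <- pos + nchar(m)
  }
  if (length(counts) == 0L || sum(counts) == 0L)
    stop("formula must contain at least one atom")
  structure(counts, class = "formula_counts")
}

#' Canonical Hill-notation string for a formula
#'
#' @param f named counts from [parse_formula()] or a formula string.
#' @return character string, carbon then hydrogen then other elements
#'   alphabetically.
#' @export
format_formula <- function(f) {
  f <- as_formula(f)
  f <- f[f > 0]
  syms <- names(f)
  ord <- if ("C" %in% syms) {
    c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  } else sort(syms)
  paste0(vapply(ord, function(s)
    paste0(s, if (f[[s]] > 1L) f[[s]] else ""), ""), collapse = "")
}

as_formula <- function(f) {
  if (inherits(f, "formula_counts")) return(f)
  if (is.character(f)) return(parse_formula(f))
  stop("expected a formula string or formula_counts object")
}

#' Element-wise formula arithmetic
#'
#' `formula_add` sums counts; `formula_subtract` errors if any count would
#' go negative (infeasible transformation).
#'
#' @param a,b formulas (strings or `formula_counts`).
#' @return `formula_counts`.
#' @export
formula_add <- function(a, b) {
  a <- as_formula(a); b <- as_formula(b)
  syms <- union(names(a), names(b))
  out <- vapply(syms, function(s) {
    (if (s %in% names(a)) a[[s]] else 0L) +
      (if (s %in% names(b)) b[[s]] else 0L)
  }, integer(1))
  structure(out, class = "formula_counts")
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  a <- as_formula(a); b <- as_formula(b)
  syms <- union(names(a), names(b))
  out <- vapply(syms, function(s) {
    (if (s %in% names(a)) a[[s]] else 0L) -
      (if (s %in% names(b)) b[[s]] else 0L)
  }, integer(1))
  if (any(out < 0L))
    stop(sprintf("infeasible transformation: negative count for %s",
                 paste(syms[out < 0L], collapse = ", ")))
  structure(out[out > 0L], class = "formula_counts")
}

#' Molecular mass of a formula
#'
#' @param f formula (string or `formula_counts`).
#' @param mode `"monoisotopic"`, `"average"` or `"nominal"`.
#' @return mass in Da.
#' @export
formula_mass <- function(f, mode = c("monoisotopic", "average", "nominal")) {
  mode <- match.arg(mode)
  f <- as_formula(f)
  sum(.element_masses[names(f), mode] * as.numeric(f))
}

#' m/z of a singly charged (or neutral) ion
#'
#' @param f formula of the neutral molecule.
#' @param ion one of `"[M+H]+"`, `"[M-H]-"`, `"M"`.
#' @param mode mass mode, as in [formula_mass()].
#' @return m/z (charge 1 assumed).
#' @export
ion_mz <- function(f, ion = c("[M+H]+", "[M-H]-", "M"),
                   mode = c("monoisotopic", "average", "nominal")) {
  ion <- match.arg(ion)
  mode <- match.arg(mode)
  m <- formula_mass(f, mode)
  p <- .proton_mass[[mode]]
  switch(ion, "[M+H]+" = m + p, "[M-H]-" = m - p, "M" = m)
}

#' Derive a product formula under a degradation/alkylation rule
#'
#' The 9-aminomethyl camptothecins carry an exocyclic CH2-NR leaving system:
#' \describe{
#'   \item{hydrolysis}{amine replaced by hydroxyl: parent - amine + H2O.}
#'   \item{retro_mannich}{loss of the whole CH2=NR fragment regenerating
#'     SN38: parent - amine - CH2 + H2.}
#'   \item{qm_alkylation}{neutral quinone-methide adduct fragment added to a
#'     nucleophile: parent - amine.}
#' }
#'
#' @param parent parent formula (string or `formula_counts`).
#' @param rule transformation name.
#' @param amine formula of the leaving amine (e.g. `"CH5N"` for methylamine,
#'   `"C4H9NO"` for morpholine).
#' @return product `formula_counts`.
#' @export
apply_transformation <- function(parent,
                                 rule = c("hydrolysis", "retro_mannich",
                                          "qm_alkylation"),
                                 amine) {
  rule <- match.arg(rule)
  parent <- as_formula(parent)
  amine <- as_formula(amine)
  switch(rule,
    hydrolysis = formula_add(formula_subtract(parent, amine), "H2O"),
    retro_mannich = formula_add(
      formula_subtract(formula_subtract(parent, amine), "CH2"), "H2"),
    qm_alkylation = formula_subtract(parent, amine))
}

#' Expected m/z of an alkylated host-ligand biohybrid
#'
#' The host (oligonucleotide) mass is taken from its observed free-host
#' peak, so the prediction is sequence independent: biohybrid m/z =
#' host peak + mass of the quinone-methide adduct fragment
#' (parent - amine).
#'
#' @param host_peak observed m/z of the free host.
#' @param ligand parent ligand formula.
#' @param amine leaving amine formula.
#' @param mode mass mode (MALDI of ~7 kDa species: `"average"`).
#' @return predicted biohybrid m/z.
#' @export
biohybrid_mz <- function(host_peak, ligand, amine, mode = "average") {
  if (!is.numeric(host_peak) || host_peak <= 0)
    stop("invalid input: host peak m/z must be positive")
  adduct <- apply_transformation(ligand, "qm_alkylation", amine)
  host_peak + formula_mass(adduct, mode)
}

#' Assign peaks in a spectrum to candidate species
#'
#' Each peak is matched to every candidate whose expected m/z lies within
#' `tolerance`; the `assigned` column keeps, per peak, the candidate with
#' the smallest absolute mass error. Unmatched peaks are listed with `NA`
#' species.
#'
#' @param peaks data frame with columns `mz` and optionally `intensity`,
#'   or a numeric vector of m/z values.
#' @param candidates data frame with columns `name` and `expected_mz`
#'   (use [candidate_table()] to build one from formulas).
#' @param tolerance matching tolerance in Da.
#' @return data frame of class `assignment_report`: `peak_mz`, `species`,
#'   `expected_mz`, `delta_Da`, `matched`.
#' @export
assign_peaks <- function(peaks, candidates, tolerance = 0.5) {
  if (is.numeric(peaks)) peaks <- data.frame(mz = peaks)
  stopifnot(is.data.frame(peaks), "mz" %in% names(peaks))
  stopifnot(is.data.frame(candidates),
            all(c("name", "expected_mz") %in% names(candidates)))
  if (tolerance <= 0) stop("tolerance must be positive")
  if (nrow(candidates) == 0L) stop("candidate list must be non-empty")
  if (any(peaks$mz <= 0)) stop("peak m/z must be positive")
  if (nrow(peaks) == 0L) {
    out <- data.frame(peak_mz = numeric(0), species = character(0),
                      expected_mz = numeric(0), delta_Da = numeric(0),
                      matched = logical(0))
    class(out) <- c("assignment_report", "data.frame")
    return(out)
  }
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    mz <- peaks$mz[i]
    delta <- mz - candidates$expected_mz
    hit <- which(abs(delta) <= tolerance)
    if (length(hit) == 0L) {
      return(data.frame(peak_mz = mz, species = NA_character_,
                        expected_mz = NA_real_, delta_Da = NA_real_,
                        matched = FALSE))
    }
    hit <- hit[order(abs(delta[hit]))][1L]
    data.frame(peak_mz = mz, species = candidates$name[hit],
               expected_mz = candidates$expected_mz[hit],
               delta_Da = delta[hit], matched = TRUE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$peak_mz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("assignment_report", "data.frame")
  out
}

#' Build a candidate table from formulas and ion types
#'
#' @param names character vector of species names.
#' @param formulas character vector of molecular formulas (same length).
#' @param ion ion type applied to every formula (see [ion_mz()]), or a
#'   vector of ion types per species.
#' @param mode mass mode.
#' @return data frame with `name`, `formula`, `ion`, `expected_mz`.
#' @export
candidate_table <- function(names, formulas, ion = "[M+H]+",
                            mode = "monoisotopic") {
  stopifnot(length(names) == length(formulas))
  ion <- rep_len(ion, length(names))
  data.frame(name = names, formula = formulas, ion = ion,
             expected_mz = mapply(function(f, i) ion_mz(f, i, mode),
                                  formulas, ion, USE.NAMES = FALSE))
}

#' Read a compound registry from JSON
#'
#' The registry maps compound names to molecular formulas and (optionally)
#' the leaving amine used by the transformation rules, e.g.
#' `{"SN38": {"formula": "C22H20N2O5"}, "2": {"formula": "C24H25N3O5",
#' "amine": "CH5N"}}`.
#'
#' @param path JSON file path.
#' @return named list of entries with `formula` and optional `amine`.
#' @export
read_compound_registry <- function(path) {
  reg <- jsonlite::read_json(path)
  for (nm in names(reg)) {
    if (is.null(reg[[nm]]$formula))
      stop(sprintf("registry entry '%s' lacks a formula", nm))
    parse_formula(reg[[nm]]$formula)  # validate
  }
  reg
}
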