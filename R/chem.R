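# Monoisotopic mass bookkeeping: elements, residues, modifications, fragments,
# and the lactyllysine diagnostic (cyclic immonium) ion.

# Monoisotopic atomic masses (Da); carbon-12 defines the scale.
.element_masses <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151
)

.proton_mass <- 1.007276466621
.electron_mass <- 0.00054857990907

# Residue (amino-acid minus water) elemental compositions.
.residue_formulas <- c(
  G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",  T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO", N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",  R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

#' Monoisotopic mass of a chemical formula
#'
#' Parses a Hill-style formula such as `"C3H4O2"` and returns its monoisotopic
#' mass. This is the single source for every modification delta used in a
#' search: lactyl (`C3H4O2`, +72.0211 Da), carbamidomethyl (`C2H3NO`,
#' +57.0215 Da), oxidation (`O`, +15.9949 Da) and acetyl (`C2H2O`,
#' +42.0106 Da).
#'
#' @param formula Character scalar, e.g. `"C3H4O2"`. The empty string has
#'   mass 0.
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' formula_mass("C3H4O2")  # the lactyl delta, rounds to 72.02
formula_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  if (!nzchar(formula)) return(0)
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (paste(tokens, collapse = "") != formula) {
    stop("malformed chemical formula: ", formula)
  }
  total <- 0
  for (tok in tokens) {
    sym <- gsub("[0-9]", "", tok)
    cnt <- gsub("[^0-9]", "", tok)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!sym %in% names(.element_masses)) {
      stop("unknown element symbol: ", sym)
    }
    total <- total + .element_masses[[sym]] * cnt
  }
  total
}

#' Monoisotopic residue masses
#' @return Named numeric vector over the 20 canonical amino acids (Da).
#' @export
residue_masses <- function() {
  vapply(.residue_formulas, formula_mass, numeric(1))
}

#' Define a peptide modification
#'
#' @param name Short token, e.g. `"lactyl"`.
#' @param formula Elemental delta, e.g. `"C3H4O2"`.
#' @param targets Character vector of residue letters the modification can sit
#'   on; `"*"` means any residue (used with an N-terminal position rule).
#' @param position_rule `"anywhere"` or `"protein-N-term"`.
#' @param variable Logical; `FALSE` marks a fixed modification applied to every
#'   target residue.
#' @return A `modification` object (list with the fields above plus the
#'   computed monoisotopic `delta` in Da).
#' @export
modification <- function(name, formula, targets,
                         position_rule = c("anywhere", "protein-N-term"),
                         variable = TRUE) {
  position_rule <- match.arg(position_rule)
  stopifnot(length(targets) >= 1L)
  out <- list(
    name = name, formula = formula, delta = formula_mass(formula),
    targets = targets, position_rule = position_rule, variable = variable
  )
  class(out) <- "modification"
  out
}

#' @export
print.modification <- function(x, ...) {
  cat(sprintf("<modification> %s (%s, %+0.4f Da) on [%s], %s, %s\n",
              x$name, x$formula, x$delta, paste(x$targets, collapse = ""),
              x$position_rule, if (x$variable) "variable" else "fixed"))
  invisible(x)
}

#' The default search modification set
#'
#' Carbamidomethylation of cysteine as fixed; methionine oxidation, lysine
#' lactylation and protein N-terminal acetylation as variable — the standard
#' lactylproteome search configuration.
#'
#' @return Named list of [modification()] objects.
#' @export
default_modifications <- function() {
  list(
    carbamidomethyl = modification("carbamidomethyl", "C2H3NO", "C",
                                   variable = FALSE),
    oxidation = modification("oxidation", "O", "M"),
    lactyl = modification("lactyl", "C3H4O2", "K"),
    acetyl_nterm = modification("acetyl_nterm", "C2H2O", "*",
                                position_rule = "protein-N-term")
  )
}

#' Load modification definitions from a JSON config
#'
#' Expects an array of objects with fields `name`, `formula`, `targets`,
#' and optionally `position_rule` and `variable`.
#'
#' @param path Path to a JSON file.
#' @return Named list of [modification()] objects.
#' @export
read_modifications <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  mods <- lapply(cfg, function(m) {
    modification(
      name = m$name, formula = m$formula,
      targets = unlist(m$targets),
      position_rule = if (is.null(m$position_rule)) "anywhere" else m$position_rule,
      variable = if (is.null(m$variable)) TRUE else isTRUE(m$variable)
    )
  })
  names(mods) <- vapply(mods, `[[`, character(1), "name")
  mods
}

#' Construct a peptide form
#'
#' A peptide form is a sequence plus positioned modifications — the unit that
#' carries mass and fragmentation semantics throughout the pipeline.
#'
#' @param sequence Uppercase amino-acid string (20 canonical letters).
#' @param mods Named list mapping 1-based position (as character or integer
#'   names) to [modification()] objects; at most one per position.
#' @param charge Positive integer precursor charge, or `NA` if unset.
#' @param is_protein_nterm Logical; whether position 1 of this peptide is the
#'   protein N-terminus (enables N-terminal position rules).
#' @return A `peptide_form` object.
#' @export
peptide_form <- function(sequence, mods = list(), charge = NA_integer_,
                         is_protein_nterm = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  residues <- strsplit(sequence, "")[[1]]
  if (!all(residues %in% names(.residue_formulas))) {
    stop("unknown residue letter in sequence: ", sequence)
  }
  if (length(mods)) {
    pos <- as.integer(names(mods))
    if (anyNA(pos) || any(pos < 1L) || any(pos > length(residues))) {
      stop("modification position out of range")
    }
    if (anyDuplicated(pos)) stop("at most one modification per position")
    for (i in seq_along(mods)) {
      m <- mods[[i]]
      ok <- ("*" %in% m$targets) || (residues[pos[i]] %in% m$targets)
      if (m$position_rule == "protein-N-term") {
        ok <- ok && pos[i] == 1L && is_protein_nterm
      }
      if (!ok) {
        stop(sprintf("modification %s not permitted at position %d (%s)",
                     m$name, pos[i], residues[pos[i]]))
      }
    }
    mods <- mods[order(pos)]
  }
  if (!is.na(charge)) stopifnot(charge >= 1L)
  structure(
    list(sequence = sequence, mods = mods, charge = as.integer(charge),
         is_protein_nterm = is_protein_nterm),
    class = "peptide_form"
  )
}

# Per-position modification deltas as a numeric vector of peptide length.
.mod_delta_vector <- function(p) {
  n <- nchar(p$sequence)
  d <- numeric(n)
  if (length(p$mods)) {
    d[as.integer(names(p$mods))] <-
      vapply(p$mods, `[[`, numeric(1), "delta")
  }
  d
}

#' Compact modification string for a peptide form
#'
#' Encodes positioned deltas as e.g. `"K5+72.021129"`, semicolon-joined;
#' the empty string for an unmodified form.
#' @param p A [peptide_form()].
#' @return Character scalar.
#' @export
mod_string <- function(p) {
  if (!length(p$mods)) return("")
  pos <- as.integer(names(p$mods))
  res <- strsplit(p$sequence, "")[[1]][pos]
  paste(sprintf("%s%d%+0.6f", res, pos,
                vapply(p$mods, `[[`, numeric(1), "delta")),
        collapse = ";")
}

# Parse "K5+72.021129;M8+15.994915" back into positions and deltas.
.parse_mod_string <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(pos = integer(0), delta = numeric(0)))
  }
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([A-Z])([0-9]+)([+-][0-9.]+)$", parts))
  if (any(lengths(m) != 4L)) stop("malformed mod string: ", s)
  data.frame(
    pos = as.integer(vapply(m, `[[`, character(1), 3L)),
    delta = as.numeric(vapply(m, `[[`, character(1), 4L))
  )
}

#' Neutral monoisotopic mass of a peptide form
#'
#' Residue masses plus water plus all modification deltas.
#'
#' @param p A [peptide_form()].
#' @return Neutral mass in Da.
#' @export
#' @examples
#' peptide_mass(peptide_form("PEPTIDE"))  # 799.3600
peptide_mass <- function(p) {
  stopifnot(inherits(p, "peptide_form"))
  rm <- residue_masses()
  sum(rm[strsplit(p$sequence, "")[[1]]]) + formula_mass("H2O") +
    sum(.mod_delta_vector(p))
}

#' Theoretical b/y fragment ions of a peptide form
#'
#' Emits the full b1..b(n-1) and y1..y(n-1) ladders at each requested charge,
#' with modification masses carried by the fragment containing the modified
#' position. m/z = (fragment neutral mass + z * proton) / z. Only b/y series
#' are modelled (HCD fragmentation).
#'
#' @param p A [peptide_form()] of length >= 2.
#' @param charges Integer vector of positive fragment charges.
#' @return data.frame with columns `series`, `index`, `charge`, `mz`, `label`,
#'   ordered by series, index, charge.
#' @export
fragment_ions <- function(p, charges = 1L) {
  stopifnot(inherits(p, "peptide_form"), nchar(p$sequence) >= 2L)
  charges <- as.integer(charges)
  if (any(charges <= 0L)) stop("fragment charge must be positive")
  rm <- residue_masses()
  res <- rm[strsplit(p$sequence, "")[[1]]] + .mod_delta_vector(p)
  n <- length(res)
  water <- formula_mass("H2O")
  b_neutral <- cumsum(res)[-n]                # prefix of length i
  y_neutral <- cumsum(rev(res))[-n] + water   # suffix of length i, plus water
  out <- do.call(rbind, lapply(charges, function(z) {
    data.frame(
      series = rep(c("b", "y"), each = n - 1L),
      index = rep(seq_len(n - 1L), 2L),
      charge = z,
      mz = c((b_neutral + z * .proton_mass) / z,
             (y_neutral + z * .proton_mass) / z),
      label = c(sprintf("b%d^%d", seq_len(n - 1L), z),
                sprintf("y%d^%d", seq_len(n - 1L), z)),
      stringsAsFactors = FALSE
    )
  }))
  out[order(out$series, out$index, out$charge), , drop = FALSE]
}

#' The lactyllysine cyclic immonium (CycIm) diagnostic ion
#'
#' The cyclic immonium ion of lactyllysine — the immonium ion
#' (residue - CO + H) with loss of ammonia, cation formula C8H14NO2+ — whose
#' presence in an MS/MS spectrum evidences an intra-peptide lactylated lysine.
#' The m/z is computed from the elemental composition (formula mass minus one
#' electron), not hard-coded.
#'
#' @return List with `name`, `formula`, `mz` (singly charged, Da).
#' @export
#' @examples
#' cycim_ion()$mz  # 156.1019
cycim_ion <- function() {
  list(name = "CycIm-Klac", formula = "C8H14NO2",
       mz = formula_mass("C8H14NO2") - .electron_mass)
}

#' The open (non-cyclic) lactyllysine immonium ion
#'
#' The plain immonium cation of lactyllysine, C8H17N2O2+; it exceeds the
#' cyclic form by exactly one ammonia.
#'
#' @return List with `name`, `formula`, `mz` (singly charged, Da).
#' @export
open_immonium_ion <- function() {
  list(name = "Im-Klac", formula = "C8H17N2O2",
       mz = formula_mass("C8H17N2O2") - .electron_mass)
}
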