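# Elemental-formula arithmetic and oligonucleotide mass calculation for
# modified RNA. All masses are computed from elemental compositions; no
# residue mass is ever stored as a decimal constant.

ELEMENTS <- c("C", "H", "N", "O", "P", "S")

# Monoisotopic masses (IUPAC/CODATA) and standard average atomic weights
# (IUPAC 2005), both to 6 decimals.
.MASS_MONO <- c(C = 12, H = 1.007825, N = 14.003074, O = 15.994915,
                P = 30.973762, S = 31.972071)
.MASS_AVG <- c(C = 12.0107, H = 1.00794, N = 14.0067, O = 15.9994,
               P = 30.973762, S = 32.065)

#' Mass of the proton used for negative-mode m/z arithmetic (Da)
#' @export
PROTON_MASS <- 1.007276

#' Build an elemental formula
#'
#' An elemental formula is a named numeric vector over the elements
#' C, H, N, O, P, S. Counts may be negative for deltas (e.g. the
#' 2-thio substitution is `+S-O`); a physical molecule has all counts
#' non-negative. Formulas add element-wise with ordinary `+`/`-`.
#'
#' @param C,H,N,O,P,S signed integer element counts.
#' @return A named numeric vector of length 6.
#' @examples
#' formula(H = 2, O = 1)            # water
#' formula(C = 1, H = 2)            # a methylation delta
#' @export
formula <- function(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0) {
  fm <- c(C = C, H = H, N = N, O = O, P = P, S = S)
  if (any(!is.finite(fm))) stop("element counts must be finite")
  fm
}

#' Parse an elemental formula string such as "C3H3N" or "S-O"
#'
#' Accepts Hill-style strings with an optional sign per element group;
#' a sign applies only to the group it prefixes (e.g. `"C5H7NO4"`;
#' `"S-O"` is +1 S, -1 O). An empty string gives the empty formula.
#'
#' @param x a single formula string.
#' @return A named numeric vector as from [formula()].
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  fm <- formula()
  x <- gsub("[[:space:]]", "", x)
  if (nchar(x) == 0L) return(fm)
  m <- gregexpr("([+-]?)([A-Z][a-z]?)([0-9]*)", x, perl = TRUE)
  parts <- regmatches(x, m)[[1]]
  if (sum(nchar(parts)) != nchar(x))
    stop("cannot parse formula string: ", x)
  for (p in parts) {
    g <- regmatches(p, regexec("([+-]?)([A-Z][a-z]?)([0-9]*)", p))[[1]]
    sign <- if (g[2] == "-") -1 else 1
    el <- g[3]
    if (!el %in% ELEMENTS) stop("unknown element symbol: ", el)
    n <- if (g[4] == "") 1L else as.integer(g[4])
    fm[el] <- fm[el] + sign * n
  }
  fm
}

#' Format an elemental formula as a string
#' @param fm an elemental formula.
#' @return A single string, e.g. `"C10H13N5O4"`.
#' @export
format_formula <- function(fm) {
  pos <- fm[fm != 0]
  if (length(pos) == 0L) return("")
  paste0(vapply(names(pos), function(el) {
    n <- pos[[el]]
    s <- if (n < 0) "-" else ""
    paste0(s, el, if (abs(n) != 1) abs(n) else "")
  }, character(1)), collapse = "")
}

#' Mass of an elemental formula
#'
#' @param fm an elemental formula (named numeric over C,H,N,O,P,S).
#' @param mode `"mono"` for monoisotopic, `"average"` for standard
#'   average atomic weights.
#' @return Mass in Da; additive over formula addition.
#' @examples
#' formula_mass(formula(H = 2, O = 1))              # 18.0106
#' formula_mass(parse_formula("C3H3N"))             # cyanoethyl, 53.0266
#' @export
formula_mass <- function(fm, mode = c("mono", "average")) {
  mode <- match.arg(mode)
  if (is.null(names(fm)) || !all(names(fm) %in% ELEMENTS))
    stop("unknown element symbol in formula")
  if (any(!is.finite(fm))) stop("element counts must be finite")
  w <- if (mode == "mono") .MASS_MONO else .MASS_AVG
  sum(w[names(fm)] * fm)
}

# ---- residue table ---------------------------------------------------------

# Nucleoside elemental formulas of the four standard ribonucleosides.
.PARENT_NUCLEOSIDE <- list(
  A = formula(C = 10, H = 13, N = 5, O = 4),
  G = formula(C = 10, H = 13, N = 5, O = 5),
  C = formula(C = 9, H = 13, N = 3, O = 5),
  U = formula(C = 9, H = 12, N = 2, O = 6)
)

# Nucleobase (neutral BH) formulas, used for a-B CID ions.
.PARENT_BASE <- list(
  A = formula(C = 5, H = 5, N = 5),
  G = formula(C = 5, H = 5, N = 5, O = 1),
  C = formula(C = 4, H = 5, N = 3, O = 1),
  U = formula(C = 4, H = 4, N = 2, O = 2)
)

# Modification deltas relative to the parent nucleoside, as elemental
# formulas (community modification-reference compositions). Y is the
# one-letter short name for pseudouridine; it is mass-silent (delta 0).
.RESIDUE_DEF <- list(
  #        parent delta
  A        = c("A", ""),
  G        = c("G", ""),
  C        = c("C", ""),
  U        = c("U", ""),
  m1A      = c("A", "CH2"),
  m1G      = c("G", "CH2"),
  m2G      = c("G", "CH2"),
  m22G     = c("G", "C2H4"),
  m3C      = c("C", "CH2"),
  m5C      = c("C", "CH2"),
  m5U      = c("U", "CH2"),
  m6A      = c("A", "CH2"),
  Y        = c("U", ""),
  ce1Y     = c("U", "C3H3N"),
  D        = c("U", "H2"),
  s2U      = c("U", "S-O"),
  i6A      = c("A", "C5H8"),
  ms2i6A   = c("A", "C6H10S"),
  t6A      = c("A", "C5H7NO4"),
  tm5U     = c("U", "C3H7NO3S"),
  tm5s2U   = c("U", "C3H7NO3S2-O"),
  cmnm5U   = c("U", "C3H5NO2"),
  cmnm5s2U = c("U", "C3H5NO2S-O"),
  f5C      = c("C", "CO"),
  Q        = c("G", "C7H10O2"),
  cetm5U   = c("U", "C6H10N2O3S"),
  cetm5s2U = c("U", "C6H10N2O3S2-O"),
  ceQ     = c("G", "C10H13NO2")
)

# Display symbols for the short names that differ from their code form.
.RESIDUE_DISPLAY <- c(Y = "Ψ", ce1Y = "ce1Ψ", tm5U = "τm5U",
                      tm5s2U = "τm5s2U")

#' Table of supported residues (standard and modified ribonucleosides)
#'
#' Short names follow field usage (`m1A`, `m22G`, `i6A`, `tm5s2U`, ...),
#' with `Y` for pseudouridine and `ce1Y` for 1-cyanoethylpseudouridine.
#' Each modified residue is defined by its parent base and an elemental
#' delta formula; the nucleoside formula is parent + delta.
#'
#' @return A data.frame with columns `short_name`, `parent`, `formula`
#'   (nucleoside), `delta` (vs parent), `display`.
#' @export
residue_table <- function() {
  sn <- names(.RESIDUE_DEF)
  data.frame(
    short_name = sn,
    parent = vapply(.RESIDUE_DEF, `[`, character(1), 1L),
    formula = vapply(sn, function(s) format_formula(residue_formula(s)),
                     character(1)),
    delta = vapply(.RESIDUE_DEF, `[`, character(1), 2L),
    display = ifelse(sn %in% names(.RESIDUE_DISPLAY),
                     .RESIDUE_DISPLAY[sn], sn),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Nucleoside elemental formula of a residue short name
#' @param short_name a residue short name, e.g. `"m1A"`.
#' @return An elemental formula.
#' @export
residue_formula <- function(short_name) {
  def <- .RESIDUE_DEF[[short_name]]
  if (is.null(def)) stop("unknown residue name: ", short_name)
  .PARENT_NUCLEOSIDE[[def[1]]] + parse_formula(def[2])
}

#' Parent base of a residue short name
#' @param short_name residue short name(s).
#' @return Character vector of parent bases in A, G, C, U.
#' @export
residue_parent <- function(short_name) {
  bad <- setdiff(short_name, names(.RESIDUE_DEF))
  if (length(bad))
    stop("unknown residue name: ", paste(bad, collapse = ", "))
  unname(vapply(.RESIDUE_DEF[short_name], `[`, character(1), 1L))
}

# ---- modified sequences ----------------------------------------------------

#' Construct a modified RNA sequence
#'
#' A `mod_seq` is an ordered vector of residue short names (1-based
#' positions) with explicit 5' and 3' terminal chemistry. Mature tRNAs
#' default to a 5'-monophosphate and 3'-hydroxyl.
#'
#' @param residues character vector of residue short names.
#' @param id sequence identifier.
#' @param five_prime `"p"` (monophosphate) or `"OH"`.
#' @param three_prime `"OH"`, `"p"` (monophosphate) or `"cp"`
#'   (2',3'-cyclic phosphate).
#' @param labels optional per-position canonical labels (e.g. `"34"`,
#'   `"-1"`); same length as `residues`.
#' @return An object of class `mod_seq`.
#' @examples
#' mod_seq(c("A", "m1A", "A", "C"), five_prime = "OH", three_prime = "p")
#' @export
mod_seq <- function(residues, id = "seq", five_prime = c("p", "OH"),
                    three_prime = c("OH", "p", "cp"), labels = NULL) {
  five_prime <- match.arg(five_prime)
  three_prime <- match.arg(three_prime)
  if (length(residues) < 1L) stop("sequence must have length >= 1")
  bad <- setdiff(residues, names(.RESIDUE_DEF))
  if (length(bad))
    stop("unknown residue name(s): ", paste(unique(bad), collapse = ", "))
  if (!is.null(labels) && length(labels) != length(residues))
    stop("labels must match sequence length")
  structure(list(id = id, residues = residues, five_prime = five_prime,
                 three_prime = three_prime, labels = labels),
            class = "mod_seq")
}

#' @export
print.mod_seq <- function(x, ...) {
  term5 <- if (x$five_prime == "p") "p" else "HO"
  term3 <- switch(x$three_prime, OH = "OH", p = "p", cp = ">p")
  cat(sprintf("mod_seq '%s' (%d nt)\n", x$id, length(x$residues)))
  cat(sprintf("  5'-%s-%s-%s-3'\n", term5,
              paste(x$residues, collapse = ""), term3))
  invisible(x)
}

#' @export
length.mod_seq <- function(x) length(x$residues)

#' Elemental formula of a complete oligonucleotide
#'
#' Residue nucleosides joined by phosphodiester linkages (each +HPO3,
#' -H2O) with the terminal chemistry of the sequence: +HPO3 per terminal
#' monophosphate; a 2',3'-cyclic phosphate is a 3'-monophosphate minus
#' H2O.
#'
#' @param seq a [mod_seq()].
#' @return An elemental formula.
#' @export
oligo_formula <- function(seq) {
  stopifnot(inherits(seq, "mod_seq"))
  fm <- Reduce(`+`, lapply(seq$residues, residue_formula))
  n <- length(seq$residues)
  bridge <- formula(H = 1, O = 3, P = 1) - formula(H = 2, O = 1)
  fm <- fm + (n - 1) * bridge
  if (seq$five_prime == "p") fm <- fm + formula(H = 1, O = 3, P = 1)
  if (seq$three_prime == "p") fm <- fm + formula(H = 1, O = 3, P = 1)
  if (seq$three_prime == "cp")
    fm <- fm + formula(H = 1, O = 3, P = 1) - formula(H = 2, O = 1)
  fm
}

#' Neutral mass of a modified oligonucleotide
#'
#' @inheritParams oligo_formula
#' @param mode `"mono"` or `"average"`.
#' @return Neutral mass in Da.
#' @examples
#' s <- mod_seq(c("A", "m1A", "A", "C"), five_prime = "OH", three_prime = "p")
#' oligo_neutral_mass(s)   # 1324.225 (m/z 661.105 at z = 2)
#' @export
oligo_neutral_mass <- function(seq, mode = c("mono", "average")) {
  formula_mass(oligo_formula(seq), match.arg(mode))
}

#' Negative-mode m/z of a deprotonated ion
#'
#' @param neutral_mass neutral mass M in Da.
#' @param charge positive integer charge z (number of protons removed).
#' @return m/z = (M - z * 1.007276) / z.
#' @examples
#' ion_mz(1324.225, 2)   # 661.105
#' @export
ion_mz <- function(neutral_mass, charge) {
  if (any(charge < 1) || any(charge != round(charge)))
    stop("charge must be a positive integer")
  (neutral_mass - charge * PROTON_MASS) / charge
}

# ---- cyanoethylation -------------------------------------------------------

# Residues derivatized by acrylonitrile (aza-Michael addition): Psi gains
# the N3-cyanoethyl to become ce1Y; the taurinomethyl side chains and the
# queuosine side chain are also reactive (+C3H3N, left annotated in place).
.CE_REACTIVE <- c("Y", "tm5U", "tm5s2U", "Q")

#' Cyanoethylate the reactive residues of a sequence
#'
#' Acrylonitrile treatment adds a cyanoethyl group (+C3H3N, nominally
#' +53 Da) to pseudouridine (converting `Y` to `ce1Y`) and to the
#' secondary-amine side chains of `tm5U`, `tm5s2U` and `Q`. By default
#' the fully derivatized sequence is returned; with `partial = TRUE`,
#' all 2^k partial-derivatization combinations of the k reactive sites
#' are returned for ambiguous matching.
#'
#' @param seq a [mod_seq()].
#' @param partial return all partial combinations?
#' @return A list of `mod_seq`; each carries an attribute
#'   `n_cyanoethyl` (number of cyanoethyl groups) and `ce_sites`
#'   (derivatized positions). For `partial = FALSE` a list of length 1.
#' @export
derivatize_cyanoethyl <- function(seq, partial = FALSE) {
  stopifnot(inherits(seq, "mod_seq"))
  sites <- which(seq$residues %in% .CE_REACTIVE)
  make_variant <- function(on) {
    res <- seq$residues
    res[on] <- ifelse(res[on] == "Y", "ce1Y", paste0("ce", res[on]))
    v <- seq
    v$residues <- res
    attr(v, "n_cyanoethyl") <- length(on)
    attr(v, "ce_sites") <- on
    v
  }
  if (!partial) return(list(make_variant(sites)))
  combos <- lapply(0:length(sites), function(k)
    utils::combn(sites, k, simplify = FALSE))
  lapply(unlist(combos, recursive = FALSE), make_variant)
}
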