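#' Default thermodynamic table for sulfur/nitrogen species
#'
#' Standard Gibbs free energies of formation (kJ/mol, 25 degrees C, aqueous
#' standard state; elements in their reference state at zero) for the species
#' appearing in the sulfide-oxidation reactions, together with their
#' elemental composition and charge. Values are from standard aqueous
#' thermodynamic compilations (e.g. Thauer, Jungermann & Decker 1977 /
#' Stumm & Morgan); the table is a plain tibble and can be swapped for any
#' other compilation with the same columns.
#'
#' @return Tibble with columns `species`, element-count columns
#'   (`S`, `O`, `N`, `H`), `charge` and `dgf0` (kJ/mol).
#' @export
#' @examples
#' thermo_table_default()
thermo_table_default <- function() {
  tibble::tribble(
    ~species,  ~S, ~O, ~N, ~H, ~charge,  ~dgf0,
    "H2S",      1,  0,  0,  2,       0,  -27.9,
    "O2",       0,  2,  0,  0,       0,    0.0,
    "SO4-2",    1,  4,  0,  0,      -2, -744.6,
    "H+",       0,  0,  0,  1,       1,    0.0,
    "S0",       1,  0,  0,  0,       0,    0.0,
    "NO3-",     0,  3,  1,  0,      -1, -111.3,
    "NO2-",     0,  2,  1,  0,      -1,  -37.2,
    "N2",       0,  0,  2,  0,       0,    0.0,
    "NH4+",     0,  0,  1,  4,       1,  -79.4,
    "H2O",      0,  1,  0,  2,       0, -237.2,
    "H2",       0,  0,  0,  2,       0,    0.0
  )
}

thermo_elements <- function(table) {
  setdiff(names(table), c("species", "charge", "dgf0"))
}

#' Construct a reaction
#'
#' A reaction is a named numeric vector of signed stoichiometric
#' coefficients (reactants negative, products positive; rational values
#' allowed) plus a label.
#'
#' @param label Short reaction identifier.
#' @param coeffs Named numeric vector, names are species, values signed
#'   coefficients. Duplicate species are summed; a reaction whose net
#'   stoichiometry is non-empty must contain at least one reactant and one
#'   product (a fully cancelling identity reaction is permitted and is
#'   trivially balanced with zero free energy).
#' @param notes Optional free-text annotation.
#' @return Object of class `reaction`.
#' @export
#' @examples
#' reaction("aerobic_complete", c("H2S" = -1, "O2" = -2, "SO4-2" = 1, "H+" = 2))
reaction <- function(label, coeffs, notes = "") {
  stopifnot(is.character(label), is.numeric(coeffs), !is.null(names(coeffs)))
  if (anyDuplicated(names(coeffs))) {
    coeffs <- tapply(coeffs, names(coeffs), sum)
    coeffs <- setNames(as.numeric(coeffs), names(coeffs))
  }
  coeffs <- coeffs[coeffs != 0]
  if (length(coeffs) > 0 && (!any(coeffs < 0) || !any(coeffs > 0))) {
    abort("a reaction needs at least one reactant (coeff < 0) and one product (coeff > 0)")
  }
  structure(list(label = label, coeffs = coeffs, notes = notes),
            class = "reaction")
}

#' @export
format.reaction <- function(x, ...) {
  side <- function(co) {
    paste(sprintf("%s %s", sub("^1 ", "", format(abs(co), trim = TRUE, digits = 4)),
                  names(co)), collapse = " + ")
  }
  lhs <- x$coeffs[x$coeffs < 0]
  rhs <- x$coeffs[x$coeffs > 0]
  fmt1 <- function(co) paste(vapply(seq_along(co), function(i) {
    a <- abs(co[i])
    if (isTRUE(all.equal(a, 1))) names(co)[i] else paste0(format(a, digits = 4), " ", names(co)[i])
  }, character(1)), collapse = " + ")
  sprintf("%s: %s -> %s", x$label, fmt1(lhs), fmt1(rhs))
}

#' @export
print.reaction <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
tidy.reaction <- function(x, ...) {
  tibble(label = x$label, species = names(x$coeffs), coeff = unname(x$coeffs))
}

lookup_species <- function(rxn, table) {
  miss <- setdiff(names(rxn$coeffs), table$species)
  if (length(miss) > 0) {
    abort(paste0("species not in thermo table: ", paste(miss, collapse = ", ")))
  }
  table[match(names(rxn$coeffs), table$species), , drop = FALSE]
}

#' Element and charge balance of a reaction
#'
#' Computes, for each element and for charge, the signed residual
#' `sum(coeff * count)`; a reaction is balanced iff all residuals vanish
#' (|residual| <= `tol`).
#'
#' @param rxn A [reaction()].
#' @param table Thermo table (see [thermo_table_default()]); all species in
#'   the reaction must resolve.
#' @param tol Residual tolerance (default 1e-9).
#' @return Tibble with columns `quantity` (element symbols then "charge"),
#'   `residual`, and attribute-free logical column `balanced` replicated for
#'   convenience; `all(out$balanced)` tests the whole reaction.
#' @export
#' @examples
#' tab <- thermo_table_default()
#' r8 <- reaction("eq8", c("H2S" = -1, "NO3-" = -1, "S0" = 1, "NO2-" = 1, "H2O" = 1))
#' balance_check(r8, tab)
balance_check <- function(rxn, table = thermo_table_default(), tol = 1e-9) {
  sp <- lookup_species(rxn, table)
  elems <- thermo_elements(table)
  comp <- as.matrix(sp[, c(elems, "charge"), drop = FALSE])
  res <- as.numeric(rxn$coeffs %*% comp)
  tibble(quantity = c(elems, "charge"),
         residual = res,
         balanced = abs(res) <= tol)
}

#' Is a reaction balanced?
#' @inheritParams balance_check
#' @return Single logical.
#' @export
is_balanced <- function(rxn, table = thermo_table_default(), tol = 1e-9) {
  all(balance_check(rxn, table, tol)$balanced)
}

#' Rebalance a reaction over free water and protons
#'
#' Several published sulfide-oxidation stoichiometries are not element- or
#' charge-balanced as typeset. This solves the element + charge linear
#' system for all species of the reaction, augmented with H2O and H+ as free
#' species, with the electron-donor coefficient held fixed (default: the
#' first reactant, at its stated coefficient). When the system is
#' underdetermined the minimal-norm solution is returned (Moore-Penrose
#' pseudoinverse); when it is inconsistent the call fails with a rank
#' report.
#'
#' @param rxn A [reaction()].
#' @param table Thermo table.
#' @param fixed_species Species whose coefficients are held fixed; default
#'   the first reactant (the electron donor).
#' @param free_species Species allowed to enter or leave the stoichiometry
#'   (default H2O and H+).
#' @param tol Zero tolerance for dropping species and checking residuals.
#' @return A balanced [reaction()] (label suffixed `_rebalanced` unless the
#'   input was already balanced, in which case it is returned unchanged).
#' @export
#' @examples
#' tab <- thermo_table_default()
#' r4 <- reaction("eq4", c("H2S" = -1, "NO3-" = -0.33, "S0" = 1, "N2" = 0.16, "H2O" = 1))
#' rebalance(r4, tab)  # -> 0.4 NO3-, 0.2 N2, 1.2 H2O, 0.4 H+ consumed
rebalance <- function(rxn, table = thermo_table_default(),
                      fixed_species = NULL,
                      free_species = c("H2O", "H+"), tol = 1e-8) {
  if (is_balanced(rxn, table)) {
    return(rxn)
  }
  if (is.null(fixed_species)) {
    fixed_species <- names(rxn$coeffs)[rxn$coeffs < 0][1]
  }
  all_sp <- union(names(rxn$coeffs), free_species)
  unknown <- setdiff(all_sp, fixed_species)
  elems <- thermo_elements(table)
  miss <- setdiff(all_sp, table$species)
  if (length(miss) > 0) {
    abort(paste0("species not in thermo table: ", paste(miss, collapse = ", ")))
  }
  comp <- t(as.matrix(table[match(all_sp, table$species),
                            c(elems, "charge"), drop = FALSE]))
  colnames(comp) <- all_sp
  A <- comp[, unknown, drop = FALSE]
  b <- -comp[, fixed_species, drop = FALSE] %*% rxn$coeffs[fixed_species]
  x <- MASS::ginv(A) %*% b
  resid <- A %*% x - b
  if (max(abs(resid)) > tol) {
    abort(sprintf(
      "no balanced solution: rank(A) = %d over %d constraints, max residual %.3g",
      qr(A)$rank, nrow(A), max(abs(resid))))
  }
  coeffs <- setNames(numeric(length(all_sp)), all_sp)
  coeffs[fixed_species] <- rxn$coeffs[fixed_species]
  coeffs[unknown] <- as.numeric(x)
  coeffs[abs(coeffs) < tol] <- 0
  reaction(paste0(rxn$label, "_rebalanced"), coeffs,
           notes = paste("rebalanced over", paste(free_species, collapse = "/")))
}

#' Standard Gibbs free energy of a reaction
#'
#' `deltaG0 = sum(coeff * dgf0)` in kJ per mole of reaction as written.
#' By default an unbalanced reaction is rejected; pass `check = FALSE` to
#' evaluate a stoichiometry verbatim (e.g. a typeset equation known to be
#' unbalanced).
#'
#' @param rxn A [reaction()].
#' @param table Thermo table.
#' @param check Reject unbalanced reactions (default `TRUE`).
#' @return deltaG0 in kJ/reaction.
#' @export
delta_g_standard <- function(rxn, table = thermo_table_default(), check = TRUE) {
  if (check && !is_balanced(rxn, table)) {
    abort(sprintf("reaction '%s' is not balanced; rebalance() it or pass check = FALSE",
                  rxn$label))
  }
  sp <- lookup_species(rxn, table)
  sum(rxn$coeffs * sp$dgf0)
}

#' pH-corrected Gibbs free energy of a reaction
#'
#' Standard-state free energy with the proton activity shifted from 1 to
#' 10^-pH: `deltaG0' = deltaG0 + nu_H * R * T * ln(10) * pH`, where `nu_H`
#' is the net signed proton coefficient. At pH 7 and 298.15 K each product
#' proton contributes -39.96 kJ/mol. All other species remain at unit
#' activity.
#'
#' @inheritParams delta_g_standard
#' @param pH Proton activity exponent (default 7).
#' @param temperature Kelvin (default 298.15).
#' @return deltaG0' in kJ/reaction.
#' @export
#' @examples
#' tab <- thermo_table_default()
#' r7 <- reaction("eq7", c("H2S" = -1, "NO3-" = -4, "SO4-2" = 1, "NO2-" = 4, "H+" = 2))
#' delta_g_prime(r7, tab)  # about -500 kJ/reaction
delta_g_prime <- function(rxn, table = thermo_table_default(), pH = 7,
                          temperature = 298.15, check = TRUE) {
  R <- 0.0083144626  # kJ / (mol K)
  dg0 <- delta_g_standard(rxn, table, check = check)
  nu_h <- if ("H+" %in% names(rxn$coeffs)) rxn$coeffs[["H+"]] else 0
  dg0 + nu_h * (-R * temperature * log(10) * pH)
}

#' The eight sulfide-oxidation reactions
#'
#' The aerobic and nitrate-coupled sulfide-oxidation stoichiometries, as
#' typeset in the source equations: complete oxidation to sulfate (1, 3, 5,
#' 7) and incomplete oxidation to elemental sulfur (2, 4, 6, 8), with O2,
#' nitrate-to-N2, nitrate-to-ammonium and nitrate-to-nitrite as electron
#' acceptors respectively. Two of the typeset equations (2 and 6) are not
#' element/charge balanced and equation 4's printed coefficients (0.33 NO3-,
#' 0.16 N2) do not close the nitrogen balance; use [rebalance()] (as
#' [sulfide_oxidation_table()] does) before computing free energies. For
#' equation 2, which produces H2 with no oxygen sink, the conventional
#' corrected stoichiometry (H2S + 0.5 O2 -> S0 + H2O) is supplied as
#' `eq2_corrected`.
#'
#' @return Named list of [reaction()] objects
#'   (`eq1` ... `eq8`, plus `eq2_corrected`).
#' @export
sulfide_reactions <- function() {
  list(
    eq1 = reaction("eq1", c("H2S" = -1, "O2" = -2, "SO4-2" = 1, "H+" = 2),
                   notes = "complete aerobic oxidation"),
    eq2 = reaction("eq2", c("H2S" = -1, "O2" = -0.5, "S0" = 1, "H2" = 1),
                   notes = "incomplete aerobic oxidation (typeset; unbalanced)"),
    eq2_corrected = reaction("eq2_corrected",
                             c("H2S" = -1, "O2" = -0.5, "S0" = 1, "H2O" = 1),
                             notes = "incomplete aerobic oxidation (corrected)"),
    eq3 = reaction("eq3", c("H2S" = -1, "NO3-" = -1.6, "SO4-2" = 1, "N2" = 0.8,
                            "H2O" = 1),
                   notes = "complete oxidation, denitrification to N2"),
    eq4 = reaction("eq4", c("H2S" = -1, "NO3-" = -0.33, "S0" = 1, "N2" = 0.16,
                            "H2O" = 1),
                   notes = "incomplete oxidation, denitrification to N2"),
    eq5 = reaction("eq5", c("H2S" = -1, "NO3-" = -1, "H2O" = -1, "SO4-2" = 1,
                            "NH4+" = 1),
                   notes = "complete oxidation, nitrate to ammonium"),
    eq6 = reaction("eq6", c("H2S" = -1, "NO3-" = -1, "H+" = -8, "S0" = 1,
                            "NH4+" = 1, "H2O" = 3),
                   notes = "incomplete oxidation, nitrate to ammonium (typeset; unbalanced)"),
    eq7 = reaction("eq7", c("H2S" = -1, "NO3-" = -4, "SO4-2" = 1, "NO2-" = 4,
                            "H+" = 2),
                   notes = "complete oxidation, nitrate to nitrite"),
    eq8 = reaction("eq8", c("H2S" = -1, "NO3-" = -1, "S0" = 1, "NO2-" = 1,
                            "H2O" = 1),
                   notes = "incomplete oxidation, nitrate to nitrite")
  )
}

#' Free-energy table for the sulfide-oxidation reactions
#'
#' Evaluates deltaG0 and pH-corrected deltaG0' for the eight
#' sulfide-oxidation stoichiometries (see [sulfide_reactions()]). Each
#' typeset equation is first balance-checked; an unbalanced stoichiometry
#' is rebalanced over free H2O / H+ with the sulfide coefficient fixed at 1
#' (the typeset eq. 2, whose H2 product cannot be balanced this way, is
#' replaced by its corrected variant) and free energies are computed on the
#' balanced form.
#'
#' @param table Thermo table (default [thermo_table_default()]).
#' @param pH pH for the proton correction (default 7).
#' @param temperature Kelvin (default 298.15).
#' @return Tibble with one row per equation: `equation`, `acceptor`,
#'   `mode` ("complete" or "incomplete"), `typeset_balanced`, `stoichiometry`
#'   (the balanced form, pretty-printed), `delta_g0`, `delta_g_prime`
#'   (kJ/reaction).
#' @export
#' @examples
#' sulfide_oxidation_table()
sulfide_oxidation_table <- function(table = thermo_table_default(), pH = 7,
                                    temperature = 298.15) {
  rxns <- sulfide_reactions()
  meta <- tibble::tribble(
    ~equation, ~acceptor,            ~mode,
    "eq1",     "O2",                 "complete",
    "eq2",     "O2",                 "incomplete",
    "eq3",     "NO3- -> N2",         "complete",
    "eq4",     "NO3- -> N2",         "incomplete",
    "eq5",     "NO3- -> NH4+",       "complete",
    "eq6",     "NO3- -> NH4+",       "incomplete",
    "eq7",     "NO3- -> NO2-",       "complete",
    "eq8",     "NO3- -> NO2-",       "incomplete"
  )
  rows <- purrr::pmap_dfr(meta, function(equation, acceptor, mode) {
    rx <- rxns[[equation]]
    ok <- is_balanced(rx, table)
    if (!ok) {
      rx <- if (equation == "eq2") rxns$eq2_corrected else rebalance(rx, table)
    }
    tibble(
      equation = equation, acceptor = acceptor, mode = mode,
      typeset_balanced = ok,
      stoichiometry = sub("^[^:]*: ", "", format(rx)),
      delta_g0 = delta_g_standard(rx, table),
      delta_g_prime = delta_g_prime(rx, table, pH = pH,
                                    temperature = temperature)
    )
  })
  class(rows) <- c("sulfide_energy_table", class(rows))
  rows
}

#' @export
autoplot.sulfide_energy_table <- function(object, ...) {
  ggplot(object, aes(x = .data$equation, y = .data$delta_g_prime,
                     fill = .data$mode)) +
    geom_col() +
    labs(x = NULL, y = "deltaG0' (kJ/reaction)",
         title = "Sulfide oxidation energetics at pH 7",
         fill = "oxidation") +
    theme_minimal()
}
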