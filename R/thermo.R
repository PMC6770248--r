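#' Standard formation free energies (kJ/mol)
#'
#' Table of standard free energies for the five species of the net
#' reaction.  The default table ships with the package
#' (`inst/extdata/free_energies.yaml`) and is used verbatim, including
#' the nonzero value for O2.
#'
#' @param values Named numeric vector or list with entries `O2`, `H2O`,
#'   `H+`, `O2-`, `H2O2` (kJ/mol).
#' @return Named numeric vector of class `"thermo_table"`.
#' @examples
#' default_thermo_table()
#' @export
thermo_table <- function(values) {
  need <- c("O2", "H2O", "H+", "O2-", "H2O2")
  values <- unlist(values)
  missing <- setdiff(need, names(values))
  if (length(missing))
    stop("thermo table is missing species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  v <- values[need]
  if (any(!is.finite(v)))
    stop("thermo table contains non-finite values", call. = FALSE)
  structure(v, class = "thermo_table")
}

#' @rdname thermo_table
#' @export
default_thermo_table <- function() {
  path <- system.file("extdata", "free_energies.yaml", package = "ceriakin")
  thermo_table(yaml::read_yaml(path))
}

#' Free-energy change of the net reaction
#'
#' Standard free-energy change of
#' `H2O2 + 2 O2- + 2 H+ -> 2 H2O + 2 O2`:
#' `dG = 2 G(O2) + 2 G(H2O) - 2 G(H+) - 2 G(O2-) - G(H2O2)`.
#' With the default table this is +42.0 kJ/mol (10.04 kcal/mol), a
#' slight thermodynamic barrier.
#'
#' @param table A [thermo_table()]; defaults to the shipped table.
#' @return Free-energy change in kJ/mol.
#' @examples
#' net_reaction_delta_g()  # 42
#' @export
net_reaction_delta_g <- function(table = default_thermo_table()) {
  table <- thermo_table(table)
  2 * table[["O2"]] + 2 * table[["H2O"]] - 2 * table[["H+"]] -
    2 * table[["O2-"]] - table[["H2O2"]]
}

#' Unit conversion between kJ/mol and kcal/mol
#'
#' Thermochemical calorie: 1 kcal = 4.184 kJ exactly.
#'
#' @param x Energy value(s).
#' @return Converted value(s).
#' @examples
#' kj_per_mol_to_kcal_per_mol(42)  # 10.038..., 10.04 at 2 dp
#' @export
kj_per_mol_to_kcal_per_mol <- function(x) x / 4.184

#' @rdname kj_per_mol_to_kcal_per_mol
#' @export
kcal_per_mol_to_kj_per_mol <- function(x) x * 4.184
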