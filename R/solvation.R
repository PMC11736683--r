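#' Solubility records and solvation free energy
#'
#' In the Henry (ideal-dilute) regime the free energy of moving a gas
#' molecule from the gas phase into a solvent follows directly from its
#' mole-fraction solubility `x`:
#' `dG_solvation = -R T ln(x)` with `R = kB N_A` in kJ/mol/K. No activity
#' corrections are applied.
#'
#' @param solvent solvent name
#' @param x mole-fraction solubility, strictly between 0 and 1
#' @param temperature temperature in K
#' @param pressure gas partial pressure in kPa (metadata; default one
#'   standard atmosphere, 101.325 kPa)
#' @return `solubility_record()`: a validated `solubility_record` list.
#' @examples
#' w <- solubility_record("water", x = 2.3e-5, temperature = 300)
#' solvation_free_energy(w)  # ~26.6 kJ/mol
#' @export
solubility_record <- function(solvent, x, temperature, pressure = 101.325) {
  stopifnot(is.character(solvent), length(solvent) == 1L)
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x >= 1)
    stop("mole-fraction solubility `x` must satisfy 0 < x < 1")
  stopifnot(is.numeric(temperature), temperature > 0)
  structure(list(solvent = solvent, x = x, temperature = temperature,
                 pressure = pressure),
            class = "solubility_record")
}

#' @rdname solubility_record
#' @param rec a `solubility_record`
#' @return `solvation_free_energy()`: the solvation free energy in kJ/mol,
#'   strictly positive for `x < 1`.
#' @export
solvation_free_energy <- function(rec) {
  stopifnot(inherits(rec, "solubility_record"))
  -.memgas$kB * rec$temperature * log(rec$x)
}

#' Transfer free energy between a solvent and water
#'
#' Computes the free energy of transferring a permeant from a (nonpolar)
#' solvent to water as the difference between its hydration and solvation
#' free energies, both referenced to the gas phase:
#' `dG_transfer = dG_hydration - dG_solvation = R T ln(x_solvent / x_water)`.
#' The sign convention is transfer FROM the solvent TO water: positive for
#' a permeant more soluble in the solvent than in water (hydrophobic
#' gases).
#'
#' @param solvent a [solubility_record()] for the solvent phase
#' @param water a [solubility_record()] for the water phase
#' @return a `transfer_result` list with `dG_hydration`, `dG_solvation`,
#'   `dG_transfer` (kJ/mol), the solvent pair, and the temperature;
#'   `dG_transfer == dG_hydration - dG_solvation` holds by construction.
#' @examples
#' hd <- solubility_record("hexadecane", x = 2.0e-3, temperature = 300)
#' w  <- solubility_record("water", x = 2.3e-5, temperature = 300)
#' transfer_free_energy(hd, w)
#' @export
transfer_free_energy <- function(solvent, water) {
  stopifnot(inherits(solvent, "solubility_record"),
            inherits(water, "solubility_record"))
  if (abs(solvent$temperature - water$temperature) > 0.01)
    stop("temperature mismatch between records (",
         solvent$temperature, " K vs ", water$temperature, " K)")
  dG_h <- solvation_free_energy(water)    # gas -> water
  dG_s <- solvation_free_energy(solvent)  # gas -> solvent
  structure(list(dG_hydration = dG_h, dG_solvation = dG_s,
                 dG_transfer = dG_h - dG_s,
                 pair = c(solvent = solvent$solvent, water = water$solvent),
                 temperature = solvent$temperature),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("<transfer_result> ", x$pair[["solvent"]], " -> ", x$pair[["water"]],
      " at ", x$temperature, " K\n", sep = "")
  cat(sprintf("  dG_hydration = %8.4f kJ/mol (gas -> water)\n", x$dG_hydration))
  cat(sprintf("  dG_solvation = %8.4f kJ/mol (gas -> solvent)\n", x$dG_solvation))
  cat(sprintf("  dG_transfer  = %8.4f kJ/mol (solvent -> water)\n", x$dG_transfer))
  invisible(x)
}

#' Transfer free energies for a table of solvents
#'
#' Convenience wrapper mapping a solubility table (one row per solvent,
#' including a water row) to a table of solvent-to-water transfer free
#' energies.
#'
#' @param solubilities data.frame with columns `solvent`, `x`,
#'   `temperature` (K)
#' @param water name of the row to use as the water phase
#' @return data.frame with columns `solvent`, `dG_hydration`,
#'   `dG_solvation`, `dG_transfer` (kJ/mol)
#' @export
transfer_table <- function(solubilities, water = "water") {
  solubilities <- as.data.frame(solubilities)
  stopifnot(all(c("solvent", "x", "temperature") %in% names(solubilities)))
  iw <- match(water, solubilities$solvent)
  if (is.na(iw)) stop("no row named `", water, "` in the solubility table")
  wrec <- solubility_record(water, solubilities$x[iw],
                            solubilities$temperature[iw])
  rows <- solubilities[-iw, , drop = FALSE]
  res <- lapply(seq_len(nrow(rows)), function(i) {
    srec <- solubility_record(rows$solvent[i], rows$x[i],
                              rows$temperature[i])
    tr <- transfer_free_energy(srec, wrec)
    data.frame(solvent = rows$solvent[i],
               dG_hydration = tr$dG_hydration,
               dG_solvation = tr$dG_solvation,
               dG_transfer = tr$dG_transfer)
  })
  do.call(rbind, res)
}
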