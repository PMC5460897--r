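#' Residue ionization model
#'
#' A `charge_table` holds everything needed to assign a charge to each amino
#' acid at a given pH: per-residue pKa values and their acid/base polarity,
#' the treatment of histidine, the rounding mode, and whether the free
#' alpha-amino / alpha-carboxyl termini of a full-length chain contribute.
#'
#' The fractional charge of a residue follows Henderson-Hasselbalch:
#' a base carries \eqn{+1/(1+10^{pH-pKa})}, an acid \eqn{-1/(1+10^{pKa-pH})}.
#' At the default pH 7.4 the bundled pKa set yields Lys +0.999, Arg +1.000,
#' His +0.048, Glu -0.999, Asp -1.000, Cys -0.085, alpha-amino +0.996 and
#' alpha-carboxyl -1.000. The pKa values are back-solved from those charges
#' rather than copied from a reference table; any entry can be overridden.
#'
#' Histidine sits close to neutrality at physiological pH, so its rounded
#' charge is set by `his_mode` rather than by its pKa: `"zero"` (default,
#' the physiological choice) or `"plus_one"` (the convention of earlier
#' charge surveys).
#'
#' @param pH solvent pH (default 7.4, physiological).
#' @param his_mode rounded-charge convention for histidine: `"zero"` or
#'   `"plus_one"`.
#' @param rounding `"integer"` (nearest-integer residue charges, the default
#'   used by all downstream analyses) or `"three_decimals"` (fractional
#'   charges kept to three decimal places).
#' @param include_termini if `TRUE`, [peptide_net_charge()] adds the
#'   alpha-amino and alpha-carboxyl charges when the peptide is a
#'   full-length protein.
#' @param pKa optional named numeric vector overriding any of
#'   `K, R, H, E, D, C, nterm, cterm`.
#'
#' @return An object of class `charge_table`.
#' @examples
#' tab <- charge_table()
#' fractional_residue_charge("K", tab)  # +0.999
#' rounded_residue_charge("E", tab)     # -1
#' @export
charge_table <- function(pH = 7.4,
                         his_mode = c("zero", "plus_one"),
                         rounding = c("integer", "three_decimals"),
                         include_termini = FALSE,
                         pKa = NULL) {
  his_mode <- match.arg(his_mode)
  rounding <- match.arg(rounding)
  stopifnot(is.numeric(pH), length(pH) == 1L, is.finite(pH))
  pka <- c(K = 10.40, R = 12.00, H = 6.10, E = 4.40, D = 3.90, C = 8.43,
           nterm = 9.80, cterm = 3.10)
  if (!is.null(pKa)) {
    bad <- setdiff(names(pKa), names(pka))
    if (length(bad)) stop("unknown pKa entries: ", paste(bad, collapse = ", "))
    pka[names(pKa)] <- pKa
  }
  polarity <- c(K = "base", R = "base", H = "base", E = "acid", D = "acid",
                C = "acid", nterm = "base", cterm = "acid")
  structure(
    list(pH = pH, pKa = pka, polarity = polarity, his_mode = his_mode,
         rounding = rounding, include_termini = include_termini),
    class = "charge_table"
  )
}

#' @export
print.charge_table <- function(x, ...) {
  cat("Residue charge table (Henderson-Hasselbalch)\n")
  cat("  pH:", x$pH, " his_mode:", x$his_mode, " rounding:", x$rounding,
      " termini:", x$include_termini, "\n")
  frac <- vapply(names(x$pKa), function(r) .hh_charge(x, r), numeric(1))
  tab <- data.frame(pKa = x$pKa, polarity = x$polarity,
                    fractional = sprintf("%+.3f", frac))
  print(tab, ...)
  invisible(x)
}

# HH charge for one named ionizable group (no rounding beyond 3 decimals)
.hh_charge <- function(table, group) {
  pka <- table$pKa[[group]]
  if (table$polarity[[group]] == "base") {
    round(1 / (1 + 10^(table$pH - pka)), 3)
  } else {
    round(-1 / (1 + 10^(pka - table$pH)), 3)
  }
}

# residues treated as charge 0 with a warning rather than an error
.AMBIGUITY <- c("B", "Z", "X", "U", "O", "J")

#' Read charge-model settings from a key/value config file
#'
#' The file is YAML (a superset of simple `key: value` lines) and may set
#' `pH`, `his_mode`, `rounding`, `include_termini`, and a `pKa` block of
#' per-group overrides.
#'
#' @param path path to the config file.
#' @return A [charge_table()].
#' @export
read_charge_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("pH", "his_mode", "rounding", "include_termini", "pKa")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown charge config keys: ", paste(bad, collapse = ", "))
  args <- cfg[intersect(names(cfg), known)]
  if (!is.null(args$pKa)) args$pKa <- unlist(args$pKa)
  do.call(charge_table, args)
}

#' Fractional residue charge at the table's pH
#'
#' Henderson-Hasselbalch ionization fraction (in elementary charge units,
#' reported to three decimals) of a single residue. Bases lie in (0, +1],
#' acids in [-1, 0); residues without an ionizable side chain are exactly 0.
#' Ambiguity codes (B, Z, X, U, O, J) are charge 0 with a warning.
#'
#' @param residue one-letter amino acid code (case-insensitive).
#' @param table a [charge_table()].
#' @return Numeric charge, three decimal places.
#' @export
fractional_residue_charge <- function(residue, table = charge_table()) {
  r <- .check_residue(residue)
  if (r %in% .AMBIGUITY) {
    warning("ambiguity code '", r, "' treated as charge 0")
    return(0)
  }
  if (!r %in% c("K", "R", "H", "E", "D", "C")) return(0)
  .hh_charge(table, r)
}

#' Rounded residue charge
#'
#' Nearest-integer simplification of the fractional charge, in {-1, 0, +1}.
#' Histidine is forced to the table's `his_mode` value (0 or +1) regardless
#' of its pKa.
#'
#' @inheritParams fractional_residue_charge
#' @return Integer charge.
#' @export
rounded_residue_charge <- function(residue, table = charge_table()) {
  r <- .check_residue(residue)
  if (r == "H") return(if (table$his_mode == "plus_one") 1L else 0L)
  as.integer(round(fractional_residue_charge(r, table)))
}

.check_residue <- function(residue) {
  if (!is.character(residue) || length(residue) != 1L || nchar(residue) != 1L)
    stop("residue must be a single letter")
  r <- toupper(residue)
  if (!r %in% LETTERS) stop("unknown residue symbol: '", residue, "'")
  r
}

# Per-letter charge lookup (A..Z) under the table's active rounding mode.
# mode can override the table (used for fractional/rounded side-by-side).
charge_lookup <- function(table, mode = table$rounding) {
  lut <- numeric(26)
  names(lut) <- LETTERS
  for (r in c("K", "R", "H", "E", "D", "C")) lut[r] <- .hh_charge(table, r)
  if (mode == "integer") {
    lut <- round(lut)
    lut["H"] <- if (table$his_mode == "plus_one") 1 else 0
  }
  lut
}

#' Per-residue charges of a sequence
#'
#' Vector of charges, one per residue, under the table's rounding mode.
#' Lowercase input is uppercased; ambiguity codes (B, Z, X, U, O, J) carry
#' charge 0 with a single warning per call; any non-letter symbol is an
#' error.
#'
#' @param sequence amino-acid string.
#' @param table a [charge_table()].
#' @return Numeric vector of length `nchar(sequence)`.
#' @export
residue_charges <- function(sequence, table = charge_table()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence")
  codes <- utf8ToInt(toupper(sequence)) - 64L
  if (any(codes < 1L | codes > 26L))
    stop("sequence contains non-letter symbols")
  amb <- intersect(intToUtf8(codes + 64L, multiple = TRUE), .AMBIGUITY)
  if (length(amb))
    warning("ambiguity codes treated as charge 0: ", paste(amb, collapse = ", "))
  unname(charge_lookup(table)[codes])
}

#' Net charge of a peptide
#'
#' Sum of per-residue charges under the table's rounding mode. When the
#' table has `include_termini = TRUE` and the peptide is a full-length
#' protein, the free alpha-amino (+0.996 at pH 7.4) and alpha-carboxyl
#' (-1.000) charges are added.
#'
#' @param sequence amino-acid string (non-empty).
#' @param table a [charge_table()].
#' @param is_full_protein does `sequence` span a complete chain, so that the
#'   terminal groups are free?
#' @return Net charge (integer-valued in `"integer"` rounding mode).
#' @export
peptide_net_charge <- function(sequence, table = charge_table(),
                               is_full_protein = FALSE) {
  q <- sum(residue_charges(sequence, table))
  if (table$include_termini && is_full_protein) {
    nt <- .hh_charge(table, "nterm")
    ct <- .hh_charge(table, "cterm")
    if (table$rounding == "integer") {
      nt <- round(nt); ct <- round(ct)
    }
    q <- q + nt + ct
  }
  q
}
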