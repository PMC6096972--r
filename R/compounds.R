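# Compound physico-chemical records, acid/base speciation, and the
# solubility design screen.

#' Create a compound record
#'
#' Bundles the physico-chemical identity of one compound: molecular weight,
#' octanol--water partition coefficient of the neutral species, acid
#' dissociation constant, acid/base class, and subcooled-liquid water
#' solubility. These are the inputs speciation and the solubility screen
#' need; nothing is predicted from structure.
#'
#' @param name Compound name.
#' @param cas CAS registry number as text (\code{"digits-digits-digit"}).
#' @param mw Molecular weight in g/mol (> 0).
#' @param log_kow log10 octanol--water partition coefficient of the neutral
#'   species (dimensionless).
#' @param pka Acid dissociation constant (for bases: of the conjugate acid),
#'   or \code{NA} for compounds with no acid/base reaction.
#' @param ion_class One of \code{"acid"}, \code{"base"}, \code{"neutral"}.
#'   Must be \code{"neutral"} exactly when \code{pka} is \code{NA}.
#' @param ws_sub Subcooled-liquid water solubility in mol/L, or \code{NA}
#'   for compounds that are liquids at room temperature (no subcooled
#'   reference state on record).
#'
#' @return An object of class \code{"compound_record"} (a named list).
#' @examples
#' compound_record("Diclofenac", "15307-86-5", 296.15, 4.51, 3.99, "acid",
#'                 1.87e-4)
#' @export
compound_record <- function(name, cas, mw, log_kow, pka = NA_real_,
                            ion_class = c("acid", "base", "neutral"),
                            ws_sub = NA_real_) {
  ion_class <- match.arg(ion_class)
  stopifnot(is.character(name), length(name) == 1L)
  if (!grepl("^[0-9]+-[0-9]+-[0-9]$", cas))
    stop("invalid CAS number '", cas, "' for ", name,
         " (expected digits-digits-digit)", call. = FALSE)
  if (!is.finite(mw) || mw <= 0)
    stop("mw must be a positive number (", name, ")", call. = FALSE)
  pka <- as.numeric(pka)
  if (ion_class == "neutral" && !is.na(pka))
    stop("neutral compounds carry no pKa (", name, ")", call. = FALSE)
  if (ion_class != "neutral" && is.na(pka))
    stop("pKa required for ion_class '", ion_class, "' (", name, ")",
         call. = FALSE)
  ws_sub <- as.numeric(ws_sub)
  if (!is.na(ws_sub) && ws_sub <= 0)
    stop("ws_sub must be positive when present (", name, ")", call. = FALSE)
  structure(
    list(name = name, cas = cas, mw = mw, log_kow = log_kow, pka = pka,
         ion_class = ion_class, ws_sub = ws_sub),
    class = "compound_record"
  )
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound_record> %s (CAS %s)\n", x$name, x$cas))
  cat(sprintf("  MW %.2f g/mol, log Kow %.2f, class %s", x$mw, x$log_kow,
              x$ion_class))
  if (!is.na(x$pka)) cat(sprintf(", pKa %.2f", x$pka))
  cat("\n")
  if (!is.na(x$ws_sub))
    cat(sprintf("  subcooled-liquid solubility %.3g mol/L\n", x$ws_sub))
  else
    cat("  liquid at room temperature (no subcooled solubility)\n")
  invisible(x)
}

#' Neutral and ionized fractions at a given pH
#'
#' Rearranged Henderson--Hasselbalch speciation for a monoprotic acid or
#' base. For an acid the neutral (protonated) fraction is
#' \eqn{f_n = 1/(1 + 10^{pH - pK_a})}; for a base, whose \code{pka} is the
#' conjugate-acid value, \eqn{f_n = 1/(1 + 10^{pK_a - pH})}. Neutral
#' compounds have \eqn{f_n = 1} at every pH. The ionized fraction is stored
#' as \eqn{f_i = 1 - f_n} so the two always sum to one exactly.
#'
#' @param ph pH value(s) in \[0, 14\] (vectorized).
#' @param pka Acid dissociation constant; required unless
#'   \code{ion_class = "neutral"}.
#' @param ion_class One of \code{"acid"}, \code{"base"}, \code{"neutral"}.
#'
#' @return A data frame of class \code{"speciation"} with columns
#'   \code{ph}, \code{f_n}, \code{f_i}.
#' @examples
#' neutral_fraction(7, pka = 3.99, ion_class = "acid")    # diclofenac
#' neutral_fraction(4, pka = 8.37, ion_class = "base")    # benzotriazole
#' @export
neutral_fraction <- function(ph, pka = NA_real_,
                             ion_class = c("acid", "base", "neutral")) {
  ion_class <- match.arg(ion_class)
  ph <- as.numeric(ph)
  if (any(!is.finite(ph)) || any(ph < 0 | ph > 14))
    stop("ph must lie in [0, 14]", call. = FALSE)
  if (ion_class != "neutral" && (length(pka) != 1L || is.na(pka)))
    stop("pKa required for ion_class '", ion_class, "'", call. = FALSE)
  f_n <- switch(ion_class,
    acid    = 1 / (1 + 10^(ph - pka)),
    base    = 1 / (1 + 10^(pka - ph)),
    neutral = rep(1, length(ph))
  )
  structure(
    data.frame(ph = ph, f_n = f_n, f_i = 1 - f_n),
    class = c("speciation", "data.frame")
  )
}

#' Speciation for a compound record
#'
#' Convenience wrapper of \code{\link{neutral_fraction}} taking the pKa and
#' class from a \code{\link{compound_record}}.
#'
#' @param compound A \code{compound_record}.
#' @param ph pH value(s).
#' @return A \code{speciation} data frame.
#' @export
speciate <- function(compound, ph) {
  stopifnot(inherits(compound, "compound_record"))
  neutral_fraction(ph, pka = compound$pka, ion_class = compound$ion_class)
}

#' Initial-concentration solubility screen
#'
#' Ratio of a spike concentration to the compound's aqueous solubility, used
#' to verify a batch design keeps initial concentrations below a fraction
#' (conventionally 1%) of solubility so that competitive sorption and
#' near-saturation artefacts are avoided. The molar subcooled-liquid
#' solubility is converted to \eqn{\mu g/L} via the molecular weight
#' (\code{ws_sub * mw * 1e6}).
#'
#' @param compound A \code{\link{compound_record}}.
#' @param c0 Initial aqueous concentration in \eqn{\mu g/L} (> 0).
#'
#' @return The dimensionless ratio \code{c0 / solubility}, or \code{NA} when
#'   the compound has no solubility on record (room-temperature liquids) —
#'   a legal, flagged outcome, not an error.
#' @examples
#' phe <- compound_record("Phenanthrene", "85-01-8", 178.24, 4.46,
#'                        ion_class = "neutral", ws_sub = 3.95e-5)
#' solubility_screen(phe, c0 = 50)   # ~0.0071, below the 1% screen
#' @export
solubility_screen <- function(compound, c0) {
  stopifnot(inherits(compound, "compound_record"))
  if (!is.finite(c0) || c0 <= 0)
    stop("c0 must be positive", call. = FALSE)
  if (is.na(compound$ws_sub)) return(NA_real_)
  ws_ug_per_L <- compound$ws_sub * compound$mw * 1e6
  c0 / ws_ug_per_L
}

#' Read a compound property table
#'
#' Reads the CSV dialect \code{name,cas,mw_g_per_mol,log_kow,pka,ion_class,}
#' \code{ws_sub_mol_per_L} (empty cell = absent; period decimal separator).
#' Each row is validated through \code{\link{compound_record}}; malformed
#' numeric cells raise an error naming the row and column. The bundled
#' 19-compound study table is available via
#' \code{mpsorb_example("compounds_table1.csv")}.
#'
#' @param path Path to the CSV file.
#' @return A list of \code{compound_record} objects, named by compound.
#' @examples
#' compounds <- read_compound_table(mpsorb_example("compounds_table1.csv"))
#' length(compounds)
#' table(vapply(compounds, `[[`, "", "ion_class"))
#' @export
read_compound_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, check.names = FALSE)
  wanted <- c("name", "cas", "mw_g_per_mol", "log_kow", "pka", "ion_class",
              "ws_sub_mol_per_L")
  if (!identical(names(raw), wanted))
    stop("malformed compound table header; expected: ",
         paste(wanted, collapse = ","), call. = FALSE)
  num_cell <- function(x, row, col) {
    if (x == "") return(NA_real_)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   x, row, col), call. = FALSE)
    v
  }
  records <- lapply(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    compound_record(
      name = r$name, cas = r$cas,
      mw = num_cell(r$mw_g_per_mol, i, "mw_g_per_mol"),
      log_kow = num_cell(r$log_kow, i, "log_kow"),
      pka = num_cell(r$pka, i, "pka"),
      ion_class = r$ion_class,
      ws_sub = num_cell(r$ws_sub_mol_per_L, i, "ws_sub_mol_per_L")
    )
  })
  names(records) <- vapply(records, `[[`, "", "name")
  records
}

#' Path to a bundled example/fixture file
#'
#' @param file File name under the package's \code{extdata} directory;
#'   with no argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
mpsorb_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "mpsorb")))
  path <- system.file("extdata", file, package = "mpsorb")
  if (path == "") stop("no bundled file '", file, "'", call. = FALSE)
  path
}
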