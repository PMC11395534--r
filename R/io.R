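# Reading molecule and activity files.

#' Read a .smi file
#'
#' One `SMILES<whitespace>name` record per line; the name is optional.
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path Path to the file.
#' @return A list of `molecule` objects.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    parse_smiles(parts[1], name = if (length(parts) > 1) parts[2] else NULL)
  })
}

#' Read molecules (and optionally activities) from CSV
#'
#' Expects columns `smiles`, `name` and optionally `ic50_uM` or `pic50`.
#' Censored IC50 values written as `"> x"` are converted to pIC50 setpoints at
#' `x` and flagged.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with columns `name`, `smiles`, `molecule`
#'   (list-column), and when activities are present `pic50` and `censored`.
#' @export
read_molecules_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"smiles" %in% names(df)) stop("CSV must have a 'smiles' column")
  if (!"name" %in% names(df)) df$name <- df$smiles
  out <- data.frame(name = df$name, smiles = df$smiles,
                    stringsAsFactors = FALSE)
  out$molecule <- lapply(seq_len(nrow(df)), function(k) {
    parse_smiles(df$smiles[k], name = df$name[k])
  })
  if ("pic50" %in% names(df)) {
    out$pic50 <- as.numeric(df$pic50)
    out$censored <- FALSE
  } else if ("ic50_uM" %in% names(df)) {
    act <- lapply(df$ic50_uM, parse_activity)
    out$pic50 <- vapply(act, `[[`, numeric(1), "pic50")
    out$censored <- vapply(act, `[[`, logical(1), "censored")
  }
  out
}

#' Parse an IC50 entry that may carry a ">" censoring mark
#'
#' An entry such as `"> 100"` (micromolar) denotes an assay setpoint: no 50%
#' inhibition was reached up to that concentration. It is mapped to the pIC50
#' at the setpoint concentration and flagged as censored.
#'
#' @param x Numeric IC50 in micromolar, or a string, possibly `"> value"`.
#' @return A list with `pic50` and `censored`.
#' @export
parse_activity <- function(x) {
  if (is.numeric(x)) return(list(pic50 = pic50_from_ic50(x), censored = FALSE))
  x <- trimws(x)
  censored <- startsWith(x, ">")
  val <- as.numeric(sub("^>", "", x))
  if (is.na(val)) stop("cannot parse activity entry: ", x)
  list(pic50 = pic50_from_ic50(val), censored = censored)
}

#' Bundled blind-validation compounds
#'
#' The four newly synthesised 5-substituted uracil/pyrimidine derivatives used
#' for blind validation of the published model: 5-(3-iodopropyl)pyrimidine-
#' 2,4-dione (40), 5-(3-chloropropyl)-2,4-dichloropyrimidine (41), 2-chloro-
#' 6,7-dihydro-5H-pyrano[2,3-d]pyrimidine (42) and 5-(3-chloropropyl)-2,4-
#' dimethoxypyrimidine (43).
#'
#' @return A named list of four `molecule` objects.
#' @export
blind_validation_compounds <- function() {
  path <- system.file("extdata", "compounds_40_43.smi", package = "pyrimqsar")
  mols <- read_smi(path)
  names(mols) <- vapply(mols, `[[`, character(1), "name")
  mols
}
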