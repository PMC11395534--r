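# Synthetic substituted-pyrimidine libraries with planted linear activities.
#
# The generator emulates the modelled chemical space: uracil (pyrimidine-
# 2,4-dione), 2,4-dimethoxypyrimidine and 2,4-dichloropyrimidine scaffolds
# decorated at the N-1/N-3 (uracil) and C-5/C-6 positions with small alkyl,
# haloalkyl, alkynyl, methoxy, phenyl and benzyloxy substituents. Activities
# are generated from a planted linear model over the computed descriptors
# plus Gaussian noise, so every stage of the pipeline (parsing, descriptors,
# splitting, selection, validation) can be exercised without external data.

# Evaluate expr with the global RNG state restored afterwards.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Scaffold grammar for the synthetic library
#'
#' Three pyrimidine scaffolds with their substitutable positions and a small
#' substituent vocabulary (kept under a dozen fragments so the combinatorial
#' space stays enumerable in tests). Nitrogen positions accept only H and
#' small alkyl/alkoxyalkyl groups; carbon positions accept the full set.
#'
#' @return A list of class `scaffold_grammar` with elements `scaffolds`,
#'   `c_substituents` and `n_substituents` (fragment SMILES; `""` is H).
#' @export
scaffold_grammar <- function() {
  structure(list(
    scaffolds = c("uracil", "dimethoxypyrimidine", "dichloropyrimidine"),
    c_substituents = c(H = "", methyl = "C", ethyl = "CC", propyl = "CCC",
                       isopropyl = "C(C)C", chloropropyl = "CCCCl",
                       iodopropyl = "CCCI", methoxy = "OC",
                       benzyloxy = "OCc9ccccc9", propynyl = "C#CC",
                       phenyl = "c9ccccc9"),
    n_substituents = c(H = "", methyl = "C", ethyl = "CC", propyl = "CCC",
                       methoxymethyl = "COC")
  ), class = "scaffold_grammar")
}

# Assemble one SMILES from scaffold + substituents ("" = H).
.build_smiles <- function(scaffold, r5, r6, r1 = "", r3 = "") {
  grp <- function(s) if (nzchar(s)) paste0("(", s, ")") else ""
  switch(scaffold,
    uracil = paste0("O=C1N", grp(r3), "C(=O)C", grp(r5), "=C", grp(r6),
                    "N1", r1),
    dimethoxypyrimidine = paste0("COc1nc(OC)c", grp(r5), "c", grp(r6), "n1"),
    dichloropyrimidine = paste0("Clc1nc(Cl)c", grp(r5), "c", grp(r6), "n1"),
    stop("unknown scaffold: ", scaffold))
}

# Deterministic enumeration of the whole combinatorial space.
.enumerate_library <- function(grammar) {
  out <- character(0)
  labels <- character(0)
  cs <- grammar$c_substituents
  ns <- grammar$n_substituents
  for (sc in grammar$scaffolds) {
    if (sc == "uracil") {
      for (r1 in names(ns)) for (r3 in names(ns))
        for (r5 in names(cs)) for (r6 in names(cs)) {
          out <- c(out, .build_smiles(sc, cs[[r5]], cs[[r6]],
                                      ns[[r1]], ns[[r3]]))
          labels <- c(labels, paste(sc, r1, r3, r5, r6, sep = "_"))
        }
    } else {
      for (r5 in names(cs)) for (r6 in names(cs)) {
        out <- c(out, .build_smiles(sc, cs[[r5]], cs[[r6]]))
        labels <- c(labels, paste(sc, r5, r6, sep = "_"))
      }
    }
  }
  data.frame(label = labels, smiles = out, stringsAsFactors = FALSE)
}

#' Generate a synthetic substituted-pyrimidine library
#'
#' Samples `n` distinct molecules from the scaffold grammar's combinatorial
#' space. Deterministic for a given seed.
#'
#' @param n Number of molecules (>= 1).
#' @param grammar A `scaffold_grammar`.
#' @param seed Integer seed.
#' @return A list of `molecule` objects of length `n`.
#' @export
generate_library <- function(n, grammar = scaffold_grammar(), seed = 1) {
  stopifnot(n >= 1)
  space <- .enumerate_library(grammar)
  if (n > nrow(space)) {
    stop("grammar exhausted: requested ", n, " molecules from a space of ",
         nrow(space))
  }
  picks <- .with_seed(seed, sample.int(nrow(space), n))
  lapply(picks, function(k) parse_smiles(space$smiles[k],
                                         name = space$label[k]))
}

#' Define a planted linear activity model
#'
#' @param descriptor_names Descriptors carrying the signal (default: the five
#'   descriptors of the published model).
#' @param coefficients True coefficients, applied to standardized descriptor
#'   columns. The defaults are the published model's per-coefficient t
#'   statistics scaled to a maximum magnitude of 1: t statistics measure
#'   standardized effect strength, so planting them reproduces a realistic
#'   relative-importance profile across the five descriptors.
#' @param intercept True intercept.
#' @param sigma Gaussian noise standard deviation. The default 0.22 echoes
#'   the residual scale of the published fit (s2 = 0.0485).
#' @param config Descriptor configuration used to compute the descriptors.
#' @return A list of class `planted_model`.
#' @export
planted_model <- function(descriptor_names = c("AATSC2s", "MDEN-23", "ATSC4c",
                                               "ATSC3e", "AATSC6p"),
                          coefficients = c(-8.23321, -5.72486, 5.41163,
                                           4.53965, -3.62229) / 8.23321,
                          intercept = 4.7326,
                          sigma = 0.22,
                          config = published_descriptor_config()) {
  stopifnot(length(descriptor_names) == length(coefficients), sigma >= 0)
  structure(list(descriptor_names = descriptor_names,
                 coefficients = stats::setNames(coefficients,
                                                descriptor_names),
                 intercept = intercept, sigma = sigma, config = config),
            class = "planted_model")
}

#' Plant activities on a molecule library
#'
#' Computes the planted model's descriptors, standardizes each column over
#' the library, forms the deterministic activity
#' `intercept + sum(beta_j * z_j)`, optionally rescales it linearly to a
#' target range, and adds seeded Gaussian noise. The result is exactly linear
#' in the raw descriptors; the effective natural-scale coefficients are
#' attached as attribute `"true_coefficients"`.
#'
#' @param mols List of `molecule` objects.
#' @param planted A `planted_model`.
#' @param seed Integer seed for the noise draw.
#' @param activity_range Optional length-2 numeric; the deterministic part is
#'   mapped linearly onto this range (e.g. `c(4.1, 6.52)` to emulate the
#'   modelled activity window).
#' @return Numeric pIC50 vector with attributes `"true_coefficients"` and
#'   `"descriptors"` (the descriptor data.frame used).
#' @export
plant_activities <- function(mols, planted = planted_model(), seed = 1,
                             activity_range = NULL) {
  pool <- descriptor_pool(mols, config = planted$config)
  missing <- setdiff(planted$descriptor_names, names(pool))
  if (length(missing)) stop("descriptors not in pool: ",
                            paste(missing, collapse = ", "))
  X <- as.matrix(pool[, planted$descriptor_names, drop = FALSE])
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0)) stop("planted descriptor with zero variance in library")
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  y_det <- planted$intercept + drop(Z %*% planted$coefficients)
  scale_fac <- 1
  offset <- 0
  if (!is.null(activity_range)) {
    lo <- min(y_det); hi <- max(y_det)
    if (hi > lo) {
      scale_fac <- diff(activity_range) / (hi - lo)
      offset <- activity_range[1] - lo * scale_fac
      y_det <- y_det * scale_fac + offset
    }
  }
  eps <- .with_seed(seed, stats::rnorm(length(mols), 0, planted$sigma))
  y <- y_det + eps
  beta_nat <- scale_fac * planted$coefficients / sdv
  attr(y, "true_coefficients") <- beta_nat
  attr(y, "descriptors") <- pool
  y
}

#' Grouped synthetic fixture emulating the modelled dataset layout
#'
#' Generates a library, plants activities, and labels the compounds with
#' three source groups of the given sizes, ready for the intuitive-rational
#' split and BMLR end-to-end tests.
#'
#' @param sizes Group sizes (default `c(5, 15, 19)`, 39 compounds).
#' @param seed Integer seed (drives both molecule sampling and noise).
#' @param sigma Noise standard deviation.
#' @param activity_range Target span of the deterministic activity.
#' @return A data.frame with columns `name`, `smiles`, `group`, `pic50` and a
#'   list-column `molecule`; the descriptor pool and true coefficients are
#'   attached as attributes `"descriptors"` and `"true_coefficients"`.
#' @export
grouped_fixture <- function(sizes = c(5, 15, 19), seed = 1, sigma = 0.22,
                            activity_range = c(4.1, 6.52)) {
  n <- sum(sizes)
  mols <- generate_library(n, seed = seed)
  planted <- planted_model(sigma = sigma)
  y <- plant_activities(mols, planted, seed = seed + 1,
                        activity_range = activity_range)
  groups <- rep(paste0("source_", seq_along(sizes)), sizes)
  out <- data.frame(
    name = vapply(mols, `[[`, character(1), "name"),
    smiles = vapply(mols, `[[`, character(1), "smiles"),
    group = groups,
    pic50 = as.numeric(y),
    stringsAsFactors = FALSE
  )
  out$molecule <- mols
  attr(out, "descriptors") <- attr(y, "descriptors")
  attr(out, "true_coefficients") <- attr(y, "true_coefficients")
  out
}
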