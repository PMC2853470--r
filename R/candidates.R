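#' @title Candidate libraries
#' @description
#' A candidate library is a local, searchable collection of structures:
#' a tibble with one row per compound (id, name, formula, precomputed
#' neutral monoisotopic mass, molecule object as a list-column). It stands
#' in for a compound-database search: candidates are retrieved by exact
#' neutral mass within a ppm window, by elemental composition, or by
#' explicit id list. A wrapper implementing the same contract can put a
#' remote database behind this interface.
#' @name candidates-model
NULL

.library_mols <- function(library) {
  if (inherits(library, "fr_library")) return(library$mol)
  if (inherits(library, "fr_mol")) return(list(library))
  if (is.list(library) && all(vapply(library, inherits, logical(1),
                                     "fr_mol"))) {
    return(library)
  }
  stop("expected a candidate library or list of molecules", call. = FALSE)
}

#' Build a candidate library from molecules
#'
#' @param mols list of `fr_mol` (ids should be unique).
#' @param source label describing where the structures came from.
#' @return tibble of class `fr_library`: `id`, `name`, `formula`, `mass`,
#'   `mol` (list-column).
#' @export
as_candidate_library <- function(mols, source = "local") {
  if (inherits(mols, "fr_mol")) mols <- list(mols)
  stopifnot(length(mols) >= 1)
  ids <- vapply(seq_along(mols), function(i) {
    id <- mols[[i]]$id
    if (is.na(id) || !nzchar(id)) sprintf("MOL%04d", i) else id
  }, character(1))
  out <- tibble::tibble(
    id = ids,
    name = vapply(mols, function(m) m$name %||% NA_character_, character(1)),
    formula = vapply(mols, function(m) formula_string(formula_of(m)),
                     character(1)),
    mass = vapply(mols, function(m) monoisotopic_mass(formula_of(m)),
                  numeric(1)),
    mol = mols
  )
  attr(out, "source") <- source
  class(out) <- c("fr_library", class(out))
  out
}

#' Load a candidate library from a file
#'
#' @param path an SDF file or a SMILES list (one record per line, optional
#'   whitespace-separated id).
#' @param format `"sdf"`, `"smiles"`, or `"auto"` (by file extension).
#' @return an `fr_library`. Unparseable records are skipped with a
#'   warning; a file with no parseable record is an error.
#' @export
load_library <- function(path, format = c("auto", "sdf", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$|\\.mol$", path, ignore.case = TRUE))
      "sdf" else "smiles"
  }
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  mols <- read_structures(text, format)
  if (!length(mols)) {
    stop("no parseable structure records in ", path, call. = FALSE)
  }
  as_candidate_library(mols, source = path)
}

.chnops <- c("C", "H", "N", "O", "P", "S")

.elements_of <- function(m) unique(m$atoms$element)

#' Search a library by exact neutral mass
#'
#' @param library an `fr_library`.
#' @param mass neutral monoisotopic query mass in Da (> 0).
#' @param ppm relative window in ppm (default 10).
#' @param chnops_only keep only compounds made of C, H, N, O, P, S.
#' @param exclude_ch_only drop pure hydrocarbons.
#' @return the matching subset, sorted by `|mass - query|` then id.
#' @export
search_by_mass <- function(library, mass, ppm = 10, chnops_only = FALSE,
                           exclude_ch_only = FALSE) {
  stopifnot(inherits(library, "fr_library"), mass > 0)
  tol <- ppm * 1e-6 * mass
  hit <- abs(library$mass - mass) <= tol
  out <- library[hit, ]
  if (chnops_only && nrow(out)) {
    keep <- vapply(out$mol, function(m) {
      all(c(.elements_of(m), if (sum(m$atoms$nH)) "H") %in% .chnops)
    }, logical(1))
    out <- out[keep, ]
  }
  if (exclude_ch_only && nrow(out)) {
    keep <- vapply(out$mol, function(m) {
      !all(c(.elements_of(m), "H") %in% c("C", "H"))
    }, logical(1))
    out <- out[keep, ]
  }
  out[order(abs(out$mass - mass), out$id), ]
}

#' Search a library by elemental composition
#'
#' @param library an `fr_library`.
#' @param formula an `fr_formula` or formula string.
#' @return rows with exactly this formula.
#' @export
search_by_formula <- function(library, formula) {
  stopifnot(inherits(library, "fr_library"))
  fs <- formula_string(if (is.character(formula)) parse_formula(formula)
                       else formula)
  library[library$formula == fs, ]
}

#' Select library records by id
#'
#' @param library an `fr_library`.
#' @param ids character ids; order is preserved, unknown ids are reported
#'   with a warning.
#' @return the selected rows.
#' @export
select_by_ids <- function(library, ids) {
  stopifnot(inherits(library, "fr_library"))
  idx <- match(ids, library$id)
  if (anyNA(idx)) {
    warning("unknown id(s): ", paste(ids[is.na(idx)], collapse = ", "),
            call. = FALSE)
    idx <- idx[!is.na(idx)]
  }
  library[idx, ]
}

#' Write a library to an SDF file
#' @param library an `fr_library`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  mols <- .library_mols(library)
  for (i in seq_along(mols)) mols[[i]]$id <- library$id[i]
  write_sdf(mols, path)
}
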