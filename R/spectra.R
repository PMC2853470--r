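#' @title Peak lists and composite spectra
#' @description
#' A spectrum is a tibble of peaks (`mz` in Thomson, `intensity` >= 0)
#' sorted by m/z, with ion mode, and optionally collision energy (eV) and
#' precursor mass as attributes. Spectra of one compound measured at
#' several collision energies are merged into a composite spectrum: peaks
#' within 0.01 Th are collapsed to their average m/z, keeping the highest
#' intensity.
#' @name spectra-model
NULL

#' Construct a spectrum
#'
#' @param mz,intensity numeric vectors; `mz > 0`, `intensity >= 0`.
#' @param ion_mode `"positive"` or `"negative"`.
#' @param collision_energy optional collision energy in eV.
#' @param precursor_mz optional precursor ion m/z.
#' @return a tibble of class `fr_spectrum`, sorted by m/z.
#' @export
spectrum <- function(mz, intensity, ion_mode = c("positive", "negative"),
                     collision_energy = NA_real_, precursor_mz = NA_real_) {
  ion_mode <- match.arg(ion_mode)
  stopifnot(length(mz) == length(intensity))
  if (length(mz) && (any(mz <= 0) || any(intensity < 0))) {
    stop("peaks need mz > 0 and intensity >= 0", call. = FALSE)
  }
  ord <- order(mz)
  out <- tibble::tibble(mz = as.numeric(mz[ord]),
                        intensity = as.numeric(intensity[ord]))
  attr(out, "ion_mode") <- ion_mode
  attr(out, "collision_energy") <- collision_energy
  attr(out, "precursor_mz") <- precursor_mz
  class(out) <- c("fr_spectrum", class(out))
  if (nrow(out) == 0) {
    warning("empty spectrum", call. = FALSE)
  }
  out
}

#' Ion mode of a spectrum
#' @param s an `fr_spectrum`.
#' @return `"positive"` or `"negative"`.
#' @export
ion_mode <- function(s) attr(s, "ion_mode") %||% "positive"

#' Read a whitespace-separated peak list
#'
#' Accepts two-column `mz intensity` text (a tolerant reader: extra
#' columns are ignored, `#` starts a comment, blank lines are skipped).
#'
#' @param text a file path or the peak-list text itself (anything
#'   containing a newline or space is treated as text).
#' @param ... passed to [spectrum()] (`ion_mode`, `collision_energy`, ...).
#' @return an `fr_spectrum`.
#' @export
read_peaklist <- function(text, ...) {
  lines <- if (length(text) == 1 && !grepl("[\n ]", text) &&
                 file.exists(text)) {
    readLines(text)
  } else {
    strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  mz <- numeric(0); int <- numeric(0)
  for (i in keep) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(tok[1:2]))
    if (length(tok) < 2 || anyNA(vals)) {
      stop("cannot parse peak list at line ", i, ": '",
           trimws(lines[i]), "'", call. = FALSE)
    }
    mz <- c(mz, vals[1]); int <- c(int, vals[2])
  }
  spectrum(mz, int, ...)
}

#' Write a spectrum as a two-column peak list
#' @param s an `fr_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(s, path) {
  writeLines(sprintf("%.6f %.6g", s$mz, s$intensity), path)
  invisible(path)
}

#' Merge spectra from different collision energies into a composite
#'
#' Peaks within `tol` Thomson of each other are merged to their average
#' m/z, retaining the maximum intensity. Merging is applied transitively by
#' greedy clustering in ascending m/z: a peak joins the current group if it
#' is within `tol` of the previous peak.
#'
#' @param spectra a list of `fr_spectrum` (or a single spectrum), all with
#'   the same ion mode.
#' @param tol merge threshold in Th (default 0.01).
#' @return the composite `fr_spectrum`.
#' @examples
#' a <- spectrum(c(100.000, 150), c(50, 10))
#' b <- spectrum(c(100.005), c(80))
#' merge_spectra(list(a, b))  # 100.0025 with intensity 80, and 150
#' @export
merge_spectra <- function(spectra, tol = 0.01) {
  if (inherits(spectra, "fr_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1)
  modes <- vapply(spectra, ion_mode, character(1))
  if (length(unique(modes)) > 1) {
    stop("cannot merge spectra with mixed ion modes", call. = FALSE)
  }
  mz <- unlist(lapply(spectra, function(s) s$mz))
  int <- unlist(lapply(spectra, function(s) s$intensity))
  if (!length(mz)) {
    return(spectrum(numeric(0), numeric(0), ion_mode = modes[1]))
  }
  ord <- order(mz)
  mz <- mz[ord]; int <- int[ord]
  grp <- cumsum(c(1, diff(mz) > tol))
  out_mz <- as.numeric(tapply(mz, grp, mean))
  out_int <- as.numeric(tapply(int, grp, max))
  prec <- stats::na.omit(vapply(spectra, function(s)
    attr(s, "precursor_mz") %||% NA_real_, numeric(1)))
  spectrum(out_mz, out_int, ion_mode = modes[1],
           precursor_mz = if (length(prec)) prec[1] else NA_real_)
}
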