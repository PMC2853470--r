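#' @title Molecular graph model and structure I/O
#' @description
#' A molecule (`fr_mol`) is a connected heavy-atom graph. Hydrogens are not
#' vertices: each heavy atom carries its attached-hydrogen count, the way
#' fragmentation treats them (H atoms travel with their heavy atom and
#' hydrogen bonds are never cleaved). Input structures in SMILES, InChI,
#' SDF or MOL format are normalized through Open Babel (explicit hydrogens,
#' kekulized bonds) and then collapsed onto the heavy-atom graph. Ring
#' membership of every bond is perceived from the graph (a bond is in a
#' ring iff it is not a bridge).
#' @name molecule-model
NULL

.new_mol <- function(atoms, bonds, id = NA_character_, name = NA_character_) {
  structure(
    list(atoms = atoms, bonds = bonds, id = id, name = name),
    class = "fr_mol"
  )
}

#' @export
print.fr_mol <- function(x, ...) {
  f <- formula_of(x)
  cat("<molecule> ", if (!is.na(x$id)) x$id else "(no id)",
      if (!is.na(x$name)) paste0(" [", x$name, "]") else "",
      "\n  formula ", formula_string(f),
      ", mass ", round(monoisotopic_mass(f), 4), " Da",
      ", ", nrow(x$atoms), " heavy atoms, ", nrow(x$bonds), " bonds (",
      sum(x$bonds$ring), " in rings)\n", sep = "")
  invisible(x)
}

# ---- Open Babel conversion -------------------------------------------------

.OB_FORMAT <- c(smiles = "SMI", smi = "SMI", sdf = "SDF", mol = "MOL",
                inchi = "INCHI")

# Convert any supported input text to normalized SDF text (explicit H,
# kekulized). Returns the SDF text or signals a structured parse error.
.to_normalized_sdf <- function(text, format) {
  from <- .OB_FORMAT[[tolower(format)]]
  if (is.null(from)) {
    stop("unsupported structure format: ", format, call. = FALSE)
  }
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      from = from, to = "SDF", source = text,
      options = data.frame(names = "h", args = "")
    )),
    error = function(e) ""
  )
  if (!nzchar(out) || !grepl("V2000", out, fixed = TRUE)) {
    stop("failed to parse ", format, " record: ",
         substr(gsub("\n.*", "", text), 1, 60), call. = FALSE)
  }
  out
}

# Split SDF text into per-record chunks (character vectors of lines).
.split_sdf_records <- function(sdf_text) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  purrr::map2(starts, ends, function(s, e) lines[s:e])
}

# Build an fr_mol from the lines of one normalized (explicit-H, V2000)
# SDF record. ChemmineR parses the atom/bond blocks; formal charges come
# from the record's M CHG lines, which ChemmineR does not expose.
.mol_from_sdf_record <- function(lines, id = NULL, name = NULL) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  txt <- lines
  if (!any(grepl("^\\$\\$\\$\\$", txt))) txt <- c(txt, "$$$$")
  writeLines(txt, tf)
  sdfset <- ChemmineR::read.SDFset(tf, skipErrors = TRUE)
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  n_all <- length(element)
  charge <- integer(n_all)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)),
                                "[[:space:]]+")[[1]])
    k <- flds[1]
    for (i in seq_len(k)) {
      charge[flds[2 * i]] <- flds[2 * i + 1]
    }
  }
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = length(bb) %/% 7, ncol = 7,
                                     byrow = TRUE)
  b1 <- as.integer(bb[, 1]); b2 <- as.integer(bb[, 2])
  border <- as.integer(bb[, 3])
  heavy <- which(element != "H")
  if (!length(heavy)) {
    stop("structure contains no heavy atoms", call. = FALSE)
  }
  is_h <- element == "H"
  nH <- integer(n_all)
  keep_bond <- logical(length(b1))
  for (i in seq_along(b1)) {
    h1 <- is_h[b1[i]]; h2 <- is_h[b2[i]]
    if (h1 && h2) next            # H2 fragments are dropped
    if (h1) nH[b2[i]] <- nH[b2[i]] + 1L
    else if (h2) nH[b1[i]] <- nH[b1[i]] + 1L
    else keep_bond[i] <- TRUE
  }
  remap <- integer(n_all)
  remap[heavy] <- seq_along(heavy)
  atoms <- tibble::tibble(
    element = element[heavy],
    charge  = charge[heavy],
    nH      = nH[heavy]
  )
  bonds <- tibble::tibble(
    a1 = remap[b1[keep_bond]],
    a2 = remap[b2[keep_bond]],
    order = pmin(pmax(border[keep_bond], 1L), 3L)
  )
  # canonical endpoint order
  swap <- bonds$a1 > bonds$a2
  tmp <- bonds$a1[swap]; bonds$a1[swap] <- bonds$a2[swap]
  bonds$a2[swap] <- tmp
  title <- trimws(lines[1])
  mol <- .new_mol(atoms, bonds,
                  id = if (!is.null(id)) id else
                    if (nzchar(title)) title else NA_character_,
                  name = if (!is.null(name)) name else
                    if (nzchar(title)) title else NA_character_)
  mol$bonds$ring <- .perceive_rings(mol)
  if (!.is_connected(seq_len(nrow(mol$atoms)), nrow(mol$atoms),
                     seq_len(nrow(mol$bonds)), mol$bonds$a1, mol$bonds$a2)) {
    warning("structure ", mol$id, " is disconnected; largest use may fail",
            call. = FALSE)
  }
  mol
}

.perceive_rings <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0) return(logical(0))
  !.bridge_flags(seq_len(nrow(mol$atoms)), nrow(mol$atoms),
                 seq_len(nb), mol$bonds$a1, mol$bonds$a2)
}

#' Parse a single structure record
#'
#' @param text one structure record: a SMILES string (optionally followed
#'   by whitespace and an identifier), an InChI string, or the text of an
#'   SDF/MOL record.
#' @param format one of `"smiles"`, `"sdf"`, `"mol"`, `"inchi"`.
#' @param id optional identifier overriding the record's own.
#' @return an `fr_mol` with explicit hydrogen counts and perceived ring
#'   flags.
#' @examples
#' m <- parse_structure("C1CCCCC1", "smiles", id = "cyclohexane")
#' formula_string(formula_of(m))
#' @export
parse_structure <- function(text, format = c("smiles", "sdf", "mol", "inchi"),
                            id = NULL) {
  format <- match.arg(format)
  mols <- read_structures(text, format, quiet = TRUE)
  if (!length(mols)) {
    stop("failed to parse ", format, " record", call. = FALSE)
  }
  m <- mols[[1]]
  if (!is.null(id)) m$id <- id
  m
}

#' Parse a multi-record structure text
#'
#' For SMILES/InChI input, one record per line (blank lines and `#`
#' comments skipped); an optional second whitespace-separated token is the
#' identifier. For SDF, records are separated by `$$$$`.
#'
#' @param text the full text.
#' @param format one of `"smiles"`, `"sdf"`, `"mol"`, `"inchi"`.
#' @param quiet suppress the skipped-record warning.
#' @return list of `fr_mol`; unparseable records are skipped with a warning.
#' @export
read_structures <- function(text, format = c("smiles", "sdf", "mol", "inchi"),
                            quiet = FALSE) {
  format <- match.arg(format)
  if (format %in% c("smiles", "inchi")) {
    lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    recs <- lines
  } else {
    recs <- paste(text, collapse = "\n")
  }
  out <- list()
  n_bad <- 0L
  for (rec in recs) {
    parsed <- tryCatch({
      sdf_text <- .to_normalized_sdf(rec, format)
      chunks <- .split_sdf_records(sdf_text)
      purrr::map(chunks, .mol_from_sdf_record)
    }, error = function(e) NULL)
    if (is.null(parsed)) {
      n_bad <- n_bad + 1L
      next
    }
    if (format %in% c("smiles", "inchi")) {
      # carry the inline identifier if Open Babel dropped it
      tok <- strsplit(rec, "[[:space:]]+")[[1]]
      if (length(tok) >= 2 && is.na(parsed[[1]]$id)) {
        parsed[[1]]$id <- tok[2]
        parsed[[1]]$name <- tok[2]
      }
    }
    out <- c(out, parsed)
  }
  if (n_bad > 0 && !quiet) {
    warning(n_bad, " record(s) could not be parsed and were skipped",
            call. = FALSE)
  }
  out
}

# ---- accessors -------------------------------------------------------------

#' Elemental composition of a molecule or fragment row
#'
#' Heavy atoms are counted from the graph; hydrogens from the
#' attached-hydrogen fields. For a fragment, pass the parent molecule and
#' the atom subset.
#'
#' @param m an `fr_mol`.
#' @param atoms optional integer vector of atom indices (a fragment's atom
#'   subset); default all atoms.
#' @return an `fr_formula`.
#' @export
formula_of <- function(m, atoms = NULL) {
  stopifnot(inherits(m, "fr_mol"))
  at <- if (is.null(atoms)) m$atoms else m$atoms[atoms, , drop = FALSE]
  counts <- table(at$element)
  f <- stats::setNames(as.integer(counts), names(counts))
  h <- sum(at$nH)
  if (h > 0) f <- c(f, c(H = h))
  as_formula(f)
}

# per-atom monoisotopic masses (heavy atom + its hydrogens)
.atom_masses <- function(m) {
  element_mass(m$atoms$element) + m$atoms$nH * .ELEMENT_MASSES[["H"]]
}

# ---- writers ---------------------------------------------------------------

# V2000 molblock text for a molecule (or an atom subset), hydrogens
# expanded to explicit atoms so round trips preserve the formula.
.mol_to_molblock <- function(m, atoms = NULL, title = NULL) {
  if (is.null(atoms)) atoms <- seq_len(nrow(m$atoms))
  at <- m$atoms[atoms, , drop = FALSE]
  remap <- integer(nrow(m$atoms)); remap[atoms] <- seq_along(atoms)
  keep <- m$bonds$a1 %in% atoms & m$bonds$a2 %in% atoms
  bd <- m$bonds[keep, , drop = FALSE]
  n_heavy <- nrow(at)
  n_h <- sum(at$nH)
  atom_lines <- character(n_heavy + n_h)
  for (i in seq_len(n_heavy)) {
    atom_lines[i] <- sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, at$element[i])
  }
  h_bonds <- matrix(integer(0), ncol = 2)
  hi <- n_heavy
  hb <- list()
  for (i in seq_len(n_heavy)) {
    if (at$nH[i] > 0) {
      for (k in seq_len(at$nH[i])) {
        hi <- hi + 1L
        atom_lines[hi] <- sprintf(
          "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
          0, 0, 0, "H")
        hb[[length(hb) + 1L]] <- c(i, hi)
      }
    }
  }
  bond_lines <- c(
    sprintf("%3d%3d%3d  0  0  0  0", remap[bd$a1], remap[bd$a2], bd$order),
    vapply(hb, function(p) sprintf("%3d%3d  1  0  0  0  0", p[1], p[2]),
           character(1))
  )
  chg <- which(at$charge != 0)
  chg_lines <- character(0)
  if (length(chg)) {
    chg_lines <- vapply(chg, function(i) {
      sprintf("M  CHG  1 %3d %3d", i, at$charge[i])
    }, character(1))
  }
  header <- c(
    if (!is.null(title)) title else if (!is.na(m$id)) m$id else "",
    " fragrank", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            n_heavy + n_h, nrow(bd) + length(hb))
  )
  paste(c(header, atom_lines, bond_lines, chg_lines, "M  END"),
        collapse = "\n")
}

#' Write molecules to an SDF file
#'
#' @param mols an `fr_mol` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "fr_mol")) mols <- list(mols)
  txt <- vapply(mols, function(m) {
    paste0(.mol_to_molblock(m), "\n$$$$")
  }, character(1))
  writeLines(txt, path)
  invisible(path)
}

#' SMILES string of a molecule (or fragment atom subset)
#'
#' Goes through Open Babel; dangling cut sites appear as atoms with reduced
#' hydrogen counts.
#'
#' @param m an `fr_mol`.
#' @param atoms optional atom subset.
#' @return a SMILES string.
#' @export
to_smiles <- function(m, atoms = NULL) {
  block <- .mol_to_molblock(m, atoms)
  out <- suppressWarnings(
    ChemmineOB::convertFormat(from = "SDF", to = "SMI",
                              source = paste0(block, "\n$$$$\n"))
  )
  trimws(strsplit(out, "[\t\n]")[[1]][1])
}
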