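#' @title End-to-end identification pipeline
#' @description
#' The file-level workflow: read one or more peak lists (different
#' collision energies of the same compound), merge them into a composite
#' spectrum, derive the neutral query mass from the precursor, search the
#' candidate library within a ppm window, fragment/match/score every
#' candidate, and write a ranked result table plus a per-candidate match
#' report. A thin command-line wrapper over these functions ships in
#' `inst/cli/fragrank.R` with subcommands `run`, `merge`, `fragment`,
#' `simulate` and `evaluate`.
#' @name pipeline-model
NULL

#' Run the identification pipeline on files
#'
#' @param peaklist_paths character vector of peak-list files (one per
#'   collision energy); merged into a composite spectrum.
#' @param library_path SDF or SMILES candidate library file.
#' @param ion_mode `"positive"` or `"negative"`.
#' @param precursor_mz precursor ion m/z; default: the highest-m/z peak of
#'   the composite spectrum. The neutral query mass subtracts (positive) or
#'   adds (negative) a proton.
#' @param search_ppm candidate-search window in ppm (default 10).
#' @param mzabs,mzppm matching tolerances (defaults 0.01 Da, 50 ppm).
#' @param max_depth fragmentation tree depth (default 2).
#' @param redundancy redundancy mode (default `"molecular_formula"`).
#' @param chnops_only restrict candidates to CHNOPS compounds.
#' @param rules_file optional neutral-loss rule file; default the bundled
#'   rules; `NA` disables rearrangements.
#' @param out_dir output directory (created if needed); writes
#'   `results.csv`, `matches.csv` and `run_log.txt`.
#' @return the `fr_result` tibble, invisibly.
#' @export
run_pipeline <- function(peaklist_paths, library_path,
                         ion_mode = c("positive", "negative"),
                         precursor_mz = NULL,
                         search_ppm = 10, mzabs = 0.01, mzppm = 50,
                         max_depth = 2L,
                         redundancy = "molecular_formula",
                         chnops_only = FALSE,
                         rules_file = NULL,
                         out_dir = ".") {
  ion_mode <- match.arg(ion_mode)
  for (p in c(peaklist_paths, library_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  spectra <- lapply(peaklist_paths, read_peaklist, ion_mode = ion_mode)
  comp <- merge_spectra(spectra)
  if (nrow(comp) == 0) stop("composite spectrum is empty", call. = FALSE)
  if (is.null(precursor_mz)) {
    precursor_mz <- attr(comp, "precursor_mz")
    if (is.null(precursor_mz) || is.na(precursor_mz)) {
      precursor_mz <- max(comp$mz)
    }
  }
  neutral_mass <- precursor_mz +
    if (ion_mode == "positive") -PROTON_MASS else PROTON_MASS
  lib <- load_library(library_path)
  hits <- search_by_mass(lib, neutral_mass, ppm = search_ppm,
                         chnops_only = chnops_only)
  if (nrow(hits) == 0) {
    stop("no candidates within ", search_ppm, " ppm of neutral mass ",
         round(neutral_mass, 4), " Da", call. = FALSE)
  }
  rules <- if (is.null(rules_file)) default_rules()
           else if (is.na(rules_file)) NULL
           else read_loss_rules(rules_file)
  res <- rank_candidates(
    hits, comp,
    config = fragmenter_config(max_depth = max_depth,
                               redundancy = redundancy),
    params = match_params(mzabs = mzabs, mzppm = mzppm,
                          ion_mode = ion_mode),
    rules = rules
  )
  if (all(res$score == 0)) {
    warning("no candidate explained any peak; all scores are zero",
            call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(dplyr::select(res, -dplyr::any_of("mol"))),
                   file.path(out_dir, "results.csv"), row.names = FALSE)
  mt <- attr(res, "matches")
  match_report <- dplyr::bind_rows(mt, .id = "candidate_id")
  utils::write.csv(as.data.frame(match_report),
                   file.path(out_dir, "matches.csv"), row.names = FALSE)
  log_lines <- c(
    "fragrank run log",
    paste0("peak lists: ", paste(peaklist_paths, collapse = ", ")),
    paste0("library: ", library_path),
    paste0("ion mode: ", ion_mode),
    paste0("precursor m/z: ", precursor_mz),
    paste0("neutral query mass: ", neutral_mass),
    paste0("search window: ", search_ppm, " ppm"),
    paste0("match tolerance: mzabs ", mzabs, " Da, mzppm ", mzppm),
    paste0("tree depth: ", max_depth, ", redundancy: ", redundancy),
    paste0("candidates: ", nrow(hits)),
    paste0("composite peaks: ", nrow(comp)),
    paste0("fragments per candidate: ",
           paste(res$id, res$n_fragments, sep = "=", collapse = ", "))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(res)
}

#' Export a fragment table with SMILES annotations
#'
#' @param frags a fragment tibble from [enumerate_fragments()].
#' @param m the parent `fr_mol`.
#' @param path output CSV path.
#' @return the annotated tibble, invisibly.
#' @export
export_fragments <- function(frags, m, path) {
  out <- dplyr::mutate(
    frags,
    smiles = vapply(.data$atoms, function(a) to_smiles(m, a), character(1)),
    broken_bonds = vapply(.data$broken_bonds, paste, character(1),
                          collapse = ";"),
    atoms = vapply(.data$atoms, paste, character(1), collapse = ";")
  )
  utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  invisible(out)
}

#' Parameter-recovery study on the synthetic fixtures
#'
#' For each of `n_molecules` fixture molecules (the first ones rich enough
#' to yield an `n_peaks`-peak spectrum), simulates a spectrum from the
#' molecule's own depth-`depth` fragments and scores it against a library
#' of the molecule plus `n_decoys` random isomer decoys, recording the
#' worst-case and cluster rank of the true molecule and the run's positive
#' predictive value.
#'
#' @param n_molecules number of fixture molecules (default 20).
#' @param n_decoys decoys per library (default 100).
#' @param n_peaks simulated peaks (default 6).
#' @param depth tree depth for both simulation and matching (default 2).
#' @param mass_noise_sd simulated m/z noise (default 0).
#' @param seed base RNG seed; molecule i uses `seed + i` for both its
#'   spectrum and its decoy library.
#' @param params matching tolerances (default high-accuracy:
#'   `mzppm = 10, mzabs = 0`).
#' @param rules neutral-loss rules.
#' @param apply_rules_to_fragments apply rules to every fragment.
#' @return tibble: `name`, `rank`, `cluster_rank`, `n_fragments` (true
#'   molecule), `n_matched` and `ppv` (true molecule's run).
#' @export
recovery_study <- function(n_molecules = 20L, n_decoys = 100L,
                           n_peaks = 6L, depth = 2L, mass_noise_sd = 0,
                           seed = 1L,
                           params = match_params(mzabs = 0, mzppm = 10),
                           rules = default_rules(),
                           apply_rules_to_fragments = FALSE) {
  toys <- fragmentable_toys(n_peaks = n_peaks, depth = depth)
  stopifnot(nrow(toys) >= n_molecules)
  toys <- toys[seq_len(n_molecules), ]
  cfg <- fragmenter_config(max_depth = depth,
                           apply_rules_to_fragments =
                             apply_rules_to_fragments)
  rows <- lapply(seq_len(n_molecules), function(i) {
    m <- toys$mol[[i]]
    spec <- simulate_spectrum(m, n_peaks = n_peaks, depth = depth,
                              mass_noise_sd = mass_noise_sd,
                              seed = seed + i)
    lib <- make_decoy_library(m, n = n_decoys, seed = seed + i)
    res <- rank_candidates(lib, spec, config = cfg, params = params,
                           rules = rules)
    j <- match(toys$name[i], res$id)
    tibble::tibble(
      name = toys$name[i],
      rank = res$rank[j],
      cluster_rank = res$cluster_rank[j],
      n_fragments = res$n_fragments[j],
      n_matched = res$n_matched_fragments[j],
      ppv = ppv(res$n_matched_fragments[j], res$n_fragments[j])
    )
  })
  dplyr::bind_rows(rows)
}

#' Positive-predictive-value study across tree depths and rule modes
#'
#' Matches each fixture molecule against its own simulated spectrum
#' (no decoys) and reports the PPV — the fraction of generated fragments
#' explaining a peak — for each configuration.
#'
#' @param n_molecules number of fixture molecules (default 20).
#' @param depths tree depths to compare (default `c(2, 3)`).
#' @param n_peaks,seed,params,rules as in [recovery_study()].
#' @param per_fragment_rules additionally evaluate each depth with
#'   neutral-loss rules applied to every fragment (default `TRUE`).
#' @return tibble: `name`, `depth`, `rules_mode`
#'   (`"candidates"`/`"fragments"`), `n_fragments`, `n_matched`, `ppv`.
#' @export
ppv_study <- function(n_molecules = 20L, depths = c(2L, 3L), n_peaks = 6L,
                      seed = 1L,
                      params = match_params(mzabs = 0, mzppm = 10),
                      rules = default_rules(),
                      per_fragment_rules = TRUE) {
  toys <- fragmentable_toys(n_peaks = n_peaks, depth = min(depths))
  stopifnot(nrow(toys) >= n_molecules)
  toys <- toys[seq_len(n_molecules), ]
  modes <- if (per_fragment_rules) c(FALSE, TRUE) else FALSE
  rows <- list()
  for (i in seq_len(n_molecules)) {
    m <- toys$mol[[i]]
    spec <- simulate_spectrum(m, n_peaks = n_peaks, depth = min(depths),
                              mass_noise_sd = 0, seed = seed + i)
    for (d in depths) {
      for (pf in modes) {
        cfg <- fragmenter_config(max_depth = d,
                                 apply_rules_to_fragments = pf)
        r <- fragment_and_match(m, spec, cfg, params, rules)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          name = toys$name[i], depth = d,
          rules_mode = if (pf) "fragments" else "candidates",
          n_fragments = r$n_fragments,
          n_matched = r$n_matched_fragments,
          ppv = ppv(r$n_matched_fragments, r$n_fragments)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Evaluate ranked results against known true candidates
#'
#' @param results a list of `fr_result` objects (one per query spectrum).
#' @param truth character vector of the true candidate ids, parallel to
#'   `results`.
#' @return list: `per_query` tibble (id, worst-case `rank`, `cluster_rank`,
#'   `ppv`), `rank_stats` and `cluster_rank_stats` ([rank_summary()] rows),
#'   `mean_ppv`.
#' @export
evaluate_results <- function(results, truth) {
  stopifnot(length(results) == length(truth))
  rows <- purrr::map2(results, truth, function(res, tid) {
    i <- match(tid, res$id)
    if (is.na(i)) stop("true id ", tid, " absent from results",
                       call. = FALSE)
    tibble::tibble(
      id = tid,
      rank = res$rank[i],
      cluster_rank = res$cluster_rank[i],
      ppv = ppv(sum(res$n_matched_fragments), sum(res$n_fragments))
    )
  })
  per_query <- dplyr::bind_rows(rows)
  list(
    per_query = per_query,
    rank_stats = rank_summary(per_query$rank),
    cluster_rank_stats = rank_summary(per_query$cluster_rank),
    mean_ppv = mean(per_query$ppv)
  )
}
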