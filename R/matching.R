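#' @title Fragment-peak matching
#' @description
#' Measured peaks are charged ions: a neutral in-silico fragment is matched
#' at its protonated (positive mode) or deprotonated (negative mode) mass.
#' A fragment carrying an intrinsic formal charge is matched at its mass
#' as-is, with a configurable penalty added to its cumulative bond
#' dissociation energy. The mass-error window combines a relative (ppm)
#' and an absolute (Da) tolerance. Matching is interleaved with fragment
#' generation: once the smallest unexplained peak is explained, the
#' minimum-mass cutoff rises and fewer fragments need to be generated.
#' @name matching-model
NULL

#' Matching parameters
#'
#' @param mzabs absolute mass tolerance in Da (default 0.01).
#' @param mzppm relative tolerance in ppm (default 50). The defaults suit
#'   a low-accuracy instrument; for high-accuracy QTOF data use
#'   `mzppm = 10, mzabs = 0`.
#' @param ion_mode `"positive"` or `"negative"`.
#' @param proton_mass proton mass constant (default 1.00728 Da).
#' @param charge_penalty BDE penalty (kJ/mol) for intrinsically charged
#'   fragments; `NULL` (default) uses the largest value in the BDE table,
#'   so an intrinsic charge is penalized no less than any single cleavage.
#' @return a list of class `fr_match_params`.
#' @export
match_params <- function(mzabs = 0.01, mzppm = 50,
                         ion_mode = c("positive", "negative"),
                         proton_mass = PROTON_MASS,
                         charge_penalty = NULL) {
  ion_mode <- match.arg(ion_mode)
  stopifnot(mzabs >= 0, mzppm >= 0)
  structure(list(mzabs = mzabs, mzppm = mzppm, ion_mode = ion_mode,
                 proton_mass = proton_mass, charge_penalty = charge_penalty),
            class = "fr_match_params")
}

#' Combined mass-error window at a given ion mass
#' @param ion_mass theoretical ion mass in Da.
#' @param p an [match_params()].
#' @return tolerance in Da.
#' @export
mass_tolerance <- function(ion_mass, p) {
  p$mzabs + p$mzppm * 1e-6 * ion_mass
}

#' Is a measured peak within tolerance of a theoretical ion mass?
#' @param peak_mz measured m/z in Th.
#' @param ion_mass theoretical ion mass in Da.
#' @param p an [match_params()].
#' @return logical.
#' @export
within_tolerance <- function(peak_mz, ion_mass, p) {
  abs(peak_mz - ion_mass) <= mass_tolerance(ion_mass, p)
}

# theoretical ion masses and effective BDEs of a set of fragment records
.ion_mass <- function(neutral_mass, net_charge, p) {
  shift <- if (p$ion_mode == "positive") p$proton_mass else -p$proton_mass
  ifelse(net_charge != 0, neutral_mass, neutral_mass + shift)
}

#' Fragment a candidate and match its fragments to a spectrum
#'
#' Runs the breadth-first fragmenter (including neutral-loss-derived
#' structures, which start fragmentation trees of their own) interleaved
#' with peak matching. Each measured peak is explained at most once, by the
#' fragment with the lowest effective BDE among those within tolerance at
#' the level where it is first explained; one fragment may explain several
#' peaks. Explaining the smallest unexplained peak raises the dynamic
#' minimum-mass cutoff.
#'
#' @param candidate an `fr_mol`.
#' @param spec an `fr_spectrum` with at least one peak.
#' @param config an [fragmenter_config()].
#' @param params an [match_params()]; its ion mode governs both the proton
#'   adjustment and which neutral-loss rules apply.
#' @param rules neutral-loss rules, or `NULL` to disable rearrangements.
#' @param bde_table BDE table.
#' @return list of class `fr_match`: `matches` (tibble: `peak_mz`,
#'   `intensity`, `formula`, `frag_mass`, `ion_mz`, `error_da`,
#'   `error_ppm`, `depth`, `bde`, `intrinsic`, `source`), `n_fragments`
#'   (total distinct fragments generated, after redundancy elimination,
#'   across the candidate and its derived structures), `n_matched_fragments`,
#'   `n_peaks`, and `candidate_id`.
#' @export
fragment_and_match <- function(candidate, spec,
                               config = fragmenter_config(),
                               params = match_params(),
                               rules = default_rules(),
                               bde_table = default_bde_table()) {
  stopifnot(inherits(candidate, "fr_mol"), inherits(spec, "fr_spectrum"))
  if (nrow(spec) == 0) {
    stop("cannot match against an empty spectrum", call. = FALSE)
  }
  penalty <- params$charge_penalty %||% max(bde_table$bde_kj_mol)

  peaks <- tibble::tibble(mz = spec$mz, intensity = spec$intensity,
                          explained = FALSE)
  # dynamic neutral-mass cutoff from the smallest unexplained peak
  floor_mass <- config$min_mass %||% 0
  cutoff <- function() {
    un <- peaks$mz[!peaks$explained]
    if (!length(un)) return(Inf)
    m <- min(un)
    bound <- m - mass_tolerance(m, params) -
      if (params$ion_mode == "positive") params$proton_mass else 0
    max(bound, floor_mass, 0)
  }

  # sources: candidate plus rule-derived structures, each its own tree
  sources <- list(list(mol = candidate, tag = NA_character_, depth0 = 0L,
                       bde0 = 0))
  if (!is.null(rules)) {
    for (d in apply_rules(candidate, rules, params$ion_mode)) {
      sources[[length(sources) + 1L]] <- list(
        mol = d, tag = attr(d, "rule"), depth0 = 0L, bde0 = 0
      )
    }
  }

  matches <- list()
  all_records <- vector("list", length(sources))  # per source
  src_queue <- list()

  add_source <- function(src) {
    ctx <- .frag_ctx(src$mol, bde_table)
    root <- .rec(seq_len(ctx$n), integer(0), src$bde0, src$depth0)
    list(src = src, ctx = ctx, seen = new.env(parent = emptyenv()),
         records = list(root), queue = list(root))
  }
  states <- lapply(sources, add_source)
  for (i in seq_along(states)) {
    assign(.rec_key(states[[i]]$queue[[1]]$atoms), 1L,
           envir = states[[i]]$seen)
  }

  match_level <- function(new_frags) {
    # new_frags: list of list(state_i, rec)
    if (!length(new_frags)) return()
    masses <- vapply(new_frags, function(nf) {
      sum(states[[nf$i]]$ctx$atom_masses[nf$rec$atoms])
    }, numeric(1))
    charges <- vapply(new_frags, function(nf) {
      as.integer(sum(states[[nf$i]]$ctx$charges[nf$rec$atoms]))
    }, integer(1))
    ion <- .ion_mass(masses, charges, params)
    bde_eff <- vapply(new_frags, function(nf) nf$rec$bde, numeric(1)) +
      ifelse(charges != 0, penalty, 0)
    tol <- mass_tolerance(ion, params)
    for (pi in which(!peaks$explained)) {
      hit <- which(abs(peaks$mz[pi] - ion) <= tol)
      if (!length(hit)) next
      # lowest effective BDE wins; ties: heavier fragment, then subset key
      keys <- vapply(hit, function(h)
        .rec_key(new_frags[[h]]$rec$atoms), character(1))
      best <- hit[order(bde_eff[hit], -masses[hit], keys)][1]
      nf <- new_frags[[best]]
      st <- states[[nf$i]]
      matches[[length(matches) + 1L]] <<- tibble::tibble(
        peak_mz = peaks$mz[pi],
        intensity = peaks$intensity[pi],
        formula = .ctx_formula_string(st$ctx, nf$rec$atoms),
        frag_mass = masses[best],
        ion_mz = ion[best],
        error_da = peaks$mz[pi] - ion[best],
        error_ppm = (peaks$mz[pi] - ion[best]) / ion[best] * 1e6,
        depth = nf$rec$depth,
        bde = bde_eff[best],
        intrinsic = charges[best] != 0,
        source = st$src$tag,
        source_index = nf$i,
        frag_key = keys[match(best, hit)]
      )
      peaks$explained[pi] <<- TRUE
    }
  }

  # level 0: the intact structures themselves are matchable
  match_level(purrr::imap(states, function(st, i)
    list(i = i, rec = st$queue[[1]])))

  depth <- 0L
  while (depth < config$max_depth &&
           any(vapply(states, function(st) length(st$queue) > 0,
                      logical(1)))) {
    depth <- depth + 1L
    mm <- cutoff()
    new_level <- list()
    for (i in seq_along(states)) {
      st <- states[[i]]
      nxt <- list()
      for (rec in st$queue) {
        if (rec$depth >= config$max_depth) next
        for (child in .expand_record(st$ctx, rec, mm)) {
          key <- .rec_key(child$atoms)
          idx <- st$seen[[key]]
          if (is.null(idx)) {
            st$records[[length(st$records) + 1L]] <- child
            assign(key, length(st$records), envir = st$seen)
            nxt[[length(nxt) + 1L]] <- child
            new_level[[length(new_level) + 1L]] <- list(i = i, rec = child)
          } else if (child$bde < st$records[[idx]]$bde) {
            st$records[[idx]] <- child
            if (child$depth < config$max_depth) {
              nxt[[length(nxt) + 1L]] <- child
            }
          }
        }
      }
      st$queue <- nxt
      states[[i]] <- st
    }
    if (config$apply_rules_to_fragments && !is.null(rules)) {
      # every new fragment may itself rearrange; derived structures join
      # the queue as roots of their own trees at the fragment's depth
      for (nf in new_level) {
        parent_mol <- states[[nf$i]]$src$mol
        if (length(nf$rec$atoms) < 2) next
        sm <- .extract_submol(parent_mol, nf$rec$atoms)
        for (d in apply_rules(sm, rules, params$ion_mode)) {
          src <- list(mol = d, tag = attr(d, "rule"),
                      depth0 = nf$rec$depth, bde0 = nf$rec$bde)
          st_new <- add_source(src)
          assign(.rec_key(st_new$queue[[1]]$atoms), 1L,
                 envir = st_new$seen)
          states[[length(states) + 1L]] <- st_new
          new_level[[length(new_level) + 1L]] <- list(
            i = length(states), rec = st_new$queue[[1]]
          )
        }
      }
    }
    match_level(new_level)
  }

  match_tbl <- if (length(matches)) dplyr::bind_rows(matches) else
    tibble::tibble(peak_mz = numeric(0), intensity = numeric(0),
                   formula = character(0), frag_mass = numeric(0),
                   ion_mz = numeric(0), error_da = numeric(0),
                   error_ppm = numeric(0), depth = integer(0),
                   bde = numeric(0), intrinsic = logical(0),
                   source = character(0), source_index = integer(0),
                   frag_key = character(0))

  # totals after report-level redundancy elimination; the candidate root is
  # not a generated fragment, rule-derived roots are
  n_frag <- 0L
  matched_keys <- character(0)
  for (i in seq_along(states)) {
    st <- states[[i]]
    recs <- st$records
    if (i == 1 && length(recs)) recs <- recs[-1]
    recs <- .dedup_records(st$src$mol, recs, config$redundancy, st$ctx)
    n_frag <- n_frag + length(recs)
    if (nrow(match_tbl)) {
      mk <- match_tbl$frag_key[match_tbl$source_index == i]
      if (length(mk)) {
        # map matched subsets onto report keys
        all_sk <- vapply(st$records, function(r) .rec_key(r$atoms),
                         character(1))
        all_rk <- .record_keys(st$src$mol, st$records, config$redundancy,
                               st$ctx)
        new_keys <- paste0(i, "|", all_rk[match(mk, all_sk)])
        if (i == 1) {
          # the intact candidate can explain the precursor peak but is not
          # a generated fragment; keep totals consistent
          new_keys <- setdiff(new_keys, paste0(i, "|", all_rk[1]))
        }
        matched_keys <- c(matched_keys, new_keys)
      }
    }
  }

  structure(list(
    matches = match_tbl[, setdiff(names(match_tbl),
                                  c("source_index", "frag_key"))],
    n_fragments = n_frag,
    n_matched_fragments = length(unique(matched_keys)),
    n_peaks = nrow(peaks),
    n_explained = sum(peaks$explained),
    candidate_id = candidate$id
  ), class = "fr_match")
}

#' @export
print.fr_match <- function(x, ...) {
  cat("<fragment/peak matching> candidate ", x$candidate_id, "\n  ",
      x$n_explained, "/", x$n_peaks, " peaks explained by ",
      x$n_matched_fragments, " of ", x$n_fragments,
      " fragments generated\n", sep = "")
  invisible(x)
}
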