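#' End-to-end phosphosite accessibility pipeline
#'
#' The analysis runs in the order of the underlying protocol: parse the
#' site table, trim windows to octapeptides, locate each octapeptide on
#' its protein's structure(s), separate terminal / disordered / mutated /
#' low-coverage sites, compute octapeptide rSASA for the matched ones,
#' classify against the accessibility threshold, and apply the rescue
#' rules. Conformational rescue via normal-mode ensembles is a separate
#' stage ([run_dynamics()]) because it is the only expensive step.
#'
#' @name cli_pipeline
NULL

#' Map and classify phosphosites on structures
#'
#' @param sites tibble with `accession`, `position`, `residue`,
#'   `window15` (as from [parse_phosphosite_table()] or
#'   [generate_cohort()])
#' @param structures named list of `phospho_structure` objects
#' @param structure_map optional tibble (`accession`, `structure_id`)
#'   linking proteins to structures; defaults to matching accessions to
#'   structure names, so several structures per accession are supported
#' @param rsasa_threshold accessibility threshold (0.2; 0.3 = stringent)
#' @param coverage_threshold minimum fraction of the primary sequence
#'   with coordinates (0.7)
#' @param params a [sasa_params()] object
#' @return tibble with one row per input site: `status` (matched /
#'   disordered / mutated / terminal / low_coverage / no_structure /
#'   unmatched), mapping columns (`structure_id`, `chain`, `match_start`,
#'   `coverage`), `rsasa`, `label`, `rescue`, and mutation detail columns;
#'   attribute `summary` holds the per-category counts
#' @export
run_map <- function(sites, structures, structure_map = NULL,
                    rsasa_threshold = 0.2, coverage_threshold = 0.7,
                    params = sasa_params()) {
  if (nrow(sites) == 0) {
    warning("empty site table; empty report")
    return(empty_report())
  }
  if (is.null(structure_map)) {
    structure_map <- tibble::tibble(accession = names(structures),
                                    structure_id = names(structures))
  }
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    rows[[i]] <- map_one_site(sites[i, ], structures, structure_map,
                              rsasa_threshold, coverage_threshold, params)
  }
  report <- dplyr::bind_rows(rows)
  attr(report, "summary") <- dplyr::count(
    report, .data$status, .data$label, .data$rescue, name = "n")
  attr(report, "rsasa_threshold") <- rsasa_threshold
  report
}

empty_report <- function() {
  tibble::tibble(accession = character(), position = integer(),
                 residue = character(), octapeptide = character(),
                 status = character(), structure_id = character(),
                 chain = character(), match_start = integer(),
                 coverage = double(), rsasa = double(), label = character(),
                 rescue = character(), mut_position = integer(),
                 mut_residue = character())
}

map_one_site <- function(site, structures, structure_map,
                         rsasa_threshold, coverage_threshold, params) {
  out <- tibble::tibble(
    accession = site$accession, position = as.integer(site$position),
    residue = site$residue, octapeptide = NA_character_,
    status = "unmatched", structure_id = NA_character_,
    chain = NA_character_, match_start = NA_integer_, coverage = NA_real_,
    rsasa = NA_real_, label = NA_character_, rescue = NA_character_,
    mut_position = NA_integer_, mut_residue = NA_character_
  )
  octa <- trim_to_octapeptide(site$window15)
  out$octapeptide <- as.character(octa)
  if (isTRUE(attr(octa, "terminal"))) {
    out$status <- "terminal"
    return(out)
  }
  sids <- structure_map$structure_id[structure_map$accession == site$accession]
  sids <- intersect(sids, names(structures))
  if (length(sids) == 0) {
    out$status <- "no_structure"
    return(out)
  }

  # locate the octapeptide on every candidate structure/chain
  hits <- list()
  for (sid in sids) {
    s <- structures[[sid]]
    for (ch in s$chains$chain) {
      loc <- locate_octapeptide(s$chains$sequence[s$chains$chain == ch],
                                octa, site$position)
      if (!loc$found) next
      res <- s$residues[s$residues$chain == ch, ]
      observed <- all(res$is_observed[match(loc$positions, res$seqpos)])
      hits[[length(hits) + 1]] <- list(
        sid = sid, chain = ch, positions = loc$positions,
        observed = observed, coverage = sequence_coverage(s, ch))
    }
  }

  if (length(hits) == 0) {
    # fall back to mutation/disorder discrimination on the best chain
    s <- structures[[sids[1]]]
    best_chain <- s$chains$chain[which.max(
      vapply(s$chains$chain, function(ch) sequence_coverage(s, ch), 0))]
    cf <- classify_failure(
      octa, s$chains$sequence[s$chains$chain == best_chain],
      s$residues[s$residues$chain == best_chain, ], site$position)
    out$status <- cf$status
    out$structure_id <- sids[1]
    out$chain <- best_chain
    out$mut_position <- as.integer(cf$mut_position)
    out$mut_residue <- as.character(cf$mut_residue)
    return(out)
  }

  if (!any(vapply(hits, function(h) h$observed, TRUE))) {
    out$status <- "disordered"
    h <- hits[[1]]
    out$structure_id <- h$sid; out$chain <- h$chain
    out$match_start <- h$positions[1]
    return(out)
  }
  hits <- hits[vapply(hits, function(h) h$observed, TRUE)]

  # per structure keep the chain with highest coverage
  by_sid <- split(hits, vapply(hits, function(h) h$sid, ""))
  by_sid <- lapply(by_sid, function(hs) {
    hs[[which.max(vapply(hs, function(h) h$coverage, 0))]]
  })

  covered <- Filter(function(h) h$coverage >= coverage_threshold, by_sid)
  if (length(covered) == 0) {
    h <- by_sid[[which.max(vapply(by_sid, function(x) x$coverage, 0))]]
    out$status <- "low_coverage"
    out$structure_id <- h$sid; out$chain <- h$chain
    out$match_start <- h$positions[1]; out$coverage <- h$coverage
    return(out)
  }

  rsasa_by_structure <- vapply(covered, function(h) {
    octapeptide_rsasa(structures[[h$sid]], h$chain, h$positions, params)
  }, 0)
  best <- covered[[which.max(rsasa_by_structure)]]
  out$status <- "matched"
  out$structure_id <- best$sid
  out$chain <- best$chain
  out$match_start <- best$positions[1]
  out$coverage <- best$coverage
  out$rsasa <- max(rsasa_by_structure)
  out$label <- classify_site(out$rsasa, rsasa_threshold)
  out$rescue <- "none"

  if (out$label == "allowed") {
    if (length(rsasa_by_structure) > 1 &&
        min(rsasa_by_structure) < rsasa_threshold) {
      out$rescue <- "alternate_structure"
    }
    return(out)
  }
  # rescue cascade for buried sites: interface, then consensus motif
  # (dynamics is the separate run_dynamics() stage)
  for (h in covered) {
    s <- structures[[h$sid]]
    if (s$assembly_size > 1) {
      ri <- rescue_interface(s, h$chain, h$positions, out$rsasa,
                             rsasa_threshold, params)
      if (ri$rescue == "interface") {
        out$label <- "allowed"; out$rescue <- "interface"
        out$rsasa <- ri$monomer_rsasa
        return(out)
      }
    }
  }
  if (consensus_override(out$octapeptide)) {
    out$label <- "allowed"
    out$rescue <- "consensus_motif"
  }
  out
}

#' Normal-mode conformational rescue of buried sites
#'
#' For each site classified disallowed, builds the C-alpha elastic
#' network of its chain, samples the low-energy conformer ensemble
#' (401 conformers with defaults) and reclassifies the site as allowed
#' when any conformer raises the coarse octapeptide rSASA above the
#' threshold.
#'
#' @param report a [run_map()] report
#' @param structures named list of structures used by the report
#' @param site_ids optional accessions to process (default: all
#'   disallowed matched sites); requesting an allowed site is a warning
#' @param rsasa_threshold accessibility threshold
#' @param R_C,n_modes,n_steps,max_amp elastic-network parameters
#' @param params a [sasa_params()] object
#' @return the report restricted to the processed sites, with
#'   `max_conformer_rsasa`, `n_conformers`, updated `label`/`rescue`, and
#'   `dynamics_note` for sites skipped as ENM-ineligible
#' @export
run_dynamics <- function(report, structures, site_ids = NULL,
                         rsasa_threshold = 0.2, R_C = 10,
                         n_modes = 20, n_steps = 20, max_amp = 2.0,
                         params = sasa_params()) {
  rows <- report
  if (!is.null(site_ids)) {
    rows <- rows[rows$accession %in% site_ids, ]
    if (any(rows$label == "allowed", na.rm = TRUE)) {
      warning("requested site(s) already allowed; skipping those")
    }
  }
  rows <- rows[!is.na(rows$label) & rows$label == "disallowed", ]
  rows$max_conformer_rsasa <- NA_real_
  rows$n_conformers <- NA_integer_
  rows$dynamics_note <- NA_character_
  if (nrow(rows) == 0) return(rows)
  for (i in seq_len(nrow(rows))) {
    s <- structures[[rows$structure_id[i]]]
    model <- tryCatch(build_enm(s, rows$chain[i], R_C = R_C),
                      error = function(e) e)
    if (inherits(model, "error")) {
      rows$dynamics_note[i] <- conditionMessage(model)
      next
    }
    idx <- match(rows$match_start[i] + 0:7, model$seqpos)
    if (anyNA(idx)) {
      rows$dynamics_note[i] <- "site residues missing from the C-alpha model"
      next
    }
    ens <- generate_conformers(model, n_modes = n_modes, n_steps = n_steps,
                               max_amp = max_amp)
    er <- ensemble_rsasa(ens, idx, params)
    rc <- reclassify_by_dynamics(rows$rsasa[i], er$rsasa, rsasa_threshold)
    rows$max_conformer_rsasa[i] <- rc$max_conformer_rsasa
    rows$n_conformers[i] <- length(ens$conformers)
    if (rc$label == "allowed") {
      rows$label[i] <- "allowed"
      rows$rescue[i] <- rc$rescue
    }
  }
  rows
}

#' Distribution and composition summaries of a classification report
#'
#' @param report a [run_map()] report (optionally after merging
#'   [run_dynamics()] updates)
#' @param structures the structures used by the report
#' @param params a [sasa_params()] object
#' @param rsasa_threshold accessibility threshold used for groupings
#' @param depth_cutoff depth cutoff for the rSASA/depth agreement; on the
#'   scale of real proteins 30 is the reported value, while small
#'   synthetic fixtures need a fixture-scale cutoff
#' @param with_depth,with_ss,with_a_rel toggle the more expensive blocks
#' @return list with `histogram` (overall), `histogram_by_residue`,
#'   `ss_composition`, `composition`, `a_rel`, `depth_agreement`
#' @export
run_summaries <- function(report, structures, params = sasa_params(),
                          rsasa_threshold = 0.2, depth_cutoff = 30,
                          with_depth = TRUE, with_ss = TRUE,
                          with_a_rel = TRUE) {
  matched <- report[report$status == "matched" & !is.na(report$rsasa), ]
  if (nrow(matched) == 0) stop("no matched sites to summarise")
  out <- list()
  out$histogram <- bin_and_summarize(matched$rsasa)
  out$histogram_by_residue <- lapply(
    split(matched$rsasa, matched$residue), bin_and_summarize)

  if (with_ss) {
    ss_strings <- vapply(seq_len(nrow(matched)), function(i) {
      octapeptide_ss(structures[[matched$structure_id[i]]],
                     matched$chain[i], matched$match_start[i] + 0:7)
    }, "")
    out$ss_composition <- ss_composition(ss_strings)
  }

  allowed <- matched$octapeptide[matched$label == "allowed"]
  disallowed <- matched$octapeptide[matched$label == "disallowed"]
  if (length(allowed) && length(disallowed)) {
    out$composition <- composition_compare(allowed, disallowed)
  }

  if (with_a_rel) {
    ids <- unique(matched$structure_id)
    out$a_rel <- dplyr::bind_cols(
      tibble::tibble(structure_id = ids),
      dplyr::bind_rows(lapply(ids, function(sid) {
        compute_a_rel(structures[[sid]], params)
      }))
    )
  }

  if (with_depth) {
    depths <- vapply(seq_len(nrow(matched)), function(i) {
      d <- residue_depth(structures[[matched$structure_id[i]]], params)
      idx <- d$chain == matched$chain[i] &
        d$resno %in% (matched$match_start[i] + 0:7)
      mean(d$depth[idx])
    }, 0)
    out$depth_agreement <- depth_consistency(
      tibble::tibble(rsasa = matched$rsasa, depth = depths),
      rsasa_threshold, depth_cutoff)
    out$site_depths <- tibble::tibble(accession = matched$accession,
                                      rsasa = matched$rsasa, depth = depths)
  }
  out
}
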