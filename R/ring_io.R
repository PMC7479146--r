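#' Merge duplicate cores from the same tree
#'
#' Ring-width archives often hold several cores per tree under IDs that agree
#' except for the final character (\code{01a}/\code{01b}, \code{ID1-1}/
#' \code{ID1-2}). Series whose IDs share the same stem - the ID minus its
#' last character, with any trailing separator (\code{-_./}) stripped - are
#' combined into one tree: the per-cambial-age mean of the available widths,
#' aligned at age 1; the merged age is the longest member age. IDs whose stem
#' would be empty are never merged.
#'
#' @param rings long-form ring data frame.
#' @param combine \code{"mean"} (default) or \code{"first"} (keep the first
#'   member's width where it exists).
#' @return the merged ring data frame; attribute \code{merge_report} lists
#'   each merged stem with its member IDs. Members of one stem with differing
#'   site or species codes raise an error.
#' @export
merge_duplicate_cores <- function(rings, combine = c("mean", "first")) {
  combine <- match.arg(combine)
  ids <- unique(rings$tree_id)
  stem_of <- function(id) {
    s <- substr(id, 1L, nchar(id) - 1L)
    sub("[-_./]+$", "", s)
  }
  stems <- vapply(ids, stem_of, character(1))
  grp <- ifelse(nchar(stems) > 0, stems, ids)
  groups <- split(ids, grp)
  merged_groups <- groups[lengths(groups) > 1L]

  if (length(merged_groups) == 0L) {
    attr(rings, "merge_report") <- data.frame(stem = character(0), members = character(0))
    return(rings)
  }

  keep <- rings[!(rings$tree_id %in% unlist(merged_groups)), , drop = FALSE]
  merged <- lapply(names(merged_groups), function(stem) {
    members <- merged_groups[[stem]]
    d <- rings[rings$tree_id %in% members, ]
    if (length(unique(d$site_id)) > 1L || length(unique(d$species)) > 1L) {
      stop(sprintf("cannot merge cores under stem '%s': differing site or species codes", stem))
    }
    max_age <- max(d$age)
    w <- if (combine == "mean") {
      tapply(d$rw_mm, factor(d$age, levels = seq_len(max_age)), mean)
    } else {
      first <- d[d$tree_id == members[1L], ]
      wf <- rep(NA_real_, max_age)
      wf[first$age] <- first$rw_mm
      rest <- tapply(d$rw_mm, factor(d$age, levels = seq_len(max_age)), mean)
      ifelse(is.na(wf), rest, wf)
    }
    ly <- suppressWarnings(max(d$last_year, na.rm = TRUE))
    st <- unique(d$status)
    data.frame(tree_id = stem, site_id = d$site_id[1L], species = d$species[1L],
               age = seq_len(max_age), rw_mm = as.numeric(w),
               status = if (length(st) == 1L) st else "unknown",
               last_year = if (is.finite(ly)) as.integer(ly) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- rbind(keep, do.call(rbind, merged))
  rownames(out) <- NULL
  attr(out, "merge_report") <- data.frame(
    stem = names(merged_groups),
    members = vapply(merged_groups, paste, character(1), collapse = "+"),
    n_members = lengths(merged_groups), row.names = NULL)
  out
}

#' Per-tree summaries: early growth, age, maximum diameter
#'
#' For every tree with at least ten rings: mean ring width over the first ten
#' rings (early growth, mm/yr), age = ring count (years), maximum diameter =
#' twice the cumulative ring width (one core approximates the radius; no bark
#' or pith-offset correction - problematic trees should be excluded upstream,
#' not corrected). Trees with fewer than ten rings are excluded and counted.
#'
#' @param rings long-form ring data frame.
#' @return data frame (tree_id, site_id, species, rw_early, age,
#'   max_diameter, status, last_year); attribute \code{excluded} holds the
#'   IDs of trees dropped for having fewer than 10 rings.
#' @export
summarize_trees <- function(rings) {
  if (nrow(rings) == 0L) {
    out <- data.frame(tree_id = character(0), site_id = character(0),
                      species = character(0), rw_early = numeric(0),
                      age = integer(0), max_diameter = numeric(0),
                      status = character(0), last_year = integer(0))
    attr(out, "excluded") <- character(0)
    return(out)
  }
  o <- rings[order(rings$tree_id, rings$age), ]
  sp <- split(seq_len(nrow(o)), o$tree_id)
  rows <- lapply(sp, function(ix) {
    n <- length(ix)
    if (n < 10L) return(NULL)
    w <- o$rw_mm[ix]
    data.frame(tree_id = o$tree_id[ix[1L]], site_id = o$site_id[ix[1L]],
               species = o$species[ix[1L]], rw_early = mean(w[1:10]),
               age = n, max_diameter = 2 * sum(w), status = o$status[ix[1L]],
               last_year = o$last_year[ix[1L]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  excluded <- names(sp)[vapply(sp, length, integer(1)) < 10L]
  if (is.null(out)) out <- summarize_trees(empty_rings())
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Classify life status from the date of the outermost ring
#'
#' Archive series whose outermost ring predates AD 1900 are assumed to come
#' from trees already dead at sampling (no collections predate 1900); the
#' rule is strict ("before 1900"). Explicit dead/subfossil flags override it.
#'
#' @param last_year integer vector of outermost-ring calendar years (NA if
#'   undated).
#' @param status existing status flags ("alive", "dead", "subfossil",
#'   "unknown"); non-"unknown"/non-"alive" flags are kept.
#' @param cutoff strict cutoff year (default 1900).
#' @return character vector of statuses: \code{dead}, \code{alive} or
#'   \code{unknown}.
#' @export
classify_dead <- function(last_year, status = "unknown", cutoff = 1900L) {
  status <- rep_len(as.character(status), length(last_year))
  out <- ifelse(is.na(last_year), "unknown",
                ifelse(last_year < cutoff, "dead", "alive"))
  keep <- !(status %in% c("unknown", "alive")) & !is.na(status)
  out[keep] <- status[keep]
  out
}

#' Screen sites on sample size and age-structure evenness
#'
#' Sites with few trees or an even age structure (young, single-cohort
#' stands) cannot yield robust lifespan estimates. A site is kept iff it has
#' at least \code{min_records} trees and a coefficient of variation of tree
#' ages (sample sd / mean * 100) of at least \code{min_cv_age_pct} percent;
#' both comparisons follow the screening rule's strict "lower than" reading
#' for CV and inclusive "at least" for counts.
#'
#' @param summaries per-tree summaries (see [summarize_trees()]).
#' @param min_records minimum trees per site (inclusive), default 20.
#' @param min_cv_age_pct minimum CV of ages in percent (sites strictly below
#'   are dropped), default 10.
#' @return list with \code{summaries} (rows from retained sites) and
#'   \code{report} (per-site n, cv_age_pct, kept, reason).
#' @export
filter_sites <- function(summaries, min_records = 20L, min_cv_age_pct = 10) {
  sp <- split(summaries$age, summaries$site_id)
  cv <- vapply(sp, function(a) if (length(a) > 1) sd(a) / mean(a) * 100 else 0, numeric(1))
  n <- lengths(sp)
  kept <- n >= min_records & cv >= min_cv_age_pct
  reason <- ifelse(kept, "", ifelse(n < min_records, "too few records", "CV_age below threshold"))
  report <- data.frame(site_id = names(sp), n = as.integer(n), cv_age_pct = cv,
                       kept = kept, reason = reason, row.names = NULL)
  list(summaries = summaries[summaries$site_id %in% names(sp)[kept], , drop = FALSE],
       report = report)
}

#' Screen species for the two analysis levels
#'
#' Returns per-species eligibility flags: \code{species_level} (cross-species
#' growth/lifespan estimates) needs at least \code{min_species_level} trees;
#' \code{within_species} (per-species trade-off fits) needs strictly more
#' than \code{min_within_species} trees from at least \code{min_sites} sites.
#' For archive (ITRDB-style) sources an additional inclusion gate applies:
#' at least \code{min_sites} sites with \code{min_records_site} records each
#' and at least \code{min_series} series in total.
#'
#' @param summaries per-tree summaries, already site-filtered.
#' @param min_sites minimum sites, default 3.
#' @param min_series minimum total series for archive inclusion, default 100.
#' @param min_species_level minimum trees for species-level use, default 30.
#' @param min_within_species within-species fits need strictly more trees
#'   than this, default 150.
#' @param min_records_site records per site counted toward archive
#'   inclusion, default 20.
#' @param source \code{"generic"} or \code{"itrdb"} (applies the archive gate
#'   to both flags).
#' @return data frame: species, n_trees, n_sites, species_level,
#'   within_species (logical flags).
#' @export
filter_species <- function(summaries, min_sites = 3L, min_series = 100L,
                           min_species_level = 30L, min_within_species = 150L,
                           min_records_site = 20L, source = c("generic", "itrdb")) {
  source <- match.arg(source)
  sp <- split(summaries, summaries$species)
  rows <- lapply(names(sp), function(s) {
    d <- sp[[s]]
    site_n <- table(d$site_id)
    n <- nrow(d)
    itrdb_ok <- sum(site_n >= min_records_site) >= min_sites && n >= min_series
    gate <- source != "itrdb" || itrdb_ok
    data.frame(species = s, n_trees = n, n_sites = length(site_n),
               species_level = gate && n >= min_species_level,
               within_species = gate && n > min_within_species && length(site_n) >= min_sites,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
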