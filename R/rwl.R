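#' Read a Tucson (RWL) ring-width file
#'
#' Parses the decadal Tucson dialect used by the International Tree-Ring Data
#' Bank: an 8-character series ID, the year of the first value on the row,
#' then up to ten ring widths. Units are auto-detected from the end-of-series
#' marker: \code{999} means widths in 0.01 mm, \code{-9999} means 0.001 mm.
#' A file mixing both markers is rejected.
#'
#' @param path path to the file.
#' @param site_id,species,status metadata to attach to every series (the
#'   Tucson format itself carries none); defaults: site from the file name,
#'   species and status unknown.
#' @return long-form data frame (tree_id, site_id, species, age, rw_mm,
#'   status, last_year) with one row per ring, cambial age starting at 1;
#'   \code{last_year} is the calendar year of the outermost ring as dated in
#'   the file. An empty file returns an empty data frame with a warning.
#' @export
read_rwl <- function(path, site_id = NULL,
                     species = NA_character_, status = "unknown") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0L) {
    warning(sprintf("empty RWL file: %s", path))
    return(empty_rings())
  }
  site_id <- site_id %||% tools::file_path_sans_ext(basename(path))

  ids <- character(0)
  vals <- list()
  years0 <- numeric(0)
  terminator <- NA_character_

  for (ln in lines_keep) {
    raw <- lines[ln]
    id <- trimws(substr(raw, 1, 8))
    rest <- strsplit(trimws(substr(raw, 9, nchar(raw))), "\\s+")[[1]]
    nums <- suppressWarnings(as.numeric(rest))
    if (length(nums) < 2L || any(is.na(nums))) {
      stop(sprintf("malformed decade row at line %d of %s", ln, path))
    }
    yr <- nums[1L]
    vv <- nums[-1L]
    term <- NULL
    if (vv[length(vv)] == -9999) term <- "0.001"
    else if (vv[length(vv)] == 999) term <- "0.01"
    if (!is.null(term)) {
      if (!is.na(terminator) && terminator != term) {
        stop(sprintf("mixed units in %s: both 999 and -9999 end-of-series markers", path))
      }
      terminator <- term
      vv <- vv[-length(vv)]
    }
    if (!(id %in% ids)) {
      ids <- c(ids, id)
      vals[[id]] <- numeric(0)
      years0[id] <- yr
    }
    vals[[id]] <- c(vals[[id]], vv)
  }
  if (is.na(terminator)) terminator <- "0.01"
  mult <- if (terminator == "0.01") 100 else 1000

  out <- lapply(ids, function(id) {
    w <- vals[[id]] / mult
    n <- length(w)
    if (n == 0L) return(NULL)
    data.frame(tree_id = id, site_id = site_id, species = species,
               age = seq_len(n), rw_mm = w, status = status,
               last_year = as.integer(years0[id] + n - 1L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write ring series to a Tucson (RWL) file
#'
#' @param rings long-form ring data frame (see [read_rwl()]). Ring widths are
#'   rounded to the format precision. If \code{last_year} is present the
#'   decade rows are dated so the outermost ring falls on it; otherwise years
#'   run from 1 (cambial dating).
#' @param path output path.
#' @param units \code{"0.01"} mm (marker 999, default) or \code{"0.001"} mm
#'   (marker -9999).
#' @return the path, invisibly.
#' @export
write_rwl <- function(rings, path, units = c("0.01", "0.001")) {
  units <- match.arg(units)
  mult <- if (units == "0.01") 100 else 1000
  marker <- if (units == "0.01") 999 else -9999
  ids <- unique(rings$tree_id)
  if (any(nchar(ids) > 8)) stop("tree IDs longer than 8 characters cannot be written to RWL")

  con <- file(path, "w")
  on.exit(close(con))
  for (id in ids) {
    d <- rings[rings$tree_id == id, ]
    d <- d[order(d$age), ]
    w <- round(d$rw_mm * mult)
    n <- length(w)
    ly <- d$last_year[1L]
    yr1 <- if (is.na(ly)) 1L else as.integer(ly - n + 1L)
    years <- yr1:(yr1 + n - 1L)
    tokens <- c(as.character(as.integer(w)), as.character(marker))
    tok_year <- c(years, years[n] + 1L)
    k <- 1L
    while (k <= length(tokens)) {
      row_start <- tok_year[k]
      decade_end <- (row_start %/% 10L) * 10L + 9L
      in_row <- which(tok_year >= row_start & tok_year <= decade_end & seq_along(tokens) >= k)
      line <- sprintf("%-8s%4d%s", id, row_start,
                      paste0(sprintf("%6s", tokens[in_row]), collapse = ""))
      writeLines(line, con)
      k <- k + length(in_row)
    }
  }
  invisible(path)
}

empty_rings <- function() {
  data.frame(tree_id = character(0), site_id = character(0),
             species = character(0), age = integer(0), rw_mm = numeric(0),
             status = character(0), last_year = integer(0),
             stringsAsFactors = FALSE)
}

#' Read/write the long-form CSV ring dialect
#'
#' Columns: \code{tree_id, site_id, species, cambial_age, ring_width_mm,
#' status} (and optionally \code{last_year}).
#'
#' @param path file path.
#' @return for the reader, a long-form ring data frame as in [read_rwl()].
#' @export
read_rings_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "site_id", "species", "cambial_age", "ring_width_mm", "status")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop(sprintf("missing columns in %s: %s", path, paste(miss, collapse = ", ")))
  data.frame(tree_id = as.character(d$tree_id), site_id = as.character(d$site_id),
             species = as.character(d$species), age = as.integer(d$cambial_age),
             rw_mm = as.numeric(d$ring_width_mm), status = as.character(d$status),
             last_year = if ("last_year" %in% names(d)) as.integer(d$last_year) else NA_integer_,
             stringsAsFactors = FALSE)
}

#' @rdname read_rings_csv
#' @param rings long-form ring data frame.
#' @export
write_rings_csv <- function(rings, path) {
  out <- data.frame(tree_id = rings$tree_id, site_id = rings$site_id,
                    species = rings$species, cambial_age = rings$age,
                    ring_width_mm = rings$rw_mm, status = rings$status,
                    last_year = rings$last_year)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read/write site metadata CSV
#'
#' Columns: \code{site_id, lat, lon, mat_c, map_mm, crown_cover_class,
#' soil_class}.
#'
#' @param path file path.
#' @return for the reader, the site data frame.
#' @export
read_sites_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "lat", "lon", "mat_c")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop(sprintf("missing columns in %s: %s", path, paste(miss, collapse = ", ")))
  if (any(d$lat < -90 | d$lat > 90)) stop("latitude outside [-90, 90]")
  d
}

#' @rdname read_sites_csv
#' @param sites site data frame.
#' @export
write_sites_csv <- function(sites, path) {
  utils::write.csv(sites, path, row.names = FALSE)
  invisible(path)
}
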