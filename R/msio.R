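# MS identification / LC-MS peak table I/O and per-residue area compilation.
#
# The LC-MS quantification bottleneck in footprinting is that an MS/MS
# identification (retention time + m/z of a peptide form) must be matched
# back to the chromatographic peak list of every dose point, and the matched
# areas compiled into oxidized / unoxidized totals per residue.

.id_cols   <- c("peptide", "start", "mod_residue", "rt", "mz", "charge")
.peak_cols <- c("dose_id", "rt", "mz", "area")

.read_mapped_csv <- function(path, required, col_map = NULL, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    # col_map: names = canonical, values = column names in the file
    for (canon in names(col_map)) {
      hit <- match(col_map[[canon]], names(df))
      if (!is.na(hit)) names(df)[hit] <- canon
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("format error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

.check_numeric <- function(df, cols, what) {
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(as.character(df[[cl]])))
    bad <- which(is.na(v) & !(is.na(df[[cl]]) | df[[cl]] == ""))
    if (length(bad) > 0) {
      stop(sprintf("unparseable %s value in column '%s' at row %d",
                   what, cl, bad[1]), call. = FALSE)
    }
    df[[cl]] <- v
  }
  df
}

#' Parse a MASCOT-style peptide identification export
#'
#' Reads a comma-separated identification table (one row per identified
#' peptide form and charge state) into a standardized data frame. Unoxidized
#' forms are flagged by an empty/absent modification-site column.
#'
#' @param path Path to a CSV file with a header row. Canonical columns:
#'   `peptide` (amino-acid string), `start` (1-based residue index of the
#'   peptide start in the protein), `mod_residue` (1-based protein index of
#'   the oxidized residue; empty for the unoxidized form), `rt` (minutes),
#'   `mz` (Th), `charge` (integer). An optional `mod_mass_shift` column (Da)
#'   is carried through if present.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the column names actually used in the export, e.g.
#'   `c(rt = "pep_scan_title_rt")`, to accommodate MASCOT/MassHunter dialects.
#' @return A data frame with columns `peptide`, `start`, `mod_residue`
#'   (`NA` for unoxidized forms), `rt`, `mz`, `charge` and, when present,
#'   `mod_mass_shift`.
#' @export
parse_identifications <- function(path, col_map = NULL) {
  df <- .read_mapped_csv(path, .id_cols, col_map, "identifications")
  df$peptide <- toupper(trimws(as.character(df$peptide)))
  df <- .check_numeric(df, c("start", "mod_residue", "rt", "mz", "charge"),
                       "identification")
  if ("mod_mass_shift" %in% names(df)) {
    df <- .check_numeric(df, "mod_mass_shift", "identification")
  }
  n <- nrow(df)
  for (i in seq_len(n)) {
    if (is.na(df$start[i]) || df$start[i] < 1) {
      stop("invalid start (must be >= 1) at row ", i, call. = FALSE)
    }
    if (is.na(df$rt[i]) || df$rt[i] <= 0) {
      stop("invalid rt (must be > 0) at row ", i, call. = FALSE)
    }
    if (is.na(df$mz[i]) || df$mz[i] <= 0) {
      stop("invalid mz (must be > 0) at row ", i, call. = FALSE)
    }
    m <- df$mod_residue[i]
    if (!is.na(m)) {
      lo <- df$start[i]
      hi <- df$start[i] + nchar(df$peptide[i]) - 1L
      if (m < lo || m > hi) {
        stop(sprintf(
          "mod_residue %d outside peptide span [%d, %d] at row %d",
          as.integer(m), as.integer(lo), as.integer(hi), i), call. = FALSE)
      }
    }
  }
  keep <- intersect(c(.id_cols, "mod_mass_shift"), names(df))
  df[, keep, drop = FALSE]
}

#' Parse an LC-MS peak list
#'
#' Reads a peak table (one row per chromatographic peak per dose point).
#' Duplicate (dose, rt, mz) rows are retained: peaks may legitimately
#' co-elute and both areas count.
#'
#' @param path Path to a CSV file with columns `dose_id` (exposure label,
#'   e.g. ms of X-ray exposure), `rt` (minutes), `mz` (Th), `area`
#'   (arbitrary units, non-negative).
#' @param col_map Optional canonical-to-file column-name map, as in
#'   [parse_identifications()].
#' @return Data frame with columns `dose_id`, `rt`, `mz`, `area`.
#' @export
parse_peak_table <- function(path, col_map = NULL) {
  df <- .read_mapped_csv(path, .peak_cols, col_map, "peaks")
  if (nrow(df) == 0) {
    warning("peak table is empty: ", path)
    return(df[, .peak_cols, drop = FALSE])
  }
  df$dose_id <- as.character(df$dose_id)
  df <- .check_numeric(df, c("rt", "mz", "area"), "peak")
  bad <- which(df$area < 0)
  if (length(bad) > 0) {
    stop("negative peak area at row ", bad[1], call. = FALSE)
  }
  df[, .peak_cols, drop = FALSE]
}

#' Match identifications to peaks and compile per-residue areas
#'
#' For every dose point, each identification row is matched to the peak(s)
#' within `rt_tol` and `mz_tol`; matched areas of the same peptide form
#' (multiple charge states) are summed, and form areas are folded into
#' per-residue oxidized / unoxidized totals.
#'
#' The unoxidized denominator at residue i is conditional on that site:
#' it is the unoxidized-peptide area plus the oxidized areas of the *other*
#' residues of the same peptide (those molecules are not oxidized at i).
#' Residues covered by no identification are absent from the output
#' ("not detected"). If any identified form of a peptide finds no peak at a
#' dose, that dose point is dropped for every residue of that peptide and
#' the event is logged; ambiguous matches (>1 peak in tolerance) are summed
#' and logged.
#'
#' @param ids Data frame from [parse_identifications()].
#' @param peaks Data frame from [parse_peak_table()].
#' @param rt_tol Retention-time tolerance in minutes (default 0.5).
#' @param mz_tol m/z tolerance in Th (default 0.02).
#' @return A tidy data frame (class `residue_area_table`) with columns
#'   `residue` (1-based protein index), `residue_type` (one-letter),
#'   `dose_id`, `area_ox`, `area_unox`. The match log (unmatched forms,
#'   ambiguous matches) is attached as `attr(, "match_log")`.
#' @export
match_and_aggregate <- function(ids, peaks, rt_tol = 0.5, mz_tol = 0.02) {
  stopifnot(rt_tol > 0, mz_tol > 0)
  doses <- unique(as.character(peaks$dose_id))
  # canonical dose order (numeric when possible) so output is invariant
  # to input row order
  dn <- suppressWarnings(as.numeric(doses))
  doses <- if (anyNA(dn)) sort(doses) else doses[order(dn)]
  log <- list()
  # peptide form key: peptide sequence + start + modified residue (NA = unox)
  form_key <- paste(ids$peptide, ids$start,
                    ifelse(is.na(ids$mod_residue), "unox", ids$mod_residue),
                    sep = "|")
  pep_key <- paste(ids$peptide, ids$start, sep = "|")

  rows <- list()
  for (pk in sort(unique(pep_key))) {
    sel <- which(pep_key == pk)
    pep <- ids$peptide[sel[1]]
    start <- as.integer(ids$start[sel[1]])
    resnos <- seq.int(start, start + nchar(pep) - 1L)
    restypes <- strsplit(pep, "")[[1]]
    forms <- sort(unique(form_key[sel]))
    for (d in doses) {
      pk_d <- peaks[peaks$dose_id == d, , drop = FALSE]
      form_area <- setNames(numeric(length(forms)), forms)
      form_hit <- setNames(logical(length(forms)), forms)
      for (r in sel) {
        hit <- which(abs(pk_d$rt - ids$rt[r]) <= rt_tol &
                     abs(pk_d$mz - ids$mz[r]) <= mz_tol)
        f <- form_key[r]
        if (length(hit) == 0) next
        if (length(hit) > 1) {
          log[[length(log) + 1L]] <- data.frame(
            event = "ambiguous", peptide = pep, start = start, dose_id = d,
            form = f, detail = sprintf("%d peaks in tolerance, areas summed",
                                       length(hit)))
        }
        form_area[f] <- form_area[f] + sum(pk_d$area[hit])
        form_hit[f] <- TRUE
      }
      if (!all(form_hit)) {
        for (f in forms[!form_hit]) {
          log[[length(log) + 1L]] <- data.frame(
            event = "unmatched", peptide = pep, start = start, dose_id = d,
            form = f, detail = "no peak in tolerance; dose dropped for peptide")
        }
        next
      }
      unox_key <- paste(pep, start, "unox", sep = "|")
      a_unox_pep <- if (unox_key %in% forms) form_area[[unox_key]] else 0
      mod_forms <- setdiff(forms, unox_key)
      mod_res <- as.integer(vapply(strsplit(mod_forms, "|", fixed = TRUE),
                                   `[`, "", 3L))
      ox_area <- setNames(rep(0, length(resnos)), resnos)
      if (length(mod_forms) > 0) {
        ox_area[as.character(mod_res)] <- form_area[mod_forms]
      }
      tot_ox <- sum(ox_area)
      rows[[length(rows) + 1L]] <- data.frame(
        residue = resnos,
        residue_type = restypes,
        dose_id = d,
        area_ox = as.numeric(ox_area),
        area_unox = a_unox_pep + tot_ox - as.numeric(ox_area),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(residue = integer(), residue_type = character(),
                      dose_id = character(), area_ox = numeric(),
                      area_unox = numeric(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    # overlapping peptides covering the same residue: evidence is summed
    agg <- stats::aggregate(cbind(area_ox, area_unox) ~ residue + residue_type + dose_id,
                            data = out, FUN = sum)
    agg <- agg[order(agg$residue, match(agg$dose_id, doses)), ]
    rownames(agg) <- NULL
    out <- agg[, c("residue", "residue_type", "dose_id", "area_ox", "area_unox")]
  }
  attr(out, "match_log") <- if (length(log)) do.call(rbind, log) else NULL
  class(out) <- c("residue_area_table", class(out))
  out
}
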