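#' Read a titration table into a list of series
#'
#' Reads a delimited text file with header columns `resonance_id`,
#' `nucleus`, `ph`, `shift_ppm`, and an optional `oxidation_state` column.
#' Rows are grouped into one [titration_series()] per
#' `(resonance_id, nucleus, oxidation_state)` combination and sorted by pH;
#' duplicate pH values within a series are repeated measurements and are
#' retained. Malformed numeric cells are reported with their row number.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return A named list of [titration_series()].
#' @export
read_titration_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop(sprintf("empty titration table: %s", path),
                            call. = FALSE)
  required <- c("resonance_id", "nucleus", "ph", "shift_ppm")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (!"oxidation_state" %in% names(raw)) raw$oxidation_state <- ""

  parse_num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) | !is.finite(x))
    if (length(bad) > 0L) {
      stop(sprintf("row %d: non-numeric %s value \"%s\"",
                   bad[1L] + 1L, col, raw[[col]][bad[1L]]), call. = FALSE)
    }
    x
  }
  ph <- parse_num("ph")
  shift <- parse_num("shift_ppm")

  key <- paste(raw$resonance_id, raw$nucleus, raw$oxidation_state, sep = "|")
  out <- lapply(split(seq_len(nrow(raw)), key)[unique(key)], function(idx) {
    titration_series(
      ph[idx], shift[idx],
      residue_label = raw$resonance_id[idx[1L]],
      nucleus_label = raw$nucleus[idx[1L]],
      state_label = raw$oxidation_state[idx[1L]]
    )
  })
  names(out) <- unique(key)
  out
}

#' Write titration series to a delimited table
#'
#' Inverse of [read_titration_table()]: serializes a list of series to the
#' same column layout at full numeric precision.
#'
#' @param series A [titration_series()] or list of them.
#' @param path Output file path.
#' @param sep Field separator.
#' @return The path, invisibly.
#' @export
write_titration_table <- function(series, path, sep = ",") {
  if (inherits(series, "titration_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(
      resonance_id = s$residue_label,
      nucleus = s$nucleus_label,
      oxidation_state = s$state_label,
      ph = s$points$ph,
      shift_ppm = s$points$shift,
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(rows, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of amino-acid sequences (e.g.
#'   from [sim_motif_sequences()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Read amino-acid sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- names(set)
  out
}

# Display formatting ----------------------------------------------------------

#' Format a pKa estimate in "mean +/- sd (n)" style
#'
#' One decimal place for the mean and standard deviation, the resonance
#' count in parentheses; the standard deviation is omitted when undefined
#' (single resonance).
#'
#' @param x A [aggregate_pka()] estimate.
#' @return A character string such as `"10.6 ± 0.2 (7)"`.
#' @export
format_pka_estimate <- function(x) {
  stopifnot(inherits(x, "pka_estimate"))
  if (x$sd_defined) {
    sprintf("%.1f ± %.1f (%d)", round_display(x$mean_pka, 1),
            round_display(x$sd_pka, 1), x$n_resonances)
  } else {
    sprintf("%.1f (%d)", round_display(x$mean_pka, 1), x$n_resonances)
  }
}

#' Format a replicate summary in "mean +/- sd (se%)" style
#'
#' Mean (with a thousands separator) and SD rounded to integers, the
#' percentage standard error in parentheses.
#'
#' @param x A [summarize_replicates()] summary.
#' @return A character string such as `"20,301 ± 2581 (7%)"`.
#' @export
format_replicate_summary <- function(x) {
  stopifnot(inherits(x, "replicate_summary"))
  sprintf("%s ± %d (%d%%)",
          formatC(round_display(x$mean), format = "d", big.mark = ","),
          round_display(x$sd), round_display(x$pct_se))
}

#' Format a relative activity in "percent +/- uncertainty" style
#'
#' @param x A [relative_activity()] object.
#' @return A character string such as `"77 ± 11"`.
#' @export
format_relative_activity <- function(x) {
  stopifnot(inherits(x, "relative_activity"))
  sprintf("%d ± %d", round_display(x$percent),
          round_display(x$uncertainty))
}

# Report writing --------------------------------------------------------------

#' @export
as.data.frame.titration_fit <- function(x, ...) {
  if (x$model_kind == "one_pka") {
    data.frame(
      residue = x$residue_label, nucleus = x$nucleus_label,
      model_kind = "one_pka",
      delta_protonated = x$params$delta_protonated,
      delta_intermediate = NA_real_,
      delta_deprotonated = x$params$delta_deprotonated,
      pka1 = x$params$pka, pka2 = NA_real_,
      stderr_pka1 = x$stderr_pka, stderr_pka2 = NA_real_,
      rss = x$rss, dof = x$dof, converged = x$converged,
      extrapolated = x$extrapolated,
      nonidentifiable = isTRUE(x$nonidentifiable),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      residue = x$residue_label, nucleus = x$nucleus_label,
      model_kind = "two_pka",
      delta_protonated = x$params$delta_state0,
      delta_intermediate = x$params$delta_state1,
      delta_deprotonated = x$params$delta_state2,
      pka1 = x$params$pka1, pka2 = x$params$pka2,
      stderr_pka1 = x$stderr_pka[1L], stderr_pka2 = x$stderr_pka[2L],
      rss = x$rss, dof = x$dof, converged = x$converged,
      extrapolated = x$extrapolated,
      nonidentifiable = isTRUE(x$nonidentifiable),
      stringsAsFactors = FALSE
    )
  }
}

#' @export
as.data.frame.pka_estimate <- function(x, ...) {
  data.frame(
    transition = x$transition,
    mean_pka = x$mean_pka,
    sd_pka = x$sd_pka,
    n_resonances = x$n_resonances,
    display = format_pka_estimate(x),
    stringsAsFactors = FALSE
  )
}

report_frame <- function(x) {
  if (is.data.frame(x)) return(x)
  if (inherits(x, c("titration_fit", "pka_estimate", "replicate_summary",
                    "relative_activity", "extended_site_record"))) {
    return(as.data.frame(x))
  }
  if (is.list(x)) return(do.call(rbind, lapply(x, report_frame)))
  stop("cannot render this object into a report", call. = FALSE)
}

#' Write an analysis report to CSV or JSON
#'
#' Renders fits, estimates, activity statistics, or extended-site records
#' (single objects, lists of them, or ready-made data frames) into a flat
#' table with deterministic column order and writes it out. Numeric columns
#' are serialized at full precision; display-rounded strings live in
#' dedicated `display` columns so that exact-reproduction checks never
#' depend on rounding. An empty list yields a valid empty report.
#'
#' @param x Object(s) to report.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_report <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- if (is.list(x) && !is.data.frame(x) && length(x) == 0L) {
    data.frame()
  } else {
    report_frame(x)
  }
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
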