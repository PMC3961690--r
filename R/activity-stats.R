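#' Summarize replicate densitometry readings
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator), and
#' percentage standard error `100 * (sd / sqrt(n)) / mean` of a set of
#' replicate densitometry peak heights.
#'
#' @param readings Numeric vector of peak heights (arbitrary units), all
#'   positive, length at least 2.
#' @param construct_label,dataset_label Optional free-text labels.
#' @return An object of class `replicate_summary` with `mean`, `sd`,
#'   `pct_se`, `n`, and the labels.
#' @export
summarize_replicates <- function(readings, construct_label = "",
                                 dataset_label = "") {
  stopifnot(is.numeric(readings), all(is.finite(readings)))
  if (length(readings) < 2L) {
    stop("need at least 2 replicate readings", call. = FALSE)
  }
  if (any(readings <= 0)) {
    stop("all replicate readings must be positive", call. = FALSE)
  }
  m <- mean(readings)
  s <- stats::sd(readings)
  structure(
    list(
      mean = m,
      sd = s,
      pct_se = 100 * (s / sqrt(length(readings))) / m,
      n = length(readings),
      construct_label = as.character(construct_label),
      dataset_label = as.character(dataset_label)
    ),
    class = "replicate_summary"
  )
}

#' Relative activity of a variant versus wild type
#'
#' Activity of a variant construct expressed as a percentage of the
#' wild-type activity measured in the same dataset, with uncertainty
#' propagated in quadrature from the relative sample standard deviations of
#' the two replicate sets:
#' `u = percent * sqrt((sd_v/mean_v)^2 + (sd_wt/mean_wt)^2)`.
#'
#' @param variant,wild_type [summarize_replicates()] objects from the same
#'   dataset (dataset labels are checked when both are non-empty).
#' @return An object of class `relative_activity` with `percent`,
#'   `uncertainty`, and `level = "per_dataset"`.
#' @export
relative_activity <- function(variant, wild_type) {
  stopifnot(inherits(variant, "replicate_summary"),
            inherits(wild_type, "replicate_summary"))
  if (nzchar(variant$dataset_label) && nzchar(wild_type$dataset_label) &&
      variant$dataset_label != wild_type$dataset_label) {
    stop(sprintf("dataset labels differ: \"%s\" vs \"%s\"",
                 variant$dataset_label, wild_type$dataset_label),
         call. = FALSE)
  }
  if (wild_type$mean == 0) stop("wild-type mean is zero", call. = FALSE)
  pct <- 100 * variant$mean / wild_type$mean
  u <- pct * sqrt((variant$sd / variant$mean)^2 +
                    (wild_type$sd / wild_type$mean)^2)
  structure(
    list(
      percent = pct,
      uncertainty = u,
      level = "per_dataset",
      construct_label = variant$construct_label,
      dataset_label = variant$dataset_label
    ),
    class = "relative_activity"
  )
}

#' Average relative activity across datasets
#'
#' Unweighted mean of per-dataset relative activities, with uncertainty
#' propagated through the mean as `sqrt(sum(u_i^2)) / n` (independent
#' per-dataset uncertainties).
#'
#' @param per_dataset A list of per-dataset [relative_activity()] objects
#'   (a single object is promoted to the average level unchanged).
#' @return A `relative_activity` with `level = "average"`.
#' @export
average_relative_activity <- function(per_dataset) {
  if (inherits(per_dataset, "relative_activity")) {
    per_dataset <- list(per_dataset)
  }
  stopifnot(length(per_dataset) >= 1L,
            all(vapply(per_dataset, inherits, logical(1),
                       "relative_activity")))
  if (!all(vapply(per_dataset, function(x) x$level, character(1)) ==
             "per_dataset")) {
    stop("all inputs must be per-dataset relative activities", call. = FALSE)
  }
  pcts <- vapply(per_dataset, function(x) x$percent, numeric(1))
  us <- vapply(per_dataset, function(x) x$uncertainty, numeric(1))
  n <- length(pcts)
  structure(
    list(
      percent = mean(pcts),
      uncertainty = sqrt(sum(us^2)) / n,
      level = "average",
      construct_label = per_dataset[[1L]]$construct_label,
      dataset_label = ""
    ),
    class = "relative_activity"
  )
}

#' Printed densitometry readings for the DsbD in vivo activity assay
#'
#' The raw densitometry peak heights from the in vivo cytochrome cd1
#' maturation assay: for each experiment the activities of a DsbD point
#' variant (Q488A or Q488K) and of wild-type DsbD were measured in three
#' replicate growths per dataset, with three datasets for Q488A and two for
#' Q488K (30 readings in all). These published values are the package's
#' reference input for the replicate-statistics pipeline.
#'
#' @return A data frame with columns `experiment` (`"Q488A"` or `"Q488K"`),
#'   `construct`, `dataset` (integer), and `reading` (arbitrary units).
#' @export
dsbd_activity_readings <- function() {
  rbind(
    data.frame(
      experiment = "Q488A",
      construct = rep(c("Wild-type DsbD", "Q488A-DsbD"), each = 9L),
      dataset = rep(rep(1:3, each = 3L), 2L),
      reading = c(
        17656, 22812, 20434,   # wild type, dataset 1
        19313, 20815, 19248,   # wild type, dataset 2
        19629, 17319, 19394,   # wild type, dataset 3
        15218, 16825, 15098,   # Q488A, dataset 1
        14507, 15261, 16927,   # Q488A, dataset 2
        13210, 15024, 14434    # Q488A, dataset 3
      )
    ),
    data.frame(
      experiment = "Q488K",
      construct = rep(c("Wild-type DsbD", "Q488K-DsbD"), each = 6L),
      dataset = rep(rep(1:2, each = 3L), 2L),
      reading = c(
        25817, 26542, 22687,   # wild type, dataset 1
        18856, 18519, 17710,   # wild type, dataset 2
        25610, 26097, 25030,   # Q488K, dataset 1
        22411, 22814, 22041    # Q488K, dataset 2
      )
    )
  )
}

#' Full activity report from a replicate reading table
#'
#' Runs the whole replicate-statistics pipeline on a long-format reading
#' table: per construct and dataset replicate summaries, per-dataset
#' relative activities of each non-wild-type construct versus the wild type,
#' and the cross-dataset average relative activity per variant. Experiments
#' (independent variant/wild-type comparisons) are processed separately when
#' an `experiment` column is present.
#'
#' @param readings Data frame with columns `construct`, `dataset`, `reading`
#'   and optionally `experiment`; defaults to the published assay readings
#'   from [dsbd_activity_readings()].
#' @param wild_type Construct label identifying the reference rows.
#' @return A list with `summaries` (data frame of per construct/dataset
#'   summary statistics, full precision plus display-rounded columns),
#'   `relative` (per-dataset relative activities), and `average`
#'   (per-variant averages).
#' @export
activity_report <- function(readings = dsbd_activity_readings(),
                            wild_type = "Wild-type DsbD") {
  stopifnot(is.data.frame(readings),
            all(c("construct", "dataset", "reading") %in% names(readings)))
  if (!"experiment" %in% names(readings)) readings$experiment <- "all"
  if (!any(readings$construct == wild_type)) {
    stop(sprintf("no rows with wild-type construct \"%s\"", wild_type),
         call. = FALSE)
  }

  summaries <- list()
  relative <- list()
  average <- list()
  for (exp_id in unique(readings$experiment)) {
    block <- readings[readings$experiment == exp_id, ]
    variants <- setdiff(unique(block$construct), wild_type)
    for (v in variants) {
      per_ds <- list()
      for (ds in sort(unique(block$dataset[block$construct == v]))) {
        wt_sum <- summarize_replicates(
          block$reading[block$construct == wild_type & block$dataset == ds],
          construct_label = wild_type, dataset_label = as.character(ds)
        )
        v_sum <- summarize_replicates(
          block$reading[block$construct == v & block$dataset == ds],
          construct_label = v, dataset_label = as.character(ds)
        )
        summaries[[length(summaries) + 1L]] <-
          cbind(experiment = exp_id, as.data.frame(wt_sum))
        summaries[[length(summaries) + 1L]] <-
          cbind(experiment = exp_id, as.data.frame(v_sum))
        rel <- relative_activity(v_sum, wt_sum)
        per_ds[[length(per_ds) + 1L]] <- rel
        relative[[length(relative) + 1L]] <-
          cbind(experiment = exp_id, as.data.frame(rel))
      }
      avg <- average_relative_activity(per_ds)
      average[[length(average) + 1L]] <-
        cbind(experiment = exp_id, as.data.frame(avg))
    }
  }
  list(
    summaries = unique(do.call(rbind, summaries)),
    relative = do.call(rbind, relative),
    average = do.call(rbind, average)
  )
}

# Display rounding used throughout the activity tables: half away from zero,
# matching how the published table rounds means, SDs, and percentages.
round_display <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
as.data.frame.replicate_summary <- function(x, ...) {
  data.frame(
    construct = x$construct_label,
    dataset = x$dataset_label,
    n = x$n,
    mean = x$mean,
    sd = x$sd,
    pct_se = x$pct_se,
    display = format_replicate_summary(x),
    stringsAsFactors = FALSE
  )
}

#' @export
as.data.frame.relative_activity <- function(x, ...) {
  data.frame(
    construct = x$construct_label,
    dataset = x$dataset_label,
    level = x$level,
    percent = x$percent,
    uncertainty = x$uncertainty,
    display = format_relative_activity(x),
    stringsAsFactors = FALSE
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("%s dataset %s: %s\n", x$construct_label, x$dataset_label,
              format_replicate_summary(x)))
  invisible(x)
}

#' @export
print.relative_activity <- function(x, ...) {
  lvl <- if (x$level == "average") "average relative activity" else
    sprintf("relative activity (dataset %s)", x$dataset_label)
  cat(sprintf("%s %s: %s\n", x$construct_label, lvl,
              format_relative_activity(x)))
  invisible(x)
}
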