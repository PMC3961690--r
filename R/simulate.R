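draw_range <- function(x, n) {
  # scalar -> fixed value, length-2 vector -> uniform draw per resonance
  if (length(x) == 1L) rep(as.numeric(x), n)
  else stats::runif(n, min(x), max(x))
}

#' Simulate one-pKa titration series
#'
#' Generates per-resonance chemical-shift titration series from the one-pKa
#' model plus i.i.d. Gaussian noise, emulating the measurement design of an
#' NMR pH-titration experiment: a pH ladder from 4 to 13, per-resonance
#' limiting shifts with amplitudes in a stated range, and per-point noise
#' small relative to the amplitude. The ground truth is returned alongside
#' the series so recovery can be tested without hidden state.
#'
#' @param pka True midpoint shared by all resonances.
#' @param n_resonances Number of series to generate.
#' @param ph_grid pH values (default 4-13 in steps of 0.5).
#' @param amplitude_range Titration amplitude in ppm; a scalar fixes it, a
#'   length-2 range draws one value per resonance.
#' @param baseline_range Protonated-limit shift in ppm (scalar or range).
#' @param noise_sd Gaussian noise SD in ppm (default 0.05).
#' @param seed Integer seed; `NULL` leaves the session RNG untouched.
#'   Identical spec and seed give identical output.
#' @param params Optional [one_pka_params()] used verbatim for every
#'   resonance, overriding `pka`/amplitude/baseline draws.
#' @return A list with `series` (list of [titration_series()]) and `truth`
#'   (list of the exact [one_pka_params()] behind each series).
#' @export
sim_one_pka_titration <- function(pka = NULL, n_resonances = 1L,
                                  ph_grid = seq(4, 13, by = 0.5),
                                  amplitude_range = c(0.5, 2.5),
                                  baseline_range = c(25, 60),
                                  noise_sd = 0.05, seed = NULL,
                                  params = NULL) {
  stopifnot(length(ph_grid) >= 1L, !is.unsorted(ph_grid), noise_sd >= 0,
            n_resonances >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  truth <- vector("list", n_resonances)
  series <- vector("list", n_resonances)
  if (is.null(params)) {
    stopifnot(is.numeric(pka), is.finite(pka))
    base <- draw_range(baseline_range, n_resonances)
    amp <- draw_range(amplitude_range, n_resonances)
  }
  for (r in seq_len(n_resonances)) {
    p <- if (is.null(params)) {
      one_pka_params(base[r], base[r] + amp[r], pka)
    } else params
    mu <- shift_one_pka(ph_grid, p)
    series[[r]] <- titration_series(
      ph_grid, mu + stats::rnorm(length(ph_grid), 0, noise_sd),
      residue_label = sprintf("sim%02d", r)
    )
    truth[[r]] <- p
  }
  list(series = series, truth = truth)
}

#' Simulate two-pKa titration series
#'
#' As [sim_one_pka_titration()] but from the double-sigmoid model. The
#' intermediate plateau sits a fraction `mid_fraction` of the way up the
#' total amplitude (0.5 gives two equal steps).
#'
#' @inheritParams sim_one_pka_titration
#' @param pka1,pka2 True midpoints (`pka1 <= pka2`).
#' @param amplitude_range Total amplitude (both steps combined), ppm.
#' @param mid_fraction Fraction of the amplitude reached at the intermediate
#'   plateau.
#' @param params Optional [two_pka_params()] used verbatim for every
#'   resonance.
#' @return A list with `series` and `truth` as in
#'   [sim_one_pka_titration()].
#' @export
sim_two_pka_titration <- function(pka1 = NULL, pka2 = NULL, n_resonances = 1L,
                                  ph_grid = seq(4, 13, by = 0.25),
                                  amplitude_range = c(1.8, 3.0),
                                  mid_fraction = 0.5,
                                  baseline_range = c(25, 60),
                                  noise_sd = 0.05, seed = NULL,
                                  params = NULL) {
  stopifnot(length(ph_grid) >= 1L, !is.unsorted(ph_grid), noise_sd >= 0,
            n_resonances >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  truth <- vector("list", n_resonances)
  series <- vector("list", n_resonances)
  if (is.null(params)) {
    stopifnot(is.finite(pka1), is.finite(pka2), pka1 <= pka2,
              mid_fraction >= 0, mid_fraction <= 1)
    base <- draw_range(baseline_range, n_resonances)
    amp <- draw_range(amplitude_range, n_resonances)
  }
  for (r in seq_len(n_resonances)) {
    p <- if (is.null(params)) {
      two_pka_params(base[r], base[r] + mid_fraction * amp[r],
                     base[r] + amp[r], pka1, pka2)
    } else params
    mu <- shift_two_pka(ph_grid, p)
    series[[r]] <- titration_series(
      ph_grid, mu + stats::rnorm(length(ph_grid), 0, noise_sd),
      residue_label = sprintf("sim%02d", r)
    )
    truth[[r]] <- p
  }
  list(series = series, truth = truth)
}

#' Simulate titration series from a coupled two-site model
#'
#' The noiseless observable is linear in each site's deprotonation
#' fraction: `shift = baseline + amp_A * fA(pH) + amp_B * fB(pH)`. The
#' defaults emulate a site-B-only observable (e.g. the C-beta shift of an
#' attacking cysteine coupled to a nearby aspartate) with the ~2.7 ppm total
#' downfield amplitude characteristic of thiolate formation; for a symmetric
#' model this produces a double sigmoid with two almost equal steps. Setting
#' one amplitude to zero yields the other site's marginal exactly.
#'
#' @inheritParams sim_one_pka_titration
#' @param model A [coupled_site_model()] ground truth.
#' @param amplitude_a,amplitude_b Shift amplitude (ppm) carried by each
#'   site's deprotonation; scalar or length-2 range per resonance.
#' @return A list with `series`, `truth` (the model), and `amplitudes`
#'   (per-resonance `amp_a`, `amp_b`, `baseline`).
#' @export
sim_coupled_titration <- function(model, n_resonances = 1L,
                                  ph_grid = seq(4, 13, by = 0.25),
                                  amplitude_a = 0, amplitude_b = 2.7,
                                  baseline_range = c(25, 60),
                                  noise_sd = 0.05, seed = NULL) {
  stopifnot(inherits(model, "coupled_site_model"),
            length(ph_grid) >= 1L, !is.unsorted(ph_grid), noise_sd >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  base <- draw_range(baseline_range, n_resonances)
  amp_a <- draw_range(amplitude_a, n_resonances)
  amp_b <- draw_range(amplitude_b, n_resonances)
  fa <- site_deprotonation_fraction(ph_grid, model, "A")
  fb <- site_deprotonation_fraction(ph_grid, model, "B")
  series <- vector("list", n_resonances)
  for (r in seq_len(n_resonances)) {
    mu <- base[r] + amp_a[r] * fa + amp_b[r] * fb
    series[[r]] <- titration_series(
      ph_grid, mu + stats::rnorm(length(ph_grid), 0, noise_sd),
      residue_label = sprintf("sim%02d", r)
    )
  }
  list(
    series = series,
    truth = model,
    amplitudes = data.frame(baseline = base, amp_a = amp_a, amp_b = amp_b)
  )
}

#' Simulate replicate densitometry readings
#'
#' Positive replicate readings per construct and dataset with a specified
#' true mean and coefficient of variation. The default lognormal noise
#' guarantees positivity with the requested mean and CV; a truncated-normal
#' alternative (resampled until positive) is available. The default CV of
#' 0.07 matches the few-percent spreads typical of replicate gel
#' densitometry.
#'
#' @param means Named numeric vector of true means, one per construct.
#' @param cv Coefficient of variation (SD / mean) of a reading.
#' @param n_replicates Replicates per construct per dataset.
#' @param n_datasets Number of datasets (independent experiment days).
#' @param dist `"lognormal"` or `"truncnorm"`.
#' @param seed Integer seed; `NULL` leaves the session RNG untouched.
#' @return A data frame with columns `construct`, `dataset`, `replicate`,
#'   `reading`, suitable for [activity_report()].
#' @export
sim_densitometry <- function(means, cv = 0.07, n_replicates = 3L,
                             n_datasets = 3L,
                             dist = c("lognormal", "truncnorm"),
                             seed = NULL) {
  dist <- match.arg(dist)
  stopifnot(is.numeric(means), length(means) >= 1L, all(means > 0),
            !is.null(names(means)), cv >= 0, n_replicates >= 2L,
            n_datasets >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  rows <- list()
  for (ds in seq_len(n_datasets)) {
    for (con in names(means)) {
      m <- means[[con]]
      x <- if (cv == 0) {
        rep(m, n_replicates)
      } else if (dist == "lognormal") {
        sdlog <- sqrt(log1p(cv^2))
        stats::rlnorm(n_replicates, meanlog = log(m) - sdlog^2 / 2,
                      sdlog = sdlog)
      } else {
        out <- numeric(n_replicates)
        for (k in seq_len(n_replicates)) {
          repeat {
            v <- stats::rnorm(1L, m, cv * m)
            if (v > 0) break
          }
          out[k] <- v
        }
        out
      }
      rows[[length(rows) + 1L]] <- data.frame(
        construct = con, dataset = ds, replicate = seq_len(n_replicates),
        reading = x
      )
    }
  }
  do.call(rbind, rows)
}

sample_freq <- function(freq, n) {
  stopifnot(is.numeric(freq), !is.null(names(freq)), all(freq >= 0))
  if (abs(sum(freq) - 1) > 1e-6) {
    stop("slot frequencies must sum to 1", call. = FALSE)
  }
  sample(names(freq), n, replace = TRUE, prob = freq)
}

#' Simulate thioredoxin-fold sequences with a planted extended active site
#'
#' Background-random amino-acid sequences with a -CXXC- motif and
#' extended-site residues planted at the designated offsets according to
#' per-slot residue frequency tables. The window scanned for the distal
#' partner is kept free of partner-class residues upstream of the planted
#' one, so extraction recovers the planted layout exactly; the background
#' alphabet excludes cysteine so the planted motif is the only one. The
#' planted residues are echoed per sequence for round-trip testing.
#'
#' @param n Number of sequences.
#' @param length Sequence length (residues).
#' @param motif_start 0-based index of the N-terminal cysteine; must leave
#'   the -6 slot and all planted offsets in bounds.
#' @param layout Named list of per-slot frequency tables (named numeric
#'   vectors summing to 1): `beta1_minus6`, `xx` (two-letter strings),
#'   `alpha1`, `partner`. Defaults emulate a cDsbD-like family: an invariant
#'   aspartate at -6, an invariant glutamate at the downstream acidic slot,
#'   and a partner that is usually glutamine but sometimes arginine or
#'   lysine (frequencies 380/494, 72/494, 42/494).
#' @param acidic_offset,partner_offset Offsets of the planted alpha-1 acid
#'   and distal partner relative to the N-terminal cysteine.
#' @param partner_window Window that downstream extraction will scan; kept
#'   clear of partner-class residues before `partner_offset`.
#' @param partner_residues Residue classes counted as potential partners.
#' @param seed Integer seed; `NULL` leaves the session RNG untouched.
#' @return A list with `sequences` (named character vector) and `truth`
#'   (data frame of planted residues per sequence).
#' @export
sim_motif_sequences <- function(n, length = 60L, motif_start = 10L,
                                layout = list(
                                  beta1_minus6 = c(D = 1),
                                  xx = c(VA = 1),
                                  alpha1 = c(E = 1),
                                  partner = c(Q = 380, R = 72, K = 42) / 494
                                ),
                                acidic_offset = 7L, partner_offset = 27L,
                                partner_window = c(20L, 35L),
                                partner_residues = c("Q", "N", "K", "R", "H"),
                                seed = NULL) {
  stopifnot(n >= 1L, motif_start >= 6L,
            motif_start + max(partner_offset, acidic_offset, 3L) < length,
            partner_window[1L] <= partner_offset,
            partner_offset <= partner_window[2L])
  if (!is.null(seed)) set.seed(as.integer(seed))
  background <- setdiff(AA_STANDARD, "C")
  quiet <- setdiff(background, partner_residues) # for the scanned window

  beta1 <- sample_freq(layout$beta1_minus6, n)
  xx <- sample_freq(layout$xx, n)
  alpha1 <- sample_freq(layout$alpha1, n)
  partner <- sample_freq(layout$partner, n)

  seqs <- character(n)
  for (k in seq_len(n)) {
    letters <- sample(background, length, replace = TRUE)
    # silence the partner window upstream of the planted partner
    pre <- seq.int(motif_start + partner_window[1L],
                   motif_start + partner_offset - 1L)
    letters[pre + 1L] <- sample(quiet, length(pre), replace = TRUE)
    i <- motif_start + 1L # 1-based N-terminal cysteine
    letters[i] <- "C"
    letters[i + 1L:2L] <- strsplit(xx[k], "", fixed = TRUE)[[1L]]
    letters[i + 3L] <- "C"
    letters[motif_start - 6L + 1L] <- beta1[k]
    letters[motif_start + acidic_offset + 1L] <- alpha1[k]
    letters[motif_start + partner_offset + 1L] <- partner[k]
    seqs[k] <- paste(letters, collapse = "")
  }
  names(seqs) <- sprintf("sim_seq_%04d", seq_len(n))
  list(
    sequences = seqs,
    truth = data.frame(
      sequence_id = names(seqs),
      motif_start = motif_start,
      beta1_minus6 = beta1,
      xx_residues = xx,
      alpha1_residue = alpha1,
      partner_residue = partner,
      partner_offset = partner_offset,
      stringsAsFactors = FALSE
    )
  )
}
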