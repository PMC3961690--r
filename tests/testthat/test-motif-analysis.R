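test_that("find_cxxc reports all motif starts, including overlaps", {
  expect_identical(find_cxxc("MDCAACK"), 2L)
  expect_identical(find_cxxc("CAACPPC"), c(0L, 3L))
  expect_identical(find_cxxc("MDAAK"), integer(0))
  expect_error(find_cxxc("MDZAK"), "invalid residue")
})

test_that("find_cxxc agrees with a brute-force scan on random sequences", {
  set.seed(21)
  for (k in 1:1000) {
    n <- sample(4:80, 1)
    # cysteine-enriched alphabet so motifs actually occur
    seq <- paste(sample(c(aa_alphabet, rep("C", 6)), n, replace = TRUE),
                 collapse = "")
    expect_identical(find_cxxc(seq), brute_force_cxxc(seq))
  }
})

test_that("extended-site extraction fills every slot on a constructed layout", {
  # D at -6, motif CVAC at 10, E at +7, Q at +27 in a 60-mer
  letters <- rep("A", 60)
  letters[10 - 6 + 1] <- "D"
  letters[11] <- "C"; letters[12] <- "V"; letters[13] <- "A"; letters[14] <- "C"
  letters[10 + 7 + 1] <- "E"
  letters[10 + 27 + 1] <- "Q"
  seq <- paste(letters, collapse = "")
  rec <- extract_extended_site(seq, 10L, sequence_id = "toy")
  expect_identical(rec$cys_n_pos, 10L)
  expect_identical(rec$xx_residues, "VA")
  expect_identical(rec$beta1_minus6, "D")
  expect_identical(rec$alpha1_residue, "E")
  expect_identical(rec$partner_residue, "Q")
  expect_identical(rec$partner_offset, 27L)
})

test_that("out-of-bounds slots are marked missing, never truncated", {
  seq <- paste(c("AAA", "CVAC", strrep("A", 40)), collapse = "")
  rec <- extract_extended_site(seq, 3L)
  expect_true(is.na(rec$beta1_minus6))
  expect_identical(rec$xx_residues, "VA")
  expect_false(is.na(rec$alpha1_residue))
  # partner window exceeding the sequence end yields a missing partner
  short <- paste(c(strrep("A", 10), "CVAC", strrep("A", 8)), collapse = "")
  rec2 <- extract_extended_site(short, 10L)
  expect_true(is.na(rec2$partner_residue))
  expect_error(extract_extended_site(seq, 0L), "motif_index")
})

test_that("extraction recovers generator-planted layouts exactly", {
  sim <- sim_motif_sequences(40, seed = 99)
  for (k in seq_along(sim$sequences)) {
    rec <- extract_extended_site(sim$sequences[[k]],
                                 sim$truth$motif_start[k],
                                 sequence_id = sim$truth$sequence_id[k])
    expect_identical(rec$beta1_minus6, sim$truth$beta1_minus6[k])
    expect_identical(rec$xx_residues, sim$truth$xx_residues[k])
    expect_identical(rec$alpha1_residue, sim$truth$alpha1_residue[k])
    expect_identical(rec$partner_residue, sim$truth$partner_residue[k])
    expect_identical(rec$partner_offset,
                     as.integer(sim$truth$partner_offset[k]))
  }
  # the configurable CcmG-like +6 acidic spacing is honoured
  sim6 <- sim_motif_sequences(5, acidic_offset = 6L, seed = 100)
  rec6 <- extract_extended_site(sim6$sequences[[1]], 10L, acidic_offset = 6L)
  expect_identical(rec6$alpha1_residue, sim6$truth$alpha1_residue[1])
  expect_identical(rec6$alpha1_offset, 6L)
})

test_that("conservation tables count present slots and track missing ones", {
  sim <- sim_motif_sequences(60, seed = 7)
  recs <- lapply(seq_along(sim$sequences), function(k) {
    extract_extended_site(sim$sequences[[k]], 10L)
  })
  tab <- tabulate_conservation(recs, "partner")
  expect_identical(sum(tab$count), attr(tab, "total"))
  expect_equal(sum(tab$percent), 100, tolerance = 0.1)
  expect_identical(attr(tab, "n_missing"), 0L)

  # the published-count pattern: 380 Q / 72 R / 42 K of 494 gives 76.9% Q
  counts <- c(rep("Q", 380), rep("R", 72), rep("K", 42))
  recs494 <- lapply(counts, function(r) {
    s <- paste(c(strrep("A", 4), "D", strrep("A", 5), "CVAC",
                 strrep("A", 13), "A", strrep("A", 6), r,
                 strrep("A", 20)), collapse = "")
    extract_extended_site(s, 10L)
  })
  tab494 <- tabulate_conservation(recs494, "partner")
  expect_identical(tab494$count[tab494$residue == "Q"], 380L)
  expect_equal(tab494$percent[tab494$residue == "Q"], 100 * 380 / 494,
               tolerance = 1e-9)
  expect_equal(round(tab494$percent[tab494$residue == "Q"], 1), 76.9)

  one <- tabulate_conservation(recs494[[1]], "beta1_minus6")
  expect_identical(one$residue, "D")
  expect_equal(one$percent, 100)
  expect_error(tabulate_conservation(list(), "partner"))
})

test_that("records with missing slots are excluded from the denominator", {
  near_edge <- extract_extended_site(
    paste(c("AAA", "CVAC", strrep("A", 40)), collapse = ""), 3L
  )
  full <- extract_extended_site(
    paste(c(strrep("A", 4), "D", strrep("A", 5), "CVAC", strrep("A", 30)),
          collapse = ""), 10L
  )
  tab <- tabulate_conservation(list(near_edge, full), "beta1_minus6")
  expect_identical(attr(tab, "total"), 1L)
  expect_identical(attr(tab, "n_missing"), 1L)
})

test_that("classification rules fire on their exemplars with a trace", {
  make_rec <- function(beta1, partner, xx = "VA") {
    letters <- rep("A", 60)
    letters[5] <- beta1
    letters[11] <- "C"
    letters[12:13] <- strsplit(xx, "")[[1]]
    letters[14] <- "C"
    letters[18] <- "E"
    if (!is.na(partner)) letters[38] <- partner
    extract_extended_site(paste(letters, collapse = ""), 10L)
  }
  # stabilized acid: hydrogen-bonding partner keeps the buried acid low
  r1 <- classify_active_site(make_rec("D", "Q"))
  expect_identical(r1$rule, "R1")
  expect_identical(r1$class, "stabilized_acid")
  # salt-bridged partner couples the two ionizations
  r2 <- classify_active_site(make_rec("D", "K"))
  expect_identical(r2$rule, "R2")
  expect_identical(r2$class, "coupled_microscopic")
  # unpartnered buried acid
  r3 <- classify_active_site(make_rec("E", NA))
  expect_identical(r3$rule, "R3")
  expect_identical(r3$class, "unstabilized_acid")
  # no beta1 acid, with the thiolate-stabilizing XX modifier
  r4 <- classify_active_site(make_rec("S", NA, xx = "PY"))
  expect_identical(r4$rule, "R4")
  expect_identical(r4$class, "no_beta1_acid")
  expect_true(r4$xx_modifier)
  expect_match(r4$description, "thiolate-stabilizing")
  # histidine partner matches no stabilization rule
  rh <- classify_active_site(make_rec("D", "H"))
  expect_identical(rh$class, "unclassified")
  expect_true(length(r1$trace) >= 2)
})

test_that("classification ignores sequence content outside the examined slots", {
  set.seed(22)
  base <- sim_motif_sequences(1, seed = 55)$sequences[[1]]
  ref <- classify_active_site(extract_extended_site(base, 10L))
  letters <- strsplit(base, "")[[1]]
  untouched <- setdiff(seq_along(letters),
                       c(5, 11:14, 18, 31:46)) # slots + scanned window
  for (k in 1:20) {
    mutated <- letters
    pos <- sample(untouched, 5)
    mutated[pos] <- sample(setdiff(aa_alphabet, "C"), 5, replace = TRUE)
    got <- classify_active_site(
      extract_extended_site(paste(mutated, collapse = ""), 10L)
    )
    expect_identical(got$class, ref$class)
    expect_identical(got$xx_modifier, ref$xx_modifier)
  }
})
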