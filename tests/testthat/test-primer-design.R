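test_that("candidate enumeration equals the exhaustive substring oracle", {
  set.seed(41)
  known <- random_acgt(50)
  got <- enumerate_candidates(known, "SSP3_FISA")
  # oracle: every 17-18-mer substring whose structure is not severe
  want <- NULL
  for (len in 17:18) for (st in 1:(50 - len + 1)) {
    s <- substr(known, st, st + len - 1)
    o <- ora_structure(s)
    if (o$stem >= 4 || o$dimer >= 5) next
    want <- rbind(want, data.frame(seq = s, start = st, length = len))
  }
  want <- want[order(want$start, want$length), ]
  expect_identical(got$seq, want$seq)
  expect_identical(got$start, want$start)
  # Tm annotations agree with the exported calculator
  expect_equal(got$tm, melting_temperature(got$seq))
  expect_identical(got$tm_in_window, got$tm >= 45 & got$tm <= 55)
  # deterministic
  expect_identical(got, enumerate_candidates(known, "SSP3_FISA"))
})

test_that("enumeration on a too-short region is empty, not an error", {
  expect_identical(nrow(enumerate_candidates(strrep("ACGTT", 2), "SSP2")), 0L)
})

test_that("fusion primers are FISA attached to the SSP1 5' end", {
  fp <- assemble_fusion("CGTAAACCTGCGTAAAAA", "GTCCATACCCTCATCTCCATT")
  expect_identical(fp$seq, "CGTAAACCTGCGTAAAAAGTCCATACCCTCATCTCCATT")
  expect_identical(fp$length, 39L)
  fp2 <- assemble_fusion("TGTTTTCTTCTTGCTCT", "ATGGTTATTCTCTGGGG")
  expect_identical(fp2$seq, "TGTTTTCTTCTTGCTCTATGGTTATTCTCTGGGG")
  expect_identical(fp2$length, 34L)
  expect_error(assemble_fusion("", "ATGGTTATTCTCTGGGG"), "empty")
  f <- primer_candidate("TGTTTTCTTCTTGCTCT", "SSP1")
  s <- primer_candidate("ATGGTTATTCTCTGGGG", "SSP1")
  expect_error(assemble_fusion(f, s), "roles")
})

test_that("designed walk sets satisfy every invariant and are reproducible", {
  for (seed in 1:3) {
    known <- synth_known_region(500, seed = seed)
    ws <- design_walk_set(known, seed = seed)
    expect_true(isTRUE(validate_walk_set(ws)))
    expect_identical(ws$fp_alpha$length,
                     ws$fisa$length + ws$ssp1_alpha$length)
    ws2 <- design_walk_set(known, seed = seed)
    expect_identical(serialize(ws, NULL), serialize(ws2, NULL))
  }
})

test_that("a region too short to order the four fragments is rejected", {
  expect_error(design_walk_set(random_acgt(80, seed = 5)),
               "too short to order")
})

test_that("the designer recovers the unique feasible combination", {
  # with SSP1 pinned to 17 nt, an 87-nt region leaves exactly one legal
  # layout: SSP1a 1-17, SSP1b 4-20, SSP2 21-45, FISA 46-62, SSP4 63-87
  cons <- design_constraints(len_ssp1 = c(17L, 17L))
  set.seed(53)
  repeat {
    known <- random_acgt(87)
    ok <- TRUE
    for (span in list(c(1, 17), c(4, 20), c(21, 45), c(46, 62), c(63, 87))) {
      o <- ora_structure(substr(known, span[1], span[2]))
      if (o$stem >= 4 || o$dimer >= 5) { ok <- FALSE; break }
    }
    if (ok && ora_cross_dimer(substr(known, 21, 45),
                              substr(known, 63, 87)) >= 5) ok <- FALSE
    if (ok) break
  }
  # exhaustive oracle over all ordered, separated candidate combinations
  c1 <- enumerate_candidates(known, "SSP1", cons)
  c24 <- enumerate_candidates(known, "SSP2", cons)
  cf <- enumerate_candidates(known, "SSP3_FISA", cons)
  pair_ok <- outer(seq_len(nrow(c1)), seq_len(nrow(c1)), "<") &
    abs(outer(c1$end, c1$end, "-")) >= 3
  pair_idx <- which(pair_ok, arr.ind = TRUE)
  pair_maxend <- pmax(c1$end[pair_idx[, 1]], c1$end[pair_idx[, 2]])
  combos <- 0L; layout <- NULL
  for (iff in seq_len(nrow(cf))) {
    i2s <- which(c24$end < cf$start[iff])
    i4s <- which(c24$start > cf$end[iff])
    if (!length(i2s) || !length(i4s)) next
    for (i2 in i2s) {
      prs <- which(pair_maxend < c24$start[i2])
      k <- length(prs) * length(i4s)
      if (k > 0L) {
        combos <- combos + k
        layout <- list(
          s1 = sort(c(c1$start[pair_idx[prs[1], 1]],
                      c1$start[pair_idx[prs[1], 2]])),
          s2 = c24$start[i2], f = cf$start[iff], s4 = c24$start[i4s[1]])
      }
    }
  }
  expect_identical(combos, 1L)
  ws <- design_walk_set(known, constraints = cons)
  expect_identical(sort(c(ws$ssp1_alpha$start, ws$ssp1_beta$start)),
                   as.integer(layout$s1))
  expect_identical(ws$ssp2$start, layout$s2)
  expect_identical(ws$fisa$start, layout$f)
  expect_identical(ws$ssp4$start, layout$s4)
})

test_that("the QC report reproduces the validation panel's window statistics", {
  panel <- load_panel()
  qc <- check_primer_table(panel)
  rs <- attr(qc, "role_summary")
  expect_true(all(qc$length[qc$role == "SSP3_FISA"] %in% 17:18))
  expect_true(all(qc$length[qc$role == "SSP1"] %in% 17:21))
  expect_true(all(qc$length[qc$role %in% c("SSP2", "SSP4")] %in% 25:30))
  # printed coordinates are surfaced, not repaired: the gadR SSP1a span
  # (38-57) disagrees with its 21-nt sequence
  expect_true(qc$span_mismatch[qc$name == "gadR-SSP1a"])
  expect_false(any(qc$span_mismatch[qc$name != "gadR-SSP1a"]))
  # the gadC FISA locus overlaps the printed SSP2 span
  expect_true(any(grepl("gadC", attr(qc, "notes"))))
  empty <- check_primer_table(panel[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("primer tables survive a TSV round trip", {
  known <- synth_known_region(500, seed = 2)
  ws <- design_walk_set(known, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_primer_tsv(ws, path)
  ws2 <- walk_set_from_table(read_primer_tsv(path), known)
  for (nm in c("ssp1_alpha", "ssp1_beta", "ssp2", "fisa", "ssp4"))
    expect_identical(ws2[[nm]]$seq, ws[[nm]]$seq)
  expect_identical(ws2$fp_alpha$seq, ws$fp_alpha$seq)
})
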