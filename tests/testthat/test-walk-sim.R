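# helpers to build bare strands for simulator unit tests
bare_strand <- function(seq, label = "KNOWN") {
  racketpcr:::new_strand(seq,
                         racketpcr:::seg_df(label, 1L, nchar(seq)),
                         origin = "test")
}

test_that("a stringent cycle spawns exactly the hand-constructed first strand", {
  ws <- toy_walk()
  # genome: known region at 1..400 plus a 150-nt unknown flank
  set.seed(101)
  flank <- random_acgt(150)
  genome <- genome_region(paste0(ws$known, flank), 1, 400)
  seeds <- racketpcr:::genome_seed_strands(genome)
  pool <- strand_pool(list(seeds$plus, seeds$minus))
  primer <- racketpcr:::fusion_sim_primer(ws$fp_alpha, "FP", 1L)
  st <- cycle_stage(55, 1, "PERFECT_3PART")
  out <- run_cycle(pool, list(primer), st, max_extension = 10000)
  expect_identical(length(out$species), 3L)
  got <- out$species[[3]]
  want <- paste0(ws$fisa$seq, substr(genome$seq, ws$ssp1_alpha$start,
                                     nchar(genome$seq)))
  expect_identical(got$seq, want)
  labs <- got$segments$label
  expect_identical(labs[1], "FISA_TAG")
  expect_true("UNKNOWN" %in% labs)
  # extension honours the run-off cap
  capped <- run_cycle(pool, list(primer), st, max_extension = 50)
  expect_identical(nchar(capped$species[[3]]$seq),
                   ws$fp_alpha$length + 50L)
})

test_that("a partial cycle with no qualifying window leaves the pool unchanged", {
  ws <- toy_walk()
  set.seed(103)
  genome <- genome_region(paste0(ws$known, random_acgt(150)), 1, 400)
  seeds <- racketpcr:::genome_seed_strands(genome)
  pool <- strand_pool(list(seeds$plus))
  primer <- racketpcr:::fusion_sim_primer(ws$fp_alpha, "FP", 1L)
  st <- cycle_stage(25, 1, "PARTIAL")
  strict <- annealing_model(min_total_matches = 35L)
  out <- run_cycle(pool, list(primer), st, model = strict)
  expect_identical(length(out$species), 1L)
})

test_that("chained cycles carry provenance through to the inverted repeat", {
  fx <- std_fixture(design_seed = 1, fixture_seed = 7, distances = 120)
  pool <- simulate_primary(fx$genome, fx$walk)
  # the target second strand is a partial-annealing product that copied
  # a first strand down to its 5' end: it must close with the fusion
  # primer's inverted repeat
  partials <- Filter(function(s) grepl(":partial", s$origin, fixed = TRUE),
                     pool$species)
  expect_true(length(partials) >= 1L)
  seconds <- Filter(function(s) {
    labs <- s$segments$label
    length(labs) >= 4L && identical(labs[1:2], c("FISA_TAG", "SSP1")) &&
      labs[length(labs)] == "RC_FISA" && "RC_UNKNOWN" %in% labs &&
      "RC_KNOWN" %in% labs
  }, partials)
  expect_gte(length(seconds), 1L)
  # the earliest such species is the canonical second strand: fusion
  # primer, then mirrored unknown/known copy, closing in the primer's
  # inverted repeat
  expect_identical(seconds[[1]]$segments$label,
                   c("FISA_TAG", "SSP1", "RC_UNKNOWN", "RC_KNOWN",
                     "RC_SSP1", "RC_FISA"))
})

test_that("loop-back detection builds the racket and annotates its anatomy", {
  ws <- toy_walk()
  fisa <- ws$fisa$seq
  # constructed strand: FISA . K . U . rc(SSP1) . rc(FISA)
  set.seed(107)
  K <- substr(ws$known, ws$ssp1_alpha$start, 400)
  U <- random_acgt(60)
  strand_seq <- paste0(fisa, K, U, reverse_complement(ws$ssp1_alpha$seq),
                       reverse_complement(fisa))
  segs <- rbind(
    racketpcr:::seg_df("FISA_TAG", 1L, 18L),
    racketpcr:::seg_df("KNOWN", 19L, 18L + nchar(K)),
    racketpcr:::seg_df("UNKNOWN", 19L + nchar(K), 18L + nchar(K) + 60L),
    racketpcr:::seg_df("RC_SSP1", 79L + nchar(K), 99L + nchar(K)),
    racketpcr:::seg_df("RC_FISA", 100L + nchar(K), 117L + nchar(K)))
  strand <- racketpcr:::new_strand(strand_seq, segs, "test")
  # two internal FISA copies exist (the 5' tag and the known-region
  # locus): the 3'-most is used and a warning raised
  expect_warning(rk <- detect_loopback(strand, fisa), "3'-most")
  expect_s3_class(rk, "fpr_racket")
  # internal FISA site is the one inside the copied known region
  p <- 18L + (ws$fisa$start - ws$ssp1_alpha$start) + 1L
  expect_identical(rk$site_start, p)
  want_tail <- reverse_complement(substr(strand_seq, 1, p - 1))
  expect_identical(rk$strand$seq, paste0(strand_seq, want_tail))
  expect_true(rk$strand$looped)
  # loop must contain the SSP4 site and the unknown segment
  ssp4_at <- 18L + (ws$ssp4$start - ws$ssp1_alpha$start) + 1L
  expect_true(rk$loop[1] <= ssp4_at && ssp4_at <= rk$loop[2])
  # strand lacking the terminal inverted repeat: no racket
  expect_null(detect_loopback(bare_strand(paste0(fisa, K)), fisa))
  # degenerate boundary: FISA directly followed by its inverted repeat
  deg <- bare_strand(paste0(fisa, reverse_complement(fisa)))
  rk0 <- detect_loopback(deg, fisa)
  expect_identical(rk0$strand$seq, deg$seq)  # empty extension
  # multiple internal sites: 3'-most wins, with a warning
  multi_seq <- paste0(fisa, "ACGTAC", fisa, U,
                      reverse_complement(fisa))
  multi <- bare_strand(multi_seq)
  expect_warning(rk2 <- detect_loopback(multi, fisa), "3'-most")
  expect_identical(rk2$site_start, 25L)
})

test_that("the primary simulation produces the second strand and a racket", {
  fx <- std_fixture(design_seed = 1, fixture_seed = 7, distances = 120)
  pool <- simulate_primary(fx$genome, fx$walk)
  expect_true(length(attr(pool, "rackets")) >= 1L)
  expect_true(any(vapply(pool$species, function(s)
    s$mclass == "EXPONENTIAL", logical(1))))
  # with partial annealing disabled there is no walk signal
  off <- annealing_model(min_total_matches = 10000L)
  pool2 <- simulate_primary(fx$genome, fx$walk, model = off)
  expect_true(any(grepl("no walk signal", attr(pool2, "warnings"))))
  expect_false(any(grepl(":partial",
                         vapply(pool2$species, `[[`, "", "origin"))))
})

test_that("two planted sites found two lineages and two amplicons", {
  fx <- std_fixture(design_seed = 2, fixture_seed = 11,
                    distances = c(80, 300), matches = c(17, 16),
                    runs = c(3, 2))
  pool <- simulate_primary(fx$genome, fx$walk)
  rep <- simulate_secondary(pool, fx$walk$ssp2, fx$walk$ssp4)
  keep <- rep[!rep$hairpin_suppressed & rep$exponential, ]
  expect_identical(nrow(keep), 2L)
  expect_setequal(keep$walk_distance, c(80L, 300L))
})

test_that("secondary amplicons require perfect convergent SSP2/SSP4 sites", {
  fx <- std_fixture(design_seed = 3, fixture_seed = 13, distances = 150)
  pool <- simulate_primary(fx$genome, fx$walk)
  # with an unrelated SSP4 no strand offers a perfect site: nothing
  # exponential can form
  set.seed(109)
  foreign <- primer_candidate(random_acgt(25), "SSP4")
  rep <- simulate_secondary(pool, fx$walk$ssp2, foreign)
  expect_false(any(rep$exponential))
})

test_that("single-primer products between inverted sites are hairpin-suppressed", {
  ws <- toy_walk()
  s2 <- ws$ssp2$seq; s4 <- ws$ssp4$seq
  set.seed(113)
  mid1 <- random_acgt(60); mid2 <- random_acgt(40); mid3 <- random_acgt(30)
  # template carrying SSP2 ... rc(SSP2): yields an SSP2-only product
  t_inv <- bare_strand(paste0(mid3, s2, mid1, reverse_complement(s2),
                              mid2))
  # template carrying SSP2 ... rc(SSP4): yields the real two-primer product
  t_good <- bare_strand(paste0(mid2, s2, mid1, reverse_complement(s4),
                               mid3))
  pool <- strand_pool(list(t_inv, t_good))
  rep <- simulate_secondary(pool, ws$ssp2, ws$ssp4)
  expect_true(nrow(rep) >= 2L)
  sup <- rep[rep$fwd_primer == rep$rev_primer, ]
  good <- rep[rep$fwd_primer != rep$rev_primer, ]
  expect_true(all(sup$hairpin_suppressed))
  expect_false(any(sup$exponential))
  expect_true(all(good$exponential))
  # suppressed products rank below the two-primer product
  expect_true(min(which(!rep$hairpin_suppressed)) <
                min(which(rep$hairpin_suppressed)))
})

test_that("amplicon/known overlap location reports abutment and novelty", {
  set.seed(127)
  known <- random_acgt(400)
  novel <- random_acgt(80)
  amp <- paste0(substr(known, 351, 400), novel)
  ov <- validate_amplicon(amp, known)
  expect_identical(ov$mode, "exact")
  expect_identical(ov$overlap_len, 50L)
  expect_true(ov$abuts_known_end)
  expect_identical(ov$novel_len, 80L)
  expect_identical(ov$novel_span, c(51L, 130L))
  # unrelated sequences: no overlap above the floor
  ov2 <- validate_amplicon(random_acgt(200), known)
  expect_identical(ov2$mode, "none")
  # an exact suffix is wholly explained by the known region
  ov3 <- validate_amplicon(substr(known, 301, 400), known)
  expect_identical(ov3$overlap_len, 100L)
  expect_identical(ov3$novel_len, 0L)
  expect_true(ov3$abuts_known_end)
})
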