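# A 34-nt fusion primer is used for boundary cases: at that length the
# 60% mismatch ceiling (20 mismatches) still admits a 14-match site, so
# the total-match floor is the operative rule.
fp34 <- function() paste0("TGTTTTCTTCTTGCTCT", "ATGGTTATTCTCTGGGG")

test_that("perfect-site search finds planted complements and nothing else", {
  set.seed(61)
  primer <- random_acgt(20)
  left <- random_acgt(500); right <- random_acgt(480)
  template <- paste0(left, reverse_complement(primer), right)
  # re-draw would be needed if the primer landed in the background by
  # chance; assert the planted situation holds
  sites <- find_perfect_sites(primer, template)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$start, 501L)
  expect_identical(sites$matches_total, 20L)
  expect_identical(sites$three_prime_run, 20L)
  expect_identical(nrow(find_perfect_sites(primer, random_acgt(300))), 0L)
  # FULL is definitionally the 3'-part search at full primer length
  expect_identical(find_perfect_sites(primer, template, part = "full"),
                   find_perfect_sites(primer, template,
                                      part = "three_prime", k = 20L))
  expect_error(find_perfect_sites(primer, template, part = "three_prime",
                                  k = 21L), "between 1 and")
})

test_that("partial sites honour the 3'-run, total-match and mismatch rules", {
  fp <- fp34()
  # plant a window with exactly 14 matches and a 2-bp matched 3' terminus
  pw <- racketpcr:::planted_window(fp, 14L, 2L, seed = 7L)
  o <- ora_window_stats(fp, pw$window)
  expect_identical(o$matches, 14L)
  expect_identical(o$run, 2L)
  set.seed(71)
  template <- paste0(random_acgt(90), pw$window, random_acgt(76))
  sites <- find_partial_sites(fp, template)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$start, 91L)
  expect_identical(sites$matches_total, 14L)
  expect_identical(sites$three_prime_run, 2L)
  # mutating the base that pairs the primer's final 3' nucleotide (the
  # window's 5'-most position) abolishes the site
  broken <- template
  substr(broken, 91, 91) <- substr(fp, 34, 34)  # same base cannot pair
  expect_identical(nrow(find_partial_sites(fp, broken)), 0L)
  # 13 total matches fails the floor
  pw13 <- racketpcr:::planted_window(fp, 13L, 2L, seed = 7L)
  t13 <- paste0(substr(template, 1, 90), pw13$window,
                substr(template, 125, 200))
  expect_identical(nrow(find_partial_sites(fp, t13)), 0L)
})

test_that("partial-site scanning equals the per-window oracle and is monotone", {
  set.seed(81)
  for (rep in 1:12) {
    L <- sample(34:39, 1)
    primer <- random_acgt(L)
    template <- random_acgt(sample(80:200, 1))
    # loose thresholds so that sites actually occur at random
    model <- annealing_model(min_three_prime_run = 1L,
                             min_total_matches = 11L,
                             max_mismatch_fraction = 1)
    got <- find_partial_sites(primer, template, model)
    want <- ora_partial_sites(primer, template, 1L, 11L, 1)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      got <- got[order(got$start), ]
      expect_identical(got$start, want$start)
      expect_identical(got$matches_total, as.integer(want$matches))
      expect_identical(got$three_prime_run, as.integer(want$run))
    }
    # lowering the total-match floor never removes sites
    looser <- find_partial_sites(primer, template,
                                 annealing_model(1L, 8L, 1))
    expect_true(all(got$start %in% looser$start))
    # a perfect site always qualifies as a partial site
    t2 <- paste0(template, reverse_complement(primer), template)
    pf <- find_perfect_sites(primer, t2)
    pa <- find_partial_sites(primer, t2, annealing_model(2L, 14L, 0.6))
    expect_true(all(pf$start %in% pa$start))
  }
})

test_that("alignment masks agree with site statistics", {
  set.seed(91)
  primer <- random_acgt(30)
  win <- reverse_complement(primer)
  mask <- align_primer_site(primer, win)
  expect_identical(as.vector(mask), strrep("|", 30))
  expect_identical(attr(mask, "three_prime_run"), 30L)
  # one internal substitution -> exactly one mismatch at that primer position
  wv <- strsplit(win, "", fixed = TRUE)[[1L]]
  wv[10] <- ora_comp1(ora_comp1(wv[10]))  # identity; force a real change:
  wv[10] <- setdiff(c("A", "C", "G", "T"), wv[10])[1]
  m2 <- align_primer_site(primer, paste(wv, collapse = ""))
  # window position 10 pairs primer position 30 - 10 + 1 = 21
  expect_identical(as.vector(m2),
                   paste0(strrep("|", 20), ".", strrep("|", 9)))
  expect_identical(attr(m2, "matches_total"), 29L)
  expect_error(align_primer_site(primer, "ACGT"), "equal length")
  # cross-operation consistency
  fp <- fp34()
  pw <- racketpcr:::planted_window(fp, 17L, 4L, seed = 3L)
  set.seed(95)
  template <- paste0(random_acgt(50), pw$window, random_acgt(50))
  site <- find_partial_sites(fp, template)
  m3 <- align_primer_site(fp, substr(template, site$start[1], site$end[1]))
  expect_identical(attr(m3, "matches_total"), site$matches_total[1])
  expect_identical(as.vector(m3), site$match_string[1])
})

test_that("sites export to BED with half-open coordinates", {
  fp <- fp34()
  pw <- racketpcr:::planted_window(fp, 18L, 3L, seed = 5L)
  set.seed(97)
  template <- paste0(random_acgt(40), pw$window, random_acgt(40))
  sites <- find_partial_sites(fp, template, template_id = "tpl",
                              primer_id = "fp")
  path <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(sites, path)
  bed <- utils::read.table(path, sep = "\t")
  expect_identical(bed$V2, sites$start - 1L)
  expect_identical(bed$V3, sites$end)
  expect_identical(bed$V5, sites$matches_total)
})

test_that("fig-style alignment rendering carries both strands and the rail", {
  fp <- fp34()
  win <- reverse_complement(fp)
  txt <- format_site_alignment(fp, win, name = "site1")
  expect_match(txt, "site1 \\(34 matches")
  expect_match(txt, "5'-")
  expect_match(txt, "-5'")
})
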