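test_that("planted sites are rediscovered with exactly the requested statistics", {
  fx <- std_fixture(design_seed = 1, fixture_seed = 7,
                    distances = c(60, 300), matches = c(16, 18),
                    runs = c(2, 4))
  fp <- fx$walk$fp_alpha$seq
  sites <- find_partial_sites(fp, fx$genome$seq)
  sites <- sites[order(sites$start), ]
  expect_identical(sites$start, fx$truth$site_start)
  expect_identical(sites$matches_total, fx$truth$total_matches)
  expect_identical(sites$three_prime_run, fx$truth$three_prime_run)
  # oracle recount on the planted windows
  for (i in seq_len(nrow(fx$truth))) {
    win <- substr(fx$genome$seq, fx$truth$site_start[i],
                  fx$truth$site_end[i])
    o <- ora_window_stats(fp, win)
    expect_identical(o$matches, fx$truth$total_matches[i])
    expect_identical(o$run, fx$truth$three_prime_run[i])
  }
  # minus-strand signal is confined to the walk's own machinery: the
  # known region (stage-1 priming) or the shadow of a planted window
  minus <- reverse_complement(fx$genome$seq)
  msites <- find_partial_sites(fp, minus)
  n <- nchar(fx$genome$seq)
  plus_span <- function(w) c(n - (w + nchar(fp) - 1L) + 1L, n - w + 1L)
  for (w in msites$start) {
    sp <- plus_span(w)
    in_known <- sp[1] >= fx$genome$known_start &&
      sp[2] <= fx$genome$known_end
    shadows <- any(sp[2] >= fx$truth$site_start &
                     sp[1] <= fx$truth$site_end)
    expect_true(in_known || shadows)
  }
})

test_that("a zero-distance site abuts the known-region 3' end", {
  fx <- std_fixture(design_seed = 2, fixture_seed = 5, distances = 0,
                    matches = 17, runs = 3)
  expect_identical(fx$truth$site_start, fx$genome$known_end + 1L)
})

test_that("infeasible planting requests are rejected", {
  expect_error(fixture_spec(planted_sites = data.frame(
    distance = 10L, total_matches = 14L, three_prime_run = 15L)),
    "generation error")
  known <- synth_known_region(500, seed = 1)
  ws <- design_walk_set(known, seed = 1)
  spec <- fixture_spec(genome_length = 1700L, known_start = 1001L,
                       planted_sites = data.frame(
                         distance = 400L, total_matches = 16L,
                         three_prime_run = 3L))
  expect_error(make_fixture(spec, ws), "too short")
  # a full-length match forces a full 3' run
  spec2 <- fixture_spec(planted_sites = data.frame(
    distance = 50L, total_matches = 37L, three_prime_run = 3L))
  expect_error(make_fixture(spec2, ws), "generation error")
})

test_that("fixture generation is byte-reproducible at a fixed seed", {
  a <- std_fixture(design_seed = 3, fixture_seed = 9, distances = 75)
  b <- std_fixture(design_seed = 3, fixture_seed = 9, distances = 75)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$truth, b$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(a, d1); write_fixture(b, d2)
  expect_identical(readLines(file.path(d1, "genome.fasta")),
                   readLines(file.path(d2, "genome.fasta")))
})

test_that("thermal programs carry the published stage structure", {
  p <- emit_protocol("primary")
  expect_identical(vapply(p$stages, `[[`, integer(1), "cycles"),
                   c(5L, 1L, 30L))
  expect_identical(vapply(p$stages, `[[`, numeric(1), "anneal_c"),
                   c(55, 25, 65))
  expect_identical(vapply(p$stages, `[[`, character(1), "annealing_mode"),
                   c("PERFECT_3PART", "PARTIAL", "PERFECT_FULL"))
  s <- emit_protocol("secondary")
  expect_identical(s$stages[[1]]$cycles, 25L)
  expect_identical(s$stages[[1]]$anneal_c, 60)
  txt <- format(p)
  expect_match(txt, "94 C 2 min")
  expect_match(txt, "x 30")
  expect_match(txt, "72 C 10 min")
})

test_that("protocol configuration round-trips through its config form", {
  for (which in c("primary", "secondary")) {
    p <- emit_protocol(which)
    cfg <- protocol_config(p)
    # via YAML text, as the config file interface would see it
    path <- withr::local_tempfile(fileext = ".yaml")
    yaml::write_yaml(cfg, path)
    p2 <- parse_protocol(yaml::read_yaml(path))
    expect_identical(format(p2), format(p))
    expect_equal(p2$stages, p$stages)
  }
})
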