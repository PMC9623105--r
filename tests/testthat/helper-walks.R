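# Shared fixtures built in code.

# the published validation primer panel (three walking experiments)
load_panel <- function() {
  path <- system.file("extdata", "validation_primers.tsv",
                      package = "racketpcr")
  read_primer_tsv(path)
}

# six fusion primers assembled from the panel's FISA/SSP1 parts
panel_fusions <- function() {
  panel <- load_panel()
  out <- list()
  for (gene in unique(panel$gene)) {
    d <- panel[panel$gene == gene, ]
    fisa <- d$sequence[d$role == "SSP3_FISA"]
    for (s1 in d$sequence[d$role == "SSP1"])
      out[[length(out) + 1L]] <- assemble_fusion(fisa, s1)
  }
  out
}

# a hand-placed 400-nt walk with loci SSP1 38-58, SSP2 194-218,
# FISA 233-250, SSP4 372-396 (plus an auxiliary SSP1-beta)
toy_walk <- function(seed = 99L) {
  known <- synth_known_region(400L, gc = 0.5, seed = seed)
  tbl <- data.frame(
    name = c("ssp1_alpha", "ssp1_beta", "ssp2", "fisa", "ssp4"),
    role = c("SSP1", "SSP1", "SSP2", "SSP3_FISA", "SSP4"),
    start = c(38L, 12L, 194L, 233L, 372L),
    end = c(58L, 28L, 218L, 250L, 396L),
    stringsAsFactors = FALSE)
  tbl$sequence <- substring(known, tbl$start, tbl$end)
  walk_set_from_table(tbl, known)
}

# designed walk + fixture genome with planted sites
std_fixture <- function(design_seed = 1L, fixture_seed = 7L,
                        distances = 120L, matches = 16L, runs = 3L,
                        genome_length = NULL, known_start = 1001L) {
  known <- synth_known_region(500L, seed = design_seed)
  ws <- design_walk_set(known, seed = design_seed)
  if (is.null(genome_length))
    genome_length <- known_start + 500L + max(distances) +
      ws$fp_alpha$length + 200L
  spec <- fixture_spec(genome_length = genome_length,
                       known_start = known_start,
                       planted_sites = data.frame(
                         distance = as.integer(distances),
                         total_matches = as.integer(rep_len(matches,
                                                            length(distances))),
                         three_prime_run = as.integer(rep_len(runs,
                                                              length(distances)))),
                       seed = fixture_seed)
  make_fixture(spec, ws)
}

random_acgt <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else { set.seed(seed); gen() }
}
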