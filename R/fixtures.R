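# Seeded synthetic-data generator: genomes with a known region and
# planted partial-annealing sites of known statistics, so that every walk
# prediction can be checked against ground truth without any download.

random_dna <- function(n, gc = 0.42) {
  if (n < 1L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

#' Generate a synthetic known region
#'
#' Random sequence at the given GC fraction, reproducible at a fixed
#' seed.  The defaults (500 nt, GC 0.42) give a region comfortably large
#' enough to host an ordered walking-primer set and resemble a
#' low-to-moderate-GC bacterial locus.
#'
#' @param length region length, nt.
#' @param gc GC fraction.
#' @param seed integer seed.
#' @return a character sequence.
#' @export
synth_known_region <- function(length = 500L, gc = 0.42, seed = 1L) {
  with_seed(seed, random_dna(as.integer(length), gc))
}

#' Specify a synthetic fixture genome
#'
#' @param genome_length total genome length, nt.
#' @param gc GC fraction of the random background.
#' @param known_start 1-based position at which the known region is
#'   embedded (the known sequence itself comes from the walk set handed to
#'   [make_fixture()]).
#' @param planted_sites data.frame with columns `distance` (nt downstream
#'   of the known-region 3' end at which the degenerate fusion-primer
#'   annealing window starts; 0 abuts the boundary), `total_matches` and
#'   `three_prime_run`.
#' @param seed integer seed for the random background and mask sampling.
#' @return an object of class `fpr_fixture_spec`.
#' @export
fixture_spec <- function(genome_length = 5000L, gc = 0.42,
                         known_start = 1001L,
                         planted_sites = data.frame(distance = 120L,
                                                    total_matches = 16L,
                                                    three_prime_run = 3L),
                         seed = 1L) {
  stopifnot(is.data.frame(planted_sites),
            all(c("distance", "total_matches", "three_prime_run") %in%
                  names(planted_sites)))
  if (any(planted_sites$distance < 0L))
    stop("generation error: planted distances must be >= 0", call. = FALSE)
  if (any(planted_sites$three_prime_run > planted_sites$total_matches))
    stop("generation error: three_prime_run cannot exceed total_matches",
         call. = FALSE)
  structure(list(genome_length = as.integer(genome_length), gc = gc,
                 known_start = as.integer(known_start),
                 planted_sites = planted_sites, seed = as.integer(seed)),
            class = "fpr_fixture_spec")
}

# the planted window: a degenerate reverse complement of the fusion
# primer with exactly the requested match count and 3'-terminal run.
# Window offset i pairs primer base L-i+1, so the primer's 3'-terminal
# run corresponds to window offsets 1..r; offset r+1 is forced to
# mismatch so the run is exact.  Mismatch positions take the complement
# of the pairing base, which is guaranteed not to pair.
planted_window <- function(fp_seq, total_matches, three_prime_run, seed) {
  L <- nchar(fp_seq)
  m <- as.integer(total_matches); r <- as.integer(three_prime_run)
  if (m > L)
    stop("generation error: total_matches (", m, ") exceeds primer length (",
         L, ")", call. = FALSE)
  if (r > m)
    stop("generation error: three_prime_run cannot exceed total_matches",
         call. = FALSE)
  if (m == L && r < L)
    stop("generation error: a fully matched window forces three_prime_run = ",
         "primer length", call. = FALSE)
  if (r < 1L) stop("generation error: three_prime_run must be >= 1",
                   call. = FALSE)
  rcp <- strsplit(reverse_complement(fp_seq), "", fixed = TRUE)[[1L]]
  matched <- rep(FALSE, L)
  matched[seq_len(r)] <- TRUE
  pool <- setdiff(seq_len(L), seq_len(r + 1L))
  extra <- m - r
  if (extra > length(pool))
    stop("generation error: requested mask is infeasible (", m,
         " matches with 3' run ", r, " on a ", L, "-mer)", call. = FALSE)
  if (extra > 0L)
    matched[with_seed(seed, sample(pool, extra))] <- TRUE
  win <- ifelse(matched, rcp, chartr("ACGT", "TGCA", rcp))
  list(window = paste(win, collapse = ""), matched = matched,
       mask = paste(ifelse(rev(matched), "|", "."), collapse = ""))
}

# change one base so that a spurious pairing is broken; returns a base
# different from `cur` that does not pair with `primer_base`
.breaking_base <- function(cur, primer_base) {
  want_not <- chartr("ACGT", "TGCA", primer_base)  # the pairing base
  for (b in c("A", "C", "G", "T"))
    if (b != cur && b != want_not) return(b)
  cur
}

#' Build a fixture genome with planted partial-annealing sites
#'
#' Embeds the walk set's known region in a random genome and writes, for
#' each planted site, a degenerate reverse complement of the fusion
#' primer into the downstream flank at the requested distance, with
#' exactly the requested match count and 3'-terminal run (non-matching
#' positions are set to guaranteed mismatches, never random bases).  The
#' flanks and (outside the designed primer loci) the known background are
#' then scrubbed of accidental perfect or partial annealing windows of
#' the walk's primers, so the planted sites are the only walk signal; the
#' walk set is returned with the (possibly scrubbed) known sequence.
#' Deterministic at a fixed seed.
#'
#' @param spec an [fixture_spec()].
#' @param walk an `fpr_walk_set`.
#' @param fp which fusion primer the sites are planted for.
#' @param model the [annealing_model()] the scrub must defeat.
#' @param scrub_rounds maximum scrub iterations.
#' @return an object of class `fpr_fixture`: list with `genome`
#'   ([genome_region()]), `truth` (data.frame: one row per planted site
#'   with its genome coordinates, mask and expected walk distance and
#'   amplicon length), `walk`, `spec`.
#' @export
make_fixture <- function(spec, walk, fp = c("alpha", "beta"),
                         model = annealing_model(), scrub_rounds = 20L) {
  stopifnot(inherits(spec, "fpr_fixture_spec"),
            inherits(walk, "fpr_walk_set"))
  fp <- match.arg(fp)
  fusion <- walk[[paste0("fp_", fp)]]
  L <- fusion$length
  known <- walk$known
  ks <- spec$known_start
  ke <- ks + nchar(known) - 1L
  ps <- spec$planted_sites
  need <- ke + max(ps$distance) + L
  if (need > spec$genome_length)
    stop("generation error: genome_length (", spec$genome_length,
         ") too short for the planted sites (needs >= ", need, ")",
         call. = FALSE)
  if (ke > spec$genome_length)
    stop("generation error: known region does not fit in the genome",
         call. = FALSE)
  # assemble genome
  g <- with_seed(spec$seed, random_dna(spec$genome_length, spec$gc))
  gv <- strsplit(g, "", fixed = TRUE)[[1L]]
  gv[ks:ke] <- strsplit(known, "", fixed = TRUE)[[1L]]
  win_start <- ke + ps$distance + 1L
  win_end <- win_start + L - 1L
  if (nrow(ps) > 1L) {
    o <- order(win_start)
    if (any(win_start[o][-1L] <= win_end[o][-nrow(ps)]))
      stop("generation error: planted windows overlap", call. = FALSE)
  }
  masks <- character(nrow(ps))
  for (i in seq_len(nrow(ps))) {
    pw <- planted_window(fusion$seq, ps$total_matches[i],
                         ps$three_prime_run[i], mix_seed(spec$seed, i))
    gv[win_start[i]:win_end[i]] <- strsplit(pw$window, "", fixed = TRUE)[[1L]]
    masks[i] <- pw$mask
  }
  # protected positions: designed primer loci (on the genome) and the
  # planted windows; everything else may be mutated by the scrub
  protected <- rep(FALSE, spec$genome_length)
  for (nm in c("ssp1_alpha", "ssp1_beta", "ssp2", "fisa", "ssp4")) {
    p <- walk[[nm]]
    protected[(ks + p$start - 1L):(ks + p$end - 1L)] <- TRUE
  }
  for (i in seq_len(nrow(ps))) protected[win_start[i]:win_end[i]] <- TRUE
  in_known <- rep(FALSE, spec$genome_length); in_known[ks:ke] <- TRUE
  fpv <- strsplit(fusion$seq, "", fixed = TRUE)[[1L]]
  rcpv <- strsplit(reverse_complement(fusion$seq), "", fixed = TRUE)[[1L]]
  planted_idx <- function(w) any(w == win_start)
  patterns <- unique(c(walk$ssp2$seq, walk$ssp4$seq, walk$fisa$seq,
                       fusion$seq,
                       reverse_complement(c(walk$ssp2$seq, walk$ssp4$seq,
                                            walk$fisa$seq, fusion$seq))))
  scrub_warn <- character(0)
  for (round in seq_len(scrub_rounds)) {
    g <- paste(gv, collapse = "")
    dirty <- FALSE
    # 1) accidental exact occurrences of walk primers outside their loci
    for (pat in patterns) {
      mm <- Biostrings::matchPattern(pat, Biostrings::DNAString(g),
                                     fixed = TRUE)
      for (st in BiocGenerics::start(mm)) {
        span <- st:(st + nchar(pat) - 1L)
        if (all(protected[span])) next
        tgt <- span[!protected[span]][ceiling(sum(!protected[span]) / 2)]
        gv[tgt] <- .breaking_base(gv[tgt], gv[tgt])  # any different base
        dirty <- TRUE
      }
    }
    if (dirty) next
    # 2) accidental partial-annealing windows of the fusion primer
    g <- paste(gv, collapse = "")
    hit_any <- FALSE
    for (sense in c("plus", "minus")) {
      tmpl <- if (sense == "plus") g else reverse_complement(g)
      sites <- find_partial_sites(fusion$seq, tmpl, model)
      for (si in seq_len(nrow(sites))) {
        w <- sites$start[si]
        span <- if (sense == "plus") w:(w + L - 1L)
                else (spec$genome_length - (w + L - 1L) + 1L):
                     (spec$genome_length - w + 1L)
        if (sense == "plus" && planted_idx(w)) next
        # the SSP1-complement window on the minus strand is the walk's own
        # stage-1 machinery, not an accident
        if (sense == "minus" && all(in_known[span])) next
        # a minus-strand window overlapping a planted site is the plant's
        # unavoidable shadow (the plant is a degenerate fusion-primer
        # complement, so its own reverse complement may weakly pair the
        # primer); it only spawns inert plus-sense copies in the simulator
        if (sense == "minus" &&
            any(vapply(seq_along(win_start), function(i)
              max(span) >= win_start[i] && min(span) <= win_end[i],
              logical(1L)))) next
        free <- span[!protected[span]]
        # attack low window offsets first: breaking the 3'-terminal
        # matched run disqualifies the site with a single mutation
        if (sense == "minus") free <- rev(free)
        if (!length(free)) {
          scrub_warn <- c(scrub_warn, sprintf(
            "unscrubbable accidental partial site at %d-%d (all positions protected)",
            min(span), max(span)))
          next
        }
        # break the pairing at one currently matched, unprotected position
        fixed_one <- FALSE
        for (pos in free) {
          off <- if (sense == "plus") pos - w + 1L
                 else (spec$genome_length - pos + 1L) - w + 1L
          pairing <- rcpv[off]          # base that would pair
          tb <- if (sense == "plus") gv[pos]
                else chartr("ACGT", "TGCA", gv[pos])
          if (tb == pairing) {          # matched position
            newt <- .breaking_base(tb, fpv[L - off + 1L])
            gv[pos] <- if (sense == "plus") newt
                       else chartr("ACGT", "TGCA", newt)
            fixed_one <- TRUE
            break
          }
        }
        if (fixed_one) hit_any <- TRUE
      }
    }
    if (!hit_any) break
  }
  genome_seq <- paste(gv, collapse = "")
  walk$known <- substr(genome_seq, ks, ke)
  genome <- genome_region(genome_seq, ks, ke, id = sprintf(
    "synthetic_fixture_seed%d", spec$seed))
  exp_len <- (nchar(walk$known) - walk$ssp4$start + 1L) + ps$distance +
    fusion$ssp1$length + fusion$fisa$length +
    (walk$fisa$start - walk$ssp2$start)
  truth <- data.frame(site_start = win_start, site_end = win_end,
                      distance = ps$distance,
                      total_matches = ps$total_matches,
                      three_prime_run = ps$three_prime_run,
                      expected_walk_distance = ps$distance,
                      expected_amplicon_length = exp_len,
                      mask = masks, stringsAsFactors = FALSE)
  structure(list(genome = genome, truth = truth, walk = walk, spec = spec,
                 fp = fp, warnings = scrub_warn),
            class = "fpr_fixture")
}

#' Write a fixture to disk
#'
#' Writes `genome.fasta`, `known.fasta`, `primers.tsv` and `truth.json`
#' into a directory.
#'
#' @param fx an `fpr_fixture`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  stopifnot(inherits(fx, "fpr_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(stats::setNames(fx$genome$seq, fx$genome$id),
              file.path(dir, "genome.fasta"))
  write_fasta(stats::setNames(fx$walk$known, "known_region"),
              file.path(dir, "known.fasta"))
  write_primer_tsv(fx$walk, file.path(dir, "primers.tsv"))
  jsonlite::write_json(list(known_start = fx$genome$known_start,
                            known_end = fx$genome$known_end,
                            fp = fx$fp,
                            sites = fx$truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
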