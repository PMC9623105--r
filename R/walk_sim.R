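# Strand-pool simulation of the two-round FPR-PCR: stage-wise strand
# synthesis, racket-like DNA formation by intramolecular loop-back,
# secondary amplicon prediction with hairpin suppression, and walk
# validation.
#
# Amplification is modeled symbolically: the pool tracks unique strand
# species and a multiplicity class, and stringent stages iterate to a
# fixed point of species discovery rather than counting 2^cycles copies.
# Product identity, not copy number, is the testable output.

# a primer prepared for simulation: sequence plus provenance template
sim_primer <- function(id, seq, segments, part_len = NULL) {
  list(id = id, seq = toupper(seq), segments = segments,
       part_len = if (is.null(part_len)) nchar(seq) else as.integer(part_len))
}

# fusion primer provenance: FISA tag + SSP1, located on the genome when a
# known-region offset is available
fusion_sim_primer <- function(fp, id, known_offset = NA_integer_) {
  fl <- fp$fisa$length; sl <- fp$ssp1$length
  ref <- function(p) if (is.na(known_offset) || is.na(p$start))
    c(NA_integer_, NA_integer_) else known_offset + c(p$start, p$end) - 1L
  rf <- ref(fp$fisa); rs <- ref(fp$ssp1)
  segs <- rbind(seg_df("FISA_TAG", 1L, fl, rf[1L], rf[2L],
                       if (is.na(rf[1L])) NA_character_ else "+"),
                seg_df("SSP1", fl + 1L, fl + sl, rs[1L], rs[2L],
                       if (is.na(rs[1L])) NA_character_ else "+"))
  sim_primer(id, fp$seq, segs, part_len = sl)
}

ssp_sim_primer <- function(p, id, known_offset = NA_integer_) {
  r <- if (is.na(known_offset) || is.na(p$start))
    c(NA_integer_, NA_integer_) else known_offset + c(p$start, p$end) - 1L
  sim_primer(id, p$seq,
             seg_df("KNOWN", 1L, p$length, r[1L], r[2L],
                    if (is.na(r[1L])) NA_character_ else "+"))
}

# synthesize the product of a primer annealed with its 3' end pairing the
# template base at w_start: primer + complement copy of the template from
# w_start-1 down to the template 5' end, truncated at max_extension
extend_product <- function(primer, template, w_start, max_extension,
                           origin, mclass = "LINEAR") {
  a <- max(1L, w_start - as.integer(max_extension))
  ext <- if (w_start > 1L)
    reverse_complement(substr(template$seq, a, w_start - 1L)) else ""
  seq <- paste0(primer$seq, ext)
  segs <- primer$segments
  if (nzchar(ext))
    segs <- rbind(segs, mirror_segments(template$segments, a, w_start - 1L,
                                        nchar(primer$seq)))
  new_strand(seq, segs, origin, mclass,
             founding_matches = template$founding_matches,
             looped = isTRUE(template$looped))
}

#' Run one annealing/extension cycle over a strand pool
#'
#' For every template strand, primer binding sites are located under the
#' stage's annealing mode (`PERFECT_3PART`: the primer's 3' part must find
#' its exact complement; `PERFECT_FULL`: the whole primer; `PARTIAL`: the
#' mismatch-tolerant model).  Each site spawns a product strand (the
#' primer followed by a complement copy of the template 5' of the site),
#' and new species are deduplicated into the pool.  During a `PARTIAL`
#' cycle only strands that carry unknown-flank provenance are scanned
#' (walking happens on the unknown region), unless `scan_all = TRUE`.
#'
#' @param pool an `fpr_pool`.
#' @param primers list of simulation primers (see [simulate_primary()]).
#' @param stage a [cycle_stage()].
#' @param model an [annealing_model()] used for `PARTIAL` stages.
#' @param max_extension polymerase run-off cap, nt.
#' @param scan_all scan all strands during a `PARTIAL` cycle.
#' @return the updated `fpr_pool`.
#' @export
run_cycle <- function(pool, primers, stage, model = annealing_model(),
                      max_extension = 10000L, scan_all = FALSE) {
  stopifnot(inherits(pool, "fpr_pool"))
  if (!length(pool$species)) stop("pool is empty", call. = FALSE)
  if (!length(primers)) stop("no primers supplied", call. = FALSE)
  mode <- stage$annealing_mode
  templates <- pool$species
  for (t_i in seq_along(templates)) {
    tmpl <- templates[[t_i]]
    if (mode == "PARTIAL" && !scan_all && !strand_has_unknown(tmpl)) next
    for (pr in primers) {
      sites <- switch(mode,
        PERFECT_3PART = find_perfect_sites(pr$seq, tmpl$seq,
                                           part = "three_prime",
                                           k = pr$part_len),
        PERFECT_FULL = find_perfect_sites(pr$seq, tmpl$seq, part = "full"),
        PARTIAL = if (nchar(tmpl$seq) >= nchar(pr$seq))
          find_partial_sites(pr$seq, tmpl$seq, model) else .empty_sites(),
        stop("unknown annealing mode '", mode, "'", call. = FALSE))
      if (!nrow(sites)) next
      for (s_i in seq_len(nrow(sites))) {
        w <- sites$start[s_i]
        prod <- extend_product(pr, tmpl, w, max_extension,
                               origin = sprintf("%s@%s:%d", pr$id,
                                                tmpl$origin, w))
        if (nchar(prod$seq) > pool$max_strand_length) {
          msg <- sprintf("product of %s exceeds max_strand_length; skipped",
                         pr$id)
          pool$warnings <- c(pool$warnings, msg)
          next
        }
        if (mode == "PARTIAL") {
          prod$founding_matches <-
            max(sites$matches_total[s_i], prod$founding_matches, na.rm = TRUE)
          prod$origin <- paste0(prod$origin, ":partial")
        }
        if (mode != "PARTIAL" && tmpl$mclass != "SEED") {
          # a perfect-primed copy of a primer-made strand: the pair
          # re-primes each other every cycle -> exponential lineage
          prod$mclass <- "EXPONENTIAL"
          tmpl$mclass <- "EXPONENTIAL"
          pool <- pool_add(pool, tmpl)  # upgrade in place via dedup
        }
        pool <- pool_add(pool, prod)
      }
    }
  }
  pool
}

#' Detect intra-strand loop-back and form racket-like DNA
#'
#' If the 3'-terminal bases of a strand equal the reverse complement of
#' the FISA fragment and the strand carries an internal FISA site 5' of
#' them, the 3' end anneals intramolecularly and is extended along the
#' rest of the strand ("loop-back"), forming a racket-like DNA whose
#' double-stranded stem is the copied known region and whose
#' single-stranded loop carries the SSP4 site and the unknown flank.
#' When several internal FISA sites exist the 3'-most is used and a
#' warning is recorded.
#'
#' @param strand an `fpr_strand`.
#' @param fisa the FISA sequence.
#' @param max_extension loop-back extension cap, nt.
#' @return an object of class `fpr_racket` (fields `strand`, `stem5`,
#'   `stem3`, `loop`, `site_start`, `warnings`), or `NULL` when the strand
#'   cannot loop back.
#' @export
detect_loopback <- function(strand, fisa, max_extension = 10000L) {
  stopifnot(inherits(strand, "fpr_strand"))
  fisa <- toupper(fisa)
  f <- nchar(fisa)
  n <- nchar(strand$seq)
  if (n < 2L * f) return(NULL)
  if (!identical(substr(strand$seq, n - f + 1L, n), reverse_complement(fisa)))
    return(NULL)
  m <- Biostrings::matchPattern(fisa, Biostrings::DNAString(strand$seq),
                                fixed = TRUE)
  starts <- BiocGenerics::start(m)
  starts <- starts[starts + f - 1L <= n - f]   # strictly 5' of the terminus
  if (!length(starts)) return(NULL)
  warnings <- character(0)
  if (length(starts) > 1L) {
    warnings <- sprintf(
      "strand has %d internal FISA sites; loop-back uses the 3'-most",
      length(starts))
    warning(warnings, call. = FALSE)
  }
  p <- max(starts)
  a <- max(1L, p - as.integer(max_extension))
  tail_seq <- if (p > 1L)
    reverse_complement(substr(strand$seq, a, p - 1L)) else ""
  segs <- strand$segments
  if (nzchar(tail_seq))
    segs <- rbind(segs, mirror_segments(strand$segments, a, p - 1L, n))
  ext <- new_strand(paste0(strand$seq, tail_seq), segs,
                    origin = paste0(strand$origin, ":racket"),
                    mclass = strand$mclass,
                    founding_matches = strand$founding_matches,
                    looped = TRUE)
  structure(list(strand = ext,
                 stem5 = c(1L, p + f - 1L),
                 stem3 = c(n - f + 1L, n + (p - a)),
                 loop = c(p + f, n - f),
                 site_start = p,
                 warnings = warnings),
            class = "fpr_racket")
}

#' Simulate the primary FPR-PCR
#'
#' Seeds the pool with the genome duplex and runs the three-stage primary
#' program with a single fusion primer: stage 1 (moderate stringency)
#' primes only where the SSP1 part finds its exact complement, producing
#' target first strands; stage 2 (one low-stringency cycle) lets the
#' fusion primer partially anneal inside unknown-flank sequence under the
#' mismatch-tolerant model, producing second strands that end in the
#' primer's inverted repeat; stage 3 (high stringency) primes with the
#' full fusion primer, applies intra-strand loop-back after each cycle
#' (forming racket-like DNA) and iterates to a fixed point of species
#' discovery.
#'
#' @param genome an [genome_region()] object.
#' @param walk an `fpr_walk_set` (or an `fpr_fusion_primer`).
#' @param fp which fusion primer drives the reaction.
#' @param program list of three [cycle_stage()]s (default
#'   [primary_program()]).
#' @param model [annealing_model()] for the low-stringency cycle.
#' @param max_extension polymerase run-off cap, nt.
#' @param max_species,max_strand_length pool caps.
#' @param scan_all_partial scan all strands (not only unknown-carrying
#'   ones) in the low-stringency cycle.
#' @return the final `fpr_pool`, with attributes `stage_summary` (species
#'   counts), `rackets` (list of `fpr_racket`), `walk`, `genome`, `fp_id`
#'   and `warnings` (including `"no walk signal"` when no partial site
#'   fired).
#' @export
simulate_primary <- function(genome, walk, fp = c("alpha", "beta"),
                             program = primary_program(),
                             model = annealing_model(),
                             max_extension = 10000L, max_species = 200L,
                             max_strand_length = 50000L,
                             scan_all_partial = FALSE) {
  stopifnot(inherits(genome, "fpr_genome"))
  fp <- match.arg(fp)
  fusion <- if (inherits(walk, "fpr_fusion_primer")) walk
            else walk[[paste0("fp_", fp)]]
  if (!inherits(fusion, "fpr_fusion_primer"))
    stop("walk must be an fpr_walk_set or fpr_fusion_primer", call. = FALSE)
  if (length(program) != 3L ||
      !identical(vapply(program, `[[`, character(1L), "annealing_mode"),
                 c("PERFECT_3PART", "PARTIAL", "PERFECT_FULL")))
    stop("primary program must have stages PERFECT_3PART, PARTIAL, ",
         "PERFECT_FULL", call. = FALSE)
  primer <- fusion_sim_primer(fusion, paste0("FP_", fp),
                              known_offset = genome$known_start)
  seeds <- genome_seed_strands(genome)
  pool <- strand_pool(list(seeds$plus, seeds$minus), max_species,
                      max_strand_length)
  rackets <- list()
  summary_rows <- list()
  n_after_stage1 <- NA_integer_
  for (st_i in seq_along(program)) {
    st <- program[[st_i]]
    for (cyc in seq_len(st$cycles)) {
      before <- length(pool$species)
      pool <- run_cycle(pool, list(primer), st, model, max_extension,
                        scan_all = scan_all_partial)
      if (st$annealing_mode == "PERFECT_FULL") {
        # loop-back competes with priming in every stringent cycle, but a
        # lineage folds back only once: after the extension its 3'
        # terminus mirrors the full stem and the flush panhandle leaves
        # nothing to extend
        for (s in pool$species) {
          if (isTRUE(s$looped)) next
          rk <- withCallingHandlers(
            detect_loopback(s, fusion$fisa$seq, max_extension),
            warning = function(w) invokeRestart("muffleWarning"))
          if (!is.null(rk)) {
            if (nchar(rk$strand$seq) <= pool$max_strand_length) {
              already <- rk$strand$seq %in% pool_seqs(pool)
              pool <- pool_add(pool, rk$strand)
              if (!already) rackets[[length(rackets) + 1L]] <- rk
            }
          }
        }
      }
      summary_rows[[length(summary_rows) + 1L]] <-
        data.frame(stage = st_i, cycle = cyc,
                   n_species = length(pool$species))
      if (length(pool$species) == before) break  # fixed point reached
    }
    if (st_i == 1L) n_after_stage1 <- length(pool$species)
  }
  warn <- pool$warnings
  second_strands <- vapply(pool$species, function(s)
    grepl(":partial", s$origin, fixed = TRUE), logical(1L))
  if (!any(second_strands)) {
    warn <- c(warn, "no walk signal: no partial annealing site fired; pool contains only first-strand species")
  }
  attr(pool, "stage_summary") <- do.call(rbind, summary_rows)
  attr(pool, "rackets") <- rackets
  attr(pool, "walk") <- if (inherits(walk, "fpr_walk_set")) walk else NULL
  attr(pool, "genome") <- genome
  attr(pool, "fp_id") <- paste0("FP_", fp)
  pool$warnings <- warn
  attr(pool, "warnings") <- warn
  pool
}

# longest terminal inverted repeat: largest k with prefix(k) == rc(suffix(k))
terminal_inverted_repeat <- function(seq) {
  n <- nchar(seq)
  kmax <- n %/% 2L
  if (kmax < 1L) return(0L)
  rcs <- reverse_complement(seq)
  # prefix of rc(seq) is rc of the suffix
  best <- 0L
  for (k in seq_len(kmax))
    if (substr(seq, 1L, k) == substr(rcs, 1L, k)) best <- k else break
  best
}

# all perfect site spans (sense and antisense) of a primer inside a seq
.primer_hit_spans <- function(primer, seq) {
  hits <- list()
  for (pat in c(primer, reverse_complement(primer))) {
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(seq),
                                  fixed = TRUE)
    st <- BiocGenerics::start(m)
    if (length(st))
      hits[[length(hits) + 1L]] <- cbind(st, st + nchar(pat) - 1L)
  }
  if (!length(hits)) matrix(integer(0), ncol = 2L) else do.call(rbind, hits)
}

#' Simulate the secondary (end-to-end) FPR-PCR
#'
#' Classical nested PCR on the primary product pool, driven by SSP2 and
#' SSP4.  Products are enumerated whose two ends are perfect convergent
#' sites of the supplied primers (either primer may serve either end) and
#' that contain no internal perfect site of either primer (internally
#' primed molecules are transient and are trimmed to the innermost product
#' during cycling).  Products whose two termini are mutually
#' reverse-complementary beyond `hairpin_threshold` are flagged
#' `hairpin_suppressed` and ranked last: such molecules preferentially
#' fold into hairpins instead of being amplified.  A product is
#' `exponential` only when its two ends are sites of the two distinct
#' primers; a same-primer (inverted-repeat) product cannot be enriched
#' end-to-end.  Recovered unknown-flank sequence and walk distance are
#' read from provenance segments.
#'
#' @param pool the `fpr_pool` returned by [simulate_primary()].
#' @param ssp2,ssp4 `fpr_primer` candidates (or sequences).
#' @param hairpin_threshold terminal inverted-repeat length (bp) at/above
#'   which suppression is flagged.
#' @param max_extension polymerase run-off cap, nt.
#' @return a data.frame of class `fpr_amplicons`, ranked; one row per
#'   predicted amplicon with columns `id`, `length`, `fwd_primer`,
#'   `rev_primer`, `exponential`, `hairpin_suppressed`,
#'   `founding_matches`, `walk_distance`, `recovered_unknown`, `seq`.
#'   Attribute `strands` holds the product strand objects.
#' @export
simulate_secondary <- function(pool, ssp2, ssp4, hairpin_threshold = 15L,
                               max_extension = 10000L) {
  stopifnot(inherits(pool, "fpr_pool"))
  genome <- attr(pool, "genome")
  offset <- if (!is.null(genome)) genome$known_start else NA_integer_
  as_p <- function(x, role) {
    if (is.character(x)) primer_candidate(x, role) else x
  }
  ssp2 <- as_p(ssp2, "SSP2"); ssp4 <- as_p(ssp4, "SSP4")
  prim <- list(SSP2 = ssp_sim_primer(ssp2, "SSP2", offset),
               SSP4 = ssp_sim_primer(ssp4, "SSP4", offset))
  found <- list(); keys <- character(0)
  for (tmpl in pool$species) {
    for (p1_id in names(prim)) {
      p1 <- prim[[p1_id]]
      s1 <- find_perfect_sites(p1$seq, tmpl$seq)
      if (!nrow(s1)) next
      for (w1 in s1$start) {
        inter <- extend_product(p1, tmpl, w1, max_extension,
                                origin = sprintf("%s@%s", p1_id, tmpl$origin))
        for (p2_id in names(prim)) {
          p2 <- prim[[p2_id]]
          s2 <- find_perfect_sites(p2$seq, inter$seq)
          if (!nrow(s2)) next
          for (w2 in s2$start) {
            amp <- extend_product(p2, inter, w2, max_extension,
                                  origin = sprintf("%s+%s@%s", p2_id, p1_id,
                                                   tmpl$origin))
            n <- nchar(amp$seq)
            # end-to-end: 3' terminus must be the full reverse primer site
            if (n < nchar(p1$seq) + nchar(p2$seq)) next
            if (substr(amp$seq, n - nchar(p1$seq) + 1L, n) !=
                reverse_complement(p1$seq)) next
            # reject molecules still carrying internal primer sites
            spans <- rbind(.primer_hit_spans(prim$SSP2$seq, amp$seq),
                           .primer_hit_spans(prim$SSP4$seq, amp$seq))
            terminal_ok <- (spans[, 1L] == 1L) |
              (spans[, 2L] == n)
            if (any(!terminal_ok)) next
            key <- min(amp$seq, reverse_complement(amp$seq))
            if (key %in% keys) next
            keys <- c(keys, key)
            found[[length(found) + 1L]] <-
              list(strand = amp, fwd = p2_id, rev = p1_id)
          }
        }
      }
    }
  }
  cols <- function(x) data.frame(
    length = nchar(x$strand$seq), fwd_primer = x$fwd, rev_primer = x$rev,
    exponential = x$fwd != x$rev,
    hairpin_suppressed =
      terminal_inverted_repeat(x$strand$seq) >= hairpin_threshold,
    founding_matches = if (is.na(x$strand$founding_matches)) NA_real_
                       else x$strand$founding_matches,
    stringsAsFactors = FALSE)
  if (!length(found)) {
    out <- data.frame(id = character(0), length = integer(0),
                      fwd_primer = character(0), rev_primer = character(0),
                      exponential = logical(0),
                      hairpin_suppressed = logical(0),
                      founding_matches = numeric(0),
                      walk_distance = integer(0),
                      recovered_unknown = character(0),
                      seq = character(0), stringsAsFactors = FALSE)
    return(structure(out, strands = list(),
                     class = c("fpr_amplicons", "data.frame")))
  }
  meta <- do.call(rbind, lapply(found, cols))
  unk <- lapply(found, function(x) recovered_unknown(x$strand))
  meta$walk_distance <- vapply(unk, function(u) u$length, integer(1L))
  meta$recovered_unknown <- vapply(unk, function(u) u$seq, character(1L))
  meta$seq <- vapply(found, function(x) x$strand$seq, character(1L))
  ord <- order(meta$hairpin_suppressed,
               -ifelse(is.na(meta$founding_matches), -Inf,
                       meta$founding_matches),
               -meta$length, meta$seq)
  meta <- meta[ord, , drop = FALSE]
  meta <- cbind(id = sprintf("amp%02d", seq_len(nrow(meta))), meta,
                stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  structure(meta, strands = found[ord],
            class = c("fpr_amplicons", "data.frame"))
}

# longest unknown-provenance run on a strand, returned in plus sense
recovered_unknown <- function(strand) {
  segs <- strand$segments
  unk <- segs[segs$label %in% c("UNKNOWN", "RC_UNKNOWN"), , drop = FALSE]
  if (!nrow(unk)) return(list(seq = "", length = 0L,
                              ref = c(NA_integer_, NA_integer_)))
  len <- unk$end - unk$start + 1L
  r <- unk[which.max(len), ]
  s <- substr(strand$seq, r$start, r$end)
  if (identical(r$label, "RC_UNKNOWN")) s <- reverse_complement(s)
  list(seq = s, length = nchar(s), ref = c(r$ref_start, r$ref_end))
}

#' Locate the overlap between an amplicon and the known region
#'
#' Gapless comparison of the amplicon (in both orientations) against the
#' known region: finds the maximal exact overlap, or failing a match of at
#' least `min_overlap`, the best >= 95%-identity gapless overlap, and
#' reports whether the overlap abuts the known region's 3' end together
#' with the novel (non-overlapping) amplicon span.
#'
#' @param amplicon amplicon sequence.
#' @param known known-region sequence.
#' @param min_overlap minimum overlap length (bp) to report.
#' @return list of class `fpr_overlap`: `mode` (`"exact"`, `"approx"` or
#'   `"none"`), `orientation` (`"fwd"`/`"rc"`), `overlap_len`, `identity`,
#'   `known_span`, `amplicon_span`, `abuts_known_end`, `novel_span`,
#'   `novel_len`.
#' @export
validate_amplicon <- function(amplicon, known, min_overlap = 20L) {
  amplicon <- toupper(amplicon); known <- toupper(known)
  if (!nzchar(amplicon) || !nzchar(known))
    stop("amplicon and known region must be non-empty", call. = FALSE)
  kc <- seq_to_int(known, allow_n = TRUE, what = "known")
  n <- length(kc)
  best <- list(mode = "none", orientation = "fwd", overlap_len = 0L,
               identity = NA_real_,
               known_span = c(NA_integer_, NA_integer_),
               amplicon_span = c(NA_integer_, NA_integer_),
               abuts_known_end = FALSE,
               novel_span = c(NA_integer_, NA_integer_), novel_len = 0L)
  consider <- function(orientation, aseq) {
    ac <- seq_to_int(aseq, allow_n = TRUE, what = "amplicon")
    m <- length(ac)
    for (s in (2L - m):n) {   # s: known position aligned with amplicon pos 1
      ks <- max(1L, s); ke <- min(n, s + m - 1L)
      if (ke - ks + 1L < 1L) next
      av <- ac[(ks - s + 1L):(ke - s + 1L)]
      kv <- kc[ks:ke]
      eq <- av == kv & av != 0L & kv != 0L
      # longest exact run at this offset
      r <- rle(eq)
      if (any(r$values)) {
        lens <- r$lengths[r$values]
        ends <- cumsum(r$lengths)[r$values]
        i <- which.max(lens)
        run_len <- lens[i]
        run_end_k <- ks + ends[i] - 1L
        run_start_k <- run_end_k - run_len + 1L
        if (run_len > best$overlap_len ||
            (run_len == best$overlap_len && best$mode != "exact")) {
          aspan <- c(run_start_k - s + 1L, run_end_k - s + 1L)
          best <<- list(mode = "exact", orientation = orientation,
                        overlap_len = as.integer(run_len), identity = 1,
                        known_span = c(run_start_k, run_end_k),
                        amplicon_span = aspan,
                        abuts_known_end = run_end_k == n,
                        novel_span = if (aspan[2L] < m)
                          c(aspan[2L] + 1L, m)
                        else c(NA_integer_, NA_integer_),
                        novel_len = m - aspan[2L])
        }
      }
    }
  }
  consider("fwd", amplicon)
  consider("rc", reverse_complement(amplicon))
  if (best$mode == "exact" && best$overlap_len >= min_overlap)
    return(structure(best, class = "fpr_overlap"))
  exact_best <- best
  # fall back: best gapless overlap at >= 95% identity
  consider95 <- function(orientation, aseq) {
    ac <- seq_to_int(aseq, allow_n = TRUE, what = "amplicon")
    m <- length(ac)
    for (s in (2L - m):n) {
      ks <- max(1L, s); ke <- min(n, s + m - 1L)
      len <- ke - ks + 1L
      if (len < min_overlap) next
      av <- ac[(ks - s + 1L):(ke - s + 1L)]
      eq <- av == kc[ks:ke] & av != 0L
      idt <- sum(eq) / len
      if (idt >= 0.95 &&
          (best$mode != "approx" || len > best$overlap_len)) {
        aspan <- c(ks - s + 1L, ke - s + 1L)
        best <<- list(mode = "approx", orientation = orientation,
                      overlap_len = as.integer(len), identity = idt,
                      known_span = c(ks, ke), amplicon_span = aspan,
                      abuts_known_end = ke == n,
                      novel_span = if (aspan[2L] < m) c(aspan[2L] + 1L, m)
                                   else c(NA_integer_, NA_integer_),
                      novel_len = m - aspan[2L])
      }
    }
  }
  if (exact_best$overlap_len < min_overlap) {
    best <- list(mode = "none", orientation = "fwd", overlap_len = 0L,
                 identity = NA_real_,
                 known_span = c(NA_integer_, NA_integer_),
                 amplicon_span = c(NA_integer_, NA_integer_),
                 abuts_known_end = FALSE,
                 novel_span = c(NA_integer_, NA_integer_), novel_len = 0L)
    consider95("fwd", amplicon)
    consider95("rc", reverse_complement(amplicon))
    if (best$mode == "none") best <- exact_best
    if (best$overlap_len < min_overlap) {
      best$mode <- "none"
    }
  }
  structure(best, class = "fpr_overlap")
}

#' Run a complete in-silico walk
#'
#' Convenience pipeline: primary simulation, secondary simulation and
#' validation of the top-ranked amplicon against the known region.
#'
#' @param genome an [genome_region()].
#' @param walk an `fpr_walk_set`.
#' @param fp which fusion primer drives the primary reaction.
#' @param model [annealing_model()] for the low-stringency cycle.
#' @param ... passed to [simulate_primary()].
#' @return an object of class `fpr_walk_report`: list with `amplicons`,
#'   `rackets`, `stage_summary`, `validation` (of the top amplicon) and
#'   `warnings`.
#' @export
simulate_walk <- function(genome, walk, fp = c("alpha", "beta"),
                          model = annealing_model(), ...) {
  fp <- match.arg(fp)
  pool <- simulate_primary(genome, walk, fp = fp, model = model, ...)
  amps <- simulate_secondary(pool, walk$ssp2, walk$ssp4)
  known <- substr(genome$seq, genome$known_start, genome$known_end)
  validation <- if (nrow(amps))
    validate_amplicon(amps$seq[1L], known) else NULL
  structure(list(amplicons = amps,
                 rackets = attr(pool, "rackets"),
                 stage_summary = attr(pool, "stage_summary"),
                 pool = pool,
                 validation = validation,
                 warnings = attr(pool, "warnings")),
            class = "fpr_walk_report")
}

#' @export
print.fpr_walk_report <- function(x, ...) {
  cat("FPR-PCR walk report\n")
  cat("  rackets formed:", length(x$rackets), "\n")
  cat("  predicted amplicons:", nrow(x$amplicons), "\n")
  if (nrow(x$amplicons)) {
    top <- x$amplicons[1L, ]
    cat(sprintf("  top amplicon: %s, %d bp, %s/%s, walk distance %d nt%s\n",
                top$id, top$length, top$fwd_primer, top$rev_primer,
                top$walk_distance,
                if (top$hairpin_suppressed) " (hairpin-suppressed)" else ""))
  }
  if (!is.null(x$validation) && x$validation$mode != "none")
    cat(sprintf("  overlap with known region: %d bp (%s), %s\n",
                x$validation$overlap_len, x$validation$mode,
                if (x$validation$abuts_known_end)
                  "abuts the known 3' end" else "internal"))
  if (length(x$warnings)) cat("  warnings:",
                              paste(unique(x$warnings), collapse = "; "),
                              "\n")
  invisible(x)
}

#' Write predicted amplicons as FASTA + JSON report
#'
#' @param amps an `fpr_amplicons` data.frame.
#' @param fasta_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the amplicon table.
#' @export
write_amplicons <- function(amps, fasta_path = NULL, json_path = NULL) {
  if (!is.null(fasta_path)) {
    if (!nrow(amps)) stop("no amplicons to write", call. = FALSE)
    seqs <- amps$seq
    names(seqs) <- sprintf("%s length=%d fwd=%s rev=%s walk=%d", amps$id,
                           amps$length, amps$fwd_primer, amps$rev_primer,
                           amps$walk_distance)
    write_fasta(seqs, fasta_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      amps[, setdiff(names(amps), "seq")], json_path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(amps)
}
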