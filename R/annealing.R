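# Stringency-dependent primer/template annealing: perfect-site matching
# for stringent cycles and the mismatch-tolerant partial-annealing model
# for the single low-stringency cycle.
#
# Orientation convention: the template is the strand the primer physically
# anneals to, read 5'->3'.  A primer pairs antiparallel, so its 3'-terminal
# base sits at the 5'-most position of the template window; comparing the
# window against the reverse complement of the primer position-by-position
# therefore puts the primer 3' terminus at window offset 1.

#' Mismatch-tolerant annealing model
#'
#' Acceptance rules for a gapless primer/template pairing during a
#' low-stringency cycle.  All three rules are enforced conjunctively: a
#' window is a site only if its 3'-terminal matched run, its total match
#' count and its mismatch fraction all pass.  Defaults reflect functional
#' partial-annealing sites recovered from sequenced walking products: at
#' least two matched base pairs at the primer 3' terminus, at least 14
#' total matches, and tolerance of mismatch up to 60% of primer length.
#'
#' @param min_three_prime_run minimum matched run at the primer 3' end (bp).
#' @param min_total_matches minimum total matched positions (bp).
#' @param max_mismatch_fraction maximum mismatches as a fraction of primer
#'   length.
#' @param mode one of `"PARTIAL"`, `"PERFECT_FULL"`, `"PERFECT_3PART"`.
#' @return an object of class `fpr_annealing_model`.
#' @export
annealing_model <- function(min_three_prime_run = 2L,
                            min_total_matches = 14L,
                            max_mismatch_fraction = 0.6,
                            mode = c("PARTIAL", "PERFECT_FULL",
                                     "PERFECT_3PART")) {
  mode <- match.arg(mode)
  if (min_three_prime_run < 1L)
    stop("min_three_prime_run must be at least 1", call. = FALSE)
  if (max_mismatch_fraction < 0 || max_mismatch_fraction > 1)
    stop("max_mismatch_fraction must be in [0, 1]", call. = FALSE)
  structure(list(min_three_prime_run = as.integer(min_three_prime_run),
                 min_total_matches = as.integer(min_total_matches),
                 max_mismatch_fraction = max_mismatch_fraction,
                 mode = mode),
            class = "fpr_annealing_model")
}

.empty_sites <- function() {
  data.frame(template_id = character(0), start = integer(0),
             end = integer(0), primer_id = character(0),
             matches_total = integer(0), three_prime_run = integer(0),
             match_string = character(0), stringsAsFactors = FALSE)
}

#' Find perfect annealing sites of a primer (or its 3' part)
#'
#' Scans a template strand (5'->3', the strand the primer anneals to) for
#' windows exactly complementary (antiparallel) to the whole primer or to
#' its 3'-terminal `k`-mer.  `N` in the template never matches.
#'
#' @param primer primer sequence, 5'->3'.
#' @param template template strand sequence, 5'->3'.
#' @param part `"full"` for the whole primer, `"three_prime"` for its
#'   3'-terminal `k` bases.
#' @param k part length when `part = "three_prime"`.
#' @param template_id,primer_id identifiers carried into the result.
#' @return a data.frame of sites (class `fpr_sites`) sorted by position,
#'   with 1-based inclusive `start`/`end` of the matched window.  The
#'   primer 3' end pairs at `start`.
#' @export
find_perfect_sites <- function(primer, template, part = c("full", "three_prime"),
                               k = NULL, template_id = "template",
                               primer_id = "primer") {
  part <- match.arg(part)
  primer <- toupper(primer); template <- toupper(template)
  check_dna(primer, allow_n = FALSE, what = "primer")
  check_dna(template, allow_n = TRUE, what = "template")
  L <- nchar(primer)
  if (part == "three_prime") {
    if (is.null(k)) stop("k is required when part = 'three_prime'",
                         call. = FALSE)
    k <- as.integer(k)
    if (k < 1L || k > L)
      stop("k must be between 1 and the primer length (", L, ")",
           call. = FALSE)
    pat <- substr(primer, L - k + 1L, L)
  } else {
    pat <- primer; k <- L
  }
  if (nchar(template) < k) return(structure(.empty_sites(),
                                            class = c("fpr_sites", "data.frame")))
  m <- Biostrings::matchPattern(reverse_complement(pat),
                                Biostrings::DNAString(template), fixed = TRUE)
  starts <- sort(BiocGenerics::start(m))
  out <- data.frame(template_id = rep(template_id, length(starts)),
                    start = as.integer(starts),
                    end = as.integer(starts + k - 1L),
                    primer_id = rep(primer_id, length(starts)),
                    matches_total = rep(as.integer(k), length(starts)),
                    three_prime_run = rep(as.integer(k), length(starts)),
                    match_string = rep(strrep("|", k), length(starts)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("fpr_sites", "data.frame"))
}

#' Find mismatch-tolerant (partial) annealing sites
#'
#' Gapless scan of every template window of primer length on the given
#' strand sense.  A window is accepted iff the 3'-terminal matched run,
#' the total match count and the mismatch fraction all satisfy the model.
#' Output is sorted by `matches_total` (descending), then position.
#' `match_string` is oriented along the primer 5'->3' (`|` match, `.`
#' mismatch).
#'
#' @param primer primer sequence, 5'->3'.
#' @param template template strand sequence, 5'->3'.
#' @param model an [annealing_model()] with `mode = "PARTIAL"`.
#' @param template_id,primer_id identifiers carried into the result.
#' @return a data.frame of accepted sites (class `fpr_sites`).
#' @export
find_partial_sites <- function(primer, template, model = annealing_model(),
                               template_id = "template",
                               primer_id = "primer") {
  stopifnot(inherits(model, "fpr_annealing_model"))
  if (model$mode != "PARTIAL")
    stop("find_partial_sites requires a model with mode = 'PARTIAL'",
         call. = FALSE)
  primer <- toupper(primer); template <- toupper(template)
  pcode <- seq_to_int(primer, allow_n = FALSE, what = "primer")
  tcode <- seq_to_int(template, allow_n = TRUE, what = "template")
  L <- length(pcode); n <- length(tcode)
  if (L > n)
    stop("primer is longer than the template", call. = FALSE)
  nw <- n - L + 1L
  # window offset i pairs the primer base L - i + 1; window vs rc(primer)
  rcp <- rev(.comp_code[pcode + 1L])
  matches <- integer(nw)
  run <- integer(nw)
  alive <- rep(TRUE, nw)
  eqs <- vector("list", L)
  for (i in seq_len(L)) {
    eq <- tcode[i:(n - L + i)] == rcp[i]
    eqs[[i]] <- eq
    matches <- matches + as.integer(eq)
    alive <- alive & eq
    run <- run + as.integer(alive)
  }
  max_mm <- floor(model$max_mismatch_fraction * L + 1e-9)
  keep <- which(run >= model$min_three_prime_run &
                  matches >= model$min_total_matches &
                  (L - matches) <= max_mm)
  if (!length(keep)) return(structure(.empty_sites(),
                                      class = c("fpr_sites", "data.frame")))
  keep <- keep[order(-matches[keep], keep)]
  mask <- vapply(keep, function(w) {
    m <- vapply(seq_len(L), function(i) eqs[[i]][w], logical(1L))
    # template-window orientation -> primer 5'->3' orientation
    paste(ifelse(rev(m), "|", "."), collapse = "")
  }, character(1L))
  out <- data.frame(template_id = rep(template_id, length(keep)),
                    start = as.integer(keep),
                    end = as.integer(keep + L - 1L),
                    primer_id = rep(primer_id, length(keep)),
                    matches_total = as.integer(matches[keep]),
                    three_prime_run = as.integer(run[keep]),
                    match_string = mask,
                    stringsAsFactors = FALSE)
  structure(out, class = c("fpr_sites", "data.frame"))
}

#' Per-position match mask of a primer against a template window
#'
#' Compares the primer (5'->3') position-by-position with the reverse
#' complement of the template window; the mask is oriented along the
#' primer, `|` for match and `.` for mismatch.
#'
#' @param primer primer sequence.
#' @param site_window template window of equal length, 5'->3'.
#' @return the mask string, with attributes `matches_total` and
#'   `three_prime_run`.
#' @export
align_primer_site <- function(primer, site_window) {
  primer <- toupper(primer); site_window <- toupper(site_window)
  pcode <- seq_to_int(primer, allow_n = FALSE, what = "primer")
  wcode <- seq_to_int(site_window, allow_n = TRUE, what = "site window")
  if (length(pcode) != length(wcode))
    stop("primer and site window must have equal lengths (",
         length(pcode), " vs ", length(wcode), ")", call. = FALSE)
  m <- pcode == rev(.comp_code[wcode + 1L])  # N codes to 0, never matches
  run <- 0L
  for (i in rev(seq_along(m))) { if (!m[i]) break; run <- run + 1L }
  structure(paste(ifelse(m, "|", "."), collapse = ""),
            matches_total = as.integer(sum(m)),
            three_prime_run = run)
}

#' Render a primer/site alignment as text
#'
#' Human-readable two-sequence alignment of a fusion primer over its
#' annealing site: primer 5'->3' on top, the template window 3'->5'
#' underneath, with a match rail between.
#'
#' @inheritParams align_primer_site
#' @param name label printed in the header line.
#' @return a character scalar (multi-line).
#' @export
format_site_alignment <- function(primer, site_window, name = "site") {
  mask <- align_primer_site(primer, site_window)
  win_rev <- paste(rev(strsplit(toupper(site_window), "",
                                fixed = TRUE)[[1L]]), collapse = "")
  paste0(name, " (", attr(mask, "matches_total"), " matches, 3' run ",
         attr(mask, "three_prime_run"), ")\n",
         "  5'-", toupper(primer), "-3'  primer\n",
         "     ", unclass(mask), "\n",
         "  3'-", win_rev, "-5'  template\n")
}

#' Export annealing sites as BED
#'
#' Writes sites in BED6: template id, 0-based half-open window, primer id
#' as name, total matches as score.  The strand column is `-` because a
#' primer lies antiparallel to the template strand it was scanned against.
#'
#' @param sites an `fpr_sites` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  stopifnot(inherits(sites, "fpr_sites") || is.data.frame(sites))
  bed <- data.frame(chrom = sites$template_id,
                    chromStart = sites$start - 1L,
                    chromEnd = sites$end,
                    name = sites$primer_id,
                    score = sites$matches_total,
                    strand = rep("-", nrow(sites)),
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
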