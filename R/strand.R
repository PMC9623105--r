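# Strand and strand-pool containers for the PCR simulator.
#
# A strand is a 5'->3' sequence annotated with provenance segments that
# tile it exactly.  Labels record what each stretch derives from: the
# fusion-primer parts (FISA_TAG, SSP1), copies of the known region
# (KNOWN), of the unknown flank (UNKNOWN), and their reverse-complement
# mirrors (RC_KNOWN, RC_UNKNOWN, RC_SSP1, RC_FISA).  Segments also carry
# the genome interval they derive from (plus-strand coordinates) and the
# sense of that derivation, so that recovered flank sequence and walk
# distances can be read off any product exactly.

.mirror_label <- c(KNOWN = "RC_KNOWN", RC_KNOWN = "KNOWN",
                   UNKNOWN = "RC_UNKNOWN", RC_UNKNOWN = "UNKNOWN",
                   SSP1 = "RC_SSP1", RC_SSP1 = "SSP1",
                   FISA_TAG = "RC_FISA", RC_FISA = "FISA_TAG",
                   EXTENSION = "EXTENSION")

seg_df <- function(label, start, end, ref_start = NA_integer_,
                   ref_end = NA_integer_, ref_strand = NA_character_) {
  data.frame(label = label, start = as.integer(start), end = as.integer(end),
             ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
             ref_strand = ref_strand, stringsAsFactors = FALSE)
}

# merge adjacent rows that continue the same provenance
merge_segments <- function(segs) {
  if (nrow(segs) < 2L) return(segs)
  out <- segs[1L, , drop = FALSE]
  for (i in 2L:nrow(segs)) {
    a <- out[nrow(out), ]; b <- segs[i, ]
    contig <-
      identical(a$label, b$label) && b$start == a$end + 1L &&
      identical(a$ref_strand, b$ref_strand) &&
      ((is.na(a$ref_start) && is.na(b$ref_start)) ||
         (!is.na(a$ref_start) && !is.na(b$ref_start) &&
            ((identical(a$ref_strand, "+") && b$ref_start == a$ref_end + 1L) ||
               (identical(a$ref_strand, "-") && b$ref_end == a$ref_start - 1L))))
    if (isTRUE(contig)) {
      out$end[nrow(out)] <- b$end
      if (!is.na(a$ref_start)) {
        if (identical(a$ref_strand, "+")) out$ref_end[nrow(out)] <- b$ref_end
        else out$ref_start[nrow(out)] <- b$ref_start
      }
    } else out <- rbind(out, b)
  }
  rownames(out) <- NULL
  out
}

# provenance of the reverse complement of template positions [a, b],
# placed into a product at 1-based offset `off` (product part starts at
# off + 1)
mirror_segments <- function(segs, a, b, off = 0L) {
  if (b < a) return(segs[0L, , drop = FALSE])
  keep <- segs$end >= a & segs$start <= b
  segs <- segs[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    r <- segs[i, ]
    cs <- max(r$start, a); ce <- min(r$end, b)
    if (is.na(r$ref_start)) { crs <- NA_integer_; cre <- NA_integer_ }
    else if (identical(r$ref_strand, "+")) {
      crs <- r$ref_start + (cs - r$start); cre <- r$ref_start + (ce - r$start)
    } else {
      cre <- r$ref_end - (cs - r$start); crs <- r$ref_end - (ce - r$start)
    }
    new_strand <- if (is.na(r$ref_strand)) NA_character_
                  else if (identical(r$ref_strand, "+")) "-" else "+"
    seg_df(.mirror_label[[r$label]],
           off + (b - ce + 1L), off + (b - cs + 1L),
           crs, cre, new_strand)
  })
  out <- do.call(rbind, rev(rows))
  rownames(out) <- NULL
  out
}

new_strand <- function(seq, segments, origin, mclass = "LINEAR",
                       founding_matches = NA_real_, looped = FALSE) {
  segments <- merge_segments(segments)
  n <- nchar(seq)
  if (nrow(segments)) {
    if (segments$start[1L] != 1L || segments$end[nrow(segments)] != n ||
        (nrow(segments) > 1L &&
         any(segments$start[-1L] != segments$end[-nrow(segments)] + 1L)))
      stop("internal error: provenance segments do not tile the strand",
           call. = FALSE)
  } else if (n > 0L)
    stop("internal error: strand without provenance", call. = FALSE)
  structure(list(seq = seq, segments = segments, origin = origin,
                 mclass = mclass, founding_matches = founding_matches,
                 looped = looped),
            class = "fpr_strand")
}

#' Create a genome with an annotated known region
#'
#' Container handed to the simulator: the plus-strand sequence with the
#' 1-based inclusive coordinates of the known region; everything outside
#' the known region is treated as unknown flank.
#'
#' @param seq genome plus strand, 5'->3'.
#' @param known_start,known_end 1-based inclusive known-region interval.
#' @param id sequence identifier.
#' @return an object of class `fpr_genome`.
#' @export
genome_region <- function(seq, known_start, known_end, id = "genome") {
  seq <- toupper(seq)
  check_dna(seq, allow_n = TRUE, what = "genome")
  n <- nchar(seq)
  known_start <- as.integer(known_start); known_end <- as.integer(known_end)
  if (known_start < 1L || known_end > n || known_start > known_end)
    stop("known region must satisfy 1 <= start <= end <= genome length",
         call. = FALSE)
  structure(list(id = id, seq = seq, known_start = known_start,
                 known_end = known_end),
            class = "fpr_genome")
}

genome_seed_strands <- function(genome) {
  n <- nchar(genome$seq)
  ks <- genome$known_start; ke <- genome$known_end
  rows <- list()
  if (ks > 1L) rows[[length(rows) + 1L]] <-
      seg_df("UNKNOWN", 1L, ks - 1L, 1L, ks - 1L, "+")
  rows[[length(rows) + 1L]] <- seg_df("KNOWN", ks, ke, ks, ke, "+")
  if (ke < n) rows[[length(rows) + 1L]] <-
      seg_df("UNKNOWN", ke + 1L, n, ke + 1L, n, "+")
  plus_segs <- do.call(rbind, rows)
  plus <- new_strand(genome$seq, plus_segs, "seed_plus", "SEED")
  minus <- new_strand(reverse_complement(genome$seq),
                      mirror_segments(plus_segs, 1L, n, 0L),
                      "seed_minus", "SEED")
  list(plus = plus, minus = minus)
}

#' Create a strand pool
#'
#' The simulator's state: a set of unique strand species with a
#' multiplicity class (`SEED`, `LINEAR`, `EXPONENTIAL`) each, plus caps on
#' species count and strand length.
#'
#' @param strands list of strand objects.
#' @param max_species species cap; overflow is reported, never silent.
#' @param max_strand_length cap on the length of any synthesized strand.
#' @return an object of class `fpr_pool`.
#' @export
strand_pool <- function(strands = list(), max_species = 200L,
                        max_strand_length = 50000L) {
  pool <- structure(list(species = list(),
                         max_species = as.integer(max_species),
                         max_strand_length = as.integer(max_strand_length),
                         warnings = character(0)),
                    class = "fpr_pool")
  for (s in strands) pool <- pool_add(pool, s)
  pool
}

pool_add <- function(pool, strand) {
  seqs <- vapply(pool$species, `[[`, character(1L), "seq")
  hit <- match(strand$seq, seqs)
  rank <- c(SEED = 1L, LINEAR = 2L, EXPONENTIAL = 3L)
  if (!is.na(hit)) {
    # multiplicity class is monotone non-decreasing
    if (rank[strand$mclass] > rank[pool$species[[hit]]$mclass])
      pool$species[[hit]]$mclass <- strand$mclass
    old <- pool$species[[hit]]$founding_matches
    if (!is.na(strand$founding_matches) &&
        (is.na(old) || strand$founding_matches > old))
      pool$species[[hit]]$founding_matches <- strand$founding_matches
    return(pool)
  }
  if (length(pool$species) >= pool$max_species) {
    msg <- sprintf("species cap (%d) reached; strand from '%s' not added",
                   pool$max_species, strand$origin)
    pool$warnings <- c(pool$warnings, msg)
    warning(msg, call. = FALSE)
    return(pool)
  }
  pool$species[[length(pool$species) + 1L]] <- strand
  pool
}

pool_seqs <- function(pool) vapply(pool$species, `[[`, character(1L), "seq")

strand_has_unknown <- function(strand)
  any(strand$segments$label %in% c("UNKNOWN", "RC_UNKNOWN"))

#' @export
print.fpr_pool <- function(x, ...) {
  cls <- table(vapply(x$species, `[[`, character(1L), "mclass"))
  cat("strand pool:", length(x$species), "species (",
      paste(names(cls), as.integer(cls), collapse = ", "), ")\n")
  if (length(x$warnings))
    cat("warnings:", paste(unique(x$warnings), collapse = "; "), "\n")
  invisible(x)
}

#' Write a strand pool as FASTA with provenance headers
#'
#' @param pool an `fpr_pool`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_pool_fasta <- function(pool, path) {
  seqs <- pool_seqs(pool)
  if (!length(seqs)) stop("empty pool", call. = FALSE)
  hdr <- vapply(seq_along(pool$species), function(i) {
    s <- pool$species[[i]]
    segs <- paste(sprintf("%s:%d-%d", s$segments$label, s$segments$start,
                          s$segments$end), collapse = ",")
    sprintf("strand%03d origin=%s class=%s segments=%s", i, s$origin,
            s$mclass, segs)
  }, character(1L))
  names(seqs) <- hdr
  write_fasta(seqs, path)
}
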