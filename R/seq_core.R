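# Sequence primitives shared by every module: alphabet handling, reverse
# complement, FASTA I/O, nearest-neighbor duplex thermodynamics and primer
# self-structure screening.

# Integer coding: A=1 C=2 G=3 T=4, N=0.  N is coded so that it can never
# equal the code of a complementary base, i.e. N never counts as a match.
.base_code <- local({
  v <- rep(NA_integer_, 127L)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("T")] <- 4L
  v[utf8ToInt("N")] <- 0L
  v
})
# complement code: comp(A)=T etc.; comp(N)=N (still never matches)
.comp_code <- c(0L, 4L, 3L, 2L, 1L)  # index by code + 1

#' @keywords internal
seq_to_int <- function(seq, allow_n = TRUE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  if (!nzchar(seq)) return(integer(0))
  raw <- utf8ToInt(seq)
  bad <- raw > 127L
  code <- rep(NA_integer_, length(raw))
  code[!bad] <- .base_code[raw[!bad]]
  off <- which(is.na(code) | (!allow_n & code == 0L))
  if (length(off)) {
    i <- off[1L]
    stop(sprintf("disallowed character '%s' at position %d in %s",
                 substr(seq, i, i), i, what), call. = FALSE)
  }
  code
}

int_to_seq <- function(code) {
  if (!length(code)) return("")
  intToUtf8(utf8ToInt("ACGT N")[c(1:4, 6L)][ifelse(code == 0L, 5L, code)])
}

check_dna <- function(seq, allow_n = TRUE, what = "sequence") {
  invisible(seq_to_int(toupper(seq), allow_n = allow_n, what = what))
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement, reversed.  `N` maps to `N`.  Vectorised over a
#' character vector; the empty string is its own reverse complement.
#'
#' @param seq character vector of sequences over `A,C,G,T,N` (5'->3').
#' @return character vector of the same length, each read 5'->3'.
#' @export
#' @examples
#' reverse_complement("CGTAAACCTGCGTAAAAA")
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    s <- toupper(s)
    check_dna(s, allow_n = TRUE)
    if (!nzchar(s)) return("")
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Read a (multi-record) FASTA file
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences; names are the
#'   full record identifiers.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(
    withCallingHandlers(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      warning = function(w) {
        if (grepl("invalid one-letter sequence", conditionMessage(w)))
          stop("illegal sequence character in '", path, "'", call. = FALSE)
        invokeRestart("muffleWarning")
      }),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  ids <- names(set)
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id: '", ids[duplicated(ids)][1L], "'",
         call. = FALSE)
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    ok <- tryCatch({ check_dna(seqs[[i]], allow_n = TRUE); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok))
      stop("FASTA record '", ids[i], "': ", ok, call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences as FASTA (wrapped at 60 columns)
#'
#' `write_fasta()` followed by [read_fasta()] is the identity on
#' (id, sequence) pairs.
#'
#' @param records named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (!length(records) || is.null(names(records)) || any(!nzchar(names(records))))
    stop("records must be a non-empty named character vector", call. = FALSE)
  set <- Biostrings::DNAStringSet(toupper(records))
  names(set) <- names(records)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Thermodynamic conditions for melting-temperature calculation
#'
#' Reaction conditions under which duplex Tm is computed.  Defaults follow
#' the recommended FPR-PCR mix: 0.2 uM primer, 50 mM monovalent cation,
#' 2.5 mM Mg2+ and 1.6 mM total dNTP (0.4 mM each).
#'
#' @param primer_conc_uM primer concentration in micromolar.
#' @param monovalent_mM monovalent salt (Na+/K+ equivalents), mM.
#' @param divalent_mM divalent cations (Mg2+), mM.
#' @param dntp_mM total dNTP concentration, mM (binds Mg2+ and is
#'   subtracted before the divalent-to-monovalent equivalence).
#' @return an object of class `fpr_thermo`.
#' @export
thermo_conditions <- function(primer_conc_uM = 0.2, monovalent_mM = 50,
                              divalent_mM = 2.5, dntp_mM = 1.6) {
  vals <- c(primer_conc_uM, monovalent_mM, divalent_mM, dntp_mM)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all thermodynamic conditions must be non-negative numbers",
         call. = FALSE)
  structure(list(primer_conc_uM = primer_conc_uM,
                 monovalent_mM = monovalent_mM,
                 divalent_mM = divalent_mM,
                 dntp_mM = dntp_mM),
            class = "fpr_thermo")
}

# Unified nearest-neighbor parameters (kcal/mol, cal/(mol K)) with
# terminal initiation terms; monovalent-salt entropy correction
# 0.368 (N-1) ln[mon], divalent cations folded in as 120*sqrt(Mg - dNTP)
# mM monovalent equivalents.
.nn_pairs <- local({
  dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
          CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  comp <- function(x) chartr("ACGT", "TGCA", x)
  rc2 <- function(x) paste0(comp(substr(x, 2, 2)), comp(substr(x, 1, 1)))
  H <- numeric(16); S <- numeric(16)
  dimn <- as.vector(outer(c("A","C","G","T"), c("A","C","G","T"),
                          function(a, b) paste0(a, b)))
  names(H) <- names(S) <- dimn
  for (k in dimn) {
    if (k %in% names(dH)) { H[k] <- dH[k]; S[k] <- dS[k] }
    else { H[k] <- dH[rc2(k)]; S[k] <- dS[rc2(k)] }
  }
  list(dH = H, dS = S)
})

# dH/dS lookup indexed by 4*(code1-1) + code2
.nn_index <- local({
  key <- as.vector(t(outer(c("A","C","G","T"), c("A","C","G","T"), paste0)))
  list(dH = .nn_pairs$dH[key], dS = .nn_pairs$dS[key])
})

.tm_one <- function(code, cond) {
  n <- length(code)
  idx <- 4L * (code[-n] - 1L) + code[-1L]
  dH <- sum(.nn_index$dH[idx])
  dS <- sum(.nn_index$dS[idx])
  for (end in c(code[1L], code[n])) {
    if (end %in% c(1L, 4L)) { dH <- dH + 2.3; dS <- dS + 4.1 }
    else { dH <- dH + 0.1; dS <- dS - 2.8 }
  }
  mg_free <- max(0, cond$divalent_mM - cond$dntp_mM)
  mon <- cond$monovalent_mM + 120 * sqrt(mg_free)  # mM equivalents
  if (mon <= 0) stop("effective monovalent concentration must be positive",
                     call. = FALSE)
  dS <- dS + 0.368 * (n - 1L) * log(mon / 1000)
  ct <- cond$primer_conc_uM * 1e-6
  if (ct <= 0) stop("primer concentration must be positive", call. = FALSE)
  dH * 1000 / (dS + 1.987 * log(ct)) - 273.15
}

#' Nearest-neighbor melting temperature
#'
#' Duplex Tm of a primer against its perfect complement, from the unified
#' nearest-neighbor parameter set with terminal-base initiation terms and a
#' salt-entropy correction (divalent cations converted to monovalent
#' equivalents after subtracting dNTP-bound Mg2+).  Deterministic in its
#' inputs.
#'
#' @param seq primer sequence (>= 8 nt, no `N`); may be a character vector.
#' @param cond a [thermo_conditions()] object.
#' @return numeric vector of melting temperatures in degrees Celsius.
#' @export
melting_temperature <- function(seq, cond = thermo_conditions()) {
  stopifnot(inherits(cond, "fpr_thermo"))
  vapply(seq, function(s) {
    code <- seq_to_int(toupper(s), allow_n = FALSE, what = "primer")
    if (length(code) < 8L)
      stop("sequence too short for nearest-neighbor Tm (need >= 8 nt, got ",
           length(code), ")", call. = FALSE)
    .tm_one(code, cond)
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Structure-screening thresholds
#'
#' A self-structure is called severe when an intramolecular hairpin stem of
#' at least `stem_bp` base pairs can close over a loop of at least
#' `loop_nt` nucleotides, or when a self-dimer run anchored at the 3'
#' terminus reaches `dimer_run_bp` base pairs.
#'
#' @param stem_bp hairpin stem length (bp) at/above which a hairpin flag is
#'   raised.
#' @param loop_nt minimum hairpin loop length (nt) considered foldable.
#' @param dimer_run_bp 3'-anchored self-dimer run (bp) at/above which a
#'   dimer flag is raised.
#' @return an object of class `fpr_struct_thresholds`.
#' @export
structure_thresholds <- function(stem_bp = 4L, loop_nt = 3L,
                                 dimer_run_bp = 5L) {
  stopifnot(stem_bp >= 1L, loop_nt >= 0L, dimer_run_bp >= 1L)
  structure(list(stem_bp = as.integer(stem_bp),
                 loop_nt = as.integer(loop_nt),
                 dimer_run_bp = as.integer(dimer_run_bp)),
            class = "fpr_struct_thresholds")
}

# Core structure scan on an integer-coded sequence.  Run[i, j] is the
# length of the consecutive complementary stack starting at pair (i, j)
# and proceeding inward ((i+1, j-1), ...).  The same matrix serves both
# the hairpin (i < j, loop constraint at the innermost pair) and the
# 3'-anchored self-dimer (runs starting at pairs (j, n), j free).
.structure_scan <- function(code, loop_nt) {
  n <- length(code)
  if (n < 2L)
    return(list(stem = 0L, loop = NA_integer_, dimer = as.integer(n > 0L &&
                  .comp_code[code[1L] + 1L] == code[1L])))
  comp <- .comp_code[code + 1L]
  C <- outer(code, comp, "==") & code > 0L   # C[i, j]: i pairs j
  run <- matrix(0L, n, n)
  run[n, ] <- as.integer(C[n, ])
  run[, 1L] <- as.integer(C[, 1L])
  for (i in (n - 1L):1L) {
    r <- as.integer(C[i, 2L:n])
    add <- run[i + 1L, 1L:(n - 1L)]
    run[i, 2L:n] <- r * (1L + add)
  }
  # hairpin: usable stem at outer pair (i, j) limited by loop >= loop_nt
  best_stem <- 0L; best_loop <- NA_integer_
  idx <- which(C & upper.tri(C, diag = FALSE), arr.ind = TRUE)
  if (nrow(idx)) {
    i <- idx[, 1L]; j <- idx[, 2L]
    geom <- floor((j - i - 1L - loop_nt) / 2) + 1L  # max pairs before loop < loop_nt
    usable <- pmin(run[idx], pmax(geom, 0L))
    k <- which.max(usable)
    if (usable[k] > 0L) {
      best_stem <- as.integer(usable[k])
      best_loop <- as.integer(j[k] - i[k] - 1L - 2L * (best_stem - 1L))
      # among maximal stems report the smallest achievable loop
      ties <- which(usable == best_stem)
      best_loop <- min(as.integer(j[ties] - i[ties] - 1L -
                                    2L * (best_stem - 1L)))
    }
  }
  dimer <- if (n >= 1L) max(run[, n]) else 0L
  list(stem = best_stem, loop = best_loop, dimer = as.integer(dimer))
}

#' Screen a primer for self-hairpin and 3'-anchored self-dimer
#'
#' Reports the longest intramolecular complementary stem that can close
#' over a loop of at least the threshold loop length, the loop length of
#' that hairpin, and the longest run of consecutive complementary base
#' pairs between two antiparallel copies of the primer that includes the
#' 3'-terminal base.  Severity flags derive deterministically from the
#' thresholds.
#'
#' @param seq primer sequence.
#' @param thresholds a [structure_thresholds()] object.
#' @return an object of class `fpr_structure`: a list with
#'   `longest_hairpin_stem`, `min_hairpin_loop`, `longest_3prime_dimer_run`,
#'   `flags` (character subset of `"hairpin"`, `"dimer"`) and `severe`.
#' @export
screen_structure <- function(seq, thresholds = structure_thresholds()) {
  stopifnot(inherits(thresholds, "fpr_struct_thresholds"))
  code <- seq_to_int(toupper(seq), allow_n = TRUE, what = "primer")
  res <- .structure_scan(code, thresholds$loop_nt)
  flags <- character(0)
  if (res$stem >= thresholds$stem_bp) flags <- c(flags, "hairpin")
  if (res$dimer >= thresholds$dimer_run_bp) flags <- c(flags, "dimer")
  structure(list(longest_hairpin_stem = res$stem,
                 min_hairpin_loop = res$loop,
                 longest_3prime_dimer_run = res$dimer,
                 flags = flags,
                 severe = length(flags) > 0L),
            class = "fpr_structure")
}

# Longest 3'-anchored cross-dimer run between two different primers:
# a run of consecutive complementary pairs between antiparallel copies of
# `a` and `b` that includes the 3'-terminal base of either primer.
cross_dimer_run <- function(a, b) {
  ca <- seq_to_int(toupper(a), allow_n = FALSE, what = "primer")
  cb <- seq_to_int(toupper(b), allow_n = FALSE, what = "primer")
  anchored <- function(p, t) {    # p's 3' end against template t
    # p[np - k + 1 .. np] pairing t[j .. j + k - 1] for some j
    np <- length(p); nt <- length(t)
    comp_p <- .comp_code[p + 1L]
    best <- 0L
    for (j in seq_len(nt)) {
      k <- 0L
      while (k < np && j + k <= nt && t[j + k] == comp_p[np - k]) k <- k + 1L
      if (k > best) best <- k
    }
    best
  }
  max(anchored(ca, cb), anchored(cb, ca))
}

#' @export
print.fpr_structure <- function(x, ...) {
  cat("primer self-structure: stem", x$longest_hairpin_stem, "bp (loop",
      x$min_hairpin_loop, "nt), 3' self-dimer run",
      x$longest_3prime_dimer_run, "bp;",
      if (x$severe) paste("SEVERE:", paste(x$flags, collapse = ","))
      else "no severe flags", "\n")
  invisible(x)
}

# restore RNG state after seeded operations so callers' streams are intact
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# deterministic derived seeds that stay inside 32-bit integer range
mix_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483587)
}
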