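# Enumeration, scoring and assembly of FPR-PCR walking-primer sets from a
# known region.
#
# Five fragments are chosen 5'->3' from the known sequence: two SSP1s
# (alpha/beta), SSP2, the FISA (SSP3, the fragment mediating intra-strand
# annealing) and SSP4.  Each fusion primer is the FISA appended to the 5'
# end of one SSP1.  The primary reaction uses a fusion primer alone; the
# secondary reaction uses SSP2 + SSP4.

#' Design constraints for FPR-PCR primer sets
#'
#' Per-role length windows (nt) and melting-temperature windows (degrees
#' Celsius), structure-severity thresholds and the minimum separation of
#' the two SSP1 3' ends.  The SSP2/SSP4 windows are shared (`ssp2_ssp4`).
#' Tm windows are enforced as warnings by default and as hard filters when
#' `strict_tm = TRUE`, because window satisfaction depends on the Tm model
#' in use; length windows are always hard.
#'
#' @param len_fisa,len_ssp1,len_fusion,len_ssp2_ssp4 integer length windows
#'   `c(min, max)`.
#' @param tm_fisa,tm_ssp1,tm_fusion,tm_ssp2_ssp4 Tm windows `c(min, max)`.
#' @param min_three_prime_sep minimum distance between the two SSP1 3' ends
#'   (nt).
#' @param structure a [structure_thresholds()] object.
#' @param strict_tm enforce Tm windows as hard constraints.
#' @return an object of class `fpr_constraints`.
#' @export
design_constraints <- function(len_fisa = c(17L, 18L),
                               len_ssp1 = c(17L, 21L),
                               len_fusion = c(34L, 39L),
                               len_ssp2_ssp4 = c(25L, 30L),
                               tm_fisa = c(45, 55),
                               tm_ssp1 = c(50, 55),
                               tm_fusion = c(65, 70),
                               tm_ssp2_ssp4 = c(60, 66),
                               min_three_prime_sep = 3L,
                               structure = structure_thresholds(),
                               strict_tm = FALSE) {
  win <- list(fisa = len_fisa, ssp1 = len_ssp1, fusion = len_fusion,
              ssp2_ssp4 = len_ssp2_ssp4)
  for (w in win) if (length(w) != 2L || w[1L] > w[2L] || w[1L] < 1L)
    stop("length windows must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  structure(list(len = lapply(win, as.integer),
                 tm = list(fisa = tm_fisa, ssp1 = tm_ssp1,
                           fusion = tm_fusion, ssp2_ssp4 = tm_ssp2_ssp4),
                 min_three_prime_sep = as.integer(min_three_prime_sep),
                 structure = structure,
                 strict_tm = strict_tm),
            class = "fpr_constraints")
}

.role_window_key <- function(role) {
  switch(role,
         SSP1 = "ssp1", SSP2 = "ssp2_ssp4", SSP4 = "ssp2_ssp4",
         SSP3_FISA = "fisa", FUSION = "fusion",
         stop("unknown primer role '", role, "'", call. = FALSE))
}

#' Construct a primer candidate
#'
#' A role-tagged oligo, optionally located on the known-region coordinate
#' system (1-based inclusive), with its Tm and self-structure report.
#'
#' @param seq primer sequence 5'->3'.
#' @param role one of `"SSP1"`, `"SSP2"`, `"SSP3_FISA"`, `"SSP4"`,
#'   `"FUSION"`.
#' @param start,end 1-based inclusive locus on the known region (optional).
#' @param cond [thermo_conditions()] used for the Tm.
#' @param thresholds [structure_thresholds()] used for the screen.
#' @return an object of class `fpr_primer`.
#' @export
primer_candidate <- function(seq, role, start = NA_integer_,
                             end = NA_integer_,
                             cond = thermo_conditions(),
                             thresholds = structure_thresholds()) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("primer sequence must be non-empty", call. = FALSE)
  check_dna(seq, allow_n = FALSE, what = "primer")
  role <- match.arg(role, c("SSP1", "SSP2", "SSP3_FISA", "SSP4", "FUSION"))
  tm <- if (nchar(seq) >= 8L) melting_temperature(seq, cond) else NA_real_
  structure(list(role = role, seq = seq, start = as.integer(start),
                 end = as.integer(end), length = nchar(seq), tm = tm,
                 structure = screen_structure(seq, thresholds)),
            class = "fpr_primer")
}

# fast per-window Tm over substrings of one coded sequence (no N)
.tm_windows <- function(code, starts, len, cond) {
  n <- length(code)
  idx <- 4L * (code[-n] - 1L) + code[-1L]
  cH <- c(0, cumsum(.nn_index$dH[idx]))
  cS <- c(0, cumsum(.nn_index$dS[idx]))
  dH <- cH[starts + len - 1L] - cH[starts]
  dS <- cS[starts + len - 1L] - cS[starts]
  initH <- function(b) ifelse(b %in% c(1L, 4L), 2.3, 0.1)
  initS <- function(b) ifelse(b %in% c(1L, 4L), 4.1, -2.8)
  dH <- dH + initH(code[starts]) + initH(code[starts + len - 1L])
  dS <- dS + initS(code[starts]) + initS(code[starts + len - 1L])
  mon <- cond$monovalent_mM + 120 * sqrt(max(0, cond$divalent_mM - cond$dntp_mM))
  dS <- dS + 0.368 * (len - 1L) * log(mon / 1000)
  dH * 1000 / (dS + 1.987 * log(cond$primer_conc_uM * 1e-6)) - 273.15
}

.score_candidates <- function(tm, stem, dimer, tm_win, thresholds) {
  center <- mean(tm_win); half <- diff(tm_win) / 2
  (1 - abs(tm - center) / half) -
    0.15 * stem / thresholds$stem_bp -
    0.15 * dimer / thresholds$dimer_run_bp
}

#' Enumerate primer candidates for one role
#'
#' Every substring of the known region whose length falls in the role's
#' window and whose self-structure is not severe, with its Tm, Tm-window
#' status and selection score.  With `constraints$strict_tm` the Tm window
#' is a hard filter; otherwise out-of-window candidates are kept and
#' flagged.  Deterministic; sorted by start, then length.
#'
#' @param known known-region sequence (plus strand, 5'->3', no `N`).
#' @param role `"SSP1"`, `"SSP2"`, `"SSP3_FISA"` or `"SSP4"`.
#' @param constraints a [design_constraints()] object.
#' @param cond [thermo_conditions()].
#' @return data.frame with columns `role`, `seq`, `start`, `end`,
#'   `length`, `tm`, `tm_in_window`, `hairpin_stem`, `dimer_run`, `score`.
#' @export
enumerate_candidates <- function(known, role,
                                 constraints = design_constraints(),
                                 cond = thermo_conditions()) {
  stopifnot(inherits(constraints, "fpr_constraints"))
  role <- match.arg(role, c("SSP1", "SSP2", "SSP3_FISA", "SSP4"))
  known <- toupper(known)
  code <- seq_to_int(known, allow_n = FALSE, what = "known region")
  key <- .role_window_key(role)
  win <- constraints$len[[key]]
  tm_win <- constraints$tm[[key]]
  n <- length(code)
  if (n < win[1L]) {
    out <- data.frame(role = character(0), seq = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), tm = numeric(0),
                      tm_in_window = logical(0), hairpin_stem = integer(0),
                      dimer_run = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  pieces <- list()
  memo <- new.env(parent = emptyenv())
  for (len in win[1L]:min(win[2L], n)) {
    starts <- seq_len(n - len + 1L)
    seqs <- substring(known, starts, starts + len - 1L)
    tm <- .tm_windows(code, starts, len, cond)
    stem <- integer(length(starts)); dimer <- integer(length(starts))
    for (i in seq_along(seqs)) {
      s <- seqs[i]
      hit <- get0(s, envir = memo, inherits = FALSE)
      if (is.null(hit)) {
        r <- .structure_scan(code[starts[i]:(starts[i] + len - 1L)],
                             constraints$structure$loop_nt)
        hit <- c(r$stem, r$dimer)
        assign(s, hit, envir = memo)
      }
      stem[i] <- hit[1L]; dimer[i] <- hit[2L]
    }
    pieces[[length(pieces) + 1L]] <-
      data.frame(role = role, seq = seqs, start = starts,
                 end = starts + len - 1L, length = len, tm = tm,
                 tm_in_window = tm >= tm_win[1L] & tm <= tm_win[2L],
                 hairpin_stem = stem, dimer_run = dimer,
                 score = .score_candidates(tm, stem, dimer, tm_win,
                                           constraints$structure),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  severe <- out$hairpin_stem >= constraints$structure$stem_bp |
    out$dimer_run >= constraints$structure$dimer_run_bp
  out <- out[!severe, , drop = FALSE]
  if (constraints$strict_tm) out <- out[out$tm_in_window, , drop = FALSE]
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a fusion primer from a FISA and an SSP1 candidate
#'
#' The fusion primer is the FISA fragment attached to the 5' end of SSP1;
#' its Tm is computed on the full fused sequence.
#'
#' @param fisa an `fpr_primer` with role `"SSP3_FISA"` (or its sequence).
#' @param ssp1 an `fpr_primer` with role `"SSP1"` (or its sequence).
#' @param cond [thermo_conditions()].
#' @return an object of class `fpr_fusion_primer` with fields `seq`,
#'   `length`, `tm`, `fisa`, `ssp1`.
#' @export
assemble_fusion <- function(fisa, ssp1, cond = thermo_conditions()) {
  if (is.character(fisa)) fisa <- primer_candidate(fisa, "SSP3_FISA", cond = cond)
  if (is.character(ssp1)) ssp1 <- primer_candidate(ssp1, "SSP1", cond = cond)
  if (!inherits(fisa, "fpr_primer") || !inherits(ssp1, "fpr_primer"))
    stop("assembly error: fisa and ssp1 must be primer candidates",
         call. = FALSE)
  if (fisa$role != "SSP3_FISA" || ssp1$role != "SSP1")
    stop("assembly error: roles must be SSP3_FISA + SSP1 (got ",
         fisa$role, " + ", ssp1$role, ")", call. = FALSE)
  if (!nzchar(fisa$seq) || !nzchar(ssp1$seq))
    stop("assembly error: empty primer part", call. = FALSE)
  seq <- paste0(fisa$seq, ssp1$seq)
  structure(list(seq = seq, length = nchar(seq),
                 tm = melting_temperature(seq, cond),
                 fisa = fisa, ssp1 = ssp1),
            class = "fpr_fusion_primer")
}

# exhaustive search for the best-scoring feasible combination over the
# supplied candidate tables; returns list(chosen = ... or NULL, reason)
.walk_search <- function(b1, b24, bf, constraints) {
  fail <- function(msg) list(chosen = NULL, reason = msg)
  pairs <- .ssp1_pair_table(b1, constraints$min_three_prime_sep)
  if (is.null(pairs))
    return(fail(paste0("infeasible design: no SSP1 pair with 3'-end ",
                       "separation >= ", constraints$min_three_prime_sep,
                       " nt")))
  # prefix-best pair for every bound on max(end): sort by maxend, run best
  pairs <- pairs[order(pairs$maxend, -pairs$score, pairs$astart), ,
                 drop = FALSE]
  best_idx <- integer(nrow(pairs)); best <- -Inf; besti <- NA_integer_
  basta <- Inf
  for (r in seq_len(nrow(pairs))) {
    if (pairs$score[r] > best ||
        (pairs$score[r] == best && pairs$astart[r] < basta)) {
      best <- pairs$score[r]; besti <- r; basta <- pairs$astart[r]
    }
    best_idx[r] <- besti
  }
  # triples SSP2 < FISA < SSP4 (non-overlapping)
  n2 <- nrow(b24); nf <- nrow(bf)
  g <- expand.grid(i2 = seq_len(n2), if_ = seq_len(nf), i4 = seq_len(n2),
                   KEEP.OUT.ATTRS = FALSE)
  keep <- bf$start[g$if_] > b24$end[g$i2] & b24$start[g$i4] > bf$end[g$if_]
  g <- g[keep, , drop = FALSE]
  if (!nrow(g))
    return(fail(paste0("infeasible design: cannot place SSP2 < FISA < ",
                       "SSP4 without overlap in this known region")))
  # best SSP1 pair entirely upstream of each SSP2 start
  pos <- findInterval(b24$start[g$i2] - 1L, pairs$maxend)
  has_pair <- pos >= 1L
  g <- g[has_pair, , drop = FALSE]; pos <- pos[has_pair]
  if (!nrow(g))
    return(fail(paste0("infeasible design: no SSP1 pair fits upstream ",
                       "of a feasible SSP2 placement")))
  pair_row <- best_idx[pos]
  total <- b24$score[g$i2] + bf$score[g$if_] + b24$score[g$i4] +
    pairs$score[pair_row]
  ord <- order(-total, pairs$astart[pair_row], b24$start[g$i2],
               bf$start[g$if_], b24$start[g$i4], b24$length[g$i2],
               b24$length[g$i4])
  dimer_memo <- new.env(parent = emptyenv())
  for (r in ord) {
    s2 <- b24[g$i2[r], ]; s4 <- b24[g$i4[r], ]
    key <- paste0(s2$seq, "~", s4$seq)
    cd <- get0(key, envir = dimer_memo, inherits = FALSE)
    if (is.null(cd)) {
      cd <- cross_dimer_run(s2$seq, s4$seq)
      assign(key, cd, envir = dimer_memo)
    }
    if (cd >= constraints$structure$dimer_run_bp) next
    pr <- pairs[pair_row[r], ]
    return(list(chosen = list(s1a = b1[pr$a, ], s1b = b1[pr$b, ], s2 = s2,
                              f = bf[g$if_[r], ], s4 = s4,
                              total = total[r], cross_dimer = cd),
                reason = NULL))
  }
  fail(paste0("infeasible design: every ordered SSP2/SSP4 pairing shows ",
              "a severe 3'-anchored cross-dimer"))
}

# best SSP1 pair (3'-end separation respected) among candidates whose ends
# lie strictly before a given position; returns prefix tables
.ssp1_pair_table <- function(cand, min_sep) {
  n <- nrow(cand)
  if (n < 2L) return(NULL)
  ij <- which(outer(seq_len(n), seq_len(n), "<"), arr.ind = TRUE)
  i <- ij[, 1L]; j <- ij[, 2L]
  ok <- abs(cand$end[i] - cand$end[j]) >= min_sep
  i <- i[ok]; j <- j[ok]
  if (!length(i)) return(NULL)
  # alpha = leftmost start (tie: leftmost end, then sequence)
  swap <- cand$start[j] < cand$start[i] |
    (cand$start[j] == cand$start[i] & cand$end[j] < cand$end[i])
  a <- ifelse(swap, j, i); b <- ifelse(swap, i, j)
  data.frame(a = a, b = b,
             maxend = pmax(cand$end[a], cand$end[b]),
             score = cand$score[a] + cand$score[b],
             astart = cand$start[a], stringsAsFactors = FALSE)
}

#' Design a complete FPR-PCR walking-primer set
#'
#' Selects FISA, two SSP1s, SSP2 and SSP4 from the known region so that
#' the fragments lie in 5'->3' order without overlap
#' (SSP1s < SSP2 < FISA < SSP4), the two SSP1 3' ends differ by at least
#' the configured separation, and the SSP2/SSP4 pair used in one tube is
#' free of a severe 3'-anchored cross-dimer.  Among feasible sets the
#' selection maximizes the sum of per-fragment scores (Tm-window
#' centrality minus self-structure penalties); ties are broken by the
#' leftmost SSP1-alpha start and then by fixed lexicographic ordering, so
#' re-running with the same inputs reproduces the identical set.  The
#' search restricts each role to its `beam` best-scoring candidates (all
#' candidates when fewer), which is exhaustive on small regions.
#'
#' @param known known-region sequence (plus strand, 5'->3').
#' @param constraints a [design_constraints()] object.
#' @param cond [thermo_conditions()].
#' @param seed integer; reserved for breaking any ties left after the
#'   deterministic ordering (none arise with the default scoring).
#' @param beam candidates per role retained in the combinatorial search.
#' @return an object of class `fpr_walk_set`.
#' @export
design_walk_set <- function(known, constraints = design_constraints(),
                            cond = thermo_conditions(), seed = 1L,
                            beam = 60L) {
  known <- toupper(known)
  min_span <- constraints$len$ssp1 [1L] + constraints$min_three_prime_sep +
    constraints$len$ssp2_ssp4[1L] + constraints$len$fisa[1L] +
    constraints$len$ssp2_ssp4[1L]
  if (nchar(known) < min_span)
    stop("infeasible design: known region (", nchar(known),
         " nt) is too short to order SSP1, SSP2, FISA and SSP4 without ",
         "overlap (needs >= ", min_span, " nt)", call. = FALSE)
  c1  <- enumerate_candidates(known, "SSP1", constraints, cond)
  c24 <- enumerate_candidates(known, "SSP2", constraints, cond)
  cf  <- enumerate_candidates(known, "SSP3_FISA", constraints, cond)
  for (nm in list(list(c1, "SSP1"), list(c24, "SSP2/SSP4"),
                  list(cf, "FISA")))
    if (!nrow(nm[[1L]]))
      stop("infeasible design: no ", nm[[2L]],
           " candidate passes the length/structure",
           if (constraints$strict_tm) "/Tm" else "", " filters",
           call. = FALSE)
  top <- function(df, k) {
    o <- order(-df$score, df$start, df$length)
    df[o[seq_len(min(k, nrow(df)))], , drop = FALSE]
  }
  res <- .walk_search(top(c1, 2L * beam), top(c24, beam), top(cf, beam),
                      constraints)
  if (is.null(res$chosen) &&
      (nrow(c1) > 2L * beam || nrow(c24) > beam || nrow(cf) > beam)) {
    # the beam held no feasible combination; retry exhaustively on the
    # feasibility-pruned full candidate lists
    f_ok <- vapply(seq_len(nrow(cf)), function(i)
      any(c24$end < cf$start[i]) && any(c24$start > cf$end[i]),
      logical(1L))
    cf_f <- cf[f_ok, , drop = FALSE]
    if (nrow(cf_f)) {
      c24_ok <- vapply(seq_len(nrow(c24)), function(i)
        any(cf_f$start > c24$end[i]) || any(cf_f$end < c24$start[i]),
        logical(1L))
      c24_f <- c24[c24_ok, , drop = FALSE]
      b1_f <- if (nrow(c1) > 600L) top(c1, 2L * beam) else c1
      if (as.double(nrow(c24_f))^2 * nrow(cf_f) <= 5e6)
        res <- .walk_search(b1_f, c24_f, cf_f, constraints)
    }
  }
  if (is.null(res$chosen)) stop(res$reason, call. = FALSE)
  chosen <- res$chosen
  as_cand <- function(row, role) {
    p <- primer_candidate(row$seq, role, row$start, row$end, cond,
                          constraints$structure)
    p$score <- row$score
    p
  }
  s1a <- as_cand(chosen$s1a, "SSP1")
  s1b <- as_cand(chosen$s1b, "SSP1")
  fis <- as_cand(chosen$f, "SSP3_FISA")
  s2  <- as_cand(chosen$s2, "SSP2")
  s4  <- as_cand(chosen$s4, "SSP4")
  ws <- structure(list(known = known,
                       ssp1_alpha = s1a, ssp1_beta = s1b,
                       ssp2 = s2, fisa = fis, ssp4 = s4,
                       fp_alpha = assemble_fusion(fis, s1a, cond),
                       fp_beta = assemble_fusion(fis, s1b, cond),
                       score = chosen$total,
                       cross_dimer_run = chosen$cross_dimer,
                       constraints = constraints, seed = as.integer(seed)),
                  class = "fpr_walk_set")
  viol <- validate_walk_set(ws, constraints)
  if (!isTRUE(viol))
    stop("internal error: designed set violates its own invariants: ",
         paste(viol, collapse = "; "), call. = FALSE)
  tm_warn <- character(0)
  for (nm in c("ssp1_alpha", "ssp1_beta", "ssp2", "fisa", "ssp4")) {
    p <- ws[[nm]]
    w <- constraints$tm[[.role_window_key(p$role)]]
    if (p$tm < w[1L] || p$tm > w[2L])
      tm_warn <- c(tm_warn, sprintf("%s Tm %.1f C outside [%g, %g]",
                                    nm, p$tm, w[1L], w[2L]))
  }
  for (nm in c("fp_alpha", "fp_beta")) {
    w <- constraints$tm$fusion
    if (ws[[nm]]$tm < w[1L] || ws[[nm]]$tm > w[2L])
      tm_warn <- c(tm_warn, sprintf("%s Tm %.1f C outside [%g, %g]",
                                    nm, ws[[nm]]$tm, w[1L], w[2L]))
  }
  attr(ws, "tm_warnings") <- tm_warn
  ws
}

#' Check the invariants of a walking-primer set
#'
#' Verifies the 5'->3' ordering SSP1 < SSP2 < FISA < SSP4 (non-overlapping
#' in the designed layout), the SSP1 3'-end separation, role length
#' windows, fusion-length additivity and absence of severe self- or
#' cross-structure.
#'
#' @param ws an `fpr_walk_set`.
#' @param constraints a [design_constraints()] object.
#' @return `TRUE`, or a character vector naming each violated invariant.
#' @export
validate_walk_set <- function(ws, constraints = design_constraints()) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  within_win <- function(p, key)
    p$length >= constraints$len[[key]][1L] &&
    p$length <= constraints$len[[key]][2L]
  chk(max(ws$ssp1_alpha$start, ws$ssp1_beta$start) <= ws$ssp2$start &&
        max(ws$ssp1_alpha$end, ws$ssp1_beta$end) < ws$ssp2$start,
      "SSP1 fragments must lie 5' of SSP2")
  chk(ws$ssp2$start < ws$fisa$start && ws$ssp2$end < ws$fisa$start,
      "SSP2 must lie 5' of FISA")
  chk(ws$fisa$start < ws$ssp4$start && ws$fisa$end < ws$ssp4$start,
      "FISA must lie 5' of SSP4")
  chk(abs(ws$ssp1_alpha$end - ws$ssp1_beta$end) >=
        constraints$min_three_prime_sep,
      sprintf("SSP1 3'-end separation below %d nt",
              constraints$min_three_prime_sep))
  chk(within_win(ws$ssp1_alpha, "ssp1"), "SSP1-alpha length outside window")
  chk(within_win(ws$ssp1_beta, "ssp1"), "SSP1-beta length outside window")
  chk(within_win(ws$ssp2, "ssp2_ssp4"), "SSP2 length outside window")
  chk(within_win(ws$ssp4, "ssp2_ssp4"), "SSP4 length outside window")
  chk(within_win(ws$fisa, "fisa"), "FISA length outside window")
  for (nm in c("fp_alpha", "fp_beta")) {
    fp <- ws[[nm]]
    chk(fp$length == fp$fisa$length + fp$ssp1$length,
        paste(nm, "length is not |FISA| + |SSP1|"))
    chk(identical(fp$seq, paste0(fp$fisa$seq, fp$ssp1$seq)),
        paste(nm, "sequence is not FISA prepended to SSP1"))
    chk(fp$length >= constraints$len$fusion[1L] &&
          fp$length <= constraints$len$fusion[2L],
        paste(nm, "length outside the fusion window"))
  }
  for (nm in c("ssp1_alpha", "ssp1_beta", "ssp2", "fisa", "ssp4"))
    chk(!ws[[nm]]$structure$severe,
        paste(nm, "has a severe self-structure"))
  chk(cross_dimer_run(ws$ssp2$seq, ws$ssp4$seq) <
        constraints$structure$dimer_run_bp,
      "severe SSP2/SSP4 cross-dimer")
  for (nm in c("ssp1_alpha", "ssp1_beta", "ssp2", "fisa", "ssp4"))
    chk(identical(ws[[nm]]$seq,
                  substr(ws$known, ws[[nm]]$start, ws[[nm]]$end)),
        paste(nm, "sequence does not match its locus on the known region"))
  if (length(v)) v else TRUE
}

#' @export
print.fpr_walk_set <- function(x, ...) {
  cat("FPR-PCR walking-primer set (known region ", nchar(x$known),
      " nt, score ", sprintf("%.3f", x$score), ")\n", sep = "")
  for (nm in c("ssp1_alpha", "ssp1_beta", "ssp2", "fisa", "ssp4")) {
    p <- x[[nm]]
    cat(sprintf("  %-10s %-22s (%d-%d) %2d nt  Tm %.1f C\n", nm, p$seq,
                p$start, p$end, p$length, p$tm))
  }
  for (nm in c("fp_alpha", "fp_beta"))
    cat(sprintf("  %-10s %-40s %2d nt  Tm %.1f C\n", nm, x[[nm]]$seq,
                x[[nm]]$length, x[[nm]]$tm))
  w <- attr(x, "tm_warnings")
  if (length(w)) cat("  Tm warnings:", paste(w, collapse = "; "), "\n")
  invisible(x)
}

#' Primer table of a walk set
#'
#' @param ws an `fpr_walk_set`.
#' @return data.frame with columns `name`, `role`, `sequence`, `start`,
#'   `end`, `tm`.
#' @export
as_primer_table <- function(ws) {
  stopifnot(inherits(ws, "fpr_walk_set"))
  rows <- list(
    c("ssp1_alpha", "SSP1"), c("ssp1_beta", "SSP1"), c("ssp2", "SSP2"),
    c("fisa", "SSP3_FISA"), c("ssp4", "SSP4"))
  tb <- do.call(rbind, lapply(rows, function(r) {
    p <- ws[[r[1L]]]
    data.frame(name = r[1L], role = r[2L], sequence = p$seq,
               start = p$start, end = p$end, tm = p$tm,
               stringsAsFactors = FALSE)
  }))
  for (nm in c("fp_alpha", "fp_beta")) {
    fp <- ws[[nm]]
    tb <- rbind(tb, data.frame(name = nm, role = "FUSION",
                               sequence = fp$seq, start = fp$ssp1$start,
                               end = fp$ssp1$end, tm = fp$tm,
                               stringsAsFactors = FALSE))
  }
  tb
}

#' Write / read a primer table as TSV
#'
#' @param tbl a data.frame as produced by [as_primer_table()] (or an
#'   `fpr_walk_set`, which is converted).
#' @param path file path.
#' @return the table (invisibly for the writer).
#' @export
write_primer_tsv <- function(tbl, path) {
  if (inherits(tbl, "fpr_walk_set")) tbl <- as_primer_table(tbl)
  utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tbl)
}

#' @rdname write_primer_tsv
#' @export
read_primer_tsv <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = NA)
  need <- c("name", "role", "sequence")
  if (!all(need %in% names(tb)))
    stop("primer TSV must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  tb
}

#' Rebuild a walk set from a primer table and its known region
#'
#' @param tbl primer table with the seven rows written by
#'   [write_primer_tsv()] (names `ssp1_alpha`, `ssp1_beta`, `ssp2`,
#'   `fisa`, `ssp4`, `fp_alpha`, `fp_beta`).
#' @param known the known-region sequence the table was designed from.
#' @param cond [thermo_conditions()].
#' @param constraints [design_constraints()].
#' @return an `fpr_walk_set`.
#' @export
walk_set_from_table <- function(tbl, known, cond = thermo_conditions(),
                                constraints = design_constraints()) {
  known <- toupper(known)
  get_row <- function(nm) {
    r <- tbl[tbl$name == nm, , drop = FALSE]
    if (nrow(r) != 1L)
      stop("primer table must contain exactly one row named '", nm, "'",
           call. = FALSE)
    r
  }
  cand <- function(nm, role) {
    r <- get_row(nm)
    primer_candidate(r$sequence, role, r$start, r$end, cond,
                     constraints$structure)
  }
  s1a <- cand("ssp1_alpha", "SSP1"); s1b <- cand("ssp1_beta", "SSP1")
  fis <- cand("fisa", "SSP3_FISA")
  s2 <- cand("ssp2", "SSP2"); s4 <- cand("ssp4", "SSP4")
  structure(list(known = known, ssp1_alpha = s1a, ssp1_beta = s1b,
                 ssp2 = s2, fisa = fis, ssp4 = s4,
                 fp_alpha = assemble_fusion(fis, s1a, cond),
                 fp_beta = assemble_fusion(fis, s1b, cond),
                 score = NA_real_,
                 cross_dimer_run = cross_dimer_run(s2$seq, s4$seq),
                 constraints = constraints, seed = NA_integer_),
            class = "fpr_walk_set")
}

#' Quality-control report for a primer table
#'
#' Per-primer length, Tm, window status and structure flags, plus surface
#' checks of printed coordinates: a `span_mismatch` flag when the printed
#' 1-based inclusive span disagrees with the sequence length, and (when a
#' `gene` column groups primers) notes on 5'->3' ordering violations among
#' the fragment loci.  Printed sequences are trusted over printed
#' coordinates; discrepancies are surfaced, never silently repaired.
#'
#' @param primers data.frame with columns `name`, `role`, `sequence` and
#'   optionally `start`, `end`, `gene`.
#' @param constraints a [design_constraints()] object.
#' @param cond [thermo_conditions()].
#' @return data.frame (class `fpr_qc`) with one row per primer; attribute
#'   `role_summary` holds min/max length per role and attribute `notes`
#'   any ordering findings.
#' @export
check_primer_table <- function(primers, constraints = design_constraints(),
                               cond = thermo_conditions()) {
  empty <- data.frame(name = character(0), role = character(0),
                      length = integer(0), tm = numeric(0),
                      len_ok = logical(0), tm_ok = logical(0),
                      hairpin_stem = integer(0), dimer_run = integer(0),
                      severe = logical(0), span = integer(0),
                      span_mismatch = logical(0), stringsAsFactors = FALSE)
  if (is.null(primers) || !nrow(primers))
    return(structure(empty, role_summary = empty[0, 0], notes = character(0),
                     class = c("fpr_qc", "data.frame")))
  has_coord <- all(c("start", "end") %in% names(primers))
  rows <- lapply(seq_len(nrow(primers)), function(i) {
    p <- primers[i, ]
    seq <- toupper(p$sequence)
    key <- .role_window_key(p$role)
    lw <- constraints$len[[key]]; tw <- constraints$tm[[key]]
    st <- screen_structure(seq, constraints$structure)
    tm <- if (nchar(seq) >= 8L) melting_temperature(seq, cond) else NA_real_
    span <- if (has_coord && !is.na(p$start) && !is.na(p$end))
      as.integer(p$end - p$start + 1L) else NA_integer_
    data.frame(name = p$name, role = p$role, length = nchar(seq), tm = tm,
               len_ok = nchar(seq) >= lw[1L] & nchar(seq) <= lw[2L],
               tm_ok = !is.na(tm) & tm >= tw[1L] & tm <= tw[2L],
               hairpin_stem = st$longest_hairpin_stem,
               dimer_run = st$longest_3prime_dimer_run,
               severe = st$severe, span = span,
               span_mismatch = !is.na(span) & span != nchar(seq),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  role_summary <- do.call(rbind, lapply(split(out, out$role), function(d)
    data.frame(role = d$role[1L], n = nrow(d), min_len = min(d$length),
               max_len = max(d$length), stringsAsFactors = FALSE)))
  rownames(role_summary) <- NULL
  notes <- character(0)
  if (has_coord && "gene" %in% names(primers)) {
    ord_roles <- c("SSP1", "SSP2", "SSP3_FISA", "SSP4")
    for (gn in unique(primers$gene)) {
      d <- primers[primers$gene == gn & primers$role %in% ord_roles &
                     !is.na(primers$start), , drop = FALSE]
      d <- d[order(match(d$role, ord_roles)), , drop = FALSE]
      for (a in seq_len(nrow(d))) for (b in seq_len(nrow(d))) {
        if (match(d$role[a], ord_roles) >= match(d$role[b], ord_roles))
          next
        if (d$end[a] >= d$start[b])
          notes <- c(notes, sprintf(
            "%s: %s (%d-%d) overlaps or follows %s (%d-%d); printed coordinates violate the 5'->3' ordering rule",
            gn, d$name[a], d$start[a], d$end[a], d$name[b], d$start[b],
            d$end[b]))
      }
    }
  }
  structure(out, role_summary = role_summary, notes = notes,
            class = c("fpr_qc", "data.frame"))
}
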