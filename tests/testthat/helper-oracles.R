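# Independent brute-force oracles.  These deliberately avoid the package's
# code paths: sequences are handled as character vectors and every score
# is recomputed with plain loops.

ora_rc <- function(s) {
  if (!nzchar(s)) return("")
  v <- rev(strsplit(s, "", fixed = TRUE)[[1L]])
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(comp[v], collapse = "")
}

ora_comp1 <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[[b]]

# match statistics of a primer over a template window (equal lengths);
# run counts matches at the primer 3' terminus
ora_window_stats <- function(primer, window) {
  p <- strsplit(primer, "", fixed = TRUE)[[1L]]
  w <- strsplit(window, "", fixed = TRUE)[[1L]]
  stopifnot(length(p) == length(w))
  L <- length(p)
  m <- logical(L)   # oriented along the window
  for (i in seq_len(L)) {
    pb <- p[L - i + 1L]
    m[i] <- w[i] != "N" && w[i] == ora_comp1(pb)
  }
  run <- 0L
  for (i in seq_len(L)) { if (!m[i]) break; run <- run + 1L }
  list(matches = sum(m), run = run,
       mask_primer = paste(ifelse(rev(m), "|", "."), collapse = ""))
}

ora_partial_sites <- function(primer, template, min_run = 2L,
                              min_tot = 14L, max_frac = 0.6) {
  L <- nchar(primer); n <- nchar(template)
  pv <- strsplit(primer, "", fixed = TRUE)[[1L]]
  tv <- strsplit(template, "", fixed = TRUE)[[1L]]
  crp <- vapply(rev(pv), ora_comp1, "")   # pairing base per window offset
  out <- NULL
  for (w in seq_len(n - L + 1L)) {
    wv <- tv[w:(w + L - 1L)]
    m <- wv != "N" & wv == crp
    run <- 0L
    for (i in seq_len(L)) { if (!m[i]) break; run <- run + 1L }
    tot <- sum(m)
    if (run >= min_run && tot >= min_tot &&
        (L - tot) <= floor(max_frac * L + 1e-9))
      out <- rbind(out, data.frame(start = w, matches = tot, run = run))
  }
  out
}

# brute-force self-structure: hairpins over all stem/loop partitions,
# dimers over all antiparallel self-alignments anchored at the 3' end
ora_structure <- function(seq, loop_nt = 3L) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(v)
  pair <- function(i, j) v[i] != "N" && v[j] == ora_comp1(v[i])
  best_stem <- 0L
  if (n >= 2L) for (l in 1L:(n %/% 2L)) for (a in 1L:(n - 2L * l + 1L)) {
    for (b in (a + l + loop_nt):(n - l + 1L)) {
      if (b < a + l + loop_nt || b + l - 1L > n) next
      ok <- TRUE
      for (t in 0L:(l - 1L))
        if (!pair(a + t, b + l - 1L - t)) { ok <- FALSE; break }
      if (ok && l > best_stem) best_stem <- l
    }
  }
  best_dimer <- 0L
  for (j in seq_len(n)) {
    k <- 0L
    while (k < n && j + k <= n && pair(n - k, j + k)) k <- k + 1L
    if (k > best_dimer) best_dimer <- k
  }
  list(stem = best_stem, dimer = best_dimer)
}

# one synthesis event: primer 3' end pairs template position w
ora_extend <- function(primer, template, w, maxext = 10000L) {
  a <- max(1L, w - maxext)
  paste0(primer, if (w > 1L) ora_rc(substr(template, a, w - 1L)) else "")
}

# all perfect priming positions of the primer part's complement
ora_perfect_starts <- function(part, template) {
  L <- nchar(part); n <- nchar(template)
  target <- ora_rc(part)
  which(vapply(seq_len(max(n - L + 1L, 0L)), function(w)
    substr(template, w, w + L - 1L) == target, logical(1L)))
}

# event-enumeration oracle over the whole primary reaction: the pool is a
# data.frame of (seq, looped); semantics mirror the simulator's model but
# the code is an independent string implementation
ora_primary_pool <- function(genome_plus, fp_seq, ssp1_len, fisa_seq,
                             cycles = c(3L, 1L, 3L),
                             min_run = 2L, min_tot = 14L, max_frac = 0.6,
                             maxext = 10000L) {
  pool <- data.frame(seq = c(genome_plus, ora_rc(genome_plus)),
                     looped = FALSE, stringsAsFactors = FALSE)
  add <- function(pool, seq, looped) {
    i <- match(seq, pool$seq)
    if (is.na(i)) rbind(pool, data.frame(seq = seq, looped = looped))
    else pool
  }
  one_cycle <- function(pool, mode) {
    templates <- pool
    for (r in seq_len(nrow(templates))) {
      tmpl <- templates$seq[r]
      ws <- switch(mode,
        p3 = ora_perfect_starts(substr(fp_seq, nchar(fp_seq) - ssp1_len + 1L,
                                       nchar(fp_seq)), tmpl),
        full = ora_perfect_starts(fp_seq, tmpl),
        partial = if (nchar(tmpl) >= nchar(fp_seq))
          ora_partial_sites(fp_seq, tmpl, min_run, min_tot, max_frac)$start
        else integer(0))
      for (w in ws)
        pool <- add(pool, ora_extend(fp_seq, tmpl, w, maxext),
                    templates$looped[r])
    }
    pool
  }
  loopback_all <- function(pool) {
    f <- nchar(fisa_seq)
    for (r in seq_len(nrow(pool))) {
      if (pool$looped[r]) next
      s <- pool$seq[r]; n <- nchar(s)
      if (n < 2L * f) next
      if (substr(s, n - f + 1L, n) != ora_rc(fisa_seq)) next
      starts <- integer(0)
      for (w in seq_len(n - 2L * f + 1L))
        if (substr(s, w, w + f - 1L) == fisa_seq) starts <- c(starts, w)
      if (!length(starts)) next
      p <- max(starts)
      ext <- paste0(s, if (p > 1L) ora_rc(substr(s, 1L, p - 1L)) else "")
      i <- match(ext, pool$seq)
      if (is.na(i)) pool <- rbind(pool, data.frame(seq = ext, looped = TRUE))
    }
    pool
  }
  for (i in seq_len(cycles[1L])) {
    before <- nrow(pool); pool <- one_cycle(pool, "p3")
    if (nrow(pool) == before) break
  }
  for (i in seq_len(cycles[2L])) pool <- one_cycle(pool, "partial")
  for (i in seq_len(cycles[3L])) {
    before <- nrow(pool)
    pool <- one_cycle(pool, "full")
    pool <- loopback_all(pool)
    if (nrow(pool) == before) break
  }
  pool
}

ora_cross_dimer <- function(a, b) {
  anchored <- function(p, t) {
    pv <- strsplit(p, "", fixed = TRUE)[[1L]]
    tv <- strsplit(t, "", fixed = TRUE)[[1L]]
    np <- length(pv); nt <- length(tv)
    best <- 0L
    for (j in seq_len(nt)) {
      k <- 0L
      while (k < np && j + k <= nt && tv[j + k] == ora_comp1(pv[np - k]))
        k <- k + 1L
      if (k > best) best <- k
    }
    best
  }
  max(anchored(a, b), anchored(b, a))
}

ora_random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")
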