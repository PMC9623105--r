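# Thermal-program emitter: the default FPR-PCR cycling programs and their
# mapping onto the simulator's discrete annealing modes.

#' Define one thermal-cycling stage
#'
#' Temperatures in degrees Celsius, durations in seconds.  The annealing
#' mode is the simulator's discrete model of the stage's stringency:
#' moderate stringency (55 C) admits only the fusion primer's SSP1 part on
#' its exact complement (`PERFECT_3PART`), the 25 C cycle admits
#' mismatch-tolerant partial annealing (`PARTIAL`), and high stringency
#' (65 C) requires the full fusion primer (`PERFECT_FULL`).
#'
#' @param anneal_c annealing temperature.
#' @param cycles number of cycles (>= 1).
#' @param annealing_mode `"PERFECT_3PART"`, `"PARTIAL"` or
#'   `"PERFECT_FULL"`.
#' @param denature_c,denature_s,anneal_s,extend_c,extend_s remaining
#'   per-cycle parameters.
#' @return an object of class `fpr_stage`.
#' @export
cycle_stage <- function(anneal_c, cycles,
                        annealing_mode = c("PERFECT_FULL", "PERFECT_3PART",
                                           "PARTIAL"),
                        denature_c = 94, denature_s = 30, anneal_s = 30,
                        extend_c = 72, extend_s = 180) {
  annealing_mode <- match.arg(annealing_mode)
  cycles <- as.integer(cycles)
  if (cycles < 1L) stop("cycles must be >= 1", call. = FALSE)
  if (any(c(denature_c, anneal_c, extend_c) <= 0))
    stop("temperatures must be positive", call. = FALSE)
  structure(list(denature_c = denature_c, denature_s = denature_s,
                 anneal_c = anneal_c, anneal_s = anneal_s,
                 extend_c = extend_c, extend_s = extend_s,
                 cycles = cycles, annealing_mode = annealing_mode),
            class = "fpr_stage")
}

#' Default primary / secondary thermal programs
#'
#' The primary program runs three annealing stages after a 94 C 2 min
#' denaturation: five moderate-stringency cycles (55 C), one
#' low-stringency cycle (25 C) and thirty high-stringency cycles (65 C),
#' each cycle 94 C 30 s / anneal 30 s / 72 C 3 min, with a final 72 C
#' 10 min extension.  The secondary program is twenty-five cycles at 60 C
#' annealing with the same cycle layout.
#'
#' @return list of [cycle_stage()] objects.
#' @export
primary_program <- function() {
  list(cycle_stage(55, 5L, "PERFECT_3PART"),
       cycle_stage(25, 1L, "PARTIAL"),
       cycle_stage(65, 30L, "PERFECT_FULL"))
}

#' @rdname primary_program
#' @export
secondary_program <- function() {
  list(cycle_stage(60, 25L, "PERFECT_FULL"))
}

#' Emit a thermal-cycling protocol
#'
#' @param which `"primary"` or `"secondary"`.
#' @return an object of class `fpr_protocol` with fields `round`, `init`
#'   (temperature, seconds), `stages` and `final`; its `format()` method
#'   renders the human-readable program and [protocol_config()] the
#'   machine-readable list.
#' @export
emit_protocol <- function(which = c("primary", "secondary")) {
  which <- match.arg(which)
  structure(list(round = which,
                 init = c(temp_c = 94, seconds = 120),
                 stages = if (which == "primary") primary_program()
                          else secondary_program(),
                 final = c(temp_c = 72, seconds = 600)),
            class = "fpr_protocol")
}

.fmt_secs <- function(s) {
  if (s %% 60 == 0 && s >= 60) paste0(s %/% 60, " min") else paste0(s, " s")
}

#' @export
format.fpr_protocol <- function(x, ...) {
  title <- paste0(toupper(substr(x$round, 1, 1)), substr(x$round, 2, nchar(x$round)))
  lines <- c(sprintf("%s PCR", title),
             sprintf("  %g C %s", x$init["temp_c"], .fmt_secs(x$init["seconds"])))
  for (st in x$stages)
    lines <- c(lines, sprintf(
      "  [%g C %s, %g C %s, %g C %s] x %d  (annealing mode %s)",
      st$denature_c, .fmt_secs(st$denature_s),
      st$anneal_c, .fmt_secs(st$anneal_s),
      st$extend_c, .fmt_secs(st$extend_s), st$cycles, st$annealing_mode))
  lines <- c(lines, sprintf("  %g C %s", x$final["temp_c"],
                            .fmt_secs(x$final["seconds"])))
  paste(lines, collapse = "\n")
}

#' @export
print.fpr_protocol <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Machine-readable protocol configuration
#'
#' @param x an `fpr_protocol`.
#' @return a plain list suitable for [yaml::write_yaml()].
#' @export
protocol_config <- function(x) {
  stopifnot(inherits(x, "fpr_protocol"))
  list(round = x$round,
       init = as.list(x$init),
       stages = lapply(x$stages, function(st) unclass(st)),
       final = as.list(x$final))
}

#' Parse a protocol configuration back into an `fpr_protocol`
#'
#' `parse_protocol(protocol_config(p))` reproduces `p` exactly.
#'
#' @param cfg a list as produced by [protocol_config()] (e.g. read back
#'   from YAML).
#' @return an `fpr_protocol`.
#' @export
parse_protocol <- function(cfg) {
  stages <- lapply(cfg$stages, function(st)
    cycle_stage(anneal_c = st$anneal_c, cycles = st$cycles,
                annealing_mode = st$annealing_mode,
                denature_c = st$denature_c, denature_s = st$denature_s,
                anneal_s = st$anneal_s, extend_c = st$extend_c,
                extend_s = st$extend_s))
  structure(list(round = cfg$round,
                 init = c(temp_c = as.numeric(cfg$init$temp_c),
                          seconds = as.numeric(cfg$init$seconds)),
                 stages = stages,
                 final = c(temp_c = as.numeric(cfg$final$temp_c),
                           seconds = as.numeric(cfg$final$seconds))),
            class = "fpr_protocol")
}
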