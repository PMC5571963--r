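#' Define a CSP-recognition motif rule
#'
#' Two kinds of rule describe the U-rich elements recognized by bacterial
#' cold-shock proteins (CSPs). An `exact_set` rule matches any of a list
#' of literal words (T and U are equivalent; everything is scanned on the
#' DNA alphabet). An `interrupted_run` rule matches a fixed-length window
#' that is a run of T except for at most one interrupting base, with
#' per-position constraints on where the interruption may sit and which
#' bases may interrupt there.
#'
#' @param id Short rule identifier.
#' @param kind `"exact_set"` or `"interrupted_run"`.
#' @param patterns For `exact_set`: character vector of literal words
#'   (U accepted, normalized to T).
#' @param run_length For `interrupted_run`: window length (default 7).
#' @param allowed_bases For `interrupted_run`: named list mapping the
#'   1-based interruption position (within the window) to the bases
#'   allowed to interrupt there, e.g. `list("2" = c("A","G"))`. Positions
#'   absent from the list may not be interrupted.
#' @param require_interruption For `interrupted_run`: if `TRUE` a pure
#'   uninterrupted T-run does not match; if `FALSE` it does.
#' @param description Free-text note.
#' @return An object of class `motif_rule`.
#' @export
motif_rule <- function(id, kind, patterns = NULL, run_length = 7L,
                       allowed_bases = NULL, require_interruption = TRUE,
                       description = "") {
  kind <- match.arg(kind, c("exact_set", "interrupted_run"))
  if (kind == "exact_set") {
    if (is.null(patterns) || !length(patterns)) {
      stop_param("motif_rule: exact_set needs at least one pattern")
    }
    patterns <- normalize_seq(patterns)
    if (any(grepl("[^ACGT]", patterns))) {
      stop_param("motif_rule: patterns must be over A/C/G/T/U")
    }
  } else {
    if (run_length < 2) stop_param("motif_rule: run_length must be >= 2")
    if (is.null(allowed_bases) || !length(allowed_bases)) {
      stop_param("motif_rule: interrupted_run needs allowed interruption positions")
    }
    pos <- as.integer(names(allowed_bases))
    if (any(is.na(pos)) || any(pos < 1) || any(pos > run_length)) {
      stop_param("motif_rule: interruption positions must lie within the window")
    }
    bad <- setdiff(unlist(allowed_bases), c("A", "C", "G"))
    if (length(bad)) {
      stop_param("motif_rule: interrupting bases must be among A/C/G (got %s)",
                 paste(bad, collapse = ","))
    }
  }
  structure(list(id = id, kind = kind, patterns = patterns,
                 run_length = as.integer(run_length),
                 allowed_bases = allowed_bases,
                 require_interruption = isTRUE(require_interruption),
                 description = description),
            class = "motif_rule")
}

#' Built-in CSP-recognition element definitions
#'
#' Returns the five recognition-element rules used for the weak- versus
#' strong-binder comparison, ordered from most to least specific:
#'
#' * `R1`: the heptamer `TTCTTTT` (B. subtilis CspB SELEX consensus).
#' * `R2`: `GTCTTTT` or `GTCTTTG` (degenerate-end heptamer).
#' * `R3`: `GTCTTTT`/`GTCTTTA` or the hexamer `TTTTTT`.
#' * `R4`: a 7-base T/U run interrupted by exactly one purine at
#'   positions 2-5, excluding G at position 3 (TmCsp-style element).
#' * `R5`: a 7-base T/U run with at most one interruption at positions
#'   2-6, excluding G at position 3 and purines at position 6 (CspE
#'   element). By default an uninterrupted T7 run also matches, as the
#'   limiting U-rich case; set `require_interruption = TRUE` to demand
#'   the interruption.
#'
#' All rules operate on DNA (U is normalized to T before scanning).
#'
#' @param require_interruption Passed to rule `R5` (default `FALSE`).
#' @return List of five `motif_rule` objects named `R1`..`R5`.
#' @export
compile_builtin_rules <- function(require_interruption = FALSE) {
  list(
    R1 = motif_rule("R1", "exact_set", patterns = "TTCTTTT",
                    description = "CspB heptamer TTCTTTT"),
    R2 = motif_rule("R2", "exact_set", patterns = c("GTCTTTT", "GTCTTTG"),
                    description = "CspB GTCTTTT/G"),
    R3 = motif_rule("R3", "exact_set",
                    patterns = c("GTCTTTT", "GTCTTTA", "TTTTTT"),
                    description = "CspB GUCUUUU/A or UUUUUU"),
    R4 = motif_rule("R4", "interrupted_run", run_length = 7L,
                    allowed_bases = list("2" = c("A", "G"),
                                         "3" = "A",
                                         "4" = c("A", "G"),
                                         "5" = c("A", "G")),
                    require_interruption = TRUE,
                    description = "7-base T/U run with one purine interruption at 2-5, no G at 3"),
    R5 = motif_rule("R5", "interrupted_run", run_length = 7L,
                    allowed_bases = list("2" = c("A", "C", "G"),
                                         "3" = c("A", "C"),
                                         "4" = c("A", "C", "G"),
                                         "5" = c("A", "C", "G"),
                                         "6" = "C"),
                    require_interruption = require_interruption,
                    description = "7-base U run interrupted at one of positions 2-6, no G at 3, no purine at 6")
  )
}

# Uppercase and map U -> T. Accepts vectors.
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Test whether a window satisfies a motif rule
#'
#' @param window A string exactly as long as the rule's window (for
#'   `exact_set` rules, any of the pattern lengths).
#' @param rule A `motif_rule`.
#' @return Logical.
#' @export
match_rule_window <- function(window, rule) {
  w <- normalize_seq(window)
  if (rule$kind == "exact_set") {
    return(w %in% rule$patterns)
  }
  if (nchar(w) != rule$run_length) return(FALSE)
  ch <- strsplit(w, "")[[1]]
  non_t <- which(ch != "T")
  if (any(!ch %in% c("A", "C", "G", "T"))) return(FALSE)
  if (length(non_t) == 0) return(!rule$require_interruption)
  if (length(non_t) > 1) return(FALSE)
  p <- as.character(non_t)
  !is.null(rule$allowed_bases[[p]]) && ch[non_t] %in% rule$allowed_bases[[p]]
}
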