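#' Scan a nucleotide sequence for motif-rule sites
#'
#' Slides every window of the rule's length(s) along the sense strand,
#' records raw matching windows, and collapses overlapping raw matches
#' into maximal sites (greedy left-to-right merge): without collapsing,
#' one biological element such as `TTTTATTTT` would be counted up to
#' three times by adjacent sliding windows. Both collapsed sites and the
#' raw window count are returned.
#'
#' @param seq A nucleotide string over `A/C/G/T/U/N` (case-insensitive;
#'   U is normalized to T, N never matches).
#' @param rule A `motif_rule`.
#' @param collapse If `FALSE`, raw windows are returned as individual
#'   sites without merging.
#' @return A data.frame with columns `start`, `end` (1-based inclusive),
#'   `match` (the matched subsequence) and `n_windows` (raw windows
#'   merged into the site), sorted by `start`. Zero rows when nothing
#'   matches or the sequence is empty.
#' @export
scan_sequence <- function(seq, rule, collapse = TRUE) {
  stopifnot(inherits(rule, "motif_rule"))
  if (length(seq) != 1 || !is.character(seq)) {
    stop_param("scan_sequence: 'seq' must be a single string")
  }
  s <- normalize_seq(seq)
  if (nchar(s) == 0) return(empty_sites())
  if (grepl("[^ACGTN]", s)) {
    stop_param("scan_sequence: illegal characters in sequence (allowed: A/C/G/T/U/N)")
  }
  widths <- if (rule$kind == "exact_set") {
    sort(unique(nchar(rule$patterns)))
  } else {
    rule$run_length
  }
  starts <- integer(0)
  ends <- integer(0)
  ch <- strsplit(s, "")[[1]]
  for (w in widths) {
    if (nchar(s) < w) next
    n_win <- nchar(s) - w + 1L
    if (rule$kind == "exact_set") {
      pats <- rule$patterns[nchar(rule$patterns) == w]
      hit <- rep(FALSE, n_win)
      for (p in pats) {
        m <- gregexpr(paste0("(?=", p, ")"), s, perl = TRUE)[[1]]
        if (m[1] != -1) hit[m] <- TRUE
      }
      idx <- which(hit)
    } else {
      # candidate windows: at most one non-T, no N
      bad <- ch != "T"
      cs <- cumsum(c(0L, as.integer(bad)))
      n_bad <- cs[seq_len(n_win) + w] - cs[seq_len(n_win)]
      idx <- which(n_bad <= 1L)
      if (length(idx)) {
        keep <- vapply(idx, function(i) {
          match_rule_window(substr(s, i, i + w - 1L), rule)
        }, logical(1))
        idx <- idx[keep]
      }
    }
    starts <- c(starts, idx)
    ends <- c(ends, idx + w - 1L)
  }
  if (!length(starts)) return(empty_sites())
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  if (!collapse) {
    return(data.frame(start = starts, end = ends,
                      match = substring(s, starts, ends),
                      n_windows = 1L, stringsAsFactors = FALSE))
  }
  merge_windows(starts, ends, s)
}

empty_sites <- function() {
  data.frame(start = integer(0), end = integer(0),
             match = character(0), n_windows = integer(0),
             stringsAsFactors = FALSE)
}

# Greedy left-to-right merge of overlapping [start, end] windows into
# maximal sites.
merge_windows <- function(starts, ends, s) {
  ms <- starts[1]; me <- ends[1]; nw <- 1L
  out_s <- integer(0); out_e <- integer(0); out_n <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) {
      me <- max(me, ends[i]); nw <- nw + 1L
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me); out_n <- c(out_n, nw)
      ms <- starts[i]; me <- ends[i]; nw <- 1L
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me); out_n <- c(out_n, nw)
  data.frame(start = out_s, end = out_e,
             match = substring(s, out_s, out_e),
             n_windows = out_n, stringsAsFactors = FALSE)
}

#' Scan many sequences with many rules
#'
#' @param sequences Named character vector or `Biostrings::DNAStringSet`
#'   of coding sequences.
#' @param rules List of `motif_rule` objects (default the built-in five).
#' @param collapse Merge overlapping windows into maximal sites
#'   (default `TRUE`).
#' @return Data frame of sites: `gene_id`, `rule_id`, `start`, `end`,
#'   `match`, `n_windows`.
#' @export
scan_sequences <- function(sequences, rules = compile_builtin_rules(),
                           collapse = TRUE) {
  sequences <- as_seq_vector(sequences)
  out <- list()
  for (g in names(sequences)) {
    for (r in rules) {
      sites <- scan_sequence(sequences[[g]], r, collapse = collapse)
      if (nrow(sites)) {
        sites$gene_id <- g
        sites$rule_id <- r$id
        out[[length(out) + 1L]] <- sites
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(0), rule_id = character(0),
                      start = integer(0), end = integer(0),
                      match = character(0), n_windows = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[, c("gene_id", "rule_id", "start", "end", "match", "n_windows")]
}

as_seq_vector <- function(sequences) {
  if (inherits(sequences, "XStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop_param("sequences must have unique names")
  }
  sequences
}

#' Per-rule, per-group motif count table
#'
#' For each rule and each named gene group, counts the genes that
#' contain at least one site and the total number of sites summed over
#' the group, and formats the cell as `"g (s)"` — the layout used to
#' compare CSP-recognition element content between weak and strong
#' CspE-binder mRNA groups.
#'
#' @param sequences Named character vector / `DNAStringSet` covering
#'   every gene listed in `groups`.
#' @param groups Named list of gene-id character vectors.
#' @param rules List of `motif_rule` objects.
#' @param collapse Count collapsed maximal sites (default) or raw
#'   windows.
#' @return A list: `counts` (long data.frame: `rule_id`, `group`,
#'   `genes_with_site`, `total_sites`, `cell`) and `table` (rule x group
#'   matrix of formatted cells).
#' @export
count_table <- function(sequences, groups, rules = compile_builtin_rules(),
                        collapse = TRUE) {
  sequences <- as_seq_vector(sequences)
  if (is.null(names(groups))) stop_param("count_table: 'groups' must be named")
  missing <- setdiff(unique(unlist(groups)), names(sequences))
  if (length(missing)) {
    stop_param("count_table: no sequence for genes: %s",
               paste(utils::head(missing, 10), collapse = ", "))
  }
  rows <- list()
  for (r in rules) {
    for (gname in names(groups)) {
      ids <- groups[[gname]]
      n_sites <- vapply(ids, function(g) {
        nrow(scan_sequence(sequences[[g]], r, collapse = collapse))
      }, integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        rule_id = r$id, group = gname,
        genes_with_site = sum(n_sites > 0),
        total_sites = sum(n_sites),
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  counts$cell <- sprintf("%d (%d)", counts$genes_with_site, counts$total_sites)
  tab <- matrix("", nrow = length(rules), ncol = length(groups),
                dimnames = list(vapply(rules, `[[`, "", "id"), names(groups)))
  for (i in seq_len(nrow(counts))) {
    tab[counts$rule_id[i], counts$group[i]] <- counts$cell[i]
  }
  list(counts = counts, table = tab)
}

#' Convert 1-based inclusive motif sites to BED intervals
#'
#' @param sites Site data.frame from [scan_sequences()].
#' @return Data frame with BED columns `chrom`, `start` (0-based),
#'   `end` (half-open), `name`.
#' @export
sites_to_bed <- function(sites) {
  data.frame(chrom = sites$gene_id,
             start = sites$start - 1L,
             end = sites$end,
             name = sites$rule_id,
             stringsAsFactors = FALSE)
}
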