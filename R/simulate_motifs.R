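#' Simulate coding sequences with planted motif sites
#'
#' Builds one synthetic CDS per catalog gene such that the motif scanner
#' has an exactly known ground truth: the background sequence is
#' rejection-sampled so that it contains no accidental match to any of
#' the supplied rules, and the requested number of sites per rule is
#' planted at non-overlapping positions, each flanked by `CC` so that no
#' window straddling a planted site can create a spurious raw match or
#' merge two planted sites into one.
#'
#' A planted window can legitimately satisfy more than one rule (the
#' recognition-element definitions overlap: e.g. `TTCTTTT` is both the
#' exact CspB heptamer and a C-interrupted T7 run), so the returned
#' truth records, for every rule, the sites expected from the full set
#' of planted windows — not just the windows planted "for" that rule.
#'
#' @param catalog Gene catalog ([build_gene_catalog()]); CDS lengths are
#'   taken from it.
#' @param rules List of `motif_rule` objects (default built-in five).
#' @param plant_counts Gene x rule integer matrix (rownames = gene ids,
#'   colnames = rule ids): how many sites of each rule to plant per
#'   gene. Genes absent from the rownames get none.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling attempts per gene before a
#'   capacity error.
#' @return List with `sequences` (named character vector),
#'   `truth` (data.frame `gene_id`, `rule_id`, `start`, `end`, `match`)
#'   giving every expected collapsed site per rule, and
#'   `planted` (data.frame of the windows as planted: `gene_id`,
#'   `rule_id`, `start`, `end`, `window`).
#' @export
simulate_transcripts_with_motifs <- function(catalog,
                                             rules = compile_builtin_rules(),
                                             plant_counts = NULL,
                                             seed = 1L,
                                             max_tries = 200L) {
  validate_catalog(catalog)
  rule_ids <- vapply(rules, `[[`, "", "id")
  names(rules) <- rule_ids
  if (is.null(plant_counts)) {
    plant_counts <- matrix(0L, nrow = nrow(catalog), ncol = length(rules),
                           dimnames = list(catalog$gene_id, rule_ids))
  }
  if (is.null(rownames(plant_counts)) || is.null(colnames(plant_counts))) {
    stop_param("plant_counts must have gene rownames and rule colnames")
  }
  bad_rule <- setdiff(colnames(plant_counts), rule_ids)
  if (length(bad_rule)) {
    stop_param("plant_counts names unknown rules: %s", paste(bad_rule, collapse = ", "))
  }
  seqs <- character(nrow(catalog))
  names(seqs) <- catalog$gene_id
  planted <- list()
  local_seed(seed, {
    for (gi in seq_len(nrow(catalog))) {
      g <- catalog$gene_id[gi]
      len <- catalog$cds_length[gi]
      want <- if (g %in% rownames(plant_counts)) plant_counts[g, ] else
        stats::setNames(rep(0L, length(rules)), rule_ids)
      # each planted window occupies window + 4 nt (CC flanks both sides)
      windows <- unlist(lapply(names(want)[want > 0], function(rid) {
        replicate(want[[rid]], sample_rule_window(rules[[rid]]))
      }))
      rule_of <- rep(names(want)[want > 0], times = want[want > 0])
      need <- sum(nchar(windows) + 4L)
      if (need > len) {
        stop_param("gene %s: cannot plant %d sites in %d nt", g, length(windows), len)
      }
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        s <- plant_in_background(len, windows, rules)
        if (!is.null(s)) { ok <- TRUE; break }
      }
      if (!ok) {
        stop_param("gene %s: failed to place %d sites after %d tries",
                   g, length(windows), max_tries)
      }
      seqs[g] <- s$seq
      if (length(windows)) {
        planted[[length(planted) + 1L]] <- data.frame(
          gene_id = g, rule_id = rule_of, start = s$starts,
          end = s$starts + nchar(windows) - 1L, window = windows,
          stringsAsFactors = FALSE)
      }
    }
  })
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(gene_id = character(0), rule_id = character(0),
               start = integer(0), end = integer(0), window = character(0),
               stringsAsFactors = FALSE)
  truth <- expected_sites_from_planted(seqs, planted, rules)
  list(sequences = seqs, truth = truth, planted = planted)
}

# Draw a literal window satisfying the rule. For exact sets, pick a
# pattern; for interrupted runs, pick an allowed position and base.
sample_rule_window <- function(rule) {
  if (rule$kind == "exact_set") {
    return(rule$patterns[sample.int(length(rule$patterns), 1)])
  }
  pos <- as.integer(names(rule$allowed_bases))
  p <- pos[sample.int(length(pos), 1)]
  b <- rule$allowed_bases[[as.character(p)]]
  b <- b[sample.int(length(b), 1)]
  ch <- rep("T", rule$run_length)
  ch[p] <- b
  paste(ch, collapse = "")
}

# Background alphabet avoids T entirely so no T-run or T-containing
# literal can arise by chance; planted windows carry their own T's and
# the CC flanks stop windows from bridging into the background.
plant_in_background <- function(len, windows, rules) {
  bg <- sample(c("A", "C", "G"), len, replace = TRUE)
  if (!length(windows)) {
    return(list(seq = paste(bg, collapse = ""), starts = integer(0)))
  }
  blocks <- paste0("CC", windows, "CC")
  sizes <- nchar(blocks)
  # choose non-overlapping placements by sampling block order positions
  slack <- len - sum(sizes)
  if (slack < 0) return(NULL)
  k <- length(blocks)
  ord <- sample.int(k)
  gaps <- if (slack > 0) {
    g <- stats::rmultinom(1, slack, rep(1, k + 1))[, 1]
    as.integer(g)
  } else rep(0L, k + 1)
  seq_chars <- bg
  pos <- 1L
  starts <- integer(k)
  for (j in seq_len(k)) {
    pos <- pos + gaps[j]
    b <- blocks[ord[j]]
    seq_chars[pos:(pos + nchar(b) - 1L)] <- strsplit(b, "")[[1]]
    starts[ord[j]] <- pos + 2L  # inside the CC flank
    pos <- pos + nchar(b)
  }
  s <- paste(seq_chars, collapse = "")
  # verify: every rule's collapsed sites must coincide with windows planted
  # inside the flanked blocks (no bridging, no accidental background hits)
  for (r in rules) {
    sites <- scan_sequence(s, r)
    if (nrow(sites) == 0) next
    win_ok <- vapply(seq_len(nrow(sites)), function(i) {
      any(sites$start[i] >= starts & sites$end[i] <= starts + nchar(windows) - 1L)
    }, logical(1))
    if (!all(win_ok)) return(NULL)
  }
  list(seq = s, starts = starts)
}

# Ground truth per rule: apply the rule's window predicate to every
# planted window (cross-rule matches included), then collapse — planted
# windows are isolated, so each matching window is one collapsed site.
expected_sites_from_planted <- function(seqs, planted, rules) {
  out <- list()
  for (r in rules) {
    if (nrow(planted)) {
      for (i in seq_len(nrow(planted))) {
        w <- planted$window[i]
        hit <- if (r$kind == "exact_set") {
          # an exact pattern may sit inside a longer planted window
          any(vapply(r$patterns, function(p) grepl(p, w, fixed = TRUE), logical(1)))
        } else {
          nchar(w) == r$run_length && match_rule_window(w, r)
        }
        if (hit) {
          out[[length(out) + 1L]] <- data.frame(
            gene_id = planted$gene_id[i], rule_id = r$id,
            start = planted$start[i], end = planted$end[i],
            match = w, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(0), rule_id = character(0),
                      start = integer(0), end = integer(0), match = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$rule_id, res$gene_id, res$start), ]
}
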