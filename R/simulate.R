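#' Fractionation experiment simulation design
#'
#' Describes a synthetic cell-fractionation RNA-seq experiment: how many
#' genes of each localization class, which subcellular fractions are
#' sequenced, replication, sequencing depth, and how much of each library
#' is consumed by ribosomal/non-coding RNA. The defaults emulate a
#' triplicate bacterial fractionation study: a total extract reference,
#' a ribosome-free gradient top, a 70S monosome pool, flotation-purified
#' membranes, and a pull-down input/elution pair. Fractions that contain
#' ribosomes lose most of their reads to rRNA; the ribosome-free fraction
#' sequences mRNA far more efficiently, which is encoded by its lower
#' `rrna_load`.
#'
#' @param n_mpr Number of membrane-protein-encoding mRNAs (MPRs).
#' @param n_cpr Number of cytoplasmic-protein-encoding mRNAs (CPRs).
#' @param n_other Number of non-mRNA features (rRNA/tRNA/ncRNA rows).
#' @param fractions Character vector of fraction labels; must contain
#'   `"extract"`, the whole-cell reference.
#' @param n_replicates Libraries per fraction.
#' @param library_size Expected mapped reads per library.
#' @param rrna_load Proportion of each library's reads consumed by
#'   non-mRNA features; scalar or named per-fraction vector, in `[0, 1)`.
#' @param dispersion Negative-binomial dispersion of counts (0 gives
#'   Poisson). The default 0.01 (biological coefficient of variation
#'   0.1) is the conventional scale for replicate libraries of a
#'   genetically identical organism grown in one culture.
#' @param seed Master integer seed; per-library substreams are derived
#'   from it by a fixed counter scheme.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(n_mpr = 200, n_cpr = 800, n_other = 12,
                       fractions = c("extract", "ribosome-free", "70S",
                                     "membrane", "pulldown-input",
                                     "pulldown-elution"),
                       n_replicates = 3,
                       library_size = 5e6,
                       rrna_load = c("extract" = 0.85, "ribosome-free" = 0.10,
                                     "70S" = 0.95, "membrane" = 0.90,
                                     "pulldown-input" = 0.10,
                                     "pulldown-elution" = 0.10),
                       dispersion = 0.01,
                       seed = 1L) {
  for (fld in c("n_mpr", "n_cpr", "n_other")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v)) {
      stop_param("sim_design: '%s' must be a single non-negative integer", fld)
    }
  }
  if (n_mpr + n_cpr + n_other < 1) {
    stop_param("sim_design: at least one gene is required (n_mpr + n_cpr + n_other >= 1)")
  }
  if (!"extract" %in% fractions) {
    stop_param("sim_design: 'fractions' must include \"extract\"")
  }
  if (anyDuplicated(fractions)) {
    stop_param("sim_design: 'fractions' must be unique")
  }
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    stop_param("sim_design: 'n_replicates' must be >= 1")
  }
  if (!is.numeric(library_size) || library_size <= 0) {
    stop_param("sim_design: 'library_size' must be positive")
  }
  if (any(rrna_load < 0) || any(rrna_load >= 1)) {
    stop_param("sim_design: 'rrna_load' must lie in [0, 1)")
  }
  if (length(rrna_load) == 1 && is.null(names(rrna_load))) {
    rrna_load <- stats::setNames(rep(rrna_load, length(fractions)), fractions)
  }
  missing_fr <- setdiff(fractions, names(rrna_load))
  if (length(missing_fr)) {
    stop_param("sim_design: 'rrna_load' missing fractions: %s",
               paste(missing_fr, collapse = ", "))
  }
  if (!is.numeric(dispersion) || dispersion < 0) {
    stop_param("sim_design: 'dispersion' must be >= 0")
  }
  structure(list(n_mpr = as.integer(n_mpr), n_cpr = as.integer(n_cpr),
                 n_other = as.integer(n_other),
                 fractions = fractions,
                 n_replicates = as.integer(n_replicates),
                 library_size = library_size,
                 rrna_load = rrna_load[fractions],
                 dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Build a synthetic gene catalog
#'
#' Generates per-gene identifiers, CDS lengths and class labels for a
#' simulated experiment. CDS lengths are log-normal with median 900 nt,
#' truncated to `[100, 6000]` nt, which matches the scale of bacterial
#' coding sequences. MPRs and CPRs are mRNA features; the remaining rows
#' are non-coding background (rRNA/tRNA/ncRNA) that the quantification
#' stage must filter out before RPKM calculation.
#'
#' @param design A [sim_design()] object.
#' @return A `data.frame` with columns `gene_id`, `cds_length`,
#'   `loc_class` (`MPR`/`CPR`/`other`) and `feature_class`
#'   (`mRNA`/`rRNA`/`tRNA`/`ncRNA`).
#' @export
build_gene_catalog <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  n <- design$n_mpr + design$n_cpr + design$n_other
  local_seed(design$seed, {
    lens <- round(stats::rlnorm(n, meanlog = log(900), sdlog = 0.6))
    lens <- pmin(pmax(lens, 100L), 6000L)
    ids <- c(sprintf("mpr_%04d", seq_len(design$n_mpr) + 0L)[seq_len(design$n_mpr)],
             sprintf("cpr_%04d", seq_len(design$n_cpr))[seq_len(design$n_cpr)],
             sprintf("nc_%04d", seq_len(design$n_other))[seq_len(design$n_other)])
    loc <- c(rep("MPR", design$n_mpr), rep("CPR", design$n_cpr),
             rep("other", design$n_other))
    feat <- c(rep("mRNA", design$n_mpr + design$n_cpr),
              if (design$n_other > 0) {
                sample(c("rRNA", "tRNA", "ncRNA"), design$n_other, replace = TRUE)
              })
    # rRNA operon rows are long and dominate ribosome-containing libraries
    if (design$n_other > 0) {
      lens[loc == "other" & feat == "rRNA"] <- 2900L
      lens[loc == "other" & feat == "tRNA"] <- 100L
    }
    data.frame(gene_id = ids, cds_length = as.integer(lens),
               loc_class = loc, feature_class = feat,
               stringsAsFactors = FALSE)
  })
}

#' Construct simulation ground truth
#'
#' Assigns every gene a baseline abundance and a per-fraction enrichment
#' multiplier (relative concentration in the fraction versus the total
#' extract; the extract multiplier is fixed at 1). Class-level effects
#' are given as a matrix of multipliers; optional per-gene log2-normal
#' scatter makes effects heterogeneous across genes of a class.
#'
#' @param catalog Gene catalog from [build_gene_catalog()].
#' @param design A [sim_design()] object.
#' @param class_multipliers Named list: for each localization class, a
#'   named numeric vector of per-fraction multipliers. Fractions not
#'   named default to 1; `extract` is always 1.
#' @param gene_sd Per-gene log2 standard deviation around the class
#'   multiplier. The default 1.0 makes classes overlap broadly along
#'   the enrichment landscape, as fractionation data show (class effects
#'   are averages, not uniform shifts); set 0 for exact class effects.
#' @param baseline_sdlog Log-sd of the log-normal baseline abundances.
#' @param seed Integer seed; defaults to `design$seed + 1`.
#' @return An object of class `sim_truth`: list with `baseline` (named
#'   vector) and `multipliers` (gene x fraction matrix, extract column 1).
#' @export
make_sim_truth <- function(catalog, design,
                           class_multipliers = list(
                             MPR = c("ribosome-free" = 2, "70S" = 0.7,
                                     "membrane" = 2, "pulldown-elution" = 4),
                             CPR = c("ribosome-free" = 0.8, "70S" = 1.3,
                                     "membrane" = 0.8, "pulldown-elution" = 0.5)),
                           gene_sd = 1.0, baseline_sdlog = 1.0,
                           seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  validate_catalog(catalog)
  seed <- seed %||% (design$seed + 1L)
  n <- nrow(catalog)
  fr <- design$fractions
  local_seed(seed, {
    baseline <- stats::setNames(stats::rlnorm(n, meanlog = 3, sdlog = baseline_sdlog),
                                catalog$gene_id)
    mult <- matrix(1, nrow = n, ncol = length(fr),
                   dimnames = list(catalog$gene_id, fr))
    for (cls in names(class_multipliers)) {
      rows <- which(catalog$loc_class == cls)
      if (!length(rows)) next
      cm <- class_multipliers[[cls]]
      for (f in intersect(names(cm), fr)) {
        eff <- rep(cm[[f]], length(rows))
        if (gene_sd > 0) {
          eff <- eff * 2^stats::rnorm(length(rows), 0, gene_sd)
        }
        mult[rows, f] <- eff
      }
    }
    mult[, "extract"] <- 1
    structure(list(baseline = baseline, multipliers = mult),
              class = "sim_truth")
  })
}

check_truth_coverage <- function(truth, catalog, design) {
  stopifnot(inherits(truth, "sim_truth"))
  miss_g <- setdiff(catalog$gene_id, names(truth$baseline))
  if (length(miss_g)) {
    stop_param("truth does not cover genes: %s",
               paste(utils::head(miss_g, 5), collapse = ", "))
  }
  miss_g <- setdiff(catalog$gene_id, rownames(truth$multipliers))
  if (length(miss_g)) {
    stop_param("truth multipliers missing genes: %s",
               paste(utils::head(miss_g, 5), collapse = ", "))
  }
  miss_f <- setdiff(design$fractions, colnames(truth$multipliers))
  if (length(miss_f)) {
    stop_param("truth multipliers missing fractions: %s",
               paste(miss_f, collapse = ", "))
  }
  if (any(truth$multipliers <= 0)) {
    stop_param("truth multipliers must be positive")
  }
  if (any(abs(truth$multipliers[catalog$gene_id, "extract"] - 1) > 1e-12)) {
    stop_param("extract multipliers must equal 1")
  }
  invisible(TRUE)
}

#' Simulate fractionation RNA-seq count libraries
#'
#' Draws one count library per fraction x replicate. Within a library,
#' the expected mRNA read share is `1 - rrna_load` for that fraction and
#' is divided among mRNAs proportionally to
#' `baseline x multiplier x length`; the remaining share goes to the
#' non-mRNA background rows. Counts are negative-binomial with the
#' design's dispersion (Poisson when dispersion is 0). Each library uses
#' a seed substream derived from the master seed and the library counter,
#' so adding libraries never perturbs existing ones.
#'
#' @param catalog Gene catalog.
#' @param design A [sim_design()].
#' @param truth A `sim_truth` covering every gene and fraction.
#' @return A list of class `count_matrix`: `counts` (gene x sample
#'   integer matrix), `samples` (data.frame: `sample_id`, `fraction`,
#'   `replicate`).
#' @export
simulate_fraction_counts <- function(catalog, design, truth) {
  stopifnot(inherits(design, "sim_design"))
  validate_catalog(catalog)
  check_truth_coverage(truth, catalog, design)
  genes <- catalog$gene_id
  is_mrna <- catalog$feature_class == "mRNA"
  base <- truth$baseline[genes]
  len <- catalog$cds_length
  samples <- expand.grid(replicate = seq_len(design$n_replicates),
                         fraction = design$fractions,
                         stringsAsFactors = FALSE)[, c("fraction", "replicate")]
  samples$sample_id <- sprintf("%s_rep%d", samples$fraction, samples$replicate)
  counts <- matrix(0L, nrow = length(genes), ncol = nrow(samples),
                   dimnames = list(genes, samples$sample_id))
  for (i in seq_len(nrow(samples))) {
    f <- samples$fraction[i]
    w <- base * truth$multipliers[genes, f] * len
    mu <- numeric(length(genes))
    load <- design$rrna_load[[f]]
    if (any(is_mrna)) {
      share <- if (any(!is_mrna)) 1 - load else 1
      mu[is_mrna] <- design$library_size * share * w[is_mrna] / sum(w[is_mrna])
    }
    if (any(!is_mrna)) {
      w_bg <- base[!is_mrna] * len[!is_mrna]
      mu[!is_mrna] <- design$library_size * load * w_bg / sum(w_bg)
    }
    # substream counter indexed by (fraction position, replicate): adding
    # replicates or appending fractions never perturbs existing libraries
    counter <- (match(f, design$fractions) - 1L) * 1000L + samples$replicate[i]
    counts[, i] <- local_seed(substream_seed(design$seed, counter), {
      as.integer(if (design$dispersion > 0) {
        stats::rnbinom(length(mu), mu = mu, size = 1 / design$dispersion)
      } else {
        stats::rpois(length(mu), lambda = mu)
      })
    })
  }
  count_matrix(counts, samples[, c("sample_id", "fraction", "replicate")])
}

#' Count matrix constructor
#'
#' @param counts Integer gene x sample matrix with dimnames.
#' @param samples Data frame with columns `sample_id`, `fraction`,
#'   `replicate`, one row per column of `counts`.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples) {
  if ((nrow(counts) > 0 && is.null(rownames(counts))) || is.null(colnames(counts))) {
    stop_param("count_matrix: 'counts' needs gene and sample dimnames")
  }
  req <- c("sample_id", "fraction", "replicate")
  if (!all(req %in% names(samples))) {
    stop_param("count_matrix: 'samples' needs columns %s", paste(req, collapse = ", "))
  }
  if (!identical(colnames(counts), samples$sample_id)) {
    stop_param("count_matrix: sample metadata does not match count columns")
  }
  if (any(counts < 0)) stop_param("count_matrix: counts must be >= 0")
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$fraction), collapse = ", ")))
  invisible(x)
}

validate_catalog <- function(catalog) {
  req <- c("gene_id", "cds_length", "loc_class", "feature_class")
  if (!is.data.frame(catalog) || !all(req %in% names(catalog))) {
    stop_param("catalog must be a data.frame with columns %s",
               paste(req, collapse = ", "))
  }
  if (anyDuplicated(catalog$gene_id)) stop_param("catalog gene ids must be unique")
  if (any(catalog$cds_length < 1)) stop_param("catalog cds_length must be >= 1")
  invisible(TRUE)
}
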