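# Prepropeptide hallmark screening: basic cleavage motifs, amidation-site
# prediction, in-silico precursor processing and secretory topology.
#
# Coordinates are 1-based closed intervals throughout. Cleavage occurs
# C-terminal to the last residue of a motif (convertase convention: after
# the P1 basic residue). Sequences may contain X; X never matches a motif.

.valid_aa <- c(names(.residue_mono), "X")

.check_valid_protein_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L)
    stop("sequence must be a single non-empty string", call. = FALSE)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), .valid_aa)
  if (length(bad) > 0L)
    stop("invalid residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  aa
}

#' Protein record
#'
#' The unit of motif screening: a sequence plus optional external
#' annotations (signal peptide, transmembrane helices).
#'
#' @param id Protein identifier.
#' @param sequence Amino-acid sequence (20 canonical letters + X; stored
#'   uppercase).
#' @param has_signal_peptide Optional logical.
#' @param signal_peptide_end Optional 1-based index of the last signal
#'   peptide residue.
#' @param tmh_spans Optional 2-column matrix (or list of length-2 vectors)
#'   of 1-based closed TMH intervals; must lie within the sequence and be
#'   non-overlapping.
#' @param annotation_source `"external"` or `"heuristic"`.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, has_signal_peptide = NA,
                           signal_peptide_end = NA_integer_,
                           tmh_spans = NULL,
                           annotation_source = "external") {
  aa <- .check_valid_protein_sequence(sequence)
  n <- length(aa)
  if (!is.na(signal_peptide_end) &&
      (signal_peptide_end < 1L || signal_peptide_end > n))
    stop("signal_peptide_end outside sequence", call. = FALSE)
  if (!is.null(tmh_spans)) {
    if (is.list(tmh_spans)) tmh_spans <- do.call(rbind, tmh_spans)
    if (length(tmh_spans) == 0L) {
      tmh_spans <- matrix(integer(), ncol = 2L)
    } else {
      tmh_spans <- matrix(as.integer(tmh_spans), ncol = 2L)
      if (any(tmh_spans[, 1L] > tmh_spans[, 2L]) ||
          any(tmh_spans < 1L) || any(tmh_spans > n))
        stop("tmh_spans outside [1, length] or inverted", call. = FALSE)
      o <- order(tmh_spans[, 1L])
      tmh_spans <- tmh_spans[o, , drop = FALSE]
      if (nrow(tmh_spans) > 1L &&
          any(tmh_spans[-1L, 1L] <= tmh_spans[-nrow(tmh_spans), 2L]))
        stop("tmh_spans overlap", call. = FALSE)
    }
    colnames(tmh_spans) <- c("start", "end")
  }
  structure(list(id = as.character(id),
                 sequence = paste(aa, collapse = ""),
                 has_signal_peptide = as.logical(has_signal_peptide),
                 signal_peptide_end = as.integer(signal_peptide_end),
                 tmh_spans = tmh_spans,
                 annotation_source = annotation_source),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa; SP=%s, TMH=%s)\n", x$id,
              nchar(x$sequence),
              ifelse(is.na(x$has_signal_peptide), "?", x$has_signal_peptide),
              if (is.null(x$tmh_spans)) "?" else nrow(x$tmh_spans)))
  invisible(x)
}

.as_record <- function(x) {
  if (inherits(x, "protein_record")) x else protein_record("seq", x)
}

#' Scan for basic cleavage motifs
#'
#' Finds prohormone convertase sites (a pair of basic residues,
#' (K/R)(K/R)) and furin-like sites (R-X-(K/R)-R). All matches of the
#' requested motif kinds are reported, including overlapping ones; a motif
#' window containing X is rejected.
#'
#' @param record A [protein_record()] or a bare sequence string.
#' @param kinds Non-empty subset of `c("PC", "FURIN")`.
#' @return data.frame with `kind`, `start`, `end` (motif span) and
#'   `cleavage_after` (= motif end; the scissile bond is C-terminal to this
#'   residue), sorted by start then end.
#' @examples
#' scan_cleavage_sites("AAKRGA")          # one PC site, span [3,4]
#' @export
scan_cleavage_sites <- function(record, kinds = c("PC", "FURIN")) {
  record <- .as_record(record)
  kinds <- unique(toupper(kinds))
  if (length(kinds) == 0L || !all(kinds %in% c("PC", "FURIN")))
    stop("kinds must be a non-empty subset of {PC, FURIN}", call. = FALSE)
  aa <- strsplit(record$sequence, "")[[1]]
  n <- length(aa)
  basic <- aa %in% c("K", "R")
  rows <- list()
  if ("PC" %in% kinds && n >= 2L) {
    i <- which(basic[-n] & basic[-1L])
    if (length(i) > 0L)
      rows$pc <- data.frame(kind = "PC", start = i, end = i + 1L,
                            cleavage_after = i + 1L)
  }
  if ("FURIN" %in% kinds && n >= 4L) {
    i <- which(aa[seq_len(n - 3L)] == "R" &
               aa[seq_len(n - 3L) + 1L] != "X" &
               basic[seq_len(n - 3L) + 2L] &
               aa[seq_len(n - 3L) + 3L] == "R")
    if (length(i) > 0L)
      rows$furin <- data.frame(kind = "FURIN", start = i, end = i + 3L,
                               cleavage_after = i + 3L)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(kind = character(), start = integer(),
                      end = integer(), cleavage_after = integer())
  rownames(out) <- NULL
  out[order(out$start, out$end), , drop = FALSE]
}

.cterm_amidation_site <- function(aa, max_basic_run) {
  # C-terminal Gly or Gly(K/R)n with 1 <= n <= max_basic_run.
  n <- length(aa)
  if (n >= 2L && aa[n] == "G")
    return(data.frame(class = "CTERM_GLY", glycine_index = n,
                      amidated_residue = n - 1L))
  run <- 0L
  while (run < n && aa[n - run] %in% c("K", "R")) run <- run + 1L
  if (run >= 1L && run <= max_basic_run) {
    g <- n - run
    if (g >= 2L && aa[g] == "G")
      return(data.frame(class = "CTERM_GLY_BASIC", glycine_index = g,
                        amidated_residue = g - 1L))
  }
  NULL
}

#' Predict amidation sites
#'
#' A residue becomes amidated when the glycine immediately C-terminal to it
#' is removed by peptidylglycine alpha-amidating monooxygenase (PAM).
#' Internal sites require a Gly immediately N-terminal to a cleavage motif;
#' C-terminal sites are a terminal Gly, or a Gly followed only by a short
#' run of basic residues (removable by carboxypeptidase B-like trimming).
#' A Gly at position 1 never yields a site (there is no residue to
#' amidate). When the same glycine abuts both a FURIN match and its
#' embedded PC pair, the FURIN classification takes precedence.
#'
#' @param record A [protein_record()] or sequence string.
#' @param sites Cleavage sites from [scan_cleavage_sites()] on the same
#'   record; computed if `NULL`.
#' @param max_basic_run Maximum length of the C-terminal (K/R)n run
#'   (default 3, covering the "-GRRR" precursor terminus).
#' @return data.frame with `class` (INTERNAL_PC, INTERNAL_FURIN, CTERM_GLY,
#'   CTERM_GLY_BASIC), `glycine_index` and `amidated_residue`.
#' @export
predict_amidation_sites <- function(record, sites = NULL, max_basic_run = 3L) {
  if (!is.numeric(max_basic_run) || max_basic_run < 1)
    stop("max_basic_run must be >= 1", call. = FALSE)
  record <- .as_record(record)
  if (is.null(sites)) sites <- scan_cleavage_sites(record)
  aa <- strsplit(record$sequence, "")[[1]]
  out <- list()
  if (nrow(sites) > 0L) {
    g <- sites$start - 1L
    ok <- g >= 2L & aa[pmax(g, 1L)] == "G"
    if (any(ok)) {
      internal <- data.frame(
        class = ifelse(sites$kind[ok] == "FURIN", "INTERNAL_FURIN",
                       "INTERNAL_PC"),
        glycine_index = g[ok],
        amidated_residue = g[ok] - 1L)
      # FURIN precedence when one glycine abuts motifs of both kinds
      internal <- internal[order(internal$glycine_index,
                                 internal$class != "INTERNAL_FURIN"), ]
      internal <- internal[!duplicated(internal$glycine_index), ]
      out$internal <- internal
    }
  }
  out$cterm <- .cterm_amidation_site(aa, as.integer(max_basic_run))
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(class = character(), glycine_index = integer(),
                      amidated_residue = integer())
  rownames(res) <- NULL
  res[order(res$glycine_index), , drop = FALSE]
}

#' Precursor processing configuration
#'
#' @param max_basic_run Maximum C-terminal K/R residues trimmed per
#'   fragment (carboxypeptidase B-like step; default 3).
#' @param min_length Minimum product length retained (default 3).
#' @param his_trim Also remove a single C-terminal His exposed after basic
#'   trimming (default `FALSE`; carboxypeptidase B-like enzymes can remove
#'   C-terminal His, a route needed by one of the identified precursors).
#' @param kinds Cleavage motif kinds used, see [scan_cleavage_sites()].
#' @export
processing_config <- function(max_basic_run = 3L, min_length = 3L,
                              his_trim = FALSE, kinds = c("PC", "FURIN")) {
  stopifnot(max_basic_run >= 1, min_length >= 1)
  list(max_basic_run = as.integer(max_basic_run),
       min_length = as.integer(min_length),
       his_trim = isTRUE(his_trim), kinds = kinds)
}

#' In-silico precursor processing
#'
#' Models the canonical secretory processing cascade: (1) endoproteolytic
#' cleavage C-terminal to every PC/furin site, (2) carboxypeptidase B-like
#' trimming of C-terminal K/R runs (optionally one His), (3) PAM-mediated
#' amidation when the exposed C terminus is glycine (the Gly is removed and
#' the product marked amidated). Non-amidated fragments are also returned.
#' The annotated signal peptide region is excluded.
#'
#' @param record A [protein_record()] or sequence string.
#' @param config A [processing_config()].
#' @return data.frame with `parent_id`, `start`, `end` (span of the
#'   retained residues in the parent), `sequence`, `amidated` and
#'   `glycine_extended_sequence` (sequence + "G" for amidated products,
#'   `NA` otherwise).
#' @examples
#' process_precursor("VLYPNDPAAYAAYAPGTGGGATIGRRR")
#' @export
process_precursor <- function(record, config = processing_config()) {
  record <- .as_record(record)
  aa <- strsplit(record$sequence, "")[[1]]
  n <- length(aa)
  offset <- 0L
  if (isTRUE(record$has_signal_peptide) && !is.na(record$signal_peptide_end))
    offset <- record$signal_peptide_end
  if (offset >= n) return(.empty_products())
  mature <- aa[(offset + 1L):n]
  m <- length(mature)
  sites <- scan_cleavage_sites(paste(mature, collapse = ""),
                               kinds = config$kinds)
  cuts <- sort(unique(sites$cleavage_after))
  cuts <- cuts[cuts < m]
  bounds <- c(0L, cuts, m)
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    s <- bounds[i] + 1L
    e <- bounds[i + 1L]
    frag <- mature[s:e]
    # carboxypeptidase B-like trimming
    trimmed <- 0L
    while (trimmed < config$max_basic_run && length(frag) > 0L &&
           frag[length(frag)] %in% c("K", "R")) {
      frag <- frag[-length(frag)]
      trimmed <- trimmed + 1L
    }
    if (config$his_trim && trimmed > 0L && length(frag) > 0L &&
        frag[length(frag)] == "H")
      frag <- frag[-length(frag)]
    amidated <- FALSE
    if (length(frag) >= 2L && frag[length(frag)] == "G") {
      frag <- frag[-length(frag)]
      amidated <- TRUE
    }
    if (length(frag) == 0L) next
    if (length(frag) < config$min_length) {
      warning(sprintf("dropping product of length %d (< min_length %d) from %s",
                      length(frag), config$min_length, record$id),
              call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      parent_id = record$id,
      start = offset + s,
      end = offset + s + length(frag) - 1L,
      sequence = paste(frag, collapse = ""),
      amidated = amidated,
      glycine_extended_sequence =
        if (amidated) paste(c(frag, "G"), collapse = "") else NA_character_)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(.empty_products())
  rownames(res) <- NULL
  res
}

.empty_products <- function() {
  data.frame(parent_id = character(), start = integer(), end = integer(),
             sequence = character(), amidated = logical(),
             glycine_extended_sequence = character())
}

#' Secretory-pathway topology classification
#'
#' Deterministic function of the signal peptide flag and TMH count:
#' Sig+/0 TMH = SECRETED; Sig+/1 TMH = TYPE_I_MEMBRANE; Sig-/1 TMH starting
#' within the first 60 residues = TYPE_II_MEMBRANE (signal-anchor,
#' cytoplasmic N terminus); >= 2 TMH = MULTIPASS; otherwise NON_SECRETORY.
#' A single Sig- TMH starting after residue 60 carries no recognizable
#' secretory targeting signal and is classified NON_SECRETORY.
#'
#' @param record A [protein_record()] with both annotations present (a TMH
#'   annotation may be an empty matrix).
#' @return One of `"SECRETED"`, `"TYPE_I_MEMBRANE"`, `"TYPE_II_MEMBRANE"`,
#'   `"MULTIPASS"`, `"NON_SECRETORY"`.
#' @export
classify_topology <- function(record) {
  if (!inherits(record, "protein_record"))
    stop("classify_topology requires a protein_record", call. = FALSE)
  if (is.na(record$has_signal_peptide) || is.null(record$tmh_spans))
    stop("annotation required: has_signal_peptide and tmh_spans must be set",
         call. = FALSE)
  n_tmh <- nrow(record$tmh_spans)
  sig <- isTRUE(record$has_signal_peptide)
  if (n_tmh >= 2L) return("MULTIPASS")
  if (sig && n_tmh == 0L) return("SECRETED")
  if (sig && n_tmh == 1L) return("TYPE_I_MEMBRANE")
  if (!sig && n_tmh == 1L && record$tmh_spans[1L, 1L] <= 60L)
    return("TYPE_II_MEMBRANE")
  "NON_SECRETORY"
}

# Kyte-Doolittle hydropathy values
.kd_hydropathy <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
                    X = 0)

#' Heuristic signal peptide prediction
#'
#' A deliberately simple hydropathy stand-in for dedicated predictors: the
#' protein is called signal-peptide-positive when the mean Kyte-Doolittle
#' hydropathy of the h-region window (residues 6-20) exceeds
#' `h_threshold` and the n-region (residues 1-5) contains a basic residue.
#' The predicted cleavage position is fixed at residue 22. Output is
#' flagged as heuristic.
#'
#' @param record A [protein_record()] or sequence string.
#' @param h_threshold Mean hydropathy threshold (default 1.0).
#' @return list with `has_signal_peptide`, `signal_peptide_end`, `source`.
#' @export
predict_signal_peptide <- function(record, h_threshold = 1.0) {
  record <- .as_record(record)
  aa <- strsplit(record$sequence, "")[[1]]
  n <- length(aa)
  has_sp <- FALSE
  if (n >= 20L) {
    h_region <- mean(.kd_hydropathy[aa[6:20]])
    n_region_basic <- any(aa[1:5] %in% c("K", "R"))
    has_sp <- h_region > h_threshold && n_region_basic
  }
  list(has_signal_peptide = has_sp,
       signal_peptide_end = if (has_sp) min(22L, n) else NA_integer_,
       source = "heuristic")
}

#' Heuristic transmembrane helix prediction
#'
#' Sliding 19-residue Kyte-Doolittle window; every maximal run of window
#' positions whose mean hydropathy exceeds `threshold` becomes one TMH span
#' (the union of the contributing windows). Output is flagged heuristic.
#'
#' @param record A [protein_record()] or sequence string.
#' @param threshold Window mean threshold (default 1.6).
#' @param window Window width (default 19).
#' @return 2-column matrix of 1-based closed TMH spans (possibly 0 rows).
#' @export
predict_tmh <- function(record, threshold = 1.6, window = 19L) {
  record <- .as_record(record)
  aa <- strsplit(record$sequence, "")[[1]]
  n <- length(aa)
  empty <- matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (n < window) return(empty)
  h <- .kd_hydropathy[aa]
  win_mean <- stats::filter(h, rep(1 / window, window), sides = 1)
  starts_ok <- which(!is.na(win_mean) & win_mean > threshold) - window + 1L
  if (length(starts_ok) == 0L) return(empty)
  # merge consecutive window starts into spans
  breaks <- c(0L, which(diff(starts_ok) > 1L), length(starts_ok))
  spans <- t(vapply(seq_len(length(breaks) - 1L), function(i) {
    s <- starts_ok[(breaks[i] + 1L):breaks[i + 1L]]
    c(min(s), max(s) + window - 1L)
  }, integer(2)))
  colnames(spans) <- c("start", "end")
  spans
}

#' Fill missing annotations with heuristics
#'
#' @param record A [protein_record()].
#' @return The record, with heuristic signal peptide / TMH annotations
#'   filled in where absent and `annotation_source` updated.
#' @export
annotate_record <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  used_heuristic <- FALSE
  if (is.na(record$has_signal_peptide)) {
    sp <- predict_signal_peptide(record)
    record$has_signal_peptide <- sp$has_signal_peptide
    record$signal_peptide_end <- sp$signal_peptide_end
    used_heuristic <- TRUE
  }
  if (is.null(record$tmh_spans)) {
    record$tmh_spans <- predict_tmh(record)
    used_heuristic <- TRUE
  }
  if (used_heuristic) record$annotation_source <- "heuristic"
  record
}

#' Proteome-wide prepropeptide screen
#'
#' Applies the motif scan and amidation-site prediction to the
#' signal-peptide-containing subset of a proteome and tallies proteins per
#' category, mirroring a genome-wide precursor census: proteins with PC
#' sites, PC sites with adjacent amidation sites, furin sites, furin sites
#' with amidation sites, C-terminal Gly, and C-terminal Gly(K/R)n. Records
#' missing annotations are completed heuristically via [annotate_record()].
#'
#' @param records List of [protein_record()] objects.
#' @param max_basic_run See [predict_amidation_sites()].
#' @return list with `summary` (one-row data.frame of protein-level counts:
#'   `n_total`, `n_signal`, `n_pc_sites`, `n_pc_amidation`, `n_furin_sites`,
#'   `n_furin_amidation`, `n_cterm_gly`, `n_cterm_gly_basic`) and
#'   `annotations` (one row per amidation site found in the signal subset).
#' @export
screen_proteome <- function(records, max_basic_run = 3L) {
  stopifnot(is.list(records))
  records <- lapply(records, annotate_record)
  n_total <- length(records)
  sig <- vapply(records, function(r) isTRUE(r$has_signal_peptide), logical(1))
  counts <- c(n_total = n_total, n_signal = sum(sig), n_pc_sites = 0L,
              n_pc_amidation = 0L, n_furin_sites = 0L,
              n_furin_amidation = 0L, n_cterm_gly = 0L,
              n_cterm_gly_basic = 0L)
  ann <- list()
  for (r in records[sig]) {
    sites <- scan_cleavage_sites(r)
    amid <- predict_amidation_sites(r, sites, max_basic_run = max_basic_run)
    has_pc <- any(sites$kind == "PC")
    has_furin <- any(sites$kind == "FURIN")
    counts["n_pc_sites"] <- counts["n_pc_sites"] + has_pc
    counts["n_furin_sites"] <- counts["n_furin_sites"] + has_furin
    counts["n_pc_amidation"] <- counts["n_pc_amidation"] +
      (has_pc && any(amid$class == "INTERNAL_PC"))
    counts["n_furin_amidation"] <- counts["n_furin_amidation"] +
      (has_furin && any(amid$class == "INTERNAL_FURIN"))
    counts["n_cterm_gly"] <- counts["n_cterm_gly"] +
      any(amid$class == "CTERM_GLY")
    counts["n_cterm_gly_basic"] <- counts["n_cterm_gly_basic"] +
      any(amid$class == "CTERM_GLY_BASIC")
    if (nrow(amid) > 0L)
      ann[[length(ann) + 1L]] <- cbind(id = r$id, amid)
  }
  annotations <- do.call(rbind, ann)
  if (is.null(annotations))
    annotations <- data.frame(id = character(), class = character(),
                              glycine_index = integer(),
                              amidated_residue = integer())
  rownames(annotations) <- NULL
  list(summary = as.data.frame(as.list(counts)), annotations = annotations)
}
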