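# Spectral-count table operations and the Gly-loss + amide evidence screen.
#
# A detection matrix is a plain numeric matrix: rows = proteins, columns =
# samples, entries = (possibly normalized) spectral counts.

.check_detection_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("counts must be a numeric matrix (proteins x samples)", call. = FALSE)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("counts matrix needs protein rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(colnames(mat)))
    stop("sample ids must be unique", call. = FALSE)
  if (any(mat < 0)) stop("counts must be nonnegative", call. = FALSE)
  invisible(mat)
}

#' Normalize spectral counts to the average sample total
#'
#' Each sample's counts are scaled by (mean of all sample totals) / (that
#' sample's total), so that after normalization every sample total equals
#' the pre-normalization mean total. The grand total is conserved exactly.
#'
#' @param mat Numeric protein x sample matrix with dimnames.
#' @return The normalized matrix, with per-sample scale factors in
#'   attribute `"scale_factors"`.
#' @export
normalize_counts <- function(mat) {
  .check_detection_matrix(mat)
  totals <- colSums(mat)
  if (any(totals == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(mat)[totals == 0], collapse = ", "), call. = FALSE)
  f <- mean(totals) / totals
  out <- sweep(mat, 2L, f, `*`)
  attr(out, "scale_factors") <- f
  out
}

#' Replicate presence filter
#'
#' Retains proteins detected (nonzero count) in at least `min_samples`
#' samples; the study's merged dataset eliminated proteins recognized in
#' fewer than four of the six samples.
#'
#' @param mat Numeric protein x sample matrix.
#' @param min_samples Integer in `[1, ncol(mat)]`.
#' @return The filtered matrix (row order preserved).
#' @export
presence_filter <- function(mat, min_samples) {
  .check_detection_matrix(mat)
  if (!is.numeric(min_samples) || length(min_samples) != 1L ||
      min_samples < 1 || min_samples > ncol(mat))
    stop("min_samples must be in [1, n_samples]", call. = FALSE)
  keep <- rowSums(mat > 0) >= min_samples
  mat[keep, , drop = FALSE]
}

#' Abundance share of the top-k proteins
#'
#' Fraction of the total (mean per-protein) spectral counts contributed by
#' the k most abundant proteins. Ties are broken by a stable sort on
#' protein id, making the share deterministic.
#'
#' @param mean_counts Named nonnegative numeric vector of per-protein mean
#'   counts, or a detection matrix (row means are taken).
#' @param k Number of top proteins, `0 <= k <= length(mean_counts)`.
#' @return Fraction in `[0, 1]`.
#' @examples
#' abundance_share(c(a = 50, b = 30, c = 20), 1)  # 0.5
#' @export
abundance_share <- function(mean_counts, k) {
  if (is.matrix(mean_counts)) mean_counts <- rowMeans(mean_counts)
  if (is.null(names(mean_counts)))
    stop("mean_counts must be named by protein id", call. = FALSE)
  if (any(mean_counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (k < 0 || k > length(mean_counts))
    stop("k must be in [0, n proteins]", call. = FALSE)
  total <- sum(mean_counts)
  if (total == 0) stop("abundance share undefined: total counts are zero",
                       call. = FALSE)
  if (k == 0) return(0)
  o <- order(-mean_counts, names(mean_counts))
  sum(mean_counts[o][seq_len(k)]) / total
}

#' Merge two detection matrices by protein id
#'
#' Column concatenation keyed on protein id; proteins absent from one
#' dataset get zero counts there (used to merge the two 3-replicate
#' datasets into one six-sample matrix).
#'
#' @param a,b Detection matrices with disjoint sample ids.
#' @return Merged matrix over the union of proteins.
#' @export
merge_detection_matrices <- function(a, b) {
  .check_detection_matrix(a); .check_detection_matrix(b)
  if (length(intersect(colnames(a), colnames(b))) > 0L)
    stop("sample ids must be disjoint", call. = FALSE)
  ids <- union(rownames(a), rownames(b))
  out <- matrix(0, nrow = length(ids), ncol = ncol(a) + ncol(b),
                dimnames = list(ids, c(colnames(a), colnames(b))))
  out[rownames(a), colnames(a)] <- a
  out[rownames(b), colnames(b)] <- b
  out
}

#' Candidate amidated peptides for the evidence screen
#'
#' Candidates come from two routes mirroring the engine-level dynamic
#' modification: (A) in-silico precursor processing products that are
#' amidated, digested with trypsin, keeping the (amide-bearing) C-terminal
#' fragments; (B) every database tryptic peptide ending in glycine, with
#' the Gly-loss + amide delta applied.
#'
#' @param proteome List of [protein_record()] objects.
#' @param processing A [processing_config()].
#' @param digest A [digest_config()].
#' @return data.frame with `peptide` (amidated form),
#'   `glycine_extended_parent` (= peptide + "G"), `parent_protein_id`,
#'   `route` ("processed" or "tryptic_G") and `mono_mass` (neutral
#'   monoisotopic mass of the amidated peptide). Duplicates within a parent
#'   are removed, the processed route taking precedence.
#' @export
build_amidation_candidates <- function(proteome,
                                       processing = processing_config(),
                                       digest = digest_config()) {
  stopifnot(is.list(proteome))
  rows <- list()
  for (rec in proteome) {
    rec <- .as_record(rec)
    if (grepl("X", rec$sequence, fixed = TRUE)) next  # mass undefined
    # Route A: processed amidated products, tryptic C-terminal fragments
    prods <- suppressWarnings(process_precursor(rec, processing))
    for (i in which(prods$amidated)) {
      pep_tab <- tryptic_digest(prods$sequence[i], digest)
      cterm <- pep_tab[pep_tab$end == nchar(prods$sequence[i]), , drop = FALSE]
      for (p in cterm$peptide)
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = p, glycine_extended_parent = paste0(p, "G"),
          parent_protein_id = rec$id, route = "processed")
    }
    # Route B: database tryptic peptides ending in G
    pep_tab <- tryptic_digest(rec$sequence, digest)
    gly <- pep_tab$peptide[substring(pep_tab$peptide,
                                     nchar(pep_tab$peptide)) == "G" &
                           nchar(pep_tab$peptide) >= 2L]
    for (p in unique(gly))
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = substr(p, 1L, nchar(p) - 1L),
        glycine_extended_parent = p,
        parent_protein_id = rec$id, route = "tryptic_G")
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(peptide = character(),
                      glycine_extended_parent = character(),
                      parent_protein_id = character(), route = character(),
                      mono_mass = numeric()))
  out <- out[order(out$parent_protein_id, out$peptide,
                   out$route != "processed"), ]
  out <- out[!duplicated(out[, c("peptide", "parent_protein_id")]), ]
  out$mono_mass <- vapply(out$glycine_extended_parent, function(s)
    peptide_mass(s, modifications = "C_TERM_GLY_LOSS_AMIDE", scale = "mono"),
    numeric(1), USE.NAMES = FALSE)
  rownames(out) <- NULL
  out
}

#' Gly-loss + amide evidence screen with replicate consensus
#'
#' For each peptide-spectrum match (PSM), the observed neutral mass is
#' tested against the theoretical monoisotopic mass of every candidate
#' amidated peptide (see [build_amidation_candidates()]). Matches within
#' `tol_ppm` become calls; calls are aggregated per (peptide, parent) with
#' their supporting samples, and only peptides supported in at least
#' `min_samples` samples survive the replicate consensus. The screen itself
#' is deterministic.
#'
#' @param psms data.frame with columns `sample_id`, `peptide_sequence`,
#'   `observed_neutral_mass` (Da, > 0), `parent_protein_id`.
#' @param proteome List of [protein_record()] objects.
#' @param tol_ppm Precursor mass tolerance (default 10 ppm, the search
#'   engine setting).
#' @param min_samples Replicate consensus threshold (default 6, the
#'   headline all-six-samples screen).
#' @param processing,digest Candidate-generation configuration.
#' @return data.frame with one row per consensus call: `peptide`,
#'   `glycine_extended_parent`, `parent_protein_id`, `route`, `n_samples`,
#'   `supporting_samples` (";"-joined), `mean_abs_error_ppm`,
#'   `max_abs_error_ppm`.
#' @export
gly_loss_amide_screen <- function(psms, proteome, tol_ppm = 10,
                                  min_samples = 6L,
                                  processing = processing_config(),
                                  digest = digest_config()) {
  need <- c("sample_id", "observed_neutral_mass")
  if (!is.data.frame(psms) || !all(need %in% names(psms)))
    stop("psms must have columns sample_id and observed_neutral_mass",
         call. = FALSE)
  if (any(psms$observed_neutral_mass <= 0))
    stop("observed_neutral_mass must be positive", call. = FALSE)
  cand <- build_amidation_candidates(proteome, processing, digest)
  if (nrow(cand) == 0L) {
    warning("no candidate amidated peptides in proteome", call. = FALSE)
    return(.empty_calls())
  }
  if (nrow(psms) == 0L) return(.empty_calls())
  # ppm error of every PSM against every candidate
  err <- outer(psms$observed_neutral_mass, cand$mono_mass,
               function(o, t) (o - t) / t * 1e6)
  hits <- which(abs(err) <= tol_ppm, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(.empty_calls())
  matched <- data.frame(
    peptide = cand$peptide[hits[, 2L]],
    glycine_extended_parent = cand$glycine_extended_parent[hits[, 2L]],
    parent_protein_id = cand$parent_protein_id[hits[, 2L]],
    route = cand$route[hits[, 2L]],
    sample_id = psms$sample_id[hits[, 1L]],
    error_ppm = err[hits])
  key <- paste(matched$peptide, matched$parent_protein_id, sep = "\r")
  calls <- lapply(split(matched, key), function(g) {
    samples <- sort(unique(g$sample_id))
    data.frame(peptide = g$peptide[1L],
               glycine_extended_parent = g$glycine_extended_parent[1L],
               parent_protein_id = g$parent_protein_id[1L],
               route = g$route[1L],
               n_samples = length(samples),
               supporting_samples = paste(samples, collapse = ";"),
               mean_abs_error_ppm = mean(abs(g$error_ppm)),
               max_abs_error_ppm = max(abs(g$error_ppm)))
  })
  out <- do.call(rbind, calls)
  out <- out[out$n_samples >= min_samples, , drop = FALSE]
  out <- out[order(out$parent_protein_id, out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_calls <- function() {
  data.frame(peptide = character(), glycine_extended_parent = character(),
             parent_protein_id = character(), route = character(),
             n_samples = integer(), supporting_samples = character(),
             mean_abs_error_ppm = numeric(), max_abs_error_ppm = numeric())
}
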