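# Readers/writers for the interchange formats (FASTA, TSV/CSV, Newick),
# run configuration and the umbrella pipeline driver. All formats are
# plain text; every artifact gets a provenance sidecar.

#' Read protein sequences from FASTA
#'
#' Accepts wrapped and single-line dialects; ids are the header up to the
#' first whitespace; sequences are uppercased; duplicate ids are rejected.
#'
#' @param path FASTA file path.
#' @return List of [protein_record()] objects (annotations unset).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  mapply(function(id, s) protein_record(id, toupper(s)),
         ids, as.character(set), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, character(1),
                                         "sequence"))
  names(seqs) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a signal-peptide / TMH annotation table
#'
#' Tab-separated columns: `id`, `signal_peptide` (0/1), `sp_end`,
#' `tmh_spans` (semicolon-separated "start-end" intervals, empty for
#' none).
#'
#' @param path TSV path.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(tmh_spans = "character"))
  need <- c("id", "signal_peptide", "sp_end", "tmh_spans")
  if (!all(need %in% names(ann)))
    stop("annotation TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ann
}

.parse_tmh_spans <- function(s) {
  if (is.na(s) || !nzchar(s)) return(matrix(integer(), ncol = 2L))
  parts <- strsplit(strsplit(s, ";")[[1]], "-")
  do.call(rbind, lapply(parts, function(p) as.integer(p)))
}

#' Merge external annotations into protein records
#'
#' @param records List of [protein_record()] objects.
#' @param annotations data.frame from [read_annotations()].
#' @return The records with annotations applied (ids not in the table are
#'   left unannotated).
#' @export
merge_annotations <- function(records, annotations) {
  idx <- match(vapply(records, `[[`, character(1), "id"), annotations$id)
  for (i in seq_along(records)) {
    j <- idx[i]
    if (is.na(j)) next
    records[[i]] <- protein_record(
      records[[i]]$id, records[[i]]$sequence,
      has_signal_peptide = annotations$signal_peptide[j] == 1,
      signal_peptide_end = annotations$sp_end[j],
      tmh_spans = .parse_tmh_spans(annotations$tmh_spans[j]),
      annotation_source = "external")
  }
  records
}

#' Read / write a spectral-count matrix
#'
#' First column = protein id, header row = sample ids; tab- or
#' comma-separated by file extension.
#'
#' @param path File path (.tsv/.txt = tab, .csv = comma).
#' @return Numeric matrix (proteins x samples).
#' @export
read_count_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_count_matrix
#' @param mat Matrix to write.
#' @export
write_count_matrix <- function(mat, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(protein = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write PSM tables (TSV)
#'
#' @param path TSV path with columns `sample_id`, `peptide_sequence`,
#'   `observed_neutral_mass`, `parent_protein_id`.
#' @export
read_psms <- function(path) {
  psms <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "peptide_sequence", "observed_neutral_mass",
            "parent_protein_id")
  if (!all(need %in% names(psms)))
    stop("PSM TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  psms
}

#' @rdname read_psms
#' @param psms PSM data.frame to write.
#' @export
write_psms <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write trajectory tables (CSV: cell,t,x,y)
#'
#' @param path CSV path.
#' @export
read_trajectories <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell", "t", "x", "y") %in% names(tr)))
    stop("trajectory CSV needs columns cell,t,x,y", call. = FALSE)
  tr
}

#' @rdname read_trajectories
#' @param trajectories data.frame to write.
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(trajectories, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read region-count tables (CSV: condition,time_h,n0,n1,n2)
#'
#' @param path CSV path.
#' @export
read_region_counts <- function(path) {
  rc <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("condition", "time_h", "n0", "n1", "n2") %in% names(rc)))
    stop("region-count CSV needs columns condition,time_h,n0,n1,n2",
         call. = FALSE)
  rc
}

#' Write a tree in Newick format
#'
#' @param tree A `upgma_tree`.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  writeLines(to_newick(tree), path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Houses the analysis defaults: 10 ppm precursor tolerance, protein
#' presence in >= 4 of 6 samples, all-6 consensus for amidation calls,
#' <= 3 missed cleavages, <= 3 trimmed basic residues.
#'
#' @param tol_ppm Precursor mass tolerance (ppm).
#' @param min_samples_protein Replicate presence threshold for proteins.
#' @param min_samples_consensus Replicate consensus for amidation calls.
#' @param max_missed Maximum missed cleavages.
#' @param max_basic_run Maximum trimmed C-terminal basic residues.
#' @param min_product_length Minimum processed-product length.
#' @param his_trim Enable single-His trimming after basic removal.
#' @param n_groups Groups to cut from the precursor tree.
#' @param seed Seed for any stochastic stage.
#' @param out_dir Output directory for artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(tol_ppm = 10, min_samples_protein = 4L,
                       min_samples_consensus = 6L, max_missed = 3L,
                       max_basic_run = 3L, min_product_length = 3L,
                       his_trim = FALSE, n_groups = 7L, seed = 1L,
                       out_dir = tempdir()) {
  stopifnot(tol_ppm > 0, min_samples_protein >= 1,
            min_samples_consensus >= 1, max_missed >= 0,
            max_basic_run >= 1, min_product_length >= 1, n_groups >= 1)
  structure(list(tol_ppm = tol_ppm,
                 min_samples_protein = as.integer(min_samples_protein),
                 min_samples_consensus = as.integer(min_samples_consensus),
                 max_missed = as.integer(max_missed),
                 max_basic_run = as.integer(max_basic_run),
                 min_product_length = as.integer(min_product_length),
                 his_trim = isTRUE(his_trim),
                 n_groups = as.integer(n_groups),
                 seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

.write_sidecar <- function(artifact_path, config) {
  side <- paste0(artifact_path, ".provenance.json")
  meta <- list(artifact = basename(artifact_path),
               package = "ciliapep",
               version = as.character(utils::packageVersion("ciliapep")),
               seed = config$seed,
               config = unclass(config))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, pretty = TRUE)
  invisible(side)
}

.write_artifact <- function(df, path, config) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  .write_sidecar(path, config)
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (`scan` ->
#' `process` -> `amidscreen`; `counts`; `tree`; `chemotax` is
#' independent), writing each stage's table under `config$out_dir`
#' together with a `.provenance.json` sidecar naming the configuration
#' and seed that produced it. Reruns with the same inputs, configuration
#' and seed produce byte-identical artifacts.
#'
#' @param config A [run_config()].
#' @param stages Subset of `c("scan", "process", "amidscreen", "counts",
#'   "tree", "chemotax")`.
#' @param inputs Named list: `records` (protein records; required by
#'   scan/process/amidscreen/tree), `psms` (PSM data.frame; amidscreen),
#'   `counts` (matrix; counts stage), `trajectories` and/or
#'   `region_counts` + `control_ratio_4h` (chemotax).
#' @return Invisibly, a named list of artifact file paths.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("scan", "process", "amidscreen",
                                    "counts", "tree"),
                         inputs = list()) {
  stopifnot(inherits(config, "run_config"))
  known <- c("scan", "process", "amidscreen", "counts", "tree", "chemotax")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "),
         call. = FALSE)
  stages <- known[known %in% stages]   # dependency order
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  need_records <- c("scan", "process", "amidscreen", "tree")
  for (st in intersect(stages, need_records))
    if (is.null(inputs$records))
      stop(sprintf("stage '%s' requires protein records (inputs$records)",
                   st), call. = FALSE)
  if ("amidscreen" %in% stages && is.null(inputs$psms))
    stop("stage 'amidscreen' requires a PSM table (inputs$psms)",
         call. = FALSE)
  if ("counts" %in% stages && is.null(inputs$counts))
    stop("stage 'counts' requires a count matrix (inputs$counts)",
         call. = FALSE)
  proc_cfg <- processing_config(max_basic_run = config$max_basic_run,
                                min_length = config$min_product_length,
                                his_trim = config$his_trim)
  dig_cfg <- digest_config(max_missed_cleavages = config$max_missed)
  artifacts <- list()
  out <- function(name) file.path(config$out_dir, name)

  if ("scan" %in% stages) {
    scr <- screen_proteome(inputs$records,
                           max_basic_run = config$max_basic_run)
    artifacts$scan_summary <-
      .write_artifact(scr$summary, out("screen_summary.tsv"), config)
    artifacts$scan_annotations <-
      .write_artifact(scr$annotations, out("amidation_sites.tsv"), config)
  }
  if ("process" %in% stages) {
    prods <- do.call(rbind, lapply(inputs$records, process_precursor,
                                   config = proc_cfg))
    artifacts$products <-
      .write_artifact(prods, out("processed_peptides.tsv"), config)
  }
  if ("amidscreen" %in% stages) {
    calls <- gly_loss_amide_screen(inputs$psms, inputs$records,
                                   tol_ppm = config$tol_ppm,
                                   min_samples = config$min_samples_consensus,
                                   processing = proc_cfg, digest = dig_cfg)
    artifacts$amidation_calls <-
      .write_artifact(calls, out("amidation_calls.tsv"), config)
  }
  if ("counts" %in% stages) {
    norm <- normalize_counts(inputs$counts)
    filt <- presence_filter(norm, config$min_samples_protein)
    artifacts$counts <-
      .write_artifact(data.frame(protein = rownames(filt), filt,
                                 check.names = FALSE),
                      out("normalized_filtered_counts.tsv"), config)
  }
  if ("tree" %in% stages) {
    seqs <- vapply(inputs$records, `[[`, character(1), "sequence")
    names(seqs) <- vapply(inputs$records, `[[`, character(1), "id")
    tree <- upgma(distance_matrix(seqs))
    nwk <- out("precursor_tree.nwk")
    write_newick(tree, nwk)
    .write_sidecar(nwk, config)
    artifacts$tree <- nwk
    groups <- cut_groups(tree, min(config$n_groups, length(seqs)))
    artifacts$groups <-
      .write_artifact(data.frame(id = names(groups), group = groups),
                      out("precursor_groups.tsv"), config)
  }
  if ("chemotax" %in% stages) {
    rows <- list()
    if (!is.null(inputs$trajectories)) {
      stats_ <- population_com(inputs$trajectories)
      rows$com <- data.frame(statistic = c("com_x", "com_y", "mean_speed",
                                           "rayleigh_p", "n_cells"),
                             value = c(stats_$com, stats_$mean_speed,
                                       stats_$rayleigh_p, stats_$n_cells))
    }
    if (!is.null(inputs$region_counts)) {
      if (is.null(inputs$control_ratio_4h))
        stop("chemotax region counts require inputs$control_ratio_4h",
             call. = FALSE)
      ci <- chemotaxis_index(inputs$region_counts, inputs$control_ratio_4h)
      artifacts$chemotaxis_index <-
        .write_artifact(ci, out("chemotaxis_index.tsv"), config)
    }
    if (!is.null(rows$com))
      artifacts$population_stats <-
        .write_artifact(rows$com, out("population_stats.tsv"), config)
    if (is.null(inputs$trajectories) && is.null(inputs$region_counts))
      stop("stage 'chemotax' requires trajectories or region_counts",
           call. = FALSE)
  }
  invisible(artifacts)
}
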