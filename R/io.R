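# File input/output: TSV tables, FASTA, model archives, run manifests.
#
# TSV dialect: tab-separated, header row, UTF-8, '.' decimal, no quoting.

#' Read and write peptide / pair / feature tables
#'
#' Thin TSV readers and writers for the table schemas used throughout the
#' package.  \code{read_peptide_table()} expects columns \code{id},
#' \code{sequence} and optionally \code{hla_allele}, \code{rank_percent},
#' \code{label}; \code{read_pair_table()} expects \code{id},
#' \code{wt_sequence}, \code{mut_sequence} and the two rank columns;
#' \code{read_feature_table()} reads back what
#' \code{write_feature_table()} wrote, with full double precision
#' round-trip.
#'
#' @param path File path.
#' @param peptides,pairs,features Tibbles to write.
#' @return Readers return tibbles; writers return the input invisibly.
#' @name table_io
NULL

.read_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

.write_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' @rdname table_io
#' @export
read_peptide_table <- function(path) {
  out <- .read_tsv(path)
  if (!"sequence" %in% names(out)) {
    abort(paste0(path, ": a peptide table needs a `sequence` column."))
  }
  validate_peptides(out, min_len = 4L, max_len = 1000L)
}

#' @rdname table_io
#' @export
write_peptide_table <- function(peptides, path) .write_tsv(peptides, path)

#' @rdname table_io
#' @export
read_pair_table <- function(path) {
  out <- .read_tsv(path)
  validate_pairs(out, require_rank = FALSE)
}

#' @rdname table_io
#' @export
write_pair_table <- function(pairs, path) .write_tsv(pairs, path)

#' @rdname table_io
#' @export
read_feature_table <- function(path) .read_tsv(path)

#' @rdname table_io
#' @export
write_feature_table <- function(features, path) .write_tsv(features, path)

#' Read peptides or a proteome from FASTA
#'
#' \code{read_peptide_fasta()} returns a peptide table (record ids from the
#' FASTA headers); per-record ranks can be supplied via a sidecar TSV with
#' columns \code{id} and \code{rank_percent}.  \code{read_proteome()}
#' returns the protein sequences as a plain character vector for the
#' proteome-identity filter and background estimation.
#'
#' @param path FASTA file path.
#' @param ranks Optional path to a sidecar rank TSV, or a data frame.
#' @return A tibble (peptides) or character vector (proteome).
#' @export
read_peptide_fasta <- function(path, ranks = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- tibble::tibble(
    id = vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1),
    sequence = unname(toupper(as.character(seqs)))
  )
  if (!is.null(ranks)) {
    rk <- if (is.data.frame(ranks)) tibble::as_tibble(ranks) else .read_tsv(ranks)
    if (!all(c("id", "rank_percent") %in% names(rk))) {
      abort("Sidecar rank table needs `id` and `rank_percent` columns.")
    }
    out <- dplyr::left_join(out, rk[, c("id", "rank_percent")], by = "id")
  }
  validate_peptides(out, min_len = 4L, max_len = 1000L)
}

#' @rdname read_peptide_fasta
#' @export
read_proteome <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  unname(toupper(as.character(seqs)))
}

# --- model persistence ---------------------------------------------------

MODEL_SCHEMA_VERSION <- 1L

#' Save and load a trained model bundle
#'
#' A bundle is persisted as a directory holding the serialized forest
#' (\code{model.rds}) next to a JSON sidecar (\code{metadata.json}) with
#' the schema version, mode, feature list, thresholds, hyperparameters and
#' seed, so the archive is auditable without loading R objects.
#' \code{load_model()} refuses archives whose schema version does not
#' match the package's.
#'
#' @param model An [ep_train()] bundle.
#' @param path Directory to create/read.
#' @return \code{save_model()} returns \code{path} invisibly;
#'   \code{load_model()} returns the \code{ep_model}.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ep_model"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(path, "model.rds"))
  meta <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    package_version = model$package_version,
    mode = model$mode,
    features = model$features,
    thresholds = as.list(model$thresholds),
    mtry = model$mtry, n_trees = model$n_trees,
    folds = model$folds, repeats = model$repeats,
    seed = model$seed,
    cv_auc = model$cv$auc,
    fingerprint = model$fingerprint
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  rds_path <- file.path(path, "model.rds")
  if (!file.exists(meta_path) || !file.exists(rds_path)) {
    abort(paste0(path, " is not a model archive (missing model.rds or ",
                 "metadata.json)."))
  }
  meta <- jsonlite::read_json(meta_path)
  if (is.null(meta$schema_version) ||
      meta$schema_version != MODEL_SCHEMA_VERSION) {
    abort(paste0("Model archive schema version ",
                 format(meta$schema_version), " does not match this ",
                 "package's version ", MODEL_SCHEMA_VERSION,
                 "; refusing to load."))
  }
  model <- readRDS(rds_path)
  stopifnot(inherits(model, "ep_model"))
  model
}

# --- run manifest --------------------------------------------------------

#' Write a machine-readable run manifest
#'
#' Records everything needed to reconstruct a run: the configuration
#' (subcommand, arguments, seed), the package version, and an MD5
#' fingerprint of every input file.
#'
#' @param out_dir Output directory (created if needed).
#' @param config Named list of run settings.
#' @param inputs Character vector of input file paths to fingerprint.
#' @return Invisible path of the manifest file.
#' @export
write_manifest <- function(out_dir, config, inputs = character(0)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "immunopep",
    package_version = as.character(utils::packageVersion("immunopep")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
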