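# Plain-text and NIfTI input/output for cohort artifacts.

#' Write a volume/mask pair as NIfTI
#'
#' @param vm A [volume_mask()].
#' @param volume_path,mask_path Output paths (`.nii` or `.nii.gz`).
#' @return Invisibly, the two paths.
#' @export
write_volume_mask <- function(vm, volume_path, mask_path) {
  stopifnot(inherits(vm, "volume_mask"))
  vol <- RNifti::asNifti(vm$intensities, pixdim = vm$spacing)
  msk <- RNifti::asNifti(array(as.integer(vm$mask), dim(vm$mask)),
                         pixdim = vm$spacing)
  RNifti::writeNifti(vol, volume_path)
  RNifti::writeNifti(msk, mask_path)
  invisible(c(volume_path, mask_path))
}

#' Read a volume/mask pair from NIfTI
#'
#' Voxel spacing is taken from the volume header.
#'
#' @param volume_path,mask_path Input paths.
#' @param patient_id Identifier for the resulting object.
#' @return A [volume_mask()].
#' @export
read_volume_mask <- function(volume_path, mask_path, patient_id = "P000") {
  vol <- RNifti::readNifti(volume_path)
  msk <- RNifti::readNifti(mask_path)
  spacing <- RNifti::pixdim(vol)[1:3]
  volume_mask(array(as.numeric(vol), dim(vol)[1:3]),
              array(as.numeric(msk) > 0.5, dim(msk)[1:3]),
              spacing, patient_id)
}

#' Write a genes-by-patients expression matrix as TSV
#'
#' Tab-separated with a `gene` first column and one column per patient.
#'
#' @param e Genes-by-patients matrix with dimnames.
#' @param path Output path.
#' @export
write_expression_tsv <- function(e, path) {
  df <- data.frame(gene = rownames(e), e, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes-by-patients expression TSV
#'
#' @param path Input path (format of [write_expression_tsv()]).
#' @return Genes-by-patients numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write / read the clinical table as CSV
#'
#' Columns `patient_id`, `histology`, `t_stage`.
#'
#' @param clinical A [clinical_table()].
#' @param path File path.
#' @export
write_clinical_csv <- function(clinical, path) {
  utils::write.csv(as.data.frame(clinical), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_clinical_csv
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  clinical_table(df$patient_id, df$histology, df$t_stage)
}

#' Write gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene symbols.
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path Input path.
#' @return Named list of gene symbol vectors; per-set descriptions are kept
#'   in the `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "descriptions") <- vapply(parts, `[`, character(1), 2L)
  sets
}

#' Persist a synthetic cohort to a directory
#'
#' Writes NIfTI volume/mask pairs under `volumes/`, the clinical table as
#' CSV, gene-level expression as TSV, gene sets (when present) as GMT, the
#' handcrafted feature matrix as CSV, and the planted truth as JSON.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param write_volumes Write the NIfTI pairs (default TRUE).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir, write_volumes = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (write_volumes) {
    vdir <- file.path(dir, "volumes")
    dir.create(vdir, showWarnings = FALSE)
    for (vm in cohort$volumes_masks) {
      write_volume_mask(vm,
                        file.path(vdir, paste0(vm$patient_id, "_vol.nii.gz")),
                        file.path(vdir, paste0(vm$patient_id, "_mask.nii.gz")))
    }
  }
  write_clinical_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.csv(data.frame(patient_id = rownames(cohort$hc_features),
                              cohort$hc_features, check.names = FALSE),
                   file.path(dir, "features_hc.csv"), row.names = FALSE)
  if (!is.null(cohort$gene_sets))
    write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
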