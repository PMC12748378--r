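# Readers and writers for the standard formats the pipeline touches:
# MatrixMarket triplet counts with feature/barcode sidecars, spot-position
# CSVs, GMT gene-set files, and plain TSV alteration tables. Readers are
# total over valid files and raise typed format errors otherwise; every
# writer/reader pair round-trips.

#' Read a 10x-style MTX triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv` and `barcodes.tsv` in `path`.
#' Gene symbols come from the second column of `features.tsv` when present
#' (10x id/symbol convention), else the first; duplicate symbols are
#' disambiguated deterministically in file order with suffixes `.1`, `.2`,
#' ... If a `cells.tsv` metadata sidecar is present (as written by
#' [write_counts_mtx()]) it is attached as the per-cell metadata.
#'
#' @param path Directory containing the triplet.
#' @return A [cell_matrix()].
#' @export
read_counts_mtx <- function(path) {
  mtx <- file.path(path, "matrix.mtx")
  feat <- file.path(path, "features.tsv")
  bar <- file.path(path, "barcodes.tsv")
  for (f in c(mtx, feat, bar)) {
    if (!file.exists(f)) stop_format(sprintf("missing file: %s", f))
  }
  counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  features <- readr::read_tsv(feat, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  barcodes <- readr::read_tsv(bar, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (nrow(features) != nrow(counts)) {
    stop_format(sprintf(
      "features.tsv has %d rows but matrix.mtx declares %d genes (%s)",
      nrow(features), nrow(counts), feat
    ))
  }
  if (nrow(barcodes) != ncol(counts)) {
    stop_format(sprintf(
      "barcodes.tsv has %d rows but matrix.mtx declares %d cells (%s)",
      nrow(barcodes), ncol(counts), bar
    ))
  }
  symbols <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  rownames(counts) <- make.unique(symbols, sep = ".")
  colnames(counts) <- barcodes[[1]]
  meta_path <- file.path(path, "cells.tsv")
  cells <- if (file.exists(meta_path)) {
    readr::read_tsv(meta_path, col_types = readr::cols(), progress = FALSE)
  } else {
    tibble(cell_id = colnames(counts))
  }
  cell_matrix(counts, cells)
}

#' Write a cell matrix as an MTX triplet directory
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv` and a `cells.tsv`
#' metadata sidecar consumed by [read_counts_mtx()].
#'
#' @param x A [cell_matrix()] (or bare gene-by-cell matrix).
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_counts_mtx <- function(x, path) {
  if (!inherits(x, "cell_matrix")) x <- cell_matrix(x, tibble(
    cell_id = colnames(x)
  ))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(path, "matrix.mtx"))
  readr::write_tsv(tibble(gene = rownames(x$counts)),
                   file.path(path, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(barcode = colnames(x$counts)),
                   file.path(path, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(x$cells, file.path(path, "cells.tsv"))
  invisible(path)
}

#' Read spot positions
#'
#' CSV with header and columns `spot_id,row,col,x,y`; an optional
#' `in_tissue` column (0/1) restricts to in-tissue spots when present.
#'
#' @param path CSV file path.
#' @return Tibble keyed by `spot_id`.
#' @export
read_spatial_positions <- function(path) {
  pos <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  needed <- c("spot_id", "row", "col", "x", "y")
  missing <- setdiff(needed, names(pos))
  if (length(missing)) {
    stop_format(sprintf("positions file %s lacks column(s): %s",
                        path, paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(pos$spot_id)) {
    dups <- unique(pos$spot_id[duplicated(pos$spot_id)])
    stop_format(sprintf("duplicate spot_id in %s: %s",
                        path, paste(head(dups, 5), collapse = ", ")))
  }
  if ("in_tissue" %in% names(pos)) {
    pos <- dplyr::filter(pos, .data$in_tissue == 1)
  }
  pos
}

#' @rdname read_spatial_positions
#' @param pos Tibble of positions to write.
#' @export
write_spatial_positions <- function(pos, path) {
  readr::write_csv(pos, path)
  invisible(path)
}

#' Read or write one spatial section
#'
#' A section on disk is an MTX triplet directory plus a `positions.csv`
#' (see [read_spatial_positions()]). Spots present in the count matrix but
#' absent from the positions file raise an error naming the missing ids.
#'
#' @param path Section directory.
#' @param section_id Section id; defaults to the directory name.
#' @return A [spatial_section()].
#' @export
read_spatial_section <- function(path, section_id = basename(path)) {
  cm <- read_counts_mtx(path)
  pos <- read_spatial_positions(file.path(path, "positions.csv"))
  missing <- setdiff(colnames(cm$counts), pos$spot_id)
  if (length(missing)) {
    stop_format(sprintf(
      "spots missing from positions.csv: %s",
      paste(head(missing, 10), collapse = ", ")
    ))
  }
  spatial_section(section_id, as.matrix(cm$counts), pos)
}

#' @rdname read_spatial_section
#' @param section A [spatial_section()] to write.
#' @export
write_spatial_section <- function(section, path) {
  cm <- cell_matrix(section$expr,
                    tibble(cell_id = colnames(section$expr)))
  write_counts_mtx(cm, path)
  write_spatial_positions(section$coords, file.path(path, "positions.csv"))
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: `name<TAB>description<TAB>member...`. Duplicate
#' members within a set are deduplicated; empty sets are dropped with a
#' warning; a line with fewer than three fields is a format error naming
#' the line.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop_format(sprintf("GMT line %d has %d field(s); need >= 3 (%s)",
                          i, length(fields), path))
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      rlang::warn(sprintf("dropping empty gene set '%s' (line %d)",
                          fields[1], i))
      next
    }
    if (fields[1] %in% names(sets)) {
      stop_format(sprintf("duplicate set name '%s' (line %d)", fields[1], i))
    }
    sets[[fields[1]]] <- members
  }
  gene_set_collection(sets)
}

#' @rdname read_gmt
#' @param collection A [gene_set_collection()] to write.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::imap_chr(collection$sets, function(members, name) {
    paste(c(name, "na", members), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read or write an alteration table
#'
#' Plain TSV with one row per patient: `patient_id`, `site`, `histology`,
#' `sample_type`, then `cn_<gene>` integer call columns and `mut_<gene>`
#' logical columns (see [generate_cohort()]).
#'
#' @param path TSV file path.
#' @return Tibble.
#' @export
read_alteration_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!"patient_id" %in% names(tab)) {
    stop_format(sprintf("%s lacks a patient_id column", path))
  }
  if (anyDuplicated(tab$patient_id)) {
    stop_format(sprintf("duplicate patient_id in %s", path))
  }
  dplyr::mutate(tab, dplyr::across(dplyr::starts_with("cn_"), as.integer))
}

#' @rdname read_alteration_table
#' @param table Alteration table to write.
#' @export
write_alteration_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}
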