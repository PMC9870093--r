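#' Read and write digital gene expression matrices
#'
#' Dense DGE TSV in the Drop-Seq DigitalExpression dialect (first column
#' `GENE`, one column per barcode) and MatrixMarket triplet format with
#' `genes.tsv` / `barcodes.tsv` sidecars.
#'
#' @param counts Genes x barcodes integer matrix with dimnames.
#' @param path Output file path (for MTX, the `.mtx` path; sidecars are
#'   written alongside).
#' @return `write_*` return `path` invisibly; `read_*` return the counts
#'   matrix.
#' @name dge_io
NULL

#' @rdname dge_io
#' @export
write_dge_tsv <- function(counts, path) {
  check_counts(counts)
  df <- as.data.frame(counts, check.names = FALSE)
  df <- cbind(GENE = rownames(counts), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}

#' @rdname dge_io
#' @export
read_dge_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    GENE = readr::col_character(), .default = readr::col_integer()
  ))
  if (names(df)[1] != "GENE") {
    abort("Expected a `GENE` first column (DigitalExpression dialect).")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$GENE
  storage.mode(m) <- "integer"
  check_counts(m)
}

#' @rdname dge_io
#' @export
write_dge_mtx <- function(counts, path) {
  check_counts(counts)
  sparse <- Matrix::Matrix(counts, sparse = TRUE)
  Matrix::writeMM(sparse, path)
  base <- dirname(path)
  readr::write_tsv(tibble(gene = rownames(counts)),
                   file.path(base, "genes.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(barcode = colnames(counts)),
                   file.path(base, "barcodes.tsv"), col_names = FALSE)
  invisible(path)
}

#' @rdname dge_io
#' @export
read_dge_mtx <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  base <- dirname(path)
  genes <- readr::read_tsv(file.path(base, "genes.tsv"),
                           col_names = "gene",
                           col_types = readr::cols(gene = readr::col_character()))
  barcodes <- readr::read_tsv(file.path(base, "barcodes.tsv"),
                              col_names = "barcode",
                              col_types = readr::cols(barcode = readr::col_character()))
  dimnames(m) <- list(genes$gene, barcodes$barcode)
  storage.mode(m) <- "integer"
  check_counts(m)
}

#' Read and write multi-channel images
#'
#' Multi-page TIFF, one 16-bit page per channel, with the channel-role map
#' stored as a JSON sidecar (`<path>_roles.json`). Intensities are stored
#' as uint16 (values clamped to 0..65535).
#'
#' @param img A [channel_image()].
#' @param path TIFF path.
#' @return `write_channel_tiff()` returns `path` invisibly;
#'   `read_channel_tiff()` returns a [channel_image()].
#' @name image_io
NULL

#' @rdname image_io
#' @export
write_channel_tiff <- function(img, path) {
  if (!inherits(img, "channel_image")) abort("`img` must be a `channel_image`.")
  n_chan <- dim(img$image)[3]
  pages <- lapply(seq_len(n_chan), function(k) {
    plane <- img$image[, , k]
    plane <- pmin(pmax(round(plane), 0), 65535)
    plane / 65535 # tiff package stores [0,1] scaled to the sample depth
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  roles_path <- paste0(sub("\\.tiff?$", "", path), "_roles.json")
  jsonlite::write_json(as.list(img$channel_roles), roles_path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname image_io
#' @export
read_channel_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  planes <- lapply(pages, function(p) round(p * 65535))
  img <- array(0, dim = c(dim(planes[[1]]), length(planes)))
  for (k in seq_along(planes)) img[, , k] <- planes[[k]]
  roles_path <- paste0(sub("\\.tiff?$", "", path), "_roles.json")
  roles <- unlist(jsonlite::read_json(roles_path))
  channel_image(img, setNames(as.integer(roles), names(roles)))
}
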