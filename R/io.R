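#' Write / read a dense matrix as TSV
#'
#' @param m numeric matrix.
#' @param path output file.
#' @return `path`, invisibly (writer) or the matrix (reader).
#' @export
write_matrix_tsv <- function(m, path) {
  write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(read.table(path, sep = "\t", header = FALSE))
}

#' Write a parcellation table as TSV
#' @param parcellation a [generate_parcellation()] table.
#' @param path output file.
#' @export
write_parcellation <- function(parcellation, path) {
  write.table(parcellation, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  out <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  class(out) <- c("parcellation", "data.frame")
  validate_parcellation(out)
}

#' Write a BOLD recording as TSV with a JSON sidecar
#'
#' The time-by-region matrix goes to `<path>`; acquisition metadata (the
#' repetition time in seconds) goes to `<path stem>.json`.
#'
#' @param rec a [bold_recording()].
#' @param path output TSV file.
#' @export
write_bold <- function(rec, path) {
  stopifnot(inherits(rec, "bold_recording"))
  write_matrix_tsv(rec$data, path)
  sidecar <- sub("\\.tsv$", "", path)
  jsonlite::write_json(list(RepetitionTime = rec$tr),
                       paste0(sidecar, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path) {
  meta <- jsonlite::read_json(paste0(sub("\\.tsv$", "", path), ".json"))
  bold_recording(read_matrix_tsv(path), meta$RepetitionTime)
}
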