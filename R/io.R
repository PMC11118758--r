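# FASTA / tabular I/O. Sequence parsing goes through Biostrings; labels
# ride in the header after a pipe ("id|class").

#' Read peptides from FASTA
#'
#' Reads a protein FASTA (single- or multi-line). If headers carry a
#' class label after a pipe (`id|label`), it is split into a `class`
#' column.
#'
#' @param path FASTA file.
#' @return Tibble with `id`, `sequence`, and `class` when labels are
#'   present.
#' @export
read_peptide_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  headers <- names(ss)
  out <- tibble::tibble(
    id = sub("\\|.*$", "", headers),
    sequence = as.character(ss)
  )
  if (any(grepl("|", headers, fixed = TRUE))) {
    out$class <- ifelse(
      grepl("|", headers, fixed = TRUE),
      sub("^[^|]*\\|", "", headers),
      NA_character_
    )
  }
  out
}

#' Write peptides to FASTA
#'
#' @param data Tibble with `id`, `sequence`, optionally `class` (written
#'   into the header after a pipe).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(data, path) {
  headers <- if ("class" %in% names(data)) {
    paste(data$id, data$class, sep = "|")
  } else {
    data$id
  }
  ss <- Biostrings::AAStringSet(data$sequence)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read DNA contigs from FASTA
#' @param path FASTA file.
#' @return Tibble with `id`, `sequence`.
#' @export
read_dna_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble::tibble(
    id = sub("\\s.*$", "", names(ss)),
    sequence = as.character(ss)
  )
}

#' Write a prediction/result table as TSV
#' @param data A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(path)
}

#' Serialize model weights with the config embedded
#'
#' Writes the classifier (config + flat weight vector) as portable JSON;
#' the frozen vocabulary and class order make the weights reusable
#' across sessions.
#'
#' @param model A `ripp_model` or `ripp_fit`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
save_ripp_model <- function(model, path) {
  if (inherits(model, "ripp_fit")) model <- model$model
  obj <- list(
    config = unclass(model$config),
    weights = unlist(model$params, use.names = FALSE)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a serialized classifier
#' @param path JSON file written by [save_ripp_model()].
#' @return A `ripp_model`.
#' @export
load_ripp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(ripp_model_config, obj$config[setdiff(
    names(obj$config), "vocab_size"
  )])
  model <- ripp_model(cfg, seed = 1L)
  skeleton <- model$params
  model$params <- utils::relist(as.numeric(obj$weights), skeleton)
  model
}
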