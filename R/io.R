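#' Write / read an RDM as square CSV
#'
#' The matrix is written with condition labels (if present, pasted from the
#' label columns) as both header row and first column, so the file
#' round-trips through [read_rdm_csv()].
#'
#' @param rdm An [euclidean_rdm()] / [crossval_pearson_rdm()] result.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_rdm_csv <- function(rdm, path) {
  m <- rdm$matrix
  lab <- if (!is.null(rdm$labels)) {
    do.call(paste, c(as.list(rdm$labels), sep = "_"))
  } else {
    paste0("c", seq_len(nrow(m)))
  }
  if (length(lab) != nrow(m)) lab <- rep_len(lab, nrow(m))
  dimnames(m) <- list(lab, lab)
  utils::write.csv(m, path)
  invisible(path)
}

#' @rdname write_rdm_csv
#' @param metric Metric tag to attach on read.
#' @export
read_rdm_csv <- function(path, metric = "euclidean") {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  dimnames(m) <- NULL
  structure(list(matrix = m, labels = NULL, metric = metric), class = "rdm")
}

#' Write a choice set to CSV
#'
#' Columns \code{context}, \code{b}, \code{l}, \code{response}.
#'
#' @param choices A [gen_synthetic_choices()] tibble.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_choices_csv <- function(choices, path) {
  utils::write.csv(choices[, c("context", "b", "l", "response")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a fit object to JSON
#'
#' Serialises the tidy() and glance() views of a fit (RDM regression,
#' parameterised geometry, psychophysics) as a JSON record.
#'
#' @param fit A fit with tidy/glance methods.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(tidy = generics::tidy(fit), glance = generics::glance(fit)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )
  invisible(path)
}
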