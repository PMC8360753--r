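#' Read and write the delimited-text formats of the pipeline
#'
#' All files are tab-delimited text. An expression file has a header row of
#' gene identifiers with a leading sample-identifier column; a response file
#' is either one value per line (aligned to the expression sample order) or
#' two columns `sample_id`, `y`; a ranking file has the columns written by
#' [write_ranking()]. Round trips are lossless for identifiers and lossless
#' to full double precision for numerics.
#'
#' @param path File path.
#' @name bnr-io
NULL

#' @rdname bnr-io
#' @return `read_expression()`: a tibble, `sample_id` plus one column per gene.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  df
}

#' @rdname bnr-io
#' @return `read_response()`: a tibble with columns `sample_id` (possibly NA
#'   for bare one-column files) and `y`.
#' @export
read_response <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_names = FALSE)
  if (ncol(df) == 1) {
    # may carry a header line; keep numeric rows
    vals <- suppressWarnings(as.numeric(df[[1]]))
    if (is.na(vals[1]) && !is.na(df[[1]][1])) vals <- vals[-1]
    if (anyNA(vals)) stop("Non-numeric response values in ", path,
                          call. = FALSE)
    return(tibble::tibble(sample_id = NA_character_, y = vals))
  }
  has_header <- is.na(suppressWarnings(as.numeric(df[[2]][1])))
  if (has_header) df <- df[-1, , drop = FALSE]
  tibble::tibble(sample_id = as.character(df[[1]]),
                 y = as.numeric(df[[2]]))
}

#' @rdname bnr-io
#' @param expression Tibble as returned by [read_expression()].
#' @export
write_expression <- function(expression, path) {
  readr::write_tsv(expression, path)
  invisible(path)
}

#' @rdname bnr-io
#' @param response Tibble with `sample_id` and `y`.
#' @export
write_response <- function(response, path) {
  readr::write_tsv(response, path)
  invisible(path)
}

#' @rdname bnr-io
#' @param net A [gene_network()].
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  readr::write_tsv(net$edges, path, col_names = FALSE)
  invisible(path)
}

#' Write a gene ranking as tab-delimited text
#'
#' Columns: `gene_id`, `rank`, `post_mean`, `post_sd`, `ci_lower`,
#' `ci_upper`. Numbers are written with full precision (17 significant
#' digits) so identical fits produce byte-identical files.
#'
#' @param ranking Tibble from [summarize_chain()].
#' @param path Output path.
#' @export
write_ranking <- function(ranking, path) {
  out <- ranking
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "rank"
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname bnr-io
#' @export
read_ranking <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a run manifest
#'
#' Records input paths, the resolved configuration (chain settings,
#' hyperparameters, seed), package version and timestamps alongside every
#' output directory, so a run can be reproduced exactly from its manifest.
#'
#' @param path Output JSON path.
#' @param inputs Named list of input file paths.
#' @param config Named list of resolved settings (must include the seed).
#' @param started,finished POSIXct timestamps.
#' @export
write_manifest <- function(path, inputs, config, started = Sys.time(),
                           finished = Sys.time()) {
  manifest <- list(
    package = "bnreg",
    version = as.character(utils::packageVersion("bnreg")),
    inputs = inputs,
    config = config,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
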