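#' Construct a gene-interaction network
#'
#' A `gene_network` is an undirected weighted graph over gene identifiers.
#' It is the carrier of pathway structure: its normalized Laplacian enters the
#' coefficient prior of [bnr_fit()] as the quadratic smoothness penalty.
#'
#' Edges are stored in canonical form (`from` < `to` lexicographically), both
#' orientations of a pair are collapsed to one undirected edge, duplicates keep
#' the last weight seen, and self-loops are dropped with a warning.
#'
#' @param edges A data frame with columns `from` and `to` (gene identifiers)
#'   and optionally `weight` (nonnegative, finite; defaults to 1). May have
#'   zero rows.
#' @param nodes Character vector of node identifiers fixing the node order.
#'   Defaults to the sorted union of edge endpoints. Must contain every edge
#'   endpoint and no duplicates.
#' @return An object of class `gene_network`: a list with elements `nodes`
#'   (character) and `edges` (a tibble with columns `from`, `to`, `weight`).
#' @examples
#' net <- gene_network(data.frame(from = c("g1", "g2"), to = c("g2", "g3")))
#' normalized_laplacian(net)
#' @export
gene_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = numeric())
  }
  edges <- tibble::as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    stop("`edges` must have columns `from` and `to`.", call. = FALSE)
  }
  if (!"weight" %in% names(edges)) edges$weight <- rep(1, nrow(edges))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (anyNA(edges$weight) || any(!is.finite(edges$weight))) {
    stop("Edge weights must be finite numbers.", call. = FALSE)
  }
  if (any(edges$weight < 0)) {
    stop("Edge weights must be nonnegative.", call. = FALSE)
  }

  loops <- edges$from == edges$to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped from edge list.", call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }

  # canonical undirected form, duplicates keep the last weight seen
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges$from <- a
  edges$to <- b
  if (nrow(edges) > 0) {
    key <- paste(edges$from, edges$to, sep = "\r")
    edges <- edges[!duplicated(key, fromLast = TRUE), , drop = FALSE]
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  }

  endpoints <- unique(c(edges$from, edges$to))
  if (is.null(nodes)) {
    nodes <- sort(endpoints)
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) {
      stop("Duplicate node identifiers: ",
           paste(unique(nodes[duplicated(nodes)]), collapse = ", "),
           call. = FALSE)
    }
    missing <- setdiff(endpoints, nodes)
    if (length(missing) > 0) {
      stop("Edge endpoints absent from `nodes`: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }

  structure(list(nodes = nodes, edges = tibble::as_tibble(edges)),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " undirected edges\n", sep = "")
  invisible(x)
}

#' Read a gene-interaction edge list from a text file
#'
#' Expects one edge per line: two gene identifiers and an optional numeric
#' weight, separated by whitespace (or the given delimiter). Lines starting
#' with `#` and blank lines are ignored. Both orientations of a pair denote
#' the same undirected edge; duplicated pairs keep the last weight seen.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field delimiter; `NULL` (default) splits on any run of
#'   whitespace, which covers both space- and tab-delimited files.
#' @return A [gene_network()].
#' @export
read_edge_list <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("Cannot read edge list: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(gene_network())
  split_re <- if (is.null(delimiter)) "[ \t]+" else delimiter
  fields <- strsplit(lines, split_re)
  nf <- lengths(fields)
  if (any(nf < 2)) {
    stop("Edge list line with fewer than 2 fields (line ",
         which(nf < 2)[1], " of non-comment lines).", call. = FALSE)
  }
  from <- vapply(fields, `[[`, character(1), 1)
  to <- vapply(fields, `[[`, character(1), 2)
  weight <- vapply(fields, function(f) {
    if (length(f) < 3) return(1)
    w <- suppressWarnings(as.numeric(f[3]))
    if (is.na(w)) stop("Non-numeric edge weight: '", f[3], "'", call. = FALSE)
    w
  }, numeric(1))
  gene_network(tibble::tibble(from = from, to = to, weight = weight))
}

#' Align a network to an expression matrix's gene order
#'
#' Returns the induced subgraph on `genes`, with node order exactly `genes`.
#' Genes absent from the network become isolated nodes (their Laplacian row is
#' zero, so the prior on them reduces to pure l1-type shrinkage); network
#' nodes absent from `genes` are discarded together with their edges. The
#' expression matrix, not the edge list, dictates indexing.
#'
#' @param net A [gene_network()].
#' @param genes Character vector of gene identifiers, no duplicates.
#' @return A [gene_network()] with `nodes` identical to `genes`.
#' @export
align_network <- function(net, genes) {
  stopifnot(inherits(net, "gene_network"))
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    stop("Duplicate identifiers in `genes`: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  keep <- net$edges$from %in% genes & net$edges$to %in% genes
  gene_network(net$edges[keep, , drop = FALSE], nodes = genes)
}

#' Normalized Laplacian of a gene network
#'
#' For degree \eqn{d_u = \sum_{v \sim u} w(u,v)}, the matrix has diagonal
#' entries 1 for nodes of positive degree (0 for isolated nodes) and
#' off-diagonal entries \eqn{-w(u,v)/\sqrt{d_u d_v}} for adjacent pairs.
#' Eigenvalues lie in \eqn{[0, 2]}; isolated nodes contribute zero rows, so
#' genes outside the network are unpenalized by the quadratic term.
#'
#' @param net A [gene_network()].
#' @return A symmetric p x p matrix with dimnames `net$nodes`, of class
#'   `c("normalized_laplacian", "matrix")`.
#' @export
normalized_laplacian <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  p <- length(net$nodes)
  W <- matrix(0, p, p, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    W[cbind(i, j)] <- net$edges$weight
    W[cbind(j, i)] <- net$edges$weight
  }
  d <- rowSums(W)
  L <- matrix(0, p, p, dimnames = dimnames(W))
  nz <- d > 0
  if (any(nz)) {
    s <- 1 / sqrt(d[nz])
    L[nz, nz] <- -W[nz, nz, drop = FALSE] * outer(s, s)
    diag(L)[nz] <- 1
  }
  class(L) <- c("normalized_laplacian", class(L))
  L
}
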