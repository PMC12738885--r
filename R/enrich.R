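#' Hypergeometric probability mass
#'
#' Exact probability of drawing k annotated genes when n genes are drawn
#' without replacement from a universe of N genes of which K carry the
#' annotation: C(K,k) C(N-K, n-k) / C(N,n), evaluated in log space.
#'
#' @param N Background universe size.
#' @param K Genes in the term.
#' @param n Genes drawn (the DEG set size).
#' @param k Overlap count.
#' @return Probability.
#' @export
hypergeom_pmf <- function(N, K, n, k) {
  N <- check_count(N, "N", min = 0); K <- check_count(K, "K", min = 0)
  n <- check_count(n, "n", min = 0); k <- check_count(k, "k", min = 0)
  if (K > N || n > N || k > min(K, n)) {
    stop("inconsistent counts: need k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  }
  if (k < max(0, n - (N - K))) return(0)
  stats::dhyper(k, m = K, n = N - K, k = n)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' P(X >= k) for the overlap between a gene set and a term.
#'
#' @inheritParams hypergeom_pmf
#' @return Upper-tail probability (1 when k = 0).
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (k == 0) return(1)
  hypergeom_pmf(N, K, n, k)  # validates the counts
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Gene-set collection
#'
#' @param sets Named list of character vectors (gene ids).
#' @param universe Character vector: the background gene universe.
#' @return Object of class \code{gene_set_collection}.
#' @export
gene_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)),
            length(universe) > 0)
  sets <- lapply(sets, function(s) sort(unique(intersect(s, universe))))
  empty <- vapply(sets, length, integer(1)) == 0
  if (any(empty)) {
    warning(sum(empty), " term(s) had no genes in the universe and were dropped")
    sets <- sets[!empty]
  }
  if (length(sets) == 0) stop("no nonempty term after universe restriction",
                              call. = FALSE)
  structure(list(sets = sets, universe = sort(unique(universe))),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' Tab-delimited: set name, description, then member genes.
#'
#' @param path File path.
#' @param universe Background universe for [gene_set_collection()].
#' @return A \code{gene_set_collection}.
#' @export
read_gmt <- function(path, universe) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40),
                                call. = FALSE)
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  gene_set_collection(sets, universe)
}

#' Write a gene-set collection to GMT
#'
#' @param collection A \code{gene_set_collection} or named list of gene sets.
#' @param path Output file.
#' @export
write_gmt <- function(collection, path) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
    else collection
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Hypergeometric enrichment of a gene set against a collection
#'
#' For each term, counts the overlap with \code{deg_set}, computes the
#' upper-tail hypergeometric p-value against the background universe, and
#' adjusts across terms by Benjamini-Hochberg.
#'
#' @param deg_set Character vector of genes (subset of the universe).
#' @param collection A [gene_set_collection()].
#' @return data.frame (term, N, K, n, k, p, adj_p), sorted by adjusted p
#'   then raw p.
#' @export
enrich_hypergeom <- function(deg_set, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(deg_set) == 0) {
    warning("empty gene set: returning no enrichment rows")
    return(data.frame(term = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p = numeric(0),
                      adj_p = numeric(0), stringsAsFactors = FALSE))
  }
  deg_set <- unique(deg_set)
  extra <- setdiff(deg_set, collection$universe)
  if (length(extra) > 0) {
    stop("gene set contains genes outside the background universe: ",
         paste(utils::head(extra, 3), collapse = ", "), call. = FALSE)
  }
  N <- length(collection$universe)
  n <- length(deg_set)
  K <- vapply(collection$sets, length, integer(1))
  k <- vapply(collection$sets, function(s) length(intersect(s, deg_set)),
              integer(1))
  p <- mapply(function(Ki, ki) hypergeom_tail(N, Ki, n, ki), K, k)
  out <- data.frame(
    term = names(collection$sets), N = N, K = K, n = n, k = k,
    p = p, adj_p = bh_adjust(p), stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$adj_p, out$p, out$term), , drop = FALSE]
}
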