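#' graph6 encoding and decoding
#'
#' graph6 is the compact one-line-per-graph ASCII format for undirected
#' simple graphs used by nauty's `geng` and by most graph-enumeration
#' tools.  These functions implement the standard encoding for graphs of
#' up to 62 nodes (one size byte), which covers every ensemble this
#' package works with.
#'
#' @param g an `igraph` object (undirected, simple).
#' @return `graph6_encode()` returns a single character string;
#'   `graph6_decode()` returns an `igraph` object.
#' @examples
#' g <- igraph::make_full_graph(3)
#' graph6_encode(g)            # "Bw"
#' igraph::gsize(graph6_decode("Bw"))
#' @export
graph6_encode <- function(g) {
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  graph6_encode_edges(n, el)
}

# Encode from a node count and an edge matrix (1-based indices).
# Kept separate from the igraph wrapper so the enumerator can encode
# candidate graphs without constructing igraph objects.
graph6_encode_edges <- function(n, edges) {
  if (n < 1 || n > 62)
    stop("graph6 support in this package is limited to 1..62 nodes")
  npairs <- n * (n - 1L) / 2L
  bits <- integer(npairs)
  if (NROW(edges) > 0) {
    i <- pmin(edges[, 1L], edges[, 2L])
    j <- pmax(edges[, 1L], edges[, 2L])
    # column-major upper triangle: pair (i, j), i < j, sits at
    # (j-1)(j-2)/2 + i
    bits[(j - 1L) * (j - 2L) / 2L + i] <- 1L
  }
  npad <- (6L - npairs %% 6L) %% 6L
  bits <- c(bits, integer(npad))
  groups <- matrix(bits, nrow = 6L)
  vals <- as.integer(colSums(groups * c(32L, 16L, 8L, 4L, 2L, 1L)))
  rawToChar(as.raw(c(n + 63L, vals + 63L)))
}

#' @param s a graph6 string (one graph).
#' @rdname graph6_encode
#' @export
graph6_decode <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  bytes <- as.integer(charToRaw(s)) - 63L
  n <- bytes[1L]
  if (n < 0L || n > 62L)
    stop("unsupported graph6 header byte (only n <= 62 handled)")
  npairs <- n * (n - 1L) / 2L
  need <- ceiling(npairs / 6L)
  if (length(bytes) - 1L != need)
    stop("graph6 string has wrong length for its node count")
  vals <- bytes[-1L]
  if (any(vals < 0L | vals > 63L)) stop("invalid graph6 character")
  bits <- as.integer(sapply(vals, function(v) bitwAnd(bitwShiftR(v, 5:0), 1L)))
  bits <- bits[seq_len(npairs)]
  idx <- which(bits == 1L)
  if (length(idx)) {
    j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
    i <- idx - (j - 1) * (j - 2) / 2
    edges <- rbind(i, j)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, as.vector(edges))
  } else {
    g <- igraph::make_empty_graph(n, directed = FALSE)
  }
  g
}

#' Read and write graph6 files
#'
#' One graph per line; the optional `>>graph6<<` header emitted by some
#' tools is skipped on read.  These files are bit-compatible with geng
#' output, so externally enumerated ensembles (for sizes this package
#' does not enumerate in-process) can be consumed directly.
#'
#' @param path file path.
#' @return `read_graph6()` returns a list of `igraph` objects.
#' @export
read_graph6 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- sub("^>>graph6<<", "", lines)
  lapply(lines, graph6_decode)
}

#' @param graphs list of `igraph` objects.
#' @rdname read_graph6
#' @export
write_graph6 <- function(graphs, path) {
  writeLines(vapply(graphs, graph6_encode, character(1)), path)
  invisible(path)
}
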