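#' Pairwise mutual-information matrix
#'
#' Plug-in MI (base 2) for every pair of columns after equal-frequency
#' discretization of continuous columns. Constant columns carry zero MI with
#' everything and trigger a warning.
#'
#' @param data tibble of features (categorical or numeric).
#' @param bins bins for continuous columns (default 4).
#' @return symmetric numeric matrix with zero diagonal by convention
#'   (self-information is not used by the pruning step).
#' @export
mutual_information_matrix <- function(data, bins = 4) {
  disc <- lapply(data, function(v) {
    if (is.numeric(v)) discretize_ef(v, bins) else as.character(v)
  })
  p <- length(disc)
  nm <- names(disc)
  constant <- vapply(disc, function(v) length(unique(stats::na.omit(v))) <= 1,
                     logical(1))
  if (any(constant)) {
    warning("mutual_information_matrix(): constant column(s): ",
            paste(nm[constant], collapse = ", "))
  }
  m <- matrix(0, p, p, dimnames = list(nm, nm))
  if (p >= 2L) {
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
      m[i, j] <- m[j, i] <- mutual_information(disc[[i]], disc[[j]])
    }
  }
  m
}

#' Data-processing-inequality pruning
#'
#' ARACNE's pruning rule: for every node triplet whose three edges are all
#' present, the edge with the smallest mutual information is removed when it
#' is smaller than both others by more than `epsilon`. With `epsilon = 0`
#' (the default, strict DPI) the weakest edge of every fully connected
#' triangle is dropped. The strictly largest edge of a triangle is never
#' removed.
#'
#' @param mi symmetric MI matrix.
#' @param epsilon non-negative tolerance (default 0).
#' @return logical adjacency matrix of kept edges.
#' @export
dpi_prune <- function(mi, epsilon = 0) {
  stopifnot(epsilon >= 0, isSymmetric(unname(mi)))
  p <- nrow(mi)
  kept <- matrix(TRUE, p, p, dimnames = dimnames(mi))
  diag(kept) <- FALSE
  if (p < 3L) return(kept)
  drop <- matrix(FALSE, p, p)
  for (i in seq_len(p - 2L)) for (j in (i + 1L):(p - 1L)) for (k in (j + 1L):p) {
    e <- c(mi[i, j], mi[i, k], mi[j, k])
    w <- which.min(e)
    if (e[w] < min(e[-w]) - epsilon) {
      pr <- rbind(c(i, j), c(i, k), c(j, k))[w, ]
      drop[pr[1], pr[2]] <- drop[pr[2], pr[1]] <- TRUE
    }
  }
  kept & !drop
}

#' ARACNE network with bootstrap edge confidence
#'
#' Computes the MI matrix, applies DPI pruning, then resamples subjects with
#' replacement `B` times and records, for every node pair, the fraction of
#' replicates in which the edge survives pruning — the edge's bootstrap
#' confidence.
#'
#' @param data tibble of features.
#' @param bins discretization bins.
#' @param epsilon DPI tolerance.
#' @param B bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return an `mi_network` list: `mi` matrix, `kept` adjacency from the full
#'   data, `confidence` matrix of bootstrap frequencies, `edges` tibble
#'   (`node1`, `node2`, `mi`, `kept`, `confidence`), `B`.
#' @export
aracne_bootstrap <- function(data, bins = 4, epsilon = 0, B = 100, seed = 1) {
  stopifnot(B >= 1)
  mi <- mutual_information_matrix(data, bins)
  kept <- dpi_prune(mi, epsilon)
  p <- nrow(mi)
  conf <- matrix(0, p, p, dimnames = dimnames(mi))
  seeds <- spawn_seeds(seed, B, "aracne")
  for (b in seq_len(B)) {
    idx <- with_seed(seeds[b], sample.int(nrow(data), replace = TRUE))
    mib <- suppressWarnings(mutual_information_matrix(data[idx, ], bins))
    conf <- conf + dpi_prune(mib, epsilon)
  }
  conf <- conf / B
  ut <- which(upper.tri(mi), arr.ind = TRUE)
  edges <- tibble(
    node1 = rownames(mi)[ut[, 1]],
    node2 = colnames(mi)[ut[, 2]],
    mi = mi[ut],
    kept = kept[ut],
    confidence = conf[ut]
  ) |> dplyr::arrange(dplyr::desc(.data$confidence), dplyr::desc(.data$mi))
  out <- list(mi = mi, kept = kept, confidence = conf, edges = edges, B = B)
  class(out) <- "mi_network"
  out
}

#' Export an MI network
#'
#' Writes the kept-edge graph as GraphML and the full edge table as TSV.
#'
#' @param net an `mi_network`.
#' @param graphml,tsv output paths (`NULL` skips either).
#' @return the edge tibble, invisibly.
#' @export
write_mi_network <- function(net, graphml = NULL, tsv = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(net$edges, tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(graphml)) {
    kept_edges <- dplyr::filter(net$edges, .data$kept)
    g <- igraph::graph_from_data_frame(kept_edges, directed = FALSE,
                                       vertices = rownames(net$mi))
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(net$edges)
}
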