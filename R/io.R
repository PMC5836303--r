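#' Read a binary expression matrix from TSV/CSV
#'
#' First column: gene identifier; remaining columns: 0/1 sample values.
#' Parsing is strict: any cell that is not exactly 0 or 1 is an error,
#' as are duplicate or missing gene identifiers.
#'
#' @param path file path.
#' @param sep field separator (default tab; use "," for CSV).
#' @param header does the file carry a header row (default TRUE)?
#' @return A \linkS4class{BinaryExpressionMatrix}.
#' @export
readBinaryMatrix <- function(path, sep = "\t", header = TRUE) {
  df <- utils::read.table(path, sep = sep, header = header,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a gene id column plus sample columns")
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!all(vals %in% c("0", "1")))
    stop("invalid cell value(s): every sample entry must be 0 or 1")
  m <- matrix(as.integer(vals), nrow = nrow(vals),
              dimnames = list(ids, colnames(vals)))
  BinaryExpressionMatrix(m)
}

#' Write a binary expression matrix as TSV/CSV
#'
#' @param m a \linkS4class{BinaryExpressionMatrix}.
#' @param path file path.
#' @param sep field separator (default tab).
#' @export
writeBinaryMatrix <- function(m, path, sep = "\t") {
  stopifnot(is(m, "BinaryExpressionMatrix"))
  df <- data.frame(gene = rownames(m@values), m@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
}

#' Write a logic network as plain-text tables
#'
#' Writes three TSV files into \code{dir}: \code{nodes.tsv} (the full
#' node set, isolated nodes included), \code{edges.tsv} (source, target,
#' logic, weight) and \code{triplets.tsv} (inputA, inputB, target,
#' logic, weight, splitA, splitB). Weights are written with full
#' precision so a write/read round trip is exact.
#'
#' @param net a \linkS4class{LogicNetwork}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
writeLogicNetwork <- function(net, dir) {
  stopifnot(is(net, "LogicNetwork"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("nodes.tsv", "edges.tsv", "triplets.tsv"))
  th <- net@thresholds
  nodes <- data.frame(gene = net@geneIds,
                      t1 = rep(th[1], length(net@geneIds)),
                      t2 = rep(th[2], length(net@geneIds)))
  wt <- function(df, p) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], format, digits = 17)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(nodes, paths[1])
  wt(net@firstOrder, paths[2])
  wt(net@secondOrder, paths[3])
  invisible(paths)
}

#' Read a logic network written by [writeLogicNetwork()]
#'
#' @param dir directory holding \code{nodes.tsv}, \code{edges.tsv},
#'   \code{triplets.tsv}.
#' @return A \linkS4class{LogicNetwork}.
#' @export
readLogicNetwork <- function(dir) {
  rd <- function(p) utils::read.table(p, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE,
                                      colClasses = NA)
  nodes <- rd(file.path(dir, "nodes.tsv"))
  edges <- rd(file.path(dir, "edges.tsv"))
  triplets <- rd(file.path(dir, "triplets.tsv"))
  th <- if (nrow(nodes)) c(nodes$t1[1], nodes$t2[1])
        else c(NA_real_, NA_real_)
  LogicNetwork(as.character(nodes$gene), edges, triplets,
               thresholds = as.numeric(th))
}

#' Export a logic network as an igraph object
#'
#' Expands the network into a directed igraph graph: first-order edges
#' become single arcs; each second-order triplet becomes two input ->
#' target arcs annotated with the logic type, weight and that input's
#' contribution split (attribute \code{split}). Arcs carry an
#' \code{order} attribute (1 or 2). Useful for GraphML export and
#' visualization via the igraph toolchain.
#'
#' @param net a \linkS4class{LogicNetwork}.
#' @return An \pkg{igraph} graph with all nodes (isolated included).
#' @export
asIgraph <- function(net) {
  stopifnot(is(net, "LogicNetwork"))
  e <- net@firstOrder
  tr <- net@secondOrder
  arcs <- data.frame(from = character(), to = character(),
                     logic = character(), weight = numeric(),
                     split = numeric(), order = integer(),
                     stringsAsFactors = FALSE)
  if (nrow(e))
    arcs <- rbind(arcs, data.frame(from = e$source, to = e$target,
                                   logic = e$logic, weight = e$weight,
                                   split = 1, order = 1L))
  if (nrow(tr)) {
    arcs <- rbind(arcs,
                  data.frame(from = tr$inputA, to = tr$target,
                             logic = tr$logic, weight = tr$weight,
                             split = tr$splitA, order = 2L),
                  data.frame(from = tr$inputB, to = tr$target,
                             logic = tr$logic, weight = tr$weight,
                             split = tr$splitB, order = 2L))
  }
  igraph::graph_from_data_frame(arcs, directed = TRUE,
                                vertices = data.frame(name = net@geneIds))
}

#' Write cascade outcomes as JSON lines and/or a TSV summary
#'
#' @param sweep list of \linkS4class{CascadeOutcome} (e.g. from
#'   [sweepAllTriggers()]).
#' @param jsonl optional path: one JSON object per trigger with fields
#'   \code{trigger}, \code{s}, \code{d}, \code{rounds}.
#' @param tsv optional path: summary table (trigger, s, d, nRounds).
#' @return Invisibly, the summary data.frame.
#' @export
writeCascadeOutcomes <- function(sweep, jsonl = NULL, tsv = NULL) {
  tab <- data.frame(
    trigger = vapply(sweep, function(x) x@trigger, character(1)),
    s = vapply(sweep, function(x) x@s, integer(1)),
    d = vapply(sweep, function(x) x@d, numeric(1)),
    nRounds = vapply(sweep, function(x) length(x@rounds) - 1L,
                     integer(1)),
    stringsAsFactors = FALSE)
  if (!is.null(jsonl)) {
    lines <- vapply(sweep, function(x)
      jsonlite::toJSON(list(trigger = x@trigger, s = x@s, d = x@d,
                            rounds = x@rounds),
                       auto_unbox = TRUE, digits = NA),
      character(1))
    writeLines(lines, jsonl)
  }
  if (!is.null(tsv))
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(tab)
}
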