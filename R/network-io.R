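# Haplotype-network serialisation: GraphML (via igraph), a PopART-style
# NEXUS with a Traits block, and a plain TSV edge list. GraphML and the
# edge list round-trip losslessly through import_network().

#' Export a haplotype network
#'
#' @param network A `haplotype_network`.
#' @param path Output file path.
#' @param format `"graphml"`, `"nexus"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("graphml", "nexus", "edgelist")) {
  format <- tryCatch(match.arg(format), error = function(e)
    coihap_error("coihap_config_error",
                 paste0("unknown network format: ", format[1])))
  switch(format,
    graphml = {
      g <- as_igraph(network)
      igraph::graph_attr(g, "epsilon") <- network$epsilon
      if (!is.null(network$traits)) {
        tw <- trait_wide(network)
        for (grp in colnames(tw))
          g <- igraph::set_vertex_attr(
            g, paste0("trait_", grp),
            value = tw[match(igraph::V(g)$name, rownames(tw)), grp])
      }
      igraph::write_graph(g, path, format = "graphml")
    },
    nexus = write_nexus_network(network, path),
    edgelist = {
      write.table(network$edges, path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
  invisible(path)
}

trait_wide <- function(network) {
  tr <- network$traits
  groups <- sort(unique(tr$group))
  ids <- network$nodes$id[network$nodes$kind == "observed"]
  m <- matrix(0L, length(ids), length(groups),
              dimnames = list(ids, groups))
  for (r in seq_len(nrow(tr)))
    if (tr$haplotype_id[r] %in% ids)
      m[tr$haplotype_id[r], tr$group[r]] <-
        m[tr$haplotype_id[r], tr$group[r]] + as.integer(tr$count[r])
  m
}

write_nexus_network <- function(network, path) {
  nodes <- network$nodes
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("#NEXUS")
  w("[ haplotype network written by coihap ]")
  obs <- nodes[nodes$kind == "observed", , drop = FALSE]
  nchar_seq <- nchar(nodes$sequence[1])
  w("BEGIN TAXA;")
  w("DIMENSIONS NTAX=%d;", nrow(obs))
  w("TAXLABELS %s;", paste(obs$id, collapse = " "))
  w("END;")
  if (nchar_seq > 0) {
    w("BEGIN CHARACTERS;")
    w("DIMENSIONS NCHAR=%d;", nchar_seq)
    w("FORMAT DATATYPE=DNA MISSING=? GAP=-;")
    w("MATRIX")
    for (i in seq_len(nrow(obs))) w("%s %s", obs$id[i], obs$sequence[i])
    w(";")
    w("END;")
  }
  if (!is.null(network$traits)) {
    tw <- trait_wide(network)
    w("BEGIN TRAITS;")
    w("Dimensions NTRAITS=%d;", ncol(tw))
    w("Format labels=yes missing=? separator=Comma;")
    w("TraitLabels %s;", paste(colnames(tw), collapse = " "))
    w("Matrix")
    for (i in seq_len(nrow(tw)))
      w("%s %s", rownames(tw)[i], paste(tw[i, ], collapse = ","))
    w(";")
    w("END;")
  }
  # private block keeping the full node/edge structure (lossless round trip)
  w("BEGIN NETWORK;")
  w("[ node <id> <kind> <size> <sequence> ]")
  for (i in seq_len(nrow(nodes)))
    w("node %s %s %d %s", nodes$id[i], nodes$kind[i], nodes$size[i],
      if (nzchar(nodes$sequence[i])) nodes$sequence[i] else ".")
  w("[ edge <from> <to> <weight> ]")
  for (i in seq_len(nrow(network$edges)))
    w("edge %s %s %d", network$edges$from[i], network$edges$to[i],
      network$edges$weight[i])
  w("epsilon %d", network$epsilon)
  w("END;")
  invisible(path)
}

#' Import a haplotype network
#'
#' Reads networks written by [export_network()]. GraphML and NEXUS imports
#' recover nodes, edges, weights, sizes and traits; the edge-list format
#' recovers edges only.
#'
#' @param path File path.
#' @param format `"graphml"`, `"nexus"` or `"edgelist"`.
#' @return A `haplotype_network` (for `"edgelist"`, a data.frame of edges).
#' @export
import_network <- function(path, format = c("graphml", "nexus", "edgelist")) {
  format <- tryCatch(match.arg(format), error = function(e)
    coihap_error("coihap_config_error",
                 paste0("unknown network format: ", format[1])))
  if (format == "edgelist")
    return(read.delim(path, stringsAsFactors = FALSE))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(id = igraph::V(g)$name,
                        sequence = igraph::V(g)$sequence,
                        kind = igraph::V(g)$kind,
                        size = as.integer(igraph::V(g)$size),
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(from = el[, 1], to = el[, 2],
                        weight = as.integer(igraph::E(g)$weight),
                        stringsAsFactors = FALSE)
    traits <- NULL
    tr_attrs <- grep("^trait_", igraph::vertex_attr_names(g), value = TRUE)
    if (length(tr_attrs)) {
      traits <- do.call(rbind, lapply(tr_attrs, function(a) {
        cnt <- igraph::vertex_attr(g, a)
        keep <- !is.na(cnt) & cnt > 0
        data.frame(haplotype_id = igraph::V(g)$name[keep],
                   group = sub("^trait_", "", a),
                   count = as.integer(cnt[keep]))
      }))
    }
    eps <- igraph::graph_attr(g, "epsilon") %||% 0L
    return(new_haplonet(nodes, edges, as.integer(eps), integer(0), traits))
  }
  # nexus: parse the private NETWORK block plus the TRAITS block
  lines <- readLines(path, warn = FALSE)
  nodes <- NULL; edges <- NULL; eps <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0L) next
    if (tok[1] == "node")
      nodes <- rbind(nodes, data.frame(
        id = tok[2], kind = tok[3], size = as.integer(tok[4]),
        sequence = if (tok[5] == ".") "" else tok[5],
        stringsAsFactors = FALSE))
    if (tok[1] == "edge")
      edges <- rbind(edges, data.frame(from = tok[2], to = tok[3],
                                       weight = as.integer(tok[4]),
                                       stringsAsFactors = FALSE))
    if (tok[1] == "epsilon") eps <- as.integer(tok[2])
  }
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        weight = integer(0))
  traits <- NULL
  tb <- grep("BEGIN TRAITS;", lines)
  if (length(tb)) {
    lab_line <- grep("^TraitLabels", trimws(lines))
    groups <- strsplit(sub(";$", "", sub("^TraitLabels\\s+", "",
                                         trimws(lines[lab_line[1]]))),
                       "\\s+")[[1]]
    mstart <- which(trimws(lines) == "Matrix")[1]
    i <- mstart + 1
    rows <- list()
    while (trimws(lines[i]) != ";") {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      cnt <- as.integer(strsplit(tok[2], ",")[[1]])
      for (k in seq_along(groups)) if (cnt[k] > 0)
        rows[[length(rows) + 1]] <- data.frame(
          haplotype_id = tok[1], group = groups[k], count = cnt[k])
      i <- i + 1
    }
    if (length(rows)) traits <- do.call(rbind, rows)
  }
  nodes <- nodes[, c("id", "sequence", "kind", "size")]
  new_haplonet(nodes, edges, eps, integer(0), traits)
}
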