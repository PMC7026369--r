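#' Construct a sparse labeled semantic network
#'
#' Words are linked by directed, labeled, weighted associations. Labels are
#' `SUBSET` (exemplar to category), `SUPERSET` (category to exemplar) and
#' `COORD` (between two contrasting exemplars). The network is deliberately
#' sparse: nothing requires every exemplar to hold a direct association to
#' its category term, and SUBSET/SUPERSET edges are stored exactly as
#' written with no automatic reciprocal. COORD is treated as a symmetric
#' relation by default: adding COORD(a, b) also records COORD(b, a) at the
#' same strength.
#'
#' @param words Character vector of word identifiers (optional; words are
#'   also implied by edges).
#' @param edges Optional data frame with columns `source`, `target`,
#'   `label`, `strength` used to seed the network.
#' @param coord_symmetric Logical; mirror COORD edges automatically.
#' @return An object of class `semantic_network`.
#' @examples
#' net <- semantic_network()
#' net <- add_association(net, "chicken", "hawk", "COORD", 0.6)
#' net <- add_association(net, "hawk", "bird", "SUBSET", 0.8)
#' enumerate_paths(net, "chicken", "bird", max_len = 2)
#' @export
semantic_network <- function(words = character(), edges = NULL,
                             coord_symmetric = TRUE) {
  net <- structure(
    list(words = sort(unique(as.character(words))),
         edges = data.frame(source = character(), target = character(),
                            label = character(), strength = numeric(),
                            stringsAsFactors = FALSE),
         coord_symmetric = isTRUE(coord_symmetric)),
    class = "semantic_network")
  if (!is.null(edges)) {
    validate_edges(edges)
    if (net$coord_symmetric) edges <- symmetrize_coord(edges)
    edges <- dedup_edges(edges)
    net$edges <- edges
    net$words <- sort(unique(c(net$words, edges$source, edges$target)))
  }
  net
}

validate_edges <- function(edges) {
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "label", "strength") %in% names(edges)))
  if (any(edges$source == edges$target))
    stop("self-loop associations are not allowed")
  bad <- !edges$label %in% .relation_labels
  if (any(bad))
    stop("unknown association label(s): ",
         paste(unique(edges$label[bad]), collapse = ", "))
  if (any(!is.finite(edges$strength) | edges$strength <= 0 |
            edges$strength > 1))
    stop("association strength must lie in (0, 1]")
  invisible(TRUE)
}

symmetrize_coord <- function(edges) {
  co <- edges[edges$label == "COORD", , drop = FALSE]
  if (nrow(co)) {
    rev <- co
    rev$source <- co$target
    rev$target <- co$source
    edges <- rbind(edges, rev)
  }
  edges
}

# keep the last occurrence of each (source, target, label) triple
dedup_edges <- function(edges) {
  key <- paste(edges$source, edges$target, edges$label, sep = "\r")
  keep <- !duplicated(key, fromLast = TRUE)
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.semantic_network <- function(x, ...) {
  cat("Sparse labeled semantic network\n")
  cat("  words:        ", length(x$words), "\n")
  cat("  associations: ", nrow(x$edges),
      if (x$coord_symmetric) " (COORD symmetric)" else "", "\n", sep = "")
  tab <- table(factor(x$edges$label, levels = .relation_labels))
  cat("  by label:      ",
      paste(names(tab), as.integer(tab), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Add (or replace) a labeled association
#'
#' Re-adding an existing `(source, target, label)` triple replaces its
#' strength. With `coord_symmetric` networks a COORD edge is mirrored.
#'
#' @param net A [semantic_network()].
#' @param source,target Word identifiers; `source != target`.
#' @param label `"SUBSET"`, `"SUPERSET"` or `"COORD"`.
#' @param strength Association strength in (0, 1].
#' @return The updated network.
#' @export
add_association <- function(net, source, target, label, strength) {
  stopifnot(inherits(net, "semantic_network"))
  new <- data.frame(source = as.character(source),
                    target = as.character(target),
                    label = as.character(label),
                    strength = as.numeric(strength),
                    stringsAsFactors = FALSE)
  validate_edges(new)
  if (net$coord_symmetric) new <- symmetrize_coord(new)
  net$edges <- dedup_edges(rbind(net$edges, new))
  net$words <- sort(unique(c(net$words, new$source, new$target)))
  net
}

check_word <- function(net, w) {
  if (!w %in% net$words) stop("unknown word: ", w)
  invisible(TRUE)
}

#' Build the ordered adjacency index of a network
#'
#' Out-edges per word, ordered by descending strength with ties broken
#' lexicographically by target then label. The retrieval simulation
#' explores edges in exactly this order; building the index once and
#' passing it down avoids rebuilding per trial.
#'
#' @param net A [semantic_network()].
#' @return A named list of data frames, one per word with out-edges.
#' @export
network_adjacency <- function(net) {
  e <- net$edges
  if (!nrow(e)) return(list())
  ord <- order(e$source, -e$strength, e$target, e$label, method = "radix")
  e <- e[ord, , drop = FALSE]
  split(e, factor(e$source, levels = unique(e$source)))
}

#' Enumerate all bounded acyclic paths between two words
#'
#' The deterministic brute-force companion of the stochastic retrieval
#' process: every acyclic path from `origin` to `target` with at most
#' `max_len` edges, in lexicographic order of the visited word sequence.
#' Zero-length paths are excluded, so `origin == target` yields an empty
#' list.
#'
#' @param net A [semantic_network()].
#' @param origin,target Words in the network.
#' @param max_len Maximum number of edges (>= 1).
#' @return A list of paths; each path is a list with `words` (the visited
#'   word sequence, origin first) and `labels` (one label per edge).
#' @export
enumerate_paths <- function(net, origin, target, max_len = 2L) {
  stopifnot(inherits(net, "semantic_network"), max_len >= 1L)
  check_word(net, origin)
  check_word(net, target)
  adj <- network_adjacency(net)
  out <- list()
  recurse <- function(words, labels) {
    here <- words[length(words)]
    if (here == target) {
      out[[length(out) + 1L]] <<- list(words = words, labels = labels)
      return(invisible())
    }
    if (length(labels) >= max_len) return(invisible())
    e <- adj[[here]]
    if (is.null(e)) return(invisible())
    for (i in seq_len(nrow(e))) {
      nxt <- e$target[i]
      if (nxt %in% words) next
      recurse(c(words, nxt), c(labels, e$label[i]))
    }
  }
  if (origin != target) recurse(origin, character())
  if (length(out)) {
    key <- vapply(out, function(p)
      paste(c(p$words, p$labels), collapse = "\r"), character(1))
    out <- out[order(key, method = "radix")]
  }
  out
}

#' Read a network from an edge-list TSV
#'
#' Expected header: `source target label strength` (tab separated); `#`
#' lines are comments. Unknown labels, self loops and strengths outside
#' (0, 1] are rejected with the offending line number.
#'
#' @param path File path.
#' @param coord_symmetric Passed to [semantic_network()].
#' @return A [semantic_network()].
#' @export
read_network_tsv <- function(path, coord_symmetric = TRUE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty network file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("source", "target", "label", "strength")))
    stop("bad header on line ", lineno[1L],
         ": expected 'source\\ttarget\\tlabel\\tstrength'")
  body <- lines[-1L]
  lineno <- lineno[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L))
    stop("malformed line ", lineno[which(nf != 4L)[1L]],
         ": expected 4 tab-separated fields")
  edges <- data.frame(source = vapply(parts, `[[`, "", 1L),
                      target = vapply(parts, `[[`, "", 2L),
                      label = vapply(parts, `[[`, "", 3L),
                      strength = suppressWarnings(
                        as.numeric(vapply(parts, `[[`, "", 4L))),
                      stringsAsFactors = FALSE)
  probl <- which(edges$source == edges$target |
                   !edges$label %in% .relation_labels |
                   !is.finite(edges$strength) |
                   edges$strength <= 0 | edges$strength > 1)
  if (length(probl))
    stop("invalid association on line ", lineno[probl[1L]], ": '",
         body[probl[1L]], "'")
  semantic_network(edges = edges, coord_symmetric = coord_symmetric)
}

#' Write a network as an edge-list TSV
#'
#' Edges are written in a canonical sort order so output is byte-stable.
#'
#' @param net A [semantic_network()].
#' @param path Target file path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  e <- net$edges
  ord <- order(e$source, e$target, e$label, method = "radix")
  e <- e[ord, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("source\ttarget\tlabel\tstrength", con)
  if (nrow(e))
    writeLines(paste(e$source, e$target, e$label,
                     format(e$strength, trim = TRUE, scientific = FALSE),
                     sep = "\t"), con)
  invisible(path)
}
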